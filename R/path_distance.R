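#' Along-tree path distances from the soma to in-target axonal points
#'
#' The distance to a point is the sum of Euclidean inter-node gaps along the
#' unique tree path from the soma (root), computed by accumulating each
#' point's gap onto its parent's distance in topological order. One row is
#' produced per axonal point falling in a requested target.
#'
#' @param neuron a [neuron_reconstruction()].
#' @param targets named list mapping target label to a character vector of
#'   parcel ids, or `NULL` for one target per observed parcel.
#' @param midline,midline_axis hemisphere convention, as in
#'   [build_projection_matrix()].
#' @return Data frame: `neuron_id`, `point_id`, `parcel`, `target`,
#'   `hemisphere`, `path_distance_um`.
#' @export
path_distances <- function(neuron, targets = NULL,
                           midline = 5695, midline_axis = "z") {
  p <- neuron$points
  ids <- p$point_id
  parent_idx <- match(p$parent_id, ids)
  coords <- as.matrix(p[, c("x", "y", "z")])
  n <- nrow(p)
  dist <- rep.int(NA_real_, n)
  root <- which(is.na(parent_idx))
  dist[root] <- 0
  # process points in increasing depth: repeat passes until filled (trees
  # from tracing files are usually already parent-before-child ordered, so
  # this loop runs once or twice)
  todo <- which(is.na(dist))
  while (length(todo)) {
    ready <- todo[!is.na(dist[parent_idx[todo]])]
    if (!length(ready)) stop("disconnected points in tree")
    gap <- sqrt(rowSums((coords[ready, , drop = FALSE] -
                           coords[parent_idx[ready], , drop = FALSE])^2))
    dist[ready] <- dist[parent_idx[ready]] + gap
    todo <- todo[is.na(dist[todo])]
  }
  ax <- which(p$structure == "axon" & !is.na(p$parcel))
  if (!length(ax)) {
    return(data.frame(neuron_id = character(0), point_id = integer(0),
                      parcel = character(0), target = character(0),
                      hemisphere = character(0),
                      path_distance_um = numeric(0)))
  }
  parcel <- p$parcel[ax]
  if (is.null(targets)) {
    targets <- setNames(as.list(sort(unique(parcel))), sort(unique(parcel)))
  }
  target_of <- rep(NA_character_, length(ax))
  for (lab in names(targets)) {
    target_of[parcel %in% targets[[lab]]] <- lab
  }
  keep <- !is.na(target_of)
  soma_side <- sign(neuron$soma_xyz[[midline_axis]] - midline)
  if (soma_side == 0) soma_side <- 1
  side <- sign(coords[ax, c(x = 1L, y = 2L, z = 3L)[[midline_axis]]] - midline)
  side[side == 0] <- soma_side
  data.frame(neuron_id = neuron$neuron_id,
             point_id = ids[ax][keep],
             parcel = parcel[keep],
             target = target_of[keep],
             hemisphere = ifelse(side == soma_side, "ipsi", "contra")[keep],
             path_distance_um = dist[ax][keep],
             stringsAsFactors = FALSE)
}

#' Path-distance table for a cohort of classified neurons
#'
#' @param neurons list of [neuron_reconstruction()].
#' @param classes `class_tree` or data frame `neuron_id`, `class`.
#' @param targets,midline,midline_axis passed to [path_distances()].
#' @return Row-bound [path_distances()] rows with a `class` column.
#' @export
path_distance_table <- function(neurons, classes, targets = NULL,
                                midline = 5695, midline_axis = "z") {
  cls <- if (inherits(classes, "class_tree")) classes$classes else classes
  out <- do.call(rbind, lapply(neurons, path_distances, targets = targets,
                               midline = midline, midline_axis = midline_axis))
  out$class <- cls$class[match(out$neuron_id, cls$neuron_id)]
  out
}

# shared machinery: pairwise two-sample rank-sum tests over a grouping
# column, BH-adjusted together. The field's reports sometimes label this a
# signed-rank test, but the samples are unpaired with unequal n, so the
# two-sample Mann-Whitney rank-sum test is the applicable routine; the
# report notes this.
rank_test_pairs <- function(rows, group_col, alpha = 0.05) {
  groups <- split(rows$path_distance_um, rows[[group_col]])
  groups <- groups[vapply(groups, length, integer(1L)) > 0L]
  if (length(groups) < 2L) {
    return(data.frame(group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0), W = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  cmb <- combn(names(groups), 2L)
  res <- lapply(seq_len(ncol(cmb)), function(k) {
    g1 <- cmb[1L, k]; g2 <- cmb[2L, k]
    wt <- suppressWarnings(wilcox.test(groups[[g1]], groups[[g2]],
                                       exact = FALSE))
    data.frame(group1 = g1, group2 = g2,
               n1 = length(groups[[g1]]), n2 = length(groups[[g2]]),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res
}

per_group_medians <- function(rows, group_col) {
  agg <- split(rows, list(rows$neuron_id, rows[[group_col]]), drop = TRUE)
  med <- do.call(rbind, lapply(agg, function(d) {
    data.frame(neuron_id = d$neuron_id[1L], group = d[[group_col]][1L],
               median_um = median(d$path_distance_um), n_points = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(med) <- NULL
  med
}

#' Divergence: does one class reach its targets at different path distances?
#'
#' For every pair of targets (ipsilateral and contralateral analyzed
#' separately, since crossing the midline systematically lengthens paths),
#' a two-sample rank-sum test compares the pooled per-point path distances;
#' p-values are Benjamini-Hochberg adjusted across all pairs of the
#' analysis. Per-neuron medians per target are reported alongside.
#'
#' @param rows [path_distance_table()] rows for one class.
#' @param alpha significance level after FDR adjustment (default 0.05).
#' @return List of class `pathdist_report`: `tests` (per target pair and
#'   hemisphere), `medians` (per neuron and target), `note` on the rank-test
#'   naming, `kind = "divergence"`.
#' @export
divergence_test <- function(rows, alpha = 0.05) {
  tests <- do.call(rbind, lapply(split(rows, rows$hemisphere), function(d) {
    r <- rank_test_pairs(d, "target", alpha)
    if (nrow(r)) r$hemisphere <- d$hemisphere[1L]
    r
  }))
  rownames(tests) <- NULL
  structure(list(kind = "divergence", tests = tests,
                 medians = per_group_medians(rows, "target"),
                 alpha = alpha,
                 note = paste("two-sample Mann-Whitney rank-sum on pooled",
                              "per-point distances; BH-adjusted")),
            class = "pathdist_report")
}

#' Convergence: do different classes reach one target at different distances?
#'
#' As [divergence_test()], grouping by class instead of target, for a single
#' target region.
#'
#' @param rows [path_distance_table()] rows for one target (one hemisphere).
#' @param alpha significance level after FDR adjustment.
#' @return A `pathdist_report` with `kind = "convergence"`; empty tests when
#'   only one class reaches the target.
#' @export
convergence_test <- function(rows, alpha = 0.05) {
  structure(list(kind = "convergence",
                 tests = rank_test_pairs(rows, "class", alpha),
                 medians = per_group_medians(rows, "class"),
                 alpha = alpha,
                 note = paste("two-sample Mann-Whitney rank-sum on pooled",
                              "per-point distances; BH-adjusted")),
            class = "pathdist_report")
}

#' @export
print.pathdist_report <- function(x, ...) {
  cat("<pathdist_report> ", x$kind, ": ", nrow(x$tests), " pairwise tests, ",
      sum(x$tests$significant), " significant at FDR ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' Box-plot summary of path distances
#'
#' Median, quartiles and whiskers at `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR` per
#' group, the convention used for path-distance box plots.
#'
#' @param rows path-distance rows.
#' @param group_col grouping column (`"target"` or `"class"`).
#' @return Data frame with one row per group.
#' @export
pathdist_boxstats <- function(rows, group_col = "target") {
  do.call(rbind, lapply(split(rows, rows[[group_col]]), function(d) {
    v <- d$path_distance_um
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(group = d[[group_col]][1L], n = length(v),
               median = q[2L], q1 = q[1L], q3 = q[3L],
               whisker_low = q[1L] - 1.5 * iqr,
               whisker_high = q[3L] + 1.5 * iqr,
               stringsAsFactors = FALSE)
  }))
}
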