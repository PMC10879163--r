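#' Decompose an axonal arbor into branches
#'
#' A branch is the path between consecutive topological events of the axonal
#' tree: arbor root, bifurcation, or terminal tip. Interior branch points have
#' exactly one child; the event nodes at either end are shared between
#' adjacent branches. Branch length is the sum of consecutive 3D Euclidean
#' gaps, and mean tracing-point spacing is `length / (n_points - 1)`.
#' Dendrites are excluded.
#'
#' @param neuron a [neuron_reconstruction()].
#' @return Data frame with one row per branch: `branch_id`, `neuron_id`,
#'   `n_points`, `length_um`, `mean_spacing_um`, `terminal` (ends at a tip),
#'   and `strahler` (centripetal order, see [strahler_orders()]). The point-id
#'   paths are attached as the `"paths"` attribute.
#' @export
segment_branches <- function(neuron) {
  p <- neuron$points
  ids <- p$point_id
  is_axon <- p$structure == "axon"
  coords <- as.matrix(p[, c("x", "y", "z")])
  parent_idx <- match(p$parent_id, ids)

  # children (within the axon) of every point, including non-axon attachment
  # points such as the soma
  kids <- vector("list", nrow(p))
  for (i in which(is_axon & !is.na(parent_idx))) {
    j <- parent_idx[i]
    kids[[j]] <- c(kids[[j]], i)
  }
  n_kids <- lengths(kids)
  # arbor roots: axon points whose parent is not an axon point
  arbor_roots <- which(is_axon & (is.na(parent_idx) | !is_axon[parent_idx]))

  paths <- list()
  ends_at <- integer(0)   # index of distal event node per branch
  starts_at <- integer(0) # index of proximal event node per branch
  walk_branch <- function(e, child) {
    # branch from event node e through child to the next event node
    path <- c(e, child)
    node <- child
    while (n_kids[node] == 1L) {
      node <- kids[[node]][1L]
      path <- c(path, node)
    }
    paths[[length(paths) + 1L]] <<- path
    starts_at <<- c(starts_at, e)
    ends_at <<- c(ends_at, node)
    node
  }
  for (r in arbor_roots) {
    # the attachment point (soma or other parent) is the proximal event
    # node of the arbor's root branch, so its gap counts toward the cable
    start <- if (is.na(parent_idx[r])) r else parent_idx[r]
    stack <- if (identical(start, r)) r else c()
    if (!identical(start, r)) {
      node <- walk_branch(start, r)
      if (n_kids[node] >= 2L) stack <- node
    }
    while (length(stack)) {
      e <- stack[[1L]]; stack <- stack[-1L]
      for (child in kids[[e]]) {
        node <- walk_branch(e, child)
        if (n_kids[node] >= 2L) stack <- c(stack, node)
      }
    }
  }
  if (!length(paths)) {
    out <- data.frame(branch_id = integer(0), neuron_id = character(0),
                      n_points = integer(0), length_um = numeric(0),
                      mean_spacing_um = numeric(0), terminal = logical(0),
                      strahler = integer(0))
    attr(out, "paths") <- list()
    return(out)
  }
  seg_len <- function(path) {
    d <- diff(coords[path, , drop = FALSE])
    sum(sqrt(rowSums(d * d)))
  }
  len <- vapply(paths, seg_len, numeric(1L))
  npt <- lengths(paths)
  terminal <- n_kids[ends_at] == 0L

  # centripetal (Strahler) order on the branch tree
  order_of <- rep.int(NA_integer_, length(paths))
  remaining <- seq_along(paths)
  while (length(remaining)) {
    progressed <- FALSE
    for (b in remaining) {
      children <- which(starts_at == ends_at[b])
      if (!length(children)) {
        order_of[b] <- 1L
      } else if (!anyNA(order_of[children])) {
        mx <- max(order_of[children])
        order_of[b] <- mx + as.integer(sum(order_of[children] == mx) >= 2L)
      } else next
      progressed <- TRUE
    }
    remaining <- remaining[is.na(order_of[remaining])]
    if (!progressed) stop("branch ordering failed to converge")
  }

  out <- data.frame(
    branch_id = seq_along(paths),
    neuron_id = neuron$neuron_id,
    n_points = as.integer(npt),
    length_um = len,
    mean_spacing_um = len / (npt - 1L),
    terminal = terminal,
    strahler = order_of,
    stringsAsFactors = FALSE
  )
  attr(out, "paths") <- lapply(paths, function(ix) ids[ix])
  out
}

#' Strahler (centripetal) branch orders
#'
#' Terminal branches have order 1; a parent branch takes the maximum of its
#' children's orders, incremented by one when at least two children attain
#' that maximum. Order 1-3 branches are the terminal, pre-terminal and
#' pre-pre-terminal part of the arbor where cortical axons carry most of
#' their presynaptic boutons; orders 4-6 are mostly fibers of passage.
#'
#' @param neuron a [neuron_reconstruction()].
#' @return Named integer vector, one order per branch id.
#' @export
strahler_orders <- function(neuron) {
  b <- segment_branches(neuron)
  setNames(b$strahler, b$branch_id)
}

#' Branch table for a cohort
#'
#' @param neurons list of [neuron_reconstruction()].
#' @return Row-bound [segment_branches()] tables.
#' @export
axonal_branch_table <- function(neurons) {
  do.call(rbind, lapply(neurons, function(n) {
    b <- segment_branches(n)
    attr(b, "paths") <- NULL
    b
  }))
}

#' Statistics justifying point counts as the axonal-extent metric
#'
#' Digitized tracings sample synapse-bearing neuropil more densely than
#' fibers of passage, so the number of tracing points tracks connectivity
#' better than raw cable length. This report quantifies that claim for a
#' cohort: (a) the Pearson correlation between branch point count and branch
#' length; (b) mean +/- SD of branch length and of mean point spacing for
#' Strahler orders 1-3 (synapse-rich) versus 4-6 (fibers of passage), using
#' per-neuron band means as the statistical unit; (c) one-tailed Welch
#' t-tests that the low band has shorter branches and tighter spacing.
#'
#' @param neurons list of [neuron_reconstruction()].
#' @param low,high integer vectors of Strahler orders defining the two bands.
#' @return List of class `metric_report`: `pearson` (estimate, n, p),
#'   `groups` (per-band mean/sd/n of length and spacing), and `tests`
#'   (one-tailed Welch t statistics with df and p). Bands with fewer than two
#'   neurons are flagged `insufficient`.
#' @export
metric_justification_report <- function(neurons, low = 1:3, high = 4:6) {
  branches <- axonal_branch_table(neurons)
  if (is.null(branches) || nrow(branches) < 2L) {
    stop("need at least two axonal branches")
  }
  if (sd(branches$n_points) == 0 || sd(branches$length_um) == 0) {
    pearson <- list(r = NA_real_, n = nrow(branches), p = NA_real_,
                    note = "undefined: zero variance")
  } else {
    ct <- stats::cor.test(branches$n_points, branches$length_um)
    pearson <- list(r = unname(ct$estimate), n = nrow(branches),
                    p = ct$p.value)
  }
  band_of <- function(s) ifelse(s %in% low, "low",
                                ifelse(s %in% high, "high", NA))
  branches$band <- band_of(branches$strahler)
  bb <- branches[!is.na(branches$band) & branches$n_points >= 2L, ]
  per_neuron <- do.call(rbind, lapply(split(bb, list(bb$neuron_id, bb$band),
                                            drop = TRUE), function(d) {
    data.frame(neuron_id = d$neuron_id[1L], band = d$band[1L],
               length_um = mean(d$length_um),
               spacing_um = mean(d$mean_spacing_um),
               stringsAsFactors = FALSE)
  }))
  grp <- function(var) {
    lapply(split(per_neuron[[var]], per_neuron$band), function(v) {
      list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
           n = length(v), insufficient = length(v) < 2L)
    })
  }
  groups <- list(length_um = grp("length_um"), spacing_um = grp("spacing_um"))
  one_tail <- function(var) {
    lo <- per_neuron[[var]][per_neuron$band == "low"]
    hi <- per_neuron[[var]][per_neuron$band == "high"]
    if (length(lo) < 2L || length(hi) < 2L || (sd(lo) == 0 && sd(hi) == 0)) {
      return(list(insufficient = TRUE))
    }
    tt <- t.test(lo, hi, alternative = "less")
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, insufficient = FALSE)
  }
  out <- list(pearson = pearson, groups = groups,
              tests = list(length_um = one_tail("length_um"),
                           spacing_um = one_tail("spacing_um")),
              bands = list(low = low, high = high),
              unit = "per-neuron band means (Welch)")
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  Pearson r(n_points, length) = %.3f (N = %d)\n",
              x$pearson$r, x$pearson$n))
  for (v in c("length_um", "spacing_um")) {
    g <- x$groups[[v]]
    cat(sprintf("  %s: Strahler low %.2f +/- %.2f (n=%d) vs high %.2f +/- %.2f (n=%d)\n",
                v, g$low$mean, g$low$sd, g$low$n,
                g$high$mean, g$high$sd, g$high$n))
    tst <- x$tests[[v]]
    if (!isTRUE(tst$insufficient)) {
      cat(sprintf("    one-tailed Welch t = %.2f, df = %.1f, p = %.3g\n",
                  tst$t, tst$df, tst$p))
    }
  }
  invisible(x)
}
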