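#' Average-linkage (UPGMA) agglomeration with deterministic tie-breaking
#'
#' Standard unweighted average linkage on a square symmetric distance
#' matrix. Ties in the minimum inter-cluster distance (compared with 1e-12
#' tolerance) are broken lowest-index-first, so the tree is fully
#' deterministic.
#'
#' @param D square symmetric numeric matrix of distances (degrees), no NAs.
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
average_linkage_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2L, ncol(D) == n)
  if (anyNA(D)) stop("NaN/NA distances")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(D) %||% as.character(seq_len(n))

  active_id <- -seq_len(n)        # negative = singleton, positive = merge row
  size <- rep.int(1L, n)
  W <- D
  diag(W) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- min(W)
    tol <- 1e-12 * max(1, abs(m))
    cand <- which(W <= m + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    height[step] <- W[i, j]
    pair <- sort(c(active_id[i], active_id[j]))
    merge[step, ] <- pair
    # Lance-Williams unweighted-average update into slot i; drop slot j
    ni <- size[i]; nj <- size[j]
    newd <- (ni * W[i, ] + nj * W[j, ]) / (ni + nj)
    W[i, ] <- newd
    W[, i] <- newd
    W[i, i] <- Inf
    keep <- setdiff(seq_along(active_id), j)
    W <- W[keep, keep, drop = FALSE]
    size[i] <- ni + nj
    active_id[i] <- step
    active_id <- active_id[keep]
    size <- size[keep]
  }
  order <- integer(0)
  walk <- function(k) {
    if (k < 0) order <<- c(order, -k)
    else { walk(merge[k, 1L]); walk(merge[k, 2L]) }
  }
  walk(n - 1L)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "arccosine",
                 call = match.call()),
            class = "hclust")
}

# full square matrix of pairwise arccosine angles for the usable rows
angle_matrix <- function(A) {
  R <- A / sqrt(rowSums(A * A))
  G <- pmax(pmin(tcrossprod(R), 1), -1)
  ang <- acos(G) * 180 / pi
  diag(ang) <- 0
  dimnames(ang) <- list(rownames(A), rownames(A))
  ang
}

#' Discover projection classes by Levene-gated recursive clustering
#'
#' Implements the class-discovery procedure: the cohort is tested against a
#' fresh swap-randomized null with the one-tailed Levene variance test on
#' pairwise arccosine distances; if the experimental variance is
#' significantly larger, the top bipartition of the average-linkage
#' dendrogram splits the cohort in two, and each subtree is re-tested on its
#' own submatrix (all columns, its rows only) against its own fresh
#' randomization. Recursion stops where the test fails or a subtree is
#' smaller than `min_subtree`; the terminal nodes are the classes, labeled
#' `A`, `B`, ... in dendrogram left-to-right order with sizes appended
#' (e.g. `A38`).
#'
#' @param M a `projection_matrix` or counts matrix.
#' @param alpha significance level for each split decision (default 0.05).
#' @param min_subtree smallest subtree that is still tested (default 3; a
#'   2-neuron subtree yields a single pairwise distance, so a variance test
#'   is impossible).
#' @param swap a [swap_config()] used for every per-node null (its `seed`,
#'   if any, seeds the whole run once).
#' @param seed optional integer seed for the whole run.
#' @return Object of class `class_tree`: `classes` (data frame `neuron_id`,
#'   `class`), `class_sizes` (named vector), `dendrogram` (`hclust` over all
#'   usable neurons), `node_tests` (per-node [levene_one_tailed()] results
#'   keyed by dendrogram path, e.g. `"root.L.R"`), `unclassified` (zero-count
#'   neurons), `config`.
#' @export
discover_classes <- function(M, alpha = 0.05, min_subtree = 3L,
                             swap = swap_config(), seed = NULL) {
  A <- counts_of(M)
  if (is.null(rownames(A))) rownames(A) <- as.character(seq_len(nrow(A)))
  usable <- rowSums(A) > 0
  unclassified <- rownames(A)[!usable]
  A <- A[usable, , drop = FALSE]
  if (nrow(A) < min_subtree) stop("need at least min_subtree usable neurons")
  if (!is.null(seed)) set.seed(seed) else if (!is.null(swap$seed)) {
    set.seed(swap$seed)
  }
  swap$seed <- NULL

  node_tests <- list()
  terminals <- list()

  recurse <- function(idx, path) {
    if (length(idx) < min_subtree) {
      terminals[[length(terminals) + 1L]] <<- list(members = rownames(A)[idx],
                                                   path = path,
                                                   reason = "below min_subtree")
      return(invisible(NULL))
    }
    sub <- A[idx, , drop = FALSE]
    exp_d <- pairwise_distances(sub, label = "experimental")
    rnd <- randomize_matrix(sub, swap)
    rnd_d <- pairwise_distances(rnd, label = "randomized")
    lev <- levene_one_tailed(exp_d, rnd_d, alpha = alpha)
    node_tests[[path]] <<- lev
    if (lev$decision == "stop") {
      terminals[[length(terminals) + 1L]] <<- list(members = rownames(A)[idx],
                                                   path = path,
                                                   reason = "levene stop")
      return(invisible(NULL))
    }
    hc <- average_linkage_tree(angle_matrix(sub))
    grp <- stats::cutree(hc, k = 2L)
    left_label <- hc$labels[hc$order[1L]]
    left <- idx[grp == grp[[left_label]]]
    right <- idx[grp != grp[[left_label]]]
    recurse(left, paste0(path, ".L"))
    recurse(right, paste0(path, ".R"))
  }
  recurse(seq_len(nrow(A)), "root")

  dendrogram <- average_linkage_tree(angle_matrix(A))
  letters_for <- function(i) {
    if (i <= 26L) LETTERS[i] else paste0(LETTERS[(i - 1L) %/% 26L],
                                         LETTERS[(i - 1L) %% 26L + 1L])
  }
  classes <- do.call(rbind, lapply(seq_along(terminals), function(i) {
    t <- terminals[[i]]
    data.frame(neuron_id = t$members,
               class = paste0(letters_for(i), length(t$members)),
               node = t$path, stringsAsFactors = FALSE)
  }))
  sizes <- vapply(terminals, function(t) length(t$members), integer(1L))
  names(sizes) <- vapply(seq_along(terminals), function(i)
    paste0(letters_for(i), sizes[i]), character(1L))
  structure(list(classes = classes[, c("neuron_id", "class")],
                 class_sizes = sizes,
                 terminal_nodes = classes$node,
                 dendrogram = dendrogram,
                 node_tests = node_tests,
                 unclassified = unclassified,
                 config = list(alpha = alpha, min_subtree = min_subtree,
                               swap = swap,
                               null_scope = "fresh randomization per subtree")),
            class = "class_tree")
}

#' @export
print.class_tree <- function(x, ...) {
  cat("<class_tree> ", length(x$class_sizes), " classes over ",
      nrow(x$classes), " neurons: ",
      paste(names(x$class_sizes), collapse = ", "), "\n", sep = "")
  if (length(x$unclassified)) {
    cat("  unclassified (zero counts): ",
        paste(x$unclassified, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a class-discovery dendrogram as Newick
#'
#' @param tree a `class_tree` or `hclust`.
#' @param file optional output path.
#' @return Newick string, invisibly when written to file.
#' @export
write_class_newick <- function(tree, file = NULL) {
  hc <- if (inherits(tree, "class_tree")) tree$dendrogram else tree
  phy <- ape::as.phylo(hc)
  if (is.null(file)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = file); invisible(file) }
}
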