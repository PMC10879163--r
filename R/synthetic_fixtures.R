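#' Generate a synthetic cohort of projection count vectors
#'
#' Each class is defined by a region-probability profile over the matrix
#' columns. Neuron i of class c draws its total axonal point count from a
#' log-normal model and distributes it multinomially according to the
#' class profile -- the minimal generative model consistent with counting
#' axonal points per region. Pure function of (spec, seed).
#'
#' @param classes named list; each element is a list with `n` (neurons) and
#'   `profile` (non-negative vector over columns, normalized internally;
#'   names become column names).
#' @param total_points `c(meanlog, sdlog)` of the per-neuron total count
#'   model (default `log(2000), 0.7`: a few thousand tracing points per
#'   axon, the scale of whole-brain reconstructions).
#' @param seed integer seed.
#' @return List: `matrix` (a `projection_matrix`), `labels` (named character
#'   vector of true class per neuron).
#' @export
generate_cohort <- function(classes, total_points = c(log(2000), 0.7),
                            seed = 1L) {
  set.seed(seed)
  profs <- lapply(classes, function(cl) cl$profile / sum(cl$profile))
  cols <- names(profs[[1L]])
  if (is.null(cols)) cols <- paste0("P", seq_along(profs[[1L]]))
  stopifnot(all(vapply(profs, length, integer(1L)) == length(cols)))
  if (is.null(names(classes))) names(classes) <- paste0("class", seq_along(classes))
  rows <- list()
  labels <- character(0)
  for (cl in names(classes)) {
    n <- classes[[cl]]$n
    totals <- pmax(1L, round(rlnorm(n, total_points[1L], total_points[2L])))
    counts <- vapply(totals, function(tt) {
      as.integer(rmultinom(1L, tt, profs[[cl]]))
    }, integer(length(cols)))
    rows[[cl]] <- t(counts)
    labels <- c(labels, rep(cl, n))
  }
  counts <- do.call(rbind, rows)
  ids <- sprintf("syn%03d", seq_len(nrow(counts)))
  dimnames(counts) <- list(ids, cols)
  names(labels) <- ids
  columns <- data.frame(parcel = cols, hemisphere = "both",
                        stringsAsFactors = FALSE)
  list(matrix = new_projection_matrix(counts, columns,
                                      zero_rows = ids[rowSums(counts) == 0]),
       labels = labels)
}

#' Presubiculum-like cohort specification
#'
#' Five classes with the population sizes observed for presubicular
#' projection neurons (38, 27, 3, 19, 6) and near-disjoint region profiles
#' over twelve target groups, emulating the signature structure of that
#' source region (a cortical block targeting entorhinal/hippocampal/
#' retrosplenial groups and a subcortical block targeting thalamic,
#' hypothalamic and midbrain groups).
#'
#' @param sizes class sizes (default `c(38, 27, 3, 19, 6)`).
#' @return `classes` list for [generate_cohort()].
#' @export
presubiculum_like_classes <- function(sizes = c(38L, 27L, 3L, 19L, 6L)) {
  regions <- c("LEC", "DG", "CA", "Sub", "gRSP", "dMEC", "ParaS",
               "aRSP", "Hyp", "MidB", "mATN_LGN", "dvATN_MGN")
  prof <- function(...) {
    p <- setNames(rep(0, length(regions)), regions)
    w <- c(...)
    p[names(w)] <- w
    p
  }
  list(
    A = list(n = sizes[1L],
             profile = prof(LEC = 0.82, gRSP = 0.06, DG = 0.03, CA = 0.03,
                            Sub = 0.06)),
    B = list(n = sizes[2L],
             profile = prof(dMEC = 0.925, ParaS = 0.05, Sub = 0.025)),
    C = list(n = sizes[3L],
             profile = prof(dMEC = 0.42, LEC = 0.40, Sub = 0.14,
                            ParaS = 0.04)),
    D = list(n = sizes[4L],
             profile = prof(Sub = 0.408, DG = 0.163, aRSP = 0.1, Hyp = 0.15,
                            MidB = 0.1, mATN_LGN = 0.079)),
    E = list(n = sizes[5L],
             profile = prof(dvATN_MGN = 0.95, mATN_LGN = 0.05))
  )
}

#' Generate a random rooted axonal tree
#'
#' Grows a binary arbor with a controllable tracing-point spacing contrast
#' between low-Strahler (terminal-side) and high-Strahler (passage) branches,
#' for exercising the branch-metric statistics. Topology: a random full
#' binary tree with `n_bifurcations` internal events; geometry: each branch
#' runs in a jittered direction with band-specific length and point spacing.
#'
#' @param n_bifurcations number of bifurcations (0 = unbranched chain).
#' @param branch_length `c(low, high)` mean branch length, micrometers, for
#'   Strahler bands 1-3 and 4-6 (defaults 150, 950).
#' @param spacing `c(low, high)` tracing-point spacing, micrometers
#'   (defaults 20, 40).
#' @param seed integer seed.
#' @param neuron_id identifier.
#' @param parcel parcel label assigned to all axonal points.
#' @return A [neuron_reconstruction()].
#' @export
generate_tree <- function(n_bifurcations = 5L,
                          branch_length = c(150, 950),
                          spacing = c(20, 40),
                          seed = 1L, neuron_id = NULL,
                          parcel = "SYN") {
  set.seed(seed)
  if (is.null(neuron_id)) neuron_id <- sprintf("tree%05d", seed)
  # topology on branch slots: start with one root branch, repeatedly split a
  # random leaf branch into two children
  children <- list(integer(0))
  for (i in seq_len(n_bifurcations)) {
    leaves <- which(lengths(children) == 0L)
    pick <- leaves[sample.int(length(leaves), 1L)]
    id1 <- length(children) + 1L
    id2 <- length(children) + 2L
    children[[pick]] <- c(id1, id2)
    children[[id1]] <- integer(0)
    children[[id2]] <- integer(0)
  }
  nb <- length(children)
  # Strahler order per branch (post-order)
  ord <- rep.int(NA_integer_, nb)
  assign_order <- function(b) {
    ch <- children[[b]]
    if (!length(ch)) { ord[b] <<- 1L; return(1L) }
    o <- vapply(ch, assign_order, integer(1L))
    mx <- max(o)
    ord[b] <<- mx + as.integer(sum(o == mx) >= 2L)
    ord[b]
  }
  assign_order(1L)
  band <- ifelse(ord <= 3L, 1L, 2L)

  points <- data.frame(point_id = 1L, structure = "soma",
                       x = 0, y = 0, z = 0, radius = 5,
                       parent_id = NA_integer_, parcel = NA_character_,
                       stringsAsFactors = FALSE)
  next_id <- 2L
  grow <- function(b, origin, parent_pt) {
    len <- max(branch_length[band[b]] * exp(rnorm(1L, 0, 0.2)),
               2 * spacing[band[b]])
    sp <- spacing[band[b]]
    n_gap <- max(1L, round(len / sp))
    dir <- rnorm(3L); dir <- dir / sqrt(sum(dir^2))
    step <- len / n_gap
    prev <- parent_pt
    pos <- origin
    for (g in seq_len(n_gap)) {
      pos <- pos + dir * step
      points[nrow(points) + 1L, ] <<- list(next_id, "axon", pos[1L], pos[2L],
                                           pos[3L], 0.5, prev, parcel)
      prev <- next_id
      next_id <<- next_id + 1L
    }
    for (ch in children[[b]]) grow(ch, pos, prev)
  }
  grow(1L, c(0, 0, 0), 1L)
  neuron_reconstruction(neuron_id, points)
}

#' Generate labeled Gaussian soma clusters
#'
#' Class centers are placed at mutual distance `separation` (equally spaced
#' directions on a circle in the xy-plane, jittered in z), and each class
#' draws isotropic Gaussian somata of SD `spread` around its center.
#'
#' @param k number of classes.
#' @param separation center-to-center distance, micrometers.
#' @param spread within-class SD, micrometers.
#' @param n_per_class somata per class (recycled to length `k`).
#' @param seed integer seed.
#' @return Data frame `x`, `y`, `z`, `class`.
#' @export
generate_soma_clusters <- function(k = 2L, separation = 500, spread = 100,
                                   n_per_class = 20L, seed = 1L) {
  set.seed(seed)
  n_per_class <- rep_len(n_per_class, k)
  radius <- if (k == 1L) 0 else separation / (2 * sin(pi / k))
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  centers <- cbind(radius * cos(ang), radius * sin(ang), 0)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(x = rnorm(n_per_class[i], centers[i, 1L], spread),
               y = rnorm(n_per_class[i], centers[i, 2L], spread),
               z = rnorm(n_per_class[i], centers[i, 3L], spread),
               class = LETTERS[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
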