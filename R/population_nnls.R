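#' Build the regional-profile vector b from anterograde tracing experiments
#'
#' For each region, the projection volume and projection density are averaged
#' across experiments and the two averages are multiplied; the resulting
#' vector is normalized to sum to one.
#'
#' @param profiles data frame with columns `region`, `experiment`, `volume`,
#'   `density` (non-negative).
#' @return Named numeric vector `b` summing to one.
#' @export
build_b <- function(profiles) {
  need <- c("region", "volume", "density")
  if (!all(need %in% names(profiles))) {
    stop("profiles needs columns region, experiment, volume, density")
  }
  if (any(profiles$volume < 0) || any(profiles$density < 0)) {
    stop("negative projection volume/density")
  }
  sp <- split(profiles, profiles$region)
  raw <- vapply(sp, function(d) mean(d$volume) * mean(d$density), numeric(1L))
  total <- sum(raw)
  if (total <= 0) stop("all regional products are zero")
  raw / total
}

#' Bi-normalize a regions-by-classes axonal count matrix
#'
#' Sequential normalization of the class-signature matrix `A`, first by
#' axonal extent and then by invaded region: (1) each row (region) is scaled
#' to sum to one; (2) every cell is multiplied by `k/m` (classes/regions) so
#' the grand total equals the number of classes `k`; (3) each column (class)
#' is scaled to sum to one.
#'
#' @param raw non-negative matrix, regions (rows) x classes (columns), with
#'   no all-zero row or column; dimnames identify regions and classes.
#' @return Matrix of class `class_signature` with every column summing to 1
#'   and total `k`; attributes `m` (regions) and `k` (classes).
#' @export
binormalize_A <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("negative counts in A")
  rz <- rowSums(raw) == 0
  cz <- colSums(raw) == 0
  if (any(rz)) stop("all-zero region row: ",
                    paste(rownames(raw)[rz] %||% which(rz), collapse = ", "))
  if (any(cz)) stop("all-zero class column: ",
                    paste(colnames(raw)[cz] %||% which(cz), collapse = ", "))
  m <- nrow(raw); k <- ncol(raw)
  A <- raw / rowSums(raw)          # rows sum to 1
  A <- A * k / m                   # grand total k
  A <- sweep(A, 2L, colSums(A), "/")  # columns sum to 1
  structure(A, class = c("class_signature", class(A)), m = m, k = k)
}

#' Estimate class population fractions by non-negative least squares
#'
#' Finds `x >= 0` minimizing `||A x - b||`, where columns of `A` are the
#' bi-normalized class signatures over regions and `b` is the normalized
#' regional anterograde profile. `x`, normalized to percentages, estimates
#' the fraction of source-region neurons belonging to each class.
#'
#' @param A matrix from [binormalize_A()] (regions x classes).
#' @param b vector from [build_b()]; region order must match `A`'s rows.
#' @return List of class `population_estimate`: `x` (raw solution),
#'   `fractions_pct` (100 * x / sum(x)), `residual_sq` (squared Euclidean
#'   norm of `A x - b`) and `residual_pct_of_b2` (as percent of `||b||^2`).
#' @export
solve_population <- function(A, b) {
  A <- unclass(A)
  attr(A, "m") <- NULL; attr(A, "k") <- NULL
  if (nrow(A) != length(b)) stop("dimension mismatch between A and b")
  fit <- pracma::lsqnonneg(A, as.numeric(b))
  x <- fit$x
  names(x) <- colnames(A)
  r <- as.numeric(b) - A %*% x
  residual_sq <- sum(r * r)
  structure(list(x = x,
                 fractions_pct = 100 * x / sum(x),
                 residual_sq = residual_sq,
                 residual_pct_of_b2 = 100 * residual_sq / sum(b^2)),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate>\n")
  print(round(x$fractions_pct, 1))
  cat(sprintf("residual ||Ax-b||^2 = %.3g (%.3g%% of ||b||^2)\n",
              x$residual_sq, x$residual_pct_of_b2))
  invisible(x)
}

#' Per-class composition of the afferents to one target
#'
#' Combines class population fractions with the classes' mean axonal counts
#' in a target region to estimate what share of the source region's
#' projection to that target comes from each class: contribution of class c
#' is proportional to `fraction_c * mean_count_c(target)`, normalized over
#' classes to 100%. The per-class mean (not sum) is used so class size does
#' not enter twice.
#'
#' @param fractions a [solve_population()] estimate (or named fraction
#'   vector; names = class labels).
#' @param M the `projection_matrix` of the classified neurons.
#' @param classes a `class_tree` (or data frame `neuron_id`, `class`).
#' @param target character vector of column names of `M` defining the
#'   target (e.g. the ipsi/contra columns of a parcel group).
#' @return Named vector of percentages over classes (sums to 100).
#' @export
afferent_composition <- function(fractions, M, classes, target) {
  fr <- if (inherits(fractions, "population_estimate")) {
    fractions$fractions_pct
  } else fractions
  cls <- if (inherits(classes, "class_tree")) classes$classes else classes
  A <- counts_of(M)
  miss <- setdiff(target, colnames(A))
  if (length(miss)) stop("unknown target column(s): ",
                         paste(miss, collapse = ", "))
  weight <- vapply(names(fr), function(cl) {
    rows <- cls$neuron_id[cls$class == cl]
    if (!length(rows)) return(0)
    mean(rowSums(A[rows, target, drop = FALSE]))
  }, numeric(1L))
  contrib <- fr * weight
  total <- sum(contrib)
  if (total <= 0) {
    warning("target has zero counts from all classes; composition undefined")
    return(setNames(rep(NA_real_, length(fr)), names(fr)))
  }
  100 * contrib / total
}
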