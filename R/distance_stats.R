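#' Arccosine projection distance between two count vectors
#'
#' The angle (degrees) between two neurons' axonal count vectors:
#' `acos(u . v / (|u| |v|))`. 0 degrees means proportional targeting, 90
#' degrees disjoint targeting. Scale-invariant: multiplying either vector by
#' a positive constant leaves the angle unchanged.
#'
#' @param u,v non-negative numeric vectors of equal length, each with
#'   positive norm.
#' @return Angle in degrees, clamped to `[0, 180]` against rounding.
#' @export
arccos_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("undefined projection angle: zero vector")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' All pairwise arccosine distances of a projection matrix
#'
#' Computes the angle for every unordered pair of usable rows in stable
#' row-major order: (1,2), (1,3), ..., (2,3), ... Rows with zero total count
#' have no defined direction and are excluded (with a message).
#'
#' @param M a `projection_matrix` or counts matrix with >= 2 usable rows.
#' @param label `"experimental"` or `"randomized"` tag carried on the sample.
#' @return Object of class `distance_sample`: list with `values` (degrees),
#'   `n_items` (number of usable neurons), `items` (their ids), `label`.
#' @export
pairwise_distances <- function(M, label = c("experimental", "randomized")) {
  label <- match.arg(label)
  A <- counts_of(M)
  usable <- rowSums(A) > 0
  if (any(!usable)) {
    message("excluding ", sum(!usable), " zero-count row(s) from distances")
  }
  A <- A[usable, , drop = FALSE]
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 usable rows for pairwise distances")
  R <- A / sqrt(rowSums(A * A))
  G <- tcrossprod(R)
  G <- pmax(pmin(G, 1), -1)  # argument order keeps the matrix dim
  ang <- acos(G) * 180 / pi
  pairs <- which(upper.tri(ang), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  values <- ang[pairs]
  structure(list(values = values, n_items = n,
                 items = rownames(A) %||% as.character(seq_len(n)),
                 label = label),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat("<distance_sample> ", x$label, ": ", length(x$values), " pairs over ",
      x$n_items, " neurons; variance ", format(var(x$values), digits = 5),
      " deg^2\n", sep = "")
  invisible(x)
}

sample_values <- function(x) if (inherits(x, "distance_sample")) x$values else x

#' One-tailed Levene test of experimental vs. randomized distance variance
#'
#' Absolute-deviation Levene test: a one-way ANOVA on `|x - group mean|`
#' across the two groups. The classification question is directional -- only
#' a *larger* experimental variance indicates class structure -- so the
#' one-tailed p is half the ANOVA p when `var(exp) > var(rnd)`, and reported
#' as not applicable (`NA`, decision `"stop"`) otherwise.
#'
#' @param exp,rnd [pairwise_distances()] samples (or bare numeric vectors)
#'   for the experimental and randomized matrices.
#' @param alpha significance level for the split decision (default 0.05).
#' @return List of class `levene_result`: `statistic` (F), `df`,
#'   `p_two_tailed`, `p_one_tailed` (`NA` when the variance direction is
#'   wrong), `var_experimental`, `var_randomized`, `decision` (`"split"` or
#'   `"stop"`), `alpha`.
#' @export
levene_one_tailed <- function(exp, rnd, alpha = 0.05) {
  x1 <- sample_values(exp); x2 <- sample_values(rnd)
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("both samples need length >= 2")
  }
  z1 <- abs(x1 - mean(x1)); z2 <- abs(x2 - mean(x2))
  n1 <- length(z1); n2 <- length(z2); N <- n1 + n2
  zbar <- (sum(z1) + sum(z2)) / N
  ssb <- n1 * (mean(z1) - zbar)^2 + n2 * (mean(z2) - zbar)^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  if (ssw == 0) {
    f <- if (ssb > 0) Inf else 0
    p_two <- if (ssb > 0) 0 else 1
  } else {
    f <- (ssb / 1) / (ssw / (N - 2))
    p_two <- pf(f, 1, N - 2, lower.tail = FALSE)
  }
  v1 <- var(x1); v2 <- var(x2)
  direction_ok <- v1 > v2
  p_one <- if (direction_ok) p_two / 2 else NA_real_
  decision <- if (direction_ok && !is.na(p_one) && p_one < alpha) "split"
              else "stop"
  structure(list(statistic = f, df = c(1L, N - 2L),
                 p_two_tailed = p_two, p_one_tailed = p_one,
                 var_experimental = v1, var_randomized = v2,
                 decision = decision, alpha = alpha),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("<levene_result> F = %.4g on (%d, %d) df; ", x$statistic,
              x$df[1L], x$df[2L]))
  if (is.na(x$p_one_tailed)) {
    cat("one-tailed p = N/A (experimental variance not larger); ")
  } else {
    cat(sprintf("one-tailed p = %.3g; ", x$p_one_tailed))
  }
  cat(sprintf("var exp = %.4g, var rnd = %.4g -> %s\n",
              x$var_experimental, x$var_randomized, x$decision))
  invisible(x)
}
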