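#' Swap-randomization configuration
#'
#' The single-class null hypothesis is embodied by matrices with the same
#' per-neuron totals (row sums: axonal sizes) and per-region totals (column
#' sums: regional targeting) as the data, reached by repeated pairwise
#' swapping of counts between two neurons across two target regions.
#'
#' @param n_swaps number of successful swaps; default `20 *` the number of
#'   nonzero cells of the matrix being randomized (`NULL` = use the default).
#' @param delta_rule how much count delta moves per swap: `"uniform"` draws
#'   delta uniformly from `1..min(M[i,a], M[j,b])` (faster mixing, default);
#'   `"max"` always moves the feasible maximum.
#' @param seed optional integer seed for reproducibility.
#' @return A list of class `swap_config`.
#' @export
swap_config <- function(n_swaps = NULL, delta_rule = c("uniform", "max"),
                        seed = NULL) {
  delta_rule <- match.arg(delta_rule)
  if (!is.null(n_swaps) && n_swaps < 1) stop("n_swaps must be >= 1")
  structure(list(n_swaps = n_swaps, delta_rule = delta_rule, seed = seed),
            class = "swap_config")
}

#' Randomize a projection matrix preserving row and column sums
#'
#' Each accepted swap picks two distinct neurons i, j and two distinct
#' columns a, b, draws `delta` with `1 <= delta <= min(M[i,a], M[j,b])`, and
#' applies `M[i,a] -= delta; M[i,b] += delta; M[j,a] += delta; M[j,b] -=
#' delta`. Row and column sums are conserved exactly; entries stay
#' non-negative integers. Draws with no feasible `delta` are rejected and do
#' not count toward `n_swaps`.
#'
#' @param M a `projection_matrix` or non-negative integer matrix with at
#'   least 2 rows and 2 columns.
#' @param cfg a [swap_config()].
#' @return Randomized object of the same type as `M`, with attribute
#'   `"n_attempts"` (total proposals including rejections).
#' @export
randomize_matrix <- function(M, cfg = swap_config()) {
  is_pm <- inherits(M, "projection_matrix")
  A <- counts_of(M)
  nr <- nrow(A); nc <- ncol(A)
  if (nr < 2L || nc < 2L) stop("null model undefined: need >= 2 rows and columns")
  if (any(A < 0) || any(A != round(A))) {
    stop("matrix must be non-negative and integral")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_swaps <- cfg$n_swaps
  if (is.null(n_swaps)) n_swaps <- 20L * max(1L, sum(A > 0))
  uniform <- identical(cfg$delta_rule, "uniform")

  done <- 0L
  attempts <- 0L
  max_attempts <- 1000 * n_swaps + 1e6
  batch <- 4096L
  while (done < n_swaps) {
    ii <- sample.int(nr, batch, replace = TRUE)
    jj <- sample.int(nr, batch, replace = TRUE)
    aa <- sample.int(nc, batch, replace = TRUE)
    bb <- sample.int(nc, batch, replace = TRUE)
    uu <- runif(batch)
    for (t in seq_len(batch)) {
      attempts <- attempts + 1L
      i <- ii[t]; j <- jj[t]; a <- aa[t]; b <- bb[t]
      if (i == j || a == b) next
      dmax <- min(A[i, a], A[j, b])
      if (dmax < 1L) next
      delta <- if (uniform) 1L + as.integer(uu[t] * dmax) else as.integer(dmax)
      if (delta > dmax) delta <- dmax
      A[i, a] <- A[i, a] - delta
      A[i, b] <- A[i, b] + delta
      A[j, a] <- A[j, a] + delta
      A[j, b] <- A[j, b] - delta
      done <- done + 1L
      if (done >= n_swaps) break
    }
    if (attempts >= max_attempts) {
      warning("swap chain stalled after ", attempts,
              " proposals (", done, "/", n_swaps, " swaps)")
      break
    }
  }
  out <- if (is_pm) {
    M$counts <- A
    M$zero_rows <- rownames(A)[rowSums(A) == 0]
    M
  } else A
  attr(out, "n_attempts") <- attempts
  out
}
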