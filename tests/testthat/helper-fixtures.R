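# shared in-code fixtures

swc_chain <- function(n = 3L, parcel = NULL) {
  # soma at origin plus (n-1) axon points along +z, unit gaps
  lines <- "1 1 0 0 0 5 -1"
  for (i in 2:n) {
    l <- sprintf("%d 2 0 0 %d 0.5 %d", i, i - 1L, i - 1L)
    if (!is.null(parcel)) l <- paste(l, parcel)
    lines <- c(lines, l)
  }
  lines
}

# soma -> 2 bifurcations, 7 points, 3 leaves:
#   1(soma)-2-3, 3 branches to 4,5; 5 branches to 6,7
swc_two_bifurcations <- function() {
  c("1 1 0 0 0 5 -1",
    "2 2 0 0 1 .5 1",
    "3 2 0 0 2 .5 2",
    "4 2 1 0 3 .5 3",
    "5 2 -1 0 3 .5 3",
    "6 2 -2 0 4 .5 5",
    "7 2 -2 1 4 .5 5")
}

count_leaves <- function(neuron) {
  p <- neuron$points
  ax <- p[p$structure == "axon", ]
  sum(!(ax$point_id %in% p$parent_id))
}

disjoint_profile <- function(active, k = 10L) {
  p <- stats::setNames(rep(0, k), paste0("P", seq_len(k)))
  p[active] <- 1 / length(active)
  p
}

unit_cube <- function() as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))

random_int_matrix <- function(nr, nc, max_count = 50L) {
  matrix(sample.int(max_count + 1L, nr * nc, replace = TRUE) - 1L, nr, nc)
}

# enumerate every non-negative integer matrix with the given margins
# (brute force; for tiny fibers only)
enumerate_fiber <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  fill <- function(M, r, c, row_left, col_left) {
    if (r > nr) {
      if (all(col_left == 0L)) out[[length(out) + 1L]] <<- M
      return(invisible(NULL))
    }
    if (c > nc) {
      if (row_left[r] == 0L) fill(M, r + 1L, 1L, row_left, col_left)
      return(invisible(NULL))
    }
    hi <- min(row_left[r], col_left[c])
    for (v in 0:hi) {
      M[r, c] <- v
      rl <- row_left; rl[r] <- rl[r] - v
      cl <- col_left; cl[c] <- cl[c] - v
      fill(M, r, c + 1L, rl, cl)
    }
  }
  fill(matrix(0L, nr, nc), 1L, 1L, as.integer(row_sums), as.integer(col_sums))
  out
}

matrix_key <- function(M) paste(as.vector(M), collapse = ",")
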