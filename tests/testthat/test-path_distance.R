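test_that("path distance accumulates gaps along the unique root path", {
  chain <- parse_swc(text = swc_chain(3L, parcel = "T"))
  pd <- path_distances(chain)
  expect_equal(pd$path_distance_um, c(1, 2))
  expect_equal(pd$target, c("T", "T"))
})

test_that("path distances equal the weighted shortest-path graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(61)
  for (s in 1:10) {
    tree <- generate_tree(n_bifurcations = sample(3:10, 1L), seed = 700L + s)
    pd <- path_distances(tree)
    p <- tree$points
    edges <- which(!is.na(p$parent_id))
    idx <- match(p$parent_id[edges], p$point_id)
    w <- sqrt((p$x[edges] - p$x[idx])^2 + (p$y[edges] - p$y[idx])^2 +
                (p$z[edges] - p$z[idx])^2)
    g <- igraph::graph_from_edgelist(
      cbind(as.character(p$parent_id[edges]), as.character(p$point_id[edges])),
      directed = FALSE)
    igraph::E(g)$weight <- w
    d <- igraph::distances(g, v = as.character(p$point_id[1L]))
    oracle <- d[1L, as.character(pd$point_id)]
    expect_equal(unname(pd$path_distance_um), unname(oracle),
                 tolerance = 1e-9)
    # triangle inequality against straight-line soma distance
    straight <- sqrt((p$x - p$x[1L])^2 + (p$y - p$y[1L])^2 +
                       (p$z - p$z[1L])^2)[match(pd$point_id, p$point_id)]
    expect_true(all(pd$path_distance_um >= straight - 1e-9))
  }
})

test_that("per-target point counts partition the in-scope axonal total", {
  set.seed(62)
  trees <- lapply(1:4, function(i) generate_tree(5L, seed = 800L + i))
  cls <- data.frame(neuron_id = vapply(trees, `[[`, "", "neuron_id"),
                    class = "A4")
  rows <- path_distance_table(trees, cls)
  per_neuron <- table(rows$neuron_id)
  expected <- vapply(trees, function(n)
    sum(n$points$structure == "axon" & !is.na(n$points$parcel)), integer(1L))
  expect_equal(as.integer(per_neuron[cls$neuron_id]), expected)
})

test_that("divergence tests flag shifted targets and spare identical ones", {
  set.seed(63)
  base <- data.frame(neuron_id = "n1", point_id = 1L, parcel = "p",
                     hemisphere = "ipsi", stringsAsFactors = FALSE)
  mk <- function(target, values) {
    d <- base[rep(1L, length(values)), ]
    d$target <- target
    d$path_distance_um <- values
    d
  }
  same <- rbind(mk("T1", rnorm(100, 5000, 400)))
  same2 <- same; same2$target <- "T2"
  rep_same <- divergence_test(rbind(same, same2))
  expect_false(any(rep_same$tests$significant))
  expect_equal(rep_same$tests$p_adj, 1, tolerance = 1e-12)

  shifted <- rbind(mk("T1", rnorm(200, 5000, 400)),
                   mk("T2", rnorm(200, 5800, 400)))
  rep_shift <- divergence_test(shifted)
  expect_true(all(rep_shift$tests$significant))

  # ipsi and contra never compared against each other
  mixed <- rbind(mk("T1", rnorm(50, 5000, 400)),
                 mk("T2", rnorm(50, 5000, 400)))
  mixed$hemisphere[seq_len(50L)] <- "contra"
  rep_mixed <- divergence_test(mixed)
  expect_equal(nrow(rep_mixed$tests), 0L)
})

test_that("shifted distributions reach significance after FDR in most runs", {
  set.seed(64)
  hits <- 0L
  for (r in 1:20) {
    d <- data.frame(
      neuron_id = "n", point_id = 1L, parcel = "p", hemisphere = "ipsi",
      target = rep(c("T1", "T2"), each = 200L),
      path_distance_um = c(rnorm(200, 5000, 300),
                           rnorm(200, 5000 + 2 * 300, 300)))
    if (all(divergence_test(d)$tests$significant)) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("convergence tests compare classes at one target", {
  set.seed(65)
  one <- data.frame(neuron_id = "n", point_id = 1L, parcel = "p",
                    hemisphere = "ipsi", target = "T",
                    class = "A1", path_distance_um = rnorm(30, 5000, 300))
  expect_equal(nrow(convergence_test(one)$tests), 0L)

  trip <- do.call(rbind, lapply(c("A1", "B1", "C1"), function(cl) {
    d <- one; d$class <- cl; d
  }))
  rep_trip <- convergence_test(trip)
  expect_equal(rep_trip$tests$p_adj, rep(1, 3L), tolerance = 1e-12)
  expect_false(any(rep_trip$tests$significant))

  # equal planted distances stay non-significant at alpha = 0.05
  keep <- 0L
  for (r in 1:20) {
    d2 <- data.frame(neuron_id = "n", point_id = 1L, parcel = "p",
                     hemisphere = "ipsi", target = "T",
                     class = rep(c("A1", "B1"), each = 100L),
                     path_distance_um = rnorm(200, 5000, 300))
    if (!any(convergence_test(d2)$tests$significant)) keep <- keep + 1L
  }
  expect_gte(keep / 20, 0.9)
})

test_that("rank test matches an exact permutation oracle on tiny samples", {
  set.seed(66)
  for (i in 1:5) {
    a <- runif(5L); b <- runif(4L)
    d <- data.frame(neuron_id = "n", point_id = 1L, parcel = "p",
                    hemisphere = "ipsi", target = rep(c("T1", "T2"), c(5L, 4L)),
                    path_distance_um = c(a, b))
    got <- divergence_test(d)$tests
    # permutation null of the rank-sum statistic, exhaustive over C(9,5)
    pooled <- c(a, b)
    ranks <- rank(pooled)
    obs <- sum(ranks[1:5]) - 5 * 6 / 2
    combs <- combn(9L, 5L)
    stats <- apply(combs, 2L, function(ix) sum(ranks[ix]) - 15)
    mid <- 5 * 4 / 2
    p_exact <- mean(abs(stats - mid) >= abs(obs - mid))
    expect_equal(got$p, p_exact, tolerance = 0.12)
  }
  # FDR adjustment is monotone
  set.seed(67)
  d3 <- data.frame(neuron_id = "n", point_id = 1L, parcel = "p",
                   hemisphere = "ipsi",
                   target = rep(paste0("T", 1:4), each = 50L),
                   path_distance_um = rnorm(200, 5000, 300))
  t3 <- divergence_test(d3)$tests
  expect_true(all(t3$p_adj >= t3$p - 1e-12))
})

test_that("box-plot summaries use the quartile/1.5 IQR convention", {
  v <- c(1, 2, 3, 4, 100)
  d <- data.frame(neuron_id = "n", point_id = 1L, parcel = "p",
                  hemisphere = "ipsi", target = "T", path_distance_um = v)
  bs <- pathdist_boxstats(d)
  q <- quantile(v, c(.25, .5, .75), names = FALSE)
  expect_equal(bs$median, q[2L])
  expect_equal(bs$whisker_low, q[1L] - 1.5 * (q[3L] - q[1L]))
  expect_equal(bs$whisker_high, q[3L] + 1.5 * (q[3L] - q[1L]))
})
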