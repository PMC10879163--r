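test_that("average linkage matches hclust heights and brute-force merges", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:12, 1L)
    P <- matrix(runif(n * 4L), n)
    D <- as.matrix(dist(P))
    dimnames(D) <- list(paste0("n", 1:n), paste0("n", 1:n))
    mine <- average_linkage_tree(D)
    ref <- stats::hclust(as.dist(D), method = "average")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
    expect_equal(stats::cophenetic(mine), stats::cophenetic(ref),
                 tolerance = 1e-10)
  }
})

test_that("two tight groups separate at the top bipartition", {
  D <- matrix(80, 6L, 6L)
  within <- matrix(runif(9, 1, 5), 3L)
  within <- (within + t(within)) / 2
  D[1:3, 1:3] <- within
  D[4:6, 4:6] <- within
  diag(D) <- 0
  dimnames(D) <- list(letters[1:6], letters[1:6])
  hc <- average_linkage_tree(D)
  grp <- stats::cutree(hc, k = 2L)
  expect_equal(length(unique(grp[1:3])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
  expect_false(grp[1L] == grp[4L])
})

test_that("tie-breaking is lowest-index-first and two points merge once", {
  D2 <- matrix(c(0, 3, 3, 0), 2L)
  hc2 <- average_linkage_tree(D2)
  expect_equal(nrow(hc2$merge), 1L)
  expect_equal(hc2$height, 3)

  # equidistant triplet: first merge is (1,2); both heights equal
  D3 <- matrix(5, 3L, 3L); diag(D3) <- 0
  hc3 <- average_linkage_tree(D3)
  expect_equal(sort(hc3$merge[1L, ]), c(-2L, -1L))
  expect_equal(hc3$height, c(5, 5))

  expect_error(average_linkage_tree(matrix(c(0, NA, NA, 0), 2L)), "NA")
})

test_that("planted two-class cohorts are recovered with exact membership", {
  co <- generate_cohort(list(X = list(n = 20L, profile = disjoint_profile(1:5)),
                             Y = list(n = 20L, profile = disjoint_profile(6:10))),
                        seed = 101L)
  tr <- discover_classes(co$matrix, seed = 102L)
  expect_length(tr$class_sizes, 2L)
  found <- tr$classes$class[match(names(co$labels), tr$classes$neuron_id)]
  expect_equal(length(unique(found[co$labels == "X"])), 1L)
  expect_equal(length(unique(found[co$labels == "Y"])), 1L)
  expect_false(found[co$labels == "X"][1L] == found[co$labels == "Y"][1L])
})

test_that("class labels follow dendrogram order with sizes appended", {
  co <- generate_cohort(list(X = list(n = 8L, profile = disjoint_profile(1:5)),
                             Y = list(n = 5L, profile = disjoint_profile(6:10))),
                        seed = 103L)
  tr <- discover_classes(co$matrix, seed = 104L)
  expect_match(names(tr$class_sizes)[1L], "^A[0-9]+$")
  expect_equal(unname(tr$class_sizes),
               as.integer(sub("^[A-Z]+", "", names(tr$class_sizes))))
  # left-to-right: first class holds the leftmost leaf of the dendrogram
  leftmost <- tr$dendrogram$labels[tr$dendrogram$order[1L]]
  first_class <- tr$classes$class[tr$classes$neuron_id == leftmost]
  expect_equal(first_class, names(tr$class_sizes)[1L])
})

test_that("single-class cohorts stay unsplit and runs are reproducible", {
  co <- generate_cohort(list(one = list(n = 30L,
                                        profile = disjoint_profile(1:7))),
                        seed = 105L)
  tr1 <- discover_classes(co$matrix, seed = 106L)
  expect_length(tr1$class_sizes, 1L)
  expect_identical(tr1$node_tests$root$decision, "stop")
  tr2 <- discover_classes(co$matrix, seed = 106L)
  expect_identical(tr1$classes, tr2$classes)
  expect_identical(tr1$node_tests$root$statistic,
                   tr2$node_tests$root$statistic)
})

test_that("every neuron lands in exactly one class; zero rows are set aside", {
  co <- generate_cohort(list(X = list(n = 10L, profile = disjoint_profile(1:3)),
                             Y = list(n = 10L, profile = disjoint_profile(4:6))),
                        seed = 107L)
  A <- as.matrix(co$matrix)
  A <- rbind(A, empty = 0L)
  suppressMessages(tr <- discover_classes(A, seed = 108L))
  expect_identical(tr$unclassified, "empty")
  expect_setequal(tr$classes$neuron_id, rownames(A)[rowSums(A) > 0])
  expect_false(anyDuplicated(tr$classes$neuron_id) > 0)
  expect_equal(sum(tr$class_sizes), 20L)
})

test_that("each subtree is tested on its own rows only", {
  co <- generate_cohort(list(X = list(n = 12L, profile = disjoint_profile(1:5)),
                             Y = list(n = 9L, profile = disjoint_profile(6:10))),
                        seed = 109L)
  tr <- discover_classes(co$matrix, seed = 110L)
  expect_true(all(c("root", "root.L", "root.R") %in% names(tr$node_tests)))
  # subtree tests involve C(n,2) pairs of their own members
  sizes <- tr$class_sizes
  dfs <- vapply(tr$node_tests[c("root.L", "root.R")],
                function(t) t$df[2L], integer(1L))
  expect_setequal(dfs, vapply(unname(sizes), function(n)
    as.integer(2L * choose(n, 2L) - 2L), integer(1L)))
})

test_that("newick export preserves the leaf set", {
  co <- generate_cohort(list(X = list(n = 6L, profile = disjoint_profile(1:5)),
                             Y = list(n = 4L, profile = disjoint_profile(6:10))),
                        seed = 111L)
  tr <- discover_classes(co$matrix, seed = 112L)
  nwk <- write_class_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, tr$classes$neuron_id)
})
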