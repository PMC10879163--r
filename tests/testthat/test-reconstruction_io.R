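test_that("parse_swc builds a validated tree from well-formed input", {
  n <- parse_swc(text = swc_chain(3), neuron_id = "chain")
  expect_s3_class(n, "neuron_reconstruction")
  expect_equal(nrow(n$points), 3L)
  expect_identical(n$points$structure[1L], "soma")
  expect_true(is.na(n$points$parent_id[1L]))

  n7 <- parse_swc(text = swc_two_bifurcations())
  expect_equal(nrow(n7$points), 7L)
  expect_equal(count_leaves(n7), 3L)
})

test_that("parse_swc rejects malformed trees with informative errors", {
  dangling <- c("1 1 0 0 0 5 -1", "2 2 0 0 1 .5 99")
  expect_error(parse_swc(text = dangling), "dangling parent")
  two_roots <- c("1 1 0 0 0 5 -1", "2 2 0 0 1 .5 -1")
  expect_error(parse_swc(text = two_roots), "exactly one root")
  short <- c("1 1 0 0 0 5")
  expect_error(parse_swc(text = short), "7 columns")
  cyc <- c("1 1 0 0 0 5 -1", "2 2 0 0 1 .5 3", "3 2 0 0 2 .5 2")
  expect_error(parse_swc(text = cyc), "cycle|dangling")
})

test_that("SWC round-trips topology and coordinates exactly", {
  tree <- generate_tree(n_bifurcations = 4L, seed = 11L)
  back <- parse_swc(text = write_swc(tree), neuron_id = tree$neuron_id)
  expect_identical(back$points$point_id, tree$points$point_id)
  expect_identical(back$points$parent_id, tree$points$parent_id)
  expect_identical(back$points$x, tree$points$x)
  expect_identical(back$points$y, tree$points$y)
  expect_identical(back$points$z, tree$points$z)
  expect_identical(back$points$parcel, tree$points$parcel)
})

test_that("MouseLight-style JSON parses points, parcels, and soma", {
  f <- system.file("extdata", "synthetic_neuron.json", package = "axoclass")
  neurons <- parse_projection_json(f)
  expect_length(neurons, 1L)
  n <- neurons[[1L]]
  ax <- n$points[n$points$structure == "axon", ]
  expect_equal(nrow(ax), 7L)
  expect_setequal(unique(ax$parcel), c("1037", "918", "502"))
  expect_identical(n$soma_parcel, "1037")

  no_soma <- '{"neuron": {"idString": "x", "axon": []}}'
  expect_error(parse_projection_json(text = no_soma), "soma")
  bad_pt <- paste0('{"neuron": {"idString": "x", ',
                   '"soma": {"x": 0, "y": 0, "z": 0}, ',
                   '"axon": [{"sampleNumber": 1, "x": 1, "y": 1, "z": 1,',
                   ' "parentNumber": -1}]}}')
  expect_error(parse_projection_json(text = bad_pt), "parcel")
})

test_that("projection matrix counts points per parcel and flags zero rows", {
  mk <- function(id, parcels, soma_z = 4000) {
    lines <- sprintf("1 1 0 0 %d 5 -1", soma_z)
    for (i in seq_along(parcels)) {
      lines <- c(lines, sprintf("%d 2 0 0 %d .5 %d %s", i + 1L,
                                soma_z + i, i, parcels[i]))
    }
    parse_swc(text = lines, neuron_id = id)
  }
  n1 <- mk("n1", rep("P", 4L))
  M1 <- build_projection_matrix(list(n1), parcel_set = "P",
                                hemisphere_split = FALSE)
  expect_equal(unname(as.matrix(M1)[1L, 1L]), 4L)

  n2 <- mk("n2", rep("Q", 3L))
  M2 <- build_projection_matrix(list(n1, n2), parcel_set = c("P", "Q"),
                                hemisphere_split = FALSE)
  expect_equal(unname(diag(as.matrix(M2))), c(4L, 3L))
  expect_equal(unname(as.matrix(M2)[1L, 2L]), 0L)

  n0 <- mk("n0", rep("OUT", 2L))
  expect_message(
    M3 <- build_projection_matrix(list(n1, n0), parcel_set = "P",
                                  hemisphere_split = FALSE),
    "zero in-scope")
  expect_identical(M3$zero_rows, "n0")
  expect_equal(unname(rowSums(as.matrix(M3))), c(4L, 0L))
})

test_that("row sums are invariant to hemisphere splitting and col order", {
  co <- generate_cohort(presubiculum_like_classes(), seed = 3L)
  A <- as.matrix(co$matrix)
  # synthesize neurons on both sides of a midline from the counts of two
  # parcels to exercise the split
  mk <- function(id, n_ipsi, n_contra) {
    lines <- "1 1 0 0 6000 5 -1"
    pid <- 2L
    for (i in seq_len(n_ipsi)) {
      lines <- c(lines, sprintf("%d 2 0 0 %d .5 1 P1", pid, 6000 + i)); pid <- pid + 1L
    }
    for (i in seq_len(n_contra)) {
      lines <- c(lines, sprintf("%d 2 0 0 %d .5 1 P1", pid, 5000 - i)); pid <- pid + 1L
    }
    parse_swc(text = lines, neuron_id = id)
  }
  neurons <- list(mk("a", 5L, 2L), mk("b", 0L, 3L))
  Msplit <- build_projection_matrix(neurons, parcel_set = "P1",
                                    hemisphere_split = TRUE)
  Mflat <- build_projection_matrix(neurons, parcel_set = "P1",
                                   hemisphere_split = FALSE)
  expect_equal(rowSums(as.matrix(Msplit)), rowSums(as.matrix(Mflat)))
  expect_equal(unname(as.matrix(Msplit)[, "P1:ipsi"] +
                        as.matrix(Msplit)[, "P1:contra"]),
               unname(as.matrix(Mflat)[, "P1"]))
  expect_equal(unname(as.matrix(Msplit)["a", ]), c(5L, 2L))
})

test_that("cohort matrix row sums recount per-neuron axonal points", {
  set.seed(20)
  neurons <- lapply(1:10, function(i) generate_tree(sample(2:6, 1L),
                                                    seed = 100L + i))
  M <- build_projection_matrix(neurons, include_source = TRUE,
                               hemisphere_split = FALSE)
  recount <- vapply(neurons, function(n) {
    sum(n$points$structure == "axon" & !is.na(n$points$parcel))
  }, integer(1L))
  expect_equal(unname(rowSums(as.matrix(M))), recount)
  expect_equal(sum(as.matrix(M)), sum(recount))
})

test_that("projection matrix CSV round-trips counts and metadata", {
  co <- generate_cohort(presubiculum_like_classes(sizes = c(5L, 4L, 3L, 3L, 3L)),
                        seed = 9L)
  f <- tempfile(fileext = ".csv")
  write_projection_matrix(co$matrix, f)
  back <- read_projection_matrix(f)
  expect_equal(as.matrix(back), as.matrix(co$matrix))
  expect_equal(back$columns$parcel, co$matrix$columns$parcel)
})
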