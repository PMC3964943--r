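test_that("dataset profiles cover the core per the flank arithmetic", {
  tab <- simulate_pentamer_table(seed = 6)
  sites <- simulate_jaspar_sites(n = 10, flank_fraction = 1, seed = 6)
  ds2 <- apply_flank_rule(sites)
  prof2 <- dataset_profiles(ds2, tab)
  m <- profile_matrix(prof2, "MGW")
  expect_false(anyNA(m))                       # flanked: fully defined core
  expect_equal(dim(m), c(10L, 6L))

  ds0 <- apply_flank_rule(simulate_jaspar_sites(n = 10, flank_fraction = 0,
                                                seed = 6))
  expect_equal(flank_width(ds0), 0L)
  prof0 <- dataset_profiles(ds0, tab)
  m0 <- profile_matrix(prof0, "MGW")
  expect_true(all(is.na(m0[, c(1, 2, 5, 6)]))) # white heat-map margins
  expect_false(anyNA(m0[, 3:4]))
  r0 <- profile_matrix(prof0, "Roll")
  expect_true(all(is.na(r0[, c(1, ncol(r0))]))) # terminal steps missing

  # single-sequence dataset equals that sequence's own profile
  one <- as_tfbs_dataset(c(x = "atCACGTGgc"))
  p1 <- dataset_profiles(one, tab)
  direct <- predict_shape(c(x = "ATCACGTGGC"), tab, origin = -2)
  direct <- direct[direct$position >= 0 & direct$position <= 5, ]
  expect_equal(p1$value, direct$value)
})

test_that("average profiles take column means over defined cells", {
  prof <- shape_tbl_from_matrix(rbind(c(4, 6), c(6, 4)))
  avg <- average_profile(prof)
  expect_equal(avg$mean, c(5, 5))

  prof2 <- shape_tbl_from_matrix(rbind(c(1, NA), c(3, NA), c(NA, NA)))
  avg2 <- average_profile(prof2)
  expect_equal(avg2$mean, c(2, NA))
  expect_equal(avg2$n, c(2L, 0L))

  prof3 <- shape_tbl_from_matrix(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(average_profile(prof3)$mean, c(1, 2, 3))
})

test_that("row clustering merges identical rows first and caps at max_rows", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(9, 9, 9))
  cl <- cluster_rows(m)
  expect_true(cl$clustered)
  expect_equal(sort(cl$tree$merge[1, ]), c(-2L, -1L))  # identical pair first
  expect_equal(cl$tree$height[1], 0)

  big <- matrix(rnorm(3001 * 3), 3001)
  expect_message(cl_big <- cluster_rows(big), "cap")
  expect_false(cl_big$clustered)
  expect_equal(cl_big$row_order, paste0("row", 1:3001))

  withNA <- rbind(a = c(1, 2, 3), b = c(NA, NA, NA), c = c(1, 2, 4))
  expect_warning(cl_na <- cluster_rows(withNA), "all-missing")
  expect_equal(cl_na$row_order[3], "b")
})

test_that("merge trees equal brute-force agglomeration (n <= 12)", {
  set.seed(14)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * 5), n)
    rownames(m) <- paste0("r", seq_len(n))
    for (method in c("average", "single", "complete")) {
      cl <- cluster_rows(m, linkage = method)
      got <- as.matrix(cophenetic(cl$tree))[rownames(m), rownames(m)]
      dm <- as.matrix(dist(m))
      exp <- brute_cophenetic(dm, method)
      dimnames(exp) <- dimnames(dm)
      expect_equal(got, exp, tolerance = 1e-10)
    }
  }
})

test_that("pairwise-complete distances rescale for missing cells", {
  m <- rbind(a = c(0, 0, 0, 0), b = c(1, 1, NA, NA))
  d <- motifshape:::pairwise_complete_ed(m)
  # squared distance 2 over 2 shared cells, rescaled to 4 columns -> sqrt(4)
  expect_equal(d["a", "b"], 2)
  full <- rbind(a = c(0, 0, 0, 0), b = c(1, 1, 1, 1))
  expect_equal(motifshape:::pairwise_complete_ed(full)["a", "b"], 2)
})

test_that("profile comparison: identity, shift and anti-correlation", {
  tab <- simulate_pentamer_table(seed = 9)
  ds <- apply_flank_rule(simulate_jaspar_sites(n = 15, flank_fraction = 1,
                                               seed = 9))
  avg <- average_profile(dataset_profiles(ds, tab))
  cmp <- compare_profiles(avg, avg, offset = 0)
  expect_equal(cmp$pcc, rep(1, 4))
  expect_equal(cmp$ed, rep(0, 4))

  shifted <- avg
  shifted$mean <- shifted$mean + 0.7
  cmp2 <- compare_profiles(avg, shifted, offset = 0)
  expect_equal(cmp2$pcc, rep(1, 4))
  expect_equal(cmp2$ed, 0.7 * sqrt(cmp2$n_positions))

  a1 <- average_profile(shape_tbl_from_matrix(matrix(c(1, 2, 3), 1)))
  a2 <- average_profile(shape_tbl_from_matrix(matrix(c(3, 2, 1), 1)))
  cmp3 <- compare_profiles(a1, a2, offset = 0)
  expect_equal(cmp3$pcc, -1)

  # overlap below 2 defined positions is an alignment error
  expect_error(compare_profiles(a1, a2, offset = 2), "overlapping")
  expect_error(compare_profiles(a1, a2, offset = 0.5), "integer")
})

test_that("comparison measures are symmetric and ED satisfies the triangle inequality", {
  set.seed(21)
  mk <- function(v) average_profile(shape_tbl_from_matrix(matrix(v, 1)))
  x <- rnorm(8); y <- rnorm(8); z <- rnorm(8)
  ax <- mk(x); ay <- mk(y); az <- mk(z)
  c_xy <- compare_profiles(ax, ay)
  c_yx <- compare_profiles(ay, ax)
  expect_equal(c_xy$pcc, c_yx$pcc)
  expect_equal(c_xy$ed, c_yx$ed)
  c_xz <- compare_profiles(ax, az)
  c_yz <- compare_profiles(ay, az)
  expect_lte(c_xz$ed, c_xy$ed + c_yz$ed + 1e-12)
})

test_that("K-S differential: identity, separation, thresholds", {
  set.seed(8)
  m1 <- matrix(rnorm(30 * 4), 30)
  prof1 <- shape_tbl_from_matrix(m1)
  self <- ks_differential(prof1, prof1, features = "MGW")
  expect_true(all(self$statistic == 0))
  expect_true(all(self$p_value == 1))
  expect_true(all(self$category == "none"))

  # disjoint supports -> D = 1 (tiny samples via min_n)
  a <- shape_tbl_from_matrix(matrix(c(1, 2, 3), 3, 1))
  b <- shape_tbl_from_matrix(matrix(c(4, 5, 6), 3, 1))
  d <- ks_differential(a, b, features = "MGW", min_n = 3)
  expect_equal(d$statistic, 1)

  # strong separation at n = 100: distributions shifted by >> spread
  set.seed(77)
  big1 <- shape_tbl_from_matrix(matrix(rnorm(100 * 3), 100))
  big2 <- shape_tbl_from_matrix(matrix(rnorm(100 * 3, mean = 5), 100))
  ks <- ks_differential(big1, big2, features = "MGW")
  expect_true(all(ks$category == "strong"))
  expect_true(all(ks$p_value < 0.001))

  # under-sized groups are reported untested
  small <- shape_tbl_from_matrix(matrix(rnorm(5 * 3), 5))
  u <- ks_differential(small, big1, features = "MGW")
  expect_true(all(!u$tested))
  expect_true(all(is.na(u$category)))

  expect_error(ks_differential(a, shape_tbl_from_matrix(matrix(1, 1, 1),
                                                        feature = "Roll")),
               "no columns")
})

test_that("dendrogram topology, heights and Newick serialization", {
  # identical profiles are siblings at height 0
  dd <- shape_dendrogram(list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 9, 9)))
  expect_equal(dd$tree$height[1], 0)
  expect_equal(sort(dd$tree$labels[-dd$tree$merge[1, ]]), c("A", "B"))

  # two factors: single join at their Euclidean distance
  d2 <- shape_dendrogram(list(X = c(0, 0), Y = c(3, 4)))
  expect_equal(d2$tree$height, 5)
  expect_match(d2$newick, "X:5")
  expect_match(d2$newick, "Y:5")

  # planted two-clade structure is recovered
  d4 <- shape_dendrogram(list(a1 = c(0, 0, 0), a2 = c(0.1, 0, 0),
                              b1 = c(10, 10, 10), b2 = c(10, 10.1, 10)))
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = d4$newick)
  expect_true(ape::is.monophyletic(tr, c("a1", "a2")))
  expect_true(ape::is.monophyletic(tr, c("b1", "b2")))
  # Newick depths equal merge heights (ultrametric: root-to-tip = max height)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(max(depths[seq_along(tr$tip.label)]),
               max(d4$tree$height), tolerance = 1e-6)

  expect_error(shape_dendrogram(list(A = c(1, 2))), "at least 2")
  expect_error(shape_dendrogram(list(A = c(1, 2), B = c(1, 2, 3))),
               "same length")
})

test_that("profile matrices round-trip through TSV bit-exactly", {
  tab <- simulate_pentamer_table(seed = 10)
  ds <- apply_flank_rule(simulate_jaspar_sites(n = 8, flank_fraction = 0,
                                               seed = 10))
  prof <- dataset_profiles(ds, tab)
  for (f in c("MGW", "Roll")) {
    path <- tempfile(fileext = ".tsv")
    write_profile_matrix(prof, f, path)
    back <- read_profile_matrix(path, f)
    expect_identical(profile_matrix(back, f), profile_matrix(prof, f))
  }
})
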