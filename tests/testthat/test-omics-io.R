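test_that("matrix round-trips through disk at full precision", {
  x <- tiny_matrix(4, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(x, path)
  y <- read_omics_matrix(path, "expression")
  expect_equal(unclass(y), unclass(x))
  expect_identical(modality(y), "expression")
})

test_that("malformed matrices are rejected with informative errors", {
  vals <- matrix(1:6, 3, 2,
                 dimnames = list(c("gA", "gA", "gB"), c("s1", "s2")))
  expect_error(omics_matrix(vals, "expression"), "gA")
  vals2 <- matrix(c(0, 1, 2, 0), 2, 2,
                  dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(omics_matrix(vals2, "mutation"), "binary")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "gA\t1\tx", "gB\t2\t3"), path)
  expect_error(read_omics_matrix(path), "non-numeric")
  expect_error(read_omics_matrix(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("mutation binarization keeps nonsynonymous hits only, once", {
  rec <- data.frame(
    gene = c("geneA", "geneA", "geneA", "geneB"),
    sample = c("s1", "s1", "s2", "s1"),
    effect = c("missense", "missense", "synonymous", "nonsense"))
  m <- binarize_mutations(rec, samples = c("s1", "s2"))
  expect_equal(m["geneA", "s1"], 1)    # present despite two records
  expect_equal(m["geneA", "s2"], 0)    # synonymous-only stays 0
  expect_equal(m["geneB", "s1"], 1)
  expect_true(all(m %in% c(0, 1)))
  expect_error(binarize_mutations(rec, samples = "s1"), "unknown sample")
  expect_warning(
    empty <- binarize_mutations(rec[0, ], samples = c("s1", "s2")),
    "empty")
  expect_equal(dim(empty), c(0L, 2L))
})

test_that("MAD ranking follows the raw definition and is deterministic", {
  vals <- rbind(f1 = c(1, 2, 3, 4, 100),
                f2 = c(5, 5, 5, 5, 5),
                f3 = c(0, 20, 40, 60, 80))
  colnames(vals) <- paste0("s", 1:5)
  x <- omics_matrix(vals, "expression")
  mads <- feature_mad(x)
  expect_equal(unname(mads["f1"]), 1)      # median 3, |devs| 2,1,0,1,97
  expect_equal(unname(mads["f2"]), 0)      # constant feature
  top1 <- select_features_mad(x, 1)
  expect_identical(rownames(top1), "f3")
  top2 <- select_features_mad(x, 2)
  expect_identical(rownames(top2), c("f1", "f3"))  # original order kept
  # permutation invariance over samples
  perm <- sample(ncol(vals))
  xp <- omics_matrix(vals[, perm], "expression")
  expect_equal(feature_mad(xp), mads)
  expect_error(select_features_mad(x, 0), "positive")
  expect_error(select_features_mad(x, 10), "exceeds")
})

test_that("two constant-vs-varying features rank as expected", {
  vals <- rbind(f1 = c(0, 0, 0, 0), f2 = c(0, 9, 0, 9))
  colnames(vals) <- paste0("s", 1:4)
  x <- omics_matrix(vals, "expression")
  expect_identical(rownames(select_features_mad(x, 1)), "f2")
  expect_equal(unname(feature_mad(x)["f2"]), 4.5)
})

test_that("unit scaling is exact, degenerate-safe and reproducible", {
  vals <- rbind(f1 = c(0, 1, 2), f2 = c(7, 7, 7))
  colnames(vals) <- paste0("s", 1:3)
  sc <- scale_features(omics_matrix(vals, "expression"))
  expect_equal(unname(unclass(sc$scaled)["f1", ]), c(0, 0.5, 1))
  expect_equal(unname(unclass(sc$scaled)["f2", ]), c(0.5, 0.5, 0.5))
  # population-sd z-scores underlie the map: check an interior value
  z <- (vals["f1", ] - 1) / sqrt(2 / 3)
  expect_equal(max(abs(z)), 1.2247, tolerance = 1e-4)
  # applying the stored model reproduces the scaled matrix exactly
  again <- apply_scaling(sc$model, omics_matrix(vals, "expression"))
  expect_identical(unclass(again), unclass(sc$scaled))
  expect_error(scale_features(omics_matrix(vals[, 1, drop = FALSE],
                                           "expression")), "2 samples")
})

test_that("scaled features span [0,1] with exact endpoints", {
  x <- tiny_matrix(8, 6, seed = 3)
  s <- unclass(scale_features(x)$scaled)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(apply(s, 1, min)), rep(0, 8))
  expect_equal(unname(apply(s, 1, max)), rep(1, 8))
})

test_that("joint scaling removes per-cohort offsets and maps new samples", {
  a <- tiny_matrix(5, 3, seed = 4)
  b_vals <- unclass(a)[, 1:2] + 10   # cohort b = shifted copy, 2 samples
  colnames(b_vals) <- c("t1", "t2")
  b <- omics_matrix(b_vals, "expression")
  js <- joint_scale(a, b)
  expect_equal(ncol(js$scaled), 5L)              # 3 + 2, a then b
  expect_identical(colnames(js$scaled), c(colnames(a), colnames(b)))
  # identical-cohort symmetry: both halves identical after the two steps
  a_copy <- unclass(a)
  colnames(a_copy) <- paste0("cc", 1:3)
  js2 <- joint_scale(a, omics_matrix(a_copy, "expression"))
  expect_equal(unclass(js2$scaled)[, 1:3], unclass(js2$scaled)[, 4:6],
               ignore_attr = TRUE)
  # the stored transform reproduces cohort a's columns
  re_a <- apply_scaling(js$model, a, cohort = "a")
  expect_equal(unclass(re_a), unclass(js$scaled)[, 1:3], ignore_attr = TRUE)
  bad <- tiny_matrix(5, 3, seed = 9)
  rownames(bad) <- paste0("other", 1:5)
  expect_error(joint_scale(a, omics_matrix(unclass(bad), "expression")),
               "feature ids")
})

test_that("stacking concatenates modalities in canonical order", {
  e <- tiny_matrix(10, 4, "expression", 1)
  m <- tiny_matrix(4, 4, "expression", 2)
  mv <- (unclass(m) > 3) * 1
  m <- omics_matrix(mv, "mutation")
  c_ <- tiny_matrix(3, 4, "cnv", 3)
  st <- stack_modalities(list(c_, m, e))        # shuffled input order
  expect_equal(nrow(st$values), 17L)
  expect_identical(st$modality_of_row,
                   rep(c("expression", "mutation", "cnv"), c(10, 4, 3)))
  single <- stack_modalities(list(e))
  expect_equal(single$values, unclass(e), ignore_attr = TRUE)
  m2 <- m; colnames(m2) <- rev(colnames(m2))
  expect_error(stack_modalities(list(e, omics_matrix(unclass(m2), "mutation"))),
               "identical sample ids")
  expect_error(stack_modalities(list()), "non-empty")
})
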