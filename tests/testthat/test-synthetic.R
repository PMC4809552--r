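small_cfg <- function(seed, ...) {
  synthetic_config(seed = seed, chrom_length = 30000, n_elements = 10,
                   ...)
}

test_that("the bundle is byte-identical for identical config and seed", {
  d1 <- file.path(tempdir(), "bun1"); d2 <- file.path(tempdir(), "bun2")
  b1 <- generate_synthetic(small_cfg(7), dir = d1)
  b2 <- generate_synthetic(small_cfg(7), dir = d2)
  for (nm in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[nm]])),
                     unname(tools::md5sum(b2$paths[[nm]])),
                     info = nm)
  }
  # and a different seed changes the alignment
  b3 <- generate_synthetic(small_cfg(8))
  expect_false(identical(b1$alignment$seqs, b3$alignment$seqs))
})

test_that("truth bookkeeping follows the configuration", {
  b <- generate_synthetic(small_cfg(9))
  expect_equal(nrow(b$truth), 10L)
  expect_true(all(b$truth$end > b$truth$start))
  # planted intervals are non-overlapping
  expect_true(all(b$truth$start[-1] >= b$truth$end[-10]))
  b0 <- generate_synthetic(small_cfg(9, accel_fraction = 0))
  expect_equal(sum(b0$truth$lambda > 1), 0L)
  expect_error(generate_synthetic(
    synthetic_config(seed = 1, chrom_length = 2000, n_elements = 50)),
    "infeasible packing")
  expect_error(synthetic_config(seed = 1, dropout = 1.5), "\\[0, 1\\]")
})

test_that("background identity matches the closed-form expectation", {
  b <- generate_synthetic(synthetic_config(seed = 10, chrom_length = 30000,
                                           n_elements = 0, dropout = 0))
  tr <- b$tree; m <- b$model
  a <- strsplit(b$alignment$seqs[["mouse"]], "")[[1]]
  c2 <- strsplit(b$alignment$seqs[["rat"]], "")[[1]]
  d <- ape::cophenetic.phylo(tr)["mouse", "rat"]
  P <- transition_matrix(m, d)
  p_same <- sum(m$pi * diag(P))
  obs <- mean(a == c2)
  se <- sqrt(p_same * (1 - p_same) / length(a))
  expect_lt(abs(obs - p_same), 3 * se)
})

test_that("accelerated elements show elevated focal-stem divergence", {
  b <- generate_synthetic(synthetic_config(seed = 11, chrom_length = 60000,
                                           n_elements = 20,
                                           accel_fraction = 0.4,
                                           dropout = 0))
  tr <- b$truth
  # per element: bat-to-reference mismatch count (substitutions on the
  # focal path, including the scaled stem)
  div <- vapply(seq_len(nrow(tr)), function(i) {
    a <- substr(b$alignment$seqs[["bat1"]], tr$start[i] + 1, tr$end[i])
    r <- substr(b$alignment$seqs[["mouse"]], tr$start[i] + 1, tr$end[i])
    mean(strsplit(a, "")[[1]] != strsplit(r, "")[[1]])
  }, numeric(1))
  expect_gt(sum(tr$accelerated), 2)
  w <- stats::wilcox.test(div[tr$accelerated], div[!tr$accelerated],
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("evaluate_calls scores matches, misses and boundary overlaps", {
  truth <- data.frame(chrom = "c1", start = c(0, 1000), end = c(100, 1100))
  ev <- evaluate_calls(truth, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdp, 0)
  expect_equal(ev$jaccard, 1)
  ev0 <- evaluate_calls(truth[0, ], truth)
  expect_equal(ev0$sensitivity, 0)
  # brute-force reciprocal-overlap oracle on random cases
  set.seed(81)
  for (rep in 1:30) {
    tpos <- sort(sample.int(5000, 3)) * 10
    truth <- data.frame(chrom = "c1", start = tpos, end = tpos + 200)
    shift <- sample(c(0, 100, 150, 300), 3, replace = TRUE)
    calls <- data.frame(chrom = "c1", start = tpos + shift,
                        end = tpos + 200 + shift)
    ev <- evaluate_calls(calls, truth)
    want_match <- vapply(1:3, function(i) {
      ov <- pmin(calls$end[i], truth$end) - pmax(calls$start[i], truth$start)
      any(ov >= 100 & ov >= 100)   # reciprocal 50% of both 200 bp lengths
    }, logical(1))
    expect_equal(ev$sensitivity, mean(want_match))
  }
})
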