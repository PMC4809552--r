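test_that("TSS distance handles inside, outside and missing chromosomes", {
  el <- data.frame(chrom = "c1", start = 1000, end = 2000)
  expect_equal(tss_distance(el, data.frame(chrom = "c1", start = 2500,
                                           end = 2501)), 500)
  expect_equal(tss_distance(el, data.frame(chrom = "c1", start = 1500,
                                           end = 1501)), 0)
  expect_equal(tss_distance(el, data.frame(chrom = "c2", start = 10,
                                           end = 11)), Inf)
  # linear-scan oracle on random fixtures
  set.seed(71)
  for (rep in 1:20) {
    el <- data.frame(chrom = "c1",
                     start = s <- sample.int(1e5, 5),
                     end = s + sample.int(2000, 5))
    tss <- data.frame(chrom = "c1", start = sample.int(1e5, 8))
    tss$end <- tss$start + 1
    got <- tss_distance(el, tss)
    for (i in 1:5) {
      want <- min(vapply(tss$start, function(p) {
        if (p >= el$start[i] && p < el$end[i]) 0
        else if (p < el$start[i]) el$start[i] - p - 1 else p - el$end[i]
      }, numeric(1)))
      expect_equal(got[i], want)
    }
  }
  # symmetric under coordinate reflection
  L <- 1e5
  el_r <- data.frame(chrom = "c1", start = L - el$end, end = L - el$start)
  tss_r <- data.frame(chrom = "c1", start = L - tss$end,
                      end = L - tss$start)
  expect_equal(sort(tss_distance(el_r, tss_r)),
               sort(tss_distance(el, tss)))
})

test_that("gene deserts require strictly more than the radius on both sides", {
  el <- data.frame(chrom = "c1", start = 1e6, end = 1e6 + 1000)
  tss_at <- function(...) {
    p <- c(...)
    data.frame(chrom = "c1", start = p, end = p + 1)
  }
  # 600 kb away on both sides: desert
  expect_true(gene_desert_flag(el, tss_at(4e5 - 1, 1.6e6 + 1000), 5e5))
  # 400 kb upstream only: not a desert
  expect_false(gene_desert_flag(el, tss_at(6e5), 5e5))
  # exactly 500 kb: not a desert (strict "greater than")
  expect_false(gene_desert_flag(el, tss_at(1e6 - 5e5 - 1), 5e5))
  expect_true(gene_desert_flag(el, tss_at(1e6 - 5e5 - 2), 5e5))
  # a TSS inside the element: not a desert
  expect_false(gene_desert_flag(el, tss_at(1e6 + 10), 5e5))
})

test_that("clustering permutation test behaves at its extremes", {
  set.seed(72)
  cand <- data.frame(chrom = "c1",
                     start = s <- sort(sample.int(1e7, 40)) , end = s + 500)
  # bars identical to candidates: the null equals the observed, p = 1
  r <- clustering_permutation_test(cand, cand, n_perm = 50, seed = 1)
  expect_equal(r$p, 1)
  # five adjacent bars within ~1 kb drawn from a 10 Mb pool
  tight <- data.frame(chrom = "c1", start = 5e6 + (0:4) * 200,
                      end = 5e6 + (0:4) * 200 + 150)
  pool <- rbind(cand, tight)
  r2 <- clustering_permutation_test(tight, pool, n_perm = 1000, seed = 2)
  expect_lte(r2$p, 0.01)
  expect_gt(r2$p, 0)
  expect_error(clustering_permutation_test(cand[1, ], cand), "at least two")
})

test_that("small-case clustering p matches exhaustive enumeration", {
  cand <- data.frame(chrom = "c1",
                     start = c(0, 1000, 2000, 50000, 60000, 70000),
                     end = c(100, 1100, 2100, 50100, 60100, 70100))
  bars <- cand[1:3, ]
  obs <- barscan:::.clustering_stat(bars)
  combs <- utils::combn(6, 3)
  exact <- mean(apply(combs, 2, function(ix)
    barscan:::.clustering_stat(cand[ix, , drop = FALSE]) <= obs))
  r <- clustering_permutation_test(bars, cand, n_perm = 4000, seed = 3)
  expect_lt(abs(r$p - exact), 0.05)
})

test_that("proximity enrichment reproduces the 2x2 arithmetic", {
  # engineered table (10, 90, 5, 195): OR = 10*195 / (90*5) = 4.333
  set.seed(73)
  cand <- data.frame(chrom = "c1", start = seq(0, by = 10000,
                                               length.out = 300))
  cand$end <- cand$start + 100
  # gene TSS right next to the first 10 bars and candidates 101..105
  bars <- cand[1:100, ]
  tss <- data.frame(chrom = "c1",
                    start = c(cand$start[1:10] + 50,
                              cand$start[101:105] + 50))
  tss$end <- tss$start + 1
  r <- proximity_enrichment(bars, cand, tss, window = 200, n_perm = 200,
                            seed = 4)
  expect_equal(unname(r$table["called", ]), c(10, 90))
  expect_equal(unname(r$table["not_called", ]), c(5, 195))
  expect_equal(r$odds_ratio, 10 * 195 / (90 * 5), tolerance = 1e-12)
  expect_gt(r$p, 0)
  # zero cell: correction keeps the OR finite and positive
  bars0 <- cand[201:250, ]
  r0 <- proximity_enrichment(bars0, cand, tss, window = 200,
                             n_perm = 100, seed = 5)
  expect_true(is.finite(r0$odds_ratio) && r0$odds_ratio > 0)
  expect_error(proximity_enrichment(bars, cand, tss[0, ]), "empty gene")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(74)
  cand <- data.frame(chrom = "c1",
                     start = s <- sort(sample.int(5e6, 60)), end = s + 300)
  ps <- vapply(1:60, function(r) {
    bars <- cand[sample.int(60, 8), ]
    clustering_permutation_test(bars, cand, n_perm = 99,
                                seed = 100 + r)$p
  }, numeric(1))
  expect_true(all(ps > 0))
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_gt(mean(ps), 0.3)
})

test_that("the annotation report states the headline fractions", {
  bars <- data.frame(chrom = "c1", start = c(0, 1e6), end = c(1000, 1e6 + 500))
  tss <- data.frame(chrom = "c1", start = 5e5, end = 5e5 + 1)
  rep_lines <- annotation_report(bars, tss)
  expect_true(any(grepl("mean length: 750.0 bp", rep_lines)))
  expect_true(any(grepl("20 kb", rep_lines)))
})
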