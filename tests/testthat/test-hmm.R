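test_that("degenerate HMM settings behave as stated", {
  m <- hky_model()
  tr <- tree8()
  aln <- simulate_alignment(tr, m, 300, seed = 12)
  # no entry into the conserved state: zero elements
  scan <- detect_conserved(aln, tr, m,
                           phylo_hmm_params(rho = 0.3, L_n = Inf))
  expect_equal(nrow(scan$elements), 0L)
  # a fully conserved block with near-certain entry: one spanning element
  aln_c <- simulate_alignment(tr, m, 1000, seed = 13, scales = 0.3)
  scan_c <- detect_conserved(aln_c, tr, m,
                             phylo_hmm_params(rho = 0.3, L_n = 1))
  expect_equal(nrow(scan_c$elements), 1L)
  expect_gte(scan_c$elements$end[1] - scan_c$elements$start[1], 950)
})

test_that("planted conserved elements are recovered accurately", {
  m <- hky_model()
  tr <- tree8()
  set.seed(77)
  segs <- list()
  truth <- data.frame(start = integer(0), end = integer(0))
  pos <- 0
  for (k in 1:6) {
    segs[[length(segs) + 1]] <- simulate_alignment(tr, m, 800)
    pos <- pos + 800
    segs[[length(segs) + 1]] <- simulate_alignment(tr, m, 200,
                                                   scales = 0.3)
    truth <- rbind(truth, data.frame(start = pos, end = pos + 200))
    pos <- pos + 200
  }
  segs[[length(segs) + 1]] <- simulate_alignment(tr, m, 800)
  seqs <- vapply(tr$tip.label, function(sp)
    paste(vapply(segs, function(s) s$seqs[[sp]], character(1)),
          collapse = ""), character(1))
  aln <- multi_alignment(seqs, ref = "s1", chrom = "c1", start = 0)
  scan <- detect_conserved(aln, tr, m, phylo_hmm_params())
  truth$chrom <- "c1"
  ev <- evaluate_calls(scan$elements, truth)
  expect_gte(ev$jaccard, 0.8)
})

test_that("forward-backward posteriors match brute-force path enumeration", {
  m <- hky_model()
  tr <- tree8()
  set.seed(5)
  aln <- simulate_alignment(tr, m, 10)
  params <- phylo_hmm_params(rho = 0.3, L_c = 50, L_n = 200)
  scan <- detect_conserved(aln, tr, m, params)
  e_n <- prune_loglik(tr, m, aln, per_column = TRUE)
  e_c <- prune_loglik(tr, m, aln, scales = 0.3, per_column = TRUE)
  expect_equal(scan$posterior,
               brute_hmm_posterior(e_n, e_c, params$mu, params$nu),
               tolerance = 1e-10)
  expect_true(all(scan$posterior >= 0 & scan$posterior <= 1))
})

test_that("the Viterbi path beats random state paths", {
  m <- hky_model()
  tr <- tree8()
  set.seed(6)
  aln <- simulate_alignment(tr, m, 60)
  params <- phylo_hmm_params()
  scan <- detect_conserved(aln, tr, m, params)
  e <- rbind(prune_loglik(tr, m, aln, per_column = TRUE),
             prune_loglik(tr, m, aln, scales = params$rho,
                          per_column = TRUE))
  lTR <- log(matrix(c(1 - params$nu, params$nu, params$mu, 1 - params$mu),
                    2, 2, byrow = TRUE))
  linit <- log(c(params$mu, params$nu) / (params$mu + params$nu))
  path_lp <- function(s) {
    lp <- linit[s[1]] + e[s[1], 1]
    for (t in 2:length(s)) lp <- lp + lTR[s[t - 1], s[t]] + e[s[t], t]
    lp
  }
  lp_vit <- path_lp(scan$viterbi)
  rand <- replicate(1000, path_lp(sample(1:2, 60, replace = TRUE)))
  expect_true(all(lp_vit >= rand))
})

test_that("merging follows the gap/span rule and agrees with the oracle", {
  # forced merges and non-merges from the stated rule
  el <- data.frame(chrom = "c1", start = c(0, 105), end = c(100, 220),
                   name = c("a", "b"), score = c(1, 2))
  mg <- merge_elements(el, 0.1)
  expect_equal(nrow(mg), 1L)
  expect_equal(c(mg$start, mg$end), c(0, 220))
  expect_equal(mg$score, 3)
  el2 <- data.frame(chrom = "c1", start = c(0, 200), end = c(100, 260),
                    name = c("a", "b"), score = c(1, 2))
  expect_equal(nrow(merge_elements(el2, 0.1)), 2L)
  expect_error(merge_elements(
    data.frame(chrom = "c1", start = c(0, 50), end = c(60, 100),
               name = c("a", "b"), score = 0)), "overlapping")

  set.seed(14)
  for (rep in 1:60) {
    el <- random_elements(sample(2:12, 1))
    got <- merge_elements(el, 0.1)
    want <- merge_oracle(el, 0.1)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # idempotence and non-decreasing coverage
    again <- merge_elements(got, 0.1)
    expect_equal(again$start, got$start)
    expect_equal(again$end, got$end)
    expect_gte(sum(got$end - got$start), sum(el$end - el$start))
  }
})
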