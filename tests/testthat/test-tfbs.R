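# enumeration oracle: exact score distribution by scoring all w-mers
enumerate_dist <- function(p, step = 1e-3) {
  inc <- round(log2(p$mat / p$bg) / step)
  words <- as.matrix(expand.grid(rep(list(1:4), p$w)))
  sc <- integer(nrow(words)); pr <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    sc[r] <- sum(inc[cbind(words[r, ], seq_len(p$w))])
    pr[r] <- prod(p$bg[words[r, ]])
  }
  tapply(pr, sc, sum)
}

test_that("the exact score distribution matches exhaustive enumeration", {
  set.seed(61)
  for (w in 2:4) {
    mat <- matrix(runif(4 * w), 4, w)
    p <- pwm("m", mat)
    d <- exact_score_distribution(p)
    expect_equal(sum(d$probs), 1, tolerance = 1e-9)
    want <- enumerate_dist(p)
    got <- d$probs[d$probs > 0]
    names(got) <- as.character(which(d$probs > 0) - 1L + d$lo)
    expect_equal(got[names(want)], want, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # tail p-values are non-increasing in the score threshold
    expect_true(all(diff(d$tail_p) <= 1e-15))
  }
  # width 1, uniform column on uniform background: single mass at 0
  d1 <- exact_score_distribution(pwm("u", matrix(0.25, 4, 1)))
  expect_equal(sum(d1$probs > 0), 1L)
  expect_equal(d1$probs[0 - d1$lo + 1], 1)
  expect_error(exact_score_distribution(pwm("w", matrix(0.25, 4, 30))),
               "cap")
})

test_that("the top-score tail equals the product of argmax background probs", {
  set.seed(62)
  mat <- matrix(runif(8), 4, 2)
  p <- pwm("m", mat, bg = c(0.4, 0.2, 0.2, 0.2))
  d <- exact_score_distribution(p)
  inc <- round(log2(p$mat / p$bg) / 1e-3)
  smax <- sum(apply(inc, 2, max))
  # P(score >= max) sums background probs of all argmax base combinations
  want <- prod(vapply(1:2, function(k)
    sum(p$bg[inc[, k] == max(inc[, k])]), numeric(1)))
  expect_equal(barscan:::.score_pvalue(d, smax), want, tolerance = 1e-12)
})

test_that("scanning finds planted sites on both strands and skips N", {
  consensus <- "ACGTACGT"
  mat <- matrix(0.02, 4, 8)
  mat[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")),
            1:8)] <- 0.94
  p <- pwm("m8", mat)
  set.seed(63)
  seq <- paste0(random_dna(5), consensus, random_dna(12))
  hits <- scan_and_call(seq, p, hit_fdr = 0.01)
  expect_true(any(hits$offset == 5 & hits$strand == "+"))
  # reverse complement: same site on the minus strand, mirrored offset
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                     collapse = ""))
  hits_rc <- scan_and_call(rc, p, hit_fdr = 0.01)
  expect_true(any(hits_rc$offset == nchar(seq) - 8 - 5 &
                    hits_rc$strand == "-"))
  # windows containing N are skipped
  seqN <- paste0(random_dna(5), "NN", random_dna(10))
  hN <- scan_and_call(seqN, p)
  # windows 1..7 on each strand overlap the N run; 3 valid per strand
  expect_equal(attr(hN, "n_slots"), 6L)
  # flat motif yields identical scores and no hits at a 0.01 threshold
  flat <- pwm("flat", matrix(0.25, 4, 6))
  expect_equal(nrow(scan_and_call(random_dna(200), flat)), 0L)
  expect_equal(nrow(scan_and_call("ACG", p)), 0L)   # shorter than width
})

test_that("the count test matches exact binomial arithmetic", {
  expect_equal(motif_count_test(3, 100, 3, 100)$p, 1)
  t2 <- motif_count_test(10, 100, 0, 100)
  expect_equal(t2$p, 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(t2$direction, "gain")
  expect_equal(motif_count_test(0, 50, 0, 80)$p, 1)
  expect_error(motif_count_test(0, 0, 0, 0), "no scannable")
  expect_error(motif_count_test(5, 3, 0, 10), "0 <= k <= n")
  # equal rates with equal trials always give p = 1
  for (k in 0:5) expect_equal(motif_count_test(k, 40, k, 40)$p, 1)
})

test_that("the divergence screen flags planted gains with correct direction", {
  consensus <- "GATTACCA"
  mat <- matrix(0.02, 4, 8)
  mat[cbind(match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")),
            1:8)] <- 0.94
  p_gain <- pwm("gain8", mat)
  p_null <- pwm("null8", matrix(c(0.94, 0.02, 0.02, 0.02), 4, 8))
  set.seed(64)
  pairs <- lapply(1:20, function(i) {
    bg <- random_dna(150)
    anc <- paste0(substr(bg, 1, 40), consensus,
                  substr(bg, 49, 90), consensus,
                  substr(bg, 99, 150))
    list(id = paste0("el", i), a = anc, b = bg)
  })
  scr <- divergence_screen(pairs, list(p_gain, p_null), pooled = TRUE)
  row <- scr[scr$motif == "gain8", ]
  expect_true(row$significant)
  expect_equal(row$direction, "gain")
  # pooled counts equal the sum of per-element counts
  per <- divergence_screen(pairs, list(p_gain), pooled = FALSE)
  expect_equal(row$k_a, sum(per$k_a))
  expect_equal(row$n_a, sum(per$n_a))
  # identical pairs: all p = 1, nothing significant
  same <- lapply(pairs, function(el) list(id = el$id, a = el$b, b = el$b))
  scr0 <- divergence_screen(same, list(p_gain, p_null))
  expect_true(all(scr0$p == 1))
  expect_false(any(scr0$significant))
  expect_error(divergence_screen(pairs, list()), "empty motif")
})

test_that("JASPAR PFM text round-trips", {
  set.seed(65)
  pw <- list(pwm("MA0001", matrix(runif(32), 4, 8)),
             pwm("MA0002", matrix(runif(24), 4, 6)))
  f <- tempfile(fileext = ".pfm")
  write_jaspar(pw, f)
  back <- read_jaspar(f)
  expect_equal(names(back), c("MA0001", "MA0002"))
  expect_equal(back$MA0001$mat, pw[[1]]$mat, tolerance = 0.01)
  expect_equal(back$MA0002$w, 6L)
})
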