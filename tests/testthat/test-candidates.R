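test_that("peak union covers exactly the union of input bases", {
  a <- data.frame(chrom = "c1", start = 0, end = 100)
  b <- data.frame(chrom = "c1", start = 50, end = 150)
  u <- union_peaks(a, b)
  expect_equal(c(u$start, u$end), c(0, 150))
  # disjoint inputs stay separate
  d <- union_peaks(data.frame(chrom = "c1", start = c(0, 500),
                              end = c(100, 600)))
  expect_equal(nrow(d), 2L)

  # bitmap oracle on a 10 kb toy chromosome
  set.seed(8)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) {
      s <- sort(sample.int(9800, 8))
      data.frame(chrom = "c1", start = s,
                 end = s + sample.int(200, 8, replace = TRUE))
    })
    u <- union_peaks(sets)
    bitmap <- logical(10000)
    for (st in sets) for (i in seq_len(nrow(st)))
      bitmap[(st$start[i] + 1):st$end[i]] <- TRUE
    expect_equal(sum(u$end - u$start), sum(bitmap))
    # disjoint and sorted
    expect_true(all(u$start[-1] > u$end[-nrow(u)]))
  }
})

test_that("candidate selection applies the strict length and 1 bp overlap rules", {
  peaks <- data.frame(chrom = "c1", start = 1149, end = 1300,
                      name = "p1", score = 0, strand = ".")
  el <- data.frame(chrom = "c1", start = c(0, 1000, 2000),
                   end = c(100, 1150, 2101),
                   name = c("m1", "m2", "m3"), score = 1)
  # length exactly 100 excluded even if overlapping; 1 bp overlap included
  got <- select_candidates(
    el, rbind(peaks, data.frame(chrom = "c1", start = c(50, 2100),
                                end = c(60, 2400), name = c("p2", "p3"),
                                score = 0, strand = ".")))
  expect_equal(got$start, c(1000, 2000))
  expect_equal(got$peak_ids, c("p1", "p3"))

  # quadratic oracle on random toys
  set.seed(9)
  for (rep in 1:15) {
    el <- random_elements(10, max_len = 300)
    pk <- random_elements(6, max_len = 400, max_gap = 500)
    got <- select_candidates(el, pk, 100)
    want <- vapply(seq_len(nrow(el)), function(i) {
      (el$end[i] - el$start[i]) > 100 &&
        any(pk$start < el$end[i] & pk$end > el$start[i])
    }, logical(1))
    expect_equal(nrow(got), sum(want))
  }
})

test_that("unmasking restores rows and computes missing fractions", {
  tr <- tree10()
  m <- hky_model()
  full <- simulate_alignment(tr, m, 400, seed = 3, ref = "mouse")
  # plant missing data: bat1 fully absent over [100,200), bat2 30% N
  s <- full$seqs
  substr(s["bat1"], 101, 200) <- strrep("-", 100)
  substr(s["bat2"], 101, 130) <- strrep("N", 30)
  full <- multi_alignment(s, "mouse", "chr1", 0)
  cands <- data.frame(chrom = "chr1", start = 100, end = 200,
                      name = "cand1", score = 1, peak_ids = "p1")
  cs <- unmask_species(cands, full, c("bat1", "bat2", "bat3", "bat4"))
  expect_equal(cs$table$missing_bat1, 1.0)
  expect_equal(cs$table$missing_bat2, 0.30)
  expect_equal(cs$table$missing_bat3, 0.0)
  expect_equal(cs$table$n_focal_present, 3)
  expect_equal(aln_species(cs$alignments[[1]]), aln_species(full))
  expect_error(unmask_species(
    data.frame(chrom = "chr1", start = 300, end = 500, name = "x",
               score = 0, peak_ids = ""), full, "bat1"), "outside")
})

test_that("filters enforce the strict boundary readings as a conjunction", {
  mk_cset <- function(missing, exon_frac_target) {
    tr <- tree10()
    full <- simulate_alignment(tr, hky_model(), 200, seed = 5,
                               ref = "mouse")
    s <- full$seqs
    nmiss <- round(missing * 100)
    if (nmiss > 0) substr(s["bat1"], 51, 50 + nmiss) <- strrep("-", nmiss)
    full <- multi_alignment(s, "mouse", "chr1", 0)
    cands <- data.frame(chrom = "chr1", start = 50, end = 150,
                        name = "cand1", score = 1, peak_ids = "p1")
    unmask_species(cands, full, c("bat1", "bat2", "bat3", "bat4"))
  }
  exons_at <- function(frac)
    data.frame(chrom = "chr1", start = 50, end = 50 + round(100 * frac),
               name = "ex1", score = 0, strand = ".")

  # missing 0.60 dropped, exactly 0.50 retained ("more than 50%")
  expect_equal(nrow(apply_filters(mk_cset(0.60, 0), NULL)$table), 0L)
  expect_equal(nrow(apply_filters(mk_cset(0.50, 0), NULL)$table), 1L)
  # exon 0.30 dropped, exactly 0.25 retained ("more than 25%")
  expect_equal(nrow(apply_filters(mk_cset(0, 0), exons_at(0.30))$table), 0L)
  expect_equal(nrow(apply_filters(mk_cset(0, 0), exons_at(0.25))$table), 1L)
  # zero focal taxa present: dropped
  cs <- mk_cset(0, 0)
  for (sp in c("bat1", "bat2", "bat3", "bat4"))
    cs$table[[paste0("missing_", sp)]] <- 1
  cs$table$n_focal_present <- 0
  f <- apply_filters(cs, NULL)
  expect_equal(nrow(f$table), 0L)
  expect_true("too_few_focal_taxa" %in% f$drop_log$reason ||
                "missing_data" %in% f$drop_log$reason)

  # conjunction: surviving candidates satisfy every predicate regardless
  # of threshold combination
  cs2 <- apply_filters(mk_cset(0.2, 0), exons_at(0.1))
  expect_equal(nrow(cs2$table), 1L)
  expect_true(all(cs2$table$exon_frac <= 0.25))
})
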