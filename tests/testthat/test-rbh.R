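# helper: candidate_set with one candidate at [300,500) of a random genome
rbh_fixture <- function(seed = 1, glen = 4000) {
  set.seed(seed)
  genome <- c(chr1 = random_dna(glen))
  tr <- tree10()
  seqs <- stats::setNames(rep(genome[["chr1"]], 10), tr$tip.label)
  full <- multi_alignment(seqs, "mouse", "chr1", 0)
  cands <- data.frame(chrom = "chr1", start = 300, end = 500,
                      name = "cand1", score = 1, peak_ids = "p1")
  list(genome = genome,
       cset = unmask_species(cands, full, c("bat1", "bat2")),
       cand_seq = substr(genome[["chr1"]], 301, 500))
}

test_that("Karlin-Altschul lambda solves its defining equation", {
  lam <- karlin_lambda(1, -2)
  expect_equal(0.25 * exp(lam) + 0.75 * exp(-2 * lam), 1,
               tolerance = 1e-9)
  expect_gt(lam, 0)
  # e-value decays exponentially in score
  expect_gt(sw_evalue(20, 200, 1e4, lam), sw_evalue(40, 200, 1e4, lam))
})

test_that("an exact-copy contig is integrated with an identical row", {
  fx <- rbh_fixture(2)
  contigs <- c(xbat1.c1 = fx$cand_seq)
  out <- rbh_integrate(fx$cset, contigs, fx$genome)
  expect_equal(out$rbh_log$decision, "integrated")
  expect_equal(out$table$n_taxa_present, out$table$n_focal_present + 1)
  expect_equal(out$alignments[[1]]$seqs[["xbat1"]], fx$cand_seq)
})

test_that("forward/reverse scores are symmetric on an exact copy", {
  fx <- rbh_fixture(3)
  sm <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
  fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(fx$cand_seq),
    Biostrings::DNAString(fx$cand_seq), type = "local",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 2,
    scoreOnly = TRUE)
  rev_hit <- barscan:::.seeded_local(fx$cand_seq, fx$genome[["chr1"]])
  expect_equal(rev_hit$score, fwd)
  expect_equal(rev_hit$start, 300)
  expect_equal(rev_hit$end, 500)
})

test_that("no alignment above threshold leaves the candidate unchanged", {
  fx <- rbh_fixture(4)
  set.seed(99)
  contigs <- c(xbat1.c1 = random_dna(600))
  out <- rbh_integrate(fx$cset, contigs, fx$genome)
  expect_equal(out$rbh_log$decision, "no_forward_hit")
  expect_false("xbat1" %in% aln_species(out$alignments[[1]]))
  # empty database: warning, no-op
  expect_warning(out2 <- rbh_integrate(fx$cset, character(0), fx$genome),
                 "empty contig")
  expect_equal(out2$table$n_taxa_present, out2$table$n_focal_present)
})

test_that("a paralogous decoy whose reverse hit maps elsewhere is rejected", {
  set.seed(5)
  left <- random_dna(1500)
  core <- random_dna(200)
  mid <- random_dna(800)
  right <- random_dna(1300)
  # genome carries two copies of `core`: the candidate locus and a decoy
  # locus; the decoy copy is exact while the candidate locus is mutated,
  # so the contig's best reverse hit is the decoy locus
  m <- subst_model("JC69")
  cand_copy <- evolve_sequence(core, m, 0.08, seed = 6)
  genome <- c(chr1 = paste0(left, cand_copy, mid, core, right))
  tr <- tree10()
  full <- multi_alignment(
    stats::setNames(rep(genome[["chr1"]], 10), tr$tip.label),
    "mouse", "chr1", 0)
  cands <- data.frame(chrom = "chr1", start = 1500, end = 1700,
                      name = "cand1", score = 1, peak_ids = "p1")
  cset <- unmask_species(cands, full, c("bat1", "bat2"))
  out <- rbh_integrate(cset, c(xbat1.c1 = core), genome)
  expect_equal(out$rbh_log$decision, "reverse_hit_elsewhere")
  expect_false("xbat1" %in% aln_species(out$alignments[[1]]))
  # oracle: the reverse best hit indeed lies at the decoy locus
  rh <- barscan:::.seeded_local(core, genome[["chr1"]])
  expect_gte(rh$start, 1500 + 200 + 700)
})
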