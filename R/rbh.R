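# Reciprocal-best-hit integration of extra-genome contigs.
#
# Forward search: Smith-Waterman local alignment (Biostrings) of each
# candidate's reference sequence against every contig of a species; the
# single best hit must reach e <= evalue_max under ungapped Karlin-Altschul
# statistics on the SW score. Reverse search: the winning contig is aligned
# back to the reference genome (exact k-mer seeding to locate the best
# diagonal window, then SW inside it — the same heuristic family BLAST
# uses); the hit is reciprocal iff the reverse top alignment interval
# overlaps the original candidate by >= 1 bp.

#' Karlin-Altschul lambda for a match/mismatch score scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for `lambda > 0`.
#'
#' @param match,mismatch Match and mismatch scores (mismatch < 0).
#' @param bg Background base frequencies.
#' @return The positive root `lambda`.
#' @export
karlin_lambda <- function(match = 1, mismatch = -2, bg = rep(0.25, 4)) {
  p_match <- sum(bg^2)
  f <- function(l) p_match * exp(l * match) +
    (1 - p_match) * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-8, 20), tol = 1e-12)$root
}

#' Ungapped Karlin-Altschul e-value of a local alignment score
#' @param score SW score.
#' @param m,n Query and database lengths.
#' @param lambda From [karlin_lambda()].
#' @param K Karlin-Altschul K (default 0.1; an approximation constant).
#' @return Expected number of chance hits at or above `score`.
#' @export
sw_evalue <- function(score, m, n, lambda, K = 0.1) {
  K * m * n * exp(-lambda * score)
}

.kmer_set <- function(seq, k = 11L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

.sub_matrix <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match,
                                           mismatch = mismatch,
                                           baseOnly = TRUE)
}

# sorted rolling k-mer index of a genome sequence (integer keys base 4)
.genome_kmer_index <- function(genome_seq, k = 11L) {
  code <- .encode_seq(genome_seq)
  n <- length(code)
  if (n < k) return(list(keys = numeric(0), pos = integer(0), k = k))
  nk <- n - k + 1L
  key <- numeric(nk)
  bad <- logical(nk)
  pow <- 4^(0:(k - 1L))
  for (j in 0:(k - 1L)) {
    seg <- code[(1L + j):(nk + j)]
    bad <- bad | seg == 0L
    key <- key + (seg - 1L) * pow[j + 1L]
  }
  key[bad] <- NA_real_
  ord <- order(key, na.last = NA)
  list(keys = key[ord], pos = ord, k = k)
}

# all genome positions (1-based) whose k-mer equals `key`
.kmer_hits <- function(idx, key) {
  lo <- findInterval(key - 0.5, idx$keys) + 1L
  hi <- findInterval(key, idx$keys)
  if (hi < lo) return(integer(0))
  idx$pos[lo:hi]
}

# best seeded local alignment of `query` against one genome sequence.
# `gidx` is the genome's .genome_kmer_index. Returns NULL if no seed
# window is found.
.seeded_local <- function(query, genome_seq, gidx = NULL, stride = 4L,
                          pad = 200L, match = 1, mismatch = -2,
                          gap_open = 5, gap_ext = 2) {
  if (is.null(gidx)) gidx <- .genome_kmer_index(genome_seq)
  k <- gidx$k
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  qcode <- .encode_seq(query)
  pow <- 4^(0:(k - 1L))
  nk <- qlen - k + 1L
  qkey <- numeric(nk); qbad <- logical(nk)
  for (j in 0:(k - 1L)) {
    seg <- qcode[(1L + j):(nk + j)]
    qbad <- qbad | seg == 0L
    qkey <- qkey + (seg - 1L) * pow[j + 1L]
  }
  offs <- seq(1L, nk, by = stride)
  offs <- offs[!qbad[offs]]
  if (!length(offs)) return(NULL)
  hi <- findInterval(qkey[offs], gidx$keys)
  lo <- findInterval(qkey[offs] - 0.5, gidx$keys) + 1L
  hit <- which(hi >= lo)
  if (!length(hit)) return(NULL)
  diag_pos <- unlist(lapply(hit, function(i)
    gidx$pos[lo[i]:hi[i]] - offs[i]), use.names = FALSE)
  if (length(diag_pos) < 2L) return(NULL)
  # bin diagonals; pick the most-supported one
  bin <- round(diag_pos / 50)
  best_bin <- as.integer(names(which.max(table(bin))))
  d <- diag_pos[bin == best_bin]
  w0 <- max(1L, min(d) + 1L - pad)
  w1 <- min(nchar(genome_seq), max(d) + qlen + pad)
  win <- substr(genome_seq, w0, w1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(win),
    type = "local", substitutionMatrix = .sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  list(score = Biostrings::score(al),
       start = w0 - 1L + Biostrings::start(Biostrings::subject(al)) - 1L,
       end = w0 - 1L + Biostrings::end(Biostrings::subject(al)))
}

# project the aligned contig segment onto candidate alignment columns
.project_row <- function(cand_aln, al) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  p0 <- Biostrings::start(Biostrings::pattern(al))   # 1-based in cand ref seq
  row_ref <- rep("-", ref_length(cand_aln))
  p <- p0
  for (i in seq_along(pat)) {
    if (pat[i] != "-") {
      row_ref[p] <- if (sub[i] == "-") "-" else sub[i]
      p <- p + 1L
    }
    # contig insertions relative to the reference are dropped
  }
  ref_chars <- strsplit(cand_aln$seqs[[cand_aln$ref]], "")[[1]]
  out <- rep("-", cand_aln$width)
  out[ref_chars != "-"] <- row_ref
  paste(out, collapse = "")
}

#' Integrate extra-genome contigs by reciprocal best hit
#'
#' For each candidate and each contig species, finds the best-scoring
#' local alignment of the candidate's reference sequence across that
#' species' contigs. If it passes `evalue_max` and its reverse best hit
#' against the reference genome overlaps the original candidate interval
#' by at least one base, the contig segment is added to the candidate's
#' alignment as a new species row (projected onto reference columns;
#' contig insertions are dropped). Decisions are logged per
#' candidate-species pair.
#'
#' Contig species are taken from the part of each contig name before the
#' first `.` (the same convention the MAF reader uses).
#'
#' @param cset A `candidate_set` from [unmask_species()].
#' @param contigs Named character vector of contig sequences
#'   (`species.contigid` names); empty set is a no-op with a warning.
#' @param genome Named character vector of reference chromosome sequences.
#' @param evalue_max Forward-hit e-value threshold (default 0.01; hits at
#'   exactly the threshold are accepted).
#' @param species Optional restriction to these contig species; other
#'   contigs are ignored.
#' @param match,mismatch,gap_open,gap_ext SW scoring scheme.
#' @param K Karlin-Altschul K for [sw_evalue()].
#' @return The `candidate_set` with integrated rows, an updated
#'   `n_taxa_present` column, and an `rbh_log` data frame (candidate,
#'   species, decision).
#' @export
rbh_integrate <- function(cset, contigs, genome, evalue_max = 0.01,
                          species = NULL, match = 1, mismatch = -2,
                          gap_open = 5, gap_ext = 2, K = 0.1) {
  stopifnot(inherits(cset, "candidate_set"))
  tab <- cset$table
  if (!is.null(species))
    contigs <- contigs[sub("\\..*$", "", names(contigs)) %in% species]
  if (!length(contigs)) {
    warning("empty contig database; candidates unchanged")
    cset$rbh_log <- data.frame(candidate = character(0),
                               species = character(0),
                               decision = character(0))
    tab$n_taxa_present <- tab$n_focal_present
    cset$table <- tab
    return(cset)
  }
  lam <- karlin_lambda(match, mismatch)
  sp_of <- sub("\\..*$", "", names(contigs))
  species <- unique(sp_of)
  added <- matrix(FALSE, nrow(tab), length(species),
                  dimnames = list(tab$name, species))
  log <- list()
  sub_mat <- .sub_matrix(match, mismatch)
  gidx_cache <- list()

  cand_seqs <- vapply(cset$alignments, ref_sequence, character(1))
  cand_kmers <- lapply(cand_seqs, .kmer_set)
  for (sp in species) {
    db <- contigs[sp_of == sp]
    n_db <- sum(nchar(db))
    db_kmers <- lapply(db, .kmer_set)
    # forward scores: candidate-contig pairs sharing >= 2 exact 11-mers
    # (seed prescreen), each contig's survivors in one vectorized C call
    scores <- matrix(-Inf, nrow(tab), length(db))
    if (nrow(tab)) {
      for (j in seq_along(db)) {
        cand_idx <- which(vapply(cand_kmers, function(ks)
          sum(ks %in% db_kmers[[j]]) >= 2L, logical(1)))
        if (!length(cand_idx)) next
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAStringSet(cand_seqs[cand_idx]),
          Biostrings::DNAString(db[[j]]), type = "local",
          substitutionMatrix = sub_mat, gapOpening = gap_open,
          gapExtension = gap_ext, scoreOnly = TRUE)
        scores[cand_idx, j] <- al
      }
    }
    for (i in seq_len(nrow(tab))) {
      j_best <- which.max(scores[i, ])
      ev <- sw_evalue(scores[i, j_best], nchar(cand_seqs[i]), n_db, lam, K)
      if (!is.finite(ev) || ev > evalue_max) {
        log[[length(log) + 1L]] <- c(tab$name[i], sp, "no_forward_hit")
        next
      }
      # reverse: contig back to the genome
      gseq <- genome[[tab$chrom[i]]]
      if (!is.null(gseq) && is.null(gidx_cache[[tab$chrom[i]]]))
        gidx_cache[[tab$chrom[i]]] <- .genome_kmer_index(gseq)
      rev_hit <- if (is.null(gseq)) NULL else
        .seeded_local(db[[j_best]], gseq, gidx_cache[[tab$chrom[i]]],
                      match = match, mismatch = mismatch,
                      gap_open = gap_open, gap_ext = gap_ext)
      ok <- !is.null(rev_hit) &&
        rev_hit$start < tab$end[i] && rev_hit$end > tab$start[i]
      if (!ok) {
        log[[length(log) + 1L]] <- c(tab$name[i], sp, "reverse_hit_elsewhere")
        next
      }
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cand_seqs[i]),
        Biostrings::DNAString(db[[j_best]]), type = "local",
        substitutionMatrix = sub_mat, gapOpening = gap_open,
        gapExtension = gap_ext)
      row <- .project_row(cset$alignments[[i]], al)
      cset$alignments[[i]] <- add_species(cset$alignments[[i]], sp, row)
      added[i, sp] <- TRUE
      log[[length(log) + 1L]] <- c(tab$name[i], sp, "integrated")
    }
  }
  tab$n_taxa_present <- tab$n_focal_present + rowSums(added)
  cset$table <- tab
  cset$rbh_log <- as.data.frame(do.call(rbind, log),
                                stringsAsFactors = FALSE)
  if (nrow(cset$rbh_log))
    names(cset$rbh_log) <- c("candidate", "species", "decision")
  cset
}
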