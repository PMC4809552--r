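# Candidate enhancer construction: peak union, intersection with merged
# conserved elements, focal-sequence restoration, and the missing-data /
# exon-overlap / taxa filters. Interval algebra is delegated to IRanges
# (intervals are 0-based half-open in all data frames; converted at the
# IRanges boundary).

.iranges <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

#' Union of peak interval sets
#'
#' Collapses any number of BED-style interval sets into their disjoint,
#' sorted base-level union per chromosome.
#'
#' @param ... Interval data frames (`chrom,start,end,...`), or a single
#'   list of them.
#' @return Data frame `chrom,start,end,name,score,strand` of disjoint
#'   intervals named `peak1, peak2, ...`.
#' @export
union_peaks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  all <- do.call(rbind, lapply(sets, function(d) d[c("chrom", "start", "end")]))
  if (!nrow(all)) stop("no peaks given")
  parts <- split(all, all$chrom)
  out <- do.call(rbind, lapply(names(parts), function(ch) {
    r <- IRanges::reduce(.iranges(parts[[ch]]))
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("peak%d", seq_len(nrow(out)))
  out$score <- 0
  out$strand <- "."
  rownames(out) <- NULL
  out
}

# fraction of each interval in `a` covered by the base-level union of `b`
overlap_fraction <- function(a, b) {
  out <- numeric(nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(bi)) next
    ra <- .iranges(a[ai, , drop = FALSE])
    rb <- IRanges::reduce(.iranges(bi))
    ov <- IRanges::findOverlaps(ra, rb)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(
      ra[S4Vectors::queryHits(ov)], rb[S4Vectors::subjectHits(ov)]))
    cov <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[ai[as.integer(names(cov))]] <- as.numeric(cov)
  }
  out / (a$end - a$start)
}

#' Intersect merged elements with peaks to form candidates
#'
#' Retains merged conserved elements strictly longer than `min_length`
#' that overlap at least one peak by at least one base, recording the
#' contributing peak ids.
#'
#' @param merged Merged element data frame (`chrom,start,end,name,score`).
#' @param peaks Peak data frame (typically from [union_peaks()]).
#' @param min_length Length threshold; elements of exactly this length are
#'   excluded (strictly greater survives).
#' @return Data frame of candidates with a `peak_ids` column
#'   (comma-separated), renamed `cand1, cand2, ...`.
#' @export
select_candidates <- function(merged, peaks, min_length = 100) {
  if (!nrow(merged)) return(cbind(merged, peak_ids = character(0)))
  long <- merged[(merged$end - merged$start) > min_length, , drop = FALSE]
  if (!nrow(long)) {
    out <- long; out$peak_ids <- character(0); return(out)
  }
  keep <- logical(nrow(long))
  pid <- character(nrow(long))
  for (ch in unique(long$chrom)) {
    ai <- which(long$chrom == ch)
    bi <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(bi)) next
    ov <- IRanges::findOverlaps(.iranges(long[ai, , drop = FALSE]),
                                .iranges(bi))
    if (!length(ov)) next
    hits <- split(bi$name[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    for (nm in names(hits)) {
      i <- ai[as.integer(nm)]
      keep[i] <- TRUE
      pid[i] <- paste(hits[[nm]], collapse = ",")
    }
  }
  out <- long[keep, , drop = FALSE]
  out$peak_ids <- pid[keep]
  out$name <- sprintf("cand%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Restore masked species and slice candidate alignments
#'
#' For each candidate interval, extracts the alignment slice from the full
#' (unmasked) blocks, restoring the focal species that detection was blind
#' to, and computes the per-focal-species missing fraction (gap or `N`
#' columns over candidate width; a species absent from the block scores 1).
#'
#' @param candidates Candidate data frame from [select_candidates()].
#' @param blocks A `multi_alignment` or list of blocks covering the
#'   candidates (with focal rows intact).
#' @param species Focal species to track missing fractions for.
#' @return An object of class `candidate_set`: list with `table` (the
#'   candidate data frame plus `missing_<species>` and `n_focal_present`
#'   columns) and `alignments` (named list of `multi_alignment` slices).
#' @export
unmask_species <- function(candidates, blocks, species) {
  if (inherits(blocks, "multi_alignment")) blocks <- list(blocks)
  tab <- candidates
  alns <- vector("list", nrow(tab))
  names(alns) <- tab$name
  mis <- matrix(1, nrow(tab), length(species),
                dimnames = list(tab$name, species))
  for (i in seq_len(nrow(tab))) {
    blk <- NULL
    for (b in blocks) {
      if (b$chrom == tab$chrom[i] && tab$start[i] >= b$start &&
          tab$end[i] <= b$start + ref_length(b)) { blk <- b; break }
    }
    if (is.null(blk))
      stop("candidate ", tab$name[i], " outside all alignment blocks")
    sl <- aln_window(blk, tab$start[i], tab$end[i])
    alns[[i]] <- sl
    for (sp in species) mis[i, sp] <- missing_fraction(sl, sp)
  }
  for (sp in species) tab[[paste0("missing_", sp)]] <- mis[, sp]
  tab$n_focal_present <- rowSums(mis < 1)
  structure(list(table = tab, alignments = alns, focal = species),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidate(s), focal species: %s\n",
              nrow(x$table), paste(x$focal, collapse = ", ")))
  invisible(x)
}

#' Missing-data, exon-overlap and taxa filters
#'
#' Applies the three candidate filters as a conjunction: drop if any focal
#' alignment species has strictly more than `max_missing` missing sequence,
#' if strictly more than `max_exon_frac` of reference bases overlap a
#' coding exon, or if fewer than `min_bats` focal taxa (alignment species
#' plus integrated contig species) are present. Boundary values are
#' retained (the thresholds are strict "more than" readings).
#'
#' @param cset A `candidate_set` from [unmask_species()] (after optional
#'   [rbh_integrate()]).
#' @param exons Exon interval data frame (may be empty).
#' @param max_missing Maximum tolerated missing fraction per focal
#'   alignment species (default 0.5).
#' @param max_exon_frac Maximum tolerated exonic fraction (default 0.25).
#' @param min_bats Minimum focal taxa present (default 1).
#' @return A `candidate_set` of survivors; dropped candidates and their
#'   reasons are attached as the `drop_log` element (data frame
#'   name/reason).
#' @export
apply_filters <- function(cset, exons, max_missing = 0.5,
                          max_exon_frac = 0.25, min_bats = 1) {
  stopifnot(inherits(cset, "candidate_set"))
  tab <- cset$table
  if (!nrow(tab)) {
    cset$drop_log <- data.frame(name = character(0), reason = character(0))
    return(cset)
  }
  mis_cols <- paste0("missing_", cset$focal)
  mis <- as.matrix(tab[mis_cols])
  too_missing <- apply(mis, 1, function(z) any(z > max_missing))
  exon_frac <- if (!is.null(exons) && nrow(exons))
    overlap_fraction(tab, exons) else numeric(nrow(tab))
  tab$exon_frac <- exon_frac
  too_exonic <- exon_frac > max_exon_frac
  present <- if ("n_taxa_present" %in% names(tab)) tab$n_taxa_present
             else tab$n_focal_present
  too_few <- present < min_bats
  drop <- too_missing | too_exonic | too_few
  reason <- character(nrow(tab))
  reason[too_few] <- "too_few_focal_taxa"
  reason[too_exonic] <- "exon_overlap"
  reason[too_missing] <- "missing_data"   # first predicate wins in the log
  cset$drop_log <- data.frame(name = tab$name[drop], reason = reason[drop],
                              stringsAsFactors = FALSE)
  cset$table <- tab[!drop, , drop = FALSE]
  cset$alignments <- cset$alignments[tab$name[!drop]]
  rownames(cset$table) <- NULL
  cset
}
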