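#' Multiple alignment block referenced to one genome
#'
#' A light container for one alignment block: named gapped sequences over
#' the alphabet `{A,C,G,T,-,N}` plus the reference species and its
#' coordinates (0-based start, half-open intervals downstream). Rows must
#' have equal width. `-` and `N` are both treated as missing data by every
#' likelihood computation.
#'
#' @param seqs Named character vector of equal-width gapped sequences.
#' @param ref Name of the reference species (must be a row).
#' @param chrom Reference chromosome/contig name.
#' @param start 0-based reference start of the block.
#' @param strand `"+"` or `"-"` (reference strand; `"+"` in practice).
#' @return An object of class `multi_alignment`.
#' @export
multi_alignment <- function(seqs, ref, chrom = "chr1", start = 0L,
                            strand = "+") {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all alignment rows must be named by species")
  if (anyDuplicated(names(seqs)))
    stop("duplicate species in alignment")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("alignment rows differ in width")
  if (!ref %in% names(seqs)) stop("reference species not in alignment: ", ref)
  structure(list(seqs = seqs, ref = ref, chrom = chrom,
                 start = as.integer(start), strand = strand, width = w),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("multi_alignment: %d species x %d columns, %s:%d-%d (ref %s)\n",
              length(x$seqs), x$width, x$chrom, x$start,
              x$start + ref_length(x), x$ref))
  invisible(x)
}

#' Number of reference (non-gap) bases in a block
#' @param aln A `multi_alignment`.
#' @return Integer count of non-gap reference positions.
#' @export
ref_length <- function(aln) {
  nchar(gsub("-", "", aln$seqs[[aln$ref]], fixed = TRUE))
}

#' Species present in an alignment block
#' @param aln A `multi_alignment`.
#' @return Character vector of row names.
#' @export
aln_species <- function(aln) names(aln$seqs)

# integer code matrix (species x columns): 0 missing, 1..4 = A,C,G,T
aln_codes <- function(aln, species = aln_species(aln)) {
  m <- do.call(rbind, lapply(aln$seqs[species], .encode_seq))
  rownames(m) <- species
  m
}

# 0-based reference coordinate carried by each column; columns where the
# reference is gapped inherit the preceding reference position (clamped to
# the block start for leading gaps).
column_ref_pos <- function(aln) {
  ref <- strsplit(aln$seqs[[aln$ref]], "")[[1]]
  idx <- cumsum(ref != "-")
  pmax(idx - 1L, 0L) + aln$start
}

#' Remove species rows from an alignment
#'
#' Drops the listed species (those absent are ignored); reference
#' coordinates are unchanged. Used to mask the focal clade before
#' conserved-element detection so that focal-lineage divergence cannot
#' suppress conservation calls.
#'
#' @param aln A `multi_alignment`.
#' @param species Character vector of species to drop.
#' @return A `multi_alignment` without the listed rows.
#' @export
mask_species <- function(aln, species) {
  if (aln$ref %in% species) stop("cannot mask the reference species")
  keep <- setdiff(aln_species(aln), species)
  multi_alignment(aln$seqs[keep], aln$ref, aln$chrom, aln$start, aln$strand)
}

#' Extract the columns covering a reference interval
#'
#' @param aln A `multi_alignment`.
#' @param start,end 0-based half-open reference interval; must lie inside
#'   the block.
#' @param species Optional subset of rows to keep.
#' @return A `multi_alignment` for the sub-interval.
#' @export
aln_window <- function(aln, start, end, species = aln_species(aln)) {
  if (start < aln$start || end > aln$start + ref_length(aln) || end <= start)
    stop("interval [", start, ",", end, ") outside alignment block")
  refseq <- aln$seqs[[aln$ref]]
  if (!grepl("-", refseq, fixed = TRUE)) {
    # ungapped reference: columns map 1:1 to reference positions
    c0 <- start - aln$start + 1L
    c1 <- end - aln$start
    seqs <- vapply(aln$seqs[species], substr, character(1), c0, c1)
  } else {
    ref <- strsplit(refseq, "")[[1]]
    pos <- cumsum(ref != "-") - 1L + aln$start   # ref pos at non-gap cols
    pos[ref == "-"] <- NA_integer_
    keep_cols <- which(!is.na(pos) & pos >= start & pos < end)
    # include reference-gap columns interior to the selected range
    cols <- seq(min(keep_cols), max(keep_cols))
    seqs <- vapply(aln$seqs[species],
                   function(s) paste(strsplit(s, "")[[1]][cols],
                                     collapse = ""),
                   character(1))
  }
  multi_alignment(seqs, aln$ref, aln$chrom, as.integer(start), aln$strand)
}

#' Ungapped reference sequence of a block
#' @param aln A `multi_alignment`.
#' @return Character string of reference bases with gaps removed.
#' @export
ref_sequence <- function(aln) {
  gsub("-", "", aln$seqs[[aln$ref]], fixed = TRUE)
}

#' Fraction of missing (gap or N) columns for one species
#' @param aln A `multi_alignment`.
#' @param species Species name; a species absent from the block has
#'   missing fraction 1.
#' @return Numeric in `[0, 1]`.
#' @export
missing_fraction <- function(aln, species) {
  if (!species %in% aln_species(aln)) return(1)
  mean(.encode_seq(aln$seqs[[species]]) == 0L)
}

#' Add (or replace) a species row
#' @param aln A `multi_alignment`.
#' @param species Row name.
#' @param seq Gapped sequence of the block's width.
#' @return A `multi_alignment`.
#' @export
add_species <- function(aln, species, seq) {
  if (nchar(seq) != aln$width) stop("new row width mismatch")
  seqs <- aln$seqs
  seqs[[species]] <- seq
  multi_alignment(seqs, aln$ref, aln$chrom, aln$start, aln$strand)
}
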