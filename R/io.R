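#' Read alignment blocks from a MAF file
#'
#' Parses the plain-text MAF format (one `a` line per block, `s` lines with
#' `src start size strand srcSize text`). The first `s` line of each block
#' is taken as the reference row; species names are the part of `src`
#' before the first `.`, the reference chromosome the part after it.
#' Starts are 0-based per the MAF specification.
#'
#' @param path Path to a MAF file.
#' @return A list of [multi_alignment()] blocks.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !length(cur$seqs)) return(NULL)
    multi_alignment(cur$seqs, cur$ref, cur$chrom, cur$start, cur$strand)
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list(seqs = character(0))
    } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L) stop("malformed MAF 's' line: ", ln)
      src <- f[2]
      sp <- sub("\\..*$", "", src)
      if (!length(cur$seqs)) {        # reference row
        cur$ref <- sp
        cur$chrom <- if (grepl(".", src, fixed = TRUE))
          sub("^[^.]*\\.", "", src) else "chr1"
        cur$start <- as.integer(f[3])
        cur$strand <- f[5]
      }
      cur$seqs[sp] <- toupper(f[7])
    }
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  if (!length(blocks)) stop("no alignment blocks found in ", path)
  blocks
}

#' Write alignment blocks to a MAF file
#' @param blocks A `multi_alignment` or list of them.
#' @param path Output path.
#' @export
write_maf <- function(blocks, path) {
  if (inherits(blocks, "multi_alignment")) blocks <- list(blocks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (aln in blocks) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    sp <- c(aln$ref, setdiff(aln_species(aln), aln$ref))
    for (s in sp) {
      seq <- aln$seqs[[s]]
      ung <- nchar(gsub("-", "", seq, fixed = TRUE))
      if (s == aln$ref) {
        writeLines(sprintf("s %s.%s %d %d %s %d %s", s, aln$chrom, aln$start,
                           ung, aln$strand, aln$start + ung, seq), con)
      } else {
        writeLines(sprintf("s %s 0 %d + %d %s", s, ung, ung, seq), con)
      }
    }
  }
  invisible(path)
}

#' Read a BED file into a data frame
#'
#' Accepts 3 to 6 columns (`chrom start end name score strand`); missing
#' columns are filled with defaults. Coordinates are 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `chrom,start,end,name,score,strand`.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("cannot read BED file ", path, ": ",
                             conditionMessage(e)))
  ncol_in <- ncol(df)
  names(df)[seq_len(min(6, ncol_in))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol_in))]
  if (ncol_in < 4L) df$name <- paste0("r", seq_len(nrow(df)))
  if (ncol_in < 5L) df$score <- 0
  if (ncol_in < 6L) df$strand <- "."
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$end <= df$start |
                 df$start < 0)
  if (length(bad))
    stop("malformed BED record at line ", bad[1], " of ", path)
  df[c("chrom", "start", "end", "name", "score", "strand")]
}

#' Write intervals to a BED6 file
#' @param df Data frame with at least `chrom,start,end`.
#' @param path Output path.
#' @param score_digits Decimal places kept for the score column.
#' @export
write_bed <- function(df, path, score_digits = 2) {
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else paste0("r", seq_len(nrow(df))),
    score = if ("score" %in% names(df)) round(df$score, score_digits) else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (uppercase).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
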