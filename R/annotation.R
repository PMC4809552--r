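# Post-hoc characterization of called regions: TSS distances, gene
# deserts, spatial clustering, and gene-proximity enrichment.

#' Distance from an element to the nearest TSS
#'
#' Zero if a TSS falls inside the (half-open) element, otherwise the
#' number of bases between the TSS and the nearest element edge (the TSS
#' occupies the single base `[p, p+1)`, so distances are symmetric under
#' coordinate reflection). Vectorized over elements; elements on
#' chromosomes with no TSS get `Inf`.
#'
#' @param elements Interval data frame (`chrom,start,end`).
#' @param tss TSS data frame (`chrom,start,end`); the 0-based `start` is
#'   the site position.
#' @return Numeric vector of distances in bp.
#' @export
tss_distance <- function(elements, tss) {
  out <- rep(Inf, nrow(elements))
  for (ch in unique(elements$chrom)) {
    idx <- which(elements$chrom == ch)
    pos <- tss$start[tss$chrom == ch]
    if (!length(pos)) next
    for (i in idx) {
      s <- elements$start[i]; e <- elements$end[i]
      d <- ifelse(pos >= s & pos < e, 0,
                  ifelse(pos < s, s - pos - 1, pos - e))
      out[i] <- min(d)
    }
  }
  out
}

#' Gene-desert flag
#'
#' `TRUE` iff no TSS lies within `radius` on either side of the element
#' (strictly: the nearest TSS in each direction, if any, is more than
#' `radius` away; a TSS inside the element means not a desert).
#'
#' @param elements Interval data frame.
#' @param tss TSS data frame.
#' @param radius Desert radius in bp (default 5e5).
#' @return Logical vector.
#' @export
gene_desert_flag <- function(elements, tss, radius = 5e5) {
  out <- logical(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    pos <- tss$start[tss$chrom == elements$chrom[i]]
    s <- elements$start[i]; e <- elements$end[i]
    if (any(pos >= s & pos < e)) { out[i] <- FALSE; next }
    up <- pos[pos < s]
    dn <- pos[pos >= e]
    near_up <- length(up) && (s - max(up) - 1) <= radius
    near_dn <- length(dn) && (min(dn) - e) <= radius
    out[i] <- !near_up && !near_dn
  }
  out
}

.midpoints <- function(df) (df$start + df$end) / 2

# median same-chromosome nearest-neighbor midpoint distance
.clustering_stat <- function(df) {
  nn <- c()
  for (ch in unique(df$chrom)) {
    m <- sort(.midpoints(df[df$chrom == ch, , drop = FALSE]))
    if (length(m) < 2) next
    gaps <- diff(m)
    nn <- c(nn, pmin(c(Inf, gaps), c(gaps, Inf)))
  }
  if (!length(nn)) return(NA_real_)
  stats::median(nn)
}

# count of same-chromosome midpoint pairs within `d`
.pairs_within_stat <- function(df, d = 1e5) {
  cnt <- 0
  for (ch in unique(df$chrom)) {
    m <- .midpoints(df[df$chrom == ch, , drop = FALSE])
    if (length(m) < 2) next
    cnt <- cnt + sum(abs(outer(m, m, "-"))[upper.tri(diag(length(m)))] <= d)
  }
  cnt
}

#' Spatial clustering permutation test
#'
#' Tests whether called regions cluster more densely than random
#' same-sized draws from the candidate pool. The default statistic is the
#' median same-chromosome nearest-neighbor midpoint distance (smaller =
#' more clustered); `statistic = "pairs_within"` counts midpoint pairs
#' within `pair_dist` (larger = more clustered). The p-value uses the
#' add-one rule, so it is never exactly zero.
#'
#' @param bars Called-region data frame (a subset of `candidates`).
#' @param candidates Candidate pool data frame.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param statistic `"median_nn"` (default) or `"pairs_within"`.
#' @param pair_dist Distance for `"pairs_within"` (default 1e5).
#' @return List with `p`, `observed`, `null` (vector of permuted
#'   statistics) and `statistic`.
#' @export
clustering_permutation_test <- function(bars, candidates, n_perm = 1000,
                                        seed = NULL,
                                        statistic = c("median_nn",
                                                      "pairs_within"),
                                        pair_dist = 1e5) {
  statistic <- match.arg(statistic)
  if (nrow(bars) < 2) stop("need at least two called regions")
  stat_fun <- if (statistic == "median_nn") .clustering_stat else
    function(d) .pairs_within_stat(d, pair_dist)
  obs <- stat_fun(bars)
  k <- nrow(bars)
  null <- .with_seed(seed, vapply(seq_len(n_perm), function(b) {
    stat_fun(candidates[sample.int(nrow(candidates), k), , drop = FALSE])
  }, numeric(1)))
  extreme <- if (statistic == "median_nn") null <= obs else null >= obs
  p <- (1 + sum(extreme, na.rm = TRUE)) / (n_perm + 1)
  list(p = p, observed = obs, null = null, statistic = statistic)
}

#' Gene-proximity enrichment of called regions
#'
#' Classifies every candidate as near (within `window` of any listed TSS)
#' or far, forms the 2x2 called-by-near table, reports the odds ratio
#' (Haldane-Anscombe 0.5 correction when any cell is zero) and a
#' resampling p-value: random candidate subsets of the called size,
#' counting how often they contain at least as many near elements.
#'
#' @param bars Called-region data frame (subset of `candidates`,
#'   matched by `chrom,start,end`).
#' @param candidates Candidate pool data frame.
#' @param gene_tss TSS data frame for the gene list of interest.
#' @param window Proximity window in bp (default 1e6).
#' @param n_perm Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return An object of class `enrichment_result`: list with `table`
#'   (2x2), `odds_ratio`, `p`, `n_perm`.
#' @export
proximity_enrichment <- function(bars, candidates, gene_tss, window = 1e6,
                                 n_perm = 1000, seed = NULL) {
  if (!nrow(gene_tss)) stop("empty gene list")
  key <- function(d) paste(d$chrom, d$start, d$end)
  is_bar <- key(candidates) %in% key(bars)
  if (!any(is_bar)) stop("no called regions found in the candidate pool")
  near <- is.finite(tss_distance(candidates, gene_tss)) &
    tss_distance(candidates, gene_tss) <= window
  a <- sum(is_bar & near);  b <- sum(is_bar & !near)
  c_ <- sum(!is_bar & near); d <- sum(!is_bar & !near)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  k <- sum(is_bar)
  null <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sum(near[sample.int(length(near), k)])
  }, numeric(1)))
  p <- (1 + sum(null >= a)) / (n_perm + 1)
  structure(list(table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                                dimnames = list(c("called", "not_called"),
                                                c("near", "far"))),
                 odds_ratio = or, p = p, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("proximity enrichment: OR = %.3f, p = %.4g (%d resamples)\n",
              x$odds_ratio, x$p, x$n_perm))
  print(x$table)
  invisible(x)
}

#' Text summary of called-region annotation
#'
#' Reproduces the usual summary-statistic style: fractions beyond 20 kb
#' and 100 kb of the nearest TSS, mean length and gene-desert count.
#'
#' @param bars Called-region data frame.
#' @param tss TSS data frame.
#' @param desert_radius Gene-desert radius (default 5e5).
#' @return Character vector of report lines (invisibly printed by
#'   callers); also returned as an attribute-free value for writing.
#' @export
annotation_report <- function(bars, tss, desert_radius = 5e5) {
  d <- tss_distance(bars, tss)
  desert <- gene_desert_flag(bars, tss, desert_radius)
  c(sprintf("called regions: %d", nrow(bars)),
    sprintf("mean length: %.1f bp", mean(bars$end - bars$start)),
    sprintf("fraction > 20 kb from nearest TSS: %.3f", mean(d > 2e4)),
    sprintf("fraction > 100 kb from nearest TSS: %.3f", mean(d > 1e5)),
    sprintf("gene deserts (> %g bp both sides): %d", desert_radius,
            sum(desert)))
}
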