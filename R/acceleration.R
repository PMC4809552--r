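#' Ancestral-branch acceleration likelihood ratio test
#'
#' Tests one candidate alignment for accelerated substitution on the stem
#' edge of a focal clade (its "ancestral lineage"). The null model fixes
#' the stem scale at 1 (the neutral model); the alternative frees a single
#' multiplicative scale `lambda >= 1` on that edge only (one-sided
#' acceleration). The statistic `D = 2 (lnL_alt - lnL_null)` is referred to
#' the boundary null `0.5 * delta_0 + 0.5 * chi^2_1`: `p = 1` when the
#' estimate sits at the boundary and `p = 0.5 * P(chi^2_1 >= D)` otherwise.
#'
#' Optionally a parametric bootstrap p-value is computed by simulating
#' `n_boot` null alignments of the same size and recomputing `D`.
#'
#' @param aln A [multi_alignment()] (or alignment input accepted by
#'   [prune_loglik()]).
#' @param tree A `phylo` object in which the focal clade is monophyletic.
#' @param model The neutral [subst_model()].
#' @param focal_clade Character vector of focal leaf names; at least one
#'   must be present (non-missing) in the alignment.
#' @param upper Upper bound of the `lambda` search (default 100).
#' @param n_boot Parametric bootstrap replicates (0 = analytic p only).
#' @param seed Seed for the bootstrap.
#' @param id Candidate identifier carried into the result.
#' @return An object of class `accel_test`: list with `id`, `lnl_null`,
#'   `lnl_alt`, `lambda_hat`, `D`, `p` (and `p_boot` if requested).
#' @export
acceleration_test <- function(aln, tree, model, focal_clade, upper = 100,
                              n_boot = 0, seed = NULL, id = "candidate") {
  stem <- clade_stem_edge(tree, focal_clade)   # checks monophyly
  codes <- .tip_code_matrix(aln, tree)
  present <- intersect(focal_clade, tree$tip.label)
  if (!any(rowSums(codes[present, , drop = FALSE] > 0L) > 0))
    stop("no focal-clade leaf with data in the alignment")
  fit <- fit_branch_scale(tree, model, codes, stem, lower = 1, upper = upper)
  lnl0 <- fit$loglik_lower
  D <- 2 * (fit$loglik - lnl0)
  D <- max(D, 0)
  p <- if (D <= 1e-10) 1 else 0.5 * stats::pchisq(D, df = 1,
                                                  lower.tail = FALSE)
  res <- list(id = id, lnl_null = lnl0, lnl_alt = fit$loglik,
              lambda_hat = fit$lambda, D = D, p = p)
  if (n_boot > 0) {
    Dsim <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
      sim <- simulate_alignment(tree, model, ncol(codes))
      fb <- fit_branch_scale(tree, model, sim, stem, lower = 1,
                             upper = upper)
      max(0, 2 * (fb$loglik - fb$loglik_lower))
    }, numeric(1)))
    res$p_boot <- (1 + sum(Dsim >= D)) / (n_boot + 1)
  }
  structure(res, class = "accel_test")
}

#' @export
print.accel_test <- function(x, ...) {
  cat(sprintf("acceleration LRT [%s]: lambda_hat = %.3f, D = %.3f, p = %.4g\n",
              x$id, x$lambda_hat, x$D, x$p))
  invisible(x)
}

#' Run the acceleration test over a candidate set
#'
#' @param cset A `candidate_set` (alignments with focal rows restored and
#'   any contig rows integrated).
#' @param tree The test tree (with grafted contig species, if any).
#' @param model The neutral [subst_model()].
#' @param focal_clade Focal leaf names (alignment species plus grafted
#'   contig species).
#' @param upper Upper bound of the `lambda` search.
#' @return Data frame with one row per candidate: `id, chrom, start, end,
#'   lnl_null, lnl_alt, lambda_hat, D, p`.
#' @export
test_candidates <- function(cset, tree, model, focal_clade, upper = 100) {
  stopifnot(inherits(cset, "candidate_set"))
  tab <- cset$table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- acceleration_test(cset$alignments[[i]], tree, model, focal_clade,
                           upper = upper, id = tab$name[i])
    data.frame(id = r$id, chrom = tab$chrom[i], start = tab$start[i],
               end = tab$end[i], lnl_null = r$lnl_null,
               lnl_alt = r$lnl_alt, lambda_hat = r$lambda_hat, D = r$D,
               p = r$p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), lnl_null = numeric(0), lnl_alt = numeric(0),
               lambda_hat = numeric(0), D = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}

#' False discovery rate adjustment
#'
#' Benjamini-Hochberg step-up q-values (default), or Benjamini-Yekutieli
#' via `method = "BY"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"BY"`.
#' @return Vector of q-values, capped at 1.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Call accelerated regions at an FDR threshold
#'
#' Adds `q` (via [bh_fdr()]) and the strict `is_bar = q < fdr_threshold`
#' flag to an acceleration result table; a q-value exactly at the
#' threshold is not called.
#'
#' @param results Data frame from [test_candidates()] (needs a `p` column).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param method FDR method passed to [bh_fdr()].
#' @return The table with `q` and `is_bar` columns.
#' @export
call_bars <- function(results, fdr_threshold = 0.05, method = "BH") {
  results$q <- if (nrow(results)) bh_fdr(results$p, method) else numeric(0)
  results$is_bar <- results$q < fdr_threshold
  results
}
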