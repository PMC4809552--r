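#' Parameters of the two-state conservation phylo-HMM
#'
#' The HMM has a neutral state (branch scales 1) and a conserved state in
#' which every branch is scaled by `rho < 1`. Transition probabilities are
#' derived from expected element and spacer lengths: the probability of
#' leaving the conserved state is `mu = 1/L_c`, of entering it `nu = 1/L_n`.
#' Parameters are fixed per run; no EM re-estimation is performed.
#'
#' @param rho Conserved rate scale, in (0, 1). Default 0.3.
#' @param L_c Expected conserved element length in bp (default 100).
#' @param L_n Expected neutral spacer length in bp (default 1000).
#' @return An object of class `phylo_hmm_params`.
#' @export
phylo_hmm_params <- function(rho = 0.3, L_c = 100, L_n = 1000) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1) stop("'rho' must be in (0,1)")
  if (L_c < 1 || L_n < 1) stop("expected lengths must be >= 1")
  structure(list(rho = rho, L_c = L_c, L_n = L_n,
                 mu = 1 / L_c, nu = 1 / L_n),
            class = "phylo_hmm_params")
}

#' Detect conserved elements with a two-state phylo-HMM
#'
#' Computes per-column log-likelihoods under the neutral model and under
#' the model with all branches scaled by `rho`, runs Viterbi decoding and
#' forward-backward smoothing over the two-state chain, and reports maximal
#' runs of the Viterbi conserved state as elements in reference
#' coordinates. Columns where the reference is gapped are assigned to the
#' preceding reference position, so elements are never zero-length.
#'
#' Each element carries a cumulative conserved-versus-neutral log-odds
#' score (sum over its columns of the emission log-likelihood difference)
#' and its mean posterior conserved probability.
#'
#' @param aln A [multi_alignment()] (typically with the focal clade already
#'   removed via [mask_species()]).
#' @param tree A `phylo` object covering the alignment species.
#' @param model A [subst_model()] for the neutral state.
#' @param params A [phylo_hmm_params()].
#' @return An object of class `conserved_scan`: list with `elements` (BED
#'   style data frame: chrom, start, end, name, score, mean_posterior),
#'   `posterior` (per-column conserved probability) and `viterbi`
#'   (per-column state, 1 neutral / 2 conserved).
#' @export
detect_conserved <- function(aln, tree, model, params = phylo_hmm_params()) {
  stopifnot(inherits(aln, "multi_alignment"),
            inherits(params, "phylo_hmm_params"))
  if (aln$width < 1L) stop("empty alignment")
  e_n <- prune_loglik(tree, model, aln, scales = 1, per_column = TRUE)
  e_c <- prune_loglik(tree, model, aln, scales = params$rho,
                      per_column = TRUE)
  n <- length(e_n)
  mu <- params$mu; nu <- params$nu
  # rows = from (1 neutral, 2 conserved)
  TR <- matrix(c(1 - nu, nu, mu, 1 - mu), 2, 2, byrow = TRUE)
  init <- c(mu, nu) / (mu + nu)               # stationary distribution

  # emissions, renormalized per column (common factor; path-invariant)
  emax <- pmax(e_n, e_c)
  E <- rbind(exp(e_n - emax), exp(e_c - emax))

  # Viterbi in log space
  lT <- log(TR); lE <- log(E)
  delta <- log(init) + lE[, 1]
  bt <- matrix(0L, 2, n)
  for (t in seq_len(n)[-1]) {
    cand1 <- delta + lT[, 1]; cand2 <- delta + lT[, 2]
    bt[1, t] <- which.max(cand1); bt[2, t] <- which.max(cand2)
    delta <- c(max(cand1), max(cand2)) + lE[, t]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in seq(n, 2)) path[t - 1] <- bt[path[t], t]

  # forward-backward, scaled
  alpha <- matrix(0, 2, n)
  cs <- numeric(n)
  a <- init * E[, 1]; cs[1] <- sum(a); alpha[, 1] <- a / cs[1]
  for (t in seq_len(n)[-1]) {
    a <- (crossprod(TR, alpha[, t - 1])) * E[, t]
    cs[t] <- sum(a)
    alpha[, t] <- a / cs[t]
  }
  beta <- matrix(0, 2, n)
  beta[, n] <- 1
  if (n > 1) for (t in seq(n - 1, 1)) {
    beta[, t] <- (TR %*% (E[, t + 1] * beta[, t + 1])) / cs[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rep(colSums(gamma), each = 2L)
  posterior <- gamma[2, ]

  pos <- column_ref_pos(aln)
  elements <- .runs_to_elements(path == 2L, pos, aln$chrom,
                                score = e_c - e_n, posterior = posterior)
  structure(list(elements = elements, posterior = posterior,
                 viterbi = path, params = params),
            class = "conserved_scan")
}

#' @export
print.conserved_scan <- function(x, ...) {
  cat(sprintf("conserved_scan: %d element(s), rho = %g\n",
              nrow(x$elements), x$params$rho))
  invisible(x)
}

.runs_to_elements <- function(flag, pos, chrom, score, posterior) {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0),
                    score = numeric(0), mean_posterior = numeric(0),
                    stringsAsFactors = FALSE)
  if (!any(flag)) return(out)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  recs <- lapply(keep, function(k) {
    cols <- starts[k]:ends[k]
    data.frame(chrom = chrom, start = min(pos[cols]),
               end = max(pos[cols]) + 1L, name = NA_character_,
               score = sum(score[cols]),
               mean_posterior = mean(posterior[cols]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$name <- sprintf("ce%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Merge fragmented conserved elements
#'
#' Iteratively merges adjacent same-chromosome elements while the ratio of
#' the gap between them to the total span of the would-be merged region is
#' at or below `ratio_threshold`, until a fixed point is reached. Scores of
#' merged members are summed. With `ratio_threshold = 0` merging is
#' disabled (a zero gap between disjoint elements is impossible).
#'
#' @param elements Data frame with `chrom,start,end` (plus optional
#'   `score`, `mean_posterior`), sorted and non-overlapping per chromosome.
#' @param ratio_threshold Maximum gap/span ratio that still merges
#'   (default 0.1).
#' @return A data frame of merged elements, renamed `m1, m2, ...`.
#' @export
merge_elements <- function(elements, ratio_threshold = 0.1) {
  if (!nrow(elements)) return(elements)
  el <- elements[order(elements$chrom, elements$start), , drop = FALSE]
  if ("score" %in% names(el) == FALSE) el$score <- 0
  parts <- split(el, el$chrom)
  merged <- lapply(parts, function(p) {
    if (any(p$start[-1] < p$end[-nrow(p)]))
      stop("overlapping elements on ", p$chrom[1])
    s <- p$start; e <- p$end; sc <- p$score
    repeat {
      changed <- FALSE
      i <- 1L
      while (i < length(s)) {
        gap <- s[i + 1L] - e[i]
        span <- e[i + 1L] - s[i]
        if (gap / span <= ratio_threshold && gap >= 0) {
          e[i] <- e[i + 1L]
          sc[i] <- sc[i] + sc[i + 1L]
          s <- s[-(i + 1L)]; e <- e[-(i + 1L)]; sc <- sc[-(i + 1L)]
          changed <- TRUE
        } else i <- i + 1L
      }
      if (!changed) break
    }
    data.frame(chrom = p$chrom[1], start = s, end = e, name = NA_character_,
               score = sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("m%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
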