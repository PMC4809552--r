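# PWM hit calling with an exact null score distribution, and the
# two-sequence TFBS count-divergence test (ancestral vs extant).
#
# Scores are log2 odds against background, discretized to a fixed grid
# (default 1e-3 bits). Window scores are computed from the same integer
# increments that build the exact distribution, so p-value lookups are
# exact with respect to the discretization.

#' Position weight matrix
#'
#' @param id Motif identifier.
#' @param mat 4 x w matrix of per-column base probabilities or counts
#'   (rows A, C, G, T). A pseudocount is added and columns renormalized.
#' @param bg Background base frequencies (default uniform).
#' @param pseudocount Added to each cell before normalization
#'   (default 0.01).
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, mat, bg = rep(0.25, 4), pseudocount = 0.01) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L || ncol(mat) < 1L)
    stop("'mat' must be a 4 x w matrix (rows A,C,G,T)")
  if (any(mat < 0)) stop("PWM cells must be nonnegative")
  mat <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  bg <- bg / sum(bg)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, w = ncol(mat), mat = mat, bg = bg),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  ic <- sum(x$mat * log2(x$mat / x$bg))
  cat(sprintf("pwm %s: width %d, information content %.2f bits\n",
              x$id, x$w, ic))
  invisible(x)
}

# integer score increments on the discretized bit grid (4 x w)
.pwm_increments <- function(p, step = 1e-3) {
  round(log2(p$mat / p$bg) / step)
}

#' Exact null distribution of PWM window scores
#'
#' Computes the exact probability distribution of the discretized log-odds
#' score of a background-generated window by column-wise convolution over
#' the score grid.
#'
#' @param p A [pwm()] of width at most `max_width`.
#' @param step Grid granularity in bits (default 1e-3).
#' @param max_width Dynamic-programming width cap (default 25).
#' @return An object of class `pwm_score_dist` with the integer grid
#'   offsets, their probabilities (summing to 1), and the upper-tail
#'   p-value lookup.
#' @export
exact_score_distribution <- function(p, step = 1e-3, max_width = 25) {
  stopifnot(inherits(p, "pwm"))
  if (p$w > max_width) stop("PWM width ", p$w, " exceeds cap ", max_width)
  inc <- .pwm_increments(p, step)
  lo <- 0L; hi <- 0L
  probs <- 1
  for (k in seq_len(p$w)) {
    dk <- inc[, k]
    nlo <- lo + min(dk); nhi <- hi + max(dk)
    new <- numeric(nhi - nlo + 1L)
    for (b in 1:4) {
      sh <- (lo + dk[b]) - nlo
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs * p$bg[b]
    }
    probs <- new; lo <- nlo; hi <- nhi
  }
  tail_p <- rev(cumsum(rev(probs)))
  structure(list(lo = lo, hi = hi, probs = probs, tail_p = tail_p,
                 step = step, id = p$id),
            class = "pwm_score_dist")
}

# upper-tail p-value P(score >= s) for integer grid scores
.score_pvalue <- function(dist, s_int) {
  i <- s_int - dist$lo + 1L
  out <- numeric(length(s_int))
  out[i <= 0L] <- 1
  inside <- i >= 1L & i <= length(dist$tail_p)
  out[inside] <- dist$tail_p[i[inside]]
  out
}

# integer window scores of `code` (0 = invalid base) under increments 4 x w;
# returns NA for windows containing an invalid base
.window_scores <- function(code, inc) {
  w <- ncol(inc)
  n <- length(code)
  if (n < w) return(integer(0))
  nw <- n - w + 1L
  bad <- code == 0L
  code1 <- code; code1[bad] <- 1L
  sc <- integer(nw)
  nbad <- integer(nw)
  for (k in seq_len(w)) {
    seg <- code1[k:(k + nw - 1L)]
    sc <- sc + inc[seg + (k - 1L) * 4L]
    nbad <- nbad + bad[k:(k + nw - 1L)]
  }
  sc[nbad > 0L] <- NA_integer_
  sc
}

#' Scan a sequence for PWM hits with FDR-controlled calling
#'
#' Scores every window on both strands with the exact-grid log-odds score,
#' attaches upper-tail p-values from [exact_score_distribution()], adjusts
#' them by Benjamini-Hochberg within the sequence (all window-strand
#' slots), and calls hits at `q <= hit_fdr`. Windows containing `N` are
#' skipped.
#'
#' @param seq Sequence string over `{A,C,G,T,N,-}`.
#' @param p A [pwm()].
#' @param hit_fdr Hit q-value threshold (default 0.01).
#' @param seq_id Identifier carried into the output.
#' @param dist Optional precomputed [exact_score_distribution()] for `p`.
#' @return Data frame of hits (`seq_id, offset` (0-based), `strand,
#'   score` (bits), `p, q`), with the number of scanned window-strand
#'   slots in attribute `n_slots`.
#' @export
scan_and_call <- function(seq, p, hit_fdr = 0.01, seq_id = "seq",
                          dist = NULL) {
  stopifnot(inherits(p, "pwm"))
  if (is.null(dist)) dist <- exact_score_distribution(p)
  code <- .encode_seq(seq)
  inc <- .pwm_increments(p, dist$step)
  inc_rc <- inc[4:1, rev(seq_len(ncol(inc))), drop = FALSE]
  s_fwd <- .window_scores(code, inc)
  s_rev <- .window_scores(code, inc_rc)
  off <- rep(seq_along(s_fwd) - 1L, 2L)
  strand <- rep(c("+", "-"), each = length(s_fwd))
  s_all <- c(s_fwd, s_rev)
  ok <- !is.na(s_all)
  empty <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0), q = numeric(0))
  if (!any(ok)) { attr(empty, "n_slots") <- 0L; return(empty) }
  pv <- .score_pvalue(dist, s_all[ok])
  qv <- stats::p.adjust(pv, "BH")
  hit <- qv <= hit_fdr
  out <- data.frame(seq_id = rep(seq_id, sum(hit)), offset = off[ok][hit],
                    strand = strand[ok][hit],
                    score = s_all[ok][hit] * dist$step,
                    p = pv[hit], q = qv[hit], stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_slots") <- sum(ok)
  out
}

#' Conditional exact test for TFBS count divergence
#'
#' Compares hit counts between two sequences (sides a and b) given their
#' scannable window-strand slot counts. Conditional on the total
#' `K = k_a + k_b`, under the null `k_a ~ Binomial(K, n_a / (n_a + n_b))`;
#' the two-sided p-value sums all outcome probabilities not exceeding the
#' observed one.
#'
#' @param k_a,n_a Hit and slot counts on side a.
#' @param k_b,n_b Hit and slot counts on side b.
#' @return List with `p` (in `(0, 1]`) and `direction` (`"gain"` /
#'   `"loss"` of sites on side a, or `"none"`).
#' @export
motif_count_test <- function(k_a, n_a, k_b, n_b) {
  if (n_a + n_b == 0) stop("no scannable positions on either side")
  if (k_a < 0 || k_b < 0 || k_a > n_a || k_b > n_b)
    stop("counts must satisfy 0 <= k <= n")
  K <- k_a + k_b
  rate_a <- if (n_a > 0) k_a / n_a else 0
  rate_b <- if (n_b > 0) k_b / n_b else 0
  direction <- if (rate_a > rate_b) "gain" else
    if (rate_a < rate_b) "loss" else "none"
  if (K == 0) return(list(p = 1, direction = "none"))
  p0 <- n_a / (n_a + n_b)
  probs <- stats::dbinom(0:K, K, p0)
  obs <- probs[k_a + 1L]
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  list(p = p, direction = direction)
}

#' TFBS gain/loss screen across element pairs
#'
#' For each motif, scans the ancestral (side a) and extant (side b)
#' sequence of every element, counts FDR-called hits and scannable slots,
#' and tests count divergence with [motif_count_test()] — per element or
#' pooled over all elements (counts and slots summed). Motif-level BH
#' adjustment; significance at `q < screen_fdr`.
#'
#' @param pairs List of `list(id, a, b)` element sequence pairs
#'   (a = ancestral, b = extant).
#' @param pwms List of [pwm()] objects (non-empty).
#' @param pooled Pool counts over elements (default `TRUE`).
#' @param hit_fdr Per-sequence hit-calling threshold (default 0.01).
#' @param screen_fdr Screen significance threshold (default 0.05).
#' @return Data frame `motif[, element], k_a, n_a, k_b, n_b, p, q,
#'   direction, significant`.
#' @export
divergence_screen <- function(pairs, pwms, pooled = TRUE, hit_fdr = 0.01,
                              screen_fdr = 0.05) {
  if (!length(pwms)) stop("empty motif set")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  rows <- list()
  for (p in pwms) {
    dist <- exact_score_distribution(p)
    per <- lapply(pairs, function(el) {
      ha <- scan_and_call(el$a, p, hit_fdr, seq_id = el$id, dist = dist)
      hb <- scan_and_call(el$b, p, hit_fdr, seq_id = el$id, dist = dist)
      c(k_a = nrow(ha), n_a = attr(ha, "n_slots"),
        k_b = nrow(hb), n_b = attr(hb, "n_slots"))
    })
    cnt <- do.call(rbind, per)
    if (pooled) {
      tot <- colSums(cnt)
      tst <- motif_count_test(tot["k_a"], tot["n_a"], tot["k_b"], tot["n_b"])
      rows[[length(rows) + 1L]] <- data.frame(
        motif = p$id, k_a = tot[["k_a"]], n_a = tot[["n_a"]],
        k_b = tot[["k_b"]], n_b = tot[["n_b"]], p = tst$p,
        direction = tst$direction, stringsAsFactors = FALSE)
    } else {
      for (i in seq_along(pairs)) {
        tst <- motif_count_test(cnt[i, "k_a"], cnt[i, "n_a"],
                                cnt[i, "k_b"], cnt[i, "n_b"])
        rows[[length(rows) + 1L]] <- data.frame(
          motif = p$id, element = pairs[[i]]$id,
          k_a = cnt[i, "k_a"], n_a = cnt[i, "n_a"],
          k_b = cnt[i, "k_b"], n_b = cnt[i, "n_b"], p = tst$p,
          direction = tst$direction, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < screen_fdr
  rownames(out) <- NULL
  out
}

#' Read PWMs from JASPAR-style PFM text
#'
#' Accepts records of the form `>ID [name]` followed by four rows
#' (optionally prefixed `A [ ... ]` etc.) of whitespace-separated counts.
#'
#' @param path Path to a PFM file.
#' @param bg,pseudocount Passed to [pwm()].
#' @return List of [pwm()] objects.
#' @export
read_jaspar <- function(path, bg = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PFM records in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i0 <- heads[h]
    i1 <- if (h < length(heads)) heads[h + 1] - 1L else length(lines)
    id <- strsplit(sub("^>", "", lines[i0]), "[ \t]+")[[1]][1]
    body <- lines[(i0 + 1L):i1]
    if (length(body) < 4L) stop("PFM record ", id, " has fewer than 4 rows")
    rows <- lapply(body[1:4], function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", ln)
      as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    })
    mat <- do.call(rbind, rows)
    out[[id]] <- pwm(id, mat, bg = bg, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs as JASPAR-style PFM text
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @param scale Probabilities are written as counts `round(prob * scale)`.
#' @export
write_jaspar <- function(pwms, path, scale = 1000) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[b],
                         paste(round(p$mat[b, ] * scale),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
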