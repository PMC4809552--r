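#' Nucleotide substitution models
#'
#' Construct a time-reversible nucleotide substitution model with unit
#' expected rate. Two families are supported: JC69 (equal rates, equal
#' frequencies) and HKY85 (unequal base frequencies \code{pi} and a
#' transition/transversion rate ratio \code{kappa}). The rate matrix Q is
#' normalized so that the expected number of substitutions per site per
#' unit branch length is 1; branch lengths are therefore interpreted as
#' expected substitutions per site under this model.
#'
#' Bases are ordered A, C, G, T throughout the package.
#'
#' @param family `"JC69"` or `"HKY85"`.
#' @param pi Equilibrium base frequencies (length 4, positive, summing
#'   to 1). Ignored for JC69, which fixes them at 1/4.
#' @param kappa Transition/transversion rate ratio (HKY85 only).
#' @return An object of class `subst_model` with elements `family`, `pi`,
#'   `kappa`, `Q` (normalized rate matrix) and a cached eigendecomposition
#'   used to compute transition matrices.
#' @examples
#' m <- subst_model("HKY85", pi = c(0.3, 0.2, 0.2, 0.3), kappa = 4)
#' transition_matrix(m, 0.1)
#' @export
subst_model <- function(family = c("HKY85", "JC69"),
                        pi = rep(0.25, 4), kappa = 4) {
  family <- match.arg(family)
  if (family == "JC69") {
    pi <- rep(0.25, 4)
    kappa <- 1
  }
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0))
    stop("'pi' must be 4 positive finite frequencies")
  pi <- pi / sum(pi)
  if (!is.finite(kappa) || kappa <= 0) stop("'kappa' must be positive")

  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    # transitions: A<->G (1,3) and C<->T (2,4)
    ti <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
          (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- pi[j] * if (ti) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))      # expected rate; rescale to 1 subst/site
  Q <- Q / mu

  # reversible Q: symmetrize with D = diag(sqrt(pi)), eigendecompose once
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  right <- diag(1 / d) %*% es$vectors    # P(t) = right exp(L t) left
  left <- t(es$vectors) %*% diag(d)

  structure(list(family = family, pi = stats::setNames(pi, bases),
                 kappa = kappa, Q = Q,
                 eig = list(values = es$values, right = right, left = left)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model (unit expected rate)\n", x$family))
  cat("  pi:", paste(sprintf("%s=%.4f", names(x$pi), x$pi), collapse = " "), "\n")
  if (x$family == "HKY85") cat(sprintf("  kappa: %.4g\n", x$kappa))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [subst_model()].
#' @param t Branch length in expected substitutions per site (`t >= 0`).
#' @return A 4x4 row-stochastic matrix; `P(0)` is the identity.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length 't' must be >= 0")
  e <- model$eig
  P <- e$right %*% (exp(e$values * t) * e$left)
  P[P < 0] <- 0      # clip eigen roundoff; magnitudes ~1e-16
  dimnames(P) <- dimnames(model$Q)
  P
}

# code a base character vector into 1..4 (A,C,G,T), 0 for missing (-, N, etc.)
.base_code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab
})

# string -> integer codes (0 = missing)
.encode_seq <- function(s) {
  .base_code_table[utf8ToInt(s)]
}

.decode_seq <- function(codes, missing_char = "N") {
  ch <- c(missing_char, "A", "C", "G", "T")[codes + 1L]
  paste(ch, collapse = "")
}
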