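# Shared fixtures and independent brute-force oracles.

# 10-leaf study tree (4-leaf focal clade) and an 8-leaf tree of total
# length ~2 used for calibration and HMM recovery checks.
tree10 <- function() parse_newick(paste0(
  "((((bat1:0.05,bat2:0.05):0.04,(bat3:0.05,bat4:0.05):0.04):0.08,",
  "(mouse:0.12,rat:0.12):0.1):0.06,",
  "((dog:0.15,cow:0.15):0.08,(human:0.12,macaque:0.1):0.09):0.05):0;"))

tree8 <- function() parse_newick(paste0(
  "((((f1:0.08,f2:0.08):0.06,(f3:0.08,f4:0.08):0.06):0.12,",
  "(s1:0.18,s2:0.18):0.14):0.1,(s3:0.3,s4:0.3):0.12):0;"))

focal8 <- c("f1", "f2", "f3", "f4")

hky_model <- function() subst_model("HKY85", pi = c(0.3, 0.2, 0.2, 0.3),
                                    kappa = 4)

# closed-form JC69 transition probability (independent of the package's
# eigendecomposition route)
jc_closed_form <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  P <- matrix(diff, 4, 4)
  diag(P) <- same
  P
}

# random rooted tree with <= n leaves and uniform branch lengths
random_tree <- function(n_leaves, min_bl = 0.01, max_bl = 0.5) {
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   br = function(k) stats::runif(k, min_bl, max_bl))
  tr$tip.label <- paste0("sp", seq_len(n_leaves))
  tr
}

# exhaustive ancestral-state enumeration likelihood of one column
brute_loglik <- function(tree, model, col, scales = 1) {
  tre <- ape::reorder.phylo(tree, "postorder")
  sc <- if (length(scales) == 1) rep(scales, nrow(tree$edge)) else scales
  sc <- sc[match(tre$edge[, 2], tree$edge[, 2])]
  ntip <- length(tre$tip.label)
  codes <- vapply(tre$tip.label, function(s) {
    b <- col[[s]]
    if (is.null(b) || b %in% c("-", "N")) 0L
    else match(b, c("A", "C", "G", "T"))
  }, integer(1))
  Ps <- lapply(seq_len(nrow(tre$edge)), function(i)
    transition_matrix(model, sc[i] * tre$edge.length[i]))
  states <- as.matrix(expand.grid(rep(list(1:4), tre$Nnode)))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    asn <- c(codes, states[r, ])
    p <- model$pi[asn[ntip + 1]]
    for (i in seq_len(nrow(tre$edge))) {
      a <- asn[tre$edge[i, 1]]; b <- asn[tre$edge[i, 2]]
      if (b != 0L) p <- p * Ps[[i]][a, b]
    }
    tot <- tot + p
  }
  unname(log(tot))
}

# exhaustive marginal posterior of one internal node for one column
brute_posterior <- function(tree, model, col, node, scales = 1) {
  tre <- ape::reorder.phylo(tree, "postorder")
  sc <- if (length(scales) == 1) rep(scales, nrow(tree$edge)) else scales
  sc <- sc[match(tre$edge[, 2], tree$edge[, 2])]
  ntip <- length(tre$tip.label)
  codes <- vapply(tre$tip.label, function(s) {
    b <- col[[s]]
    if (is.null(b) || b %in% c("-", "N")) 0L
    else match(b, c("A", "C", "G", "T"))
  }, integer(1))
  Ps <- lapply(seq_len(nrow(tre$edge)), function(i)
    transition_matrix(model, sc[i] * tre$edge.length[i]))
  states <- as.matrix(expand.grid(rep(list(1:4), tre$Nnode)))
  post <- numeric(4)
  for (r in seq_len(nrow(states))) {
    asn <- c(codes, states[r, ])
    p <- model$pi[asn[ntip + 1]]
    for (i in seq_len(nrow(tre$edge))) {
      a <- asn[tre$edge[i, 1]]; b <- asn[tre$edge[i, 2]]
      if (b != 0L) p <- p * Ps[[i]][a, b]
    }
    post[asn[node]] <- post[asn[node]] + p
  }
  post / sum(post)
}

# brute-force forward-backward posterior by enumerating all state paths
brute_hmm_posterior <- function(e_n, e_c, mu, nu) {
  n <- length(e_n)
  TR <- matrix(c(1 - nu, nu, mu, 1 - mu), 2, 2, byrow = TRUE)
  init <- c(mu, nu) / (mu + nu)
  E <- rbind(exp(e_n), exp(e_c))
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  pp <- apply(paths, 1, function(s) {
    p <- init[s[1]] * E[s[1], 1]
    if (n > 1) for (t in 2:n) p <- p * TR[s[t - 1], s[t]] * E[s[t], t]
    p
  })
  vapply(seq_len(n), function(t)
    sum(pp[paths[, t] == 2]) / sum(pp), numeric(1))
}

# best-ratio-first merging oracle (same gap/span rule, different order)
merge_oracle <- function(el, thr = 0.1) {
  s <- el$start; e <- el$end
  repeat {
    if (length(s) < 2) break
    gaps <- s[-1] - e[-length(e)]
    spans <- e[-1] - s[-length(s)]
    ratio <- gaps / spans
    i <- which.min(ratio)
    if (ratio[i] > thr) break
    e[i] <- e[i + 1]
    s <- s[-(i + 1)]; e <- e[-(i + 1)]
  }
  data.frame(start = s, end = e)
}

# random element list on one chromosome (sorted, non-overlapping)
random_elements <- function(n, max_len = 200, max_gap = 300) {
  lens <- sample.int(max_len, n, replace = TRUE)
  gaps <- sample.int(max_gap, n, replace = TRUE)
  starts <- cumsum(gaps) + c(0, cumsum(lens))[seq_len(n)]
  data.frame(chrom = "c1", start = starts, end = starts + lens,
             name = paste0("e", seq_len(n)), score = 1)
}

random_dna <- function(n, bg = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = bg),
        collapse = "")
}
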