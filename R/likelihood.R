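# Felsenstein pruning engine.
#
# All computations are vectorized over alignment columns: per-node partial
# likelihoods are 4 x n matrices and each edge contributes one 4x4 by 4xn
# product. Partials are rescaled per column to avoid underflow; the log of
# the scale factors is accumulated and restored in the column log-likelihoods.

# Coerce input to an integer code matrix with one row per tree tip, in tip
# order (0 = missing). Accepts a multi_alignment, a named character vector
# of single bases (one column), or a species x column integer matrix.
.tip_code_matrix <- function(x, tree, strict = FALSE) {
  tips <- tree$tip.label
  if (inherits(x, "multi_alignment")) {
    m0 <- aln_codes(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("a column must be a named base vector")
    m0 <- matrix(vapply(x, function(b) .base_code_table[utf8ToInt(b)[1]],
                        integer(1)), ncol = 1,
                 dimnames = list(names(x), NULL))
  } else if (is.matrix(x) && is.numeric(x)) {
    m0 <- x
    storage.mode(m0) <- "integer"
  } else stop("unsupported alignment input")
  absent <- setdiff(tips, rownames(m0))
  if (length(absent) && strict)
    stop("leaves absent from column mapping: ", paste(absent, collapse = ", "))
  m <- matrix(0L, length(tips), ncol(m0), dimnames = list(tips, NULL))
  common <- intersect(tips, rownames(m0))
  m[common, ] <- m0[common, , drop = FALSE]
  m
}

# expand a branch scale spec (scalar or per-edge vector in tree$edge order)
.expand_scales <- function(tree, scales) {
  ne <- nrow(tree$edge)
  if (length(scales) == 1L) return(rep(as.numeric(scales), ne))
  if (length(scales) != ne) stop("'scales' must be scalar or one per edge")
  as.numeric(scales)
}

.col_max <- function(M) pmax(M[1, ], M[2, ], M[3, ], M[4, ])

.tip_partial <- function(code_row, n) {
  M <- matrix(0, 4, n)
  obs <- code_row > 0L
  if (any(obs)) M[cbind(code_row[obs], which(obs))] <- 1
  if (any(!obs)) M[, !obs] <- 1
  M
}

# Core pruning pass. Returns column log-likelihoods; with keep = TRUE also
# returns everything needed for the marginal up-pass (per-node down partials
# F, per-edge messages P %*% F_child, transition matrices, non-missing tip
# counts per node and column).
.prune <- function(tree, model, codes, scales, keep = FALSE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  # reorder() permutes edge rows; carry the per-edge scales along by child id
  sc <- .expand_scales(tree, scales)[match(tr$edge[, 2], tree$edge[, 2])]
  edge <- tr$edge
  len <- tr$edge.length * sc
  ntip <- length(tr$tip.label)
  total <- ntip + tr$Nnode
  root <- ntip + 1L
  n <- ncol(codes)

  Ps <- lapply(len, function(t) transition_matrix(model, t))
  L <- vector("list", total)
  msg <- if (keep) vector("list", nrow(edge)) else NULL
  nm <- if (keep) matrix(0L, total, n) else NULL
  logsc <- numeric(n)

  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    if (ch <= ntip) {
      Lc <- .tip_partial(codes[ch, ], n)
      if (keep) { L[[ch]] <- Lc; nm[ch, ] <- as.integer(codes[ch, ] > 0L) }
    } else {
      Lc <- L[[ch]]
      if (!keep) L[ch] <- list(NULL)
    }
    contrib <- Ps[[i]] %*% Lc
    if (keep) {
      msg[[i]] <- contrib
      nm[p, ] <- nm[p, ] + nm[ch, ]
    }
    if (is.null(L[[p]])) L[[p]] <- contrib else L[[p]] <- L[[p]] * contrib
    m <- .col_max(L[[p]])
    m[m == 0] <- 1
    L[[p]] <- L[[p]] / rep(m, each = 4L)
    logsc <- logsc + log(m)
  }
  col_ll <- log(colSums(model$pi * L[[root]])) + logsc
  if (!keep) return(list(col_loglik = col_ll))
  list(col_loglik = col_ll, L = L, msg = msg, edge = edge, Ps = Ps,
       ntip = ntip, root = root, nm = nm, n = n)
}

#' Alignment log-likelihood by the pruning algorithm
#'
#' Computes the phylogenetic log-likelihood of alignment columns on a rooted
#' tree under a substitution model, with optional per-edge branch scale
#' multipliers. Gaps and `N` are missing data (partial likelihood of ones);
#' species in the tree but absent from the data are treated as missing
#' unless `strict = TRUE`. A column with no data has log-likelihood 0.
#'
#' @param tree A `phylo` object.
#' @param model A [subst_model()].
#' @param x A [multi_alignment()], a named base vector (one column), or an
#'   integer code matrix (rows named by species; 0 missing, 1..4 = A,C,G,T).
#' @param scales Branch scale multipliers: scalar or one value per row of
#'   `tree$edge` (see [branch_scales()]).
#' @param per_column If `TRUE`, return the vector of per-column
#'   log-likelihoods instead of their sum.
#' @param strict Error if a tree leaf is absent from the data.
#' @return Log-likelihood (sum over columns) or per-column vector.
#' @export
prune_loglik <- function(tree, model, x, scales = 1, per_column = FALSE,
                         strict = FALSE) {
  codes <- .tip_code_matrix(x, tree, strict = strict)
  ll <- .prune(tree, model, codes, scales)$col_loglik
  if (per_column) ll else sum(ll)
}

#' Maximum-likelihood scale of one branch
#'
#' Fits a single multiplicative rate scale on one edge of the tree by
#' bounded one-dimensional search (golden-section/parabolic via
#' [stats::optimize()] on the log scale), holding everything else fixed.
#' With the default `lower = 1` this is the one-sided acceleration
#' alternative: the branch may be faster than the background, never slower.
#' Flat or boundary-tied likelihoods resolve to `lower`.
#'
#' @param tree A `phylo` object.
#' @param model A [subst_model()].
#' @param x Alignment input as in [prune_loglik()].
#' @param edge Integer edge index (row of `tree$edge`), e.g. from
#'   [clade_stem_edge()].
#' @param lower,upper Search bounds for the scale (defaults 1 and 100).
#' @param scales Baseline branch scales the fitted scale multiplies.
#' @param tol Convergence tolerance on the scale.
#' @return List with `lambda` (the fitted scale), `loglik` at the optimum,
#'   and `loglik_lower` at the lower bound.
#' @export
fit_branch_scale <- function(tree, model, x, edge, lower = 1, upper = 100,
                             scales = 1, tol = 1e-6) {
  ne <- nrow(tree$edge)
  if (length(edge) != 1L || edge < 1 || edge > ne)
    stop("'edge' must index a row of tree$edge")
  codes <- .tip_code_matrix(x, tree)
  base <- .expand_scales(tree, scales)
  f <- function(lam) {
    s <- base
    s[edge] <- base[edge] * lam
    sum(.prune(tree, model, codes, s)$col_loglik)
  }
  ll_lower <- f(lower)
  opt <- stats::optimize(function(lg) f(exp(lg)),
                         interval = log(c(lower, upper)),
                         maximum = TRUE, tol = tol / 2)
  lam_hat <- exp(opt$maximum)
  ll_hat <- opt$objective
  # also probe the upper bound, and resolve ties to the lower bound
  ll_upper <- f(upper)
  if (ll_upper > ll_hat) { lam_hat <- upper; ll_hat <- ll_upper }
  if (ll_lower >= ll_hat - 1e-9) { lam_hat <- lower; ll_hat <- ll_lower }
  list(lambda = lam_hat, loglik = ll_hat, loglik_lower = ll_lower)
}

#' Marginal ancestral sequence reconstruction
#'
#' Computes, for one internal node, the per-column marginal posterior over
#' bases given the whole alignment (down partials from the pruning pass,
#' up partials from a root-to-node pass), and the maximum a posteriori
#' base per column. Ties break in base order A < C < G < T. Columns with no
#' observed data anywhere below the node are reported as `N`.
#'
#' @param tree A `phylo` object.
#' @param model A [subst_model()].
#' @param x Alignment input as in [prune_loglik()].
#' @param node Internal node id (ape numbering), or a character vector of
#'   two or more leaf names whose MRCA is reconstructed.
#' @param scales Branch scale multipliers as in [prune_loglik()].
#' @return List with `seq` (MAP sequence, `N` at data-free columns),
#'   `posterior` (4 x n matrix, rows A,C,G,T, columns summing to 1) and
#'   `node` (the resolved node id).
#' @export
reconstruct_ancestor <- function(tree, model, x, node, scales = 1) {
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    if (length(node) < 2L) stop("give >= 2 leaf names to resolve an ancestor")
    node <- ape::getMRCA(tree, node)
  }
  node <- as.integer(node)
  if (node <= ntip) stop("'node' is a leaf; pick an internal node")
  if (node > ntip + tree$Nnode) stop("no such node: ", node)

  codes <- .tip_code_matrix(x, tree)
  pr <- .prune(tree, model, codes, scales, keep = TRUE)
  n <- pr$n
  edge <- pr$edge

  # up pass: G[root] = pi; G[child] = t(P) (G[parent] * prod sibling msgs)
  G <- vector("list", ntip + tree$Nnode)
  G[[pr$root]] <- matrix(model$pi, 4, n)
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (i in rev(seq_len(nrow(edge)))) {
    ch <- edge[i, 2]
    if (ch <= ntip) next
    p <- edge[i, 1]
    acc <- G[[p]]
    for (j in setdiff(kids[[as.character(p)]], i)) acc <- acc * pr$msg[[j]]
    Gc <- crossprod(pr$Ps[[i]], acc)
    m <- .col_max(Gc); m[m == 0] <- 1
    G[[ch]] <- Gc / rep(m, each = 4L)
  }

  post <- pr$L[[node]] * G[[node]]
  tot <- colSums(post)
  tot[tot == 0] <- 1
  post <- post / rep(tot, each = 4L)
  rownames(post) <- c("A", "C", "G", "T")

  map_idx <- max.col(t(post), ties.method = "first")
  chars <- c("A", "C", "G", "T")[map_idx]
  chars[pr$nm[node, ] == 0L] <- "N"
  list(seq = paste(chars, collapse = ""), posterior = post, node = node)
}
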