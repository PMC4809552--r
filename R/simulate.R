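# run an expression under a locally seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an alignment along a tree
#'
#' Draws root states from the model's equilibrium frequencies and evolves
#' them down every edge with transition matrices `P(scale * t)`. No indels
#' are generated; all rows are ungapped and share the reference coordinate
#' system.
#'
#' @param tree A `phylo` object.
#' @param model A [subst_model()].
#' @param n_sites Number of columns to simulate (`>= 1`).
#' @param scales Branch scale multipliers as in [prune_loglik()].
#' @param seed Optional integer seed; a fixed seed reproduces the alignment
#'   exactly and the global RNG state is left untouched.
#' @param ref Reference species (defaults to the first tip).
#' @param chrom,start Reference coordinates assigned to the block.
#' @param return_states If `TRUE`, also return the simulated internal-node
#'   state matrix (nodes x sites, integer codes 1..4).
#' @return A [multi_alignment()]; with `return_states = TRUE`, a list
#'   `list(alignment, states)`.
#' @export
simulate_alignment <- function(tree, model, n_sites, scales = 1, seed = NULL,
                               ref = tree$tip.label[1], chrom = "chr1",
                               start = 0L, return_states = FALSE) {
  stopifnot(n_sites >= 1)
  .with_seed(seed, {
    sc <- .expand_scales(tree, scales)
    tr <- ape::reorder.phylo(tree, "postorder")
    sc <- sc[match(tr$edge[, 2], tree$edge[, 2])]
    ntip <- length(tr$tip.label)
    total <- ntip + tr$Nnode
    root <- ntip + 1L
    states <- matrix(0L, total, n_sites)
    states[root, ] <- sample.int(4, n_sites, replace = TRUE, prob = model$pi)
    for (i in rev(seq_len(nrow(tr$edge)))) {      # preorder
      p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      P <- transition_matrix(model, sc[i] * tr$edge.length[i])
      ps <- states[p, ]
      out <- integer(n_sites)
      for (s in 1:4) {
        idx <- which(ps == s)
        if (length(idx))
          out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[ch, ] <- out
    }
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(ntip),
                   function(i) paste(bases[states[i, ]], collapse = ""),
                   character(1))
    names(seqs) <- tr$tip.label
    aln <- multi_alignment(seqs, ref = ref, chrom = chrom, start = start)
    if (return_states) list(alignment = aln, states = states) else aln
  })
}

#' Evolve one sequence for a further branch
#'
#' Applies one round of substitution `P(t)` independently per base; gap and
#' `N` characters are passed through unchanged. Used by the synthetic
#' genome generator to derive extra-genome contigs from an extant leaf.
#'
#' @param seq A sequence string over `{A,C,G,T,-,N}`.
#' @param model A [subst_model()].
#' @param t Branch length.
#' @param seed Optional integer seed.
#' @return The evolved sequence string.
#' @export
evolve_sequence <- function(seq, model, t, seed = NULL) {
  .with_seed(seed, {
    code <- .encode_seq(seq)
    P <- transition_matrix(model, t)
    out <- strsplit(seq, "")[[1]]
    bases <- c("A", "C", "G", "T")
    for (s in 1:4) {
      idx <- which(code == s)
      if (length(idx))
        out[idx] <- bases[sample.int(4, length(idx), replace = TRUE,
                                     prob = P[s, ])]
    }
    paste(out, collapse = "")
  })
}
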