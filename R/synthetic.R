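# Truth-labeled synthetic genome generator.
#
# Emulates the statistical structure of the real inputs at desk scale: a
# neutrally evolving chromosome with planted conserved elements (rate
# scale rho < 1), a subset of which carry an additional acceleration scale
# lambda > 1 on the focal clade's stem edge; whole-species dropout within
# elements; peaks overlapping a subset of elements; exons; TSSs; two
# extra focal-clade genomes emitted only as contigs (to exercise
# reciprocal-best-hit integration); and a small motif set.

.default_tree <- paste0(
  "((((bat1:0.05,bat2:0.05):0.04,(bat3:0.05,bat4:0.05):0.04):0.08,",
  "(mouse:0.12,rat:0.12):0.1):0.06,",
  "((dog:0.15,cow:0.15):0.08,(human:0.12,macaque:0.1):0.09):0.05):0;")

#' Configuration of the synthetic genome generator
#'
#' Defaults define the reference study conditions: a 10-leaf tree whose
#' 4-leaf focal clade plays the bats, a 200 kb chromosome, 60 conserved
#' elements at rate scale `rho = 0.3`, 10% of them accelerated at
#' `lambda = 10` on the clade's stem edge, whole-species dropout within
#' elements at rate 0.1, peaks over 70% of elements, and two extra focal
#' genomes present only as contigs.
#'
#' @param seed Mandatory integer seed; the bundle is byte-identical for
#'   identical config and seed.
#' @param tree_newick Newick for the alignment species.
#' @param reference Reference species name.
#' @param focal_species Focal-clade leaves in the alignment.
#' @param extra_species Named list of extra focal genomes emitted as
#'   contigs: `list(name = list(sister = leaf, branch = t))`.
#' @param chrom,chrom_length Chromosome name and length (bp).
#' @param n_elements Number of planted conserved elements.
#' @param element_length Length range (uniform draw), bp.
#' @param min_gap Minimum spacing between planted elements, bp.
#' @param rho Conserved rate scale of planted elements.
#' @param accel_fraction Fraction of elements accelerated (per-element
#'   Bernoulli).
#' @param lambda_grid Acceleration scales sampled per accelerated element.
#' @param accel_scope `"stem"` (default) scales only the focal stem edge;
#'   `"clade"` also scales edges inside the clade (to probe test
#'   misspecification).
#' @param dropout Per-element, per-focal-species whole-species dropout
#'   probability.
#' @param peak_overlap_frac Fraction of elements covered by a peak.
#' @param n_bg_peaks,peak_pad Background peak count and peak padding range.
#' @param exon_frac Fraction of elements heavily overlapped by an exon.
#' @param n_bg_exons Background exon count.
#' @param n_tss Number of TSS positions.
#' @param contig_coverage Per-element, per-extra-species probability that
#'   a contig covering the element is emitted.
#' @param contig_flank Flank added around the element in each contig, bp.
#' @param n_decoy_contigs Random background contigs with no true origin.
#' @param n_pwms,pwm_width,pwm_consensus_prob Motif set size, width, and
#'   consensus base probability.
#' @param model_family,kappa,pi Neutral substitution model.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             tree_newick = .default_tree,
                             reference = "mouse",
                             focal_species = c("bat1", "bat2", "bat3", "bat4"),
                             extra_species = list(
                               xbat1 = list(sister = "bat1", branch = 0.04),
                               xbat2 = list(sister = "bat3", branch = 0.04)),
                             chrom = "chrS", chrom_length = 200000,
                             n_elements = 60,
                             element_length = c(150, 350),
                             min_gap = 1200,
                             rho = 0.3,
                             accel_fraction = 0.1,
                             lambda_grid = 10,
                             accel_scope = c("stem", "clade"),
                             dropout = 0.1,
                             peak_overlap_frac = 0.7,
                             n_bg_peaks = 20, peak_pad = c(50, 250),
                             exon_frac = 0.1, n_bg_exons = 10,
                             n_tss = 40,
                             contig_coverage = 0.8, contig_flank = 150,
                             n_decoy_contigs = 2,
                             n_pwms = 5, pwm_width = 8,
                             pwm_consensus_prob = 0.85,
                             model_family = "HKY85", kappa = 4,
                             pi = c(0.3, 0.2, 0.2, 0.3)) {
  if (missing(seed)) stop("'seed' is mandatory")
  accel_scope <- match.arg(accel_scope)
  cfg <- as.list(environment())
  probs <- c(cfg$accel_fraction, cfg$dropout, cfg$peak_overlap_frac,
             cfg$exon_frac, cfg$contig_coverage)
  if (any(probs < 0 | probs > 1)) stop("rates/fractions must be in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Generate a truth-labeled synthetic bundle
#'
#' Simulates the chromosome alignment, plants elements, derives peaks,
#' exons, TSSs, extra-genome contigs and motifs, and (optionally) writes
#' every file the pipeline consumes. The truth table records, per planted
#' element, its interval, rates, peak/exon status, per-species dropout,
#' and the filter fate expected from the planted properties alone.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, writes
#'   `alignment.maf, tree.nwk, peaks.bed, exons.bed, tss.bed, contigs.fa,
#'   genome.fa, motifs.pfm, truth.tsv, config.yaml`.
#' @return An object of class `synthetic_bundle`: list with `alignment`
#'   (a [multi_alignment()]), `tree`, `model`, `peaks`, `exons`, `tss`,
#'   `contigs`, `genome`, `pwms`, `truth`, `config` and (if written)
#'   `paths`.
#' @export
generate_synthetic <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  tree <- parse_newick(cfg$tree_newick)
  model <- subst_model(cfg$model_family, pi = cfg$pi, kappa = cfg$kappa)
  stem <- clade_stem_edge(tree, cfg$focal_species)
  # edges whose child subtree lies entirely inside the focal clade
  mrca <- ape::getMRCA(tree, cfg$focal_species)
  clade_edges <- which(vapply(tree$edge[, 2], function(nd)
    all(.node_tips(tree, nd) %in% .node_tips(tree, mrca)), logical(1)))

  .with_seed(cfg$seed, {
    n <- cfg$n_elements
    lens <- if (n > 0)
      round(stats::runif(n, cfg$element_length[1], cfg$element_length[2]))
      else integer(0)
    slack <- cfg$chrom_length - sum(lens) - cfg$min_gap * (n + 1)
    if (slack < 0)
      stop("infeasible packing: elements exceed the chromosome")
    cuts <- diff(c(0, sort(stats::runif(n)), 1))
    gaps <- cfg$min_gap + floor(cuts * slack)
    starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
    ends <- starts + lens

    accelerated <- stats::runif(n) < cfg$accel_fraction
    lambda <- rep(1, n)
    if (any(accelerated))
      lambda[accelerated] <- sample(rep(cfg$lambda_grid, 2),
                                    sum(accelerated), replace = TRUE)

    # simulate the chromosome segment by segment
    seg_bounds <- sort(unique(c(0, starts, ends, cfg$chrom_length)))
    pieces <- vector("list", length(seg_bounds) - 1L)
    for (si in seq_along(pieces)) {
      s0 <- seg_bounds[si]; s1 <- seg_bounds[si + 1L]
      el <- which(starts <= s0 & ends >= s1)
      sc <- if (length(el)) {
        sc_el <- branch_scales(tree, scale = cfg$rho)
        if (lambda[el] > 1) {
          tgt <- if (cfg$accel_scope == "stem") stem
                 else unique(c(stem, clade_edges))
          sc_el[tgt] <- sc_el[tgt] * lambda[el]
        }
        sc_el
      } else branch_scales(tree, scale = 1)
      pieces[[si]] <- simulate_alignment(tree, model, s1 - s0, scales = sc,
                                         ref = cfg$reference,
                                         chrom = cfg$chrom, start = s0)
    }
    seqs <- vapply(tree$tip.label, function(sp)
      paste(vapply(pieces, function(p) p$seqs[[sp]], character(1)),
            collapse = ""), character(1))

    # whole-species dropout within elements
    drop_mat <- matrix(FALSE, n, length(cfg$focal_species),
                       dimnames = list(NULL, cfg$focal_species))
    if (n > 0) {
      for (i in seq_len(n)) for (sp in cfg$focal_species) {
        if (stats::runif(1) < cfg$dropout) {
          drop_mat[i, sp] <- TRUE
          substr(seqs[sp], starts[i] + 1L, ends[i]) <-
            strrep("-", ends[i] - starts[i])
        }
      }
    }
    aln <- multi_alignment(seqs, ref = cfg$reference, chrom = cfg$chrom,
                           start = 0L)
    genome <- stats::setNames(gsub("-", "", seqs[[cfg$reference]],
                                   fixed = TRUE), cfg$chrom)

    # peaks
    peaks <- list()
    has_peak <- if (n > 0) stats::runif(n) < cfg$peak_overlap_frac
                else logical(0)
    for (i in which(has_peak)) {
      p0 <- max(0, starts[i] - round(stats::runif(1, cfg$peak_pad[1],
                                                  cfg$peak_pad[2])))
      p1 <- min(cfg$chrom_length,
                ends[i] + round(stats::runif(1, cfg$peak_pad[1],
                                             cfg$peak_pad[2])))
      peaks[[length(peaks) + 1L]] <- c(p0, p1)
    }
    for (j in seq_len(cfg$n_bg_peaks)) {
      w <- round(stats::runif(1, 300, 800))
      p0 <- floor(stats::runif(1, 0, cfg$chrom_length - w))
      peaks[[length(peaks) + 1L]] <- c(p0, p0 + w)
    }
    peaks <- data.frame(chrom = cfg$chrom,
                        start = vapply(peaks, `[`, numeric(1), 1),
                        end = vapply(peaks, `[`, numeric(1), 2))
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    peaks$name <- sprintf("p%d", seq_len(nrow(peaks)))
    peaks$score <- 0; peaks$strand <- "."
    rownames(peaks) <- NULL

    # exons: heavy overlap for a subset of elements, plus background
    exons <- list()
    has_exon <- if (n > 0) stats::runif(n) < cfg$exon_frac else logical(0)
    for (i in which(has_exon)) {
      w <- max(40L, round((ends[i] - starts[i]) * stats::runif(1, 0.4, 0.8)))
      e0 <- starts[i] + round(stats::runif(1, 0, (ends[i] - starts[i]) * 0.2))
      exons[[length(exons) + 1L]] <- c(e0, min(cfg$chrom_length, e0 + w))
    }
    for (j in seq_len(cfg$n_bg_exons)) {
      w <- round(stats::runif(1, 100, 250))
      e0 <- floor(stats::runif(1, 0, cfg$chrom_length - w))
      exons[[length(exons) + 1L]] <- c(e0, e0 + w)
    }
    exons <- if (length(exons))
      data.frame(chrom = cfg$chrom,
                 start = vapply(exons, `[`, numeric(1), 1),
                 end = vapply(exons, `[`, numeric(1), 2))
      else data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
    if (nrow(exons)) {
      exons <- exons[order(exons$start), , drop = FALSE]
      exons$name <- sprintf("ex%d", seq_len(nrow(exons)))
      exons$score <- 0; exons$strand <- "."
      rownames(exons) <- NULL
    }

    # TSS positions
    tss <- data.frame(chrom = cfg$chrom,
                      start = sort(floor(stats::runif(cfg$n_tss, 0,
                                                      cfg$chrom_length))))
    tss$end <- tss$start + 1L
    tss$name <- sprintf("gene%d", seq_len(nrow(tss)))
    tss$score <- 0; tss$strand <- "+"

    # extra-genome contigs (focal species outside the alignment)
    contigs <- character(0)
    for (xsp in names(cfg$extra_species)) {
      ex <- cfg$extra_species[[xsp]]
      src <- seqs[[ex$sister]]
      for (i in seq_len(n)) {
        if (stats::runif(1) >= cfg$contig_coverage) next
        c0 <- max(0L, starts[i] - cfg$contig_flank)
        c1 <- min(cfg$chrom_length, ends[i] + cfg$contig_flank)
        base <- substr(src, c0 + 1L, c1)
        base <- gsub("-", "", base, fixed = TRUE)   # dropout leaves gaps
        if (nchar(base) < 50) next
        contigs[sprintf("%s.c%03d", xsp, i)] <-
          evolve_sequence(base, model, ex$branch)
      }
    }
    for (j in seq_len(cfg$n_decoy_contigs)) {
      contigs[sprintf("decoy.d%02d", j)] <-
        paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE,
                     prob = model$pi), collapse = "")
    }

    # motifs
    pwms <- lapply(seq_len(cfg$n_pwms), function(k) {
      cons <- sample.int(4, cfg$pwm_width, replace = TRUE)
      mat <- matrix((1 - cfg$pwm_consensus_prob) / 3, 4, cfg$pwm_width)
      mat[cbind(cons, seq_len(cfg$pwm_width))] <- cfg$pwm_consensus_prob
      pwm(sprintf("MOTIF%d", k), mat)
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "id")

    # truth table with expected filter fate
    exon_fr <- if (n > 0 && nrow(exons))
      overlap_fraction(data.frame(chrom = cfg$chrom, start = starts,
                                  end = ends), exons)
      else numeric(n)
    pk_ov <- if (n > 0 && nrow(peaks))
      overlap_fraction(data.frame(chrom = cfg$chrom, start = starts,
                                  end = ends), peaks) > 0
      else logical(n)
    fate <- rep("pass", n)
    fate[apply(drop_mat, 1, any)] <- "missing_data"
    fate[exon_fr > 0.25] <- "exon_overlap"
    fate[!pk_ov] <- "no_peak"
    truth <- data.frame(
      name = sprintf("el%d", seq_len(n)), chrom = rep(cfg$chrom, n),
      start = starts, end = ends, rho = rep(cfg$rho, n),
      lambda = lambda, accelerated = accelerated,
      peak_overlap = pk_ov, exon_frac = exon_fr,
      n_dropout = if (n > 0) rowSums(drop_mat) else integer(0),
      expected_fate = fate, stringsAsFactors = FALSE)

    bundle <- structure(
      list(alignment = aln, tree = tree, model = model, peaks = peaks,
           exons = exons, tss = tss, contigs = contigs, genome = genome,
           pwms = pwms, truth = truth, config = cfg),
      class = "synthetic_bundle")
    if (!is.null(dir)) bundle <- write_bundle(bundle, dir)
    bundle
  })
}

# tip labels below a node (the node itself if a tip)
.node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic_bundle: %d bp chromosome, %d planted ",
                     "elements (%d accelerated), %d peaks, %d contigs\n"),
              x$config$chrom_length, nrow(x$truth),
              sum(x$truth$accelerated), nrow(x$peaks), length(x$contigs)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The bundle with a `paths` element added.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    maf = file.path(dir, "alignment.maf"),
    tree = file.path(dir, "tree.nwk"),
    peaks = file.path(dir, "peaks.bed"),
    exons = file.path(dir, "exons.bed"),
    tss = file.path(dir, "tss.bed"),
    contigs = file.path(dir, "contigs.fa"),
    genome = file.path(dir, "genome.fa"),
    pwms = file.path(dir, "motifs.pfm"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  write_maf(bundle$alignment, p$maf)
  writeLines(write_newick(bundle$tree), p$tree)
  write_bed(bundle$peaks, p$peaks)
  if (nrow(bundle$exons)) write_bed(bundle$exons, p$exons) else
    file.create(p$exons)
  write_bed(bundle$tss, p$tss)
  if (length(bundle$contigs)) write_fasta(bundle$contigs, p$contigs) else
    file.create(p$contigs)
  write_fasta(bundle$genome, p$genome)
  write_jaspar(bundle$pwms, p$pwms)
  utils::write.table(bundle$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- bundle$config
  cfg$extra_species <- lapply(cfg$extra_species, function(e)
    list(sister = e$sister, branch = e$branch))
  yaml::write_yaml(unclass(cfg), p$config)
  bundle$paths <- p
  bundle
}

#' Score called intervals against the planted truth
#'
#' A call matches a truth element when their reciprocal overlap is at
#' least `min_reciprocal` of both lengths.
#'
#' @param calls Interval data frame of calls.
#' @param truth Interval data frame of truth elements (any subset of the
#'   bundle's `truth`).
#' @param min_reciprocal Reciprocal-overlap threshold (default 0.5).
#' @return List with `sensitivity` (truth matched), `fdp` (calls matching
#'   nothing), and `jaccard` (base-level).
#' @export
evaluate_calls <- function(calls, truth, min_reciprocal = 0.5) {
  match_mat <- function(a, b) {
    if (!nrow(a) || !nrow(b)) return(matrix(FALSE, nrow(a), nrow(b)))
    ov_s <- outer(a$start, b$start, pmax)
    ov_e <- outer(a$end, b$end, pmin)
    ov <- pmax(ov_e - ov_s, 0)
    same <- outer(a$chrom, b$chrom, "==")
    la <- a$end - a$start; lb <- b$end - b$start
    same & ov >= min_reciprocal * outer(la, rep(1, nrow(b))) &
      ov >= min_reciprocal * outer(rep(1, nrow(a)), lb)
  }
  m <- match_mat(calls, truth)
  sens <- if (nrow(truth)) mean(apply(m, 2, any)) else NA_real_
  fdp <- if (nrow(calls)) mean(!apply(m, 1, any)) else 0
  base_union <- function(d) {
    if (!nrow(d)) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
  }
  ra <- base_union(calls); rb <- base_union(truth)
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  jac <- if (uni > 0) inter / uni else NA_real_
  list(sensitivity = sens, fdp = fdp, jaccard = jac)
}
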