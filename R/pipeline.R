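# End-to-end orchestration: mask -> detect -> merge -> select -> unmask ->
# RBH -> filter -> test -> FDR -> call -> reconstruct -> TFBS screen ->
# annotate, with per-stage record counts and reproducible outputs.

#' Pipeline configuration
#'
#' Collects inputs (as file paths or in-memory objects) and every stage
#' threshold. Thresholds default to the reference settings: merge ratio
#' 0.1, minimum element length 100 bp, maximum missing fraction 0.5 per
#' focal alignment species, maximum exonic fraction 0.25, forward e-value
#' 0.01, region FDR 0.05, TFBS hit FDR 0.01, screen FDR 0.05, proximity
#' window 1 Mb, gene-desert radius 500 kb.
#'
#' @param alignment MAF path or `multi_alignment`/list of blocks.
#' @param tree Newick path/string or `phylo`.
#' @param peaks One or more BED paths or interval data frames (list).
#' @param exons,tss BED path or data frame (exons may be `NULL`).
#' @param contigs FASTA path or named character vector (optional).
#' @param genome FASTA path or named character vector (needed for RBH).
#' @param pwms PFM path or list of [pwm()] (optional).
#' @param focal_species Focal-clade leaves present in the alignment.
#' @param extra_species Named list `list(name = list(sister, branch,
#'   stem_fraction))` of contig-only focal genomes grafted into the test
#'   tree (`stem_fraction` defaults to 0).
#' @param model `list(family, kappa, pi)`; `pi = NULL` estimates base
#'   frequencies from the reference sequence.
#' @param rho,hmm_L_c,hmm_L_n Conservation HMM parameters.
#' @param merge_ratio,min_length,max_missing,max_exon_frac,min_bats
#'   Candidate-stage thresholds.
#' @param evalue_max RBH forward e-value threshold.
#' @param bar_fdr,hit_fdr,screen_fdr FDR thresholds for region calling,
#'   TFBS hit calling, and the gain/loss screen.
#' @param proximity_window,desert_radius,n_perm Annotation-stage settings.
#' @param seed Seed for permutation statistics.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, tree, peaks, exons = NULL, tss,
                            contigs = NULL, genome = NULL, pwms = NULL,
                            focal_species,
                            extra_species = list(),
                            model = list(family = "HKY85", kappa = 4,
                                         pi = NULL),
                            rho = 0.3, hmm_L_c = 100, hmm_L_n = 1000,
                            merge_ratio = 0.1, min_length = 100,
                            max_missing = 0.5, max_exon_frac = 0.25,
                            min_bats = 1, evalue_max = 0.01,
                            bar_fdr = 0.05, hit_fdr = 0.01,
                            screen_fdr = 0.05,
                            proximity_window = 1e6, desert_radius = 5e5,
                            n_perm = 1000, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(rho > 0, rho < 1, merge_ratio >= 0, min_length >= 0,
            max_missing >= 0, max_missing <= 1,
            max_exon_frac >= 0, max_exon_frac <= 1,
            evalue_max > 0, bar_fdr > 0, bar_fdr < 1)
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration from a synthetic bundle
#' @param bundle A `synthetic_bundle`.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
bundle_config <- function(bundle, ...) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  extras <- lapply(bundle$config$extra_species, function(e)
    list(sister = e$sister, branch = e$branch, stem_fraction = 0))
  defaults <- list(
    alignment = bundle$alignment, tree = bundle$tree,
    peaks = list(bundle$peaks), exons = bundle$exons, tss = bundle$tss,
    contigs = bundle$contigs, genome = bundle$genome, pwms = bundle$pwms,
    focal_species = bundle$config$focal_species,
    extra_species = extras,
    model = list(family = bundle$config$model_family,
                 kappa = bundle$config$kappa, pi = bundle$config$pi),
    rho = bundle$config$rho, seed = bundle$config$seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(pipeline_config, args)
}

.load_blocks <- function(x) {
  if (inherits(x, "multi_alignment")) return(list(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_maf(x))
  if (is.list(x)) return(x)
  stop("cannot interpret alignment input")
}

.load_tree <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(parse_newick(paste(readLines(x),
                                                  collapse = "")))
    return(parse_newick(x))
  }
  stop("cannot interpret tree input")
}

.load_bed <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.character(x) && file.exists(x)) {
    if (file.size(x) == 0) return(data.frame(chrom = character(0),
                                             start = integer(0),
                                             end = integer(0)))
    return(read_bed(x))
  }
  stop("cannot interpret interval input: ", x)
}

.load_fasta <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (file.size(x) == 0) return(character(0))
    return(read_fasta(x))
  }
  if (is.character(x)) return(x)
  stop("cannot interpret FASTA input")
}

.load_pwms <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && !is.character(x)) return(x)
  if (is.character(x) && file.exists(x)) return(read_jaspar(x))
  stop("cannot interpret PWM input")
}

#' Run the discovery pipeline
#'
#' Executes all stages in order on the configured inputs and (optionally)
#' writes per-stage outputs and a machine-readable stage log to a run
#' directory. A rerun with the same config and inputs reproduces every
#' output byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory.
#' @param through_stage Last stage to execute: `"bars"` stops after region
#'   calling, `"tfbs"` after the motif screen, `"annotate"` (default) runs
#'   everything.
#' @return An object of class `bar_pipeline`: list with `conserved`,
#'   `merged`, `peak_union`, `candidates` (filtered `candidate_set`),
#'   `results` (acceleration table with q and `is_bar`), `bars`,
#'   `ancestors`, `tfbs_screen`, `annotation`, `stage_counts`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         through_stage = c("annotate", "tfbs", "bars")) {
  stopifnot(inherits(config, "pipeline_config"))
  through_stage <- match.arg(through_stage)
  blocks <- .load_blocks(config$alignment)
  tree <- .load_tree(config$tree)
  peaks_in <- lapply(if (is.list(config$peaks) &&
                         !is.data.frame(config$peaks)) config$peaks
                     else list(config$peaks), .load_bed)
  exons <- .load_bed(config$exons)
  tss <- .load_bed(config$tss)
  contigs <- .load_fasta(config$contigs)
  genome <- .load_fasta(config$genome)
  pwms <- .load_pwms(config$pwms)

  ref <- blocks[[1]]$ref
  pi_hat <- config$model$pi
  if (is.null(pi_hat)) {
    codes <- unlist(lapply(blocks, function(b) .encode_seq(ref_sequence(b))))
    pi_hat <- tabulate(codes[codes > 0L], 4)
    pi_hat <- pi_hat / sum(pi_hat)
  }
  model <- subst_model(config$model$family, pi = pi_hat,
                       kappa = config$model$kappa)

  counts <- list()
  # 1. mask focal clade, detect conserved elements per block
  masked_tree <- ape::drop.tip(tree, intersect(config$focal_species,
                                               tree$tip.label))
  hmm <- phylo_hmm_params(rho = config$rho, L_c = config$hmm_L_c,
                          L_n = config$hmm_L_n)
  cons <- do.call(rbind, lapply(blocks, function(b) {
    scan <- detect_conserved(mask_species(b, config$focal_species),
                             masked_tree, model, hmm)
    scan$elements
  }))
  if (is.null(cons)) cons <- data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        name = character(0), score = numeric(0))
  cons$name <- sprintf("ce%d", seq_len(nrow(cons)))
  counts$conserved <- nrow(cons)

  # 2. merge fragmented elements
  merged <- merge_elements(cons[c("chrom", "start", "end", "name", "score")],
                           config$merge_ratio)
  counts$merged <- nrow(merged)

  # 3. peak union, candidate selection
  pk <- union_peaks(peaks_in)
  counts$peaks <- nrow(pk)
  cands <- select_candidates(merged, pk, config$min_length)
  counts$selected <- nrow(cands)

  # 4. unmask focal species
  cset <- unmask_species(cands, blocks, config$focal_species)

  # 5. reciprocal-best-hit contig integration
  if (!is.null(contigs) && length(contigs) && !is.null(genome)) {
    cset <- rbh_integrate(cset, contigs, genome, config$evalue_max,
                          species = names(config$extra_species))
    counts$rbh_integrated <- if (nrow(cset$rbh_log))
      sum(cset$rbh_log$decision == "integrated") else 0L
  } else {
    cset$table$n_taxa_present <- cset$table$n_focal_present
  }

  # 6. filters
  cset <- apply_filters(cset, exons, config$max_missing,
                        config$max_exon_frac, config$min_bats)
  counts$candidates <- nrow(cset$table)

  # 7-9. acceleration test, FDR, region calling on the grafted test tree
  test_tree <- tree
  for (xsp in names(config$extra_species)) {
    ex <- config$extra_species[[xsp]]
    sf <- if (is.null(ex$stem_fraction)) 0 else ex$stem_fraction
    test_tree <- graft_leaf(test_tree, ex$sister, xsp,
                            stem_fraction = sf,
                            new_branch_length = ex$branch)
  }
  focal_all <- c(config$focal_species, names(config$extra_species))
  results <- test_candidates(cset, test_tree, model, focal_all)
  results <- call_bars(results, config$bar_fdr)
  bars <- results[results$is_bar, , drop = FALSE]
  counts$bars <- nrow(bars)

  out <- structure(list(conserved = cons, merged = merged, peak_union = pk,
                        candidates = cset, results = results, bars = bars,
                        model = model, test_tree = test_tree,
                        stage_counts = counts, config = config),
                   class = "bar_pipeline")

  # 10-11. ancestral reconstruction + TFBS screen over called regions
  if (through_stage %in% c("tfbs", "annotate") && nrow(bars) &&
      !is.null(pwms) && length(pwms)) {
    mrca_leaves <- intersect(focal_all, test_tree$tip.label)
    pairs <- lapply(bars$id, function(id) {
      a <- cset$alignments[[id]]
      rec <- reconstruct_ancestor(test_tree, model, a, mrca_leaves)
      # compare on reference coordinates: drop reference-gap columns
      keep <- strsplit(a$seqs[[a$ref]], "")[[1]] != "-"
      anc <- paste(strsplit(rec$seq, "")[[1]][keep], collapse = "")
      list(id = id, a = anc, b = ref_sequence(a))
    })
    out$ancestors <- stats::setNames(
      vapply(pairs, `[[`, character(1), "a"), bars$id)
    out$tfbs_screen <- divergence_screen(pairs, pwms, pooled = TRUE,
                                         hit_fdr = config$hit_fdr,
                                         screen_fdr = config$screen_fdr)
    counts$tfbs_significant <- sum(out$tfbs_screen$significant)
  }

  # 12. annotation statistics
  if (through_stage == "annotate" && nrow(bars) >= 2 && nrow(cset$table)) {
    cand_iv <- cset$table[c("chrom", "start", "end")]
    bar_iv <- bars[c("chrom", "start", "end")]
    out$annotation <- list(
      tss_distance = tss_distance(bar_iv, tss),
      gene_desert = gene_desert_flag(bar_iv, tss, config$desert_radius),
      clustering = clustering_permutation_test(bar_iv, cand_iv,
                                               n_perm = config$n_perm,
                                               seed = config$seed),
      enrichment = tryCatch(
        proximity_enrichment(bar_iv, cand_iv, tss,
                             window = config$proximity_window,
                             n_perm = config$n_perm, seed = config$seed),
        error = function(e) NULL),
      report = annotation_report(bar_iv, tss, config$desert_radius))
  }
  out$stage_counts <- counts

  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

#' @export
print.bar_pipeline <- function(x, ...) {
  cat("acceleration discovery pipeline run\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-16s %d\n", nm, x$stage_counts[[nm]]))
  invisible(x)
}

.write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(run$conserved, file.path(dir, "01_conserved.bed"))
  write_bed(run$merged, file.path(dir, "02_merged.bed"))
  write_bed(run$peak_union, file.path(dir, "03_peak_union.bed"))
  utils::write.table(run$candidates$table,
                     file.path(dir, "04_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$candidates$drop_log))
    utils::write.table(run$candidates$drop_log,
                       file.path(dir, "04_drop_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(run$results, digits = 10),
                     file.path(dir, "05_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(run$bars))
    write_bed(data.frame(chrom = run$bars$chrom, start = run$bars$start,
                         end = run$bars$end, name = run$bars$id,
                         score = run$bars$lambda_hat),
              file.path(dir, "06_bars.bed"))
  if (!is.null(run$ancestors))
    write_fasta(run$ancestors, file.path(dir, "07_ancestors.fa"))
  if (!is.null(run$tfbs_screen))
    utils::write.table(format(run$tfbs_screen, digits = 10),
                       file.path(dir, "08_tfbs_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$annotation))
    writeLines(c(run$annotation$report,
                 sprintf("clustering p: %.6g", run$annotation$clustering$p),
                 if (!is.null(run$annotation$enrichment))
                   sprintf("proximity OR: %.6g p: %.6g",
                           run$annotation$enrichment$odds_ratio,
                           run$annotation$enrichment$p)),
               file.path(dir, "09_annotation.txt"))
  cnt <- data.frame(stage = names(run$stage_counts),
                    n = unlist(run$stage_counts))
  utils::write.table(cnt, file.path(dir, "stage_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
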