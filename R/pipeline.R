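# End-to-end pipeline: synthetic data -> differential regulation -> cohort
# partition -> regulatory integration -> motif permutation test ->
# prioritization, each stage reading and writing files under the configured
# output directory so stages can also be run individually. All thresholds
# live in the config; one global seed is expanded into per-stage substreams.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage files.
#' @param seed Global integer seed (default 1), expanded per stage.
#' @param fold_threshold Regulated-gene fold threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param pseudocount Pseudocount in TPM (default 0.5).
#' @param window Peak-to-gene assignment window in bp (default 10000).
#' @param n_iter Permutation iterations (default 10000).
#' @param alpha Significance level for reporting (default 0.05).
#' @param motifs Motifs to test: subset of `c("wgatar", "ebox")`.
#' @param statistic Permutation group statistic, `"presence"` or `"count"`.
#' @param top_k Number of prioritized candidates to report (default 10).
#' @param synthetic A `synthetic_config` (default `synthetic_config(seed =
#'   seed)`); its seed is overridden by the pipeline seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            fold_threshold = 1.5, fdr_threshold = 0.05,
                            pseudocount = 0.5, window = 10000,
                            n_iter = 10000, alpha = 0.05,
                            motifs = c("wgatar", "ebox"),
                            statistic = c("presence", "count"),
                            top_k = 10,
                            synthetic = NULL) {
  statistic <- match.arg(statistic)
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must be in (0, 1]")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  synthetic$seed <- seed
  structure(list(
    out_dir = out_dir, seed = seed,
    fold_threshold = fold_threshold, fdr_threshold = fdr_threshold,
    pseudocount = pseudocount, window = window,
    n_iter = n_iter, alpha = alpha,
    motifs = motifs, statistic = statistic, top_k = top_k,
    synthetic = synthetic
  ), class = "pipeline_config")
}

#' Write a pipeline config to a YAML key-value file
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a pipeline config from a YAML file
#' @param path Input path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, x$synthetic[names(x$synthetic) %in%
    names(formals(synthetic_config))])
  pipeline_config(
    out_dir = x$out_dir, seed = x$seed,
    fold_threshold = x$fold_threshold, fdr_threshold = x$fdr_threshold,
    pseudocount = x$pseudocount, window = x$window,
    n_iter = x$n_iter, alpha = x$alpha,
    motifs = unlist(x$motifs), statistic = x$statistic, top_k = x$top_k,
    synthetic = syn
  )
}

p_ <- function(config, name) file.path(config$out_dir, name)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}

read_samples <- function(config, contrast) {
  s <- read_tsv(p_(config, "samples.tsv"))
  s <- s[s$contrast == contrast, ]
  stats::setNames(s$group, s$sample)
}

read_genome <- function(config) {
  x <- Biostrings::readDNAStringSet(p_(config, "genome.fa"))
  stats::setNames(as.character(x), names(x))
}

#' Run a single pipeline stage
#'
#' Stages: `"simulate"`, `"de"`, `"partition"`, `"integrate"`,
#' `"motif-test"`, `"prioritize"`, `"summary"`. Each stage reads its inputs
#' from, and writes its outputs to, `config$out_dir`, so later stages can be
#' rerun without regenerating earlier ones.
#'
#' @param config A `pipeline_config`.
#' @param stage Stage name.
#' @return Invisibly, the stage's main output (varies by stage).
#' @export
run_stage <- function(config, stage = c("simulate", "de", "partition",
                                        "integrate", "motif-test",
                                        "prioritize", "summary")) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(stage,
    "simulate" = stage_simulate, "de" = stage_de,
    "partition" = stage_partition, "integrate" = stage_integrate,
    "motif-test" = stage_motif_test, "prioritize" = stage_prioritize,
    "summary" = stage_summary)
  tryCatch(fn(config),
           error = function(e) stop("stage '", stage, "' failed: ",
                                    conditionMessage(e), call. = FALSE))
}

stage_simulate <- function(config) {
  invisible(write_synthetic_dataset(config$synthetic, config$out_dir))
}

stage_de <- function(config) {
  registry <- read_transporter_registry(p_(config, "registry.tsv"))
  gm <- read_gene_models(p_(config, "genes.gff3"), "gff3")
  families <- stats::setNames(gm$genes$family, gm$genes$gene_id)
  out <- list()
  for (contrast in c("gata1", "gata2")) {
    expr <- read_expression_table(p_(config, paste0("expr_", contrast,
                                                    ".tsv")),
                                  read_samples(config, contrast))
    groups <- if (contrast == "gata1") c("untreated", "estradiol") else
      c("wt", "mut")
    fc <- compute_fold_changes(expr, groups[1], groups[2],
                               pseudocount = config$pseudocount)
    write_tsv(fc, p_(config, paste0("fold_changes_", contrast, ".tsv")))
    calls <- call_regulated_genes(
      fc, factor_name = if (contrast == "gata1") "GATA1" else "GATA2",
      fold_threshold = config$fold_threshold,
      fdr_threshold = config$fdr_threshold,
      active_condition = if (contrast == "gata1") "b" else "a",
      family_filter = "SLC", families = families
    )
    write_tsv(calls, p_(config, paste0("calls_", contrast, ".tsv")))
    out[[contrast]] <- calls
  }
  invisible(out)
}

read_calls <- function(config, contrast) {
  x <- read_tsv(p_(config, paste0("calls_", contrast, ".tsv")))
  class(x) <- c("regulation_calls", "data.frame")
  x
}

stage_partition <- function(config) {
  calls1 <- read_calls(config, "gata1")
  calls2 <- read_calls(config, "gata2")
  part <- partition_cohorts(calls1, calls2)
  venn <- rbind(
    data.frame(gene_id = part$g1_only, venn_set = "g1_only",
               direction_group = NA_character_),
    data.frame(gene_id = part$g2_only, venn_set = "g2_only",
               direction_group = NA_character_),
    data.frame(gene_id = part$shared, venn_set = "shared",
               direction_group = vapply(part$shared, direction_group_of, "",
                                        calls_g1 = calls1,
                                        calls_g2 = calls2))
  )
  write_tsv(venn, p_(config, "partition.tsv"))
  registry <- read_transporter_registry(p_(config, "registry.tsv"))
  enr <- do.call(rbind, lapply(
    c("amino acid", "metal", "nucleoside/nucleotide"),
    function(cl) substrate_enrichment(part$shared, cl, registry)))
  write_tsv(enr, p_(config, "enrichment.tsv"))
  invisible(part)
}

stage_integrate <- function(config) {
  gm <- read_gene_models(p_(config, "genes.gff3"), "gff3")
  sequences <- read_genome(config)
  peak_files <- c(GATA1 = "gata1_peaks.bed", GATA2 = "gata2_peaks.bed",
                  ATAC = "atac_peaks.bed", cCRE = "ccres.bed")
  asn <- do.call(rbind, lapply(names(peak_files), function(a)
    assign_peaks_to_genes(read_bed(p_(config, peak_files[[a]])), gm,
                          window = config$window, assay = a)))
  write_tsv(asn, p_(config, "assignments.tsv"))
  occ <- occupancy_summary(gm$genes$gene_id, asn)
  write_tsv(occ, p_(config, "occupancy.tsv"))
  cand <- call_intronic_enhancers(
    asn[asn$assay == "GATA2", , drop = FALSE], gm, sequences,
    atac_peaks = read_bed(p_(config, "atac_peaks.bed")),
    ccres = read_bed(p_(config, "ccres.bed")),
    gata1_peaks = read_bed(p_(config, "gata1_peaks.bed"))
  )
  write_tsv(cand, p_(config, "enhancer_candidates.tsv"))
  pred <- cand[cand$predicted_enhancer, , drop = FALSE]
  write_bed(genomic_intervals(pred$chrom, pred$start, pred$end,
                              name = pred$gene_id),
            p_(config, "predicted_enhancers.bed"))
  invisible(cand)
}

stage_motif_test <- function(config) {
  gm <- read_gene_models(p_(config, "genes.gff3"), "gff3")
  sequences <- read_genome(config)
  cand <- read_tsv(p_(config, "enhancer_candidates.tsv"))
  obs <- cand[cand$predicted_enhancer,
              c("chrom", "start", "end"), drop = FALSE]
  motif_set <- list(wgatar = motif_wgatar(), ebox = motif_ebox())
  results <- list()
  hist_rows <- list()
  for (m in config$motifs) {
    if (nrow(obs) == 0) {
      results[[m]] <- data.frame(
        motif = motif_set[[m]]$name, statistic_type = config$statistic,
        observed_statistic = NA, n_sequences = 0,
        n_iter = config$n_iter, p_empirical = NA, p_corrected = NA,
        p_mid = NA)
      next
    }
    res <- permutation_test(obs, gm, sequences, motif_set[[m]],
                            n_iter = config$n_iter,
                            seed = stage_seed(config$seed,
                                              paste0("motif-", m)),
                            statistic = config$statistic)
    results[[m]] <- data.frame(
      motif = res$motif, statistic_type = res$statistic,
      observed_statistic = res$observed_statistic,
      n_sequences = res$n_sequences, n_iter = res$n_iter,
      p_empirical = res$p_empirical, p_corrected = res$p_corrected,
      p_mid = res$p_mid)
    hist_rows[[m]] <- data.frame(
      motif = res$motif, statistic = as.integer(names(res$null_counts)),
      count = as.integer(res$null_counts))
  }
  write_tsv(do.call(rbind, results), p_(config, "motif_enrichment.tsv"))
  if (length(hist_rows))
    write_tsv(do.call(rbind, hist_rows), p_(config, "null_histogram.tsv"))
  invisible(results)
}

stage_prioritize <- function(config) {
  calls1 <- read_calls(config, "gata1")
  calls2 <- read_calls(config, "gata2")
  part <- partition_cohorts(calls1, calls2)
  occ <- read_tsv(p_(config, "occupancy.tsv"))
  cand <- read_tsv(p_(config, "enhancer_candidates.tsv"))
  registry <- read_transporter_registry(p_(config, "registry.tsv"))
  pr <- select_candidates(part, occ, cand, registry, calls1, calls2,
                          k = config$top_k)
  write_tsv(pr, p_(config, "priorities.tsv"))
  invisible(pr)
}

stage_summary <- function(config) {
  part <- read_tsv(p_(config, "partition.tsv"))
  enr <- read_tsv(p_(config, "enrichment.tsv"))
  cand <- read_tsv(p_(config, "enhancer_candidates.tsv"))
  occ <- read_tsv(p_(config, "occupancy.tsv"))
  mot <- read_tsv(p_(config, "motif_enrichment.tsv"))
  pr <- read_tsv(p_(config, "priorities.tsv"))
  shared <- part$gene_id[part$venn_set == "shared"]
  n_g1_only <- sum(part$venn_set == "g1_only")
  n_g2_only <- sum(part$venn_set == "g2_only")
  dg <- table(factor(part$direction_group[part$venn_set == "shared"],
                     levels = c("up/up", "up/down", "down/up", "down/down")))
  pred_genes <- unique(cand$gene_id[cand$predicted_enhancer])
  occ_shared <- occ[occ$gene_id %in% shared, ]
  kv <- function(key, value) data.frame(key = key, value = as.character(value),
                                        stringsAsFactors = FALSE)
  rows <- rbind(
    kv("seed", config$seed),
    kv("fold_threshold", config$fold_threshold),
    kv("fdr_threshold", config$fdr_threshold),
    kv("pseudocount", config$pseudocount),
    kv("window", config$window),
    kv("n_iter", config$n_iter),
    kv("alpha", config$alpha),
    kv("statistic", config$statistic),
    kv("n_gata1_cohort", n_g1_only + length(shared)),
    kv("n_gata2_cohort", n_g2_only + length(shared)),
    kv("n_g1_only", n_g1_only),
    kv("n_g2_only", n_g2_only),
    kv("n_shared", length(shared)),
    kv("n_union", n_g1_only + n_g2_only + length(shared)),
    kv("group_up_up", dg[["up/up"]]),
    kv("group_up_down", dg[["up/down"]]),
    kv("group_down_up", dg[["down/up"]]),
    kv("group_down_down", dg[["down/down"]]),
    kv("n_gata2_occupied_shared", sum(occ_shared$GATA2)),
    kv("n_gata1_gata2_occupied_shared",
       sum(occ_shared$GATA1 & occ_shared$GATA2)),
    kv("n_accessible_shared", sum(occ_shared$ATAC)),
    kv("n_predicted_enhancers", sum(cand$predicted_enhancer)),
    kv("n_predicted_enhancer_genes", length(pred_genes)),
    kv("top_candidates", paste(pr$gene_id, collapse = ","))
  )
  for (i in seq_len(nrow(enr)))
    rows <- rbind(rows,
                  kv(paste0("enrichment_p[", enr$class[i], "]"),
                     signif(enr$p_value[i], 6)))
  for (i in seq_len(nrow(mot)))
    rows <- rbind(rows,
                  kv(paste0("motif_p_empirical[", mot$motif[i], "]"),
                     mot$p_empirical[i]),
                  kv(paste0("motif_p_corrected[", mot$motif[i], "]"),
                     mot$p_corrected[i]))
  write_tsv(rows, p_(config, "summary.tsv"))
  invisible(rows)
}

#' Run the full pipeline
#'
#' Runs simulate, de, partition, integrate, motif-test, prioritize and
#' summary in order. Every output file is regenerated from scratch; identical
#' config and seed yield byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the summary table (key/value data.frame).
#' @export
run_all <- function(config) {
  for (stage in c("simulate", "de", "partition", "integrate", "motif-test",
                  "prioritize"))
    run_stage(config, stage)
  invisible(run_stage(config, "summary"))
}
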