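#' Demo run configuration
#'
#' Collects the seed, output paths, chemistry parameters and every
#' analysis threshold (all defaulting to the workflow's canonical values)
#' for [run_demo()]. Thresholds are serialized into the provenance header
#' of every output file.
#'
#' @param seed Integer seed driving every stage.
#' @param out_dir Output directory.
#' @param reads_per_allele_per_gene Amplicon reads per gene, allele and
#'   sample (default 1000; desk-scale).
#' @param chemistry A [chemistry_model()].
#' @param n_genes_allelic,n_probes,n_samples_per_arm,n_screen_genes
#'   Simulation sizes for the tabular stages.
#' @param thresholds Named list of analysis thresholds; defaults:
#'   npc_ratio 0.135, min_cas_fraction 0.25, hmc_discard_below -1,
#'   min_intensity 1000, max_detection_p 0.01, dmp_p 0.01, dmp_lfc 0.1,
#'   screen_rra 0.05, screen_lfc 0.8, screen_goodsgrna 3, top_n 250,
#'   essential_lfc -0.75.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("astaseq_demo_"),
                       reads_per_allele_per_gene = 1000L,
                       chemistry = chemistry_model(),
                       n_genes_allelic = 60L, n_probes = 600L,
                       n_samples_per_arm = 3L, n_screen_genes = 1000L,
                       thresholds = list()) {
  defaults <- list(npc_ratio = 0.135, min_cas_fraction = 0.25,
                   hmc_discard_below = -1, min_intensity = 1000,
                   max_detection_p = 0.01, dmp_p = 0.01, dmp_lfc = 0.1,
                   screen_rra = 0.05, screen_lfc = 0.8,
                   screen_goodsgrna = 3, top_n = 250,
                   essential_lfc = -0.75)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) stopf("unknown threshold(s): %s",
                             paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  if (reads_per_allele_per_gene < 1L) {
    stopf("reads_per_allele_per_gene must be >= 1")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 reads_per_allele_per_gene =
                   as.integer(reads_per_allele_per_gene),
                 chemistry = chemistry,
                 n_genes_allelic = as.integer(n_genes_allelic),
                 n_probes = as.integer(n_probes),
                 n_samples_per_arm = as.integer(n_samples_per_arm),
                 n_screen_genes = as.integer(n_screen_genes),
                 thresholds = defaults),
            class = "run_config")
}

# Shifted truth for the IFNg arm of the demo: reactivating-gene promoters
# gain 5hmC and lose 5mC, escapees stay flat.
shift_truth_ifng <- function(truth, escapee_genes = c("Ddx3x", "Eif2s3x"),
                             gain_5hmc = 0.08, loss_5mc = 0.10) {
  tr <- truth
  hit <- !tr$gene %in% escapee_genes
  tr$f_5hmC[hit] <- pmin(1, tr$f_5hmC[hit] + gain_5hmc)
  tr$f_5mC[hit] <- pmax(0, tr$f_5mC[hit] - loss_5mc)
  tr$f_C <- 1 - tr$f_5mC - tr$f_5hmC
  validate_truth(tr)
  tr
}

#' End-to-end demo run binding every stage
#'
#' Simulates the default amplicon panel and quantifies it, simulates
#' allele-resolved counts and classifies genes, scores pluripotency,
#' simulates a BS/OxBS array with a planted IFNg 5hmC shift and runs
#' QC / deconvolution / delta-beta / DMP filtering, and simulates screen
#' tables and applies the hit filters. All outputs land in
#' `config$out_dir` as TSV files with provenance headers; a fixed seed
#' yields byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a report list with the key numbers per stage and
#'   md5 sums of every output file.
#' @export
run_demo <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  out <- config$out_dir
  th <- config$thresholds
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("demo stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- amplicon stage ------------------------------------------------------
  pan <- stage("panel", make_default_panel(seed))
  truth <- list(control = pan$truth,
                IFNg = shift_truth_ifng(pan$truth))
  manifest <- sim_manifest(
    reads_per_allele_per_gene = config$reads_per_allele_per_gene)
  sim <- stage("simulate_reads",
               simulate_reads(pan$panel, truth, config$chemistry, manifest,
                              out_dir = file.path(out, "fastq"),
                              seed = seed))
  fit <- stage("amplicon_pipeline",
               asta_quantify(sim$manifest, pan$panel))
  write_tsv_prov(fit$tally$counts, file.path(out, "cpg_tally.tsv"),
                 seed = seed, thresholds = th)
  write_tsv_prov(fit$estimates, file.path(out, "cpg_estimates.tsv"),
                 seed = seed, thresholds = th)
  write_tsv_prov(fit$tally$sample_accounting,
                 file.path(out, "read_accounting.tsv"),
                 seed = seed, thresholds = th)

  # -- allelic expression stage -------------------------------------------
  ac <- stage("allelic_counts",
              simulate_allelic_counts(config$n_genes_allelic, seed = seed))
  cls <- stage("classify",
               classify_genes(ac$table, "NPC", th$npc_ratio,
                              th$min_cas_fraction))
  write_tsv_prov(cls, file.path(out, "gene_classes.tsv"), seed = seed,
                 thresholds = th)
  expr <- stage("pluripotency", demo_expression_table(seed))
  score <- pluripotency_score(expr, esc_samples = c("ESC_r1", "ESC_r2"))
  write_tsv_prov(data.frame(sample = names(score), score = score),
                 file.path(out, "pluripotency_score.tsv"), seed = seed,
                 thresholds = th)

  # -- array stage ---------------------------------------------------------
  bm <- stage("beta_matrix",
              simulate_beta_matrix(config$n_probes,
                                   config$n_samples_per_arm,
                                   delta_5hmc = 0.05, seed = seed))
  qc <- probe_qc(bm$table, th$min_intensity, th$max_detection_p)
  wide <- beta_wide(qc$table)
  dec <- deconvolve_beta(wide$beta_BS, wide$beta_OxBS)
  hmc <- cbind(wide[, c("probe_id", "chromosome", "genomic_feature",
                        "arm")],
               value = dec$beta_5hmC)
  strat <- stratum_summary(hmc)
  dmp <- dmp_filter(dmp_test(hmc), th$dmp_p, th$dmp_lfc)
  write_tsv_prov(strat, file.path(out, "array_strata.tsv"), seed = seed,
                 thresholds = th)
  write_tsv_prov(dmp, file.path(out, "array_dmp.tsv"), seed = seed,
                 thresholds = th)

  # -- screen stage --------------------------------------------------------
  comps <- c("non_vs_npc", "early_vs_npc", "late_vs_npc")
  core <- sprintf("gene%05d", seq_len(max(10L, config$n_screen_genes %/% 10L)))
  tabs <- lapply(seq_along(comps), function(i) {
    simulate_screen_table(config$n_screen_genes, comparison = comps[i],
                          seed = seed + i)
  })
  # populations share a depleted core, as a real essentialome does
  ess_tabs <- lapply(seq_along(comps), function(i) {
    simulate_screen_table(config$n_screen_genes, comparison = comps[i],
                          seed = seed + 10L + i, signal_genes = core,
                          signal_direction = "depleted")
  })
  top <- top_overrepresented(tabs, th$top_n)
  ess <- essential_filter(ess_tabs, th$screen_rra, th$essential_lfc)
  hits <- hit_filter(tabs[[3L]], "depleted", th$screen_rra, th$screen_lfc,
                     th$screen_goodsgrna)
  writeLines(c(provenance_lines(seed, th), top),
             file.path(out, "screen_top_overrepresented.txt"))
  writeLines(c(provenance_lines(seed, th), ess),
             file.path(out, "screen_essential.txt"))
  writeLines(c(provenance_lines(seed, th), hits),
             file.path(out, "screen_hits_depleted.txt"))

  files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- substring(files, nchar(out) + 2L)
  report <- list(
    seed = seed,
    n_reads = sum(fit$tally$sample_accounting$n_total),
    frac_gene_assigned =
      sum(fit$tally$sample_accounting$n_gene_assigned) /
      sum(fit$tally$sample_accounting$n_total),
    n_cpg_cells = nrow(fit$estimates),
    n_reactivating = sum(cls$class == "reactivating"),
    n_escapee = sum(cls$class == "escapee"),
    pluripotency_scores = score,
    n_probes_removed = sum(qc$report$n_removed),
    chrx_delta_beta_5hmc =
      strat$delta_beta[strat$chrom_class == "chrX" &
                         strat$feature == "global"],
    n_dmp = sum(dmp$significant),
    n_top_overrepresented = length(top),
    n_essential = length(ess),
    n_hits_depleted = length(hits),
    md5 = md5)
  writeLines(c(provenance_lines(seed, th),
               utils::capture.output(utils::str(report, digits.d = 10))),
             file.path(out, "report.txt"))
  invisible(report)
}

# Small deterministic expression table for the pluripotency score demo.
demo_expression_table <- function(seed) {
  genes <- c("Nanog", "Zfp42", "Dppa4", "Dppa5a", "Esrrb", "Prdm14",
             "Sall4")
  with_seed(seed + 17L, {
    base <- stats::runif(length(genes), 20, 200)
    samples <- c(ESC_r1 = 1, ESC_r2 = 1, d2_r1 = 0.05, d2_r2 = 0.06,
                 d5_r1 = 0.3, d5_r2 = 0.32, d7_r1 = 0.8, d7_r2 = 0.78)
    do.call(rbind, lapply(names(samples), function(s) {
      data.frame(gene = genes, sample = s,
                 expression = base * samples[[s]] *
                   stats::runif(length(genes), 0.95, 1.05),
                 stringsAsFactors = FALSE)
    }))
  })
}

# Pivot a QC-passed long beta table to one row per
# (probe, sample replicate, arm) with BS and OxBS columns.
beta_wide <- function(table) {
  table$rep_id <- sub("_(BS|OxBS)$", "", table$sample_id)
  key <- c("probe_id", "chromosome", "genomic_feature", "arm", "rep_id")
  bs <- table[table$chemistry == "BS", c(key, "beta")]
  ox <- table[table$chemistry == "OxBS", c(key, "beta")]
  names(bs)[6L] <- "beta_BS"
  names(ox)[6L] <- "beta_OxBS"
  merge(bs, ox, by = key)
}
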