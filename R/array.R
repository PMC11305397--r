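#' Probe quality control for BS/OxBS methylation arrays
#'
#' Removes probes with signal intensity below `min_intensity` (default
#' 1000; a probe at exactly 1000 is kept) or detection p-value above
#' `max_detection_p` (default 0.01; exactly 0.01 is kept). By default a
#' probe failing in any sample is removed from all samples
#' (`per_sample = FALSE`); with `per_sample = TRUE` only the offending
#' rows are dropped.
#'
#' @param table Long beta table: columns probe_id, sample_id, beta,
#'   intensity, detection_p (other columns pass through).
#' @param min_intensity,max_detection_p QC thresholds.
#' @param per_sample Apply per row instead of per probe.
#' @return List: `table` (filtered), `report` (disjoint removal counts by
#'   cause; they sum to input minus output probes).
#' @export
probe_qc <- function(table, min_intensity = 1000, max_detection_p = 0.01,
                     per_sample = FALSE) {
  need <- c("probe_id", "intensity", "detection_p")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("beta table missing columns: %s",
                          paste(miss, collapse = ", "))
  low_int <- table$intensity < min_intensity
  high_p <- table$detection_p > max_detection_p
  if (per_sample) {
    keep_row <- !(low_int | high_p)
    out <- table[keep_row, , drop = FALSE]
    report <- data.frame(
      cause = c("low_intensity", "high_detection_p_only"),
      n_removed = c(sum(low_int), sum(high_p & !low_int)))
  } else {
    bad_int <- unique(table$probe_id[low_int])
    bad_p <- setdiff(unique(table$probe_id[high_p]), bad_int)
    out <- table[!table$probe_id %in% c(bad_int, bad_p), , drop = FALSE]
    report <- data.frame(
      cause = c("low_intensity", "high_detection_p_only"),
      n_removed = c(length(bad_int), length(bad_p)))
  }
  list(table = out, report = report)
}

#' Deconvolve array beta values into 5mC and 5hmC signal
#'
#' `beta_5mC = beta_OxBS` (only 5mC survives oxidation plus bisulfite) and
#' `beta_5hmC = beta_BS - beta_OxBS` (5hmC reads methylated in BS but not
#' in OxBS). Negative 5hmC values from noise are retained; the array
#' workflow applies no clamp.
#'
#' @param beta_bs,beta_oxbs Beta values in `[0,1]` (vectorized).
#' @return data.frame with columns `beta_5mC`, `beta_5hmC`.
#' @export
deconvolve_beta <- function(beta_bs, beta_oxbs) {
  stopifnot(length(beta_bs) == length(beta_oxbs))
  vals <- stats::na.omit(c(beta_bs, beta_oxbs))
  if (any(vals < 0 | vals > 1)) stopf("beta values must lie in [0,1]")
  data.frame(beta_5mC = beta_oxbs, beta_5hmC = beta_bs - beta_oxbs)
}

#' Delta-beta between treatment arms
#'
#' `mean(IFNg values) - mean(control values)`; `NA` when either group is
#' empty.
#'
#' @param values_ifng,values_control Numeric vectors of beta(-derived)
#'   values.
#' @return Single delta-beta value.
#' @export
delta_beta <- function(values_ifng, values_control) {
  values_ifng <- values_ifng[!is.na(values_ifng)]
  values_control <- values_control[!is.na(values_control)]
  if (!length(values_ifng) || !length(values_control)) return(NA_real_)
  mean(values_ifng) - mean(values_control)
}

#' Per-probe two-group test for differential (hydroxy)methylation
#'
#' A plain Welch two-sample t test per probe between arms on the beta
#' scale; logFC is the mean difference (IFNg minus control).
#' Benjamini-Hochberg adjusted p-values are reported alongside, but the
#' downstream selection rule ([dmp_filter()]) uses raw p.
#'
#' @param values data.frame with columns probe_id, arm
#'   (`"control"`/`"IFNg"`), value.
#' @return data.frame: probe_id, logFC, p_value, p_adj.
#' @export
dmp_test <- function(values) {
  need <- c("probe_id", "arm", "value")
  miss <- setdiff(need, names(values))
  if (length(miss)) stopf("dmp_test input missing columns: %s",
                          paste(miss, collapse = ", "))
  res <- lapply(split(values, values$probe_id), function(df) {
    i <- df$value[df$arm == "IFNg"]
    c0 <- df$value[df$arm == "control"]
    p <- tryCatch(stats::t.test(i, c0)$p.value, error = function(e) NA_real_)
    data.frame(probe_id = df$probe_id[1L], logFC = mean(i) - mean(c0),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Flag differentially (hydroxy)methylated positions
#'
#' A probe is significant iff raw `p_value < p_threshold` (default 0.01)
#' and `|logFC| >= lfc_threshold` (default 0.1 on the beta scale).
#' Direction is `"hyper"`/`"hypo"` by sign of logFC.
#'
#' @param stats_table Output of [dmp_test()] (or any table with probe_id,
#'   logFC, p_value).
#' @param p_threshold,lfc_threshold Selection thresholds.
#' @return Input with `significant` and `direction` columns added.
#' @export
dmp_filter <- function(stats_table, p_threshold = 0.01,
                       lfc_threshold = 0.1) {
  need <- c("probe_id", "logFC", "p_value")
  miss <- setdiff(need, names(stats_table))
  if (length(miss)) stopf("dmp_filter input missing columns: %s",
                          paste(miss, collapse = ", "))
  out <- stats_table
  out$significant <- !is.na(out$p_value) & out$p_value < p_threshold &
    abs(out$logFC) >= lfc_threshold
  out$direction <- ifelse(out$logFC >= 0, "hyper", "hypo")
  out
}

#' Stratified arm comparison of beta-derived signal
#'
#' Summarizes a signal by chromosome class (autosome vs chrX) crossed with
#' genomic feature (global = all features, promoter, gene body, distal):
#' per-arm means, delta-beta, and an unpaired Welch t test. Strata with
#' fewer than two values in an arm report means only.
#'
#' @param table Long data.frame: chromosome, genomic_feature, arm, value.
#' @param features Feature strata (besides `"global"`).
#' @return data.frame: chrom_class, feature, n_control, n_ifng,
#'   mean_control, mean_ifng, delta_beta, t_stat, p_value.
#' @export
stratum_summary <- function(table,
                            features = c("promoter", "gene_body",
                                         "distal")) {
  need <- c("chromosome", "genomic_feature", "arm", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("stratum_summary input missing columns: %s",
                          paste(miss, collapse = ", "))
  table$chrom_class <- ifelse(table$chromosome == "chrX", "chrX",
                              "autosome")
  rows <- list()
  for (cc in c("autosome", "chrX")) {
    for (ft in c("global", features)) {
      sub <- table[table$chrom_class == cc &
                     (ft == "global" | table$genomic_feature == ft), ]
      ctl <- sub$value[sub$arm == "control"]
      ifn <- sub$value[sub$arm == "IFNg"]
      tt <- if (length(ctl) >= 2L && length(ifn) >= 2L) {
        tryCatch(stats::t.test(ifn, ctl),
                 error = function(e) NULL)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom_class = cc, feature = ft,
        n_control = length(ctl), n_ifng = length(ifn),
        mean_control = if (length(ctl)) mean(ctl) else NA_real_,
        mean_ifng = if (length(ifn)) mean(ifn) else NA_real_,
        delta_beta = delta_beta(ifn, ctl),
        t_stat = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
        p_value = if (!is.null(tt)) tt$p.value else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
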