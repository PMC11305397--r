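#' Allelic expression ratio
#'
#' The fraction of allele-resolved expression carried by the mus (Mus
#' musculus, reporter-bearing) X chromosome:
#' `count_mus / (count_mus + count_cas)`. Near 0 when the mus X is
#' inactive; library-size normalization cancels in the ratio, so raw
#' allele-resolved counts are the expected input.
#'
#' @param count_mus,count_cas Non-negative allele-resolved counts
#'   (vectorized).
#' @return Ratio in `[0,1]`; `NA` when both counts are zero.
#' @export
allelic_ratio <- function(count_mus, count_cas) {
  if (any(stats::na.omit(c(count_mus, count_cas)) < 0)) {
    stopf("allele counts must be non-negative")
  }
  total <- count_mus + count_cas
  ifelse(total > 0, count_mus / total, NA_real_)
}

validate_allelic_table <- function(table) {
  need <- c("gene", "population", "count_mus", "count_cas")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("allelic count table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(table$count_mus < 0 | table$count_cas < 0)) {
    stopf("allele counts must be non-negative")
  }
  if (anyDuplicated(table[, c("gene", "population")])) {
    stopf("duplicate (gene, population) rows")
  }
  invisible(table)
}

#' Select allelically informative genes
#'
#' Keeps genes whose cas-allele share of expression,
#' `count_cas / (count_mus + count_cas)`, exceeds `min_cas_fraction`
#' strictly ("over 25%") in every population. Genes with any
#' zero-total population are dropped (their cas share is undefined there).
#'
#' @param table data.frame with columns gene, population, count_mus,
#'   count_cas.
#' @param min_cas_fraction Strict lower bound on the cas fraction
#'   (default 0.25).
#' @return Character vector of informative gene names (sorted).
#' @export
select_informative <- function(table, min_cas_fraction = 0.25) {
  validate_allelic_table(table)
  total <- table$count_mus + table$count_cas
  cas_frac <- ifelse(total > 0, table$count_cas / total, NA_real_)
  ok <- tapply(cas_frac > min_cas_fraction, table$gene,
               function(x) all(!is.na(x)) && all(x))
  sort(names(ok)[ok])
}

#' Classify informative genes as X-reactivating or escapee
#'
#' Based on the allelic ratio in the NPC (neural precursor) population, in
#' which the mus X is inactive: a ratio equal to or under `threshold`
#' (default 0.135, inclusive) means the gene is silenced on the mus X and
#' will reactivate during reprogramming (`"reactivating"`); above it the
#' gene escapes inactivation (`"escapee"`). Genes failing
#' [select_informative()] are `"uninformative"`.
#'
#' @param table Allelic count table (all populations).
#' @param npc_population Name of the NPC population (default `"NPC"`).
#' @param threshold Inclusive upper bound for reactivating genes
#'   (default 0.135).
#' @param min_cas_fraction Passed to [select_informative()].
#' @return data.frame with columns `gene`, `npc_ratio`, `class`
#'   (`reactivating` / `escapee` / `uninformative`); the partition is
#'   exhaustive and exclusive.
#' @export
classify_genes <- function(table, npc_population = "NPC",
                           threshold = 0.135, min_cas_fraction = 0.25) {
  validate_allelic_table(table)
  if (!npc_population %in% table$population) {
    stopf("NPC population '%s' absent from table", npc_population)
  }
  informative <- select_informative(table, min_cas_fraction)
  npc <- table[table$population == npc_population, ]
  genes <- sort(unique(table$gene))
  ratio <- stats::setNames(
    allelic_ratio(npc$count_mus, npc$count_cas)[match(genes, npc$gene)],
    genes)
  cls <- ifelse(!genes %in% informative | is.na(ratio), "uninformative",
                ifelse(ratio <= threshold, "reactivating", "escapee"))
  data.frame(gene = genes, npc_ratio = unname(ratio), class = cls,
             stringsAsFactors = FALSE)
}

#' Pluripotency score
#'
#' Mean, over seven naive-pluripotency marker genes (Nanog, Zfp42, Dppa4,
#' Dppa5a, Esrrb, Prdm14, Sall4), of each gene's expression relative to
#' its mean expression in embryonic stem cells (ESCs). ESCs self-score 1;
#' the score is linear in each gene's ratio and invariant under gene
#' permutation.
#'
#' @param expr data.frame with columns gene, sample, expression (one row
#'   per gene per sample; non-negative FPKM-like units).
#' @param esc_samples Character vector naming the ESC reference samples in
#'   `expr$sample`.
#' @param genes Marker gene set (default the seven above).
#' @return Named numeric vector: score per non-reference sample.
#' @export
pluripotency_score <- function(expr, esc_samples,
                               genes = c("Nanog", "Zfp42", "Dppa4",
                                         "Dppa5a", "Esrrb", "Prdm14",
                                         "Sall4")) {
  need <- c("gene", "sample", "expression")
  miss <- setdiff(need, names(expr))
  if (length(miss)) stopf("expression table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(expr$expression < 0)) stopf("expression must be non-negative")
  if (!all(esc_samples %in% expr$sample)) {
    stopf("ESC reference sample(s) absent: %s",
          paste(setdiff(esc_samples, expr$sample), collapse = ", "))
  }
  esc <- expr[expr$sample %in% esc_samples & expr$gene %in% genes, ]
  esc_ref <- tapply(esc$expression, esc$gene, mean)
  missing_genes <- setdiff(genes, names(esc_ref))
  samples <- setdiff(unique(expr$sample), esc_samples)
  for (s in samples) {
    have <- expr$gene[expr$sample == s]
    missing_genes <- union(missing_genes, setdiff(genes, have))
  }
  if (length(missing_genes)) {
    stopf("marker gene(s) missing from table: %s",
          paste(sort(missing_genes), collapse = ", "))
  }
  if (any(esc_ref[genes] <= 0)) {
    stopf("zero ESC reference expression for: %s",
          paste(genes[esc_ref[genes] <= 0], collapse = ", "))
  }
  vapply(samples, function(s) {
    sub <- expr[expr$sample == s & expr$gene %in% genes, ]
    mean(sub$expression[match(genes, sub$gene)] / esc_ref[genes])
  }, numeric(1L))
}

#' qRT-PCR relative expression (2^-dCT)
#'
#' `2^-(CT_gene - mean CT_Gapdh)`: expression relative to the Gapdh
#' housekeeping mean on the same sample.
#'
#' @param ct_gene Cycle-threshold value(s) for the gene of interest.
#' @param ct_gapdh_mean Mean Gapdh cycle threshold of the sample.
#' @return Relative expression, `2^-dCT`.
#' @export
qpcr_expression <- function(ct_gene, ct_gapdh_mean) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_gapdh_mean))) {
    stopf("CT values must be finite")
  }
  2^(-(ct_gene - ct_gapdh_mean))
}
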