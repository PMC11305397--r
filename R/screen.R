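# CRISPR-screen hit-selection filters over MAGeCK-style gene summaries.
# The RRA (robust rank aggregation) scoring itself comes from MAGeCK and is
# not reimplemented here; these are the selection rules applied to its
# per-gene output (smaller RRA score = stronger evidence).

validate_screen_table <- function(table, score_cols) {
  miss <- setdiff(c("gene", score_cols, "log2FC", "goodsgrna"),
                  names(table))
  if (length(miss)) stopf("screen table missing columns: %s",
                          paste(miss, collapse = ", "))
  for (sc in score_cols) {
    if (any(table[[sc]] < 0 | table[[sc]] > 1, na.rm = TRUE)) {
      stopf("RRA scores in '%s' must lie in [0,1]", sc)
    }
  }
  if (any(table$goodsgrna < 0)) stopf("goodsgrna must be non-negative")
  invisible(table)
}

# Pick the RRA column for a direction: the direction-specific column when
# present, else a single "rra_score" column.
rra_column <- function(table, direction) {
  pref <- if (direction == "enriched") "rra_score_pos" else "rra_score_neg"
  if (pref %in% names(table)) return(pref)
  if ("rra_score" %in% names(table)) return("rra_score")
  stopf("no '%s' or 'rra_score' column in screen table", pref)
}

#' Top-N overrepresented genes across comparisons
#'
#' Per comparison table, takes the `n` genes with the smallest
#' positive-direction RRA score (ties at rank `n` broken by gene name for
#' determinism), then returns the deduplicated union.
#'
#' @param tables A single MAGeCK-style gene-summary data.frame or a list
#'   of them (one per comparison).
#' @param n Genes taken per comparison (default 250).
#' @return Sorted character vector of unique gene names.
#' @export
top_overrepresented <- function(tables, n = 250L) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stopf("at least one comparison table required")
  picked <- lapply(tables, function(tb) {
    sc <- rra_column(tb, "enriched")
    validate_screen_table(tb, sc)
    if (nrow(tb) < n) {
      warning(sprintf("table has only %d genes (< n = %d); taking all",
                      nrow(tb), n), call. = FALSE)
    }
    ord <- order(tb[[sc]], tb$gene)
    tb$gene[utils::head(ord, n)]
  })
  sort(unique(unlist(picked)))
}

#' Essentialome filter: depleted in every population
#'
#' Genes with RRA score strictly below `rra_max` and log2 fold change
#' strictly below `lfc_max` (default -0.75) in every supplied population
#' table (intersection).
#'
#' @param tables List of gene-summary data.frames, one per population.
#' @param rra_max,lfc_max Strict thresholds (defaults 0.05 and -0.75).
#' @return Sorted character vector of genes passing in all populations.
#' @export
essential_filter <- function(tables, rra_max = 0.05, lfc_max = -0.75) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stopf("at least one population table required")
  per_pop <- lapply(tables, function(tb) {
    sc <- rra_column(tb, "depleted")
    validate_screen_table(tb, sc)
    tb$gene[tb[[sc]] < rra_max & tb$log2FC < lfc_max]
  })
  sort(Reduce(intersect, per_pop))
}

#' Screen hit filter for one pairwise comparison
#'
#' Hits satisfy: RRA score strictly below `rra_max`, `log2FC > lfc_abs`
#' (enriched) or `log2FC < -lfc_abs` (depleted) — strict in both
#' directions — and `goodsgrna >= min_goodsgrna` (inclusive).
#'
#' @param table Gene-summary data.frame.
#' @param direction `"enriched"` or `"depleted"`.
#' @param rra_max,lfc_abs,min_goodsgrna Thresholds (defaults 0.05, 0.8, 3).
#' @param audit Return the full pass/fail table per criterion instead of
#'   the gene list.
#' @return Sorted character vector of hits, or (with `audit = TRUE`) a
#'   data.frame with per-criterion logical columns and `hit`.
#' @export
hit_filter <- function(table, direction = c("enriched", "depleted"),
                       rra_max = 0.05, lfc_abs = 0.8, min_goodsgrna = 3L,
                       audit = FALSE) {
  direction <- match.arg(direction)
  sc <- rra_column(table, direction)
  validate_screen_table(table, sc)
  pass_rra <- table[[sc]] < rra_max
  pass_lfc <- if (direction == "enriched") table$log2FC > lfc_abs
              else table$log2FC < -lfc_abs
  pass_grna <- table$goodsgrna >= min_goodsgrna
  hit <- pass_rra & pass_lfc & pass_grna
  if (audit) {
    return(data.frame(gene = table$gene, rra_score = table[[sc]],
                      log2FC = table$log2FC, goodsgrna = table$goodsgrna,
                      pass_rra = pass_rra, pass_lfc = pass_lfc,
                      pass_goodsgrna = pass_grna, hit = hit,
                      stringsAsFactors = FALSE))
  }
  sort(table$gene[hit])
}

#' Average gRNAs per gene of a screen library
#'
#' Defaults describe the genome-wide mouse KO library used with this
#' workflow: 90,230 gRNAs targeting 18,424 genes, i.e. an average of 5
#' gRNAs per gene once rounded.
#'
#' @param n_grnas,n_genes Library composition.
#' @return The average `n_grnas / n_genes` (unrounded).
#' @export
grnas_per_gene <- function(n_grnas = 90230, n_genes = 18424) {
  if (n_genes <= 0) stopf("n_genes must be positive")
  n_grnas / n_genes
}
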