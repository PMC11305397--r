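#' Simulate allele-resolved expression count tables
#'
#' Per gene and population the total count is negative-binomial
#' (`mean_total`, `dispersion` = NB size) and the mus/cas split binomial
#' with a known true mus ratio. The gene set is engineered to exercise the
#' downstream filters: clearly reactivating genes (true NPC ratio well
#' under 0.135, including one gene at exactly 0), clear escapees (well
#' above), genes near the 0.135 threshold, and genes that fail the
#' strict >25% cas-fraction informativeness rule in at least one
#' population.
#'
#' @param n_genes Number of genes (default 60).
#' @param populations Population labels; must include `"NPC"`.
#' @param mean_total,dispersion Negative-binomial total-count parameters
#'   (defaults 10000 and 10).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List: `table` (gene, population, count_mus, count_cas),
#'   `truth` (gene, population, true_ratio), `classes` (gene,
#'   true_class in reactivating/escapee/uninformative).
#' @export
simulate_allelic_counts <- function(n_genes = 60L,
                                    populations = c("NPC", "d2", "d5",
                                                    "d7_neg", "d7_med",
                                                    "d7_high", "ESC"),
                                    mean_total = 10000, dispersion = 10,
                                    seed = 1L) {
  if (!length(populations)) stopf("populations must be non-empty")
  if (!"NPC" %in% populations) stopf("populations must include 'NPC'")
  n_genes <- as.integer(n_genes)
  if (n_genes < 5L) stopf("n_genes must be at least 5")
  with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    n_re <- max(2L, round(0.4 * n_genes))
    n_es <- max(1L, round(0.3 * n_genes))
    n_near <- max(1L, round(0.15 * n_genes))
    n_un <- n_genes - n_re - n_es - n_near
    kind <- rep(c("reactivating", "escapee", "near", "uninformative"),
                c(n_re, n_es, n_near, n_un))

    npc_ratio <- numeric(n_genes)
    npc_ratio[kind == "reactivating"] <-
      stats::runif(n_re, 0.005, 0.110)
    npc_ratio[kind == "reactivating"][1L] <- 0      # silenced mus allele
    npc_ratio[kind == "escapee"] <- stats::runif(n_es, 0.160, 0.50)
    npc_ratio[kind == "near"] <- stats::runif(n_near, 0.120, 0.150)
    npc_ratio[kind == "uninformative"] <- stats::runif(n_un, 0.1, 0.5)

    truth <- expand.grid(gene = genes, population = populations,
                         stringsAsFactors = FALSE)
    truth$true_ratio <- npc_ratio[match(truth$gene, genes)]
    # reactivation: the mus share rises after NPC, but stays < 0.6 so
    # informative genes keep a cas fraction > 0.25 in every population
    later <- truth$population != "NPC" &
      kind[match(truth$gene, genes)] == "reactivating" &
      truth$true_ratio > 0                 # the fully silenced gene stays 0
    truth$true_ratio[later] <- pmin(
      0.6, truth$true_ratio[later] + stats::runif(sum(later), 0.05, 0.35))
    # uninformative genes: mus-dominated (cas fraction <= 0.25) in one
    # non-NPC population
    for (g in genes[kind == "uninformative"]) {
      pop <- sample(setdiff(populations, "NPC"), 1L)
      truth$true_ratio[truth$gene == g & truth$population == pop] <-
        stats::runif(1L, 0.80, 0.95)
    }

    total <- pmax(1L, stats::rnbinom(nrow(truth), mu = mean_total,
                                     size = dispersion))
    count_mus <- stats::rbinom(nrow(truth), total, truth$true_ratio)
    table <- data.frame(gene = truth$gene, population = truth$population,
                        count_mus = count_mus,
                        count_cas = total - count_mus,
                        stringsAsFactors = FALSE)
    true_class <- ifelse(kind == "uninformative", "uninformative",
                         ifelse(npc_ratio <= 0.135, "reactivating",
                                "escapee"))
    list(table = table, truth = truth,
         classes = data.frame(gene = genes, true_class = true_class,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate paired BS/OxBS methylation-array beta tables
#'
#' Per probe the true state is a (f_C, f_5mC, f_5hmC) composition;
#' `beta_BS ~ f_5mC + f_5hmC` and `beta_OxBS ~ f_5mC` plus Gaussian noise
#' truncated to `[0,1]`. An optional shift is planted on the IFNg arm
#' (`delta_5hmc` added to f_5hmC, `delta_5mc` to f_5mC) to exercise
#' delta-beta and DMP recovery. A binomial fraction of probes is given a
#' failing intensity or detection p-value to exercise QC.
#'
#' @param n_probes Probes (default 1000).
#' @param n_samples_per_arm Samples per arm per chemistry (default 3).
#' @param noise_sd Beta noise SD (default 0.05).
#' @param qc_fail_fraction Probability a probe is planted as a QC failure
#'   (default 0.1).
#' @param delta_5hmc,delta_5mc Planted IFNg-arm shifts (default 0).
#' @param chrx_fraction Fraction of probes on chrX (default 0.3).
#' @param seed Integer seed.
#' @return List: `table` (long: probe_id, chromosome, genomic_feature,
#'   sample_id, arm, chemistry, beta, intensity, detection_p), `truth`
#'   (probe_id, arm, f_5mC, f_5hmC, qc_fail).
#' @export
simulate_beta_matrix <- function(n_probes = 1000L, n_samples_per_arm = 3L,
                                 noise_sd = 0.05, qc_fail_fraction = 0.1,
                                 delta_5hmc = 0, delta_5mc = 0,
                                 chrx_fraction = 0.3, seed = 1L) {
  if (n_probes < 1L) stopf("n_probes must be >= 1")
  with_seed(seed, {
    probes <- sprintf("cg%06d", seq_len(n_probes))
    chrom <- ifelse(stats::runif(n_probes) < chrx_fraction, "chrX",
                    paste0("chr", sample(1:19, n_probes, replace = TRUE)))
    feat <- sample(c("promoter", "gene_body", "distal"), n_probes,
                   replace = TRUE)
    f_5mC <- stats::runif(n_probes, 0.10, 0.60)
    f_5hmC <- stats::runif(n_probes, 0.02, 0.15)
    qc_fail <- stats::runif(n_probes) < qc_fail_fraction
    fail_kind <- sample(c("intensity", "detection"), n_probes,
                        replace = TRUE)

    truth <- rbind(
      data.frame(probe_id = probes, arm = "control", f_5mC = f_5mC,
                 f_5hmC = f_5hmC, qc_fail = qc_fail,
                 stringsAsFactors = FALSE),
      data.frame(probe_id = probes, arm = "IFNg",
                 f_5mC = pmin(1, pmax(0, f_5mC + delta_5mc)),
                 f_5hmC = pmin(1, pmax(0, f_5hmC + delta_5hmc)),
                 qc_fail = qc_fail, stringsAsFactors = FALSE))

    rows <- list()
    for (arm in c("control", "IFNg")) {
      tr <- truth[truth$arm == arm, ]
      for (rep_i in seq_len(n_samples_per_arm)) {
        sid <- sprintf("%s_rep%d", arm, rep_i)
        for (chem in c("BS", "OxBS")) {
          mu <- if (chem == "BS") tr$f_5mC + tr$f_5hmC else tr$f_5mC
          beta <- pmin(1, pmax(0, stats::rnorm(n_probes, mu, noise_sd)))
          intensity <- stats::runif(n_probes, 2000, 8000)
          detp <- stats::runif(n_probes, 0, 0.005)
          bad_int <- qc_fail & fail_kind == "intensity"
          bad_det <- qc_fail & fail_kind == "detection"
          intensity[bad_int] <- stats::runif(sum(bad_int), 100, 999)
          detp[bad_det] <- stats::runif(sum(bad_det), 0.011, 0.2)
          rows[[length(rows) + 1L]] <- data.frame(
            probe_id = probes, chromosome = chrom, genomic_feature = feat,
            sample_id = paste(sid, chem, sep = "_"), arm = arm,
            chemistry = chem, beta = beta, intensity = intensity,
            detection_p = detp, stringsAsFactors = FALSE)
        }
      }
    }
    list(table = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate a MAGeCK-style gene summary table
#'
#' Random gene-level screen summaries for exercising the hit filters: a
#' `signal_fraction` of genes get small RRA scores with large fold
#' changes in the matching direction and supportive goodsgrna counts; the
#' rest are null.
#'
#' @param n_genes Genes (default 1000).
#' @param signal_fraction Fraction of non-null genes (default 0.1);
#'   ignored when `signal_genes` is given.
#' @param comparison Label recorded in the `comparison` column.
#' @param seed Integer seed.
#' @param signal_genes Optional character vector naming the signal genes
#'   explicitly — lets several simulated populations share a common core,
#'   as a real essentialome does.
#' @param signal_direction `"mixed"` (random per gene), `"depleted"` or
#'   `"enriched"`.
#' @return data.frame: gene, rra_score_pos, rra_score_neg, log2FC,
#'   goodsgrna, comparison.
#' @export
simulate_screen_table <- function(n_genes = 1000L, signal_fraction = 0.1,
                                  comparison = "comparison1", seed = 1L,
                                  signal_genes = NULL,
                                  signal_direction = c("mixed", "depleted",
                                                       "enriched")) {
  signal_direction <- match.arg(signal_direction)
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    sig <- if (is.null(signal_genes)) {
      stats::runif(n_genes) < signal_fraction
    } else {
      genes %in% signal_genes
    }
    up <- switch(signal_direction,
                 mixed = sig & stats::runif(n_genes) < 0.5,
                 depleted = rep(FALSE, n_genes),
                 enriched = sig)
    dn <- sig & !up
    lfc <- stats::rnorm(n_genes, 0, 0.4)
    lfc[up] <- stats::runif(sum(up), 0.5, 3)
    lfc[dn] <- -stats::runif(sum(dn), 0.5, 3)
    pos <- stats::runif(n_genes, 0.05, 1)
    neg <- stats::runif(n_genes, 0.05, 1)
    pos[up] <- stats::runif(sum(up), 0, 0.1)
    neg[dn] <- stats::runif(sum(dn), 0, 0.1)
    goods <- sample(0:2, n_genes, replace = TRUE)
    goods[sig] <- sample(2:5, sum(sig), replace = TRUE)
    data.frame(gene = genes, rra_score_pos = pos, rra_score_neg = neg,
               log2FC = lfc, goodsgrna = goods, comparison = comparison,
               stringsAsFactors = FALSE)
  })
}
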