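test_that("gene assignment finds the primer and rejects junk", {
  fx <- fixture_panel()
  ref <- fx$refs$Mtm1
  reads <- c(clean_read(ref, "mus", "TAG"),          # 3 stagger bases
             strrep("A", 250L),                      # junk
             clean_read(fx$refs$Ddx3x, "cas", "GT"))
  expect_identical(assign_gene(reads, fx$refs),
                   c("Mtm1", "unassigned", "Ddx3x"))
  expect_identical(assign_gene(character(0), fx$refs), character(0))
  expect_identical(assign_gene("", fx$refs), "unassigned")
})

test_that("allele assignment reads the base 3' of the SNP anchor", {
  fx <- fixture_panel()
  ref <- fx$refs$Mtm1
  r_mus <- clean_read(ref, "mus")
  r_cas <- clean_read(ref, "cas")
  trunc <- substr(r_mus, 1L, ref$snp_anchor$start)  # anchor incomplete
  third <- r_mus
  at <- 3L + ref$snp_pos                            # stagger "TAG" offset
  substr(third, at, at) <- "C"                      # neither allele
  expect_identical(assign_allele(c(r_mus, r_cas, trunc, third), ref),
                   c("mus", "cas", "ambiguous", "ambiguous"))
})

test_that("CpG calling returns CG, TG or other per the 2-mer rule", {
  fx <- fixture_panel()
  ref <- fx$refs$Mtm1
  p <- ref$cpg_pos[1L]
  r_meth <- clean_read(ref, "mus")                  # CpG kept as C
  r_unmeth <- r_meth
  substr(r_unmeth, 3L + p, 3L + p) <- "T"           # converted
  r_err <- r_meth
  substr(r_err, 3L + p + 1L, 3L + p + 1L) <- "A"    # G->A sequencing error
  expect_identical(call_cpg(c(r_meth, r_unmeth, r_err), ref, p),
                   c("CG", "TG", "other"))
  # anchor absent (truncated before the CpG) -> other
  r_short <- substr(r_meth, 1L, 3L + p - 2L)
  expect_identical(call_cpg(r_short, ref, p), "other")
})

test_that("percent_cg follows 100*CG/(CG+TG) with missing on empty cells", {
  expect_identical(astaseq:::pct_cg_counts(60L, 40L), 60)
  expect_identical(astaseq:::pct_cg_counts(0L, 40L), 0)
  expect_equal(astaseq:::pct_cg_counts(1L, 2L), 100 / 3)  # repeating
  expect_true(is.na(astaseq:::pct_cg_counts(0L, 0L)))
})

test_that("deconvolution is the BS-minus-OxBS identity", {
  expect_equal(deconvolve(60, 40), data.frame(pct_5mC = 40,
                                              pct_5hmC_raw = 20))
  expect_equal(deconvolve(30, 30)$pct_5hmC_raw, 0)
  expect_equal(deconvolve(30, 32)$pct_5hmC_raw, -2)
  expect_error(deconvolve(101, 40), "\\[0,100\\]")
})

make_cells <- function(raws) {
  data.frame(gene = "G", cpg_pos = 10L,
             allele = rep(c("mus", "cas"), 2L),
             condition = rep(c("control", "IFNg"), each = 2L),
             pct_CG_BS = NA_real_, pct_CG_OxBS = NA_real_,
             coverage_BS = 1000L, coverage_OxBS = 1000L,
             pct_5mC = 40, pct_5hmC_raw = raws,
             stringsAsFactors = FALSE)
}

test_that("negative-5hmC rules: discard below -1 hits all four cells", {
  est <- apply_5hmc_filters(make_cells(c(-2, 5, 5, 5)))
  expect_identical(unique(est$status), "discarded")
  expect_true(all(is.na(est$pct_5hmC)))
})

test_that("negative-5hmC rules: values in [-1, 0) clamp to zero", {
  est <- apply_5hmc_filters(make_cells(c(-0.5, 2, 3, -1)))
  expect_identical(est$status, c("clamped", "kept", "kept", "clamped"))
  expect_identical(est$pct_5hmC, c(0, 2, 3, 0))
  # all non-negative: untouched
  est2 <- apply_5hmc_filters(make_cells(c(0, 1, 2, 3)))
  expect_identical(unique(est2$status), "kept")
  expect_identical(est2$pct_5hmC, est2$pct_5hmC_raw)
})

test_that("5hmC filtering is idempotent and order-independent", {
  base <- rbind(make_cells(c(-0.5, 2, 3, 5)),
                transform(make_cells(c(-3, 1, 1, 1)), cpg_pos = 20L))
  once <- apply_5hmc_filters(base)
  twice <- apply_5hmc_filters(once[, names(base)])
  expect_identical(once$status, twice$status)
  expect_identical(once$pct_5hmC, twice$pct_5hmC)
  perm <- sample(nrow(base))
  shuffled <- apply_5hmc_filters(base[perm, ])
  expect_identical(shuffled$status, once$status[perm])
})

test_that("tally conserves reads at every stage", {
  sim <- small_run(n = 60L, model = chemistry_model(0.99, 0.95, 0.002))
  fx <- fixture_panel()
  fit <- asta_quantify(sim$manifest, fx$panel, min_coverage = 10L)
  ga <- fit$tally$gene_accounting
  sa <- fit$tally$sample_accounting
  for (s in sa$sample_id) {
    g <- ga[ga$sample_id == s, ]
    expect_identical(sum(g$n_allele_mus + g$n_allele_cas + g$n_ambiguous),
                     sum(g$n_gene_assigned))
    expect_identical(sum(g$n_gene_assigned) +
                       sa$n_unassigned[sa$sample_id == s],
                     sa$n_total[sa$sample_id == s])
  }
  # CG+TG+other accounts for every used read at single-CpG resolution
  expect_true(all(fit$tally$counts$n_CG >= 0L))
})

test_that("error-free runs classify every read correctly", {
  sim <- small_run(n = 40L, model = chemistry_model(1, 1, 0))
  fx <- fixture_panel()
  reads <- astaseq:::read_fastq(sim$manifest$fastq[1L])
  rt <- sim$read_truth[sim$read_truth$sample_id ==
                         sim$manifest$sample_id[1L], ]
  rt <- rt[match(names(reads), rt$read_id), ]
  genes <- assign_gene(unname(reads), fx$refs)
  expect_identical(genes, rt$gene)                  # 100% gene accuracy
  for (g in unique(rt$gene)) {
    idx <- rt$gene == g
    alleles <- assign_allele(unname(reads)[idx], fx$refs[[g]])
    expect_identical(alleles, rt$allele[idx])       # 100% allele accuracy
  }
})

test_that("realistic error rates keep gene assignment above 99%", {
  sim <- small_run(n = 400L, model = chemistry_model(0.99, 0.95, 0.001))
  fx <- fixture_panel()
  fit <- asta_quantify(sim$manifest, fx$panel)
  sa <- fit$tally$sample_accounting
  expect_true(all(sa$n_gene_assigned >= 0.99 * sa$n_total))
})

test_that("empty FASTQ yields an all-zero tally without crashing", {
  d <- withr::local_tempdir()
  f <- file.path(d, "empty.fastq")
  writeLines(character(0), f)
  fx <- fixture_panel()
  tly <- tally_reads(
    data.frame(fastq = f, condition = "control", chemistry = "BS",
               stringsAsFactors = FALSE),
    fx$panel)
  expect_identical(sum(tly$counts$n_CG + tly$counts$n_TG +
                         tly$counts$n_other), 0L)
  expect_identical(tly$sample_accounting$n_total, 0L)
})

test_that("unknown sample labels are a hard error", {
  fx <- fixture_panel()
  expect_error(
    tally_reads(data.frame(fastq = "x.fastq", condition = "control",
                           chemistry = "oxidative"), fx$panel),
    "unknown sample label")
})

test_that("lower oxidation efficiency inflates 5mC monotonically", {
  fx <- fixture_panel()
  panel <- fx$panel["Dlg3"]
  spec <- panel[[1L]]
  truth <- data.frame(gene = "Dlg3",
                      allele = rep(c("mus", "cas"),
                                   each = length(spec$cpg_pos)),
                      cpg_pos = rep(spec$cpg_pos, 2L),
                      f_C = 0.4, f_5mC = 0.3, f_5hmC = 0.3,
                      stringsAsFactors = FALSE)
  est_5mc <- vapply(c(1.0, 0.95, 0.9), function(ox) {
    d <- withr::local_tempdir()
    m <- sim_manifest(conditions = "control",
                      reads_per_allele_per_gene = 4000L)
    sim <- simulate_reads(panel, truth, chemistry_model(1, ox, 0), m,
                          out_dir = d, seed = 21L)
    fit <- asta_quantify(sim$manifest, panel)
    mean(fit$estimates$pct_5mC)
  }, numeric(1L))
  # ox = 1 recovers truth; each efficiency loss shifts 5hmC into 5mC
  expect_lt(abs(est_5mc[1L] - 30), 2)
  expect_true(all(diff(est_5mc) > 0))
  expect_gte(est_5mc[3L], 30)
})

test_that("incomplete conversion inflates %CG in both arms", {
  fx <- fixture_panel()
  panel <- fx$panel["Eda"]
  spec <- panel[[1L]]
  truth <- data.frame(gene = "Eda",
                      allele = rep(c("mus", "cas"),
                                   each = length(spec$cpg_pos)),
                      cpg_pos = rep(spec$cpg_pos, 2L),
                      f_C = 0.6, f_5mC = 0.3, f_5hmC = 0.1,
                      stringsAsFactors = FALSE)
  pct <- lapply(c(1.0, 0.9), function(conv) {
    d <- withr::local_tempdir()
    m <- sim_manifest(conditions = "control",
                      reads_per_allele_per_gene = 4000L)
    sim <- simulate_reads(panel, truth, chemistry_model(conv, 1, 0), m,
                          out_dir = d, seed = 22L)
    fit <- asta_quantify(sim$manifest, panel)
    c(bs = mean(fit$estimates$pct_CG_BS),
      ox = mean(fit$estimates$pct_CG_OxBS))
  })
  expect_gt(pct[[2L]]["bs"], pct[[1L]]["bs"])
  expect_gt(pct[[2L]]["ox"], pct[[1L]]["ox"])
})

test_that("escapee amplicons stay below 7% for both marks", {
  sim <- small_run(n = 1500L, model = chemistry_model(1, 1, 0))
  fx <- fixture_panel()
  fit <- asta_quantify(sim$manifest, fx$panel)
  esc <- fit$estimates[fit$estimates$gene %in% c("Ddx3x", "Eif2s3x"), ]
  expect_true(all(esc$pct_5mC <= 7))
  expect_true(all(esc$pct_5hmC <= 7, na.rm = TRUE))
})

test_that("low-coverage cells are flagged", {
  sim <- small_run(n = 30L)
  fx <- fixture_panel()
  fit <- asta_quantify(sim$manifest, fx$panel, min_coverage = 100L)
  expect_true(all(fit$estimates$low_coverage))
  fit2 <- asta_quantify(sim$manifest, fx$panel, min_coverage = 1L)
  expect_false(any(fit2$estimates$low_coverage))
})

test_that("asta_fit methods expose estimates coherently", {
  sim <- small_run(n = 50L, model = chemistry_model(1, 1, 0))
  fx <- fixture_panel()
  fit <- asta_quantify(sim$manifest, fx$panel, min_coverage = 10L)
  expect_s3_class(fit, "asta_fit")
  cm <- coef(fit)
  expect_identical(colnames(cm), c("pct_5mC", "pct_5hmC"))
  expect_identical(nrow(cm), nrow(fit$estimates))
  expect_output(print(fit), "Allele-specific amplicon")
  expect_output(print(summary(fit)), "Read accounting")
})
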