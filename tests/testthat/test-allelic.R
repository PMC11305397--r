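test_that("allelic ratio is mus/(mus+cas) with a missing degenerate case", {
  expect_identical(allelic_ratio(20, 80), 0.2)
  expect_identical(allelic_ratio(0, 50), 0)
  expect_true(is.na(allelic_ratio(0, 0)))
  expect_error(allelic_ratio(-1, 5), "non-negative")
  # bounded and strictly increasing in count_mus
  r <- allelic_ratio(0:100, 50)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(diff(r) > 0))
})

allelic_fixture <- function(cas_fracs, pops = c("NPC", "d2")) {
  do.call(rbind, lapply(names(cas_fracs), function(g) {
    data.frame(gene = g, population = pops,
               count_mus = round(1000 * (1 - cas_fracs[[g]])),
               count_cas = round(1000 * cas_fracs[[g]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("informative-gene selection applies the strict >25% rule", {
  tb <- allelic_fixture(list(a = c(0.26, 0.26),   # just over: kept
                             b = c(0.26, 0.25),   # exactly 25% once: drop
                             c = c(0.90, 0.90),   # clearly kept
                             d = c(0.10, 0.80)))  # under once: drop
  expect_identical(select_informative(tb), c("a", "c"))
  # zero-total population drops the gene
  tb2 <- rbind(tb, data.frame(gene = "e", population = c("NPC", "d2"),
                              count_mus = c(0, 10),
                              count_cas = c(0, 90)))
  expect_false("e" %in% select_informative(tb2))
})

test_that("classification threshold 0.135 is inclusive downward", {
  tb <- do.call(rbind, lapply(
    list(c("at", 0.135), c("above", 0.14), c("below", 0.05)),
    function(x) {
      r <- as.numeric(x[2L])
      data.frame(gene = x[1L], population = c("NPC", "d2"),
                 count_mus = round(10000 * c(r, 0.5)),
                 count_cas = round(10000 * c(1 - r, 0.5)),
                 stringsAsFactors = FALSE)
    }))
  cls <- classify_genes(tb, "NPC")
  got <- stats::setNames(cls$class, cls$gene)
  expect_identical(got[["at"]], "reactivating")
  expect_identical(got[["above"]], "escapee")
  expect_identical(got[["below"]], "reactivating")
  # non-informative gene
  tb2 <- rbind(tb, data.frame(gene = "mus_only", population = c("NPC", "d2"),
                              count_mus = c(9000, 9000),
                              count_cas = c(1000, 1000)))
  cls2 <- classify_genes(tb2, "NPC")
  expect_identical(cls2$class[cls2$gene == "mus_only"], "uninformative")
  expect_error(classify_genes(tb, "NPC_missing"), "absent")
})

test_that("classification is idempotent and partitions the gene set", {
  sim <- simulate_allelic_counts(n_genes = 40L, seed = 3L)
  c1 <- classify_genes(sim$table)
  c2 <- classify_genes(sim$table)
  expect_identical(c1, c2)
  expect_setequal(c1$gene, unique(sim$table$gene))
  expect_true(all(c1$class %in% c("reactivating", "escapee",
                                  "uninformative")))
})

test_that("simulated allelic counts honour their engineered truth", {
  sim <- simulate_allelic_counts(n_genes = 60L, seed = 2L)
  # identical seed, identical table; different seed differs
  expect_identical(sim$table,
                   simulate_allelic_counts(n_genes = 60L, seed = 2L)$table)
  expect_false(identical(
    sim$table, simulate_allelic_counts(n_genes = 60L, seed = 9L)$table))
  # the zero-ratio gene has zero mus counts everywhere
  zero_gene <- sim$truth$gene[sim$truth$true_ratio == 0][1L]
  expect_identical(
    sum(sim$table$count_mus[sim$table$gene == zero_gene]), 0L)
  # both sides of 0.135 and both sides of the 25% rule are represented
  expect_true(all(c("reactivating", "escapee", "uninformative") %in%
                    sim$classes$true_class))
})

test_that("estimated ratios recover truth within binomial error", {
  sim <- simulate_allelic_counts(n_genes = 50L, mean_total = 10000,
                                 dispersion = 1e6, seed = 4L)
  tb <- merge(sim$table, sim$truth, by = c("gene", "population"))
  est <- allelic_ratio(tb$count_mus, tb$count_cas)
  n <- tb$count_mus + tb$count_cas
  se <- sqrt(pmax(tb$true_ratio * (1 - tb$true_ratio), 1e-6) / n)
  z <- abs(est - tb$true_ratio) / (se + 1 / n)
  # per-cell binomial error: ~99.7% within 3 SE, none grossly outside
  expect_gte(mean(z <= 3), 0.99)
  expect_true(all(z <= 4.5))
})

test_that("pluripotency score is the mean of ESC-normalized ratios", {
  genes <- c("Nanog", "Zfp42", "Dppa4", "Dppa5a", "Esrrb", "Prdm14",
             "Sall4")
  base <- c(100, 50, 80, 120, 60, 40, 90)
  mk <- function(sample, vals) {
    data.frame(gene = genes, sample = sample, expression = vals,
               stringsAsFactors = FALSE)
  }
  expr <- rbind(mk("ESC_r1", base), mk("ESC_r2", base),
                mk("self", base), mk("half", base / 2),
                mk("mixed", base * c(1, 1, 1, 1, 1, 1, 0.3)))
  sc <- pluripotency_score(expr, esc_samples = c("ESC_r1", "ESC_r2"))
  expect_identical(unname(sc["self"]), 1)
  expect_identical(unname(sc["half"]), 0.5)
  expect_equal(unname(sc["mixed"]), 0.9)     # (6 + 0.3)/7
  # permutation invariance over gene order
  perm <- expr[sample(nrow(expr)), ]
  sc_perm <- pluripotency_score(perm, c("ESC_r1", "ESC_r2"))
  expect_equal(sc_perm[names(sc)], sc)
  # linearity in a single gene's ratio
  lin <- vapply(c(0.2, 0.4, 0.6), function(a) {
    e <- rbind(mk("ESC_r1", base), mk("s", base * c(a, rep(1, 6))))
    pluripotency_score(e, "ESC_r1")[["s"]]
  }, numeric(1L))
  expect_equal(diff(lin), rep(0.2 / 7, 2L))
  # errors: missing gene, zero ESC expression
  expect_error(pluripotency_score(expr[expr$gene != "Nanog", ],
                                  c("ESC_r1", "ESC_r2")), "Nanog")
  zero <- expr
  zero$expression[zero$sample %in% c("ESC_r1", "ESC_r2") &
                    zero$gene == "Sall4"] <- 0
  expect_error(pluripotency_score(zero, c("ESC_r1", "ESC_r2")), "Sall4")
})

test_that("qPCR relative expression follows 2^-dCT", {
  expect_identical(qpcr_expression(20, 20), 1)
  expect_identical(qpcr_expression(21, 20), 0.5)
  expect_identical(qpcr_expression(18, 20), 4)
  expect_error(qpcr_expression(NA, 20), "finite")
})
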