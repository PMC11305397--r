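# Shared fixtures, all generated in code.

# Cached default panel + references (building anchors is cheap but used in
# many files).
fixture_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pan <- make_default_panel(seed = 1L)
      cache <<- list(panel = pan$panel, truth = pan$truth,
                     refs = lapply(pan$panel, bs_convert_reference))
    }
    cache
  }
})

# A clean read for one allele of a reference: stagger + bisulfite-space
# body with every CpG left as C (fully methylated read).
clean_read <- function(ref, allele = "mus", stagger = "TAG") {
  body <- if (allele == "mus") ref$bs_mus else ref$bs_cas
  paste0(stagger, body)
}

# Simulate one small run and return manifest + truth + fit pieces.
small_run <- function(n = 500L, model = chemistry_model(1, 1, 0),
                      conditions = "control", seed = 7L,
                      panel = NULL, truth = NULL) {
  fx <- fixture_panel()
  panel <- panel %||% fx$panel
  truth <- truth %||% fx$truth
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  m <- sim_manifest(conditions = conditions,
                    reads_per_allele_per_gene = n)
  sim <- simulate_reads(panel, truth, model, m, out_dir = dir, seed = seed)
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Binomial standard error on the percent scale.
pct_se <- function(p, n) 100 * sqrt(p * (1 - p) / n)

# Independent Welch t-test oracle: statistic and p from first principles.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}
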