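# Internal helpers shared across modules.

# Collapse C to T so comparisons happen in fully bisulfite-converted space.
bs_collapse <- function(x) chartr("C", "T", x)

# Split one sequence into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Provenance header written at the top of every output table (criterion:
# outputs are reproducible from seed + thresholds alone).
provenance_lines <- function(seed = NA, thresholds = list()) {
  kv <- c(
    sprintf("astaseq_version=%s",
            as.character(utils::packageVersion("astaseq"))),
    sprintf("seed=%s", seed),
    if (length(thresholds)) {
      sprintf("%s=%s", names(thresholds),
              vapply(thresholds, format, character(1L)))
    }
  )
  paste0("# ", kv)
}

write_tsv_prov <- function(df, path, seed = NA, thresholds = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed, thresholds), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
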