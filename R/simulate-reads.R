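#' Build a simulation manifest
#'
#' One sample per condition x chemistry combination. Every condition must
#' carry both a BS and an OxBS sample (paired mock-oxidation and oxidation
#' aliquots of the same DNA), which [simulate_reads()] enforces.
#'
#' @param conditions Character vector of condition labels.
#' @param chemistries Chemistry labels; must be `"BS"` and `"OxBS"`.
#' @param reads_per_allele_per_gene Reads simulated per gene, allele and
#'   sample.
#' @return data.frame with columns sample_id, condition, chemistry,
#'   reads_per_allele_per_gene, fastq.
#' @export
sim_manifest <- function(conditions = c("control", "IFNg"),
                         chemistries = c("BS", "OxBS"),
                         reads_per_allele_per_gene = 20000L) {
  grid <- expand.grid(chemistry = chemistries, condition = conditions,
                      stringsAsFactors = FALSE)[, c("condition", "chemistry")]
  grid$sample_id <- paste(grid$condition, grid$chemistry, sep = "_")
  grid$reads_per_allele_per_gene <- as.integer(reads_per_allele_per_gene)
  grid$fastq <- paste0(grid$sample_id, ".fastq")
  validate_manifest(grid)
  grid[, c("sample_id", "condition", "chemistry",
           "reads_per_allele_per_gene", "fastq")]
}

validate_manifest <- function(manifest) {
  need <- c("sample_id", "condition", "chemistry",
            "reads_per_allele_per_gene", "fastq")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stopf("manifest missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(!manifest$chemistry %in% c("BS", "OxBS"))) {
    stopf("manifest chemistry must be 'BS' or 'OxBS'")
  }
  if (any(manifest$reads_per_allele_per_gene < 1L)) {
    stopf("reads_per_allele_per_gene must be >= 1")
  }
  if (anyDuplicated(manifest$sample_id)) stopf("duplicate sample_id")
  for (cond in unique(manifest$condition)) {
    chem <- manifest$chemistry[manifest$condition == cond]
    if (!all(c("BS", "OxBS") %in% chem)) {
      stopf("condition '%s' lacks a paired BS/OxBS sample", cond)
    }
  }
  invisible(manifest)
}

#' Simulate targeted-amplicon BS/OxBS reads
#'
#' Emits single-end MiSeq-like reads: 2-5 random stagger bases, then the
#' bisulfite-space amplicon body (whose prefix is the gene-specific
#' primer), truncated to 300 bp. Per read, each CpG cytosine is emitted as
#' C with probability
#' \deqn{p_C^{BS} = f_{5mC} + f_{5hmC} + f_C (1 - conv\_rate)}
#' \deqn{p_C^{OxBS} = f_{5mC} + f_{5hmC} (1 - ox\_rate) + f_C (1 - conv\_rate)}
#' non-CpG cytosines convert to T with probability `conv_rate`, the SNP base
#' comes from the read's allele, and a uniform substitution error
#' (`seq_err`) is applied last. Deterministic given `seed`.
#'
#' @param panel Named list of [amplicon_spec()] objects.
#' @param truth Truth table (see [validate_truth()]), or a named list of
#'   truth tables keyed by condition when conditions differ.
#' @param model A [chemistry_model()].
#' @param manifest A [sim_manifest()]-style data.frame.
#' @param out_dir Output directory (created if needed); FASTQ files and the
#'   truth TSV(s) are written there.
#' @param seed Integer seed.
#' @return Invisibly, a list: `manifest` (with absolute fastq paths),
#'   `read_truth` (data.frame sample_id, read_id, gene, allele — for
#'   validation only; read names in the FASTQ leak no truth), and
#'   `truth_files`.
#' @export
simulate_reads <- function(panel, truth, model = chemistry_model(),
                           manifest = sim_manifest(), out_dir, seed = 1L) {
  validate_manifest(manifest)
  truth_by_cond <- if (is.data.frame(truth)) {
    validate_truth(truth)
    stats::setNames(rep(list(truth), length(unique(manifest$condition))),
                    unique(manifest$condition))
  } else {
    lapply(truth, validate_truth)
    miss <- setdiff(unique(manifest$condition), names(truth))
    if (length(miss)) stopf("no truth table for condition(s): %s",
                            paste(miss, collapse = ", "))
    truth
  }
  for (spec in panel) check_read_span(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- with_seed(seed, {
    rt <- list()
    paths <- character(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      smp <- manifest[i, ]
      n <- smp$reads_per_allele_per_gene
      tr <- truth_by_cond[[smp$condition]]
      seqs <- character(0)
      gene_of <- character(0)
      allele_of <- character(0)
      for (spec in panel) {
        for (allele in c("mus", "cas")) {
          seqs <- c(seqs,
                    sim_read_batch(spec, tr, allele, smp$chemistry, model, n))
          gene_of <- c(gene_of, rep(spec$gene_name, n))
          allele_of <- c(allele_of, rep(allele, n))
        }
      }
      ord <- sample.int(length(seqs))
      seqs <- seqs[ord]
      gene_of <- gene_of[ord]
      allele_of <- allele_of[ord]
      ids <- sprintf("%s_%07d", smp$sample_id, seq_along(seqs))
      fp <- file.path(out_dir, smp$fastq)
      write_fastq(seqs, ids, fp)
      paths[i] <- fp
      rt[[i]] <- data.frame(sample_id = smp$sample_id, read_id = ids,
                            gene = gene_of, allele = allele_of,
                            stringsAsFactors = FALSE)
    }
    list(paths = paths, read_truth = do.call(rbind, rt))
  })

  manifest$fastq <- res$paths
  truth_files <- character(0)
  for (cond in names(truth_by_cond)) {
    tf <- file.path(out_dir, sprintf("truth_%s.tsv", cond))
    write_truth(truth_by_cond[[cond]], tf, seed = seed)
    truth_files <- c(truth_files, tf)
  }
  invisible(list(manifest = manifest, read_truth = res$read_truth,
                 truth_files = truth_files))
}

# Reads are truncated at 300 bp; with the maximum stagger every CpG (and
# its G) and the SNP must still fall inside the read.
check_read_span <- function(spec, read_len = 300L) {
  smax <- spec$stagger_range[2L]
  worst <- max(spec$snp_pos, spec$cpg_pos + 1L) + smax
  if (worst > read_len) {
    stopf("%s: SNP or CpG beyond the %d bp read span (needs %d bp)",
          spec$gene_name, read_len, worst)
  }
  invisible(spec)
}

# Vectorized batch of n reads for one (gene, allele, chemistry).
sim_read_batch <- function(spec, truth, allele, chemistry, model, n) {
  hap <- if (allele == "mus") spec$seq_mus else spec$seq_cas
  tmpl <- seq_chars(hap)
  L <- length(tmpl)
  m <- matrix(rep(tmpl, each = n), nrow = n)
  conv <- model$conv_rate
  tr <- truth[truth$gene == spec$gene_name & truth$allele == allele, ]
  for (j in setdiff(which(tmpl == "C"), spec$cpg_pos)) {
    m[, j] <- c("C", "T")[(stats::runif(n) < conv) + 1L]
  }
  for (p in spec$cpg_pos) {
    row <- tr[tr$cpg_pos == p, ]
    if (nrow(row) != 1L) {
      stopf("truth missing for %s/%s CpG %d", spec$gene_name, allele, p)
    }
    p_C <- if (chemistry == "BS") {
      row$f_5mC + row$f_5hmC + row$f_C * (1 - conv)
    } else {
      row$f_5mC + row$f_5hmC * (1 - model$ox_rate) + row$f_C * (1 - conv)
    }
    m[, p] <- c("T", "C")[(stats::runif(n) < p_C) + 1L]
  }
  if (model$seq_err > 0) {
    nerr <- stats::rbinom(1L, n * L, model$seq_err)
    if (nerr > 0L) {
      pos <- sample.int(n * L, nerr)
      bases <- c("A", "C", "G", "T")
      cur <- match(m[pos], bases)
      m[pos] <- bases[((cur - 1L + sample.int(3L, nerr, replace = TRUE)) %% 4L) + 1L]
    }
  }
  body <- do.call(paste0, asplit(m, 2L))
  smin <- spec$stagger_range[1L]
  smax <- spec$stagger_range[2L]
  slen <- sample(seq.int(smin, smax), n, replace = TRUE)
  sm <- matrix(sample(c("A", "C", "G", "T"), n * smax, replace = TRUE),
               nrow = n)
  stag <- substr(do.call(paste0, asplit(sm, 2L)), 1L, slen)
  substr(paste0(stag, body), 1L, 300L)
}

# FASTQ IO via Biostrings; quality fixed at Q40 ('I'), unused downstream.
write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}
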