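#' Assign reads to genes by PCR2 primer
#'
#' Scans the first `max(stagger) + nchar(primer)` bases of each read for an
#' exact occurrence of each gene's primer, compared in C/T-collapsed space
#' (primers live in bisulfite space, and an unconverted C in the read must
#' still match). Reads matching zero or more than one primer are
#' `"unassigned"`.
#'
#' @param reads Character vector of read sequences.
#' @param refs Named list of [bs_convert_reference()] objects.
#' @return Character vector: gene name or `"unassigned"` per read.
#' @export
assign_gene <- function(reads, refs) {
  out <- rep("unassigned", length(reads))
  if (!length(reads)) return(out)
  nhit <- integer(length(reads))
  collapsed <- bs_collapse(reads)
  for (ref in refs) {
    window <- substr(collapsed, 1L, ref$stagger_range[2L] + nchar(ref$primer))
    hit <- regexpr(ref$primer, window, fixed = TRUE) > 0L
    out[hit & nhit == 0L] <- ref$gene_name
    nhit <- nhit + hit
  }
  out[nhit > 1L] <- "unassigned"
  out
}

# Locate an anchor in each read. Returns the 1-based start of a unique
# match, -1 when absent, -2 when the anchor occurs more than once
# (conflicting hits are treated as unresolvable).
locate_anchor <- function(reads, anchor, max_mismatch = 0L) {
  if (max_mismatch > 0L) return(locate_anchor_mm(reads, anchor, max_mismatch))
  pat <- anchor$pattern
  fixed <- !grepl("[", pat, fixed = TRUE)
  m1 <- regexpr(pat, reads, fixed = fixed, perl = !fixed)
  pos <- as.integer(m1)
  found <- pos > 0L
  if (any(found)) {
    rest <- substr(reads[found], pos[found] + 1L, nchar(reads[found]))
    m2 <- regexpr(pat, rest, fixed = fixed, perl = !fixed)
    dup <- m2 > 0L
    pos[found][dup] <- -2L
  }
  pos
}

# Mismatch-tolerant slide (slow path, only when max_mismatch > 0): compares
# the anchor against every read offset, C/T-collapsed at ambiguous
# positions, and keeps a unique best hit within the mismatch budget.
locate_anchor_mm <- function(reads, anchor, max_mismatch) {
  ach <- seq_chars(anchor$seq)
  # positions marked [CT] in the pattern:
  ambig_rel <- which(seq_chars(gsub("\\[CT\\]", "?", anchor$pattern)) == "?")
  alen <- anchor$len
  vapply(reads, function(r) {
    rch <- seq_chars(r)
    nr <- length(rch)
    if (nr < alen) return(-1L)
    hits <- integer(0)
    for (s in seq_len(nr - alen + 1L)) {
      win <- rch[s:(s + alen - 1L)]
      mm <- win != ach
      if (length(ambig_rel)) {
        mm[ambig_rel] <- !(win[ambig_rel] %in% c("C", "T"))
      }
      if (sum(mm) <= max_mismatch) hits <- c(hits, s)
      if (length(hits) > 1L) return(-2L)
    }
    if (length(hits) == 1L) hits else -1L
  }, integer(1L), USE.NAMES = FALSE)
}

#' Assign gene-matched reads to alleles by the SNP anchor
#'
#' Locates the 15-20 nt bisulfite-space anchor immediately 5' of the SNP
#' (exact match; C/T-collapsed only at CpG ambiguity positions) and
#' inspects the base immediately 3' of it. Returns `"mus"` or `"cas"` when
#' that base equals the respective bisulfite-space SNP allele, otherwise
#' `"ambiguous"` (anchor absent, duplicated, read truncated, or a third
#' base at the SNP).
#'
#' @param reads Character vector of reads already assigned to this gene.
#' @param ref A [bs_convert_reference()].
#' @param max_mismatch Mismatches tolerated in the anchor (default 0).
#' @return Character vector in `c("mus", "cas", "ambiguous")`.
#' @export
assign_allele <- function(reads, ref, max_mismatch = 0L) {
  out <- rep("ambiguous", length(reads))
  if (!length(reads)) return(out)
  pos <- locate_anchor(reads, ref$snp_anchor, max_mismatch)
  ok <- pos > 0L
  at <- pos + ref$snp_anchor$len
  base <- substr(reads, at, at)
  out[ok & base == ref$snp_base_bs[["mus"]]] <- "mus"
  out[ok & base == ref$snp_base_bs[["cas"]]] <- "cas"
  out
}

#' Call CG/TG state at one CpG per read
#'
#' Locates the CpG's upstream anchor and reads the 2-mer immediately 3' of
#' it: `"CG"` (methylated, unconverted), `"TG"` (unmethylated, converted)
#' or `"other"` (anchor missing or duplicated, read truncated, or a 2-mer
#' outside \{CG, TG\}, e.g. from a sequencing error). `"other"` calls are
#' excluded from %CG denominators.
#'
#' @param reads Character vector of reads assigned to this gene.
#' @param ref A [bs_convert_reference()].
#' @param cpg_pos CpG cytosine position (1-based, reference coordinates).
#' @param max_mismatch Mismatches tolerated in the anchor (default 0).
#' @return Character vector in `c("CG", "TG", "other")`.
#' @export
call_cpg <- function(reads, ref, cpg_pos, max_mismatch = 0L) {
  calls <- call_cpg_full(reads, ref, cpg_pos, max_mismatch)
  calls[calls == "missing"] <- "other"
  calls
}

# Internal variant keeping "missing" (anchor/2-mer not recoverable)
# distinct from "other" (recovered but non-CG/TG), which the tally needs
# for the "SNP and at least one CpG in the same read" inclusion rule.
call_cpg_full <- function(reads, ref, cpg_pos, max_mismatch = 0L) {
  out <- rep("missing", length(reads))
  if (!length(reads)) return(out)
  anchor <- ref$cpg_anchors[[as.character(cpg_pos)]]
  if (is.null(anchor)) stopf("%s has no CpG at position %s",
                             ref$gene_name, cpg_pos)
  pos <- locate_anchor(reads, anchor, max_mismatch)
  at <- pos + anchor$len
  ok <- pos > 0L & (at + 1L) <= nchar(reads)
  dimer <- substr(reads, at, at + 1L)
  out[ok] <- "other"
  out[ok & dimer == "CG"] <- "CG"
  out[ok & dimer == "TG"] <- "TG"
  out
}

#' Tally CG/TG calls over FASTQ samples
#'
#' Streams each FASTQ once through the full classification chain: gene by
#' primer, allele by SNP anchor, CG/TG per CpG. Only reads in which the SNP
#' and at least one CpG are both recoverable contribute to the counts.
#' Per-gene read accounting (assigned / mus / cas / ambiguous) is retained
#' so that conservation can be audited: classified + ambiguous +
#' unassigned = input reads at every stage.
#'
#' @param samples data.frame with columns `fastq`, `condition`,
#'   `chemistry` (`"BS"`/`"OxBS"`), and optionally `sample_id`.
#' @param panel Named list of [amplicon_spec()] objects (or pre-built
#'   references via `refs`).
#' @param max_mismatch Anchor mismatches tolerated (default 0).
#' @param refs Optional pre-computed list of [bs_convert_reference()].
#' @return An object of class `"cpg_tally"`: `counts` (gene, condition,
#'   chemistry, allele, cpg_pos, n_CG, n_TG, n_other),
#'   `gene_accounting`, `sample_accounting`.
#' @export
tally_reads <- function(samples, panel, max_mismatch = 0L, refs = NULL) {
  need <- c("fastq", "condition", "chemistry")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("sample sheet missing columns: %s",
                          paste(miss, collapse = ", "))
  bad <- !samples$chemistry %in% c("BS", "OxBS") |
    is.na(samples$condition) | samples$condition == ""
  if (any(bad)) {
    stopf("unknown sample label in rows: %s",
          paste(which(bad), collapse = ","))
  }
  if (is.null(samples$sample_id)) {
    samples$sample_id <- basename(samples$fastq)
  }
  if (is.null(refs)) refs <- lapply(panel, bs_convert_reference)

  counts <- list()
  gene_acc <- list()
  samp_acc <- list()
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    reads <- read_fastq(smp$fastq)
    n_total <- length(reads)
    genes <- assign_gene(reads, refs)
    n_assigned <- sum(genes != "unassigned")
    samp_acc[[i]] <- data.frame(
      sample_id = smp$sample_id, condition = smp$condition,
      chemistry = smp$chemistry, n_total = n_total,
      n_gene_assigned = n_assigned,
      n_unassigned = n_total - n_assigned, stringsAsFactors = FALSE)
    for (ref in refs) {
      g <- ref$gene_name
      greads <- reads[genes == g]
      alleles <- assign_allele(greads, ref, max_mismatch)
      calls <- lapply(ref$cpg_pos, function(p) {
        call_cpg_full(greads, ref, p, max_mismatch)
      })
      names(calls) <- as.character(ref$cpg_pos)
      any_cpg <- Reduce(`|`, lapply(calls, function(x) x != "missing"),
                        accumulate = FALSE,
                        init = rep(FALSE, length(greads)))
      for (allele in c("mus", "cas")) {
        use <- alleles == allele & any_cpg
        for (p in ref$cpg_pos) {
          cl <- calls[[as.character(p)]][use]
          counts[[length(counts) + 1L]] <- data.frame(
            gene = g, condition = smp$condition, chemistry = smp$chemistry,
            allele = allele, cpg_pos = p,
            n_CG = sum(cl == "CG"), n_TG = sum(cl == "TG"),
            n_other = sum(cl == "other"), stringsAsFactors = FALSE)
        }
      }
      gene_acc[[length(gene_acc) + 1L]] <- data.frame(
        sample_id = smp$sample_id, condition = smp$condition,
        chemistry = smp$chemistry, gene = g,
        n_gene_assigned = length(greads),
        n_allele_mus = sum(alleles == "mus"),
        n_allele_cas = sum(alleles == "cas"),
        n_ambiguous = sum(alleles == "ambiguous"),
        n_used = sum(alleles != "ambiguous" & any_cpg),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, counts)
  # pool samples sharing (condition, chemistry)
  counts <- stats::aggregate(
    counts[, c("n_CG", "n_TG", "n_other")],
    by = counts[, c("gene", "condition", "chemistry", "allele", "cpg_pos")],
    FUN = sum)
  ord <- order(counts$gene, counts$condition, counts$chemistry,
               counts$allele, counts$cpg_pos)
  structure(
    list(counts = counts[ord, , drop = FALSE],
         gene_accounting = do.call(rbind, gene_acc),
         sample_accounting = do.call(rbind, samp_acc),
         max_mismatch = max_mismatch),
    class = "cpg_tally")
}

#' @export
print.cpg_tally <- function(x, ...) {
  sa <- x$sample_accounting
  cat(sprintf("<cpg_tally> %d sample(s), %d reads, %.1f%% gene-assigned\n",
              nrow(sa), sum(sa$n_total),
              100 * sum(sa$n_gene_assigned) / max(1L, sum(sa$n_total))))
  cat(sprintf("counts: %d (gene x condition x chemistry x allele x CpG) cells\n",
              nrow(x$counts)))
  invisible(x)
}

#' Percentage of CG calls for one tally cell
#'
#' `100 * n_CG / (n_CG + n_TG)`; `"other"` calls are excluded from the
#' denominator. A zero denominator yields `NA` (missing), never 0.
#'
#' @param tally A [tally_reads()] result.
#' @param gene,condition,chemistry,allele,cpg_pos Cell coordinates.
#' @return Percentage in `[0,100]`, or `NA`.
#' @export
percent_cg <- function(tally, gene, condition, chemistry, allele, cpg_pos) {
  ct <- tally$counts
  row <- ct[ct$gene == gene & ct$condition == condition &
              ct$chemistry == chemistry & ct$allele == allele &
              ct$cpg_pos == cpg_pos, ]
  if (nrow(row) != 1L) return(NA_real_)
  pct_cg_counts(row$n_CG, row$n_TG)
}

pct_cg_counts <- function(n_CG, n_TG) {
  denom <- n_CG + n_TG
  ifelse(denom > 0L, 100 * n_CG / denom, NA_real_)
}

#' Deconvolve 5mC and 5hmC percentages from paired BS/OxBS %CG
#'
#' In the BS arm both 5mC and 5hmC read as C; in the OxBS arm only 5mC
#' does. Hence `pct_5mC = pct_CG_OxBS` and
#' `pct_5hmC_raw = pct_CG_BS - pct_CG_OxBS`, which may be negative at this
#' stage (sampling noise); see [apply_5hmc_filters()] for the clamp and
#' discard rules.
#'
#' @param pct_cg_bs,pct_cg_oxbs %CG in the BS and OxBS arms, in `[0,100]`.
#' @return data.frame with columns `pct_5mC`, `pct_5hmC_raw`.
#' @export
deconvolve <- function(pct_cg_bs, pct_cg_oxbs) {
  stopifnot(length(pct_cg_bs) == length(pct_cg_oxbs))
  if (any(stats::na.omit(c(pct_cg_bs, pct_cg_oxbs)) < 0) ||
      any(stats::na.omit(c(pct_cg_bs, pct_cg_oxbs)) > 100)) {
    stopf("%%CG inputs must lie in [0,100]")
  }
  data.frame(pct_5mC = pct_cg_oxbs,
             pct_5hmC_raw = pct_cg_bs - pct_cg_oxbs)
}

#' Assemble per-CpG 5mC/5hmC estimates from a tally
#'
#' Joins the BS and OxBS arms per (gene, condition, allele, CpG), computes
#' %CG for each arm and deconvolves. Coverage is the %CG denominator
#' (n_CG + n_TG) per arm.
#'
#' @param tally A [tally_reads()] result.
#' @return data.frame with pct_CG_BS, pct_CG_OxBS, coverage_BS,
#'   coverage_OxBS, pct_5mC, pct_5hmC_raw per cell.
#' @export
cpg_estimates <- function(tally) {
  ct <- tally$counts
  ct$pct <- pct_cg_counts(ct$n_CG, ct$n_TG)
  ct$coverage <- ct$n_CG + ct$n_TG
  key <- c("gene", "condition", "allele", "cpg_pos")
  bs <- ct[ct$chemistry == "BS", c(key, "pct", "coverage")]
  ox <- ct[ct$chemistry == "OxBS", c(key, "pct", "coverage")]
  names(bs)[5:6] <- c("pct_CG_BS", "coverage_BS")
  names(ox)[5:6] <- c("pct_CG_OxBS", "coverage_OxBS")
  est <- merge(bs, ox, by = key, all = TRUE)
  dec <- deconvolve(est$pct_CG_BS, est$pct_CG_OxBS)
  est$pct_5mC <- dec$pct_5mC
  est$pct_5hmC_raw <- dec$pct_5hmC_raw
  est[order(est$gene, est$cpg_pos, est$allele, est$condition), ,
      drop = FALSE]
}

#' Apply the negative-5hmC clamp and discard rules
#'
#' Per CpG, across all its allele x condition cells (by design
#' mus/cas x control/IFNg): if any cell's raw 5hmC is below -1%, the whole
#' CpG is biologically unexplainable and every cell is `"discarded"`;
#' otherwise cells with raw values in `[-1, 0)` are within acceptable
#' variability and `"clamped"` to 0; all others are `"kept"`. CpGs with a
#' missing cell are flagged `"missing"` and not filtered. The operation is
#' idempotent and order-independent.
#'
#' @param estimates A [cpg_estimates()] data.frame.
#' @param discard_below Raw 5hmC percentage (default -1) strictly below
#'   which a CpG is discarded.
#' @return The input with columns `pct_5hmC` and
#'   `status` (`kept`/`clamped`/`discarded`/`missing`) added.
#' @export
apply_5hmc_filters <- function(estimates, discard_below = -1) {
  est <- estimates
  est$pct_5hmC <- est$pct_5hmC_raw
  est$status <- "kept"
  for (key in split(seq_len(nrow(est)),
                    paste(est$gene, est$cpg_pos, sep = "\r"))) {
    raw <- est$pct_5hmC_raw[key]
    if (anyNA(raw)) {
      est$status[key] <- "missing"
      est$pct_5hmC[key] <- NA_real_
    } else if (any(raw < discard_below)) {
      est$status[key] <- "discarded"
      est$pct_5hmC[key] <- NA_real_
    } else {
      clamp <- raw >= discard_below & raw < 0
      est$status[key][clamp] <- "clamped"
      est$pct_5hmC[key][clamp] <- 0
    }
  }
  est
}

#' Quantify allele-specific 5mC/5hmC from amplicon BS/OxBS FASTQ samples
#'
#' The end-to-end estimator: tallies CG/TG calls per gene, allele,
#' condition and CpG over all samples, computes %CG per arm, deconvolves
#' 5mC/5hmC and applies the clamp/discard filters. Returns a fitted-object
#' style result with `print`, `summary`, `coef` and `plot` methods.
#'
#' @inheritParams tally_reads
#' @param min_coverage Cells with fewer than this many CG+TG calls in
#'   either arm are flagged `low_coverage` (default 100).
#' @return An object of class `"asta_fit"` with elements `estimates`,
#'   `tally`, `min_coverage`, `call`.
#' @export
asta_quantify <- function(samples, panel, max_mismatch = 0L,
                          min_coverage = 100L) {
  tally <- tally_reads(samples, panel, max_mismatch = max_mismatch)
  est <- apply_5hmc_filters(cpg_estimates(tally))
  est$low_coverage <- is.na(est$coverage_BS) | is.na(est$coverage_OxBS) |
    est$coverage_BS < min_coverage | est$coverage_OxBS < min_coverage
  structure(list(estimates = est, tally = tally,
                 min_coverage = min_coverage, call = match.call()),
            class = "asta_fit")
}

#' @export
print.asta_fit <- function(x, ...) {
  est <- x$estimates
  cat("Allele-specific amplicon 5mC/5hmC quantification\n")
  cat(sprintf("  genes: %s\n", paste(unique(est$gene), collapse = ", ")))
  cat(sprintf("  CpG cells: %d (%d kept, %d clamped, %d discarded, %d missing)\n",
              nrow(est), sum(est$status == "kept"),
              sum(est$status == "clamped"), sum(est$status == "discarded"),
              sum(est$status == "missing")))
  invisible(x)
}

#' @export
summary.asta_fit <- function(object, ...) {
  est <- object$estimates
  sa <- object$tally$sample_accounting
  structure(list(estimates = est, sample_accounting = sa,
                 min_coverage = object$min_coverage),
            class = "summary.asta_fit")
}

#' @export
print.summary.asta_fit <- function(x, ...) {
  cat("Read accounting per sample:\n")
  print(x$sample_accounting, row.names = FALSE)
  cat("\nPer-CpG estimates (percent):\n")
  cols <- c("gene", "cpg_pos", "allele", "condition",
            "pct_5mC", "pct_5hmC", "status")
  out <- x$estimates[, cols]
  out$pct_5mC <- round(out$pct_5mC, 2)
  out$pct_5hmC <- round(out$pct_5hmC, 2)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.asta_fit <- function(object, ...) {
  est <- object$estimates
  m <- as.matrix(est[, c("pct_5mC", "pct_5hmC")])
  rownames(m) <- paste(est$gene, est$cpg_pos, est$allele, est$condition,
                       sep = ":")
  m
}

#' @export
plot.asta_fit <- function(x, mark = c("pct_5mC", "pct_5hmC"), ...) {
  mark <- match.arg(mark)
  est <- x$estimates
  est <- est[!is.na(est[[mark]]), ]
  lab <- paste(est$gene, est$cpg_pos, est$allele, est$condition, sep = ":")
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(est[[mark]], names.arg = lab, las = 2,
                    cex.names = 0.6, ylab = paste(mark, "(%)"),
                    main = sub("pct_", "", mark), ...)
  invisible(x)
}
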