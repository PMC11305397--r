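#' Define a two-haplotype amplicon
#'
#' An amplicon spans one species-specific SNP and at least one CpG, with a
#' gene-specific PCR primer forming the (bisulfite-converted) prefix of the
#' read after 2-5 random stagger bases. The two haplotypes (mus = Mus
#' musculus, cas = Mus castaneus) are identical except at the SNP.
#'
#' All positions are 1-based indices into the amplicon sequence.
#'
#' @param gene_name Gene identifier.
#' @param seq_mus,seq_cas Haplotype sequences (A/C/G/T, 200-500 bp, equal
#'   length, differing only at `snp_pos`).
#' @param snp_pos 1-based position of the discriminating SNP.
#' @param snp_base_mus,snp_base_cas The SNP alleles; must remain
#'   distinguishable after bisulfite conversion (a non-CpG C reads as T, so
#'   e.g. a C/T SNP on this strand is rejected).
#' @param cpg_pos Sorted 1-based positions of CpG cytosines present on both
#'   haplotypes.
#' @param primer Gene-specific PCR2 primer: a prefix of the BS-converted
#'   amplicon containing no CpG cytosine and not covering the SNP.
#' @param stagger_range Integer pair, range of random leading bases
#'   (within 2-5).
#' @return An object of class `"amplicon_spec"`.
#' @export
amplicon_spec <- function(gene_name, seq_mus, seq_cas, snp_pos,
                          snp_base_mus, snp_base_cas, cpg_pos, primer,
                          stagger_range = c(2L, 5L)) {
  spec <- structure(
    list(gene_name = as.character(gene_name),
         seq_mus = toupper(seq_mus), seq_cas = toupper(seq_cas),
         snp_pos = as.integer(snp_pos),
         snp_base_mus = toupper(snp_base_mus),
         snp_base_cas = toupper(snp_base_cas),
         cpg_pos = sort(as.integer(cpg_pos)),
         primer = toupper(primer),
         stagger_range = as.integer(stagger_range)),
    class = "amplicon_spec")
  validate_amplicon_spec(spec)
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("<amplicon_spec> %s: %d bp, SNP %s/%s @%d, %d CpG(s) @ %s\n",
              x$gene_name, nchar(x$seq_mus), x$snp_base_mus, x$snp_base_cas,
              x$snp_pos, length(x$cpg_pos),
              paste(x$cpg_pos, collapse = ",")))
  invisible(x)
}

# BS-space image of a single base at a non-CpG position.
bs_base <- function(base) ifelse(base == "C", "T", base)

validate_amplicon_spec <- function(spec) {
  g <- spec$gene_name
  L <- nchar(spec$seq_mus)
  if (L != nchar(spec$seq_cas)) {
    stopf("%s: haplotype sequences differ in length", g)
  }
  if (L < 200L || L > 500L) {
    stopf("%s: amplicon length %d outside 200-500 bp", g, L)
  }
  mus <- seq_chars(spec$seq_mus)
  cas <- seq_chars(spec$seq_cas)
  if (!all(c(mus, cas) %in% c("A", "C", "G", "T"))) {
    stopf("%s: non-ACGT base in haplotype sequence", g)
  }
  diffs <- which(mus != cas)
  if (!identical(diffs, spec$snp_pos)) {
    stopf("%s: haplotypes must differ exactly at snp_pos %d (differ at: %s)",
          g, spec$snp_pos, paste(diffs, collapse = ","))
  }
  if (mus[spec$snp_pos] != spec$snp_base_mus ||
      cas[spec$snp_pos] != spec$snp_base_cas) {
    stopf("%s: snp_base_mus/cas do not match the sequences at snp_pos", g)
  }
  if (spec$snp_base_mus == spec$snp_base_cas) {
    stopf("%s: SNP alleles identical", g)
  }
  # BS conversion must not erase the SNP (e.g. C/T SNP on this strand).
  if (bs_base(spec$snp_base_mus) == bs_base(spec$snp_base_cas)) {
    stopf("%s: SNP %s/%s indistinguishable after bisulfite conversion",
          g, spec$snp_base_mus, spec$snp_base_cas)
  }
  if (length(spec$cpg_pos) < 1L) stopf("%s: no CpG positions", g)
  for (p in spec$cpg_pos) {
    if (p < 1L || p >= L) stopf("%s: CpG position %d out of range", g, p)
    if (mus[p] != "C" || mus[p + 1L] != "G" ||
        cas[p] != "C" || cas[p + 1L] != "G") {
      stopf("%s: position %d is not a CpG cytosine on both haplotypes", g, p)
    }
  }
  if (spec$snp_pos %in% spec$cpg_pos) {
    stopf("%s: SNP coincides with a CpG cytosine", g)
  }
  np <- nchar(spec$primer)
  if (np < 10L || np > L) stopf("%s: primer length %d implausible", g, np)
  if (spec$snp_pos <= np) {
    stopf("%s: primer covers the SNP position", g)
  }
  if (any(spec$cpg_pos <= np)) {
    stopf("%s: primer covers a CpG cytosine", g)
  }
  if (bs_collapse(substr(spec$seq_mus, 1L, np)) != spec$primer ||
      grepl("C", spec$primer, fixed = TRUE)) {
    stopf("%s: primer must equal the BS-converted amplicon prefix", g)
  }
  sr <- spec$stagger_range
  if (length(sr) != 2L || sr[1L] > sr[2L] || sr[1L] < 2L || sr[2L] > 5L) {
    stopf("%s: stagger_range must lie within [2,5]", g)
  }
  spec
}

#' Default six-gene X-chromosome amplicon panel with ground truth
#'
#' Builds a synthetic panel named after the X-linked loci assayed in the
#' study design this package supports: four reactivating-gene promoters
#' (Mtm1, Dlg3, Eda, Zfp185) and two escapee-gene promoters (Ddx3x,
#' Eif2s3x). Sequences are random (seeded) subject to the amplicon
#' invariants; they are not genomic sequences. Reactivating amplicons carry
#' substantial 5mC and 5hmC on the mus (inactive X) allele and low marks on
#' cas; escapee amplicons carry near-zero 5mC/5hmC on both alleles.
#'
#' @param seed Integer seed; the same seed yields a byte-identical panel.
#' @return A list with elements `panel` (named list of
#'   [amplicon_spec()] objects) and `truth` (data.frame with columns
#'   gene, allele, cpg_pos, f_C, f_5mC, f_5hmC summing to 1 per row).
#' @export
make_default_panel <- function(seed = 1L) {
  genes <- c("Mtm1", "Dlg3", "Eda", "Zfp185", "Ddx3x", "Eif2s3x")
  escapee <- genes %in% c("Ddx3x", "Eif2s3x")
  with_seed(seed, {
    panel <- vector("list", length(genes))
    names(panel) <- genes
    truth <- list()
    for (i in seq_along(genes)) {
      spec <- random_amplicon(genes[i])
      panel[[i]] <- spec
      truth[[i]] <- random_truth(spec, escapee = escapee[i])
    }
    primers <- vapply(panel, `[[`, "", "primer")
    if (anyDuplicated(primers)) stopf("panel primers not unique")
    list(panel = panel, truth = do.call(rbind, truth))
  })
}

# One random amplicon satisfying all spec invariants plus anchor
# feasibility; retries deterministically until bs_convert_reference accepts.
# The demultiplexing primer is kept short (10 nt): with exact matching, the
# chance a read is lost to a sequencing error inside the primer grows with
# its length (~1 - (1-seq_err)^len), and 10 nt keeps that loss under 1% at
# the default error rate while still being unique across a 6-gene panel.
random_amplicon <- function(gene_name, primer_len = 10L) {
  repeat {
    L <- sample(240:280, 1L)
    s <- sample(c("A", "G", "T"), L, replace = TRUE,
                prob = c(0.4, 0.25, 0.35))
    # sprinkle non-CpG cytosines (never before a G, so no stray CpG forms)
    cand <- which(s[-L] != "G" & seq_len(L - 1L) > 1L)
    cand <- cand[s[cand + 1L] != "G"]
    ncs <- sample(cand, size = max(4L, round(0.12 * length(cand))))
    s[ncs] <- "C"
    # CpG sites: 2-3, spaced >= 26 so every anchor window is CpG-free
    k <- sample(2:3, 1L)
    first <- primer_len + 30L + 12L
    cpg_pos <- first + cumsum(c(0L, sample(26:40, k - 1L, replace = TRUE)))
    if (max(cpg_pos) + 1L > L - 30L) next
    s[cpg_pos] <- "C"
    s[cpg_pos + 1L] <- "G"
    # kill any accidental CpG elsewhere
    cg <- which(s[-L] == "C" & s[-1L] == "G")
    stray <- setdiff(cg, cpg_pos)
    if (length(stray)) s[stray] <- "T"
    # SNP: A(mus)/G(cas), > 25 nt clear of every CpG and past the primer
    snp_pos <- max(cpg_pos) + 26L
    if (snp_pos > L - 5L) next
    if (s[snp_pos - 1L] == "C") s[snp_pos - 1L] <- "T"
    mus <- cas <- s
    mus[snp_pos] <- "A"
    cas[snp_pos] <- "G"
    if (snp_pos + 1L <= L && s[snp_pos + 1L] == "G") s[snp_pos + 1L] <- "A"
    mus[snp_pos + 1L] <- cas[snp_pos + 1L] <- s[snp_pos + 1L]
    seq_mus <- paste(mus, collapse = "")
    seq_cas <- paste(cas, collapse = "")
    primer <- bs_collapse(substr(seq_mus, 1L, primer_len))
    spec <- try(amplicon_spec(gene_name, seq_mus, seq_cas, snp_pos,
                              "A", "G", cpg_pos, primer), silent = TRUE)
    if (inherits(spec, "try-error")) next
    ref <- try(bs_convert_reference(spec), silent = TRUE)
    if (inherits(ref, "try-error")) next
    return(spec)
  }
}

random_truth <- function(spec, escapee) {
  rows <- expand.grid(allele = c("mus", "cas"), cpg_pos = spec$cpg_pos,
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  if (escapee) {
    f_5mC <- rep(0.02, n)
    f_5hmC <- rep(0.01, n)
  } else {
    inactive <- rows$allele == "mus"
    f_5mC <- ifelse(inactive, round(stats::runif(n, 0.55, 0.75), 3),
                    round(stats::runif(n, 0.08, 0.18), 3))
    f_5hmC <- ifelse(inactive, round(stats::runif(n, 0.10, 0.20), 3),
                     round(stats::runif(n, 0.04, 0.10), 3))
  }
  data.frame(gene = spec$gene_name, allele = rows$allele,
             cpg_pos = rows$cpg_pos,
             f_C = 1 - f_5mC - f_5hmC, f_5mC = f_5mC, f_5hmC = f_5hmC,
             stringsAsFactors = FALSE)
}

#' Validate a methylation truth table
#'
#' @param truth data.frame with columns gene, allele, cpg_pos, f_C, f_5mC,
#'   f_5hmC; each row's fractions must sum to 1 (tolerance 1e-9).
#' @return The table, invisibly, or an error.
#' @export
validate_truth <- function(truth) {
  need <- c("gene", "allele", "cpg_pos", "f_C", "f_5mC", "f_5hmC")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stopf("truth table missing columns: %s",
                          paste(miss, collapse = ", "))
  f <- as.matrix(truth[, c("f_C", "f_5mC", "f_5hmC")])
  if (any(f < 0 | f > 1)) stopf("truth fractions outside [0,1]")
  bad <- which(abs(rowSums(f) - 1) > 1e-9)
  if (length(bad)) {
    stopf("truth rows do not sum to 1 (rows: %s)",
          paste(utils::head(bad, 5L), collapse = ","))
  }
  if (anyDuplicated(truth[, c("gene", "allele", "cpg_pos")])) {
    stopf("duplicate (gene, allele, cpg_pos) in truth table")
  }
  invisible(truth)
}

#' Read and write amplicon panels (JSON or YAML)
#'
#' Panels serialize with the `amplicon_spec` field names; positions are
#' 1-based. Format chosen by file extension (.json / .yaml / .yml).
#'
#' @param panel Named list of [amplicon_spec()] objects.
#' @param path Output (input) file path.
#' @return `write_panel` the path invisibly; `read_panel` a validated
#'   named list of amplicon specs.
#' @export
write_panel <- function(panel, path) {
  recs <- lapply(panel, function(s) s[names(s)])
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(recs, path)
  } else {
    stopf("unsupported panel format: .%s", ext)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stopf("unsupported panel format: .%s", ext)
  }
  panel <- lapply(recs, function(r) {
    amplicon_spec(r$gene_name, r$seq_mus, r$seq_cas, r$snp_pos,
                  r$snp_base_mus, r$snp_base_cas, unlist(r$cpg_pos),
                  r$primer, unlist(r$stagger_range))
  })
  names(panel) <- vapply(panel, `[[`, "", "gene_name")
  panel
}

#' Read and write methylation truth tables (TSV)
#'
#' @param truth Truth data.frame (see [validate_truth()]).
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @return Path (write) or validated data.frame (read).
#' @export
write_truth <- function(truth, path, seed = NA) {
  validate_truth(truth)
  write_tsv_prov(truth, path, seed = seed)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- read_tsv_prov(path)
  validate_truth(truth)
  truth
}

#' Chemistry model for BS/OxBS read simulation
#'
#' Parameterizes the TrueMethyl-style chemistry: `conv_rate` is the
#' probability that an unmethylated C is converted (read as T) after
#' bisulfite treatment; `ox_rate` the probability that a 5hmC is oxidized in
#' the OxBS arm (and hence read as T); `seq_err` the per-base substitution
#' error applied last. The kit's true efficiencies are not published;
#' defaults are configurable assumptions, not claims.
#'
#' @param conv_rate,ox_rate,seq_err Probabilities in `[0,1]`.
#' @return A list of class `"chemistry_model"`.
#' @export
chemistry_model <- function(conv_rate = 0.99, ox_rate = 0.95,
                            seq_err = 0.001) {
  p <- c(conv_rate = conv_rate, ox_rate = ox_rate, seq_err = seq_err)
  if (any(p < 0 | p > 1)) stopf("chemistry probabilities must lie in [0,1]")
  structure(as.list(p), class = "chemistry_model")
}
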