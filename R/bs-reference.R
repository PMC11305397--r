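#' Bisulfite-convert an amplicon reference and derive anchors
#'
#' Projects both haplotypes of an amplicon into bisulfite space: every
#' non-CpG cytosine becomes T, while CpG cytosines are kept as ambiguity
#' positions that match either C (methylated, unconverted) or T
#' (unmethylated, converted) in reads. From the converted reference it
#' derives the literal anchors the read classifier uses:
#'
#' * `snp_anchor` — 15-20 nt immediately 5' of the SNP; the base just 3' of
#'   a match identifies the allele.
#' * one `cpg_anchor` per CpG — 15-20 nt immediately 5' of the CpG
#'   cytosine, required to contain no CpG cytosine itself (an anchor whose
#'   own bases depended on methylation state could not be matched
#'   literally).
#'
#' For each anchor the shortest length in `[anchor_min, anchor_max]` whose
#' occurrence in the converted amplicon is unique is chosen.
#'
#' @param spec An [amplicon_spec()].
#' @param anchor_min,anchor_max Anchor length bounds (defaults 15 and 20).
#' @return An object of class `"bs_reference"`.
#' @export
bs_convert_reference <- function(spec, anchor_min = 15L, anchor_max = 20L) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (anchor_min < 15L || anchor_max > 20L || anchor_min > anchor_max) {
    stopf("anchor lengths must satisfy 15 <= min <= max <= 20")
  }
  bs_mus <- bs_convert_seq(spec$seq_mus, spec$cpg_pos)
  bs_cas <- bs_convert_seq(spec$seq_cas, spec$cpg_pos)

  snp_anchor <- pick_anchor(spec, bs_mus, target = spec$snp_pos,
                            avoid_cpg = FALSE, anchor_min, anchor_max,
                            what = "SNP")
  cpg_anchors <- lapply(spec$cpg_pos, function(p) {
    pick_anchor(spec, bs_mus, target = p, avoid_cpg = TRUE,
                anchor_min, anchor_max, what = "CpG")
  })
  names(cpg_anchors) <- as.character(spec$cpg_pos)

  # Anchors are derived from the mus haplotype; the cas haplotype must agree
  # at every anchored position or allele/CpG calls would be haplotype-biased.
  for (a in c(list(snp_anchor), cpg_anchors)) {
    win <- seq.int(a$start, a$start + a$len - 1L)
    if (spec$snp_pos %in% win) {
      stopf("%s: anchor upstream of position %d overlaps the SNP; panel unsupported",
            spec$gene_name, a$start + a$len)
    }
  }

  structure(
    list(gene_name = spec$gene_name,
         primer = spec$primer,
         stagger_range = spec$stagger_range,
         snp_pos = spec$snp_pos,
         cpg_pos = spec$cpg_pos,
         bs_mus = bs_mus, bs_cas = bs_cas,
         snp_base_bs = c(mus = bs_base(spec$snp_base_mus),
                         cas = bs_base(spec$snp_base_cas)),
         snp_anchor = snp_anchor,
         cpg_anchors = cpg_anchors),
    class = "bs_reference")
}

#' @export
print.bs_reference <- function(x, ...) {
  cat(sprintf(
    "<bs_reference> %s: snp_anchor %d nt, cpg_anchors %s nt\n",
    x$gene_name, x$snp_anchor$len,
    paste(vapply(x$cpg_anchors, `[[`, 0L, "len"), collapse = "/")))
  invisible(x)
}

# In-silico full bisulfite conversion of one haplotype: non-CpG C -> T,
# CpG cytosines retained (they are the ambiguity positions).
bs_convert_seq <- function(seq, cpg_pos) {
  s <- seq_chars(seq)
  conv <- s == "C"
  conv[cpg_pos] <- FALSE
  s[conv] <- "T"
  paste(s, collapse = "")
}

# Choose the shortest unique anchor of length in [amin, amax] ending
# immediately 5' of `target`. Ambiguous (CpG) positions become [CT] in the
# match pattern. Errors name the gene and position per the contract.
pick_anchor <- function(spec, bs_seq, target, avoid_cpg, amin, amax, what) {
  g <- spec$gene_name
  collapsed_ref <- bs_collapse(bs_seq)
  for (len in amin:amax) {
    start <- target - len
    if (start < 1L) {
      stopf("%s: %s anchor at position %d would run past the read start",
            g, what, target)
    }
    win <- seq.int(start, target - 1L)
    if (avoid_cpg && any(spec$cpg_pos %in% win)) next
    anchor <- substr(bs_seq, start, target - 1L)
    # uniqueness checked in fully collapsed space (worst case over the
    # ambiguity assignments)
    hits <- gregexpr(bs_collapse(anchor), collapsed_ref, fixed = TRUE)[[1L]]
    if (length(hits) == 1L && hits[1L] != -1L) {
      ambig_rel <- which(win %in% spec$cpg_pos)
      return(list(start = start, len = len, seq = anchor,
                  pattern = anchor_pattern(anchor, ambig_rel)))
    }
  }
  if (avoid_cpg) {
    stopf("%s: no CpG-free unique anchor of length %d-%d upstream of %s at %d",
          g, amin, amax, what, target)
  }
  stopf("%s: no unique anchor of length %d-%d upstream of %s at %d",
        g, amin, amax, what, target)
}

# Perl regex for an anchor: literal bases, [CT] at ambiguous positions.
anchor_pattern <- function(anchor, ambig_rel) {
  ch <- seq_chars(anchor)
  ch[ambig_rel] <- "[CT]"
  paste(ch, collapse = "")
}
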