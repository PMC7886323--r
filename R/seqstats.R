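#' Annotate a coding sequence
#'
#' @param sequence In-frame coding sequence beginning with ATG (character or
#'   `DNAString`); length must be divisible by 3.
#' @param subunits Optional data frame with columns `name`, `start`, `end`
#'   (1-based amino-acid coordinates) tiling the protein without overlap,
#'   e.g. [k1_subunits()] for the K1 preprotoxin.
#' @return An object of class `orf_annotation`.
#' @export
orf_annotation <- function(sequence, subunits = NULL) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must be A/C/G/T only")
  if (nchar(sequence) %% 3L != 0L) stop("ORF length must be divisible by 3")
  if (substr(sequence, 1L, 3L) != "ATG") stop("ORF must start with ATG")
  if (!is.null(subunits)) {
    subunits <- as.data.frame(subunits)
    stopifnot(all(c("name", "start", "end") %in% names(subunits)))
    o <- order(subunits$start)
    subunits <- subunits[o, ]
    if (any(subunits$start[-1L] != subunits$end[-nrow(subunits)] + 1L))
      stop("subunit intervals must tile the protein without gaps or overlap")
  }
  structure(list(sequence = sequence, n_codons = nchar(sequence) %/% 3L,
                 subunits = subunits),
            class = "orf_annotation")
}

#' K1 preprotoxin subunit boundaries
#'
#' Default amino-acid intervals of the four preprotoxin segments
#' (delta leader, alpha, gamma, beta) for a 316-residue K1 preprotoxin, as
#' commonly drawn in the K1 literature. These are configuration data: pass
#' your own table to [orf_annotation()] to override.
#'
#' @param n_aa Protein length in residues (default 316).
#' @return Data frame with columns `name`, `start`, `end`.
#' @export
k1_subunits <- function(n_aa = 316L) {
  data.frame(name = c("delta", "alpha", "gamma", "beta"),
             start = c(1L, 45L, 150L, 234L),
             end = c(44L, 149L, 233L, n_aa),
             stringsAsFactors = FALSE)
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Synthetic K1-like preprotoxin ORF
#'
#' Deterministically constructs a 951-nt coding sequence (316 codons plus a
#' terminal stop) with the layout of the K1 preprotoxin: it starts with ATG,
#' contains no internal stop codons, and carries aspartate codons at residues
#' 106 and 253 and an isoleucine codon at residue 292, so the recurrent
#' killer-virus changes D106G, D253N and I292M can be expressed against it.
#' This is a synthetic stand-in for demonstration and testing, not the real
#' M1 sequence.
#'
#' @return Character scalar DNA sequence.
#' @export
synthetic_k1_orf <- function() {
  safe <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT", "AAA",
            "TTG", "ATG", "AAT", "CCT", "CAA", "AGA", "TCT", "ACT", "GTT",
            "TGG", "TAT")
  codons <- c("ATG", safe[((2:316) %% 20) + 1L])
  codons[106] <- "GAT"   # D106
  codons[253] <- "GAT"   # D253
  codons[292] <- "ATA"   # I292
  paste0(paste(codons, collapse = ""), "TAA")
}

#' Recurrent ancestral killer-virus polymorphisms (synthetic coordinates)
#'
#' The three recurrent single-nucleotide polymorphisms that pre-existed in
#' the founding culture, with their per-population recurrence counts among
#' killing-loss populations (13, 14 and 15), expressed as coordinates on
#' [synthetic_k1_orf()] so that [classify_variant()] yields the protein
#' changes D106G, D253N and I292M.
#'
#' @return Data frame with columns `pos`, `ref`, `alt`, `n`.
#' @export
ancestral_snp_table <- function() {
  data.frame(pos = c(317L, 757L, 876L),
             ref = c("A", "G", "A"),
             alt = c("G", "A", "G"),
             n = c(13L, 14L, 15L),
             stringsAsFactors = FALSE)
}

#' Classify the coding effect of a variant
#'
#' Substitutions are classified by codon comparison (synonymous, missense, or
#' nonsense when the derived codon is a stop); indels whose length difference
#' is not a multiple of 3 are frameshifts, others in-frame indels. The
#' protein change is reported in single-letter `D106G` form (1-based residue
#' in the preprotoxin), and the subunit containing the residue is looked up
#' when the annotation carries subunit boundaries.
#'
#' @param orf An [orf_annotation()].
#' @param v A [variant_spec()] with 1-based coordinates on the ORF.
#' @return List with `effect` (one of `"synonymous"`, `"missense"`,
#'   `"nonsense"`, `"frameshift"`, `"inframe_indel"`), `protein_change`
#'   (`NA` for indels), `aa_pos`, `subunit` (`NA` without an annotation).
#' @export
#'
#' @examples
#' orf <- orf_annotation("ATGAAATAA")
#' classify_variant(orf, variant_spec(4, "A", "G"))  # missense K2E
classify_variant <- function(orf, v) {
  stopifnot(inherits(orf, "orf_annotation"), inherits(v, "variant_spec"))
  if (v$pos < 1L || v$pos + nchar(v$ref) - 1L > nchar(orf$sequence))
    stop("variant outside the ORF")
  if (substr(orf$sequence, v$pos, v$pos + nchar(v$ref) - 1L) != v$ref)
    stop("variant ref allele does not match the ORF sequence at position ", v$pos)
  aa_pos <- (v$pos - 1L) %/% 3L + 1L
  subunit <- NA_character_
  if (!is.null(orf$subunits)) {
    hit <- which(orf$subunits$start <= aa_pos & orf$subunits$end >= aa_pos)
    if (length(hit)) subunit <- orf$subunits$name[hit[1L]]
  }
  if (v$kind %in% c("insertion", "deletion")) {
    shift <- abs(nchar(v$alt) - nchar(v$ref)) %% 3L
    return(list(effect = if (shift != 0L) "frameshift" else "inframe_indel",
                protein_change = NA_character_, aa_pos = aa_pos,
                subunit = subunit))
  }
  if (v$kind != "snv") stop("only snv and indel variants are supported")
  cstart <- (aa_pos - 1L) * 3L + 1L
  ref_codon <- substr(orf$sequence, cstart, cstart + 2L)
  off <- v$pos - cstart + 1L
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- v$alt
  ref_aa <- codon_aa(ref_codon); alt_aa <- codon_aa(alt_codon)
  effect <- if (alt_aa == ref_aa) "synonymous"
            else if (alt_aa == "*") "nonsense"
            else "missense"
  list(effect = effect,
       protein_change = paste0(ref_aa, aa_pos, alt_aa),
       aa_pos = aa_pos, subunit = subunit)
}

#' Transition:transversion spectrum statistics
#'
#' Transitions are A<->G and C<->T; everything else is a transversion. The
#' bias ratio `R = ts / tv` is tested against the null expectation of one
#' transition per two transversions (the proportions expected without bias,
#' since each base has one transition and two transversion partners) with a
#' df = 1 Pearson chi-squared test.
#'
#' @param variants List of [variant_spec()] objects (snvs only), or a data
#'   frame with columns `ref`, `alt` and optionally `n` (per-occurrence
#'   recurrence counts; default 1 per row).
#' @return An object of class `spectrum_stats`: list with `ts_count`,
#'   `tv_count`, `R` (`NA` when `tv_count` is 0), `chisq`, `df`, `p`.
#' @export
ts_tv_stats <- function(variants) {
  if (is.data.frame(variants)) {
    ref <- toupper(variants$ref); alt <- toupper(variants$alt)
    n <- if (is.null(variants$n)) rep(1, length(ref)) else variants$n
  } else {
    ref <- toupper(vapply(variants, `[[`, character(1), "ref"))
    alt <- toupper(vapply(variants, `[[`, character(1), "alt"))
    n <- rep(1, length(ref))
  }
  if (!length(ref)) stop("at least one snv is required")
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("ts_tv_stats accepts single-nucleotide variants only")
  is_ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
           (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ts <- sum(n[is_ts]); tv <- sum(n[!is_ts]); tot <- ts + tv
  expected <- c(tot / 3, 2 * tot / 3)
  chisq <- sum((c(ts, tv) - expected)^2 / expected)
  structure(list(ts_count = ts, tv_count = tv,
                 R = if (tv > 0) ts / tv else NA_real_,
                 chisq = chisq, df = 1L, p = chisq_sf(chisq, 1L)),
            class = "spectrum_stats")
}

#' @export
print.spectrum_stats <- function(x, ...) {
  cat(sprintf("Mutation spectrum: %g transitions, %g transversions (R = %s)\n",
              x$ts_count, x$tv_count,
              if (is.na(x$R)) "undefined" else sprintf("%.1f", x$R)))
  cat(sprintf("  vs 1:2 null: chisq = %.1f, df = 1, p = %.3g\n", x$chisq, x$p))
  invisible(x)
}

# Per-codon expected synonymous site count: for each position, the fraction
# of the three possible changes that preserve the amino acid (NG86; changes
# to stop codons count as nonsynonymous).
codon_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (codon_aa(alt) == aa) s <- s + 1 / 3
    }
  }
  s
}

#' Nei-Gojobori (1986) dN/dS on observed variants
#'
#' Expected synonymous and nonsynonymous site counts are computed per
#' reference codon by the proportion-of-changes method; observed single
#' nucleotide differences are classed by their coding effect. Proportions
#' `pN = N_diff / N_sites` and `pS = S_diff / S_sites` are reported without
#' multiple-hit correction (appropriate for the small per-gene counts this
#' is used for), together with their ratio when `pS > 0`.
#'
#' @param orf An [orf_annotation()].
#' @param variants List of snv [variant_spec()]s on the ORF, or a data frame
#'   with columns `pos`, `ref`, `alt` and optionally `n` (recurrence counts,
#'   counted per-occurrence).
#' @return An object of class `dnds_result`: list with `N_sites`, `S_sites`,
#'   `N_diff`, `S_diff`, `pN`, `pS`, `ratio` (`NA` with explanation in
#'   `note` when `pS` is 0).
#' @export
dnds <- function(orf, variants) {
  stopifnot(inherits(orf, "orf_annotation"))
  if (is.data.frame(variants)) {
    n <- if (is.null(variants$n)) rep(1, nrow(variants)) else variants$n
    variants <- lapply(seq_len(nrow(variants)), function(i)
      variant_spec(variants$pos[i], variants$ref[i], variants$alt[i]))
  } else n <- rep(1, length(variants))
  codons <- substring(orf$sequence, seq(1L, nchar(orf$sequence), 3L),
                      seq(3L, nchar(orf$sequence), 3L))
  S_sites <- sum(vapply(codons, codon_syn_sites, numeric(1)))
  N_sites <- nchar(orf$sequence) - S_sites
  S_diff <- N_diff <- 0
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (v$kind != "snv") stop("dnds accepts single-nucleotide variants only")
    eff <- classify_variant(orf, v)$effect
    if (eff == "synonymous") S_diff <- S_diff + n[i] else N_diff <- N_diff + n[i]
  }
  pN <- N_diff / N_sites; pS <- S_diff / S_sites
  ratio <- if (pS > 0) pN / pS else NA_real_
  structure(list(N_sites = N_sites, S_sites = S_sites,
                 N_diff = N_diff, S_diff = S_diff, pN = pN, pS = pS,
                 ratio = ratio,
                 note = if (pS > 0) NULL else
                   "no synonymous differences: dN/dS undefined"),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("NG86 sites: N = %.2f, S = %.2f; differences: N = %g, S = %g\n",
              x$N_sites, x$S_sites, x$N_diff, x$S_diff))
  cat(sprintf("  pN = %.4g, pS = %.4g, dN/dS = %s\n", x$pN, x$pS,
              if (is.na(x$ratio)) "undefined" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Deterministic selective-sweep time
#'
#' Time for a beneficial allele under logistic (frequency-independent)
#' selection to go from frequency `f0` to `f_end`:
#' `t = (1/s) * ln(f_end (1 - f0) / (f0 (1 - f_end)))`. With the defaults
#' `f0 = 1/N` and `f_end = 1 - 1/N` this is the minimum time for a new
#' mutation to sweep a population of size `N`, approximately `(2/s) ln N`.
#'
#' @param s Per-generation selection coefficient, > 0.
#' @param N Census population size, > 1 (sets the default frequency bounds).
#' @param f0,f_end Start and end frequencies, `0 < f0 < f_end < 1`.
#' @return Sweep time in generations.
#' @export
#'
#' @examples
#' sweep_time(0.30, 4e9)  # ~147, i.e. ~150 generations
sweep_time <- function(s, N, f0 = 1 / N, f_end = 1 - 1 / N) {
  if (s <= 0) stop("s must be > 0")
  if (N <= 1) stop("N must be > 1")
  if (!(f0 > 0 && f0 < f_end && f_end < 1))
    stop("frequency bounds must satisfy 0 < f0 < f_end < 1")
  (1 / s) * log(f_end * (1 - f0) / (f0 * (1 - f_end)))
}
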