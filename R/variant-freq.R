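#' Specify a variant on a reference sequence
#'
#' Coordinates are 1-based on the reference (ORF or amplicon). The kind is
#' inferred from the allele lengths: equal single-base alleles are `snv`,
#' longer alt is `insertion`, longer ref is `deletion`.
#'
#' @param pos 1-based position of the first affected reference base.
#' @param ref,alt Reference and alternate alleles (non-empty, A/C/G/T).
#' @return An object of class `variant_spec` with fields `pos`, `ref`, `alt`,
#'   `kind`.
#' @export
variant_spec <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    stop("ref and alt must be non-empty A/C/G/T strings")
  if (ref == alt) stop("alt allele equals ref allele: not a variant")
  kind <- if (nchar(ref) == nchar(alt)) {
    if (nchar(ref) == 1L) "snv" else "mnv"
  } else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  structure(list(pos = as.integer(pos), ref = ref, alt = alt, kind = kind),
            class = "variant_spec")
}

#' Parse a `pos:ref>alt` variant string
#'
#' @param x String such as `"875:A>G"` (1-based position).
#' @return A [variant_spec()].
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([ACGTacgt]+)>([ACGTacgt]+)$", x))[[1L]]
  if (length(m) != 4L) stop("cannot parse variant string '", x, "' (use pos:ref>alt)")
  variant_spec(as.integer(m[2L]), m[3L], m[4L])
}

#' Build flanked allele probes for a variant
#'
#' The ancestral and derived probes are the variant site plus `flank`
#' reference bases on each side (11 nt for a substitution with the default
#' flank of 5). Near sequence ends the flanks truncate to the available
#' bases; a total probe length below 6 is rejected as uninformative.
#'
#' @param reference Reference sequence (character or `DNAString`).
#' @param variant A [variant_spec()], 1-based on `reference`.
#' @param flank Flank width in nt (default 5).
#' @return An object of class `allele_probe`: list with `ancestral`,
#'   `derived`, `ancestral_rc`, `derived_rc`, `variant`, `flank`.
#' @export
build_allele_probes <- function(reference, variant, flank = 5L) {
  reference <- toupper(as.character(reference))
  stopifnot(inherits(variant, "variant_spec"))
  pos <- variant$pos
  if (pos < 1L || pos + nchar(variant$ref) - 1L > nchar(reference))
    stop("variant position outside the reference")
  if (substr(reference, pos, pos + nchar(variant$ref) - 1L) != variant$ref)
    stop("variant ref allele '", variant$ref,
         "' does not match the reference at position ", pos)
  lo <- max(1L, pos - flank)
  hi <- min(nchar(reference), pos + nchar(variant$ref) - 1L + flank)
  anc <- substr(reference, lo, hi)
  der <- paste0(substr(reference, lo, pos - 1L), variant$alt,
                substr(reference, pos + nchar(variant$ref), hi))
  if (nchar(anc) < 6L || nchar(der) < 6L)
    stop("probe shorter than 6 nt: variant too close to the sequence end")
  structure(list(ancestral = anc, derived = der,
                 ancestral_rc = revcomp(anc), derived_rc = revcomp(der),
                 variant = variant, flank = as.integer(flank)),
            class = "allele_probe")
}

#' Count reads carrying the ancestral or derived allele
#'
#' A read is counted as ancestral (derived) when it contains the ancestral
#' (derived) probe or its reverse complement as an exact substring; reads
#' matching both probes are ambiguous, reads matching neither (including
#' reads with sequencing errors inside the probe span) are unmatched.
#'
#' @param reads Character vector of read sequences, a `fastq_reads` data
#'   frame (from [emit_amplicon_reads()] or [read_fastq()]), or a
#'   `DNAStringSet`.
#' @param probe An [build_allele_probes()] result.
#' @return An object of class `read_count_result`: list with `n_ancestral`,
#'   `n_derived`, `n_ambiguous`, `n_unmatched`, `n_total`.
#' @export
count_reads <- function(reads, probe) {
  stopifnot(inherits(probe, "allele_probe"))
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- toupper(as.character(reads))
  anc <- grepl(probe$ancestral, reads, fixed = TRUE) |
    grepl(probe$ancestral_rc, reads, fixed = TRUE)
  der <- grepl(probe$derived, reads, fixed = TRUE) |
    grepl(probe$derived_rc, reads, fixed = TRUE)
  structure(list(
    n_ancestral = sum(anc & !der),
    n_derived = sum(der & !anc),
    n_ambiguous = sum(anc & der),
    n_unmatched = sum(!anc & !der),
    n_total = length(reads)
  ), class = "read_count_result")
}

#' @export
print.read_count_result <- function(x, ...) {
  cat(sprintf("Reads: %d ancestral, %d derived, %d ambiguous, %d unmatched (of %d)\n",
              x$n_ancestral, x$n_derived, x$n_ambiguous, x$n_unmatched, x$n_total))
  invisible(x)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Variant frequency from allele-specific read counts
#'
#' Point estimate `n_derived / (n_ancestral + n_derived)` with a 95% Wilson
#' score interval; ambiguous and unmatched reads are excluded from the
#' denominator and carried along for reporting.
#'
#' @param counts A [count_reads()] result.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `frequency_estimate`: list with `f`, `ci_low`,
#'   `ci_high`, `n_informative`, `n_excluded`, `method = "read_count"`.
#' @export
variant_frequency <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "read_count_result"))
  n <- counts$n_ancestral + counts$n_derived
  if (n < 1L) stop("no informative reads: frequency undefined")
  f <- counts$n_derived / n
  ci <- wilson_ci(counts$n_derived, n, conf)
  structure(list(f = f, ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 n_informative = n,
                 n_excluded = counts$n_ambiguous + counts$n_unmatched,
                 method = "read_count"),
            class = "frequency_estimate")
}

#' Variant frequency from Sanger chromatogram peak heights
#'
#' @param peak_derived,peak_ancestral Non-negative peak heights at the
#'   variant site (not both zero).
#' @return A `frequency_estimate` with `method = "sanger_peak"` and no
#'   confidence interval.
#' @export
sanger_peak_frequency <- function(peak_derived, peak_ancestral) {
  if (peak_derived < 0 || peak_ancestral < 0) stop("peak heights must be >= 0")
  if (peak_derived + peak_ancestral == 0) stop("both peak heights are zero")
  structure(list(f = peak_derived / (peak_derived + peak_ancestral),
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_informative = NA_integer_, n_excluded = NA_integer_,
                 method = "sanger_peak"),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("Variant frequency: %.3f", x$f))
  if (!is.na(x$ci_low))
    cat(sprintf(" [%.3f, %.3f] (n = %d informative reads)",
                x$ci_low, x$ci_high, x$n_informative))
  cat(sprintf(" [%s]\n", x$method))
  invisible(x)
}

#' Classify an intracellular variant-frequency trajectory
#'
#' Rules, applied in order: `fixed` when the final frequency is at least
#' `fix_threshold`; `lost` when the final frequency is at most
#' `loss_threshold`; `transient` when the trajectory rose to at least
#' `fix_threshold - 0.25` but ended at or below `loss_threshold + 0.25`
#' (rose then fell, as when a later variant displaces the focal one);
#' otherwise `segregating`.
#'
#' @param freqs Ordered numeric frequencies, or a list of
#'   `frequency_estimate` objects (>= 2 timepoints).
#' @param fix_threshold,loss_threshold Classification thresholds (defaults
#'   0.95 and 0.05).
#' @return One of `"fixed"`, `"lost"`, `"transient"`, `"segregating"`.
#' @export
trajectory_classify <- function(freqs, fix_threshold = 0.95, loss_threshold = 0.05) {
  if (is.list(freqs))
    freqs <- vapply(freqs, function(x)
      if (inherits(x, "frequency_estimate")) x$f else as.numeric(x), numeric(1))
  if (length(freqs) < 2L) stop("at least 2 timepoints are required")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  final <- freqs[length(freqs)]
  if (final >= fix_threshold) return("fixed")
  if (final <= loss_threshold) return("lost")
  if (max(freqs) >= fix_threshold - 0.25 && final <= loss_threshold + 0.25)
    return("transient")
  "segregating"
}
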