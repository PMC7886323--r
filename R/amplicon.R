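#' Emit synthetic amplicon reads over a variant site
#'
#' Generates error-prone amplicon reads from a mixture of the ancestral and
#' derived template at a configured variant frequency, for exercising the
#' read-counting frequency estimator. Each read is drawn from the derived
#' template with probability `true_freq`, starts at a uniform position chosen
#' so the read covers the variant's probe span (site +/- 5 nt), acquires
#' independent per-base substitution errors at `error_rate`, and is emitted as
#' a reverse complement with probability 1/2. Qualities are constant Phred+33
#' 'I' (Q40).
#'
#' @param reference Character scalar (or `DNAString`) reference sequence.
#' @param variant A [variant_spec()] (substitution or indel) on the reference,
#'   1-based.
#' @param true_freq Frequency of the derived template in \[0, 1\].
#' @param depth Number of reads.
#' @param read_length Read length; must be at least the 11-nt probe span.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#'
#' @return A data frame of class `fastq_reads` with columns `id`, `seq`,
#'   `qual`; write with [write_fastq()].
#' @export
emit_amplicon_reads <- function(reference, variant, true_freq, depth,
                                read_length = 100L, error_rate = 0.001,
                                seed = 1L) {
  reference <- toupper(as.character(reference))
  stopifnot(inherits(variant, "variant_spec"))
  if (true_freq < 0 || true_freq > 1) stop("true_freq must lie in [0, 1]")
  if (read_length < 11L)
    stop("read_length must be at least the 11-nt probe span around the variant")
  pos <- variant$pos
  if (pos < 1L || pos + nchar(variant$ref) - 1L > nchar(reference))
    stop("variant position outside the reference")
  if (substr(reference, pos, pos + nchar(variant$ref) - 1L) != variant$ref)
    stop("variant ref allele does not match the reference sequence")

  derived <- paste0(substr(reference, 1L, pos - 1L), variant$alt,
                    substr(reference, pos + nchar(variant$ref), nchar(reference)))

  with_stream(seed, 0L, {
    is_derived <- stats::runif(depth) < true_freq
    reads <- character(depth)
    for (i in seq_len(depth)) {
      tmpl <- if (is_derived[i]) derived else reference
      span_end <- pos + (if (is_derived[i]) nchar(variant$alt) else nchar(variant$ref)) - 1L
      lo <- max(1L, span_end + 5L - read_length + 1L)
      hi <- min(nchar(tmpl) - read_length + 1L, pos - 5L)
      if (hi < lo) { lo <- max(1L, min(lo, hi)); hi <- max(lo, hi) }
      start <- if (hi > lo) sample(lo:hi, 1L) else lo
      reads[i] <- substr(tmpl, start, start + read_length - 1L)
    }
    if (error_rate > 0) {
      m <- matrix(unlist(strsplit(reads, "")), nrow = depth, byrow = TRUE)
      err <- matrix(stats::runif(length(m)) < error_rate, nrow = depth)
      if (any(err)) {
        bases <- c("A", "C", "G", "T")
        repl <- vapply(m[err], function(b) sample(setdiff(bases, b), 1L), character(1))
        m[err] <- repl
        reads <- apply(m, 1L, paste0, collapse = "")
      }
    }
    flip <- stats::runif(depth) < 0.5
    reads[flip] <- revcomp(reads[flip])
    structure(data.frame(
      id = sprintf("read%06d", seq_len(depth)),
      seq = reads,
      qual = strrep("I", nchar(reads)),
      stringsAsFactors = FALSE
    ), class = c("fastq_reads", "data.frame"),
    truth = list(true_freq = true_freq, derived = is_derived))
  })
}

# Reverse complement of plain character sequences (delegates to Biostrings).
revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
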