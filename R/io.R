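#' Read and write competition time courses as CSV
#'
#' Columns: `competitor_a`, `competitor_b` (constant per file), `generation`,
#' `count_a`, `count_b`, `sample_size`.
#'
#' @param tc A [competition_timecourse()].
#' @param path File path.
#' @return `write_timecourse_csv()` returns `path` invisibly;
#'   `read_timecourse_csv()` returns a `competition_timecourse`.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "competition_timecourse"))
  df <- data.frame(competitor_a = attr(tc, "competitor_a"),
                   competitor_b = attr(tc, "competitor_b"),
                   as.data.frame(tc))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("competitor_a", "competitor_b", "generation", "count_a", "count_b",
            "sample_size")
  if (!all(need %in% names(df)))
    stop("timecourse CSV needs columns ", paste(need, collapse = ", "))
  competition_timecourse(df$competitor_a[1L], df$competitor_b[1L],
                         df[, c("generation", "count_a", "count_b", "sample_size")])
}

#' Read and write phenotype tables as CSV
#'
#' Columns: `population`, `generation`, `killing`, `immunity` with grades
#' `"full"`, `"weak"`, `"none"`.
#'
#' @param records Phenotype data frame.
#' @param path File path.
#' @return `write_phenotypes_csv()` returns `path` invisibly;
#'   `read_phenotypes_csv()` returns the validated data frame.
#' @export
write_phenotypes_csv <- function(records, path) {
  records <- check_phenotype_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  check_phenotype_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read and write viral variant frequency trajectories as CSV
#'
#' Long format: `population`, `generation`, `variant_id`, `frequency`.
#'
#' @param trajectories Long-format data frame.
#' @param path File path.
#' @return `write_trajectories_csv()` returns `path` invisibly;
#'   `read_trajectories_csv()` returns the data frame.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  need <- c("population", "generation", "variant_id", "frequency")
  if (!all(need %in% names(trajectories)))
    stop("trajectories need columns ", paste(need, collapse = ", "))
  utils::write.csv(trajectories[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads A `fastq_reads` data frame (columns `id`, `seq`, `qual`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  seqs <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id))
  quals <- Biostrings::BStringSet(stats::setNames(reads$qual, reads$id))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a `fastq_reads` data frame
#'
#' @param path FASTQ path (Phred+33).
#' @return Data frame of class `fastq_reads` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  structure(data.frame(id = names(x),
                       seq = as.character(x),
                       qual = as.character(S4Vectors::mcols(x)$qualities),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("fastq_reads", "data.frame"))
}

#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping plain named character vectors on the
#' package side.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` a named
#'   character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read and write variant tables as CSV
#'
#' Columns: `pos` (1-based on the ORF), `ref`, `alt`, and optionally `n`
#' (number of populations the change was observed in).
#'
#' @param variants Data frame of variants.
#' @param path File path.
#' @return `write_variants_csv()` returns `path` invisibly;
#'   `read_variants_csv()` returns the data frame.
#' @export
write_variants_csv <- function(variants, path) {
  if (!all(c("pos", "ref", "alt") %in% names(variants)))
    stop("variants need columns pos, ref, alt")
  utils::write.csv(variants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_variants_csv
#' @export
read_variants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "ref", "alt") %in% names(df)))
    stop("variant CSV needs columns pos, ref, alt")
  df
}

#' Read a simulator configuration from YAML
#'
#' Recognised keys mirror the [sim_config()] arguments; `protocol:` and
#' `toxin:` are nested maps with the corresponding constructor arguments.
#' Unknown keys are an error, so typos do not silently become defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- c("protocol", "toxin", "viral_copy_number", "viral_mutation_rate",
             "ts_tv_bias", "seed", "theta_K", "theta_I", "grade_hi", "grade_lo")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- raw
  if (!is.null(raw$protocol))
    args$protocol <- do.call(serial_transfer_protocol, raw$protocol)
  if (!is.null(raw$toxin))
    args$toxin <- do.call(toxin_model, raw$toxin)
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

#' Write a simulator configuration (including the seed) to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(list(
    protocol = list(dilution_factor = config$protocol$dilution_factor,
                    bottleneck_size = config$protocol$bottleneck_size,
                    n_transfers = config$protocol$n_transfers),
    toxin = list(kill_coefficient = config$toxin$kill_coefficient,
                 saturating = config$toxin$saturating),
    viral_copy_number = config$viral_copy_number,
    viral_mutation_rate = config$viral_mutation_rate,
    ts_tv_bias = config$ts_tv_bias,
    seed = config$seed,
    theta_K = config$theta_K, theta_I = config$theta_I,
    grade_hi = config$grade_hi, grade_lo = config$grade_lo
  ), path)
  invisible(path)
}
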