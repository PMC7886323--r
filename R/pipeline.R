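#' Three-clone nontransitivity demonstration scenario
#'
#' Builds the canonical three-clone lineage: an ancestral killer clone
#' (K+I+, reference fitness), an intermediate clone that lost killing but
#' kept immunity and carries a beneficial nuclear mutation, and a late clone
#' that lost both viral phenotypes and carries a second beneficial nuclear
#' mutation. With toxin killing active this lineage is the minimal system in
#' which every step is adaptive yet the late clone loses to the ancestor at
#' low frequency.
#'
#' @param s_intermediate Nuclear advantage of the intermediate clone over the
#'   ancestor (default 0.038).
#' @param s_late_step Additional nuclear advantage of the late clone over the
#'   intermediate (default 0.012).
#' @param cured If `TRUE`, the early clone is virus-cured (no toxin, no
#'   immunity), the control that abolishes frequency dependence.
#' @return List with `early`, `intermediate`, `late` ([host_genotype()]s).
#' @export
three_clone_scenario <- function(s_intermediate = 0.038, s_late_step = 0.012,
                                 cured = FALSE) {
  list(
    early = if (cured) clone_cured("early") else clone_killer("early"),
    intermediate = clone_neutral_virus("intermediate", s = s_intermediate),
    late = clone_sensitive("late", s = s_intermediate + s_late_step)
  )
}

#' Measure a pairwise fitness matrix by simulated competitions
#'
#' Runs [simulate_competition()] for each ordered clone pair at each starting
#' frequency, estimates fitness with [log_ratio_slope()] (later vs earlier
#' orientation), and assembles a [pairwise_fitness_matrix()].
#'
#' @param config A [sim_config()].
#' @param clones Named list of [host_genotype()]s in genealogical order.
#' @param f0_grid Starting frequencies of the later clone.
#' @param n_generations,sample_size,deterministic Passed to
#'   [simulate_competition()].
#' @return A [pairwise_fitness_matrix()] with one row per (pair, f0).
#' @export
measure_fitness_matrix <- function(config, clones, f0_grid = c(0.1, 0.5, 0.9),
                                   n_generations = 50L, sample_size = 1e4,
                                   deterministic = FALSE) {
  rows <- list(); stream <- 0L
  ids <- names(clones)
  for (i in seq_along(clones)) for (j in seq_along(clones)) {
    if (j <= i) next
    for (f0 in f0_grid) {
      stream <- stream + 1L
      tc <- simulate_competition(config, clones[[j]], clones[[i]],
                                 start_freq_a = f0,
                                 n_generations = n_generations,
                                 sample_size = sample_size,
                                 deterministic = deterministic,
                                 stream = stream)
      est <- log_ratio_slope(tc)
      rows[[length(rows) + 1L]] <- data.frame(
        earlier = ids[i], later = ids[j], f0 = f0,
        s_hat = est$s_hat, stderr = est$stderr)
    }
  }
  pairwise_fitness_matrix(do.call(rbind, rows))
}

#' Run the end-to-end demonstration pipeline
#'
#' Orchestrates simulate -> fitness -> transitivity for the three-clone
#' scenario: simulates all pairwise competitions across a starting-frequency
#' grid, estimates per-interval and whole-course fitness, tests the
#' late-vs-early competition for frequency dependence, classifies the triple
#' for transitivity, and writes every table plus a JSON run manifest to
#' `out_dir`. Rerunning with an identical config and seed reproduces the
#' data files byte for byte.
#'
#' @param config A [sim_config()], or the path to a YAML file for
#'   [read_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param cured If `TRUE`, use the virus-cured early clone (control run).
#' @param f0_grid Starting frequencies of the later clone in each pair.
#' @param deterministic Use expectation dynamics instead of sampling.
#' @param quiet Suppress the progress messages written to `stderr`.
#' @return The run manifest (class `run_manifest`), invisibly written to
#'   `manifest.json`: config snapshot, seed, file registry, the transitivity
#'   verdict and the frequency-dependence summary.
#' @export
run_pipeline <- function(config, out_dir, cured = FALSE,
                         f0_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         deterministic = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("run_pipeline: seed = ", config$seed, ", kappa = ",
      config$toxin$kill_coefficient, ", cured = ", cured)

  clones <- three_clone_scenario(cured = cured)
  say("simulating ", 3 * length(f0_grid), " pairwise competitions")
  mat <- measure_fitness_matrix(config, clones, f0_grid = f0_grid,
                                deterministic = deterministic)

  files <- character(0)
  reg <- function(name) { files[length(files) + 1L] <<- name; file.path(out_dir, name) }
  utils::write.csv(as.data.frame(mat), reg("fitness_matrix.csv"),
                   row.names = FALSE, quote = FALSE)

  # per-interval analysis of the long-range (early vs late) competition
  intervals <- list()
  for (k in seq_along(f0_grid)) {
    tc <- simulate_competition(config, clones$late, clones$early,
                               start_freq_a = f0_grid[k],
                               deterministic = deterministic,
                               stream = 1000L + k)
    write_timecourse_csv(tc, reg(sprintf("timecourse_late_vs_early_f%02.0f.csv",
                                         100 * f0_grid[k])))
    intervals[[k]] <- as.data.frame(interval_fitness(tc))
  }
  intervals <- do.call(rbind, intervals)
  utils::write.csv(intervals, reg("intervals_late_vs_early.csv"),
                   row.names = FALSE, quote = FALSE)
  fdep <- frequency_dependence(intervals)
  say("late vs early frequency dependence: ", fdep$classification)

  verdict <- classify_triple(mat, c("early", "intermediate", "late"))
  say("triple verdict: ", verdict$verdict)

  write_sim_config(config, reg("config.yaml"))
  manifest <- list(
    seed = config$seed,
    cured = cured,
    deterministic = deterministic,
    f0_grid = f0_grid,
    files = files,
    verdict = verdict$verdict,
    expected_s_late_vs_early = verdict$expected_s_ik,
    observed_s_late_vs_early = verdict$observed_s_ik,
    frequency_dependence = list(classification = fdep$classification,
                                beta = fdep$beta, p_value = fdep$p_value,
                                f_star = fdep$f_star),
    package_version = as.character(utils::packageVersion("nontransim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d%s): verdict %s\n", x$seed,
              if (x$cured) ", virus-cured early clone" else "", x$verdict))
  cat(sprintf("  expected s(early -> late) = %+.4f; frequency dependence: %s\n",
              x$expected_s_late_vs_early, x$frequency_dependence$classification))
  cat(sprintf("  %d files in registry\n", length(x$files)))
  invisible(x)
}
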