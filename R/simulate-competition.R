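#' Simulate a pairwise serial-transfer competition
#'
#' Two host genotypes compete under the serial-transfer protocol. Each
#' generation, cohorts grow by a factor `2 * exp(s_i)` (so `s` is a Malthusian
#' per-generation selection coefficient and the log-ratio slope of a
#' noise-free run equals `s_a - s_b` exactly), then toxin-mediated killing
#' removes susceptible non-immune cells with per-generation probability
#' `kill_coefficient * f_killer`, and every `generations_per_transfer`
#' generations the culture passes a dilution bottleneck. At sampled
#' generations an aliquot of `sample_size` cells is drawn, emulating
#' flow-cytometry event counts.
#'
#' Killer and immunity status of each competitor are derived from its viral
#' composition via the `theta_K`/`theta_I` thresholds in `config`; a cured
#' genotype (no viral copies) is neither killer nor immune.
#'
#' @param config A [sim_config()].
#' @param genotype_a,genotype_b [host_genotype()] competitors.
#' @param start_freq_a Starting frequency of competitor a, strictly in (0, 1).
#' @param n_generations Total generations of competition (default 50).
#' @param sampling_interval Generations between samples; must divide
#'   `n_generations` (default 10).
#' @param sample_size Aliquot size per sample (flow events), default 1e4.
#' @param deterministic If `TRUE`, all sampling (growth, killing, bottleneck,
#'   aliquot) is replaced by its expectation; counts may be non-integer.
#' @param stream Integer index of the random sub-stream derived from
#'   `config$seed` (use distinct values for replicate competitions).
#'
#' @return A [competition_timecourse()].
#' @export
#'
#' @examples
#' cfg <- sim_config(toxin = toxin_model(kill_coefficient = 0))
#' a <- host_genotype("A", nuclear_fitness_s = 0.05)
#' b <- host_genotype("B")
#' tc <- simulate_competition(cfg, a, b, start_freq_a = 0.5, deterministic = TRUE)
#' log_ratio_slope(tc)$s_hat  # 0.05
simulate_competition <- function(config, genotype_a, genotype_b, start_freq_a,
                                 n_generations = 50L, sampling_interval = 10L,
                                 sample_size = 1e4, deterministic = FALSE,
                                 stream = 0L) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotype_a, "host_genotype"),
            inherits(genotype_b, "host_genotype"))
  if (!(start_freq_a > 0 && start_freq_a < 1))
    stop("start_freq_a must lie strictly in (0, 1)")
  if (n_generations %% sampling_interval != 0)
    stop("sampling_interval must divide n_generations")

  registry <- competitor_registry(config, genotype_a, genotype_b)
  ph_a <- cell_phenotype(genotype_a$viral_composition, registry,
                         config$theta_K, config$theta_I)
  ph_b <- cell_phenotype(genotype_b$viral_composition, registry,
                         config$theta_K, config$theta_I)
  kappa <- config$toxin$kill_coefficient
  sat <- config$toxin$saturating
  Nb <- config$protocol$bottleneck_size
  g_per <- config$protocol$generations_per_transfer
  s_a <- genotype_a$nuclear_fitness_s
  s_b <- genotype_b$nuclear_fitness_s

  run <- function() {
    if (deterministic) {
      n_a <- Nb * start_freq_a
      n_b <- Nb * (1 - start_freq_a)
    } else {
      n_a <- stats::rbinom(1L, size = as.integer(Nb), prob = start_freq_a)
      n_b <- Nb - n_a
    }
    sample_counts <- function() {
      f <- n_a / (n_a + n_b)
      if (deterministic) c(f * sample_size, (1 - f) * sample_size)
      else { k <- stats::rbinom(1L, as.integer(sample_size), f); c(k, sample_size - k) }
    }
    gens <- seq(0L, n_generations, by = sampling_interval)
    out <- matrix(NA_real_, nrow = length(gens), ncol = 2L)
    out[1L, ] <- sample_counts()
    row <- 2L
    for (gen in seq_len(n_generations)) {
      # growth
      n_a <- n_a * 2 * exp(s_a)
      n_b <- n_b * 2 * exp(s_b)
      # toxin-mediated killing of susceptible non-immune cells
      if (kappa > 0) {
        tot <- n_a + n_b
        f_kill <- (if (ph_a$killer) n_a else 0) + (if (ph_b$killer) n_b else 0)
        f_kill <- f_kill / tot
        p <- kappa * f_kill
        if (p > 1) {
          if (!sat) stop("kill probability exceeds 1 with saturating = FALSE")
          p <- 1
        }
        die <- function(n) {
          if (deterministic) n * (1 - p)
          else n - stats::rbinom(1L, as.integer(round(n)), p)
        }
        if (!ph_a$immune && f_kill > 0) n_a <- die(n_a)
        if (!ph_b$immune && f_kill > 0) n_b <- die(n_b)
      }
      # dilution bottleneck at the end of each transfer
      if (gen %% g_per == 0L) {
        f <- n_a / (n_a + n_b)
        if (deterministic) {
          n_a <- Nb * f; n_b <- Nb * (1 - f)
        } else {
          n_a <- stats::rbinom(1L, as.integer(Nb), f)
          n_b <- Nb - n_a
        }
      }
      if (gen %% sampling_interval == 0L) {
        out[row, ] <- sample_counts()
        row <- row + 1L
      }
    }
    competition_timecourse(genotype_a$id, genotype_b$id,
                           data.frame(generation = gens,
                                      count_a = out[, 1L],
                                      count_b = out[, 2L],
                                      sample_size = sample_size))
  }
  if (deterministic) run() else with_stream(config$seed, stream, run())
}

# Registry of the viral variants referenced by two competitors; unknown ids
# default to wild-type-like (toxin and immunity functional).
competitor_registry <- function(config, ...) {
  registry <- list()
  for (sv in config$standing_variants) registry[[sv$variant$id]] <- sv$variant
  for (gt in list(...)) {
    for (id in names(gt$viral_composition)) {
      if (is.null(registry[[id]])) {
        registry[[id]] <- if (identical(id, "WT")) viral_variant("WT")
                          else attr(gt, "variants")[[id]] %||% viral_variant(id)
      }
    }
  }
  registry
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convenience constructors for the canonical killer-yeast clones
#'
#' `clone_killer()` carries wild-type virus (K+I+); `clone_neutral_virus()`
#' carries a toxin-null but immunity-positive variant (K-I+);
#' `clone_sensitive()` carries a toxin-null, immunity-null variant (K-I-);
#' `clone_cured()` has no virus at all (also K-I-, but contributes no viral
#' genomes).
#'
#' @param id Genotype id.
#' @param s Nuclear per-generation selection coefficient.
#' @param copies Viral copies per cell.
#' @return A [host_genotype()] whose referenced non-WT variants are attached
#'   as the `variants` attribute (picked up by [simulate_competition()]).
#' @export
clone_killer <- function(id = "early", s = 0, copies = 100) {
  host_genotype(id, nuclear_fitness_s = s,
                viral_composition = stats::setNames(copies, "WT"))
}

#' @rdname clone_killer
#' @export
clone_neutral_virus <- function(id = "intermediate", s = 0, copies = 100) {
  gt <- host_genotype(id, nuclear_fitness_s = s,
                      viral_composition = stats::setNames(copies, "KnegIpos"))
  attr(gt, "variants") <- list(
    KnegIpos = viral_variant("KnegIpos", toxin_functional = FALSE,
                             immunity_functional = TRUE))
  gt
}

#' @rdname clone_killer
#' @export
clone_sensitive <- function(id = "late", s = 0, copies = 100) {
  gt <- host_genotype(id, nuclear_fitness_s = s,
                      viral_composition = stats::setNames(copies, "KnegIneg"))
  attr(gt, "variants") <- list(
    KnegIneg = viral_variant("KnegIneg", toxin_functional = FALSE,
                             immunity_functional = FALSE))
  gt
}

#' @rdname clone_killer
#' @export
clone_cured <- function(id = "early_cured", s = 0) {
  host_genotype(id, nuclear_fitness_s = s, viral_composition = numeric(0))
}
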