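#' Simulate killer-phenotype evolution across replicate populations
#'
#' Cohort-based multilevel simulation of the 1000-generation serial-transfer
#' experiment. Each population starts from the shared founding composition
#' (wild-type killer virus plus any `standing_variants` in `config`) and
#' evolves independently on a random sub-stream derived from
#' `(config$seed, population index)`.
#'
#' Cells are grouped into cohorts by their resident viral variant
#' (heteroplasmic transients are collapsed: within-cell sweeps at viral copy
#' number Nv are fast relative to the population timescale). Within-cell
#' dynamics enter through the per-division conversion hazard
#' `mu_v * Nv * P_fix`, where `P_fix` is the Wright-Fisher fixation
#' probability of a single new copy in a pool of Nv copies given its
#' within-cell advantage relative to the resident. Converted cells found a
#' cohort of the new variant, drawn from `config$effect_table` (point
#' mutations are labelled transition/transversion with odds
#' `ts_tv_bias : 2`). Each generation the population then grows, susceptible
#' non-immune cells are killed at rate `kill_coefficient * f_killer`, and at
#' the end of each transfer a multinomial bottleneck to `bottleneck_size`
#' cells is applied (the drift source).
#'
#' @param config A [sim_config()].
#' @param n_populations Number of replicate populations (>= 1).
#' @param n_generations Total generations (default 1000).
#' @param record_generations Generations at which phenotype grades and variant
#'   frequencies are recorded; generation 0 is always included.
#' @param deterministic If `TRUE`, conversion, killing and bottleneck use
#'   expectations instead of sampling (deterministic mutation flow is pooled
#'   into one cohort per effect class).
#'
#' @return A list with elements
#'   \describe{
#'     \item{phenotypes}{data frame `population`, `generation`, `killing`,
#'       `immunity` (grades `"full"`/`"weak"`/`"none"`).}
#'     \item{trajectories}{long data frame `population`, `generation`,
#'       `variant_id`, `frequency` (fraction of cells resident for the
#'       variant).}
#'     \item{variants}{registry data frame of every variant generated, with
#'       phenotype flags and mutation class.}
#'   }
#' @export
simulate_population_evolution <- function(config, n_populations,
                                          n_generations = 1000L,
                                          record_generations = seq(0L, n_generations, by = 100L),
                                          deterministic = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_populations >= 1)
  record_generations <- sort(unique(c(0L, record_generations[record_generations <= n_generations])))

  res <- lapply(seq_len(n_populations), function(pop) {
    with_stream(config$seed, pop,
                sim_one_population(pop, config, n_generations,
                                   record_generations, deterministic))
  })

  list(
    phenotypes = do.call(rbind, lapply(res, `[[`, "phenotypes")),
    trajectories = do.call(rbind, lapply(res, `[[`, "trajectories")),
    variants = do.call(rbind, lapply(res, `[[`, "variants"))
  )
}

sim_one_population <- function(pop, config, n_generations, record_generations,
                               deterministic) {
  pop_id <- sprintf("pop%03d", pop)
  eff <- config$effect_table
  Nv <- config$viral_copy_number
  mu <- config$viral_mutation_rate
  kappa <- config$toxin$kill_coefficient
  sat <- config$toxin$saturating
  Nb <- config$protocol$bottleneck_size
  g_per <- config$protocol$generations_per_transfer
  R <- config$ts_tv_bias

  # cohort state as parallel vectors
  ids <- "WT"; cnt <- Nb; tox <- TRUE; imm <- TRUE; adv <- 0
  kinds <- NA_character_
  for (sv in config$standing_variants) {
    v <- sv$variant
    take <- Nb * sv$fraction
    cnt[1L] <- cnt[1L] - take
    ids <- c(ids, v$id); cnt <- c(cnt, take)
    tox <- c(tox, v$toxin_functional); imm <- c(imm, v$immunity_functional)
    adv <- c(adv, v$within_cell_advantage); kinds <- c(kinds, v$mutation_kind)
  }
  if (any(cnt < 0)) stop("standing variant fractions exceed 1 in total")

  # per-class conversion hazard depends only on the resident's advantage;
  # cache over the handful of advantage values present
  hazard <- function(res_adv) {
    vapply(seq_len(nrow(eff)), function(ei) {
      a_rel <- (1 + eff$within_cell_advantage[ei]) / (1 + res_adv) - 1
      mu * Nv * eff$weight[ei] * wf_fixation_prob(1 / Nv, a_rel, Nv)
    }, numeric(1))
  }

  ph_rows <- vector("list", length(record_generations))
  tr_rows <- vector("list", length(record_generations))
  rec_i <- 0L
  record <- function(gen) {
    rec_i <<- rec_i + 1L
    tot <- sum(cnt)
    ph_rows[[rec_i]] <<- data.frame(
      population = pop_id, generation = gen,
      killing = grade_from_fraction(sum(cnt[tox]) / tot, config$grade_hi, config$grade_lo),
      immunity = grade_from_fraction(sum(cnt[imm]) / tot, config$grade_hi, config$grade_lo),
      stringsAsFactors = FALSE)
    tr_rows[[rec_i]] <<- data.frame(
      population = pop_id, generation = gen,
      variant_id = ids, frequency = cnt / tot, stringsAsFactors = FALSE)
  }
  record(0L)

  if (n_generations >= 1L) for (gen in seq_len(n_generations)) {
    # within-cell conversion by de novo mutation
    if (mu > 0) {
      # hazards depend only on the resident advantage; compute per unique value
      ua <- unique(adv)
      hz_u <- vapply(ua, hazard, numeric(nrow(eff)))
      hz <- matrix(hz_u, nrow = nrow(eff))[, match(adv, ua), drop = FALSE]
      if (deterministic) {
        k <- hz * rep(cnt, each = nrow(eff))
      } else {
        k <- matrix(stats::rbinom(length(hz), rep(as.integer(round(cnt)), each = nrow(eff)),
                                  pmin(1, as.vector(hz))), nrow = nrow(eff))
      }
      if (any(k > 0)) {
        for (ci in which(colSums(k) > 0)) {
          for (ei in which(k[, ci] > 0)) {
            kk <- k[ei, ci]
            cnt[ci] <- cnt[ci] - kk
            if (eff$is_snv[ei]) {
              k_ts <- if (deterministic) kk * R / (R + 2)
                      else stats::rbinom(1L, as.integer(kk), R / (R + 2))
              parts <- c(transition = k_ts, transversion = kk - k_ts)
            } else parts <- c(indel = kk)
            # a mutation can break toxin or immunity function but never
            # restore it: effective flags are resident AND class
            e_tox <- tox[ci] && eff$toxin_functional[ei]
            e_imm <- imm[ci] && eff$immunity_functional[ei]
            for (kind in names(parts)) {
              if (parts[[kind]] <= 0) next
              # cohort members are exchangeable given (class, kind, flags), so
              # de novo conversions pool into one cohort per combination
              vid <- sprintf("%s_dn_%s_%s_K%dI%d", pop_id, eff$class[ei], kind,
                             as.integer(e_tox), as.integer(e_imm))
              at <- match(vid, ids)
              if (is.na(at)) {
                ids <- c(ids, vid); cnt <- c(cnt, parts[[kind]])
                tox <- c(tox, e_tox)
                imm <- c(imm, e_imm)
                adv <- c(adv, eff$within_cell_advantage[ei])
                kinds <- c(kinds, kind)
              } else cnt[at] <- cnt[at] + parts[[kind]]
            }
          }
        }
      }
    }
    # growth (nuclear fitness identical within a population here)
    cnt <- cnt * 2
    # toxin-mediated killing of susceptible non-immune cells
    if (kappa > 0) {
      p <- kappa * sum(cnt[tox]) / sum(cnt)
      if (p > 1) {
        if (!sat) stop("kill probability exceeds 1 with saturating = FALSE")
        p <- 1
      }
      if (p > 0 && any(!imm)) {
        at <- which(!imm)
        if (deterministic) cnt[at] <- cnt[at] * (1 - p)
        else cnt[at] <- cnt[at] -
            stats::rbinom(length(at), as.integer(round(cnt[at])), p)
      }
    }
    # dilution bottleneck
    if (gen %% g_per == 0L) {
      f <- cnt / sum(cnt)
      if (deterministic) cnt <- Nb * f
      else cnt <- as.numeric(stats::rmultinom(1L, as.integer(Nb), f))
      keep <- cnt > 0
      if (!all(keep)) {
        ids <- ids[keep]; cnt <- cnt[keep]; tox <- tox[keep]
        imm <- imm[keep]; adv <- adv[keep]; kinds <- kinds[keep]
      }
    }
    if (gen %in% record_generations) record(gen)
  }

  list(phenotypes = do.call(rbind, ph_rows[seq_len(rec_i)]),
       trajectories = do.call(rbind, tr_rows[seq_len(rec_i)]),
       variants = data.frame(population = pop_id, id = ids,
                             toxin_functional = tox, immunity_functional = imm,
                             within_cell_advantage = adv, mutation_kind = kinds,
                             stringsAsFactors = FALSE))
}

#' Wright-Fisher fixation probability
#'
#' Probability that an allele at frequency `p0` with selection coefficient `s`
#' fixes in a haploid Wright-Fisher population of size `N` (diffusion
#' approximation; exactly `p0` for `s = 0`).
#'
#' @param p0 Initial frequency in \[0, 1\].
#' @param s Selection coefficient (>= -1).
#' @param N Population size.
#' @return Fixation probability.
#' @export
wf_fixation_prob <- function(p0, s, N) {
  stopifnot(p0 >= 0, p0 <= 1, N >= 1)
  if (abs(s) < 1e-12) return(p0)
  (1 - exp(-2 * N * s * p0)) / (1 - exp(-2 * N * s))
}
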