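#' Simulate heteroplasmic single-cell-bottleneck lines
#'
#' Emulates the intracellular competition experiment: a heteroplasmic cell
#' (ancestral wild-type virus plus a focal variant at `initial_freq` of its
#' `viral_copy_number` copies) founds a line that is grown for
#' `generations_per_bottleneck` cell divisions and then passed through a
#' single-cell bottleneck, repeated `n_bottlenecks` times.
#'
#' Because bottleneck founders are drawn uniformly (no among-cell selection),
#' the sampled cell is exchangeable with any other lineage, so the simulation
#' follows a single cell lineage: at each division the viral pool is doubled
#' by sampling `2 * Nv` copies with weights proportional to
#' `count * (1 + within_cell_advantage)`, each new copy mutates with
#' probability `viral_mutation_rate` (drawing its effect from
#' `config$effect_table`), and the daughter inherits `Nv` copies sampled
#' without replacement. Per-bottleneck records report the founder cell's
#' composition.
#'
#' @param config A [sim_config()].
#' @param variant The focal [viral_variant()] segregating against wild-type.
#' @param initial_freq Initial within-cell frequency of the focal variant,
#'   in \[0, 1\].
#' @param n_lines Number of replicate lines.
#' @param n_bottlenecks Number of single-cell bottlenecks (default 7).
#' @param generations_per_bottleneck Cell divisions between bottlenecks
#'   (default 20, a ~48-hr colony).
#' @param deterministic If `TRUE`, replication is deterministic
#'   (`x' proportional to x * (1 + advantage)`, no drift, no mutation), the
#'   infinite-copy-number limit.
#'
#' @return A data frame of class `intracellular_trajectories` with columns
#'   `line`, `bottleneck` (0-based, 0 = founding cell), `frequency` (focal
#'   variant), `killing`, `immunity` (cell-level grades `"full"`/`"weak"`/
#'   `"none"`).
#' @export
simulate_heteroplasmic_lines <- function(config, variant, initial_freq,
                                         n_lines = 3L, n_bottlenecks = 7L,
                                         generations_per_bottleneck = 20L,
                                         deterministic = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(variant, "viral_variant"))
  if (initial_freq < 0 || initial_freq > 1)
    stop("initial_freq must lie in [0, 1]")
  if (n_bottlenecks < 1) stop("n_bottlenecks must be >= 1")
  Nv <- config$viral_copy_number
  mu <- config$viral_mutation_rate
  eff <- config$effect_table

  reg0 <- data.frame(id = c("WT", variant$id),
                     toxin = c(TRUE, variant$toxin_functional),
                     immunity = c(TRUE, variant$immunity_functional),
                     advantage = c(0, variant$within_cell_advantage),
                     stringsAsFactors = FALSE)

  one_line <- function(line) {
    reg <- reg0
    if (deterministic) {
      counts <- c(WT = Nv * (1 - initial_freq))
      counts[variant$id] <- Nv * initial_freq
    } else {
      k <- stats::rbinom(1L, Nv, initial_freq)
      counts <- c(WT = Nv - k)
      counts[variant$id] <- k
    }
    denovo_i <- 0L
    rows <- vector("list", n_bottlenecks + 1L)
    rec <- function(b) {
      tot <- sum(counts)
      m <- match(names(counts), reg$id)
      f_tox <- sum(counts[reg$toxin[m]]) / tot
      f_imm <- sum(counts[reg$immunity[m]]) / tot
      data.frame(
        line = sprintf("line%02d", line), bottleneck = b,
        frequency = (if (variant$id %in% names(counts)) counts[[variant$id]] else 0) / tot,
        killing = grade_from_fraction(f_tox, config$theta_K, config$theta_K / 2),
        immunity = grade_from_fraction(f_imm, config$theta_I, config$theta_I / 5),
        stringsAsFactors = FALSE)
    }
    rows[[1L]] <- rec(0L)
    for (b in seq_len(n_bottlenecks)) {
      for (division in seq_len(generations_per_bottleneck)) {
        if (deterministic) {
          m <- match(names(counts), reg$id)
          w <- counts * (1 + reg$advantage[m])
          counts <- Nv * w / sum(w)
          next
        }
        # absorbed and mutation-free: composition can no longer change
        if (mu == 0 && sum(counts > 0) == 1L) break
        m <- match(names(counts), reg$id)
        w <- counts * (1 + reg$advantage[m])
        pool <- stats::setNames(
          as.numeric(stats::rmultinom(1L, 2L * Nv, w / sum(w))), names(counts))
        if (mu > 0) {
          n_mut <- stats::rbinom(1L, 2L * Nv, mu)
          if (n_mut > 0) {
            src <- sample(rep(names(pool), pool), n_mut)
            for (sv in src) {
              pool[sv] <- pool[sv] - 1
              ei <- sample.int(nrow(eff), 1L, prob = eff$weight)
              denovo_i <- denovo_i + 1L
              vid <- sprintf("dn%03d_%s", denovo_i, eff$class[ei])
              si <- match(sv, reg$id)
              # mutation can break but never restore toxin/immunity function
              reg <- rbind(reg, data.frame(
                id = vid,
                toxin = reg$toxin[si] && eff$toxin_functional[ei],
                immunity = reg$immunity[si] && eff$immunity_functional[ei],
                advantage = eff$within_cell_advantage[ei],
                stringsAsFactors = FALSE))
              pool[vid] <- 1
            }
          }
        }
        # daughter inherits Nv copies without replacement
        inherit <- sample(rep(names(pool), pool), Nv)
        counts <- stats::setNames(as.numeric(table(factor(inherit, levels = names(pool)))),
                                  names(pool))
        counts <- counts[counts > 0]
      }
      rows[[b + 1L]] <- rec(b)
    }
    do.call(rbind, rows)
  }

  out <- if (deterministic) {
    do.call(rbind, lapply(seq_len(n_lines), one_line))
  } else {
    do.call(rbind, lapply(seq_len(n_lines), function(l)
      with_stream(config$seed, 100000L + l, one_line(l))))
  }
  rownames(out) <- NULL
  class(out) <- c("intracellular_trajectories", "data.frame")
  out
}
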