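#' Describe an intracellular viral variant
#'
#' A variant of the M1-like satellite virus is summarised by what it does to
#' the cell that carries it (toxin production, immunity) and by how it
#' replicates relative to other variants within the same cell.
#'
#' @param id Character scalar, unique variant identifier (e.g. `"WT"`,
#'   `"I292M"`).
#' @param toxin_functional Logical; does the variant encode a functional
#'   secreted toxin?
#' @param immunity_functional Logical; does the variant encode a preprotoxin
#'   capable of conferring immunity? A variant may be toxin-null but
#'   immunity-positive (K-I+).
#' @param within_cell_advantage Per-replication selective advantage of this
#'   variant over others within one cell's viral pool; must be >= -1.
#' @param is_deletion Logical; internally deleted (defective-interfering-like)
#'   genome. Deletions are necessarily toxin-null and immunity-null.
#' @param mutation_kind Optional character label for spectrum bookkeeping:
#'   one of `"transition"`, `"transversion"`, `"indel"`, or `NA`.
#'
#' @return An object of class `viral_variant`.
#' @export
viral_variant <- function(id, toxin_functional = TRUE, immunity_functional = TRUE,
                          within_cell_advantage = 0, is_deletion = FALSE,
                          mutation_kind = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(within_cell_advantage) || within_cell_advantage < -1)
    stop("within_cell_advantage must be a number >= -1")
  if (is_deletion && (toxin_functional || immunity_functional))
    stop("a deletion variant cannot be toxin_functional or immunity_functional")
  structure(list(
    id = id,
    toxin_functional = isTRUE(toxin_functional),
    immunity_functional = isTRUE(immunity_functional),
    within_cell_advantage = as.numeric(within_cell_advantage),
    is_deletion = isTRUE(is_deletion),
    mutation_kind = mutation_kind
  ), class = "viral_variant")
}

#' Describe a host genotype
#'
#' @param id Character scalar identifier.
#' @param nuclear_fitness_s Per-generation (Malthusian) selection coefficient
#'   conferred by the nuclear genome, relative to the reference genotype.
#' @param label `"unlabeled"` or `"fluorescent"` (flow-cytometry marker).
#' @param viral_composition Named non-negative integer vector of viral copy
#'   counts per variant id. An empty or all-zero vector means the genotype is
#'   cured of the virus.
#'
#' @return An object of class `host_genotype`.
#' @export
host_genotype <- function(id, nuclear_fitness_s = 0,
                          label = c("unlabeled", "fluorescent"),
                          viral_composition = c(WT = 100)) {
  stopifnot(is.character(id), length(id) == 1L)
  label <- match.arg(label)
  if (length(viral_composition)) {
    if (is.null(names(viral_composition)) || any(!nzchar(names(viral_composition))))
      stop("viral_composition must be a named vector of counts per variant id")
    if (any(viral_composition < 0)) stop("viral counts must be >= 0")
  }
  structure(list(
    id = id,
    nuclear_fitness_s = as.numeric(nuclear_fitness_s),
    label = label,
    viral_composition = viral_composition
  ), class = "host_genotype")
}

#' Serial-transfer protocol
#'
#' Daily 1:D dilution into fresh medium; regrowth to saturation corresponds to
#' log2(D) generations per transfer. The default mirrors a 1:2^10 dilution,
#' i.e. 10 generations of growth per day at a bottleneck of ~1e5 cells.
#'
#' @param dilution_factor Integer dilution factor D; must be an exact power
#'   of two.
#' @param bottleneck_size Number of cells surviving each dilution.
#' @param n_transfers Number of transfers (used by [run_pipeline()] configs).
#'
#' @return An object of class `serial_transfer_protocol` with the derived
#'   field `generations_per_transfer = log2(dilution_factor)`.
#' @export
serial_transfer_protocol <- function(dilution_factor = 1024L,
                                     bottleneck_size = 1e5,
                                     n_transfers = 100L) {
  g <- log2(dilution_factor)
  if (g != round(g)) stop("dilution_factor must be an exact power of two")
  if (bottleneck_size < 1) stop("bottleneck_size must be >= 1")
  structure(list(
    dilution_factor = as.integer(dilution_factor),
    generations_per_transfer = as.integer(round(g)),
    bottleneck_size = bottleneck_size,
    n_transfers = as.integer(n_transfers)
  ), class = "serial_transfer_protocol")
}

#' Toxin-mediated killing model
#'
#' Well-mixed, memoryless kinetics: each generation a susceptible (non-immune)
#' cell dies with probability `kill_coefficient * f_killer`, where `f_killer`
#' is the current frequency of toxin-producing cells. With `saturating = TRUE`
#' the probability is capped at 1; otherwise a probability above 1 is an error.
#'
#' @param kill_coefficient Non-negative per-generation death probability per
#'   unit killer frequency.
#' @param saturating Logical, see Details.
#'
#' @return An object of class `toxin_model`.
#' @export
toxin_model <- function(kill_coefficient = 0.2, saturating = TRUE) {
  if (kill_coefficient < 0) stop("kill_coefficient must be >= 0")
  structure(list(
    kill_coefficient = as.numeric(kill_coefficient),
    saturating = isTRUE(saturating)
  ), class = "toxin_model")
}

#' Default spectrum of de novo viral mutation effects
#'
#' Relative weights and phenotypic consequences of the mutation classes the
#' population simulator can generate. Missense toxin-null (K-I+) changes
#' dominate, as in observed M1 spectra; nonsense/frameshift changes abolish
#' both toxin and immunity; internal deletions behave as
#' defective-interfering-like genomes with a large within-cell advantage.
#'
#' @param advantage Within-cell advantage given to phenotype-altering point
#'   variants.
#' @param deletion_advantage Within-cell advantage of internal deletions.
#' @return A data frame with columns `class`, `weight`, `toxin_functional`,
#'   `immunity_functional`, `within_cell_advantage`, `is_deletion`, `is_snv`.
#' @export
default_effect_table <- function(advantage = 0.1, deletion_advantage = 0.3) {
  data.frame(
    class = c("synonymous", "missense_KnegIpos", "nonsense_KnegIneg", "deletion"),
    weight = c(0.25, 0.55, 0.15, 0.05),
    toxin_functional = c(TRUE, FALSE, FALSE, FALSE),
    immunity_functional = c(TRUE, TRUE, FALSE, FALSE),
    within_cell_advantage = c(0, advantage, advantage, deletion_advantage),
    is_deletion = c(FALSE, FALSE, FALSE, TRUE),
    is_snv = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration
#'
#' Bundles the serial-transfer protocol, toxin kinetics, the intracellular
#' viral parameters and the root seed. All stochastic simulator entry points
#' derive independent, reproducible streams from `(seed, index)`.
#'
#' @param protocol A [serial_transfer_protocol()].
#' @param toxin A [toxin_model()].
#' @param viral_copy_number Viral copies per cell (Nv), default 100.
#' @param viral_mutation_rate Mutation probability per viral copy per
#'   replication, in \[0, 1\].
#' @param ts_tv_bias Weight of the single transition relative to each of the
#'   two transversion classes when labelling de novo point mutations;
#'   default 6.4.
#' @param seed Integer root seed.
#' @param standing_variants List of `list(variant = viral_variant, fraction =)`
#'   entries: variants segregating in the founding culture, as the fraction of
#'   founding cells whose viral pool is (destined to be) taken over by the
#'   variant. Default none (opt-in).
#' @param effect_table Data frame as returned by [default_effect_table()].
#' @param theta_K Minimum fraction of toxin-functional copies for a cell to
#'   produce toxin (default 0.5).
#' @param theta_I Minimum fraction of immunity-functional copies for a cell to
#'   be immune (default 0.05; sparse functional preprotoxin copies suffice).
#' @param grade_hi,grade_lo Population-level phenotype grading: fraction of
#'   cells with the property >= `grade_hi` scores `"full"`, < `grade_lo`
#'   scores `"none"`, in between `"weak"`.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(protocol = serial_transfer_protocol(),
                       toxin = toxin_model(),
                       viral_copy_number = 100L,
                       viral_mutation_rate = 1e-6,
                       ts_tv_bias = 6.4,
                       seed = 1L,
                       standing_variants = list(),
                       effect_table = default_effect_table(),
                       theta_K = 0.5, theta_I = 0.05,
                       grade_hi = 0.75, grade_lo = 0.25) {
  stopifnot(inherits(protocol, "serial_transfer_protocol"),
            inherits(toxin, "toxin_model"))
  if (viral_mutation_rate < 0 || viral_mutation_rate > 1)
    stop("viral_mutation_rate must lie in [0, 1]")
  if (viral_copy_number < 1) stop("viral_copy_number must be >= 1")
  for (sv in standing_variants) {
    if (!inherits(sv$variant, "viral_variant"))
      stop("each standing variant needs a $variant of class viral_variant")
    if (is.null(sv$fraction) || sv$fraction < 0 || sv$fraction > 1)
      stop("each standing variant needs a $fraction in [0, 1]")
  }
  structure(list(
    protocol = protocol,
    toxin = toxin,
    viral_copy_number = as.integer(viral_copy_number),
    viral_mutation_rate = viral_mutation_rate,
    ts_tv_bias = ts_tv_bias,
    seed = as.integer(seed),
    standing_variants = standing_variants,
    effect_table = effect_table,
    theta_K = theta_K, theta_I = theta_I,
    grade_hi = grade_hi, grade_lo = grade_lo
  ), class = "sim_config")
}

#' Competition time course
#'
#' Per-timepoint competitor counts from a pairwise competition, emulating
#' flow-cytometry event counts. In deterministic simulations the counts are
#' expectations and need not be integers; they still sum to `sample_size`.
#'
#' @param competitor_a,competitor_b Competitor identifiers.
#' @param timepoints Data frame with columns `generation`, `count_a`,
#'   `count_b`, `sample_size`.
#'
#' @return An object of class `competition_timecourse` (a data frame with
#'   attributes `competitor_a`, `competitor_b`).
#' @export
competition_timecourse <- function(competitor_a, competitor_b, timepoints) {
  need <- c("generation", "count_a", "count_b", "sample_size")
  if (!all(need %in% names(timepoints)))
    stop("timepoints must have columns ", paste(need, collapse = ", "))
  tp <- as.data.frame(timepoints)[, need]
  if (nrow(tp) == 0) stop("at least one timepoint is required")
  if (tp$generation[1] != 0 || is.unsorted(tp$generation, strictly = TRUE))
    stop("generations must increase strictly from 0")
  if (any(tp$count_a < 0) || any(tp$count_b < 0)) stop("counts must be >= 0")
  if (any(abs(tp$count_a + tp$count_b - tp$sample_size) > 1e-8 * pmax(1, tp$sample_size)))
    stop("count_a + count_b must equal sample_size at every timepoint")
  structure(tp, class = c("competition_timecourse", "data.frame"),
            competitor_a = competitor_a, competitor_b = competitor_b)
}

#' @export
print.competition_timecourse <- function(x, ...) {
  cat(sprintf("Competition time course: %s vs %s (%d timepoints, %d generations)\n",
              attr(x, "competitor_a"), attr(x, "competitor_b"),
              nrow(x), max(x$generation)))
  print.data.frame(x, ...)
  invisible(x)
}

# Derive a reproducible sub-stream seed from (root seed, index); kept < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 65011 * 33013 + as.double(index) * 7919 + 104729) %%
               2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, index),
# restoring the caller's state afterwards.
with_stream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, index))
  force(expr)
}

# Cell phenotype from a viral composition (named counts) and the variant
# registry (named list of viral_variant).
cell_phenotype <- function(composition, registry, theta_K = 0.5, theta_I = 0.05) {
  total <- sum(composition)
  if (total <= 0) return(list(killer = FALSE, immune = FALSE, cured = TRUE))
  ids <- names(composition)
  tox <- vapply(ids, function(i) registry[[i]]$toxin_functional, logical(1))
  imm <- vapply(ids, function(i) registry[[i]]$immunity_functional, logical(1))
  list(killer = sum(composition[tox]) / total >= theta_K,
       immune = sum(composition[imm]) / total >= theta_I,
       cured = FALSE)
}

# Map a fraction of cells with a property to an ordinal grade.
grade_from_fraction <- function(f, hi = 0.75, lo = 0.25) {
  ifelse(f >= hi, "full", ifelse(f >= lo, "weak", "none"))
}
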