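GRADE_LEVELS <- c("none", "weak", "full")

grade_rank <- function(g) {
  r <- match(g, GRADE_LEVELS)
  if (anyNA(r)) stop("grades must be one of: ", paste(GRADE_LEVELS, collapse = ", "))
  r
}

check_phenotype_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("population", "generation", "killing", "immunity")
  if (!all(need %in% names(records)))
    stop("phenotype records need columns ", paste(need, collapse = ", "))
  if (anyDuplicated(records[, c("population", "generation")]))
    stop("one record per (population, generation) is required")
  grade_rank(records$killing); grade_rank(records$immunity)
  records[order(records$population, records$generation), ]
}

#' Killer-phenotype retention trajectories
#'
#' Fraction of populations retaining killing ability and immunity at each
#' recorded generation, i.e. with a grade at or above `threshold`. Missing
#' observations are carried forward from the population's last recorded
#' grade. Every population must be observed at generation 0.
#'
#' @param records Phenotype table: data frame with columns `population`,
#'   `generation`, `killing`, `immunity` (grades `"full"`, `"weak"`,
#'   `"none"`).
#' @param threshold Minimum grade that counts as retained (default `"full"`,
#'   so any weakening counts as loss).
#' @return Data frame with columns `generation`, `killing_retained`,
#'   `immunity_retained`, `n_populations`.
#' @export
phenotype_trajectory <- function(records, threshold = "full") {
  records <- check_phenotype_records(records)
  thr <- grade_rank(threshold)
  pops <- unique(records$population)
  gens <- sort(unique(records$generation))
  if (gens[1L] != 0 || !all(pops %in% records$population[records$generation == 0]))
    stop("every population must be observed at generation 0")
  kill <- imm <- matrix(NA_integer_, nrow = length(pops), ncol = length(gens),
                        dimnames = list(pops, gens))
  idx <- cbind(match(records$population, pops), match(records$generation, gens))
  kill[idx] <- grade_rank(records$killing)
  imm[idx] <- grade_rank(records$immunity)
  for (j in seq_along(gens)[-1L]) {           # carry last observation forward
    miss <- is.na(kill[, j])
    kill[miss, j] <- kill[miss, j - 1L]
    imm[miss, j] <- imm[miss, j - 1L]
  }
  data.frame(generation = gens,
             killing_retained = colMeans(kill >= thr),
             immunity_retained = colMeans(imm >= thr),
             n_populations = length(pops),
             row.names = NULL)
}

#' Audit phenotype transitions for biologically forbidden patterns
#'
#' Flags two patterns never observed in the killer-yeast system:
#' (a) immunity below full while killing ability is still full (immunity is
#' conferred by the preprotoxin, so a fully killing population cannot have
#' lost immunity), and (b) any increase of either grade over time (killing
#' ability and immunity, once weakened or lost, do not reappear).
#' Simultaneous loss of both phenotypes is legal.
#'
#' @param records Phenotype table (see [phenotype_trajectory()]), with at
#'   least 2 generations per population.
#' @return Data frame of violations with columns `population`, `generation`,
#'   `type` (`"immunity_before_killing"` or `"grade_increase"`), `detail`;
#'   zero rows when the table is clean.
#' @export
transition_audit <- function(records) {
  records <- check_phenotype_records(records)
  out <- list()
  flag <- function(population, generation, type, detail)
    out[[length(out) + 1L]] <<- data.frame(population, generation, type, detail,
                                           stringsAsFactors = FALSE)
  for (p in unique(records$population)) {
    rp <- records[records$population == p, ]
    k <- grade_rank(rp$killing); m <- grade_rank(rp$immunity)
    for (t in seq_len(nrow(rp))) {
      if (k[t] == 3L && m[t] < 3L)
        flag(p, rp$generation[t], "immunity_before_killing",
             sprintf("killing full but immunity %s", rp$immunity[t]))
      if (t > 1L) {
        if (k[t] > k[t - 1L])
          flag(p, rp$generation[t], "grade_increase",
               sprintf("killing %s -> %s", rp$killing[t - 1L], rp$killing[t]))
        if (m[t] > m[t - 1L])
          flag(p, rp$generation[t], "grade_increase",
               sprintf("immunity %s -> %s", rp$immunity[t - 1L], rp$immunity[t]))
      }
    }
  }
  if (!length(out))
    return(data.frame(population = character(), generation = numeric(),
                      type = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Association between a genotype indicator and a phenotype indicator, e.g.
#' presence of viral mutations versus loss of killing ability. All marginals
#' must be positive. The default is the uncorrected statistic; set
#' `yates = TRUE` for the continuity correction.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return List with `chisq`, `df` (always 1), `p`.
#' @export
#'
#' @examples
#' contingency_chisq(matrix(c(57, 1, 0, 9), 2))$chisq  # 59.3
contingency_chisq <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals must be positive for the chi-squared test")
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Chi-squared survival function
#'
#' Upper-tail probability of the chi-squared distribution, used to turn a
#' printed statistic into its p-value.
#'
#' @param x Statistic, >= 0.
#' @param df Degrees of freedom, >= 1.
#' @return `P(X >= x)` for `X ~ chi-squared(df)`.
#' @export
chisq_sf <- function(x, df = 1) {
  if (any(x < 0)) stop("x must be >= 0")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}
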