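#' Expected long-range fitness gain from stepwise gains
#'
#' Under transitivity, the fitness of a descendant relative to a distant
#' ancestor is predicted from the stepwise gains along the lineage: their sum
#' (`mode = "sum"`, the field's usual arithmetic for small coefficients) or
#' their compound product `prod(1 + s_i) - 1` (`mode = "compound"`).
#'
#' @param steps Numeric vector of per-step selection coefficients (>= 1 step).
#' @param mode `"sum"` or `"compound"`.
#' @return The expected overall selection coefficient.
#' @export
#'
#' @examples
#' additive_expectation(c(0.038, 0.012))              # 0.050
#' additive_expectation(c(0.038, 0.012), "compound")  # 0.050456
additive_expectation <- function(steps, mode = c("sum", "compound")) {
  mode <- match.arg(mode)
  if (!length(steps)) stop("at least one step is required")
  if (mode == "sum") sum(steps) else prod(1 + steps) - 1
}

#' Pairwise fitness matrix in long format
#'
#' Validates a long-format table of pairwise fitness measurements along a
#' genealogical lineage: each row gives the per-generation fitness `s_hat` of
#' the `later` clone relative to the `earlier` clone, optionally at a
#' starting frequency `f0` of the later clone, with `stderr` if available.
#'
#' @param df Data frame with columns `earlier`, `later`, `s_hat`, and
#'   optionally `f0` and `stderr`.
#' @return The data frame with class `pairwise_fitness_matrix`.
#' @export
pairwise_fitness_matrix <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("earlier", "later", "s_hat") %in% names(df)))
    stop("matrix must have columns earlier, later, s_hat")
  if (is.null(df$f0)) df$f0 <- NA_real_
  if (is.null(df$stderr)) df$stderr <- NA_real_
  structure(df, class = c("pairwise_fitness_matrix", "data.frame"))
}

matrix_entries <- function(m, earlier, later) {
  m[m$earlier == earlier & m$later == later, , drop = FALSE]
}

# "Significantly" signed estimate: sign decided only when |s| > 2 * stderr
# (a missing stderr falls back to the sign alone).
sig_sign <- function(s, se) {
  thr <- ifelse(is.na(se), 0, 2 * se)
  ifelse(s > thr, 1L, ifelse(s < -thr, -1L, 0L))
}

#' Classify a genealogical triple for transitivity
#'
#' For clones `i -> j -> k` ordered by genealogical time, compares the direct
#' competition `s(i -> k)` with the additive expectation from the steps
#' `s(i -> j)` and `s(j -> k)`. With both steps positive, the triple is
#' `nontransitive` when the direct estimate is significantly negative (the
#' descendant loses to its distant ancestor) at any tested starting
#' frequency, and `frequency_dependent_nontransitive` when the direct
#' estimate changes sign across the tested frequencies (significantly
#' negative at one, significantly positive at another). Otherwise the triple
#' is `transitive`. An estimate is called negative (positive) only when it
#' exceeds twice its standard error in magnitude; ties are conservatively
#' transitive.
#'
#' @param matrix A [pairwise_fitness_matrix()].
#' @param triple Character vector `c(i, j, k)` of clone ids.
#' @param mode Mode for [additive_expectation()] (default `"sum"`).
#' @return An object of class `transitivity_verdict`: list with `triple`,
#'   `expected_s_ik`, `observed_s_ik` (data frame of the direct entries),
#'   `verdict`, and `deviation` (mean observed minus expected).
#' @export
classify_triple <- function(matrix, triple, mode = "sum") {
  stopifnot(inherits(matrix, "pairwise_fitness_matrix"), length(triple) == 3L)
  i <- triple[1L]; j <- triple[2L]; k <- triple[3L]
  e_ij <- matrix_entries(matrix, i, j)
  e_jk <- matrix_entries(matrix, j, k)
  e_ik <- matrix_entries(matrix, i, k)
  if (!nrow(e_ij) || !nrow(e_jk) || !nrow(e_ik))
    stop("matrix is missing entries for the triple ",
         paste(triple, collapse = " -> "))
  s_ij <- mean(e_ij$s_hat); s_jk <- mean(e_jk$s_hat)
  expected <- additive_expectation(c(s_ij, s_jk), mode)
  signs <- sig_sign(e_ik$s_hat, e_ik$stderr)
  verdict <- if (s_ij > 0 && s_jk > 0 && any(signs < 0)) {
    if (any(signs > 0)) "frequency_dependent_nontransitive" else "nontransitive"
  } else "transitive"
  structure(list(triple = triple,
                 expected_s_ik = expected,
                 observed_s_ik = e_ik[, c("f0", "s_hat", "stderr")],
                 verdict = verdict,
                 deviation = mean(e_ik$s_hat) - expected),
            class = "transitivity_verdict")
}

#' @export
print.transitivity_verdict <- function(x, ...) {
  cat(sprintf("Triple %s: %s\n", paste(x$triple, collapse = " -> "), x$verdict))
  cat(sprintf("  expected s(%s -> %s) = %+.4f, mean observed = %+.4f (deviation %+.4f)\n",
              x$triple[1L], x$triple[3L], x$expected_s_ik,
              mean(x$observed_s_ik$s_hat), x$deviation))
  invisible(x)
}

#' Enumerate dominance cycles in a win/loss digraph
#'
#' Finds all elementary directed cycles (rock-paper-scissors-like loops) in a
#' tournament-style digraph of competition outcomes, shortest first. The
#' digraph may have at most one directed edge per clone pair.
#'
#' @param edges Data frame with columns `winner`, `loser` (one row per
#'   decided pair).
#' @return A list of character vectors, each an elementary cycle given from
#'   its lexicographically smallest vertex; ordered by length, then
#'   lexicographically.
#' @export
#'
#' @examples
#' rps <- data.frame(winner = c("rock", "scissors", "paper"),
#'                   loser = c("scissors", "paper", "rock"))
#' dominance_cycles(rps)
dominance_cycles <- function(edges) {
  edges <- as.data.frame(edges)
  if (!all(c("winner", "loser") %in% names(edges)))
    stop("edges must have columns winner, loser")
  pair <- paste(pmin(edges$winner, edges$loser), pmax(edges$winner, edges$loser))
  if (anyDuplicated(pair)) stop("at most one directed edge per pair is allowed")
  verts <- sort(unique(c(edges$winner, edges$loser)))
  adj <- lapply(stats::setNames(verts, verts),
                function(v) sort(edges$loser[edges$winner == v]))
  cycles <- list()
  # DFS rooted at each vertex; only record cycles whose smallest vertex is the
  # root, so each elementary cycle is found exactly once.
  for (root in verts) {
    stack <- list(list(path = root))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      tail_v <- fr$path[length(fr$path)]
      for (nb in adj[[tail_v]]) {
        if (nb == root && length(fr$path) >= 2L) {
          cycles[[length(cycles) + 1L]] <- fr$path
        } else if (nb > root && !nb %in% fr$path) {
          stack[[length(stack) + 1L]] <- list(path = c(fr$path, nb))
        }
      }
    }
  }
  if (!length(cycles)) return(list())
  keys <- vapply(cycles, function(cy)
    sprintf("%03d %s", length(cy), paste(cy, collapse = " ")), character(1))
  cycles[order(keys)]
}
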