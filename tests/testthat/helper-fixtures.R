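# Noise-free competition time course following an exact exponential ratio:
# ln(count_a / count_b) = lr0 + s * generation, counts scaled to sample_size.
exact_timecourse <- function(s, gens = seq(0, 50, 10), f0 = 0.5,
                             sample_size = 1000) {
  lr <- log(f0 / (1 - f0)) + s * gens
  fa <- 1 / (1 + exp(-lr))
  competition_timecourse("a", "b", data.frame(
    generation = gens,
    count_a = fa * sample_size,
    count_b = (1 - fa) * sample_size,
    sample_size = sample_size))
}

# Random stop-free ORF of n_codons codons (including the leading ATG).
random_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                                  b2 = c("A", "C", "G", "T"),
                                  b3 = c("A", "C", "G", "T")), 1, paste0,
                      collapse = "")
  safe <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(safe, n_codons - 1, replace = TRUE), collapse = ""))
}

# Random snv on an ORF (uniform position, uniform non-ref base).
random_snv <- function(orf_seq) {
  pos <- sample.int(nchar(orf_seq), 1)
  ref <- substr(orf_seq, pos, pos)
  variant_spec(pos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1))
}

# Brute-force effect classification by whole-protein translation comparison.
translate_effect_oracle <- function(orf_seq, v) {
  alt_seq <- orf_seq
  substr(alt_seq, v$pos, v$pos) <- v$alt
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  p_ref <- tr(orf_seq); p_alt <- tr(alt_seq)
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  if (substr(p_alt, d, d) == "*") "nonsense" else "missense"
}

# Brute-force elementary-cycle enumeration: every subset permutation that
# forms a directed cycle, canonicalised to start at its smallest vertex.
cycles_oracle <- function(edges) {
  verts <- sort(unique(c(edges$winner, edges$loser)))
  has <- function(a, b) any(edges$winner == a & edges$loser == b)
  found <- list()
  for (size in 2:length(verts)) {
    combs <- utils::combn(verts, size, simplify = FALSE)
    for (cs in combs) {
      perms <- perms_of(cs)
      for (p in perms) {
        if (p[1] != min(cs)) next  # canonical start
        ok <- all(vapply(seq_along(p), function(i)
          has(p[i], p[(i %% length(p)) + 1]), logical(1)))
        if (ok) found[[length(found) + 1]] <- p
      }
    }
  }
  keys <- vapply(found, function(cy)
    sprintf("%03d %s", length(cy), paste(cy, collapse = " ")), character(1))
  found <- found[!duplicated(keys)]
  found[order(keys[!duplicated(keys)])]
}

perms_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# Random win/loss tournament on n clones where every pair is decided.
random_tournament <- function(n) {
  v <- sprintf("c%d", seq_len(n))
  pairs <- utils::combn(v, 2)
  flip <- stats::runif(ncol(pairs)) < 0.5
  data.frame(winner = ifelse(flip, pairs[1, ], pairs[2, ]),
             loser = ifelse(flip, pairs[2, ], pairs[1, ]),
             stringsAsFactors = FALSE)
}
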