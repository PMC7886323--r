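test_that("allele probes carry the 5-nt flanks and truncate at sequence ends", {
  ref <- "ACGTACGTACGTACGTACGT"
  p <- build_allele_probes(ref, variant_spec(10, "C", "A"))
  expect_identical(nchar(p$ancestral), 11L)
  expect_identical(p$ancestral, substr(ref, 5, 15))
  expect_identical(p$derived, paste0(substr(ref, 5, 9), "A", substr(ref, 11, 15)))
  expect_identical(p$ancestral_rc,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(p$ancestral))))
  # near the left end the flank truncates (position 3: 2 left + 1 + 5 right)
  p2 <- build_allele_probes(ref, variant_spec(3, "G", "T"))
  expect_identical(nchar(p2$ancestral), 8L)
  # degenerate and inconsistent variants are rejected
  expect_error(variant_spec(10, "G", "G"), "equals ref")
  expect_error(build_allele_probes(ref, variant_spec(10, "G", "A")),
               "does not match")
})

test_that("read counting classifies by exact probe match on either strand", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(876, "A", "G")
  probe <- build_allele_probes(ref, v)
  # zero reads
  z <- count_reads(character(0), probe)
  expect_identical(z$n_total, 0L)
  expect_identical(z$n_ancestral + z$n_derived + z$n_ambiguous + z$n_unmatched, 0L)
  # a read that is the reverse complement of the derived template is derived
  der_tmpl <- paste0(substr(ref, 1, 875), "G", substr(ref, 877, nchar(ref)))
  window <- substr(der_tmpl, 850, 900)
  rc_read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(window)))
  rc <- count_reads(rc_read, probe)
  expect_identical(rc$n_derived, 1L)
  # a read not overlapping the probe span is unmatched
  expect_identical(count_reads(substr(ref, 1, 60), probe)$n_unmatched, 1L)
})

test_that("reverse-complementing every read leaves the counts unchanged", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(317, "A", "G")
  reads <- emit_amplicon_reads(ref, v, 0.5, depth = 500, error_rate = 0.01,
                               seed = 4)
  probe <- build_allele_probes(ref, v)
  fwd <- count_reads(reads, probe)
  rev <- count_reads(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$seq))), probe)
  expect_identical(fwd, rev)
})

test_that("substitution probes cannot be ambiguous on error-free reads", {
  ref <- synthetic_k1_orf()
  for (v in list(variant_spec(317, "A", "G"), variant_spec(757, "G", "A"))) {
    reads <- emit_amplicon_reads(ref, v, 0.5, depth = 400, error_rate = 0,
                                 seed = 9)
    expect_identical(count_reads(reads, build_allele_probes(ref, v))$n_ambiguous, 0L)
  }
})

test_that("variant frequency and its Wilson interval match the closed form", {
  counts <- structure(list(n_ancestral = 700L, n_derived = 300L,
                           n_ambiguous = 5L, n_unmatched = 10L,
                           n_total = 1015L), class = "read_count_result")
  est <- variant_frequency(counts)
  expect_equal(est$f, 0.3)
  expect_identical(est$n_informative, 1000L)
  z <- qnorm(0.975); n <- 1000; p <- 0.3
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(est$ci_low, centre - half, tolerance = 1e-12)
  expect_equal(est$ci_high, centre + half, tolerance = 1e-12)
  # all-ancestral counts give zero frequency; no informative reads error
  zero <- structure(list(n_ancestral = 100L, n_derived = 0L, n_ambiguous = 0L,
                         n_unmatched = 0L, n_total = 100L),
                    class = "read_count_result")
  expect_equal(variant_frequency(zero)$f, 0)
  none <- structure(list(n_ancestral = 0L, n_derived = 0L, n_ambiguous = 3L,
                         n_unmatched = 7L, n_total = 10L),
                    class = "read_count_result")
  expect_error(variant_frequency(none), "no informative")
})

test_that("read-count estimates track the true frequency across its range", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(757, "G", "A")
  probe <- build_allele_probes(ref, v)
  for (f in c(0.1, 0.5, 0.9)) {
    reads <- emit_amplicon_reads(ref, v, f, depth = 5000, error_rate = 0.001,
                                 seed = round(100 * f))
    est <- variant_frequency(count_reads(reads, probe))
    expect_lt(abs(est$f - f), 0.02)
  }
})

test_that("Sanger peak-height frequencies are simple ratios", {
  expect_equal(sanger_peak_frequency(500, 500)$f, 0.5)
  expect_equal(sanger_peak_frequency(750, 250)$f, 0.75)
  expect_identical(sanger_peak_frequency(750, 250)$method, "sanger_peak")
  expect_error(sanger_peak_frequency(0, 0), "both peak heights")
})

test_that("co-simulated Sanger and read-count estimates agree closely", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(317, "A", "G")
  truth <- 0.6
  reads <- emit_amplicon_reads(ref, v, truth, depth = 4000, error_rate = 0.002,
                               seed = 14)
  f_reads <- variant_frequency(count_reads(reads, build_allele_probes(ref, v)))$f
  # peak heights proportional to template amounts with mild noise
  set.seed(15)
  f_sanger <- sanger_peak_frequency(rpois(1, 10000 * truth),
                                    rpois(1, 10000 * (1 - truth)))$f
  expect_lt(abs(f_reads - f_sanger), 0.05)
})

test_that("trajectory classification follows the rule order", {
  expect_identical(trajectory_classify(c(0.1, 0.4, 0.8, 0.99)), "fixed")
  expect_identical(trajectory_classify(c(0.4, 0.8, 0.1)), "transient")
  expect_identical(trajectory_classify(c(0, 0, 0)), "lost")
  expect_identical(trajectory_classify(c(0.5, 0.45, 0.55)), "segregating")
  # frequency_estimate lists are accepted
  ests <- list(sanger_peak_frequency(1, 9), sanger_peak_frequency(0, 1))
  expect_identical(trajectory_classify(ests), "lost")
  expect_error(trajectory_classify(0.5), "at least 2")
})

test_that("variant strings parse to 1-based specs", {
  v <- parse_variant("875:A>G")
  expect_identical(v$pos, 875L)
  expect_identical(v$kind, "snv")
  expect_identical(parse_variant("10:AC>A")$kind, "deletion")
  expect_error(parse_variant("banana"), "cannot parse")
})
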