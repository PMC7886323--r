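test_that("neutral deterministic competition keeps the frequency constant", {
  cfg <- sim_config(toxin = toxin_model(0))
  a <- host_genotype("A", nuclear_fitness_s = 0.02)
  b <- host_genotype("B", nuclear_fitness_s = 0.02)
  tc <- simulate_competition(cfg, a, b, start_freq_a = 0.37, deterministic = TRUE)
  expect_equal(tc$count_a / tc$sample_size, rep(0.37, 6), tolerance = 1e-12)
})

test_that("a 0.05 fitness gap moves the log ratio by exactly 0.5 per 10 generations", {
  cfg <- sim_config(toxin = toxin_model(0))
  a <- host_genotype("A", nuclear_fitness_s = 0.05)
  b <- host_genotype("B", nuclear_fitness_s = 0)
  tc <- simulate_competition(cfg, a, b, start_freq_a = 0.5, deterministic = TRUE)
  lr <- log(tc$count_a / tc$count_b)
  expect_equal(diff(lr), rep(0.5, 5), tolerance = 1e-10)
})

test_that("toxin production lets a killer beat a fitter sensitive clone only at high killer frequency", {
  cfg <- sim_config(toxin = toxin_model(0.2))
  killer <- clone_killer("K", s = 0)
  sensitive <- clone_sensitive("S", s = 0.043)
  # sensitive starting high (killer rare): sensitive wins
  hi <- log_ratio_slope(simulate_competition(cfg, sensitive, killer, 0.9,
                                             deterministic = TRUE))
  # sensitive starting low (killer common): sensitive loses
  lo <- log_ratio_slope(simulate_competition(cfg, sensitive, killer, 0.1,
                                             deterministic = TRUE))
  expect_gt(hi$s_hat, 0)
  expect_lt(lo$s_hat, 0)
})

test_that("competition rejects invalid inputs", {
  cfg <- sim_config(toxin = toxin_model(0))
  a <- host_genotype("A"); b <- host_genotype("B")
  expect_error(simulate_competition(cfg, a, b, 0), "strictly in")
  expect_error(simulate_competition(cfg, a, b, 1), "strictly in")
  expect_error(simulate_competition(cfg, a, b, 0.5, n_generations = 50,
                                    sampling_interval = 7), "divide")
  # unsaturated kill probability above 1 is an error
  cfg2 <- sim_config(toxin = toxin_model(1.5, saturating = FALSE))
  expect_error(
    simulate_competition(cfg2, clone_sensitive("S"), clone_killer("K"), 0.1,
                         deterministic = TRUE),
    "exceeds 1")
})

test_that("neutral genotype frequencies are a martingale over replicate seeds", {
  cfg <- sim_config(toxin = toxin_model(0), seed = 42)
  a <- host_genotype("A"); b <- host_genotype("B")
  finals <- vapply(1:200, function(i) {
    tc <- simulate_competition(cfg, a, b, 0.3, n_generations = 20,
                               sampling_interval = 20, stream = i)
    tc$count_a[2] / tc$sample_size[2]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.3), 3 * se + 1e-4)
})

test_that("identical config and seed give bit-identical simulator output", {
  cfg <- sim_config(toxin = toxin_model(0.2), seed = 99)
  run <- function() simulate_competition(cfg, clone_sensitive("S", s = 0.05),
                                         clone_killer("K"), 0.4, stream = 3)
  expect_identical(run(), run())
  pe1 <- simulate_population_evolution(cfg, 2, n_generations = 50,
                                       record_generations = c(0, 50))
  pe2 <- simulate_population_evolution(cfg, 2, n_generations = 50,
                                       record_generations = c(0, 50))
  expect_identical(pe1, pe2)
})

test_that("without mutation or standing variants every population stays K+I+", {
  cfg <- sim_config(toxin = toxin_model(0.2), viral_mutation_rate = 0, seed = 7)
  pe <- simulate_population_evolution(cfg, 5, n_generations = 100,
                                      record_generations = seq(0, 100, 50))
  expect_true(all(pe$phenotypes$killing == "full"))
  expect_true(all(pe$phenotypes$immunity == "full"))
  expect_true(all(pe$trajectories$variant_id == "WT"))
})

test_that("killing-loss fraction by a fixed generation is non-decreasing in the viral mutation rate", {
  loss_frac <- vapply(c(1e-6, 1e-4), function(m) {
    cfg <- sim_config(toxin = toxin_model(0.2), viral_mutation_rate = m,
                      seed = 11)
    pe <- simulate_population_evolution(cfg, 20, n_generations = 300,
                                        record_generations = c(0, 300))
    tr <- phenotype_trajectory(pe$phenotypes)
    1 - tr$killing_retained[tr$generation == 300]
  }, numeric(1))
  expect_true(loss_frac[2] >= loss_frac[1])
})

test_that("population simulator output never violates the phenotype transition rules", {
  cfg <- sim_config(toxin = toxin_model(0.2), viral_mutation_rate = 1e-4,
                    seed = 13)
  pe <- simulate_population_evolution(cfg, 20, n_generations = 300,
                                      record_generations = seq(0, 300, 50))
  expect_identical(nrow(transition_audit(pe$phenotypes)), 0L)
})

test_that("deterministic infinite-copy heteroplasmy is frozen without selection", {
  cfg <- sim_config(toxin = toxin_model(0))
  v <- viral_variant("neutral", toxin_functional = FALSE)
  tr <- simulate_heteroplasmic_lines(cfg, v, 0.31, n_lines = 2,
                                     n_bottlenecks = 5, deterministic = TRUE)
  expect_equal(tr$frequency, rep(0.31, 12), tolerance = 1e-12)
})

test_that("neutral within-cell drift conserves the expected variant frequency", {
  cfg <- sim_config(toxin = toxin_model(0), seed = 5)
  v <- viral_variant("neutral", toxin_functional = FALSE)
  tr <- simulate_heteroplasmic_lines(cfg, v, 0.3, n_lines = 150,
                                     n_bottlenecks = 10)
  fin <- tr$frequency[tr$bottleneck == 10]
  se <- stats::sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 0.3), 3 * se)
})

test_that("an advantaged toxin-null variant sweeps all heteroplasmic lines", {
  # three lines, seven single-cell bottlenecks, variant at ~0.5 with a
  # within-cell replication advantage: killing ability is lost from all lines
  cfg <- sim_config(toxin = toxin_model(0), seed = 21)
  for (v in list(
    viral_variant("I292M", toxin_functional = FALSE, immunity_functional = TRUE,
                  within_cell_advantage = 0.1),
    viral_variant("fs-1", toxin_functional = FALSE, immunity_functional = FALSE,
                  within_cell_advantage = 0.1))) {
    tr <- simulate_heteroplasmic_lines(cfg, v, 0.5, n_lines = 3, n_bottlenecks = 7)
    expect_true(all(tr$killing[tr$bottleneck == 7] == "none"), info = v$id)
  }
})

test_that("amplicon reads at frequency 1 all carry the derived allele", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(317, "A", "G")
  reads <- emit_amplicon_reads(ref, v, true_freq = 1, depth = 200,
                               error_rate = 0, seed = 2)
  rc <- count_reads(reads, build_allele_probes(ref, v))
  expect_identical(rc$n_derived, 200L)
  expect_identical(rc$n_ancestral + rc$n_ambiguous + rc$n_unmatched, 0L)
})

test_that("error-free derived-read fraction matches the template mixture binomially", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(317, "A", "G")
  depth <- 10000
  reads <- emit_amplicon_reads(ref, v, true_freq = 0.3, depth = depth,
                               error_rate = 0, seed = 8)
  rc <- count_reads(reads, build_allele_probes(ref, v))
  expect_identical(rc$n_unmatched + rc$n_ambiguous, 0L)
  f <- rc$n_derived / depth
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / depth))
})

test_that("reads shorter than the probe span are rejected", {
  expect_error(emit_amplicon_reads(synthetic_k1_orf(),
                                   variant_spec(317, "A", "G"),
                                   0.5, 10, read_length = 10),
               "11-nt probe")
})

test_that("the generator and counter round-trip through FASTQ", {
  ref <- synthetic_k1_orf()
  v <- variant_spec(757, "G", "A")
  reads <- emit_amplicon_reads(ref, v, true_freq = 0.4, depth = 3000,
                               error_rate = 0.002, seed = 17)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$seq, reads$seq)
  est <- variant_frequency(count_reads(back, build_allele_probes(ref, v)))
  expect_true(est$ci_low <= 0.4 && 0.4 <= est$ci_high)
})
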