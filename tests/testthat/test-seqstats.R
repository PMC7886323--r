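test_that("variant effects follow the codon table on a toy ORF", {
  orf <- orf_annotation("ATGAAATAA")
  # third-position change preserving lysine
  expect_identical(classify_variant(orf, variant_spec(6, "A", "G"))$effect,
                   "synonymous")
  # AAA -> GAA: K2E missense
  mis <- classify_variant(orf, variant_spec(4, "A", "G"))
  expect_identical(mis$effect, "missense")
  expect_identical(mis$protein_change, "K2E")
  # AAA -> TAA: premature stop
  expect_identical(classify_variant(orf, variant_spec(4, "A", "T"))$effect,
                   "nonsense")
  # single-base deletion shifts the frame; 3-base deletion does not
  expect_identical(classify_variant(orf, variant_spec(4, "AA", "A"))$effect,
                   "frameshift")
  expect_identical(classify_variant(orf, variant_spec(4, "AAAT", "A"))$effect,
                   "inframe_indel")
  expect_error(classify_variant(orf, variant_spec(4, "C", "G")),
               "does not match")
  expect_error(orf_annotation("ATGAA"), "divisible by 3")
  expect_error(orf_annotation("AAAGGGTTT"), "start with ATG")
})

test_that("recurrent ancestral polymorphisms annotate onto the synthetic K1 ORF", {
  orf <- orf_annotation(synthetic_k1_orf(), subunits = k1_subunits())
  tb <- ancestral_snp_table()
  changes <- vapply(seq_len(nrow(tb)), function(i)
    classify_variant(orf, variant_spec(tb$pos[i], tb$ref[i], tb$alt[i]))$protein_change,
    character(1))
  expect_identical(changes, c("D106G", "D253N", "I292M"))
  subs <- vapply(seq_len(nrow(tb)), function(i)
    classify_variant(orf, variant_spec(tb$pos[i], tb$ref[i], tb$alt[i]))$subunit,
    character(1))
  expect_identical(subs, c("alpha", "beta", "beta"))
})

test_that("effect classification agrees with whole-protein translation", {
  set.seed(2024)
  for (rep in 1:200) {
    orf_seq <- random_orf(sample(4:20, 1))
    orf <- orf_annotation(orf_seq)
    v <- random_snv(orf_seq)
    expect_identical(classify_variant(orf, v)$effect,
                     translate_effect_oracle(orf_seq, v),
                     info = sprintf("%s %d%s>%s", orf_seq, v$pos, v$ref, v$alt))
  }
})

test_that("transition:transversion statistics follow the 1:2 null", {
  # all transitions: ratio undefined
  all_ts <- data.frame(ref = rep("A", 10), alt = rep("G", 10))
  st <- ts_tv_stats(all_ts)
  expect_identical(st$ts_count, 10)
  expect_identical(st$tv_count, 0)
  expect_true(is.na(st$R))
  # exactly the null proportions: chi-squared 0
  null3 <- data.frame(ref = c("A", "A", "A"), alt = c("G", "C", "T"))
  expect_equal(ts_tv_stats(null3)$chisq, 0, tolerance = 1e-12)
  # 32 transitions vs 5 transversions: R = 6.4; hand-computed chi-squared
  sp <- data.frame(ref = c(rep("C", 32), rep("C", 5)),
                   alt = c(rep("T", 32), rep("G", 5)))
  st2 <- ts_tv_stats(sp)
  expect_equal(st2$R, 6.4)
  E <- c(37 / 3, 74 / 3)
  expect_equal(st2$chisq, sum((c(32, 5) - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(st2$chisq, 1), 47.0)
  # recurrence counts weight the spectrum
  wt <- data.frame(ref = c("A", "A"), alt = c("G", "C"), n = c(12, 3))
  expect_equal(ts_tv_stats(wt)$R, 4)
})

test_that("NG86 site counting matches the hand-computed toy table", {
  orf <- orf_annotation("ATGTTTAAA")
  # ATG: 0 synonymous sites; TTT and AAA: 1/3 each (third position)
  res <- dnds(orf, list(variant_spec(9, "A", "G"),   # AAA->AAG synonymous
                        variant_spec(4, "T", "A"))) # TTT->ATT missense
  expect_equal(res$S_sites, 2 / 3, tolerance = 1e-12)
  expect_equal(res$N_sites, 9 - 2 / 3, tolerance = 1e-12)
  expect_equal(res$S_diff, 1)
  expect_equal(res$N_diff, 1)
  expect_equal(res$ratio, (1 / (9 - 2 / 3)) / (1 / (2 / 3)), tolerance = 1e-12)
  # no synonymous differences: ratio undefined with an explanation
  res2 <- dnds(orf, list(variant_spec(4, "T", "A")))
  expect_true(is.na(res2$ratio))
  expect_match(res2$note, "undefined")
  # empty variant set
  res3 <- dnds(orf, list())
  expect_identical(res3$N_diff + res3$S_diff, 0)
  expect_true(is.na(res3$ratio))
})

test_that("NG86 sites partition the sequence length and synonymous sets give zero N_diff", {
  set.seed(31)
  for (rep in 1:50) {
    orf_seq <- random_orf(sample(3:15, 1))
    orf <- orf_annotation(orf_seq)
    res <- dnds(orf, list())
    expect_equal(res$N_sites + res$S_sites, nchar(orf_seq), tolerance = 1e-9)
  }
  # an all-synonymous variant set on the toy ORF
  orf <- orf_annotation("ATGTTTAAA")
  res <- dnds(orf, list(variant_spec(6, "T", "C"), variant_spec(9, "A", "G")))
  expect_equal(res$N_diff, 0)
})

test_that("deterministic sweep times match the logistic closed form", {
  # hexose-transporter-scale advantage in a chemostat-sized population
  t1 <- sweep_time(0.30, 4e9)
  # with f0 = 1/N and f_end = 1 - 1/N the closed form reduces to (2/s) ln(N-1)
  expect_equal(t1, (2 / 0.3) * log(4e9 - 1), tolerance = 1e-6)
  expect_equal(round(t1 / 10) * 10, 150)
  expect_equal(t1, 147.4, tolerance = 0.05)
  # doubling s halves the time exactly
  expect_equal(sweep_time(0.6, 4e9), t1 / 2, tolerance = 1e-12)
  # (2/s) ln N approximation
  expect_equal(sweep_time(0.1, 1e6), 276.3, tolerance = 0.05)
  expect_error(sweep_time(-0.1, 1e6), "> 0")
  expect_error(sweep_time(0.1, 1e6, f0 = 0.9, f_end = 0.1), "bounds")
})

test_that("sweep time decreases in s and increases in N", {
  s_grid <- c(0.05, 0.1, 0.2, 0.4)
  expect_true(all(diff(vapply(s_grid, sweep_time, numeric(1), N = 1e7)) < 0))
  N_grid <- c(1e4, 1e6, 1e8, 1e10)
  expect_true(all(diff(vapply(N_grid, function(N) sweep_time(0.1, N),
                              numeric(1))) > 0))
})
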