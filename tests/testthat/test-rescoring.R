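test_that("q-values follow the decoy/target estimate with cumulative min", {
  # ranked list T,T,D,T: FDR by rank = 0, 0, 1/2, 1/3; q from the bottom
  q <- q_values(c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(q, c(0, 0, 1 / 3, 1 / 3))
  expect_equal(q_values(rep(FALSE, 5)), rep(0, 5))
  # alternating T,D,...: bottom q approaches 1
  q2 <- q_values(rep(c(FALSE, TRUE), 10))
  expect_equal(q2[20], 1)
  expect_true(all(diff(q2) >= -1e-12))  # monotone down the list
  # decoys before the first target: FDR defined as 0 until a target shows,
  # then capped at 1
  expect_equal(q_values(c(TRUE, FALSE)), c(0, 1))
  expect_equal(q_values(c(TRUE, TRUE, FALSE)), c(0, 0, 1))
})

test_that("q-value vectors are monotone for random label sequences", {
  set.seed(41)
  for (rep in 1:50) {
    lab <- runif(sample(5:60, 1)) < 0.4
    expect_true(all(diff(q_values(lab)) >= -1e-12))
  }
})

test_that("feature assembly is deterministic and passes DL scores through", {
  sim <- cached_sim(n_psms = 40)
  locs <- localize_all(sim$psms, sim$spectra, sim$predictions)
  ft <- assemble_feature_table(locs, sim$psms, sim$spectra)
  ft2 <- assemble_feature_table(locs, sim$psms, sim$spectra)
  expect_identical(ft, ft2)
  for (i in c(1, 17)) {
    summ <- localization_summary(locs[[i]])
    expect_equal(ft$ss[i], summ$ss)
    expect_equal(ft$rtr[i], summ$rtr)
  }
  z <- vapply(sim$psms, function(p) p$charge, integer(1))
  expect_equal(ft$charge2, as.numeric(z == 2))
  expect_equal(ft$charge3, as.numeric(z == 3))
  expect_equal(ft$peptide_length,
               nchar(vapply(sim$psms, function(p) p$peptide, "")))
  expect_true(all(is.finite(ft$mass_error_ppm)))
  expect_true(all(abs(ft$mass_error_ppm) < 20))
})

test_that("missed cleavages count internal K/R not followed by P", {
  expect_equal(missed_cleavages("SASTK"), 0L)
  expect_equal(missed_cleavages("SAKTR"), 1L)
  expect_equal(missed_cleavages("SAKPTK"), 0L)  # KP is not cleaved
  expect_equal(missed_cleavages("KRKAK"), 3L)
})

test_that("a perfectly separating feature ranks all true targets above
           decoys after rescoring", {
  set.seed(42)
  n <- 120
  is_decoy <- rep(c(FALSE, TRUE), n / 2)
  ft <- data.frame(
    spectrum_id = sprintf("s%03d", seq_len(n)),
    peptide = sprintf("PEPTIDE%03dK", seq_len(n)),
    positions = "1", modified_sequence = sprintf("x%03d", seq_len(n)),
    is_decoy = is_decoy, proteins = "P", observed_rt = 30,
    min_site_probability = 1, matched_ions = "",
    engine_score = rnorm(n, 10, 4),        # uninformative engine score
    delta_score = rnorm(n), peptide_length = 10,
    mass_error_ppm = rnorm(n), charge2 = 1, charge3 = 0, charge4plus = 0,
    missed_cleavages = 0, frac_matched = ifelse(is_decoy, 0.1, 0.9),
    log_matched_intensity = rnorm(n), ss = 0.5, rtr = 0.9)
  out <- semi_supervised_rescore(ft, seed = 7)
  ranked <- out$is_decoy
  expect_true(all(which(!ranked) < min(which(ranked))))
  expect_equal(sum(out$q_value <= 0.01 & !out$is_decoy), n / 2)
})

test_that("rescoring is deterministic under a fixed seed", {
  sim <- cached_sim(n_psms = 80, seed = 404)
  locs <- localize_all(sim$psms, sim$spectra, sim$predictions)
  ft <- assemble_feature_table(locs, sim$psms, sim$spectra)
  r1 <- semi_supervised_rescore(ft, seed = 99)
  r2 <- semi_supervised_rescore(ft, seed = 99)
  expect_identical(r1$discriminant, r2$discriminant)
  r3 <- semi_supervised_rescore(ft, seed = 100)
  expect_false(identical(r1$discriminant, r3$discriminant))
})

test_that("rescoring refuses degenerate target/decoy sets", {
  sim <- cached_sim(n_psms = 40)
  locs <- localize_all(sim$psms, sim$spectra, sim$predictions)
  ft <- assemble_feature_table(locs, sim$psms, sim$spectra)
  expect_error(semi_supervised_rescore(ft[!ft$is_decoy, ]), "no decoys")
  expect_error(semi_supervised_rescore(ft, folds = 1), "folds")
})

test_that("pure-noise features do not inflate the 1% FDR count over the
           engine-score baseline", {
  set.seed(43)
  counts <- replicate(20, {
    n <- 200
    is_decoy <- rep(c(FALSE, TRUE), n / 2)
    escore <- ifelse(is_decoy, rnorm(n, 8, 3), rnorm(n, 14, 3))
    ft <- data.frame(
      spectrum_id = sprintf("s%03d", seq_len(n)),
      peptide = sprintf("P%03dK", seq_len(n)), positions = "1",
      modified_sequence = sprintf("x%03d", seq_len(n)),
      is_decoy = is_decoy, proteins = "P", observed_rt = 30,
      min_site_probability = 1, matched_ions = "",
      engine_score = escore, delta_score = rnorm(n), peptide_length = 10,
      mass_error_ppm = rnorm(n), charge2 = 1, charge3 = 0,
      charge4plus = 0, missed_cleavages = 0, frac_matched = runif(n),
      log_matched_intensity = rnorm(n), ss = runif(n), rtr = runif(n))
    base_q <- phosloc:::add_q_values(ft, "engine_score")
    out <- semi_supervised_rescore(ft, seed = sample.int(1e6, 1))
    c(base = sum(base_q$q_value <= 0.01 & !base_q$is_decoy),
      resc = sum(out$q_value <= 0.01 & !out$is_decoy))
  })
  # features beyond the engine score are noise here: the SVM may tidy up
  # the ranking but must not systematically fabricate identifications
  expect_lte(mean(counts["resc", ]), mean(counts["base", ]) * 1.25 + 5)
})

test_that("confident filtering applies all three thresholds", {
  tab <- data.frame(
    spectrum_id = c("a", "b", "c", "d", "e"),
    modified_sequence = c("m1", "m1", "m2", "m3", "m4"),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    discriminant = c(9, 3, 8, 7, -2),
    q_value = c(0.004, 0.02, 0.005, 0.005, 0.8),
    min_site_probability = c(0.9, 0.9, 0.6, 0.9, 0.9))
  out <- filter_confident(tab)
  # peptide q comes from the best PSM per modified sequence
  expect_equal(out$peptide_q_value[out$spectrum_id == "b"],
               out$peptide_q_value[out$spectrum_id == "a"])
  expect_true(out$passes[out$spectrum_id == "a"])
  expect_false(out$passes[out$spectrum_id == "b"])   # PSM q too high
  expect_false(out$passes[out$spectrum_id == "c"])   # site prob 0.6
  expect_true(out$passes[out$spectrum_id == "d"])
  expect_false(out$passes[out$spectrum_id == "e"])   # decoy
})

test_that("fine-tuning split is exact, seeded, and guarded", {
  conf <- data.frame(modified_sequence = sprintf("m%04d", 1:2500),
                     observed_rt = runif(2500, 10, 100),
                     charge3 = 0, charge4plus = 0,
                     matched_ions = "b2_z1:10.0")
  sp <- split_finetune_sets(conf, test_n = 500, seed = 5)
  expect_equal(nrow(sp$test), 500)
  expect_equal(nrow(sp$train), 2000)
  expect_length(intersect(sp$test$modified_sequence,
                          sp$train$modified_sequence), 0)
  sp2 <- split_finetune_sets(conf, test_n = 500, seed = 5)
  expect_identical(sp$test$modified_sequence, sp2$test$modified_sequence)
  expect_error(split_finetune_sets(conf[1:400, ], test_n = 500),
               "too few")
  dir <- tempfile()
  paths <- write_finetune_tsvs(sp, dir)
  expect_true(all(file.exists(file.path(
    dir, c("rt_train.tsv", "rt_test.tsv", "ions_train.tsv",
           "ions_test.tsv")))))
  rt_train <- read.delim(file.path(dir, "rt_train.tsv"))
  expect_equal(names(rt_train), c("sequence", "rt"))
  expect_equal(nrow(rt_train), 2000)
})
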