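test_that("the same seed yields a bit-identical bundle", {
  tr <- toy_truth(noise = 8)
  cfg <- generator_config(n_runs = 2, cage_replicates = 3,
                          chamber_replicates = 3)
  s1 <- simulate_study(tr, cfg, seed = 42)
  s2 <- simulate_study(tr, cfg, seed = 42)
  expect_identical(s1$bundle, s2$bundle)
  s3 <- simulate_study(tr, cfg, seed = 43)
  expect_false(identical(s1$bundle$cages, s3$bundle$cages))
})

test_that("run substreams are independent of the number of other runs", {
  tr <- toy_truth(noise = 8)
  one <- simulate_study(tr, generator_config(n_runs = 1, cage_replicates = 2,
                                             chamber_replicates = 2), seed = 5)
  two <- simulate_study(tr, generator_config(n_runs = 2, cage_replicates = 2,
                                             chamber_replicates = 2), seed = 5)
  # run 1 draws the same reference-diet records either way
  ref1 <- one$bundle$cages[one$bundle$cages$diet_id == "ref" &
                             one$bundle$cages$run_id == "run_01", ]
  ref2 <- two$bundle$cages[two$bundle$cages$diet_id == "ref" &
                             two$bundle$cages$run_id == "run_01", ]
  expect_equal(ref1$feed_intake_dm, ref2$feed_intake_dm)
})

test_that("the truth set validates its domain", {
  expect_error(truth_set(data.frame(ingredient_id = "x", ame = 10,
                                    amen = 9.8, ne = 11)),
               class = "bne_validation_error")   # NE above AME
  expect_error(truth_set(toy_truth()$ingredients,
                         noise_cvs = c(bogus = 5)),
               class = "bne_validation_error")
  tr <- truth_set(toy_truth()$ingredients, noise_cvs = c(fi = 0))
  expect_equal(unname(tr$noise_cvs["fi"]), 0)
  expect_equal(unname(tr$noise_cvs["thp"]), 8)   # untouched default
})

test_that("the packaged-trial truth carries the measured panel", {
  tr <- study_truth("wheat")
  expect_equal(tr$ingredients$ne[1], 9.34)
  expect_equal(tr$ingredients$ame[tr$ingredients$ingredient_id == "wheat_4"],
               13.75)
  expect_equal(tr$scheme$a_pct, 67.58)
  expect_equal(tr$scheme$b_pct, 31.32)
  expect_equal(tr$ref_ame, 13.29)
  bran <- study_truth("wheat_bran")
  expect_equal(bran$ingredients$ame[1], 7.72)
})

test_that("noise-free simulation is a fixed point of the analysis", {
  tr <- study_truth("wheat")
  tr$noise_cvs[] <- 0
  sim <- simulate_study(tr, generator_config(n_runs = 5, cage_replicates = 2,
                                             chamber_replicates = 2), seed = 1)
  an <- analyze_trial(sim$bundle, scheme = tr$scheme)
  got <- an$ingredient_energy
  got <- got[match(paste0(tr$ingredients$ingredient_id),
                   got$ingredient_id), ]
  expect_equal(got$ame, tr$ingredients$ame, tolerance = 1e-9)
  expect_equal(got$amen, tr$ingredients$amen, tolerance = 1e-9)
  expect_equal(got$ne, tr$ingredients$ne, tolerance = 1e-9)
  # performance follows the linear growth model: FCR equals the configured one
  perf <- performance(sim$bundle$cages)
  expect_equal(perf$fcr, rep(1.5, nrow(perf)), tolerance = 1e-9)
})

test_that("simulated gas volumes hit the target RQ and temper with CV", {
  tr <- toy_truth(noise = 0)
  tr$noise_cvs["rq"] <- 4
  sim <- simulate_study(tr, generator_config(n_runs = 2, cage_replicates = 2,
                                             chamber_replicates = 40), seed = 8)
  rq <- respiratory_quotient(sim$bundle$chambers$o2_consumed,
                             sim$bundle$chambers$co2_produced)
  expect_equal(mean(rq), tr$rq_true, tolerance = 0.02)  # mean-preserving noise
  tr$noise_cvs["rq"] <- 0
  sim0 <- simulate_study(tr, generator_config(n_runs = 1, cage_replicates = 2,
                                              chamber_replicates = 5), seed = 8)
  rq0 <- respiratory_quotient(sim0$bundle$chambers$o2_consumed,
                              sim0$bundle$chambers$co2_produced)
  expect_equal(rq0, rep(tr$rq_true, 15), tolerance = 1e-12)
})

test_that("raising a noise CV raises the Monte-Carlo spread of the estimate", {
  tr_lo <- toy_truth(noise = 0); tr_lo$noise_cvs["thp"] <- 3
  tr_hi <- toy_truth(noise = 0); tr_hi$noise_cvs["thp"] <- 12
  cfg <- generator_config(n_runs = 1, cage_replicates = 2,
                          chamber_replicates = 3)
  one_ne <- function(tr, s) {
    tr$ingredients <- tr$ingredients[1, , drop = FALSE]
    an <- analyze_trial(simulate_study(tr, cfg, seed = s)$bundle,
                        scheme = tr$scheme)
    an$ingredient_energy$ne
  }
  lo <- vapply(1:40, function(s) one_ne(tr_lo, s), numeric(1))
  hi <- vapply(1:40, function(s) one_ne(tr_hi, s), numeric(1))
  expect_gt(sd(hi), sd(lo))
})
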