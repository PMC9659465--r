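test_that("metabolic weight follows the allometric definition", {
  expect_equal(metabolic_weight(1000), 1.0)
  expect_equal(metabolic_weight(414.34), 0.5397, tolerance = 1e-4)
  expect_error(metabolic_weight(0), class = "bne_domain_error")
  expect_error(metabolic_weight(-5), class = "bne_domain_error")
  # exponent is configurable
  expect_equal(metabolic_weight(500, energy_constants(mbw_exponent = 0.75)),
               0.5^0.75)
})

test_that("performance metrics follow their definitions", {
  obs <- make_cage(bw_initial = 300, bw_final = 420, days = 3, n_birds = 4,
                   feed_intake_dm = 720)
  p <- performance(obs)
  expect_equal(p$abw, 360)
  expect_equal(p$adg, 40)
  expect_equal(p$fi, 60)
  expect_equal(p$fcr, 1.5)
  # zero gain: FCR absent with a warning, no division by zero
  flat <- make_cage(bw_initial = 300, bw_final = 300)
  expect_warning(pf <- performance(flat), class = "bne_degenerate_warning")
  expect_true(is.na(pf$fcr))
})

test_that("heat production from gas exchange is the linear Brouwer-type form", {
  expect_equal(thp_from_gas(0, 0), 0)
  expect_equal(thp_from_gas(1, 1), 21.1961)
  expect_equal(thp_from_gas(100, 99), 2114.5892)
  expect_error(thp_from_gas(-1, 0), class = "bne_domain_error")
  # linear and monotone in both arguments
  set.seed(1)
  o2 <- runif(20, 0, 500); co2 <- runif(20, 0, 500)
  expect_equal(thp_from_gas(2 * o2, 2 * co2), 2 * thp_from_gas(o2, co2))
  expect_true(all(thp_from_gas(o2 + 1, co2) > thp_from_gas(o2, co2)))
  expect_true(all(thp_from_gas(o2, co2 + 1) > thp_from_gas(o2, co2)))
})

test_that("respiratory quotient is CO2/O2 with a guarded domain", {
  expect_equal(respiratory_quotient(50, 50), 1.0)
  expect_equal(respiratory_quotient(100, 98), 0.98)
  expect_error(respiratory_quotient(0, 10), class = "bne_domain_error")
})

test_that("diet AME and the nitrogen correction behave at the boundaries", {
  assay <- data.frame(diet_id = "d1", ge = 19.5)
  # zero excreta: AME equals diet GE, AMEn subtracts the full feed N
  obs <- make_cage(excreta_dm = 0, feed_n = 32)
  res <- diet_ame(obs, assay)
  expect_equal(res$ame, 19.5)
  expect_equal(res$amen, 19.5 - 34.39 * 32 / 1000)
  # zero retention: AMEn equals AME
  obs2 <- make_cage(excreta_dm = 360, feed_n = 32, excreta_n = 64)
  res2 <- diet_ame(obs2, assay)
  expect_equal(res2$tnr_per_kg_feed, 0)
  expect_equal(res2$amen, res2$ame)
  # excreta energy above intake energy: warned and flagged, not clipped
  obs3 <- make_cage(excreta_dm = 720, excreta_ge = 25)
  expect_warning(res3 <- diet_ame(obs3, assay), class = "bne_flagged_warning")
  expect_true(res3$ame < 0)
  expect_true(res3$flag_negative_ame)
})

test_that("AMEn never exceeds AME when N retention is non-negative", {
  set.seed(42)
  assay <- data.frame(diet_id = "d1", ge = 19.5)
  for (i in 1:25) {
    obs <- make_cage(excreta_dm = runif(1, 50, 400),
                     excreta_ge = runif(1, 10, 18),
                     feed_n = runif(1, 25, 40),
                     excreta_n = runif(1, 10, 60))
    res <- diet_ame(obs, assay)
    if (res$tnr_per_kg_feed >= 0) {
      expect_true(res$amen <= res$ame)
    } else {
      expect_true(res$amen > res$ame)
    }
  }
})

test_that("energy balance satisfies the conservation identities", {
  set.seed(7)
  for (i in 1:10) {
    ch <- make_chamber(o2 = runif(1, 500, 2000), co2 = runif(1, 400, 2000),
                       feed_intake_dm = runif(1, 400, 900))
    b <- energy_balance(ch, ame = 13.0, amen = 12.8, tnr_per_kg_feed = 6.5)
    expect_equal(b$amei, b$nei + b$hi, tolerance = 1e-12)
    expect_equal(b$re, b$amei - b$thp, tolerance = 1e-12)
    expect_equal(b$re_fat, b$re - b$re_protein, tolerance = 1e-12)
    expect_identical(b$hi, b$thp - b$fhp)
  }
})

test_that("energy balance units reproduce the worked reference-diet flows", {
  # AMEI from diet AME, intake and body weight of the reference diet
  amei <- 13.29 * (56.37 / 1000) / metabolic_weight(414.34)
  expect_equal(amei, 1.388, tolerance = 1e-3)
  # HI is THP minus the 0.450 MJ/kg^0.70/d fasting heat production
  ch <- make_chamber()
  b <- energy_balance(ch, ame = 13.29)
  expect_equal(b$fhp, 0.450)
  expect_equal(b$hi, b$thp - 0.450)
  # without paired N retention the protein/fat partition is absent
  expect_true(is.na(b$re_protein))
})

test_that("negative heat increment is flagged, not clipped", {
  ch <- make_chamber(o2 = 10, co2 = 10)   # far too little heat
  expect_warning(b <- energy_balance(ch, ame = 13.0),
                 class = "bne_flagged_warning")
  expect_true(b$hi < 0)
  expect_true(b$flag_negative_hi)
})

test_that("diet net energy scales AME by the NEI/AMEI fraction", {
  expect_equal(diet_net_energy(13.29, 1.5, 1.5)$ne, 13.29)  # zero-HI limit
  got <- diet_net_energy(13.29, 1.388, 0.938)
  expect_equal(got$ne, 13.29 * 0.938 / 1.388, tolerance = 1e-12)
  expect_equal(got$ne_ame, 100 * 0.938 / 1.388, tolerance = 1e-12)
  expect_error(diet_net_energy(13.29, 0, 1), class = "bne_domain_error")
  # identity holds for any positive intake
  for (x in c(0.1, 1, 2.7)) {
    expect_equal(diet_net_energy(11.2, x, x)$ne, 11.2)
  }
})

test_that("noise-free synthetic records recover the generator's truth exactly", {
  tr <- toy_truth(noise = 0)
  sim <- simulate_study(tr, generator_config(n_runs = 2, cage_replicates = 2,
                                             chamber_replicates = 2), seed = 9)
  an <- analyze_trial(sim$bundle, scheme = tr$scheme)
  truth_diet <- sim$truth$diet_truth
  got <- an$diet_energy[match(truth_diet$diet_id, an$diet_energy$diet_id), ]
  expect_equal(got$ame, truth_diet$ame, tolerance = 1e-10)
  expect_equal(got$amen, truth_diet$amen, tolerance = 1e-10)
  expect_equal(got$ne, truth_diet$ne, tolerance = 1e-10)
  expect_equal(an$balance$rq, rep(tr$rq_true, nrow(an$balance)),
               tolerance = 1e-12)
})
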