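# Small builders used across test files.

# a minimal valid cage record
make_cage <- function(diet_id = "d1", run_id = "run_01", n_birds = 4, days = 3,
                      bw_initial = 300, bw_final = 420, feed_intake_dm = 720,
                      excreta_dm = 200, excreta_ge = 14, feed_n = 32,
                      excreta_n = 60, replicate_id = "c1") {
  data.frame(run_id = run_id, diet_id = diet_id, replicate_id = replicate_id,
             n_birds = n_birds, days = days, bw_initial = bw_initial,
             bw_final = bw_final, feed_intake_dm = feed_intake_dm,
             excreta_dm = excreta_dm, excreta_ge = excreta_ge,
             feed_n = feed_n, excreta_n = excreta_n)
}

make_chamber <- function(diet_id = "d1", run_id = "run_01", n_birds = 4,
                         days = 3, bw_initial = 300, bw_final = 420,
                         feed_intake_dm = 720, o2 = 1000, co2 = 1000,
                         chamber_id = "ch1") {
  data.frame(run_id = run_id, diet_id = diet_id, chamber_id = chamber_id,
             n_birds = n_birds, days = days, bw_initial = bw_initial,
             bw_final = bw_final, feed_intake_dm = feed_intake_dm,
             o2_consumed = o2, co2_produced = co2)
}

# a tiny noise-free truth set with two synthetic ingredients
toy_truth <- function(noise = 0) {
  tr <- truth_set(
    ingredients = data.frame(
      ingredient_id = c("ing_a", "ing_b"), kind = "other",
      ame = c(13.0, 7.0), amen = c(12.8, 6.8), ne = c(10.3, 5.0),
      cp = c(14, 18), ee = c(2, 4), cf = c(2.5, 14), ndf = c(38, 48),
      adf = c(4, 16), st = c(650, 150)),
    scheme = substitution_scheme(67.58, 31.32))
  tr$noise_cvs[] <- noise
  tr
}

# write an ingredient CSV with the standard header
write_ingredient_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "ingredient_id,kind,dm,cp,ee,cf,ndf,adf,st,ge"
  writeLines(c(header, rows), path)
  path
}
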