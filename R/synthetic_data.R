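#' Generator configuration for synthetic feeding trials
#'
#' Design parameters of the simulated trial. Defaults mirror the study
#' design the analysis assumes: runs of two diets (the reference diet plus a
#' test diet), 6 replicate cages of 8 birds for total collection and 6
#' chambers of 4 birds for calorimetry per diet and run, a 3-day balance
#' window, and starting body weights around 355 g at the start of the
#' balance period.
#'
#' @param n_runs number of runs; test ingredients are assigned to runs
#'   round-robin and every run also measures the reference diet.
#' @param cage_replicates total-collection cages per diet per run.
#' @param chamber_replicates calorimetry chambers per diet per run.
#' @param birds_per_cage,birds_per_chamber birds per replicate.
#' @param days balance-period length, days.
#' @param bw_start_mean,bw_start_sd initial body weight, g per bird.
#' @param fi_mean mean DM feed intake, g per bird per day.
#' @param fcr feed conversion ratio used for the linear growth model.
#' @param excreta_fraction excreta DM output as a fraction of DM intake.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_runs = 6, cage_replicates = 6,
                             chamber_replicates = 6, birds_per_cage = 8,
                             birds_per_chamber = 4, days = 3,
                             bw_start_mean = 355, bw_start_sd = 15,
                             fi_mean = 56, fcr = 1.5,
                             excreta_fraction = 0.30) {
  cfg <- list(n_runs = n_runs, cage_replicates = cage_replicates,
              chamber_replicates = chamber_replicates,
              birds_per_cage = birds_per_cage,
              birds_per_chamber = birds_per_chamber, days = days,
              bw_start_mean = bw_start_mean, bw_start_sd = bw_start_sd,
              fi_mean = fi_mean, fcr = fcr,
              excreta_fraction = excreta_fraction)
  counts <- c("n_runs", "cage_replicates", "chamber_replicates",
              "birds_per_cage", "birds_per_chamber", "days")
  if (!all(vapply(cfg[counts], function(x) x >= 1 && x == round(x), logical(1)))) {
    bne_stop("generator_config: counts must be positive integers",
             "bne_validation_error")
  }
  if (excreta_fraction <= 0 || excreta_fraction >= 1) {
    bne_stop("generator_config: excreta_fraction must lie in (0, 1)",
             "bne_validation_error")
  }
  structure(cfg, class = "generator_config")
}

#' Ground-truth parameter set for the generator
#'
#' True energy values and noise levels from which a synthetic trial is
#' simulated and against which the analysis pipeline can be checked.
#' Noise is multiplicative lognormal, parameterized by percent CVs per
#' observable and mean-preserving (a CV of 0 gives the exact truth).
#' Default CVs are calibrated to the across-replicate relative standard
#' deviations the trial reports (feed intake about 7 percent, diet AME
#' about 1.7 percent, heat production about 8 percent, RQ about 3.5
#' percent).
#'
#' @param ingredients data frame with columns `ingredient_id`, `kind`,
#'   `ame`, `amen`, `ne` (MJ/kg DM) and optionally composition columns.
#' @param ref_ame,ref_amen,ref_ne reference-diet true energies, MJ/kg DM.
#' @param ref_ge reference-diet gross energy, MJ/kg DM.
#' @param scheme a [substitution_scheme] for composing test diets.
#' @param rq_true true respiratory quotient.
#' @param tnr_per_kg_feed_true true N retention, g N per kg DM feed.
#' @param feed_n_per_kg feed N content, g N per kg DM.
#' @param noise_cvs named percent CVs for observables `fi`, `bw`, `ame`,
#'   `thp`, `rq`, `tnr`; omitted names keep their defaults.
#' @return an object of class `truth_set`.
#' @export
truth_set <- function(ingredients,
                      ref_ame = 13.29, ref_amen = 13.06, ref_ne = 8.20,
                      ref_ge = 19.51,
                      scheme = substitution_scheme(),
                      rq_true = 1.00,
                      tnr_per_kg_feed_true = (ref_ame - ref_amen) * 1000 / 34.39,
                      feed_n_per_kg = 32,
                      noise_cvs = NULL) {
  default_cvs <- c(fi = 7.4, bw = 5.2, ame = 1.7, thp = 8, rq = 3.5, tnr = 10)
  cvs <- default_cvs
  if (!is.null(noise_cvs)) {
    unknown <- setdiff(names(noise_cvs), names(default_cvs))
    if (length(unknown) > 0) {
      bne_stop(sprintf("truth_set: unknown noise CV name(s): %s",
                       paste(unknown, collapse = ", ")), "bne_validation_error")
    }
    cvs[names(noise_cvs)] <- noise_cvs
  }
  if (any(cvs < 0)) {
    bne_stop("truth_set: noise CVs must be non-negative", "bne_validation_error")
  }
  need <- c("ingredient_id", "ame", "amen", "ne")
  missing <- setdiff(need, names(ingredients))
  if (length(missing) > 0) {
    bne_stop(sprintf("truth_set: ingredients lack column(s): %s",
                     paste(missing, collapse = ", ")), "bne_validation_error")
  }
  if (any(ingredients$ne > ingredients$ame) || ref_ne > ref_ame) {
    bne_stop("truth_set: NE must not exceed AME", "bne_validation_error")
  }
  if (!"kind" %in% names(ingredients)) ingredients$kind <- "other"
  structure(list(ingredients = ingredients, ref_ame = ref_ame,
                 ref_amen = ref_amen, ref_ne = ref_ne, ref_ge = ref_ge,
                 scheme = scheme, rq_true = rq_true,
                 tnr_per_kg_feed_true = tnr_per_kg_feed_true,
                 feed_n_per_kg = feed_n_per_kg, noise_cvs = cvs),
            class = "truth_set")
}

#' Ground truth matching the packaged trial dataset
#'
#' A [truth_set] whose ingredient energies equal the measured values of the
#' packaged 5-wheat / 5-wheat-bran determination panel, with the
#' reference-diet energies, substitution scheme, RQ and N retention of the
#' packaged trial summaries. Simulating from this truth set emulates the
#' original study design with known ground truth.
#'
#' @inheritParams trial_dataset
#' @return a `truth_set`.
#' @export
study_truth <- function(kind = "all") {
  energy <- study_ingredient_energy(kind = kind, experiment = 2)
  comp <- study_ingredients(kind = kind, experiment = 2)
  ing <- merge(energy[c("ingredient_id", "kind", "ame", "amen", "ne")],
               comp[c("ingredient_id", "cp", "ee", "cf", "ndf", "adf", "st")],
               by = "ingredient_id", sort = FALSE)
  wheat_summary <- study_diet_summary("wheat")
  ref_col <- function(item) wheat_summary$ref[wheat_summary$item == item]
  assays <- study_diet_assays()
  truth_set(
    ingredients = ing,
    ref_ame = ref_col("ame"), ref_amen = ref_col("amen"), ref_ne = ref_col("ne"),
    ref_ge = assays$ge[assays$diet_id == "ref"],
    scheme = substitution_scheme(),
    rq_true = ref_col("rq")
  )
}

# mean-preserving multiplicative lognormal noise
rlnorm_cv <- function(n, mean, cv_pct) {
  if (cv_pct == 0) return(rep(mean, n))
  sigma <- sqrt(log(1 + (cv_pct / 100)^2))
  mean * stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a complete synthetic feeding trial
#'
#' Generates a full observation bundle (ingredients, diet formulations,
#' diet assays, cage and chamber records) with the statistical structure
#' the analysis assumes, carrying its ground truth. Test-diet true energies
#' follow the linear mixing rule
#' `E_test = E_ref * a/100 + E_ingredient * b/100`; cage excreta mass,
#' energy and nitrogen are back-solved so that the total-collection
#' calculation recovers the (noise-perturbed) diet AME and N retention;
#' chamber gas volumes are back-solved from the true heat production implied
#' by the diet's AME-to-NE gap, the fasting heat production constant and the
#' true RQ. With all noise CVs zero the analysis pipeline recovers every
#' true energy exactly; the same seed yields a bit-identical bundle.
#'
#' @param truth a [truth_set].
#' @param config a [generator_config].
#' @param seed integer seed; per-run substreams are derived from it so a
#'   run's records do not depend on how many other runs are generated.
#' @param constants an [energy_constants] object.
#' @return a list with elements `bundle` (named list of the five component
#'   tables), `truth` (the input truth plus the per-diet true energies) and
#'   `seed`.
#' @export
simulate_study <- function(truth, config = generator_config(), seed = 1,
                           constants = energy_constants()) {
  if (!inherits(truth, "truth_set")) {
    bne_stop("simulate_study: 'truth' must be a truth_set", "bne_validation_error")
  }
  cvs <- truth$noise_cvs
  a <- truth$scheme$a_pct / 100
  b <- truth$scheme$b_pct / 100
  ing <- truth$ingredients
  n_ing <- nrow(ing)
  run_of <- ((seq_len(n_ing) - 1) %% config$n_runs) + 1

  # true per-diet energies (reference diet plus one test diet per ingredient)
  diet_truth <- data.frame(
    diet_id = c("ref", paste0("test_", ing$ingredient_id)),
    ame = c(truth$ref_ame, truth$ref_ame * a + ing$ame * b),
    amen = c(truth$ref_amen, truth$ref_amen * a + ing$amen * b),
    ne = c(truth$ref_ne, truth$ref_ne * a + ing$ne * b)
  )
  # diet GE keeps the reference diet's AME:GE utilization; each diet's true
  # N retention is the one its AME-AMEn gap implies, so the nitrogen
  # correction is internally consistent
  diet_truth$ge <- diet_truth$ame / (truth$ref_ame / truth$ref_ge)
  diet_truth$tnr_per_kg <- (diet_truth$ame - diet_truth$amen) * 1000 /
    constants$n_correction
  diet_truth$feed_n <- truth$feed_n_per_kg

  cages <- list()
  chambers <- list()
  f_e <- config$excreta_fraction
  for (r in seq_len(config$n_runs)) {
    run_seed <- (seed + 7919L * r) %% .Machine$integer.max
    set.seed(run_seed)
    run_id <- sprintf("run_%02d", r)
    ids_r <- ing$ingredient_id[run_of == r]
    run_diets <- c("ref", if (length(ids_r) > 0) paste0("test_", ids_r))
    for (d in run_diets) {
      dt <- diet_truth[diet_truth$diet_id == d, ]
      # total-collection cages
      for (j in seq_len(config$cage_replicates)) {
        nb <- config$birds_per_cage
        fi_rate <- rlnorm_cv(1, config$fi_mean, cvs["fi"])
        bw_i <- rlnorm_cv(1, config$bw_start_mean, cvs["bw"])
        adg <- fi_rate / config$fcr
        fi_total <- fi_rate * config$days * nb
        ame_obs <- rlnorm_cv(1, dt$ame, cvs["ame"])
        tnr_obs <- rlnorm_cv(1, dt$tnr_per_kg, cvs["tnr"])
        cages[[length(cages) + 1]] <- data.frame(
          run_id = run_id, diet_id = d,
          replicate_id = sprintf("%s_cage_%d", d, j),
          n_birds = nb, days = config$days,
          bw_initial = bw_i, bw_final = bw_i + adg * config$days,
          feed_intake_dm = fi_total,
          excreta_dm = f_e * fi_total,
          excreta_ge = (dt$ge - ame_obs) / f_e,
          feed_n = dt$feed_n,
          excreta_n = (dt$feed_n - tnr_obs) / f_e
        )
      }
      # calorimetry chambers
      for (j in seq_len(config$chamber_replicates)) {
        nb <- config$birds_per_chamber
        fi_rate <- rlnorm_cv(1, config$fi_mean, cvs["fi"])
        bw_i <- rlnorm_cv(1, config$bw_start_mean, cvs["bw"])
        adg <- fi_rate / config$fcr
        bw_f <- bw_i + adg * config$days
        abw <- (bw_i + bw_f) / 2
        mbw <- metabolic_weight(abw, constants)
        amei <- dt$ame * (fi_rate / 1000) / mbw          # MJ/kg^0.70/d
        hi_true <- amei * (1 - dt$ne / dt$ame)
        thp_true <- hi_true + constants$fhp_coef / 1000  # MJ/kg^0.70/d
        thp_obs <- rlnorm_cv(1, thp_true, cvs["thp"])
        rq_obs <- rlnorm_cv(1, truth$rq_true, cvs["rq"])
        heat_kj <- thp_obs * mbw * 1000 * nb * config$days
        o2 <- heat_kj / (constants$thp_o2 + constants$thp_co2 * rq_obs)
        chambers[[length(chambers) + 1]] <- data.frame(
          run_id = run_id, diet_id = d,
          chamber_id = sprintf("%s_chamber_%d", d, j),
          n_birds = nb, days = config$days,
          bw_initial = bw_i, bw_final = bw_f,
          feed_intake_dm = fi_rate * config$days * nb,
          o2_consumed = o2, co2_produced = rq_obs * o2
        )
      }
    }
  }

  # component tables in the study_io schemas
  ing_table <- data.frame(
    ingredient_id = c("ref_mix", ing$ingredient_id),
    kind = c("other", ing$kind),
    dm = 100,
    cp = c(NA, if ("cp" %in% names(ing)) ing$cp else rep(NA, n_ing)),
    ee = c(NA, if ("ee" %in% names(ing)) ing$ee else rep(NA, n_ing)),
    cf = c(NA, if ("cf" %in% names(ing)) ing$cf else rep(NA, n_ing)),
    ndf = c(NA, if ("ndf" %in% names(ing)) ing$ndf else rep(NA, n_ing)),
    adf = c(NA, if ("adf" %in% names(ing)) ing$adf else rep(NA, n_ing)),
    st = c(NA, if ("st" %in% names(ing)) ing$st else rep(NA, n_ing)),
    ge = NA_real_,
    dm_source = "synthetic"
  )
  sub_pct <- truth$scheme$b_pct
  diets <- rbind(
    data.frame(diet_id = "ref", role = "reference", ingredient_id = "ref_mix",
               inclusion_pct = 100, energy_yielding = TRUE,
               test_ingredient = FALSE),
    do.call(rbind, lapply(seq_len(n_ing), function(i) data.frame(
      diet_id = rep(paste0("test_", ing$ingredient_id[i]), 2),
      role = "test",
      ingredient_id = c("ref_mix", ing$ingredient_id[i]),
      inclusion_pct = c(100 - sub_pct, sub_pct),
      energy_yielding = TRUE,
      test_ingredient = c(FALSE, TRUE)
    )))
  )
  assays <- data.frame(diet_id = diet_truth$diet_id, dm = 100,
                       ge = diet_truth$ge,
                       cp = diet_truth$feed_n * constants$protein_per_n / 10,
                       basis = "dm")
  bundle <- list(
    ingredients = ing_table,
    diets = diets,
    diet_assays = assays,
    cages = do.call(rbind, cages),
    chambers = do.call(rbind, chambers)
  )
  truth$diet_truth <- diet_truth
  list(bundle = bundle, truth = truth, seed = seed)
}

#' Write a synthetic bundle to disk
#'
#' Writes the five component tables as CSV in the `study_io` schemas plus a
#' `truth.json` sidecar with the ground truth, and a `trial.yaml` config
#' that [load_trial] can consume.
#'
#' @param sim result of [simulate_study].
#' @param path output directory.
#' @return invisibly, the directory path.
#' @export
write_bundle <- function(sim, path) {
  write_tables(list(ingredients = sim$bundle$ingredients,
                    diets = sim$bundle$diets,
                    diet_assays = sim$bundle$diet_assays,
                    cage_obs = sim$bundle$cages,
                    chamber_obs = sim$bundle$chambers), path)
  truth <- unclass(sim$truth)
  truth$scheme <- unclass(truth$scheme)
  truth$noise_cvs <- as.list(truth$noise_cvs)
  jsonlite::write_json(
    list(seed = sim$seed, truth = truth),
    file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  yaml::write_yaml(list(paths = list(
    ingredients = "ingredients.csv", diets = "diets.csv",
    diet_assays = "diet_assays.csv", cage_obs = "cage_obs.csv",
    chamber_obs = "chamber_obs.csv")), file.path(path, "trial.yaml"))
  invisible(path)
}
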