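#' Analyze a trial bundle
#'
#' Runs the full energy-balance chain on an observation bundle:
#' total-collection AME/AMEn and N retention per cage, per-run-and-diet
#' means, chamber energy balance using the paired cage values of the same
#' run and diet, diet net energy, and substitution-method ingredient
#' energies of every test diet against the reference diet of its own run,
#' averaged across runs per ingredient.
#'
#' @param bundle a trial bundle as returned by [load_trial] or the `bundle`
#'   element of [simulate_study].
#' @param scheme a [substitution_scheme]; the default carries the trial's
#'   constants. Pass the result of [substitution_levels] to use shares
#'   recomputed from the formulations.
#' @param constants an [energy_constants] object.
#' @return a list with data frames `cage_energy` (per-cage AME/AMEn/TNR),
#'   `balance` (per-chamber energy balance and diet NE), `diet_energy`
#'   (per run and diet means) and `ingredient_energy` (per-ingredient
#'   substitution-method values).
#' @export
analyze_trial <- function(bundle, scheme = substitution_scheme(),
                          constants = energy_constants()) {
  check_bundle_integrity(bundle)
  cage_energy <- diet_ame(bundle$cages, bundle$diet_assays, constants)

  # per run x diet means of the total-collection quantities
  key <- interaction(cage_energy$run_id, cage_energy$diet_id, drop = TRUE)
  diet_run <- do.call(rbind, lapply(split(cage_energy, key), function(g) {
    data.frame(run_id = g$run_id[1], diet_id = g$diet_id[1],
               ame = mean(g$ame), amen = mean(g$amen),
               tnr_per_kg_feed = mean(g$tnr_per_kg_feed))
  }))
  rownames(diet_run) <- NULL

  # chamber balance with the paired cage values of the same run x diet
  ch <- bundle$chambers
  idx <- match(paste(ch$run_id, ch$diet_id),
               paste(diet_run$run_id, diet_run$diet_id))
  if (anyNA(idx)) {
    bne_stop(sprintf("no paired total-collection record for chamber diet(s): %s",
                     paste(unique(ch$diet_id[is.na(idx)]), collapse = ", ")),
             "bne_referential_error")
  }
  balance <- energy_balance(ch, ame = diet_run$ame[idx],
                            amen = diet_run$amen[idx],
                            tnr_per_kg_feed = diet_run$tnr_per_kg_feed[idx],
                            constants = constants)
  nex <- diet_net_energy(balance$ame, balance$amei, balance$nei, balance$amen)
  balance$ne <- nex$ne
  balance$ne_ame <- nex$ne_ame
  balance$ne_amen <- nex$ne_amen

  # per run x diet energy table
  bkey <- interaction(balance$run_id, balance$diet_id, drop = TRUE)
  diet_energy <- do.call(rbind, lapply(split(balance, bkey), function(g) {
    data.frame(run_id = g$run_id[1], diet_id = g$diet_id[1], n = nrow(g),
               ame = g$ame[1], amen = g$amen[1],
               amei = mean(g$amei), nei = mean(g$nei), thp = mean(g$thp),
               hi = mean(g$hi), re = mean(g$re),
               re_protein = mean(g$re_protein), re_fat = mean(g$re_fat),
               rq = mean(g$rq), ne = mean(g$ne),
               abw = mean(g$abw), fi = mean(g$fi))
  }))
  rownames(diet_energy) <- NULL

  # substitution-method ingredient values, per run against that run's REF
  test_info <- bundle$diets[bundle$diets$role == "test" &
                              bundle$diets$test_ingredient, ]
  per_run <- list()
  for (i in seq_len(nrow(diet_energy))) {
    row <- diet_energy[i, ]
    tid <- test_info$ingredient_id[match(row$diet_id, test_info$diet_id)]
    if (is.na(tid)) next
    ref_row <- diet_energy[diet_energy$run_id == row$run_id &
                             !diet_energy$diet_id %in% test_info$diet_id, ]
    if (nrow(ref_row) != 1) {
      bne_stop(sprintf("run %s lacks a unique reference diet", row$run_id),
               "bne_referential_error")
    }
    per_run[[length(per_run) + 1]] <- cbind(
      run_id = row$run_id,
      ingredient_energy(row, ref_row, scheme, ingredient_id = tid)
    )
  }
  per_run <- if (length(per_run) > 0) do.call(rbind, per_run) else NULL
  ingredient <- NULL
  if (!is.null(per_run)) {
    ingredient <- do.call(rbind, lapply(split(per_run, per_run$ingredient_id),
      function(g) {
        data.frame(ingredient_id = g$ingredient_id[1], n_runs = nrow(g),
                   ame = mean(g$ame), amen = mean(g$amen), ne = mean(g$ne),
                   ne_ame = 100 * mean(g$ne) / mean(g$ame),
                   ne_amen = 100 * mean(g$ne) / mean(g$amen))
      }))
    rownames(ingredient) <- NULL
  }

  list(cage_energy = cage_energy, balance = balance,
       diet_energy = diet_energy, ingredient_energy = ingredient)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete chain behind a single entry point: obtain a
#' bundle (simulate one, load one from disk, or start from the packaged
#' ingredient panel), run the energy balance and substitution stages,
#' summarize ingredient panels, screen correlations, fit the stepwise NE
#' prediction equation per ingredient class, and validate against holdout
#' samples when given. Deterministic for a fixed seed; re-running on
#' identical inputs yields identical tables.
#'
#' @param config a YAML file path or named list. Recognized keys:
#'   \describe{
#'     \item{input}{`"synthetic"` (default), `"paths"`, or `"panel"`. With
#'       `paths`, key `paths:` names the five component CSVs as in
#'       [load_trial]. With `panel`, the packaged ingredient energy panel is
#'       analyzed directly (no raw observations).}
#'     \item{seed}{integer seed for synthetic input.}
#'     \item{synthetic}{sub-keys passed to [generator_config], plus
#'       optional `kind` selecting the truth panel for [study_truth].}
#'     \item{constants}{overrides for [energy_constants].}
#'     \item{scheme}{`a_pct`/`b_pct` overrides; default uses the trial's
#'       printed substitution constants.}
#'     \item{fit}{`alpha_enter`, `alpha_remove`, `collinearity_alpha`,
#'       `candidates` (character vector) for [stepwise_fit].}
#'     \item{out}{optional output directory for [write_tables].}
#'   }
#' @return an object of class `ne_report`: the stage outputs plus a
#'   `provenance` block (constants, scheme, seed, config hash, package
#'   version).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, bne_error = function(e) {
      bne_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "bne_stage_error")
    })
  }
  constants <- do.call(energy_constants, config$constants %||% list())
  scheme <- do.call(substitution_scheme, config$scheme %||% list())
  input <- config$input %||% "synthetic"
  seed <- config$seed %||% 1L

  panels <- NULL   # named list of data frames: predictors + measured ne
  results <- NULL
  if (input == "panel") {
    panels <- stage("panel", {
      lapply(stats::setNames(nm = c("wheat", "wheat_bran")), function(k) {
        en <- study_ingredient_energy(kind = k, experiment = 2)
        comp <- study_ingredients(kind = k, experiment = 2)
        merge(en[c("ingredient_id", "ame", "amen", "ne")],
              comp[c("ingredient_id", "cp", "ee", "cf", "ndf", "adf", "st")],
              by = "ingredient_id", sort = FALSE)
      })
    })
  } else {
    bundle <- if (input == "paths") {
      stage("load", load_trial(config$paths))
    } else {
      syn <- config$synthetic %||% list()
      kind <- syn$kind %||% "all"
      syn$kind <- NULL
      sim <- stage("simulate",
                   simulate_study(study_truth(kind = kind),
                                  do.call(generator_config, syn),
                                  seed = seed, constants = constants))
      results <- list(truth = sim$truth)
      sim$bundle
    }
    analysis <- stage("balance", analyze_trial(bundle, scheme, constants))
    results <- c(results, analysis)
    # assemble per-kind panels from recovered ingredient values
    ing <- analysis$ingredient_energy
    if (!is.null(ing)) {
      comp <- bundle$ingredients
      merged <- merge(ing, comp[c("ingredient_id", "kind", "cp", "ee", "cf",
                                  "ndf", "adf", "st")],
                      by = "ingredient_id", sort = FALSE)
      panels <- split(merged, merged$kind)
    }
  }

  fit_cfg <- config$fit %||% list()
  candidates <- fit_cfg$candidates %||% c("ame", "amen", "cp", "ee", "cf",
                                          "ndf", "adf", "st")
  correlations <- list(); equations <- list(); summaries <- list()
  for (k in names(panels)) {
    panel <- panels[[k]]
    cand <- panel[intersect(candidates, names(panel))]
    cand <- cand[vapply(cand, function(v) !anyNA(v) && stats::var(v) > 0,
                        logical(1))]
    summaries[[k]] <- do.call(rbind, lapply(
      stats::setNames(nm = intersect(c("ame", "amen", "ne"), names(panel))),
      function(col) cbind(item = col, summarize_samples(panel[[col]]))))
    if (nrow(panel) >= 3 && ncol(cand) >= 2) {
      correlations[[k]] <- stage("correlation",
                                 pearson_matrix(cbind(cand, ne = panel$ne)))
      equations[[k]] <- stage("fit", stepwise_fit(
        panel$ne, cand,
        alpha_enter = fit_cfg$alpha_enter %||% 0.05,
        alpha_remove = fit_cfg$alpha_remove %||% 0.10,
        collinearity_alpha = fit_cfg$collinearity_alpha %||% 0.05))
    }
  }

  validations <- list()
  if (input == "panel") {
    for (k in names(equations)) {
      holdout_en <- study_ingredient_energy(kind = k, experiment = 3)
      holdout_comp <- study_ingredients(kind = k, experiment = 3)
      holdout <- merge(holdout_en, holdout_comp, by = c("ingredient_id", "kind"))
      if (nrow(holdout) > 0) {
        validations[[k]] <- stage("validate", validate_equation(
          equations[[k]], holdout, holdout$ne,
          training = list(data = panels[[k]], measured = panels[[k]]$ne)))
      }
    }
  }

  report <- structure(list(
    panels = panels, summaries = summaries, correlations = correlations,
    equations = equations, validations = validations,
    diet_energy = results$diet_energy, balance = results$balance,
    cage_energy = results$cage_energy,
    ingredient_energy = results$ingredient_energy,
    truth = results$truth,
    provenance = list(
      input = input, seed = seed,
      constants = unclass(constants), scheme = unclass(scheme),
      config_hash = fnv1a(config),
      package_version = as.character(utils::packageVersion("broilerNE"))
    )
  ), class = "ne_report")

  if (!is.null(config$out)) {
    tables <- Filter(is.data.frame, list(
      diet_energy = report$diet_energy,
      ingredient_energy = report$ingredient_energy,
      balance = report$balance, cage_energy = report$cage_energy))
    for (k in names(report$equations)) {
      tables[[paste0("equation_", k)]] <- as.data.frame(report$equations[[k]])
    }
    write_tables(tables, config$out)
  }
  report
}

#' @export
print.ne_report <- function(x, ...) {
  cat("Net-energy pipeline report\n")
  cat(sprintf("  input: %s   seed: %s   config: %s\n", x$provenance$input,
              x$provenance$seed, x$provenance$config_hash))
  if (!is.null(x$ingredient_energy)) {
    cat(sprintf("  ingredient energies: %d ingredient(s)\n",
                nrow(x$ingredient_energy)))
  }
  for (k in names(x$equations)) {
    cat(sprintf("  %s equation: ", k)); print(x$equations[[k]])
  }
  for (k in names(x$validations)) {
    cat(sprintf("  %s validation: r = %.3f\n", k, x$validations[[k]]$pearson_r))
  }
  invisible(x)
}
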