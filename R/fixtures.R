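#' Packaged broiler trial dataset
#'
#' The package ships, as plain-text tables under `inst/extdata/`, the data of
#' a broiler net-energy trial on 5 wheat and 5 wheat bran samples (plus one
#' validation sample of each, measured in a separate run): proximate
#' compositions, reference/test diet formulations, diet assay values, the
#' per-diet performance and energy-balance summaries, the substitution-method
#' ingredient energy values, and the fitted NE prediction equations. These
#' accessors load and subset the tables.
#'
#' DM contents of the minor (non-test) formulation ingredients were not
#' assayed in the trial; the packaged table carries nominal handbook values
#' for them, flagged by the `dm_source` column.
#'
#' @param kind ingredient class: `"wheat"`, `"wheat_bran"` or `"all"`.
#' @param experiment trial phase: `2` (the 5-sample determination panel),
#'   `3` (the single validation sample) or `"all"`.
#' @name trial_dataset
NULL

bne_extdata <- function(file) {
  p <- system.file("extdata", file, package = "broilerNE")
  if (p == "") bne_stop(sprintf("packaged table %s not found", file), "bne_io_error")
  p
}

#' @rdname trial_dataset
#' @param assayed_only drop the minor formulation ingredients whose DM is
#'   nominal rather than assayed.
#' @export
study_ingredients <- function(kind = "all", experiment = "all", assayed_only = TRUE) {
  df <- load_ingredients(bne_extdata("ingredients.csv"))
  if (assayed_only) df <- df[df$dm_source == "assayed", ]
  if (kind != "all") df <- df[df$kind == kind, ]
  if (!identical(experiment, "all")) {
    valid <- grepl("_v$", df$ingredient_id)
    df <- df[if (experiment == 3) valid else !valid, ]
  }
  rownames(df) <- NULL
  df
}

#' @rdname trial_dataset
#' @return `study_ingredient_energy()`: measured AME, AMEn and NE (MJ/kg DM)
#'   with utilization ratios (percent) per ingredient sample.
#' @export
study_ingredient_energy <- function(kind = "all", experiment = 2) {
  df <- read_checked(bne_extdata("ingredient_energy.csv"),
    required = c("ingredient_id", "kind", "experiment", "ame", "amen", "ne"),
    numeric_cols = c("experiment", "ame", "amen", "ne",
                     "ame_ge", "amen_ge", "ne_ame", "ne_amen"))
  if (kind != "all") df <- df[df$kind == kind, ]
  if (!identical(experiment, "all")) df <- df[df$experiment == experiment, ]
  rownames(df) <- NULL
  df
}

#' @rdname trial_dataset
#' @param panel diet panel: `"wheat"` or `"wheat_bran"`.
#' @return `study_diet_summary()`: the per-diet trial summary (rows are
#'   items: performance, energy balance in MJ/kg BW^0.70/d, energy values in
#'   MJ/kg DM, utilization in percent; columns are the single-diet
#'   uniformity run, the reference diet, the five test diets, pooled SEM and
#'   p-value, and the validation run).
#' @export
study_diet_summary <- function(panel = c("wheat", "wheat_bran")) {
  panel <- match.arg(panel)
  df <- utils::read.csv(bne_extdata("diet_summary.csv"), stringsAsFactors = FALSE)
  df <- df[df$panel == panel, ]
  rownames(df) <- NULL
  df
}

#' @rdname trial_dataset
#' @export
study_diet_formulations <- function() {
  load_diets(bne_extdata("diets.csv"))
}

#' @rdname trial_dataset
#' @export
study_diet_assays <- function() {
  load_diet_assays(bne_extdata("diet_assays.csv"))
}

#' @rdname trial_dataset
#' @return `study_equations()`: a named list of [ne_equation] objects, the
#'   NE prediction equations fitted in the trial (`wheat`: NE on AME and
#'   ADF; `wheat_bran`: NE on CP, CF and ADF).
#' @export
study_equations <- function() {
  df <- utils::read.csv(bne_extdata("equations.csv"), stringsAsFactors = FALSE)
  out <- list()
  term_cols <- c("ame", "amen", "cp", "ee", "cf", "adf", "ndf", "st")
  for (i in seq_len(nrow(df))) {
    terms <- unlist(df[i, term_cols])
    terms <- terms[!is.na(terms)]
    out[[df$class[i]]] <- ne_equation(
      response = df$response[i],
      intercept = df$intercept[i],
      terms = terms,
      r2 = df$r2[i],
      n = NA_integer_
    )
  }
  out
}
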