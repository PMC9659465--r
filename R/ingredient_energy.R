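#' Substitution scheme of a test diet
#'
#' The substitution method derives an ingredient's energy from a test diet
#' in which the ingredient replaces part of a reference diet. `a_pct` is the
#' DM share of the test diet contributed by the reference diet's
#' energy-yielding ingredients, `b_pct` the DM share contributed by the test
#' ingredient. Defaults are the trial's values (a = 67.58, b = 31.32).
#'
#' @param a_pct percent of test-diet DM from reference-origin energy-yielding
#'   ingredients.
#' @param b_pct percent of test-diet DM from the test ingredient (the
#'   substitution level).
#' @return an object of class `substitution_scheme`.
#' @export
substitution_scheme <- function(a_pct = 67.58, b_pct = 31.32) {
  if (!(a_pct > 0 && a_pct < 100 && b_pct > 0 && b_pct < 100 &&
        a_pct + b_pct <= 100)) {
    bne_stop("substitution_scheme: need 0 < a, b < 100 and a + b <= 100",
             "bne_validation_error")
  }
  structure(list(a_pct = a_pct, b_pct = b_pct), class = "substitution_scheme")
}

#' Substitution levels recomputed from diet formulations
#'
#' Recomputes the DM-basis substitution shares from the air-dry inclusion
#' percentages and ingredient DM contents: each inclusion is weighted by the
#' ingredient's DM, and `a_pct` is the resulting share of the
#' reference-origin energy-yielding ingredients in the test diet, `b_pct`
#' the share of the test ingredient. Ingredients without a DM record use
#' `dm_default`. The recomputed values depend on the (often unassayed) DM of
#' minor ingredients; [substitution_scheme()] with its defaults carries the
#' trial's own constants.
#'
#' @param ref rows of a diet formulation table for the reference diet.
#' @param test rows of a diet formulation table for the test diet; exactly
#'   one row must be flagged `test_ingredient`.
#' @param ingredients ingredient table supplying DM contents.
#' @param dm_default percent DM assumed for ingredients absent from
#'   `ingredients`.
#' @return a `substitution_scheme`.
#' @export
substitution_levels <- function(ref, test, ingredients, dm_default = 90) {
  tid <- test$ingredient_id[which(test$test_ingredient)]
  if (length(tid) != 1) {
    bne_stop("substitution_levels: test diet must flag exactly one test ingredient",
             "bne_config_error")
  }
  if (!tid %in% test$ingredient_id || test$inclusion_pct[test$ingredient_id == tid] <= 0) {
    bne_stop("substitution_levels: test ingredient absent from test diet",
             "bne_config_error")
  }
  dm_of <- function(ids) {
    dm <- ingredients$dm[match(ids, ingredients$ingredient_id)]
    dm[is.na(dm)] <- dm_default
    dm
  }
  dm_share <- test$inclusion_pct * dm_of(test$ingredient_id)
  total <- sum(dm_share)
  ref_origin <- test$energy_yielding & !test$test_ingredient &
    test$ingredient_id %in% ref$ingredient_id
  a_pct <- 100 * sum(dm_share[ref_origin]) / total
  b_pct <- 100 * dm_share[test$ingredient_id == tid] / total
  substitution_scheme(a_pct = a_pct, b_pct = b_pct)
}

#' Ingredient energy values by the substitution method
#'
#' Decomposes test-diet energy values against the same-run reference diet:
#' `E_ingredient = (E_test - E_ref * a/100) / (b/100)` for each of AME, AMEn
#' and NE. This is the exact inverse of the linear mixing rule
#' `E_test = E_ref * a/100 + E_ingredient * b/100`. Utilization ratios
#' against the ingredient's gross energy are reported when `ge` is given.
#'
#' @param test_diet named list or one-row data frame with test-diet `ame`,
#'   `amen`, `ne` (MJ/kg DM); missing components give `NA` results.
#' @param ref_diet the same for the reference diet of the same run.
#' @param scheme a [substitution_scheme].
#' @param ingredient_id identifier carried into the result.
#' @param ge optional ingredient gross energy, MJ/kg DM.
#' @return a one-row data frame with `ame`, `amen`, `ne` (MJ/kg DM) and
#'   percent ratios `ame_ge`, `amen_ge`, `ne_ame`, `ne_amen`.
#' @export
ingredient_energy <- function(test_diet, ref_diet, scheme = substitution_scheme(),
                              ingredient_id = NA_character_, ge = NULL) {
  if (scheme$b_pct == 0) {
    bne_stop("ingredient_energy: substitution level b must be non-zero",
             "bne_domain_error")
  }
  unmix <- function(comp) {
    t <- test_diet[[comp]] %||% NA_real_
    r <- ref_diet[[comp]] %||% NA_real_
    (t - r * scheme$a_pct / 100) / (scheme$b_pct / 100)
  }
  ame <- unmix("ame"); amen <- unmix("amen"); ne <- unmix("ne")
  data.frame(
    ingredient_id = ingredient_id,
    ame = ame, amen = amen, ne = ne,
    ame_ge = if (is.null(ge)) NA_real_ else 100 * ame / ge,
    amen_ge = if (is.null(ge)) NA_real_ else 100 * amen / ge,
    ne_ame = 100 * ne / ame,
    ne_amen = 100 * ne / amen
  )
}

#' Cross-sample summary statistics
#'
#' Mean, sample (n-1) standard deviation, coefficient of variation and
#' standard error across ingredient samples, as reported in cross-sample
#' summary columns. With replicate-level data the SEM is the pooled ANOVA
#' standard error `sqrt(MSE / harmonic mean n)` and the RSD the pooled
#' replicate CV; without replicates SEM falls back to `sd/sqrt(n)` and RSD
#' equals the cross-sample CV.
#'
#' @param x numeric vector of per-sample values (e.g. one energy column of
#'   an ingredient panel).
#' @param replicates optional list of numeric vectors, the replicate
#'   measurements behind each element of `x`.
#' @return a one-row data frame: `n`, `mean`, `sd`, `cv_pct`, `sem`,
#'   `rsd_pct`. With fewer than two samples the dispersion fields are `NA`.
#' @export
summarize_samples <- function(x, replicates = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) {
    return(data.frame(n = n, mean = mean(x), sd = NA_real_, cv_pct = NA_real_,
                      sem = NA_real_, rsd_pct = NA_real_))
  }
  m <- mean(x)
  s <- stats::sd(x)
  cv <- 100 * s / m
  if (!is.null(replicates)) {
    k <- length(replicates)
    ni <- lengths(replicates)
    if (any(ni < 2)) {
      bne_stop("summarize_samples: each replicate group needs >= 2 values",
               "bne_validation_error")
    }
    mse <- sum(vapply(replicates, function(v) sum((v - mean(v))^2), numeric(1))) /
      sum(ni - 1)
    n_h <- k / sum(1 / ni)
    sem <- sqrt(mse / n_h)
    grand <- mean(unlist(replicates))
    rsd <- 100 * sqrt(mse) / grand
  } else {
    sem <- s / sqrt(n)
    rsd <- cv
  }
  data.frame(n = n, mean = m, sd = s, cv_pct = cv, sem = sem, rsd_pct = rsd)
}
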