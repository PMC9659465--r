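#' Energy constants for calorimetry and balance calculations
#'
#' Thermal equivalents and partition constants used throughout the energy
#' balance. Defaults follow the trial's calculation conventions: heat
#' production from gas exchange at 16.1753 kJ per liter O2 consumed and
#' 5.0208 kJ per liter CO2 produced; fasting heat production 450 kJ per kg
#' metabolic body weight (BW^0.70) per day; the nitrogen correction of AMEn
#' at 34.39 kJ per g retained N; 6.25 g protein per g N; and 23.85 kJ per g
#' protein (5.7 kcal/g) for the energy retained as protein.
#'
#' @param thp_o2 kJ per liter O2 consumed.
#' @param thp_co2 kJ per liter CO2 produced.
#' @param fhp_coef fasting heat production, kJ per kg^`mbw_exponent` per day.
#' @param mbw_exponent allometric exponent of metabolic body weight.
#' @param n_correction kJ per g retained nitrogen.
#' @param protein_per_n g protein per g nitrogen.
#' @param protein_energy kJ per g protein.
#' @return an object of class `energy_constants`.
#' @export
energy_constants <- function(thp_o2 = 16.1753, thp_co2 = 5.0208,
                             fhp_coef = 450, mbw_exponent = 0.70,
                             n_correction = 34.39, protein_per_n = 6.25,
                             protein_energy = 23.85) {
  k <- list(thp_o2 = thp_o2, thp_co2 = thp_co2, fhp_coef = fhp_coef,
            mbw_exponent = mbw_exponent, n_correction = n_correction,
            protein_per_n = protein_per_n, protein_energy = protein_energy)
  if (!all(vapply(k, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1)))) {
    bne_stop("all energy constants must be single positive numbers",
             "bne_validation_error")
  }
  structure(k, class = "energy_constants")
}

#' Metabolic body weight
#'
#' Allometric scaling basis for the energy flows: body mass in kg raised to
#' the metabolic exponent (0.70 by default), i.e. `(abw/1000)^0.70` for a
#' body weight given in grams.
#'
#' @param abw average body weight, g per bird.
#' @param constants an [energy_constants] object.
#' @return kg^0.70 (vectorized).
#' @export
metabolic_weight <- function(abw, constants = energy_constants()) {
  if (any(!is.finite(abw)) || any(abw <= 0)) {
    bne_stop("metabolic_weight: body weight must be positive",
             "bne_domain_error")
  }
  (abw / 1000)^constants$mbw_exponent
}

#' Growth performance of a replicate
#'
#' Average body weight (mean of initial and final), average daily gain per
#' bird, daily DM feed intake per bird, and feed conversion ratio, from a
#' cage or chamber record. When a replicate shows zero or negative gain the
#' FCR is reported as `NA` with a warning rather than dividing by it.
#'
#' @param obs a data frame of cage or chamber observations (columns
#'   `bw_initial`, `bw_final`, `days`, `n_birds`, `feed_intake_dm`).
#' @inheritParams metabolic_weight
#' @return a data frame with columns `abw` (g), `adg` (g/bird/d), `fi`
#'   (g DM/bird/d), `fcr` (g feed DM per g gain) and `mbw` (kg^0.70).
#' @export
performance <- function(obs, constants = energy_constants()) {
  if (any(obs$days < 1) || any(obs$n_birds < 1)) {
    bne_stop("performance: days and n_birds must be positive", "bne_domain_error")
  }
  abw <- (obs$bw_initial + obs$bw_final) / 2
  adg <- (obs$bw_final - obs$bw_initial) / obs$days
  fi <- obs$feed_intake_dm / (obs$days * obs$n_birds)
  fcr <- rep(NA_real_, length(adg))
  pos <- adg > 0
  fcr[pos] <- fi[pos] / adg[pos]
  if (any(!pos)) {
    bne_warn(sprintf("%d replicate(s) with non-positive gain: FCR reported as NA",
                     sum(!pos)), "bne_degenerate_warning")
  }
  data.frame(abw = abw, adg = adg, fi = fi, fcr = fcr,
             mbw = metabolic_weight(abw, constants))
}

#' Total heat production from gas exchange
#'
#' Heat production by indirect calorimetry from total O2 consumption and CO2
#' production, `thp_o2 * O2 + thp_co2 * CO2`, in kJ. The coefficients are
#' thermal equivalents in kJ per liter of gas.
#'
#' @param o2 liters of O2 consumed.
#' @param co2 liters of CO2 produced.
#' @inheritParams metabolic_weight
#' @return heat production in kJ (vectorized).
#' @export
thp_from_gas <- function(o2, co2, constants = energy_constants()) {
  if (any(o2 < 0) || any(co2 < 0)) {
    bne_stop("thp_from_gas: gas volumes must be non-negative", "bne_domain_error")
  }
  constants$thp_o2 * o2 + constants$thp_co2 * co2
}

#' Respiratory quotient
#'
#' Volume ratio of CO2 produced to O2 consumed.
#'
#' @inheritParams thp_from_gas
#' @return dimensionless ratio (vectorized).
#' @export
respiratory_quotient <- function(o2, co2) {
  if (any(o2 <= 0)) {
    bne_stop("respiratory_quotient: O2 consumed must be positive",
             "bne_domain_error")
  }
  if (any(co2 < 0)) {
    bne_stop("respiratory_quotient: CO2 produced must be non-negative",
             "bne_domain_error")
  }
  co2 / o2
}

#' Diet AME and AMEn from total collection
#'
#' Apparent metabolizable energy of a diet from a cage-level total
#' collection record: GE intake minus excreta GE, per kg DM feed. The
#' nitrogen-corrected value subtracts the energy equivalent of retained
#' nitrogen (per kg DM feed) at the `n_correction` constant.
#'
#' @param obs cage observation data frame (see [load_cage_obs]).
#' @param assay diet assay table with columns `diet_id` and `ge`
#'   (MJ/kg DM); matched to `obs` by `diet_id`.
#' @inheritParams metabolic_weight
#' @return a data frame with per-replicate `ame` and `amen` (MJ/kg DM),
#'   `tnr_per_kg_feed` (g N retained per kg DM feed) and `tnr`
#'   (g N/bird/d), alongside the identifying columns of `obs`.
#' @export
diet_ame <- function(obs, assay, constants = energy_constants()) {
  if (any(obs$feed_intake_dm <= 0)) {
    bne_stop("diet_ame: feed intake must be positive", "bne_domain_error")
  }
  ge <- assay$ge[match(obs$diet_id, assay$diet_id)]
  if (anyNA(ge)) {
    bne_stop(sprintf("diet_ame: no assay GE for diet(s): %s",
                     paste(unique(obs$diet_id[is.na(ge)]), collapse = ", ")),
             "bne_referential_error")
  }
  excreta_frac <- obs$excreta_dm / obs$feed_intake_dm
  ame <- ge - obs$excreta_ge * excreta_frac
  if (any(ame < 0)) {
    bne_warn("diet_ame: excreta energy exceeds intake energy; negative AME flagged",
             "bne_flagged_warning")
  }
  tnr_per_kg <- obs$feed_n - obs$excreta_n * excreta_frac
  amen <- ame - constants$n_correction * tnr_per_kg / 1000
  tnr <- tnr_per_kg * obs$feed_intake_dm / 1000 / (obs$days * obs$n_birds)
  out <- data.frame(
    run_id = obs$run_id, diet_id = obs$diet_id, replicate_id = obs$replicate_id,
    ame = ame, amen = amen, tnr_per_kg_feed = tnr_per_kg, tnr = tnr
  )
  out$flag_negative_ame <- ame < 0
  out
}

#' Per-chamber energy balance
#'
#' Partitions AME intake of a chamber replicate into heat and retention, all
#' expressed per kg metabolic body weight (kg^0.70) per day:
#' AMEI = diet AME x feed intake; THP from gas exchange; FHP the allometric
#' fasting heat production constant (0.450 MJ/kg^0.70/d at defaults);
#' HI = THP - FHP; NEI = AMEI - HI; RE = AMEI - THP; RE as protein from
#' retained nitrogen, RE as fat the remainder. Chamber birds have no excreta
#' collection, so `ame`, `amen` and `tnr_per_kg_feed` come from the paired
#' total-collection replicates of the same run and diet.
#'
#' @param chamber chamber observation data frame (see [load_chamber_obs]).
#' @param ame diet AME, MJ/kg DM (scalar or one value per chamber row).
#' @param amen optional diet AMEn, MJ/kg DM.
#' @param tnr_per_kg_feed optional N retention of the paired cage replicates,
#'   g N per kg DM feed; when absent the protein/fat partition of RE is `NA`.
#' @inheritParams metabolic_weight
#' @return a data frame (class `energy_balance`) with columns `amei`, `nei`,
#'   `thp`, `fhp`, `hi`, `re`, `re_protein`, `re_fat` (MJ/kg^0.70/d), `rq`,
#'   `tnr` (g N/bird/d), the performance columns, and a `flag_negative_hi`
#'   diagnostic.
#' @export
energy_balance <- function(chamber, ame, amen = NULL, tnr_per_kg_feed = NULL,
                           constants = energy_constants()) {
  if (anyNA(ame) || any(ame <= 0)) {
    bne_stop("energy_balance: diet AME must be present and positive",
             "bne_domain_error")
  }
  perf <- performance(chamber, constants)
  fi_kg <- perf$fi / 1000                       # kg DM/bird/d
  amei <- ame * fi_kg / perf$mbw                # MJ/kg^0.70/d
  thp_bird <- thp_from_gas(chamber$o2_consumed, chamber$co2_produced, constants) /
    (chamber$n_birds * chamber$days) / 1000     # MJ/bird/d
  thp <- thp_bird / perf$mbw
  fhp <- constants$fhp_coef / 1000              # MJ/kg^0.70/d by definition
  hi <- thp - fhp
  nei <- amei - hi
  re <- amei - thp
  if (any(hi < 0)) {
    bne_warn("energy_balance: negative heat increment (THP below FHP) flagged",
             "bne_flagged_warning")
  }
  if (is.null(tnr_per_kg_feed)) {
    tnr <- rep(NA_real_, nrow(chamber))
  } else {
    tnr <- tnr_per_kg_feed * fi_kg              # g N/bird/d
  }
  re_protein <- tnr * constants$protein_per_n * constants$protein_energy /
    1000 / perf$mbw                             # MJ/kg^0.70/d
  re_fat <- re - re_protein
  out <- data.frame(
    run_id = chamber$run_id, diet_id = chamber$diet_id,
    chamber_id = chamber$chamber_id,
    amei = amei, nei = nei, thp = thp, fhp = fhp, hi = hi,
    re = re, re_protein = re_protein, re_fat = re_fat,
    rq = respiratory_quotient(chamber$o2_consumed, chamber$co2_produced),
    tnr = tnr,
    ame = ame, amen = if (is.null(amen)) NA_real_ else amen,
    abw = perf$abw, adg = perf$adg, fi = perf$fi, fcr = perf$fcr,
    mbw = perf$mbw,
    flag_negative_hi = hi < 0
  )
  class(out) <- c("energy_balance", "data.frame")
  out
}

#' Diet-level net energy
#'
#' NE of a diet from its AME and the measured intake flows: the fraction of
#' AME intake that remains as NE intake, applied to the diet AME
#' concentration, `ne = ame * nei / amei` (MJ/kg DM). When NEI equals AMEI
#' (zero heat increment) the diet NE equals its AME.
#'
#' @param ame diet AME, MJ/kg DM.
#' @param amei AME intake, MJ/kg^0.70/d (must be positive).
#' @param nei NE intake, MJ/kg^0.70/d.
#' @param amen optional diet AMEn (MJ/kg DM) for the NE/AMEn ratio.
#' @return a data frame with `ne` (MJ/kg DM) and percent ratios `ne_ame`
#'   and (when `amen` is given) `ne_amen`.
#' @export
diet_net_energy <- function(ame, amei, nei, amen = NULL) {
  if (any(!is.finite(amei)) || any(amei <= 0)) {
    bne_stop("diet_net_energy: AME intake must be positive", "bne_domain_error")
  }
  ne <- ame * nei / amei
  data.frame(
    ne = ne,
    ne_ame = 100 * ne / ame,
    ne_amen = if (is.null(amen)) NA_real_ else 100 * ne / amen
  )
}
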