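#' Read and validate trial tables
#'
#' Readers for the delimited tables a metabolism trial produces: ingredient
#' proximate compositions, diet formulations, diet assays, cage-level total
#' collection records and chamber-level gas-exchange records. All readers
#' enforce the schema (an informative error names any missing column), parse
#' numerics strictly (a non-numeric cell reports its row), and check the
#' domain invariants of each record type. Compositions and energies are kept
#' on a dry-matter (DM) basis internally; tables declaring an `air_dry`
#' basis are converted on load using each record's DM content.
#'
#' @name study_io
NULL

# ---- generic checked CSV reader --------------------------------------------

read_checked <- function(path, required, numeric_cols, optional = character()) {
  if (!file.exists(path)) {
    bne_stop(sprintf("file not found: %s", path), "bne_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    bne_stop(sprintf("missing column(s) in %s: %s", basename(path),
                     paste(missing, collapse = ", ")), "bne_schema_error")
  }
  for (col in intersect(numeric_cols, names(raw))) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      bne_stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                       v[bad[1]], col, bad[1], basename(path)),
               "bne_parse_error")
    }
    raw[[col]] <- parsed
  }
  raw
}

check_range <- function(df, col, lo, hi, what, lo_open = FALSE, allow_na = FALSE) {
  v <- df[[col]]
  if (allow_na) {
    keep <- !is.na(v)
  } else {
    if (anyNA(v)) {
      bne_stop(sprintf("%s: column '%s' has missing values", what, col),
               "bne_validation_error")
    }
    keep <- rep(TRUE, length(v))
  }
  bad <- keep & (if (lo_open) v <= lo else v < lo | v > hi)
  bad <- bad | (keep & v > hi)
  if (any(bad, na.rm = TRUE)) {
    bne_stop(sprintf("%s: column '%s' outside [%s, %s] at row %d (value %s)",
                     what, col, lo, hi, which(bad)[1], v[which(bad)[1]]),
             "bne_validation_error")
  }
  invisible(df)
}

# ---- ingredients -----------------------------------------------------------

#' @rdname study_io
#' @param path path to a CSV file.
#' @return `load_ingredients()`: a data frame with one row per ingredient
#'   (columns `ingredient_id`, `kind`, `dm`, `cp`, `ee`, `cf`, `ndf`, `adf`,
#'   `st`, `ge`); proximate values are percent of DM, starch (`st`) g/kg DM,
#'   gross energy (`ge`, optional) MJ/kg DM, `dm` percent as-fed.
#' @export
load_ingredients <- function(path) {
  df <- read_checked(path,
    required = c("ingredient_id", "kind", "dm", "cp", "ee", "cf", "ndf", "adf", "st"),
    numeric_cols = c("dm", "cp", "ee", "cf", "ndf", "adf", "st", "ge"))
  if (!"ge" %in% names(df)) df$ge <- NA_real_
  if (nrow(df) == 0) {
    bne_warn("ingredient table has a header but no data rows")
    return(df)
  }
  validate_ingredients(df)
  class(df) <- c("ingredient_table", "data.frame")
  df
}

validate_ingredients <- function(df) {
  check_range(df, "dm", 0, 100, "ingredients", lo_open = TRUE)
  for (col in c("cp", "ee", "cf", "ndf", "adf")) {
    check_range(df, col, 0, 100, "ingredients", allow_na = TRUE)
  }
  check_range(df, "st", 0, 1000, "ingredients", allow_na = TRUE)
  ge <- df$ge[!is.na(df$ge)]
  if (any(ge <= 0 | ge >= 30)) {
    bne_stop("ingredients: gross energy outside (0, 30) MJ/kg DM",
             "bne_validation_error")
  }
  if (anyDuplicated(df$ingredient_id)) {
    bne_stop("ingredients: duplicated ingredient_id", "bne_validation_error")
  }
  invisible(df)
}

# ---- diet formulations -----------------------------------------------------

#' @rdname study_io
#' @details Diet formulations are stored in long form (one row per diet and
#'   ingredient, inclusion on an air-dry basis). Inclusions of each diet must
#'   sum to 100 within 0.05. Logical columns `energy_yielding` and
#'   `test_ingredient` mark the energy-contributing set and the substituted
#'   test ingredient of a test diet.
#' @export
load_diets <- function(path) {
  df <- read_checked(path,
    required = c("diet_id", "role", "ingredient_id", "inclusion_pct"),
    numeric_cols = "inclusion_pct")
  if (!"energy_yielding" %in% names(df)) df$energy_yielding <- TRUE
  if (!"test_ingredient" %in% names(df)) df$test_ingredient <- FALSE
  df$energy_yielding <- as.logical(df$energy_yielding)
  df$test_ingredient <- as.logical(df$test_ingredient)
  validate_diets(df)
  class(df) <- c("diet_table", "data.frame")
  df
}

validate_diets <- function(df) {
  if (!all(df$role %in% c("reference", "test"))) {
    bne_stop("diets: role must be 'reference' or 'test'", "bne_validation_error")
  }
  sums <- tapply(df$inclusion_pct, df$diet_id, sum)
  off <- abs(sums - 100) > 0.05
  if (any(off)) {
    bne_stop(sprintf("diets: inclusions of diet '%s' sum to %.3f, not 100",
                     names(sums)[off][1], sums[off][1]), "bne_validation_error")
  }
  test_diets <- unique(df$diet_id[df$role == "test"])
  for (d in test_diets) {
    sub <- df[df$diet_id == d, ]
    if (sum(sub$test_ingredient) != 1) {
      bne_stop(sprintf("diets: test diet '%s' must flag exactly one test ingredient", d),
               "bne_validation_error")
    }
  }
  invisible(df)
}

#' @rdname study_io
#' @export
load_diet_assays <- function(path) {
  df <- read_checked(path,
    required = c("diet_id", "dm", "ge"),
    numeric_cols = c("dm", "ge", "cp"))
  if (!"cp" %in% names(df)) df$cp <- NA_real_
  if (!"basis" %in% names(df)) df$basis <- "dm"
  check_range(df, "dm", 0, 100, "diet assays", lo_open = TRUE)
  # convert air-dry GE/CP to a DM basis using the assayed DM content
  air <- df$basis == "air_dry"
  df$ge[air] <- df$ge[air] / df$dm[air] * 100
  df$cp[air] <- df$cp[air] / df$dm[air] * 100
  df$basis <- "dm"
  if (any(df$ge <= 0 | df$ge >= 30)) {
    bne_stop("diet assays: GE outside (0, 30) MJ/kg DM", "bne_validation_error")
  }
  class(df) <- c("diet_assay_table", "data.frame")
  df
}

# ---- observations ----------------------------------------------------------

#' @rdname study_io
#' @export
load_cage_obs <- function(path) {
  df <- read_checked(path,
    required = c("run_id", "diet_id", "replicate_id", "n_birds", "days",
                 "bw_initial", "bw_final", "feed_intake_dm", "excreta_dm",
                 "excreta_ge", "feed_n", "excreta_n"),
    numeric_cols = c("n_birds", "days", "bw_initial", "bw_final",
                     "feed_intake_dm", "excreta_dm", "excreta_ge",
                     "feed_n", "excreta_n"))
  validate_obs(df, "cage observations")
  if (any(df$excreta_dm < 0)) {
    bne_stop("cage observations: negative excreta mass", "bne_validation_error")
  }
  class(df) <- c("cage_table", "data.frame")
  df
}

#' @rdname study_io
#' @export
load_chamber_obs <- function(path) {
  df <- read_checked(path,
    required = c("run_id", "diet_id", "chamber_id", "n_birds", "days",
                 "bw_initial", "bw_final", "feed_intake_dm",
                 "o2_consumed", "co2_produced"),
    numeric_cols = c("n_birds", "days", "bw_initial", "bw_final",
                     "feed_intake_dm", "o2_consumed", "co2_produced"))
  validate_obs(df, "chamber observations")
  if (any(df$o2_consumed <= 0)) {
    bne_stop("chamber observations: O2 consumed must be positive",
             "bne_validation_error")
  }
  if (any(df$co2_produced < 0)) {
    bne_stop("chamber observations: negative CO2 volume", "bne_validation_error")
  }
  class(df) <- c("chamber_table", "data.frame")
  df
}

validate_obs <- function(df, what) {
  if (any(df$n_birds < 1) || any(df$days < 1)) {
    bne_stop(sprintf("%s: n_birds and days must be >= 1", what),
             "bne_validation_error")
  }
  if (any(df$bw_final <= 0) || any(df$feed_intake_dm <= 0)) {
    bne_stop(sprintf("%s: bw_final and feed_intake_dm must be positive", what),
             "bne_validation_error")
  }
  invisible(df)
}

# ---- whole-trial bundle ----------------------------------------------------

#' Load a complete trial bundle
#'
#' Reads all component tables of a trial, either from a YAML config file
#' whose `paths:` section names each CSV, or from a named list of paths,
#' and checks referential integrity: every observation's `diet_id` must
#' appear in the diet tables and every formulation `ingredient_id` in the
#' ingredient table.
#'
#' @param config path to a YAML file with a `paths:` section (keys
#'   `ingredients`, `diets`, `diet_assays`, `cage_obs`, `chamber_obs`), or a
#'   named list with those keys.
#' @return a list with elements `ingredients`, `diets`, `diet_assays`,
#'   `cages`, `chambers`.
#' @export
load_trial <- function(config) {
  paths <- if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    p <- cfg$paths %||% cfg
    base <- dirname(config)
    lapply(p, function(f) if (file.exists(f)) f else file.path(base, f))
  } else {
    config
  }
  need <- c("ingredients", "diets", "diet_assays", "cage_obs", "chamber_obs")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0) {
    bne_stop(sprintf("trial config missing component(s): %s",
                     paste(missing, collapse = ", ")), "bne_config_error")
  }
  bundle <- list(
    ingredients = load_ingredients(paths$ingredients),
    diets       = load_diets(paths$diets),
    diet_assays = load_diet_assays(paths$diet_assays),
    cages       = load_cage_obs(paths$cage_obs),
    chambers    = load_chamber_obs(paths$chamber_obs)
  )
  check_bundle_integrity(bundle)
  bundle
}

check_bundle_integrity <- function(bundle) {
  known_diets <- unique(bundle$diets$diet_id)
  for (tab in c("cages", "chambers")) {
    dangling <- setdiff(unique(bundle[[tab]]$diet_id), known_diets)
    if (length(dangling) > 0) {
      bne_stop(sprintf("%s reference unknown diet(s): %s", tab,
                       paste(dangling, collapse = ", ")),
               "bne_referential_error")
    }
  }
  dangling <- setdiff(unique(bundle$diets$ingredient_id),
                      bundle$ingredients$ingredient_id)
  if (length(dangling) > 0) {
    bne_stop(sprintf("diet formulations reference unknown ingredient(s): %s",
                     paste(dangling, collapse = ", ")),
             "bne_referential_error")
  }
  dangling <- setdiff(unique(bundle$cages$diet_id),
                      unique(bundle$diet_assays$diet_id))
  if (length(dangling) > 0) {
    bne_stop(sprintf("no assay for diet(s): %s", paste(dangling, collapse = ", ")),
             "bne_referential_error")
  }
  invisible(bundle)
}

#' Write result tables to a directory
#'
#' Writes each element of a named list of data frames as `<name>.csv` in
#' `path`. Values round-trip: re-reading reproduces them at full printed
#' precision (no rounding is applied on write).
#'
#' @param results named list of data frames (any pipeline output).
#' @param path output directory; created if absent.
#' @return invisibly, the written file paths.
#' @export
write_tables <- function(results, path) {
  if (!is.list(results) || is.null(names(results)) || any(names(results) == "")) {
    bne_stop("write_tables: 'results' must be a named list of data frames",
             "bne_validation_error")
  }
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) bne_stop(sprintf("cannot create directory %s", path), "bne_io_error")
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x)) next
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(x, f, row.names = FALSE, quote = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}
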