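#' NE prediction equation
#'
#' A fitted linear prediction equation for ingredient net energy: an
#' intercept plus named coefficients on composition and/or energy
#' predictors, with its coefficient of determination.
#'
#' @param response name of the predicted quantity (usually `"ne"`).
#' @param intercept intercept, MJ/kg DM.
#' @param terms named numeric vector of coefficients.
#' @param r2 coefficient of determination in `[0, 1]` (`NA` allowed for
#'   equations quoted without a refit).
#' @param n number of observations behind the fit.
#' @param trace optional data frame of enter/remove events from a stepwise
#'   selection.
#' @return an object of class `ne_equation`.
#' @export
ne_equation <- function(response, intercept, terms, r2 = NA_real_,
                        n = NA_integer_, trace = NULL) {
  terms <- unlist(terms)
  if (length(terms) > 0 && is.null(names(terms))) {
    bne_stop("ne_equation: terms must be named", "bne_validation_error")
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) {
    bne_stop("ne_equation: R^2 must lie in [0, 1]", "bne_validation_error")
  }
  structure(list(response = response, intercept = unname(intercept),
                 terms = terms, r2 = r2, n = n, trace = trace),
            class = "ne_equation")
}

#' @export
print.ne_equation <- function(x, digits = 3, ...) {
  rhs <- if (length(x$terms) == 0) "" else paste(
    sprintf("%s %s*%s", ifelse(x$terms < 0, "-", "+"),
            formatC(abs(x$terms), digits = digits, format = "f"),
            toupper(names(x$terms))),
    collapse = " ")
  cat(sprintf("%s = %s %s %s", toupper(x$response), rhs,
              ifelse(x$intercept < 0, "-", "+"),
              formatC(abs(x$intercept), digits = digits, format = "f")))
  if (!is.na(x$r2)) cat(sprintf("   (R^2 = %.3f", x$r2)) else cat("   (")
  if (!is.na(x$n)) cat(sprintf(", n = %d)", x$n)) else cat(")")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.ne_equation <- function(x, ...) {
  out <- data.frame(response = x$response, intercept = x$intercept,
                    r2 = x$r2, n = x$n)
  for (nm in names(x$terms)) out[[nm]] <- unname(x$terms[nm])
  out
}

ols_fit <- function(y, X) {
  dat <- data.frame(.y = y, X, check.names = FALSE)
  stats::lm(.y ~ ., data = dat)
}

#' Bidirectional stepwise regression with a collinearity screen
#'
#' Selects a linear NE prediction equation by bidirectional stepwise least
#' squares. At each forward step the candidate with the smallest partial-F
#' p-value enters if it is below `alpha_enter`; after each entry, any
#' included term whose p-value exceeds `alpha_remove` is removed (largest
#' first). A candidate is barred from entering when its Pearson correlation
#' with any already-included predictor is significant at
#' `collinearity_alpha`, keeping the predictor set mutually uncorrelated;
#' set `collinearity_alpha = 0` to disable the screen (with
#' `alpha_enter = 1` the procedure then reduces to ordinary multiple OLS on
#' all candidates).
#'
#' @param y numeric response (ingredient NE, MJ/kg DM).
#' @param candidates data frame of candidate predictor columns.
#' @param alpha_enter entry threshold on the partial-F p-value.
#' @param alpha_remove removal threshold on an included term's p-value.
#' @param collinearity_alpha significance level of the pairwise predictor
#'   correlation screen.
#' @return an [ne_equation] with a `trace` data frame of enter/remove/block
#'   events. If no candidate passes entry, an intercept-only equation is
#'   returned with a warning.
#' @export
stepwise_fit <- function(y, candidates, alpha_enter = 0.05,
                         alpha_remove = 0.10, collinearity_alpha = 0.05) {
  candidates <- as.data.frame(candidates)
  if (length(y) <= 2) {
    bne_stop("stepwise_fit: need more observations than fitted parameters",
             "bne_validation_error")
  }
  included <- character(0)
  pool <- names(candidates)
  trace <- data.frame(step = integer(0), action = character(0),
                      term = character(0), p_value = numeric(0))
  step_no <- 0
  repeat {
    changed <- FALSE
    # forward step
    best <- NULL
    for (cand in setdiff(pool, included)) {
      if (length(y) <= length(included) + 2) next  # keep residual df >= 1
      blocked <- FALSE
      for (inc in included) {
        ctp <- stats::cor.test(candidates[[cand]], candidates[[inc]])$p.value
        if (collinearity_alpha > 0 && ctp < collinearity_alpha) {
          blocked <- TRUE
          break
        }
      }
      if (blocked) {
        trace <- rbind(trace, data.frame(step = step_no + 1, action = "blocked",
                                         term = cand, p_value = ctp))
        next
      }
      fit <- ols_fit(y, candidates[c(included, cand)])
      pv <- summary(fit)$coefficients
      p_cand <- pv[nrow(pv), 4]
      if (is.finite(p_cand) && p_cand < alpha_enter &&
          (is.null(best) || p_cand < best$p)) {
        best <- list(term = cand, p = p_cand)
      }
    }
    if (!is.null(best)) {
      step_no <- step_no + 1
      included <- c(included, best$term)
      trace <- rbind(trace, data.frame(step = step_no, action = "enter",
                                       term = best$term, p_value = best$p))
      changed <- TRUE
    }
    # backward step(s)
    repeat {
      if (length(included) == 0) break
      fit <- ols_fit(y, candidates[included])
      pv <- summary(fit)$coefficients[-1, 4, drop = TRUE]
      names(pv) <- included
      worst <- names(pv)[which.max(pv)]
      if (max(pv) > alpha_remove) {
        step_no <- step_no + 1
        included <- setdiff(included, worst)
        trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                         term = worst, p_value = max(pv)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(included) == 0) {
    bne_warn("stepwise_fit: no candidate passed the entry threshold; returning intercept-only equation",
             "bne_flagged_warning")
    return(ne_equation(response = "ne", intercept = mean(y), terms = numeric(0),
                       r2 = 0, n = length(y), trace = trace))
  }
  fit <- ols_fit(y, candidates[included])
  cf <- stats::coef(fit)
  ne_equation(response = "ne", intercept = cf[1],
              terms = stats::setNames(cf[-1], included),
              r2 = summary(fit)$r.squared, n = length(y), trace = trace)
}

#' Apply an NE prediction equation
#'
#' Evaluates `intercept + sum(coefficient * predictor)` for each row of
#' `newdata`. Every predictor named in the equation must be present; a
#' missing one raises an error naming it.
#'
#' @param equation an [ne_equation].
#' @param newdata named list, or data frame with one row per prediction,
#'   holding the predictor values (composition on a DM basis and, where the
#'   equation uses them, measured AME/AMEn).
#' @return predicted values, MJ/kg DM.
#' @export
predict_ne <- function(equation, newdata) {
  newdata <- as.data.frame(as.list(newdata))
  missing <- setdiff(names(equation$terms), names(newdata))
  if (length(missing) > 0) {
    bne_stop(sprintf("predict_ne: missing predictor(s): %s",
                     paste(missing, collapse = ", ")), "bne_validation_error")
  }
  out <- rep(equation$intercept, nrow(newdata))
  for (nm in names(equation$terms)) {
    v <- newdata[[nm]]
    if (anyNA(v)) {
      bne_stop(sprintf("predict_ne: predictor '%s' has missing values", nm),
               "bne_validation_error")
    }
    out <- out + equation$terms[[nm]] * v
  }
  out
}

#' Predicted-versus-measured validation
#'
#' Pairs the equation's predictions with measured NE values and reports
#' their Pearson correlation. With `training` supplied, the training points
#' are pooled with the holdout points before correlating (the pooled mode
#' used when a single validation sample is plotted alongside the fitted
#' panel).
#'
#' @param equation an [ne_equation].
#' @param data data frame of predictor values for the holdout samples.
#' @param measured measured NE of the holdout samples, MJ/kg DM.
#' @param training optional list with elements `data` and `measured` for the
#'   fitted panel, pooled into the comparison.
#' @return an object of class `ne_validation`: data frame `pairs` with
#'   columns `measured`, `predicted`, `set` and the pooled `pearson_r`.
#' @export
validate_equation <- function(equation, data, measured, training = NULL) {
  pairs <- data.frame(measured = measured,
                      predicted = predict_ne(equation, data),
                      set = "holdout")
  if (!is.null(training)) {
    pairs <- rbind(data.frame(measured = training$measured,
                              predicted = predict_ne(equation, training$data),
                              set = "training"),
                   pairs)
  }
  if (nrow(pairs) < 2) {
    bne_stop("validate_equation: need at least two points", "bne_validation_error")
  }
  if (stats::var(pairs$predicted) == 0 || stats::var(pairs$measured) == 0) {
    bne_warn("validate_equation: constant predictions or measurements; r undefined",
             "bne_degenerate_warning")
    r <- NA_real_
  } else {
    r <- stats::cor(pairs$measured, pairs$predicted)
  }
  structure(list(pairs = pairs, pearson_r = r), class = "ne_validation")
}

#' @export
print.ne_validation <- function(x, ...) {
  cat(sprintf("Predicted vs measured NE: %d points, Pearson r = %s\n",
              nrow(x$pairs),
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Scatter plot of predicted versus measured NE
#'
#' Measured NE on the x axis, predicted on the y axis, identity line for
#' reference; holdout points are drawn as triangles, training points as
#' circles.
#'
#' @param x an `ne_validation` object.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot_validation <- function(x, ...) {
  p <- x$pairs
  rng <- range(c(p$measured, p$predicted))
  plot(p$measured, p$predicted,
       pch = ifelse(p$set == "holdout", 17, 1),
       xlim = rng, ylim = rng,
       xlab = "Measured NE (MJ/kg DM)", ylab = "Predicted NE (MJ/kg DM)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
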