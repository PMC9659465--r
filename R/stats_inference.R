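#' Pairwise Pearson correlation matrix
#'
#' Pearson correlations between all column pairs of a numeric table, with
#' two-sided t-test p-values, computed on pairwise-complete observations.
#' A zero-variance column yields `NA` correlations for its pairs with a
#' warning.
#'
#' @param table a data frame or matrix of named numeric columns, at least
#'   3 rows and 2 columns.
#' @return an object of class `correlation_matrix`: list with `variables`,
#'   symmetric matrices `r` and `p`, and pair count matrix `n`.
#' @export
pearson_matrix <- function(table) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[num]
  if (nrow(table) < 3 || ncol(table) < 2) {
    bne_stop("pearson_matrix: need at least 3 rows and 2 numeric columns",
             "bne_validation_error")
  }
  vars <- names(table)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  degenerate <- character(0)
  for (i in seq_len(k)) {
    r[i, i] <- 1; p[i, i] <- 0; n[i, i] <- sum(!is.na(table[[i]]))
    for (j in seq_len(k)) {
      if (j >= i) next
      ok <- stats::complete.cases(table[[i]], table[[j]])
      xi <- table[[i]][ok]; xj <- table[[j]][ok]
      n[i, j] <- n[j, i] <- length(xi)
      if (length(xi) < 3 || stats::var(xi) == 0 || stats::var(xj) == 0) {
        degenerate <- union(degenerate,
                            vars[c(i, j)[c(stats::var(xi) == 0, stats::var(xj) == 0)]])
        next
      }
      ct <- stats::cor.test(xi, xj, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (length(degenerate) > 0) {
    bne_warn(sprintf("pearson_matrix: zero-variance column(s): %s",
                     paste(degenerate, collapse = ", ")),
             "bne_degenerate_warning")
  }
  structure(list(variables = vars, r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (", length(x$variables), " variables)\n", sep = "")
  stars <- ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))
  out <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), stars),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  out[is.na(x$r)] <- "."
  out[upper.tri(out)] <- ""
  print(out, quote = FALSE)
  invisible(x)
}

#' One-way ANOVA with Duncan's multiple-range grouping
#'
#' Fits a one-way fixed-effects ANOVA across treatment groups and labels the
#' group means with Duncan's multiple-range letters at level `alpha`. The
#' pooled SEM is `sqrt(MSE / harmonic mean group size)`.
#'
#' @param groups a named list of numeric vectors, one per treatment; at
#'   least two groups of at least two replicates each.
#' @param alpha significance level for the F test and the range test.
#' @return an object of class `anova_result`: group names, means, `f_stat`,
#'   `p_value`, `mse`, `df_error`, `pooled_sem`, `duncan_letters`, and a
#'   `degenerate` flag set when the within-group mean square is zero.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) {
    bne_stop("one_way_anova: need at least two groups", "bne_validation_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ni <- lengths(groups)
  if (any(ni < 2)) {
    bne_stop("one_way_anova: every group needs at least two replicates",
             "bne_validation_error")
  }
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ni), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = dat)
  tab <- stats::anova(fit)
  mse <- tab["Residuals", "Mean Sq"]
  df_error <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, numeric(1))
  degenerate <- mse == 0
  if (degenerate) {
    bne_warn("one_way_anova: zero within-group variance; F and p degenerate",
             "bne_degenerate_warning")
  }
  letters <- duncan_groups(means, mse = mse, df_error = df_error,
                           n_per_group = ni, alpha = alpha)
  structure(list(
    groups = names(groups), means = means,
    f_stat = tab["group", "F value"], p_value = tab["group", "Pr(>F)"],
    mse = mse, df_error = df_error,
    pooled_sem = sqrt(mse / (length(ni) / sum(1 / ni))),
    duncan_letters = letters, alpha = alpha, degenerate = degenerate
  ), class = "anova_result")
}

#' Duncan's multiple-range letters
#'
#' Assigns compact letter groupings by Duncan's multiple-range test. Means
#' are ordered descending; a stretch of `p` ordered means is declared
#' non-significant when the difference of its extremes is below the critical
#' range `q(p, df, protection level (1-alpha)^(p-1)) * sqrt(MSE/n)`, with
#' the studentized-range quantile taken from [stats::qtukey] (no table
#' lookups). Means covered by a common non-significant stretch share a
#' letter. Unequal group sizes are handled by their harmonic mean, with a
#' warning.
#'
#' @param means named numeric vector of group means.
#' @param mse error (within-group) mean square.
#' @param df_error error degrees of freedom (>= 1).
#' @param n_per_group replicates per group (scalar or per-group vector).
#' @param alpha significance level.
#' @return character vector of letter labels, named and ordered as `means`.
#' @export
duncan_groups <- function(means, mse, df_error, n_per_group, alpha = 0.05) {
  if (df_error < 1) {
    bne_stop("duncan_groups: df_error must be >= 1", "bne_domain_error")
  }
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  if (length(unique(n_per_group)) > 1) {
    bne_warn("duncan_groups: unequal group sizes; using harmonic mean n",
             "bne_flagged_warning")
  }
  n_h <- length(n_per_group) / sum(1 / n_per_group)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  # critical range for a stretch spanning p ordered means
  crit <- function(p) {
    q <- suppressWarnings(
      stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df_error))
    if (is.nan(q)) q <- Inf   # protection level ~1: no range is significant
    q * sqrt(mse / n_h)
  }
  # furthest index reachable from i through a non-significant stretch
  reach <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (m[i] - m[j + 1]) <= crit(j + 2 - i)) j <- j + 1
    reach[i] <- j
  }
  # maximal non-significant stretches (those not nested in an earlier one)
  # each receive one letter; a mean carries the letters of all stretches
  # covering it
  labels <- rep("", k)
  letter_idx <- 0
  best_end <- 0
  for (i in seq_len(k)) {
    if (reach[i] > best_end || i > best_end) {
      letter_idx <- letter_idx + 1
      if (letter_idx > length(letters)) {
        bne_stop("duncan_groups: more than 26 letter groups", "bne_domain_error")
      }
      cover <- seq(i, reach[i])
      labels[cover] <- paste0(labels[cover], letters[letter_idx])
      best_end <- max(best_end, reach[i])
    }
  }
  names(labels) <- names(m)
  labels[match(names(means), names(labels))]
}
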