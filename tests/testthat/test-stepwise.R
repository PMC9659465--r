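test_that("noise-free single-predictor structure is recovered exactly", {
  set.seed(21)
  x <- rnorm(12, 10, 2)
  cands <- data.frame(x = x, n1 = rnorm(12), n2 = rnorm(12))
  eq <- stepwise_fit(3 * x - 2, cands)
  expect_equal(names(eq$terms), "x")
  expect_equal(unname(eq$terms["x"]), 3, tolerance = 1e-9)
  expect_equal(eq$intercept, -2, tolerance = 1e-8)
  expect_equal(eq$r2, 1, tolerance = 1e-12)
})

test_that("stepwise with open thresholds equals ordinary least squares", {
  set.seed(33)
  n <- 30
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1.5 * X$a - 0.7 * X$b + 0.2 * X$c + rnorm(n, sd = 0.3)
  eq <- stepwise_fit(y, X, alpha_enter = 1, alpha_remove = 1,
                     collinearity_alpha = 0)
  # independent oracle: normal-equations solve
  M <- cbind(1, as.matrix(X))
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(eq$intercept, beta[1], tolerance = 1e-8)
  expect_equal(unname(eq$terms[c("a", "b", "c")]), unname(beta[2:4, 1]),
               tolerance = 1e-8)
  # residuals orthogonal to every included predictor
  resid <- y - predict_ne(eq, X)
  for (v in names(X)) expect_lt(abs(sum(resid * X[[v]])), 1e-8)
})

test_that("the collinearity screen blocks redundant correlated predictors", {
  set.seed(55)
  latent <- rnorm(40)
  cands <- data.frame(p1 = latent + rnorm(40, sd = 0.05),
                      p2 = latent + rnorm(40, sd = 0.05))
  y <- latent + rnorm(40, sd = 0.1)
  eq <- stepwise_fit(y, cands)
  expect_equal(length(eq$terms), 1)        # second predictor barred
  expect_true(any(eq$trace$action == "blocked"))
  # with the screen disabled both may enter
  eq2 <- stepwise_fit(y, cands, alpha_enter = 1, alpha_remove = 1,
                      collinearity_alpha = 0)
  expect_equal(length(eq2$terms), 2)
})

test_that("wheat panel selects AME and ADF with the trial's coefficients", {
  en <- study_ingredient_energy("wheat")
  comp <- study_ingredients("wheat", experiment = 2)
  cands <- data.frame(ame = en$ame, amen = en$amen, cp = comp$cp,
                      ee = comp$ee, cf = comp$cf, ndf = comp$ndf,
                      adf = comp$adf, st = comp$st)
  eq <- stepwise_fit(en$ne, cands)
  expect_setequal(names(eq$terms), c("ame", "adf"))
  expect_equal(unname(eq$terms["ame"]), 1.9684, tolerance = 1e-3)
  expect_equal(unname(eq$terms["adf"]), -0.4105, tolerance = 1e-3)
  expect_equal(eq$intercept, -14.2273, tolerance = 1e-3)
  expect_gt(eq$r2, 0.99)
  # AMEn was the second-best single predictor but is collinear with AME
  blocked <- eq$trace$term[eq$trace$action == "blocked"]
  expect_true("amen" %in% blocked)
})

test_that("pure-noise candidates give an intercept-only equation", {
  set.seed(77)
  y <- rnorm(10)
  cands <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_warning(eq <- stepwise_fit(y, cands), class = "bne_flagged_warning")
  expect_equal(length(eq$terms), 0)
  expect_equal(eq$intercept, mean(y))
})

test_that("coefficient recovery is unbiased on synthetic linear panels", {
  set.seed(99)
  reps <- 500
  b1 <- b2 <- numeric(reps)
  for (i in seq_len(reps)) {
    x1 <- rnorm(20); x2 <- rnorm(20)
    y <- 2 * x1 - 0.5 * x2 + rnorm(20, sd = 0.5)
    eq <- stepwise_fit(y, data.frame(x1 = x1, x2 = x2),
                       alpha_enter = 1, alpha_remove = 1,
                       collinearity_alpha = 0)
    b1[i] <- eq$terms["x1"]; b2[i] <- eq$terms["x2"]
  }
  # Monte-Carlo means within 2 standard errors of the truth
  expect_lt(abs(mean(b1) - 2) / (sd(b1) / sqrt(reps)), 2)
  expect_lt(abs(mean(b2) + 0.5) / (sd(b2) / sqrt(reps)), 2)
})

test_that("prediction evaluates the linear form and names missing inputs", {
  eq <- ne_equation("ne", intercept = 20.87,
                    terms = c(cp = -0.362, cf = -0.382, adf = -0.244))
  expect_equal(predict_ne(eq, data.frame(cp = 18.30, cf = 13.96, adf = 15.78)),
               5.0624, tolerance = 1e-4)
  expect_error(predict_ne(eq, data.frame(cp = 18, cf = 14)),
               "adf")
  # intercept-only equation returns the intercept for any input
  eq0 <- ne_equation("ne", intercept = 7.5, terms = numeric(0))
  expect_equal(predict_ne(eq0, data.frame(anything = 0)), 7.5)
})

test_that("validation correlates predicted with measured values", {
  eq <- ne_equation("ne", intercept = 0, terms = c(x = 2))
  # points exactly on the fitted plane: r = 1
  d <- data.frame(x = 1:4)
  v <- validate_equation(eq, d, measured = 2 * (1:4))
  expect_equal(v$pearson_r, 1)
  # anti-correlated toy pairs: r = -1
  v2 <- validate_equation(eq, d, measured = -2 * (1:4))
  expect_equal(v2$pearson_r, -1)
  # constant predictions: r absent with a warning
  eqc <- ne_equation("ne", intercept = 5, terms = numeric(0))
  expect_warning(v3 <- validate_equation(eqc, d, measured = c(1, 2, 3, 4)),
                 class = "bne_degenerate_warning")
  expect_true(is.na(v3$pearson_r))
})

test_that("wheat validation pooled with the training panel gives r near 0.96", {
  eq <- study_equations()$wheat
  train_en <- study_ingredient_energy("wheat")
  train_comp <- study_ingredients("wheat", experiment = 2)
  train <- data.frame(ame = train_en$ame, adf = train_comp$adf)
  hold <- data.frame(ame = 13.79, adf = 4.78)
  v <- validate_equation(eq, hold, measured = 10.48,
                         training = list(data = train,
                                         measured = train_en$ne))
  expect_equal(v$pearson_r, 0.9593, tolerance = 1e-3)
  expect_equal(nrow(v$pairs), 6)
})
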