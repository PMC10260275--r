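test_that("lateralization index: arithmetic, antisymmetry, scale invariance", {
  expect_equal(lateralization_index(3, 3), 0)
  expect_equal(lateralization_index(3, 2), 0.4)
  expect_equal(lateralization_index(2, 3), -0.4)
  set.seed(3)
  r <- runif(50, 0.5, 5); l <- runif(50, 0.5, 5)
  expect_equal(lateralization_index(r, l), -lateralization_index(l, r))
  expect_equal(lateralization_index(3 * r, 3 * l), lateralization_index(r, l))
  # denominator guard: missing value, never infinity
  expect_true(is.na(lateralization_index(1e-9, -1e-9, guard_eps = 1e-6)))
  expect_true(all(is.finite(lateralization_index(r, l))))
})

test_that("identical cells everywhere give F = 0 for every effect", {
  arr <- array(1.7, c(4, 3, 2),
               dimnames = list(NULL, c("immediate", "12h", "24h"),
                               c("neutral", "emotional")))
  res <- rm_anova_d(arr)
  expect_equal(res$effects$F, c(0, 0, 0))
})

test_that("RM-ANOVA F statistics match the brute-force oracle", {
  for (seed in 1:20) {
    arr <- rand_array(4, seed)
    got <- rm_anova_d(arr)$effects
    want <- rm_anova_oracle(arr)
    expect_equal(got$F, unname(want[got$effect]), tolerance = 1e-10)
  }
  # the reported dfs carry the within-subject error structure
  got <- rm_anova_d(rand_array(12, 99))$effects
  expect_equal(got$df1, c(2, 1, 2))
  expect_equal(got$df2, c(22, 11, 22))
})

test_that("the retrieval decline shows up as a strong time effect", {
  spec <- simulation_spec()
  hits <- 0L
  for (seed in 1:5) {
    sc <- simulate_score_cohort(spec, seed = 200 + seed)
    res <- rm_anova_d(sc$d_array)
    eff <- res$effects
    hits <- hits + (eff$p[eff$effect == "time"] < 0.05)
    expect_equal(eff$df2[eff$effect == "time"], 62)   # n = 32
  }
  expect_gte(hits, 5L)
})

test_that("contrast-regression t^2 equals the ANCOVA F for 1-df effects", {
  spec <- simulation_spec()
  sc <- simulate_score_cohort(spec, seed = 3)
  cov <- sc$covariates
  res <- rm_ancova_d(sc$d_array, cov$coupling_lat_true, cov, "model1")
  expect_equal(res$df1, c(1, 2, 1, 2))
  expect_equal(res$df2, c(27, 54, 27, 54))            # n - 5 parameters
  emo <- (sc$d_array[, , 1] - sc$d_array[, , 2])
  delta <- rowMeans(emo)
  fr <- followup_regression(delta, cov$coupling_lat_true, cov, "model1")
  expect_equal(fr$t^2, res$F[res$effect == "x_emotion"], tolerance = 1e-9)
})

test_that("the ANCOVA flags collinear controls", {
  spec <- simulation_spec()
  sc <- simulate_score_cohort(spec, seed = 4)
  cov <- sc$covariates
  cov$sleep_h <- 2 * cov$bdi_ln + 1                   # perfectly collinear
  expect_error(rm_ancova_d(sc$d_array, cov$coupling_lat_true, cov, "model2"),
               "collinear")
})

test_that("Model 2 consumes the questionnaire controls and imputes gaps", {
  spec <- simulation_spec()
  sc <- simulate_score_cohort(spec, seed = 5)
  cov <- sc$covariates
  cov$bdi_ln[3] <- NA                                 # mean-imputed
  res <- rm_ancova_d(sc$d_array, cov$coupling_lat_true, cov, "model2")
  expect_equal(res$df2, c(25, 50, 25, 50))            # n - 7 parameters
  expect_true(all(is.finite(res$F)))
})

test_that("follow-up regression recovers an exact linear relation", {
  set.seed(6)
  x <- rnorm(30)
  fr <- suppressWarnings(followup_regression(2 * x, x))  # perfect-fit lm note
  expect_equal(fr$coefficient, 2, tolerance = 1e-10)
  expect_lt(fr$p, 1e-12)
})

test_that("a prior-delta confound absorbs the predictor's effect", {
  set.seed(7)
  prior <- rnorm(40)
  pred <- prior + rnorm(40, sd = 0.3)                 # correlated with prior
  delta <- prior + rnorm(40, sd = 0.05)               # fully explained by prior
  t_without <- abs(followup_regression(delta, pred)$t)
  t_with <- abs(followup_regression(delta, pred, prior_delta = prior)$t)
  expect_lt(t_with, t_without / 3)
  expect_lt(t_with, 2)
})

test_that("rank deficiency in the follow-up design is a diagnostics error", {
  set.seed(8)
  x <- rnorm(20)
  expect_error(followup_regression(rnorm(20), x, prior_delta = x),
               "rank-deficient")
})

test_that("preliminary screens: correlations, group tests, outliers", {
  set.seed(9)
  n <- 40
  df <- data.frame(sex = rep(c("F", "M"), each = n / 2),
                   v = rep(rnorm(n / 2), 2),          # identical across groups
                   x = rnorm(n))
  df$y <- df$x                                        # exact linear relation
  df$const <- 1
  scr <- preliminary_screens(df, vars = c("v", "x", "const"),
                             group_vars = "sex",
                             cor_pairs = rbind(c("x", "y"), c("x", "const")),
                             chisq_pair = c("sex", "sex"))
  gv <- scr$group_tests[scr$group_tests$variable == "v", ]
  expect_gt(gv$p, 0.5)                                # identical group means
  expect_equal(scr$correlations$r[1], 1)
  expect_true(is.na(scr$correlations$r[2]))           # constant: undefined
  expect_true(is.na(scr$group_tests$p[scr$group_tests$variable == "const"]))
  expect_false(any(scr$outliers$flagged[scr$outliers$variable == "v"]))

  # a planted extreme value is flagged at |z| > 3, a milder one is not
  base <- rnorm(60)
  base <- (base - mean(base)) / sd(base)
  df2 <- data.frame(w = c(base, 6), u = c(base, 2.0))
  scr2 <- preliminary_screens(df2, vars = c("w", "u"), group_vars = character(0))
  z_w <- scr2$outliers$z[scr2$outliers$variable == "w"]
  z_u <- scr2$outliers$z[scr2$outliers$variable == "u"]
  expect_true(abs(z_w[61]) > 3 &&
                scr2$outliers$flagged[scr2$outliers$variable == "w"][61])
  expect_true(abs(z_u[61]) < 3 &&
                !scr2$outliers$flagged[scr2$outliers$variable == "u"][61])
  expect_equal(scr2$outliers$flagged,
               !is.na(scr2$outliers$z) & abs(scr2$outliers$z) > 3)
})
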