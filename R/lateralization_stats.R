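# Lateralization indices and the repeated-measures statistical battery:
# two-way RM-ANOVA on d', RM-ANCOVA with a continuous oscillatory
# covariate (within-subject contrast regression), follow-up
# difference-score regressions, and preliminary confounder screens.

#' Right-versus-left lateralization index
#'
#' `(right - left) / ((right + left) / 2)`: positive values mean
#' right-hemisphere dominance. When the denominator magnitude falls below
#' `guard_eps` the index is returned as `NA` (flagged missing, never
#' infinite).
#'
#' @param right,left hemisphere values (vectorized).
#' @param guard_eps minimum |mean| for a defined index.
#' @return index values, `NA` where guarded.
#' @export
lateralization_index <- function(right, left, guard_eps = 1e-6) {
  m <- (right + left) / 2
  out <- (right - left) / m
  out[!is.finite(out) | abs(m) < guard_eps] <- NA_real_
  out
}

d_long <- function(d_array) {
  n <- dim(d_array)[1]
  data.frame(
    subject = factor(rep(seq_len(n), times = 6L)),
    retrieval = factor(rep(rep(RETRIEVALS, each = n), times = 2L),
                       levels = RETRIEVALS),
    emotion = factor(rep(EMOTIONS, each = 3L * n), levels = EMOTIONS),
    d = as.vector(d_array))
}

#' Two-way repeated-measures ANOVA on d'
#'
#' Within-subject factors retrieval time (3 levels) and emotion (2 levels);
#' univariate F tests with no sphericity correction, each effect tested
#' against its own subject-by-effect error stratum. Bonferroni-corrected
#' paired comparisons follow up the time effect (on emotion-pooled d') and
#' the emotion effect within each retrieval.
#'
#' @param d_array numeric array `n x 3 x 2` (subject x retrieval x emotion),
#'   complete cases.
#' @return list with `effects` (data.frame: effect, F, df1, df2, p,
#'   eta_p_sq), `posthoc_time`, `posthoc_emotion_within_time`.
#' @export
rm_anova_d <- function(d_array) {
  n <- dim(d_array)[1]
  if (n < 3L) stop("repeated-measures ANOVA needs at least 3 subjects",
                   call. = FALSE)
  if (anyNA(d_array)) stop("d' array must be complete", call. = FALSE)
  if (stats::sd(d_array) == 0) {
    # degenerate input: no variance anywhere, every effect is exactly null
    effects <- data.frame(effect = c("time", "emotion", "time_x_emotion"),
                          F = 0, df1 = c(2, 1, 2), df2 = (n - 1) * c(2, 1, 2),
                          p = 1, eta_p_sq = 0, stringsAsFactors = FALSE)
    ph0 <- data.frame(contrast = character(0), t = numeric(0),
                      p_raw = numeric(0), p_bonf = numeric(0))
    return(list(effects = effects, posthoc_time = ph0,
                posthoc_emotion_within_time = ph0))
  }
  df <- d_long(d_array)
  fit <- stats::aov(d ~ retrieval * emotion +
                      Error(subject / (retrieval * emotion)), data = df)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    i <- i[trimws(rownames(tab))[i] == term][1]
    err <- grep("Residuals", rownames(tab))
    ss_h <- tab[i, "Sum Sq"]; ss_e <- tab[err, "Sum Sq"]
    Fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
    if (!is.finite(Fv) && ss_h < 1e-12) { Fv <- 0; pv <- 1 }  # degenerate data
    c(F = Fv, df1 = tab[i, "Df"], df2 = tab[err, "Df"], p = pv,
      eta = if (ss_h + ss_e > 0) ss_h / (ss_h + ss_e) else 0)
  }
  rows <- rbind(
    time = grab("Error: subject:retrieval", "retrieval"),
    emotion = grab("Error: subject:emotion", "emotion"),
    time_x_emotion = grab("Error: subject:retrieval:emotion",
                          "retrieval:emotion"))
  effects <- data.frame(effect = rownames(rows), F = rows[, "F"],
                        df1 = rows[, "df1"], df2 = rows[, "df2"],
                        p = rows[, "p"], eta_p_sq = rows[, "eta"],
                        row.names = NULL, stringsAsFactors = FALSE)

  pooled <- apply(d_array, c(1, 2), mean)     # n x 3, over emotions
  combs <- utils::combn(3L, 2L)
  ph_time <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    tt <- stats::t.test(pooled[, a], pooled[, b], paired = TRUE)
    data.frame(contrast = paste(RETRIEVALS[a], "-", RETRIEVALS[b]),
               t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  ph_time$p_bonf <- pmin(1, ph_time$p_raw * nrow(ph_time))
  ph_emo <- do.call(rbind, lapply(seq_len(3L), function(r) {
    tt <- stats::t.test(d_array[, r, 1], d_array[, r, 2], paired = TRUE)
    data.frame(retrieval = RETRIEVALS[r], t = unname(tt$statistic),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  ph_emo$p_bonf <- pmin(1, ph_emo$p_raw * nrow(ph_emo))
  list(effects = effects, posthoc_time = ph_time,
       posthoc_emotion_within_time = ph_emo)
}

# orthonormal within-subject contrast matrices over the 6 cells,
# cell order = retrieval fastest within emotion (matches scores_array)
ws_contrasts <- function() {
  P3 <- stats::contr.poly(3)                 # orthonormal columns
  e2 <- c(1, -1) / sqrt(2)
  list(mean = matrix(rep(1 / sqrt(6), 6), ncol = 1),
       time = kronecker(rep(1, 2) / sqrt(2), P3),
       emotion = kronecker(matrix(e2, ncol = 1), rep(1, 3) / sqrt(3)),
       time_x_emotion = kronecker(matrix(e2, ncol = 1), P3))
}

build_controls_matrix <- function(controls, model = c("model1", "model2"), n) {
  model <- match.arg(model)
  if (is.null(controls)) return(matrix(numeric(0), nrow = n, ncol = 0))
  need <- c("sex", "location", "sleep_h")
  if (model == "model2") need <- c(need, "bdi_ln", "gad7_ln")
  miss <- setdiff(need, names(controls))
  if (length(miss))
    stop("controls missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cc <- controls[need]
  for (v in need) {                          # mean-impute missing numerics
    if (is.numeric(cc[[v]]) && anyNA(cc[[v]]))
      cc[[v]][is.na(cc[[v]])] <- mean(cc[[v]], na.rm = TRUE)
    if (!is.numeric(cc[[v]])) cc[[v]] <- factor(cc[[v]])
  }
  X <- stats::model.matrix(~ ., data = cc)
  X[, -1, drop = FALSE]                      # intercept added by caller
}

#' Repeated-measures ANCOVA with a continuous oscillatory covariate
#'
#' Tests a subject-level covariate (an oscillatory or lateralization
#' variable) against overall d' and against the within-subject contrasts
#' for time, emotion and time x emotion, controlling for sex, measurement
#' location and sleep duration (Model 1; Model 2 adds log-transformed BDI
#' and GAD-7, with missing questionnaire scores mean-imputed).
#'
#' Implementation: the d' cells are projected onto orthonormal
#' within-subject contrasts; each contrast set is regressed on the
#' (mean-centered) covariate plus controls, and the covariate's extra sum
#' of squares is pooled across the contrast columns, giving the averaged
#' univariate F with `df1 = k`, `df2 = k (n - p)`. For single-df effects
#' this F equals the squared t of the contrast regression.
#'
#' @param d_array numeric `n x 3 x 2` array of d' (complete cases).
#' @param covariate numeric subject-level covariate, length n.
#' @param controls data.frame of subject covariates (`sex`, `location`,
#'   `sleep_h`, and for Model 2 `bdi_ln`, `gad7_ln`); `NULL` for an
#'   unadjusted model.
#' @param model `"model1"` or `"model2"`.
#' @param max_kappa condition-number threshold for the design matrix.
#' @return data.frame: `effect` (main, x_time, x_emotion,
#'   x_time_x_emotion), `F`, `df1`, `df2`, `p`, `eta_p_sq`.
#' @export
rm_ancova_d <- function(d_array, covariate, controls = NULL,
                        model = "model1", max_kappa = 1e8) {
  n <- dim(d_array)[1]
  if (anyNA(d_array)) stop("d' array must be complete", call. = FALSE)
  if (length(covariate) != n)
    stop("covariate must have one value per subject", call. = FALSE)
  if (anyNA(covariate)) covariate[is.na(covariate)] <- mean(covariate, na.rm = TRUE)
  cov_c <- covariate - mean(covariate)
  Xc <- build_controls_matrix(controls, model, n)
  X_full <- cbind(`(Intercept)` = 1, covariate = cov_c, Xc)
  X_red <- cbind(`(Intercept)` = 1, Xc)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full) || kappa(X_full) > max_kappa) {
    drop <- if (qr_full$rank < ncol(X_full))
      colnames(X_full)[qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]]
    else colnames(X_full)[-1]
    stop("collinear/ill-conditioned design; offending columns: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  qr_red <- qr(X_red)
  p_full <- ncol(X_full)
  Y <- matrix(d_array, nrow = n)             # n x 6, retrieval fastest
  C <- ws_contrasts()
  eff_names <- c(main = "mean", x_time = "time", x_emotion = "emotion",
                 x_time_x_emotion = "time_x_emotion")
  rows <- lapply(names(eff_names), function(nm) {
    Z <- Y %*% C[[eff_names[nm]]]
    k <- ncol(Z)
    rss_full <- colSums(qr.resid(qr_full, Z)^2)
    rss_red <- colSums(qr.resid(qr_red, Z)^2)
    ss_hyp <- sum(rss_red - rss_full)
    ss_err <- sum(rss_full)
    df1 <- k
    df2 <- k * (n - p_full)
    Fv <- (ss_hyp / df1) / (ss_err / df2)
    data.frame(effect = nm, F = Fv, df1 = df1, df2 = df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               eta_p_sq = ss_hyp / (ss_hyp + ss_err),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Follow-up difference-score regression
#'
#' Ordinary least squares of a difference score on the oscillatory
#' predictor plus the model's controls; when the difference score comes
#' from a later retrieval the matching earlier difference score is added
#' as a further control, isolating the change between retrievals.
#'
#' @param delta numeric difference scores, one per subject.
#' @param predictor numeric oscillatory/lateralization variable.
#' @param controls optional data.frame as in [rm_ancova_d()].
#' @param model `"model1"` or `"model2"` (ignored when `controls` is NULL).
#' @param prior_delta optional earlier-retrieval difference score control.
#' @return list: `coefficient`, `t`, `p`, `df`, `n`.
#' @export
followup_regression <- function(delta, predictor, controls = NULL,
                                model = "model1", prior_delta = NULL) {
  n <- length(delta)
  Xc <- build_controls_matrix(controls, model, n)
  dat <- data.frame(delta = delta, predictor = predictor)
  if (!is.null(prior_delta)) dat$prior_delta <- prior_delta
  X <- cbind(dat[-1], as.data.frame(Xc))
  keep <- stats::complete.cases(dat)
  fit <- stats::lm(delta ~ ., data = cbind(dat["delta"], X), subset = keep)
  if (any(is.na(coef(fit))))
    stop("rank-deficient follow-up design: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  cf <- summary(fit)$coefficients
  list(coefficient = cf["predictor", "Estimate"],
       t = cf["predictor", "t value"],
       p = cf["predictor", "Pr(>|t|)"],
       df = fit$df.residual, n = sum(keep))
}

#' Preliminary confounder screens
#'
#' One-way ANOVA of each candidate variable over each grouping factor,
#' Pearson correlations for requested variable pairs, an optional
#' chi-squared test of two categorical columns, and |z| > 3 outlier flags.
#' Constant variables yield `NA` (undefined) rather than an error.
#'
#' @param data subject-level data.frame.
#' @param vars numeric columns to screen.
#' @param group_vars grouping factor columns (e.g. sex, location).
#' @param cor_pairs optional 2-column character matrix of variable pairs to
#'   correlate.
#' @param chisq_pair optional length-2 character vector of categorical
#'   columns for a chi-squared association test.
#' @param outlier_z |z| threshold for outlier flagging.
#' @return list: `group_tests`, `correlations`, `chisq`, `outliers`.
#' @export
preliminary_screens <- function(data, vars, group_vars,
                                cor_pairs = NULL, chisq_pair = NULL,
                                outlier_z = 3) {
  gt <- list()
  for (g in group_vars) for (v in vars) {
    x <- data[[v]]; grp <- factor(data[[g]])
    ok <- is.finite(x) & !is.na(grp)
    res <- if (length(unique(grp[ok])) < 2L || stats::sd(x[ok]) == 0 ||
               min(table(grp[ok])) < 3L)
      c(NA_real_, NA_real_)
    else {
      a <- stats::anova(stats::lm(x[ok] ~ grp[ok]))
      c(a$`F value`[1], a$`Pr(>F)`[1])
    }
    gt[[length(gt) + 1L]] <- data.frame(variable = v, group = g,
                                        F = res[1], p = res[2],
                                        stringsAsFactors = FALSE)
  }
  cors <- NULL
  if (!is.null(cor_pairs)) {
    cors <- do.call(rbind, lapply(seq_len(nrow(cor_pairs)), function(i) {
      x <- data[[cor_pairs[i, 1]]]; y <- data[[cor_pairs[i, 2]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(data.frame(x = cor_pairs[i, 1], y = cor_pairs[i, 2],
                          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
      ct <- stats::cor.test(x[ok], y[ok])
      data.frame(x = cor_pairs[i, 1], y = cor_pairs[i, 2],
                 r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  chi <- NULL
  if (!is.null(chisq_pair)) {
    tab <- table(data[[chisq_pair[1]]], data[[chisq_pair[2]]])
    ct <- suppressWarnings(stats::chisq.test(tab))
    chi <- data.frame(x = chisq_pair[1], y = chisq_pair[2],
                      statistic = unname(ct$statistic), p = ct$p.value,
                      stringsAsFactors = FALSE)
  }
  outliers <- do.call(rbind, lapply(vars, function(v) {
    x <- data[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) rep(NA_real_, length(x))
    else (x - mean(x, na.rm = TRUE)) / s
    data.frame(variable = v, row = seq_along(x), z = z,
               flagged = !is.na(z) & abs(z) > outlier_z,
               stringsAsFactors = FALSE)
  }))
  list(group_tests = do.call(rbind, gt), correlations = cors, chisq = chi,
       outliers = outliers)
}
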