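#' Verbal and non-verbal developmental quotients
#'
#' From Mullen age-equivalent (AE) subscale scores:
#' `VDQ = ((RL + EL)/2) / age_months * 100` and
#' `NVDQ = ((VR + FM)/2) / age_months * 100`. Missing inputs yield missing
#' outputs (never imputed).
#'
#' @param ae_scores data.frame or list with columns/fields RL, EL, VR, FM
#'   (age-equivalent months); GM is carried but unused.
#' @param age_months chronological age in months (> 0).
#' @return data.frame with VDQ and NVDQ.
#' @examples
#' compute_dq(data.frame(RL = 24, EL = 26, VR = 30, FM = 20), age_months = 25)
#' @export
compute_dq <- function(ae_scores, age_months) {
  if (any(age_months <= 0)) stop("age_months must be positive")
  vdq <- ((ae_scores$RL + ae_scores$EL) / 2) / age_months * 100
  nvdq <- ((ae_scores$VR + ae_scores$FM) / 2) / age_months * 100
  data.frame(VDQ = vdq, NVDQ = nvdq)
}

#' Linear mixed-effects model for network laterality
#'
#' Fits `outcome ~ fixed effects + (1 | subject)` with lme4, the model used
#' for laterality-age and laterality-behavior associations. Sessions with a
#' missing outcome or predictor are excluded. Degrees of freedom use the
#' residual approximation (n - rank(X) - 1 for the random intercept);
#' Satterthwaite-type df are reported instead when a provider is installed
#' — the method used is recorded in the result. P-values are uncorrected.
#'
#' @param data data.frame with one row per session; must contain `subject`
#'   (or `subject_id`) plus the model variables.
#' @param outcome name of the response column (e.g. `"li"`).
#' @param fixed character vector of fixed-effect column names (e.g.
#'   `c("age_years", "VDQ")`).
#' @return a `model_result`: `coefficients` data.frame (term, estimate, se,
#'   t, df, p), `random_intercept_sd`, `sigma`, `n_sessions`, `n_subjects`,
#'   `df_method`, `singular`, and the lme4 `fit`.
#' @export
fit_laterality_model <- function(data, outcome, fixed) {
  subj_col <- if ("subject" %in% names(data)) "subject" else "subject_id"
  if (!subj_col %in% names(data)) stop("data needs a subject / subject_id column")
  vars <- c(outcome, fixed, subj_col)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) stop("missing column(s): ",
                                 paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  if (length(unique(d[[subj_col]])) < 2) stop("need at least 2 subjects")
  fml <- stats::as.formula(paste(
    outcome, "~", paste(fixed, collapse = " + "), "+ (1 |", subj_col, ")"))
  # nobs checks relaxed so the one-session-per-subject limiting case (which
  # degenerates to OLS, usually with a singular random intercept) still fits
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular =
                        lme4::.makeCC(action = "message", tol = 1e-4),
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore"))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- cf / se
  n <- nrow(d)
  p_fixed <- length(cf)
  df_resid <- n - p_fixed - 1  # one random-intercept variance parameter
  df_method <- "residual"
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = data.frame(
      term = names(cf), estimate = unname(cf), se = unname(se),
      t = unname(tval), df = df_resid, p = unname(pval),
      stringsAsFactors = FALSE),
    random_intercept_sd = vc$sdcor[vc$grp == subj_col][1],
    sigma = stats::sigma(fit),
    n_sessions = n,
    n_subjects = length(unique(d[[subj_col]])),
    df_method = df_method,
    singular = singular,
    fit = fit
  ), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %d sessions, %d subjects (df method: %s%s)\n",
              x$n_sessions, x$n_subjects, x$df_method,
              if (x$singular) "; SINGULAR FIT" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Paired comparison of within-network FC across topographies
#'
#' Per-network paired t-test of individualized vs consensus within-network
#' FC across sessions, with Benjamini-Hochberg FDR correction across
#' networks.
#'
#' @param fc_individualized,fc_consensus sessions x networks matrices of
#'   within-network FC on matched sessions.
#' @return data.frame: network, mean_diff (individualized - consensus), t,
#'   df, p, p_fdr, direction.
#' @export
compare_within_fc <- function(fc_individualized, fc_consensus) {
  fi <- as.matrix(fc_individualized)
  fc <- as.matrix(fc_consensus)
  if (!all(dim(fi) == dim(fc))) stop("matrices must match session x network")
  if (nrow(fi) < 3) stop("need at least 3 paired sessions")
  k <- ncol(fi)
  res <- lapply(seq_len(k), function(net) {
    diffs <- fi[, net] - fc[, net]
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 3 || stats::sd(diffs) == 0) {
      # degenerate: identical inputs (t = 0) or an exactly constant shift
      m <- mean(diffs)
      return(data.frame(network = net, mean_diff = m,
                        t = if (m == 0) 0 else sign(m) * Inf,
                        df = length(diffs) - 1,
                        p = if (m == 0) 1 else 0))
    }
    tt <- stats::t.test(diffs)
    data.frame(network = net, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$mean_diff > 0, "individualized_higher",
                          ifelse(out$mean_diff < 0, "consensus_higher",
                                 "equal"))
  out
}

#' Subject-grouped cross-validated age prediction with ridge regression
#'
#' Ridge regression of age on mean FD plus within-network FC features, with
#' outer folds grouped by subject (all sessions of a subject share a fold)
#' and the penalty chosen by inner cross-validation over a logarithmic grid
#' within each training fold. Out-of-sample predictions are aggregated
#' across folds before computing `r = cor(predicted, true)` and
#' `R^2 = 1 - SSE/SST`. Also reports the in-sample Delta-R^2 / adjusted-R^2
#' comparison of an FD-only linear model vs FD + features at identical
#' complexity.
#'
#' @param features sessions x features matrix (column 1 conventionally mean
#'   FD; remaining columns within-network FC).
#' @param ages true age per session.
#' @param subject_ids subject of each session (grouping unit).
#' @param n_folds outer folds (default 5).
#' @param seed integer seed (fold shuffling).
#' @param fd_column index of the mean-FD column for the Delta-R^2 contrast;
#'   NULL skips that contrast.
#' @return list: `r`, `r2`, `predictions` (data.frame), `delta_r2`,
#'   `adjusted_r2` (named: fd_only, full), `folds`.
#' @export
age_prediction_cv <- function(features, ages, subject_ids, n_folds = 5,
                              seed = 1, fd_column = 1) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(ages), nrow(x) == length(subject_ids))
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < 2 * n_folds) {
    stop("need at least ", 2 * n_folds, " subjects for ", n_folds,
         " grouped folds")
  }
  withr_seed(seed, {
    shuffled <- sample(subjects)
    fold_of_subject <- rep(seq_len(n_folds), length.out = length(shuffled))
    names(fold_of_subject) <- shuffled
    fold <- fold_of_subject[as.character(subject_ids)]

    pred <- rep(NA_real_, nrow(x))
    for (f in seq_len(n_folds)) {
      test <- fold == f
      if (!any(test)) stop("fold ", f, " has no test subjects")
      train_subj <- as.character(subject_ids[!test])
      inner_fold <- fold_of_subject[train_subj]
      inner_fold <- as.integer(factor(inner_fold))  # compact 1..n_folds-1
      cvfit <- glmnet::cv.glmnet(x[!test, , drop = FALSE], ages[!test],
                                 alpha = 0, foldid = inner_fold,
                                 lambda = 10^seq(2, -4, length.out = 60))
      pred[test] <- as.numeric(stats::predict(
        cvfit, newx = x[test, , drop = FALSE], s = "lambda.min"))
    }
  })
  sse <- sum((ages - pred)^2)
  sst <- sum((ages - mean(ages))^2)
  out <- list(
    r = stats::cor(pred, ages),
    r2 = 1 - sse / sst,
    predictions = data.frame(subject_id = as.character(subject_ids),
                             fold = unname(fold), age = ages,
                             predicted = pred),
    folds = fold_of_subject
  )
  if (!is.null(fd_column)) {
    d <- data.frame(age = ages, x)
    fd_name <- colnames(d)[1 + fd_column]
    m0 <- stats::lm(stats::reformulate(fd_name, "age"), data = d)
    m1 <- stats::lm(age ~ ., data = d)
    r2_0 <- summary(m0)$r.squared
    r2_1 <- summary(m1)$r.squared
    out$delta_r2 <- r2_1 - r2_0
    out$adjusted_r2 <- c(fd_only = summary(m0)$adj.r.squared,
                         full = summary(m1)$adj.r.squared)
  }
  out
}
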