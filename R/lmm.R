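#' Time-resolved random-intercept mixed-model t statistics
#'
#' Fits, independently at each window, the linear mixed model
#' `outcome ~ predictor (+ covariates) + (1 | participant)` by restricted
#' maximum likelihood and returns the fixed-effect t statistic of the
#' predictor (estimate divided by its standard error). Repeated recordings
#' of the same participant across waves are absorbed by the random
#' intercept. Windows with missing outcome or predictor values are dropped
#' pairwise; a window whose fit fails (too few observations, constant
#' predictor, non-convergence) is recorded as missing with a warning, never
#' silently zero.
#'
#' Two estimation engines are available: `"reml"`, a compiled profiled-REML
#' solver specialized to the single-random-intercept structure (used inside
#' the bootstrap for tractability), and `"lme4"`, which delegates to
#' [lme4::lmer()]. Both minimize the same REML criterion; the test suite
#' checks their t statistics agree to 1e-4.
#'
#' @param data long-format data frame: one row per recording and window,
#'   with columns `window_ms`, `recording_id`, `participant`, the outcome,
#'   the predictor, and any covariates.
#' @param outcome name of the outcome column (e.g. `"eig1"`, `"rt_mean"`).
#' @param predictor name of the fixed-effect predictor column tested
#'   (e.g. `"age"`, `"eig2"`).
#' @param covariates optional character vector of covariate columns (e.g.
#'   `"age"` when testing sex).
#' @param engine `"reml"` (compiled) or `"lme4"`.
#' @return tibble with one row per window: `window_ms`, `estimate`, `se`,
#'   `t`, `n_obs`, `converged`.
#' @export
lmm_timecourse <- function(data, outcome, predictor, covariates = NULL,
                           engine = c("reml", "lme4")) {
  engine <- match.arg(engine)
  mats <- build_lmm_matrices(data, outcome, predictor, covariates)
  if (engine == "reml") {
    res <- lmm_t_series_cpp(mats$Y, mats$P, mats$C, mats$g, mats$G, tol = 1e-7)
    out <- tibble::tibble(window_ms = mats$windows,
                          estimate = as.numeric(res$estimate),
                          se = as.numeric(res$se),
                          t = as.numeric(res$t),
                          n_obs = as.integer(res$n_obs),
                          converged = is.finite(as.numeric(res$t)))
  } else {
    rows <- purrr::map(seq_along(mats$windows), function(w) {
      df <- data.frame(y = mats$Y[w, ], x = mats$P[w, ],
                       participant = factor(mats$g))
      if (!is.null(covariates))
        for (j in seq_along(covariates)) df[[covariates[j]]] <- mats$C[, j]
      df <- df[stats::complete.cases(df), , drop = FALSE]
      fml <- stats::as.formula(paste(
        "y ~ x", if (length(covariates)) paste("+", paste(covariates, collapse = "+")) else "",
        "+ (1 | participant)"))
      fit <- tryCatch(
        suppressMessages(suppressWarnings(lme4::lmer(
          fml, data = df, REML = TRUE,
          control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                      check.nobs.vs.nRE = "ignore",
                                      calc.derivs = FALSE)))),
        error = function(e) NULL)
      if (is.null(fit))
        return(tibble::tibble(window_ms = mats$windows[w], estimate = NA_real_,
                              se = NA_real_, t = NA_real_,
                              n_obs = nrow(df), converged = FALSE))
      cf <- coef(summary(fit))
      tibble::tibble(window_ms = mats$windows[w],
                     estimate = cf["x", "Estimate"],
                     se = cf["x", "Std. Error"],
                     t = cf["x", "t value"],
                     n_obs = nrow(df), converged = TRUE)
    })
    out <- dplyr::bind_rows(rows)
  }
  nbad <- sum(!out$converged)
  if (nbad > 0)
    rlang::warn(sprintf("lmm_timecourse: %d window(s) failed to fit and are reported missing", nbad))
  out
}

# Pivot the long table into windows x recordings matrices for the compiled
# path: Y outcome, P predictor (both may vary by window), C covariates
# (per-recording constants), g participant index.
build_lmm_matrices <- function(data, outcome, predictor, covariates = NULL) {
  need <- c("window_ms", "recording_id", "participant", outcome, predictor, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_invalid(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  data <- dplyr::arrange(tibble::as_tibble(data), .data$window_ms, .data$recording_id)
  windows <- sort(unique(data$window_ms))
  recs <- unique(data$recording_id)
  nr <- length(recs); nw <- length(windows)
  ri <- match(data$recording_id, recs)
  wi <- match(data$window_ms, windows)
  Y <- matrix(NA_real_, nw, nr); P <- matrix(NA_real_, nw, nr)
  Y[cbind(wi, ri)] <- to_num(data[[outcome]])
  P[cbind(wi, ri)] <- to_num(data[[predictor]])
  first <- match(recs, data$recording_id)
  C <- if (length(covariates)) {
    vapply(covariates, function(cv) to_num(data[[cv]])[first], numeric(nr))
  } else matrix(0, nr, 0)
  C <- matrix(C, nrow = nr)
  part <- as.character(data$participant)[first]
  g <- as.integer(factor(part)) - 1L
  list(Y = Y, P = P, C = C, g = g, G = length(unique(g)),
       windows = windows, recordings = recs, participants = part)
}

# numeric coercion for predictors: factors/characters with 2 levels -> 0/1
to_num <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  f <- factor(x)
  if (nlevels(f) > 2)
    stop_invalid("non-numeric predictors must have at most 2 levels")
  as.numeric(f) - 1
}
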