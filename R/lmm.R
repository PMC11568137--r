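## term names accepted in model specifications -> analysis-table columns
TERM_COLUMNS <- c(
  device = "device", run = "run", age = "age", ecc = "eccentricity_deg",
  onl = "onl_um", ez = "ez_um", drusen = "drusen_nl", hrf = "hrf_nl",
  sdd = "sdd_nl"
)

#' Mixed-model specification
#'
#' Fixed-effect terms are named by biomarker (`device`, `run`, `age`, `ecc`,
#' `onl`, `ez`, `drusen`, `hrf`, `sdd`); interactions are unordered pairs of
#' those names. Marginality is enforced: an interaction may only appear when
#' both its main effects are present. The random structure is always a
#' per-patient intercept.
#'
#' @param fixed Character vector of main-effect term names.
#' @param interactions List of length-2 character vectors (may be empty).
#' @param estimation `"ML"` (used during model selection) or `"REML"` (used
#'   for the reported final fit).
#' @return A `model_spec`.
#' @export
model_spec <- function(fixed = character(), interactions = list(),
                       estimation = c("ML", "REML")) {
  estimation <- match.arg(estimation)
  fixed <- unique(as.character(fixed))
  bad <- setdiff(fixed, names(TERM_COLUMNS))
  assert_that(length(bad) == 0, "unknown terms: ", paste(bad, collapse = ", "))
  interactions <- lapply(interactions, function(i) sort(as.character(i)))
  for (i in interactions) {
    assert_that(length(i) == 2 && all(i %in% names(TERM_COLUMNS)),
                "interactions must pair two known terms")
    assert_that(all(i %in% fixed),
                "marginality violated: interaction ", paste(i, collapse = ":"),
                " lacks a main effect")
  }
  structure(list(fixed = fixed, interactions = interactions,
                 estimation = estimation), class = "model_spec")
}

#' The published final structure/function model
#'
#' Mains: device, ONL, EZ, eccentricity, drusen, HRF; interactions:
#' ONL x eccentricity and EZ x eccentricity. The reported coefficient table
#' omits an eccentricity main-effect row (eccentricity is absorbed into the
#' per-eccentricity slope rows), but the fitted design keeps the
#' eccentricity main effect so that marginality holds.
#'
#' @param estimation `"ML"` or `"REML"`.
#' @param include_ecc_main Keep the eccentricity main effect (default TRUE).
#' @return A [model_spec()].
#' @export
final_model_spec <- function(estimation = "REML", include_ecc_main = TRUE) {
  fixed <- c("device", "onl", "ez", "drusen", "hrf",
             if (include_ecc_main) "ecc")
  ints <- if (include_ecc_main) list(c("ecc", "onl"), c("ecc", "ez")) else list()
  spec <- model_spec(fixed, ints, estimation)
  if (!include_ecc_main) {
    ## slope-only parameterization: interactions without the ecc main effect
    spec$interactions <- list(c("ecc", "onl"), c("ecc", "ez"))
  }
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> pws_db ~", spec_label(x), "+ (1 | patient) [", x$estimation, "]\n")
  invisible(x)
}

spec_label <- function(spec) {
  terms <- c(sort(spec$fixed),
             vapply(spec$interactions, paste, "", collapse = ":"))
  if (!length(terms)) "1" else paste(terms, collapse = " + ")
}

spec_formula <- function(spec) {
  mains <- unname(TERM_COLUMNS[spec$fixed])
  ints <- vapply(spec$interactions, function(i) {
    paste(TERM_COLUMNS[i], collapse = ":")
  }, "")
  rhs <- c(mains, ints, "(1 | patient_id)")
  stats::as.formula(paste("pws_db ~", paste(rhs, collapse = " + ")))
}

## number of estimated parameters: fixed effects + 2 variance components
spec_n_parameters <- function(fit) length(lme4::fixef(fit)) + 2L

#' Fit a random-intercept linear mixed model
#'
#' Fits the structure/function model `pws_db ~ fixed terms + (1 | patient)`
#' by ML or REML (via `lme4::lmer`). Only included records with complete
#' covariates are used. Reports Wald (large-sample z) standard errors, 95%
#' CIs and p-values, the two variance components, the log-likelihood and
#' BIC computed as -2 logLik + k log(n) with k = fixed effects + 2 variance
#' parameters, and the Nakagawa-Schielzeth marginal R-squared.
#'
#' @param table An analysis table (from [assemble_table()] or
#'   [read_analysis_table()]).
#' @param spec A [model_spec()].
#' @return An `octmp_fit`: `coefficients` data frame, `varcomp`, `logLik`,
#'   `n_obs`, `n_parameters`, `bic`, `marginal_r2`, `spec`, `vcov` and the
#'   underlying `lme4` object in `$fit`.
#' @export
fit_lmm <- function(table, spec) {
  dat <- prepare_model_frame(table, spec)
  assert_that(length(unique(dat$patient_id)) >= 2,
              "need at least 2 patients", class = "octmp_data_error")
  for (tm in spec$fixed) {
    col <- TERM_COLUMNS[[tm]]
    assert_that(length(unique(dat[[col]])) > 1,
                "singular design: covariate '", col, "' is constant",
                class = "octmp_data_error")
  }
  fit <- lme4::lmer(spec_formula(spec), data = dat,
                    REML = spec$estimation == "REML",
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore",
                                                check.scaleX = "ignore"))
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    ci_lo = unname(beta - qnorm(0.975) * se),
    ci_hi = unname(beta + qnorm(0.975) * se),
    z = unname(z), p = unname(2 * pnorm(-abs(z))),
    row.names = NULL
  )
  vc <- lme4::VarCorr(fit)
  var_random <- as.numeric(vc$patient_id[1, 1])
  var_resid <- attr(vc, "sc")^2
  ll <- as.numeric(logLik(fit))
  n <- nrow(dat)
  k <- spec_n_parameters(fit)
  out <- structure(list(
    coefficients = coefs, varcomp = c(random_intercept = var_random,
                                      residual = var_resid),
    logLik = ll, n_obs = n, n_parameters = k,
    bic = -2 * ll + k * log(n),
    spec = spec, vcov = V, fit = fit,
    fitted_fixed = as.numeric(stats::model.matrix(fit) %*% beta)
  ), class = "octmp_fit")
  out$marginal_r2 <- marginal_r2(out)
  out
}

prepare_model_frame <- function(table, spec) {
  dat <- as.data.frame(table)
  if (!is.null(dat$included)) dat <- dat[dat$included, , drop = FALSE]
  cols <- unique(c("pws_db", "patient_id",
                   unname(TERM_COLUMNS[union(spec$fixed,
                                             unlist(spec$interactions))])))
  dat <- dat[complete.cases(dat[, cols]), , drop = FALSE]
  dat$device <- factor(dat$device, levels = c("MP3", "MAIA"))
  dat$run <- factor(dat$run, levels = c(1, 2))
  dat$patient_id <- factor(dat$patient_id)
  dat
}

#' @export
print.octmp_fit <- function(x, digits = 3, ...) {
  cat("Linear mixed model:", deparse(spec_formula(x$spec)), "\n")
  cat(sprintf("  %s fit, n = %d, logLik = %.2f, BIC = %.2f, marginal R2 = %.3f\n",
              x$spec$estimation, x$n_obs, x$logLik, x$bic, x$marginal_r2))
  co <- x$coefficients
  co[, -1] <- round(co[, -1], digits)
  print(co, row.names = FALSE)
  cat(sprintf("  variance components: random intercept %.3f, residual %.3f\n",
              x$varcomp[1], x$varcomp[2]))
  invisible(x)
}

#' Marginal R-squared (GLMM) of a mixed-model fit
#'
#' Nakagawa-Schielzeth variance decomposition: the variance of the
#' fixed-effect linear predictor over the fitted data divided by the sum of
#' fixed, random-intercept and residual variances — the share of outcome
#' variance explained by the fixed effects.
#'
#' @param fit An `octmp_fit`.
#' @return A number in [0, 1].
#' @export
marginal_r2 <- function(fit) {
  var_f <- var(fit$fitted_fixed)
  tot <- var_f + fit$varcomp[["random_intercept"]] + fit$varcomp[["residual"]]
  assert_that(tot > 0, "zero total variance: marginal R2 undefined")
  var_f / tot
}

#' Thickness slope at a given eccentricity
#'
#' The per-eccentricity sensitivity slope of a thickness covariate is the
#' linear combination `beta_main + r * beta_interaction` of its 0-degree
#' main effect and its per-degree eccentricity interaction, with variance
#' `Var(main) + r^2 Var(int) + 2 r Cov` and a Wald 95% CI. Can be evaluated
#' either from a fitted model or directly from coefficient values (e.g. to
#' reproduce a published per-eccentricity row from the printed 0-degree
#' estimate and interaction).
#'
#' @param x An `octmp_fit`, or the numeric main-effect estimate.
#' @param ... Method arguments.
#' @return An `eccentricity_slope` list: `variable`, `r_deg`, `estimate`,
#'   `se`, `ci_lo`, `ci_hi`.
#' @export
slope_at_eccentricity <- function(x, ...) UseMethod("slope_at_eccentricity")

#' @rdname slope_at_eccentricity
#' @param interaction Per-degree interaction coefficient.
#' @param r Eccentricity in degrees.
#' @param var_main,var_int,cov_main_int Optional (co)variances for the CI.
#' @param variable Label for the covariate (default `"onl"`).
#' @export
slope_at_eccentricity.numeric <- function(x, interaction, r, var_main = 0,
                                          var_int = 0, cov_main_int = 0,
                                          variable = "onl", ...) {
  est <- x + r * interaction
  v <- var_main + r^2 * var_int + 2 * r * cov_main_int
  se <- sqrt(v)
  structure(list(variable = variable, r_deg = r, estimate = est, se = se,
                 ci_lo = est - qnorm(0.975) * se,
                 ci_hi = est + qnorm(0.975) * se),
            class = "eccentricity_slope")
}

#' @rdname slope_at_eccentricity
#' @export
slope_at_eccentricity.octmp_fit <- function(x, variable = c("onl", "ez"), r, ...) {
  variable <- match.arg(variable)
  col <- TERM_COLUMNS[[variable]]
  ecc <- TERM_COLUMNS[["ecc"]]
  terms <- x$coefficients$term
  main_i <- match(col, terms)
  int_i <- which(terms %in% paste(c(col, ecc), rev(c(col, ecc)), sep = ":"))
  assert_that(!is.na(main_i) && length(int_i) == 1,
              "fit lacks main effect or eccentricity interaction for '",
              variable, "'")
  slope_at_eccentricity(
    x$coefficients$estimate[main_i],
    x$coefficients$estimate[int_i], r,
    var_main = x$vcov[main_i, main_i], var_int = x$vcov[int_i, int_i],
    cov_main_int = x$vcov[main_i, int_i], variable = variable
  )
}

#' @export
print.eccentricity_slope <- function(x, ...) {
  cat(sprintf("%s slope at %.1f deg: %.3f [%.3f; %.3f] dB/um\n",
              toupper(x$variable), x$r_deg, x$estimate, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Univariate SDD mixed models
#'
#' SDD was excluded from the final multivariable model (collinearity with
#' EZ thickness), so its effect is assessed in two univariate
#' random-intercept models: sensitivity on metric SDD volume (dB/nl) and on
#' dichotomized SDD presence (dB).
#'
#' @param table An analysis table (needs `sdd_nl`).
#' @return List with `metric` and `presence` `octmp_fit`s.
#' @export
univariate_sdd_models <- function(table) {
  metric <- fit_lmm(table, model_spec("sdd", estimation = "REML"))
  tab2 <- dichotomize(table)
  tab2$sdd_nl <- as.numeric(tab2$sdd_present) # reuse the sdd term slot
  presence <- fit_lmm(tab2, model_spec("sdd", estimation = "REML"))
  presence$coefficients$term <- sub("sdd_nl", "sdd_present",
                                    presence$coefficients$term)
  list(metric = metric, presence = presence)
}
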