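test_that("fit_lmm matches closed-form estimates on a balanced design", {
  # balanced within-patient device factor: the GLS estimator reduces to
  # plain group-mean differences regardless of the variance components
  set.seed(21)
  n_pat <- 8; n_per <- 10
  tab <- do.call(rbind, lapply(seq_len(n_pat), function(p) {
    data.frame(patient_id = p,
               device = rep(c("MP3", "MAIA"), each = n_per / 2),
               run = 1, point_id = seq_len(n_per), eccentricity_deg = 0,
               age = 70, ez_um = 0, onl_um = 0, drusen_nl = 0, sdd_nl = 0,
               hrf_nl = 0, included = TRUE,
               pws_db = 25 - 3.5 * rep(c(0, 1), each = n_per / 2) +
                 rnorm(1, 0, 2) + rnorm(n_per, 0, 1.5))
  }))
  fit <- fit_lmm(tab, model_spec("device", estimation = "REML"))
  closed <- mean(tab$pws_db[tab$device == "MAIA"]) -
    mean(tab$pws_db[tab$device == "MP3"])
  expect_equal(fit$coefficients$estimate[2], closed, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[1],
               mean(tab$pws_db[tab$device == "MP3"]), tolerance = 1e-6)
})

test_that("with no between-patient variance the fit collapses to OLS", {
  set.seed(22)
  tab <- make_lmm_table(n_patients = 10, n_per = 30, sd_u = 0, sd_e = 2)
  fit <- fit_lmm(tab, model_spec(c("device", "ez"), estimation = "ML"))
  ols <- coef(lm(pws_db ~ device + ez_um, data = fit$fit@frame))
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-3)
})

test_that("ML log-likelihood matches numerical maximization to 1e-4", {
  for (seed in c(1, 2)) {
    tab <- make_lmm_table(n_patients = 5, n_per = 30, seed = seed)
    spec <- model_spec(c("device", "onl", "drusen"), estimation = "ML")
    fit <- fit_lmm(tab, spec)
    expect_lte(fit$n_obs, 200)
    X <- stats::model.matrix(~ device + onl_um + drusen_nl,
                             data = as.data.frame(fit$fit@frame))
    ll <- oracle_lmm_loglik(tab$pws_db, X, tab$patient_id)
    expect_equal(fit$logLik, ll, tolerance = 1e-4)
  }
})

test_that("BIC equals -2 logLik + k log(n) for every fit", {
  tab <- make_lmm_table(n_patients = 6, n_per = 25, seed = 3)
  for (spec in list(model_spec("device"),
                    model_spec(c("device", "onl", "ecc"),
                               list(c("ecc", "onl"))),
                    final_model_spec("ML"))) {
    spec$estimation <- "ML"
    f <- fit_lmm(tab, spec)
    expect_equal(f$bic - (-2 * f$logLik + f$n_parameters * log(f$n_obs)), 0)
    expect_equal(f$n_parameters, nrow(f$coefficients) + 2)
  }
})

test_that("singular designs raise informative errors", {
  tab <- make_lmm_table(n_patients = 4, n_per = 20, seed = 4)
  tab$sdd_nl <- 0
  expect_error(fit_lmm(tab, model_spec("sdd")), "constant",
               class = "octmp_data_error")
  tab1 <- tab[tab$patient_id == 1, ]
  expect_error(fit_lmm(tab1, model_spec("device")), "2 patients",
               class = "octmp_data_error")
})

test_that("candidate enumeration respects marginality and matches brute force", {
  # 2 mains, no interactions: 4 subsets
  expect_length(enumerate_candidates(model_spec(c("onl", "ez"))), 4)
  # mains {a, b} with a x b: 5 candidates
  cands <- enumerate_candidates(model_spec(c("onl", "ez"),
                                           list(c("ez", "onl"))))
  expect_length(cands, 5)
  labs <- vapply(cands, octmp:::spec_label, "")
  expect_true("ez + onl + ez:onl" %in% labs)
  expect_false(any(grepl("ez:onl", setdiff(labs, "ez + onl + ez:onl"))))

  # full global spec: 9 mains, 7 interactions; count must match an
  # independent brute-force filter of all 2^16 subsets
  global <- model_spec(
    c("device", "run", "age", "ecc", "onl", "ez", "drusen", "hrf", "sdd"),
    list(c("ez", "onl"), c("drusen", "sdd"), c("drusen", "ecc"),
         c("ecc", "sdd"), c("ecc", "ez"), c("ecc", "onl"),
         c("drusen", "onl")))
  cands <- enumerate_candidates(global)
  mains <- sort(global$fixed)
  ints_idx <- lapply(global$interactions, function(i) match(sort(i), mains))
  expect_equal(length(cands), oracle_count_marginal_subsets(9, ints_idx))
  # every enumerated candidate satisfies marginality (constructor enforces,
  # but verify independently)
  ok <- vapply(cands, function(sp) {
    all(vapply(sp$interactions, function(i) all(i %in% sp$fixed), logical(1)))
  }, logical(1))
  expect_true(all(ok))
  # deterministic order
  labs2 <- vapply(enumerate_candidates(global), octmp:::spec_label, "")
  expect_identical(vapply(cands, octmp:::spec_label, ""), labs2)
})

test_that("BIC selection finds the generating structure", {
  # intercept-only truth: the null model wins at moderate n
  m0 <- sensitivity_model(device_offset = 0, drusen = 0, hrf = 0, sdd = 0,
                          onl = 0, ez = 0, onl_ecc = 0, ez_ecc = 0)
  tab <- make_lmm_table(n_patients = 12, n_per = 60, seed = 5, model = m0)
  cands <- enumerate_candidates(model_spec(c("device", "drusen")))
  sel <- select_by_bic(tab, cands)
  expect_equal(octmp:::spec_label(sel$best_spec), "1")
  expect_equal(sel$best_spec$estimation, "REML")
  expect_s3_class(sel$best_fit, "octmp_fit")
  expect_equal(sel$ranking$bic, sort(sel$ranking$bic))

  # strong drusen effect: the drusen model wins consistently
  m1 <- sensitivity_model(device_offset = 0, drusen = -6, hrf = 0, sdd = 0,
                          onl = 0, ez = 0, onl_ecc = 0, ez_ecc = 0)
  wins <- 0
  for (s in 1:10) {
    tabs <- make_lmm_table(n_patients = 10, n_per = 40, seed = 100 + s,
                           model = m1)
    sels <- select_by_bic(tabs, cands)
    wins <- wins + grepl("drusen", octmp:::spec_label(sels$best_spec))
  }
  expect_gte(wins, 9)
})

test_that("selection frequency of the true model grows with n", {
  m1 <- sensitivity_model(device_offset = 0, drusen = -1.2, hrf = 0, sdd = 0,
                          onl = 0, ez = 0, onl_ecc = 0, ez_ecc = 0)
  cands <- enumerate_candidates(model_spec(c("device", "drusen")))
  freq <- vapply(c(4, 10, 24), function(n_pat) {
    hits <- 0
    for (s in 1:8) {
      tabs <- make_lmm_table(n_patients = n_pat, n_per = 30,
                             seed = 1000 * n_pat + s, model = m1)
      lbl <- octmp:::spec_label(select_by_bic(tabs, cands)$best_spec)
      hits <- hits + (lbl == "drusen")
    }
    hits / 8
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
})

test_that("marginal R2 follows the variance decomposition", {
  fake <- structure(list(fitted_fixed = rnorm(1000),
                         varcomp = c(random_intercept = 1, residual = 2)),
                    class = "octmp_fit")
  fake$fitted_fixed <- fake$fitted_fixed / sd(fake$fitted_fixed) # var 1
  expect_equal(marginal_r2(fake), 0.25, tolerance = 1e-12)

  # intercept-only model explains nothing
  tab <- make_lmm_table(n_patients = 6, n_per = 25, seed = 7)
  null_fit <- fit_lmm(tab, model_spec(character(), estimation = "ML"))
  expect_equal(null_fit$marginal_r2, 0, tolerance = 1e-12)
})

test_that("eccentricity slopes are the stated linear combinations", {
  # r = 0 returns the main effect itself
  s0 <- slope_at_eccentricity(0.016, 0.008, 0, var_main = 0.0001)
  expect_equal(s0$estimate, 0.016)
  expect_equal(s0$ci_lo, 0.016 - qnorm(0.975) * 0.01)

  # published-row arithmetic (checked against the printed per-degree rows)
  expect_equal(slope_at_eccentricity(0.016, 0.008, 2.5)$estimate, 0.036)
  expect_equal(round(slope_at_eccentricity(0.016, 0.008, 5.2)$estimate, 3),
               0.058)
  # printed-rounding agreement: 0.148 - 0.025 * 2.5 = 0.0855, half a
  # rounding unit from the printed 0.086
  expect_lte(abs(slope_at_eccentricity(0.148, -0.025, 2.5)$estimate - 0.086),
             5.1e-4)
  expect_lt(abs(slope_at_eccentricity(0.148, -0.0247, 5.2)$estimate - 0.020),
            5e-4)

  # the fit-based method agrees with the numeric route and errs when the
  # interaction is absent
  tab <- make_lmm_table(n_patients = 8, n_per = 40, seed = 8)
  fit <- fit_lmm(tab, final_model_spec("REML"))
  co <- fit$coefficients
  direct <- co$estimate[co$term == "onl_um"] +
    2.5 * co$estimate[co$term == "onl_um:eccentricity_deg"]
  expect_equal(slope_at_eccentricity(fit, "onl", 2.5)$estimate, direct)
  fit0 <- fit_lmm(tab, model_spec(c("onl"), estimation = "ML"))
  expect_error(slope_at_eccentricity(fit0, "onl", 2.5), "interaction")
})

test_that("variance of the slope combines main, interaction and covariance", {
  tab <- make_lmm_table(n_patients = 8, n_per = 40, seed = 9)
  fit <- fit_lmm(tab, final_model_spec("REML"))
  co <- fit$coefficients
  i <- which(co$term == "ez_um"); j <- which(co$term == "ez_um:eccentricity_deg")
  r <- 1.5
  v <- fit$vcov[i, i] + r^2 * fit$vcov[j, j] + 2 * r * fit$vcov[i, j]
  expect_equal(slope_at_eccentricity(fit, "ez", r)$se, sqrt(v))
})

test_that("spearman_rho matches the rank formula and guards input", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  x <- c(1, 2, 2, 3, 5); y <- c(10, 9, 7, 7, 1)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "lengths")
})

test_that("dichotomization flags strict positivity", {
  tab <- data.frame(drusen_nl = c(0, 1e-9, 0.3), sdd_nl = c(0, 0, 1),
                    hrf_nl = c(0.05, 0, 0))
  d <- dichotomize(tab)
  expect_equal(d$drusen_present, c(FALSE, TRUE, TRUE))
  expect_equal(d$sdd_present, c(FALSE, FALSE, TRUE))
  expect_equal(d$hrf_present, c(TRUE, FALSE, FALSE))
  expect_true(all(c("drusen_nl", "sdd_nl", "hrf_nl") %in% names(d)))
})

test_that("descriptive summary applies the positive-value restriction", {
  tab <- data.frame(
    patient_id = 1, device = rep(c("MP3", "MAIA"), each = 4),
    run = 1, point_id = 1:8, eccentricity_deg = 1, age = 70,
    ez_um = 29, onl_um = 64,
    drusen_nl = c(0, 0, 0.2, 0.4, 0, 0, 0, 0),
    sdd_nl = 0, hrf_nl = 0,
    pws_db = c(1, 3, 1, 3, 25, 25, 25, 25), included = TRUE)
  s <- descriptive_summary(tab)
  mp3 <- s[s$device == "MP3", ]
  expect_equal(mp3$pws_mean, 2)
  expect_equal(mp3$pws_sd, sd(c(1, 3, 1, 3)))
  expect_equal(mp3$drusen_median, 0.3)
  expect_equal(mp3$drusen_n_pos, 2)
  expect_true(is.na(s[s$device == "MAIA", "drusen_median"]))
})

test_that("univariate SDD models recover generating effects", {
  m <- sensitivity_model(device_offset = 0, drusen = 0, hrf = 0, onl = 0,
                         ez = 0, onl_ecc = 0, ez_ecc = 0, sdd = -1.18)
  ests <- vapply(1:6, function(s) {
    tab <- make_lmm_table(n_patients = 14, n_per = 45, seed = 300 + s,
                          model = m)
    fits <- univariate_sdd_models(tab)
    expect_equal(fits$presence$coefficients$term[2], "sdd_present")
    fits$metric$coefficients$estimate[2]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-1.18)), 3 * mc_se + 0.05)

  tab0 <- make_lmm_table(n_patients = 4, n_per = 20, seed = 1)
  tab0$sdd_nl <- 0
  expect_error(univariate_sdd_models(tab0), class = "octmp_data_error")
})

test_that("both final-model parameterizations expose consistent slopes", {
  tab <- make_lmm_table(n_patients = 10, n_per = 50, seed = 13)
  with_main <- fit_lmm(tab, final_model_spec("REML"))
  no_main <- fit_lmm(tab, final_model_spec("REML", include_ecc_main = FALSE))
  # the slope-only design drops one column, nothing else
  expect_equal(nrow(no_main$coefficients), nrow(with_main$coefficients) - 1)
  expect_false("eccentricity_deg" %in% no_main$coefficients$term)
  # per-eccentricity slope rows agree within their uncertainty (data are
  # generated without an eccentricity main effect)
  for (r in c(0, 1.5, 2.5, 5.2)) {
    s1 <- slope_at_eccentricity(with_main, "ez", r)
    s0 <- slope_at_eccentricity(no_main, "ez", r)
    expect_lt(abs(s1$estimate - s0$estimate), 2 * (s1$se + s0$se))
  }
})
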