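#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (used for the
#' between-covariate correlation analyses, e.g. ONL thickness versus
#' eccentricity).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1]; constant input is an error.
#' @export
spearman_rho <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need equal lengths >= 3")
  assert_that(sd(x) > 0 && sd(y) > 0,
              "constant vector: rank correlation undefined")
  cor(rank(x), rank(y))
}

#' Dichotomize deposit volumes into presence flags
#'
#' Adds `drusen_present`, `sdd_present`, `hrf_present` columns (present
#' means volume strictly greater than 0); original volume columns are
#' retained.
#'
#' @param table An analysis table with the volume columns.
#' @return The table with three added logical columns.
#' @export
dichotomize <- function(table) {
  for (v in c("drusen", "sdd", "hrf")) {
    col <- paste0(v, "_nl")
    assert_that(col %in% names(table), "missing column ", col)
    table[[paste0(v, "_present")]] <- table[[col]] > 0
  }
  table
}

#' Feature prevalence in percent
#'
#' @param n_positive,n_total Counts (e.g. stimuli with drusen volume > 0 out
#'   of all valid stimuli).
#' @return 100 * n_positive / n_total.
#' @export
feature_prevalence <- function(n_positive, n_total) {
  assert_that(n_total > 0 && n_positive >= 0 && n_positive <= n_total,
              "need 0 <= n_positive <= n_total")
  100 * n_positive / n_total
}

#' Pool per-run device means
#'
#' The device-level mean sensitivity quoted alongside per-run descriptive
#' rows is the average of the two run means (runs are balanced: identical
#' grids and counts).
#'
#' @param run_means Numeric vector of per-run means.
#' @return Their mean.
#' @export
pool_run_means <- function(run_means) mean(run_means)

#' Rescale a per-unit effect estimate
#'
#' Converts an effect quoted per 1 unit into an effect per `per` units, e.g.
#' a dB/nl HRF estimate into dB per 0.1 nl (the more interpretable scale
#' given sub-0.1 nl median component volumes).
#'
#' @param estimate Effect per unit (CI bounds rescale the same way).
#' @param per New unit size.
#' @return `estimate * per`.
#' @export
rescale_effect <- function(estimate, per = 0.1) estimate * per

#' Descriptive summary of the analysis table
#'
#' Per device x run: observation counts, mean +/- SD of sensitivity and of
#' EZ/ONL thickness over included records, and median [min-max] of the
#' deposit volumes restricted to values > 0 together with the
#' feature-positive counts.
#'
#' @param table An analysis table.
#' @return A data frame, one row per device x run.
#' @export
descriptive_summary <- function(table) {
  assert_that(nrow(table) > 0, "empty table")
  tab <- as.data.frame(table)
  groups <- split(tab, list(tab$device, tab$run), drop = TRUE)
  out <- lapply(groups, function(g) {
    inc <- g[g$included %||% TRUE, , drop = FALSE]
    pos_stats <- function(v) {
      p <- inc[[v]][!is.na(inc[[v]]) & inc[[v]] > 0]
      c(median = if (length(p)) median(p) else NA_real_,
        min = if (length(p)) min(p) else NA_real_,
        max = if (length(p)) max(p) else NA_real_,
        n = length(p))
    }
    dr <- pos_stats("drusen_nl"); sd_ <- pos_stats("sdd_nl"); hf <- pos_stats("hrf_nl")
    data.frame(
      device = g$device[1], run = g$run[1],
      n = nrow(g), n_included = nrow(inc),
      pws_mean = mean(g$pws_db), pws_sd = sd(g$pws_db),
      ez_mean = mean(inc$ez_um, na.rm = TRUE), ez_sd = sd(inc$ez_um, na.rm = TRUE),
      onl_mean = mean(inc$onl_um, na.rm = TRUE), onl_sd = sd(inc$onl_um, na.rm = TRUE),
      drusen_median = dr["median"], drusen_min = dr["min"], drusen_max = dr["max"],
      drusen_n_pos = dr["n"],
      sdd_median = sd_["median"], sdd_min = sd_["min"], sdd_max = sd_["max"],
      sdd_n_pos = sd_["n"],
      hrf_median = hf["median"], hrf_min = hf["min"], hrf_max = hf["max"],
      hrf_n_pos = hf["n"],
      row.names = NULL
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$device, res$run), , drop = FALSE]
  rownames(res) <- NULL
  res
}
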