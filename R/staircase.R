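#' Staircase configuration
#'
#' Parameters of the 4-2 threshold staircase: the first stimulus is
#' presented at 17 dB, steps are 4 dB until the first response reversal and
#' 2 dB afterwards, and the point terminates at the second reversal. The
#' dB scale is attenuation, so *higher* dB means a *dimmer* stimulus: a seen
#' stimulus is followed by a dimmer one (+step), a missed stimulus by a
#' brighter one (-step). Presentation levels are clamped to the device range
#' (0-34 dB on MP-3, 0-36 dB on MAIA). When no stimulus is ever seen the
#' MAIA reports a raw -1 dB (adjusted to 0 downstream); the MP-3 reports 0.
#'
#' @param device `"MP3"` or `"MAIA"` (sets the range and raw floor).
#' @param start_db First presentation level (17 dB).
#' @param coarse_step,fine_step Step sizes in dB (4 and 2).
#' @param max_presentations Safety cap for pathological observers (50).
#' @return A `staircase_config` list.
#' @export
staircase_config <- function(device = c("MP3", "MAIA"), start_db = 17,
                             coarse_step = 4, fine_step = 2,
                             max_presentations = 50) {
  device <- match.arg(device)
  range_db <- if (device == "MP3") c(0, 34) else c(0, 36)
  raw_floor <- if (device == "MP3") 0 else -1
  assert_that(start_db >= range_db[1] && start_db <= range_db[2],
              "start_db outside device range")
  assert_that(coarse_step > fine_step && fine_step > 0,
              "need coarse_step > fine_step > 0")
  structure(list(device = device, start_db = start_db,
                 coarse_step = coarse_step, fine_step = fine_step,
                 range_db = range_db, raw_floor = raw_floor,
                 max_presentations = as.integer(max_presentations)),
            class = "staircase_config")
}

#' Observer response model
#'
#' Probability of reporting a stimulus of attenuation `level` as seen given a
#' true threshold T:
#' `p = fp + (1 - fp - fn) * Phi((T - level) / sigma)`,
#' a cumulative-Gaussian psychometric function with lapse (`fn`) and guess
#' (`fp`) rates. `sigma = 0` with zero rates gives the deterministic step
#' observer (seen iff level <= T) used by the exactness properties.
#'
#' @param sigma_psy Psychometric slope in dB (>= 0; 0 = step observer).
#' @param false_positive_rate,false_negative_rate Probabilities in [0, 0.2].
#' @return An `observer_model` list.
#' @export
observer_model <- function(sigma_psy = 1, false_positive_rate = 0.03,
                           false_negative_rate = 0.03) {
  assert_that(sigma_psy >= 0, "sigma_psy must be >= 0")
  assert_that(false_positive_rate >= 0 && false_positive_rate <= 0.2 &&
                false_negative_rate >= 0 && false_negative_rate <= 0.2,
              "response error rates must lie in [0, 0.2]")
  structure(list(sigma_psy = sigma_psy,
                 false_positive_rate = false_positive_rate,
                 false_negative_rate = false_negative_rate),
            class = "observer_model")
}

#' Deterministic step observer (no noise)
#' @return An [observer_model()] with `sigma_psy = 0` and zero error rates.
#' @export
deterministic_observer <- function() observer_model(0, 0, 0)

## P(seen) for a stimulus at `level` dB given threshold `threshold`
p_seen <- function(level, threshold, observer) {
  base <- if (observer$sigma_psy == 0) {
    as.numeric(level <= threshold)
  } else {
    pnorm((threshold - level) / observer$sigma_psy)
  }
  observer$false_positive_rate +
    (1 - observer$false_positive_rate - observer$false_negative_rate) * base
}

#' Run one 4-2 staircase
#'
#' Simulates the threshold staircase at a single stimulus location. Responses
#' are drawn from the observer model (draws consume the current RNG stream;
#' seed externally for reproducibility). The estimate is the last-seen
#' presentation level; if nothing is ever seen the device floor is returned
#' (raw -1 for MAIA, 0 for MP-3 — the -1 is a *raw* value that downstream
#' [adjust_sensitivity()] maps to 0).
#'
#' @param threshold True threshold in dB.
#' @param observer An [observer_model()].
#' @param config A [staircase_config()].
#' @return A list with `estimate_db` (raw measured value), `n_presentations`,
#'   `levels`, `responses` (logical) and `n_reversals`.
#' @export
run_staircase <- function(threshold, observer = deterministic_observer(),
                          config = staircase_config()) {
  assert_that(is.finite(threshold), "threshold must be finite")
  lo <- config$range_db[1]; hi <- config$range_db[2]
  level <- config$start_db
  step <- config$coarse_step
  levels <- numeric(0); responses <- logical(0)
  last_seen <- NA_real_
  n_rev <- 0L
  prev <- NA
  for (k in seq_len(config$max_presentations)) {
    seen <- runif(1) < p_seen(level, threshold, observer)
    levels <- c(levels, level); responses <- c(responses, seen)
    if (seen) last_seen <- level
    if (!is.na(prev) && xor(seen, prev)) {
      n_rev <- n_rev + 1L
      if (n_rev == 1L) step <- config$fine_step
      if (n_rev >= 2L) break
    }
    prev <- seen
    nxt <- if (seen) level + step else level - step
    nxt <- min(max(nxt, lo), hi)
    if (nxt == level) break # pinned at a range bound: nothing left to test
    level <- nxt
  }
  estimate <- if (is.na(last_seen)) config$raw_floor else last_seen
  list(estimate_db = estimate, n_presentations = length(levels),
       levels = levels, responses = responses, n_reversals = n_rev)
}

#' Simulate a fixation sequence and P1/P2 stability indices
#'
#' Draws gaze samples around the fixation centre and reports the fraction
#' within the central 2 degrees (P1) and 4 degrees (P2). Jitter is an
#' isotropic Gaussian optionally inflated to a heavy-tailed (Student-t
#' scale-mixture) distribution: published P1/P2 pairs are not consistent
#' with a single Gaussian, so the tail is configurable.
#'
#' @param stability_config List with `sigma_deg` (Gaussian jitter SD, default
#'   0.9) and `t_df` (degrees of freedom of the scale mixture; `Inf` =
#'   Gaussian, default 4).
#' @param n_samples Number of gaze samples (>= 1).
#' @return List with `samples` (n x 2 matrix, degrees), `p1`, `p2` (percent).
#' @export
simulate_fixation <- function(stability_config = list(sigma_deg = 0.9, t_df = 4),
                              n_samples = 500) {
  assert_that(n_samples >= 1, "need n_samples >= 1")
  sigma <- stability_config$sigma_deg %||% 0.9
  df <- stability_config$t_df %||% 4
  z <- matrix(rnorm(2 * n_samples), ncol = 2)
  if (is.finite(df)) {
    w <- sqrt(df / stats::rchisq(n_samples, df))
    z <- z * w
  }
  samples <- z * sigma
  r <- sqrt(rowSums(samples^2))
  list(samples = samples,
       p1 = 100 * mean(r <= 2),
       p2 = 100 * mean(r <= 4))
}
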