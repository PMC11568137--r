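#' Enumerate candidate models under marginality
#'
#' Dredge-style candidate generation: every subset of the global model's
#' main effects combined with every subset of its interactions whose two
#' parent mains are both present. The order is deterministic: main-effect
#' subsets in binary counting order over the sorted term list, then
#' interaction subsets likewise.
#'
#' @param global A [model_spec()] describing the full candidate space.
#' @return A list of [model_spec()]s (all with `estimation = "ML"`, the
#'   criterion used for selection).
#' @export
enumerate_candidates <- function(global) {
  mains <- sort(global$fixed)
  ints <- global$interactions[order(vapply(global$interactions, paste, "",
                                           collapse = ":"))]
  out <- list()
  n_m <- length(mains)
  for (mbits in 0:(2^n_m - 1)) {
    msub <- mains[bitwAnd(mbits, 2^(seq_len(n_m) - 1)) > 0]
    allowed <- Filter(function(i) all(i %in% msub), ints)
    n_i <- length(allowed)
    for (ibits in 0:(2^max(n_i, 0) - 1)) {
      isub <- if (n_i) allowed[bitwAnd(ibits, 2^(seq_len(n_i) - 1)) > 0] else list()
      out[[length(out) + 1L]] <- model_spec(msub, isub, "ML")
    }
  }
  out
}

#' Select the best model by BIC
#'
#' Fits every candidate by maximum likelihood on the identical record set,
#' ranks them by BIC (= -2 logLik + k log n) and declares the lowest-BIC
#' model best; ties are broken by fewer parameters, then lexicographic term
#' order. The winning specification is refit by REML for reporting.
#' Candidates that fail to fit are dropped with a warning.
#'
#' @param table An analysis table.
#' @param candidates List of [model_spec()]s (e.g. from
#'   [enumerate_candidates()]).
#' @return A list: `best_spec`, `best_fit` (REML refit), `ranking` (data
#'   frame with label, k, logLik, BIC sorted best-first).
#' @export
select_by_bic <- function(table, candidates) {
  assert_that(length(candidates) >= 1, "no candidates supplied")
  rows <- list(); fits <- list()
  for (ci in seq_along(candidates)) {
    spec <- candidates[[ci]]
    spec$estimation <- "ML"
    f <- tryCatch(fit_lmm(table, spec), error = function(e) {
      warning("candidate '", spec_label(spec), "' dropped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      index = ci, label = spec_label(spec), k = f$n_parameters,
      logLik = f$logLik, bic = f$bic
    )
    fits[[length(fits) + 1L]] <- spec
  }
  assert_that(length(rows) > 0, "every candidate failed to fit")
  ranking <- do.call(rbind, rows)
  ord <- order(ranking$bic, ranking$k, ranking$label)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  best_spec <- candidates[[ranking$index[1]]]
  best_spec$estimation <- "REML"
  list(best_spec = best_spec,
       best_fit = fit_lmm(table, best_spec),
       ranking = ranking)
}
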