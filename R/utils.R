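## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_octmp <- function(..., class = "octmp_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_octmp(...)
  invisible(TRUE)
}

## derive a child RNG seed from a base seed and a stream label;
## kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x)) else as.numeric(x)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + (p %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}

## evaluate expr with a local, restorable RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## round half down: 10.5 -> 10 (used for the nearest-B-scan tie rule)
round_half_down <- function(x) ceiling(x - 0.5)
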