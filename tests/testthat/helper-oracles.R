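# Independent oracles kept deliberately naive: they never share code with
# the implementation paths they check.

# brute-force disc aggregation: loop over every raster pixel
oracle_disc_stats <- function(raster, geometry, center_um, radius_um) {
  vals <- c()
  for (i in seq_len(geometry$n_bscans)) {
    for (j in seq_len(geometry$n_ascans)) {
      x <- (j - 1) * geometry$ascan_spacing_um
      y <- (i - 1) * geometry$bscan_spacing_um
      if ((x - center_um[1])^2 + (y - center_um[2])^2 <= radius_um^2 + 1e-9) {
        vals <- c(vals, raster[i, j])
      }
    }
  }
  list(n = length(vals), mean = mean(vals),
       volume_nl = sum(vals) * geometry$ascan_spacing_um *
         geometry$bscan_spacing_um / 1e6)
}

# direct numerical maximization of the marginal Gaussian likelihood of a
# random-intercept model (profiled GLS beta; Nelder-Mead over variances)
oracle_lmm_loglik <- function(y, X, group) {
  groups <- split(seq_along(y), group)
  loglik <- function(par) {
    vb <- exp(par[1]); ve <- exp(par[2])
    # GLS beta via per-group Woodbury
    A <- matrix(0, ncol(X), ncol(X)); b <- rep(0, ncol(X))
    for (idx in groups) {
      Xg <- X[idx, , drop = FALSE]; yg <- y[idx]; ng <- length(idx)
      w <- vb / (ve + ng * vb)
      A <- A + (t(Xg) %*% Xg - w * tcrossprod(colSums(Xg))) / ve
      b <- b + (t(Xg) %*% yg - w * colSums(Xg) * sum(yg)) / ve
    }
    beta <- solve(A, b)
    ll <- 0
    for (idx in groups) {
      Xg <- X[idx, , drop = FALSE]; ng <- length(idx)
      r <- y[idx] - as.numeric(Xg %*% beta)
      w <- vb / (ve + ng * vb)
      quad <- (sum(r^2) - w * sum(r)^2) / ve
      ll <- ll - 0.5 * (ng * log(2 * pi * ve) + log(1 + ng * vb / ve) + quad)
    }
    -ll
  }
  v0 <- var(y)
  opt <- optim(log(c(v0 / 4, v0 / 2)), loglik, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  -opt$value
}

# Spearman by the textbook route: Pearson correlation of average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force marginality filter over all 2^(m+i) term subsets
oracle_count_marginal_subsets <- function(n_mains, interactions) {
  # interactions: list of integer pairs indexing mains
  n_int <- length(interactions)
  count <- 0L
  for (code in 0:(2^(n_mains + n_int) - 1)) {
    mains_in <- bitwAnd(code, 2^(0:(n_mains - 1))) > 0
    ok <- TRUE
    for (ii in seq_len(n_int)) {
      if (bitwAnd(code, 2^(n_mains + ii - 1)) > 0 &&
          !all(mains_in[interactions[[ii]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) count <- count + 1L
  }
  count
}
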