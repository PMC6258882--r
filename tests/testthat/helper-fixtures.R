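# Shared fixtures and independent oracles.

fx_train <- echo_train()                 # 32 echoes, ESP 10 ms
fx_grid <- make_t2_grid()                # 40 points, 0.015-2 s
fx_cfg <- fit_config()
fx_bases <- candidate_bases(fx_grid, fx_train, fx_cfg)

# Two-pool white-matter-like voxel with both pools on the default grid
# (myelin at grid point 4 = 21.9 ms, IE water at grid point 13 = 67.6 ms),
# so noiseless curves are exactly representable.
fx_wm_curve <- function(mwf, angle, myelin_t2 = fx_grid[4],
                        ie_t2 = fx_grid[13], train = fx_train) {
  mwf * epg_echo_amplitudes(myelin_t2, 1, angle, train) +
    (1 - mwf) * epg_echo_amplitudes(ie_t2, 1, angle, train)
}

# Brute-force NNLS oracle: enumerate every active set, solve the
# unconstrained LS on the passive columns, keep feasible candidates,
# return the minimizer. Exponential in ncol(A) -- use only for <= 8 cols.
nnls_enum_oracle <- function(A, b) {
  p <- ncol(A)
  best_x <- rep(0, p)
  best_chi2 <- sum(b^2)                  # empty active set: x = 0
  for (code in seq_len(2^p - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    z <- tryCatch(qr.solve(A[, S, drop = FALSE], b),
                  error = function(e) NULL)
    if (is.null(z) || any(z < 0)) next
    x <- rep(0, p); x[S] <- z
    chi2 <- sum((A %*% x - b)^2)
    if (chi2 < best_chi2 - 1e-12) { best_chi2 <- chi2; best_x <- x }
  }
  structure(best_x, chi2 = best_chi2)
}

# Sort-and-interpolate percentile oracle (type-7 definition, written out).
percentile_oracle <- function(values, q) {
  v <- sort(values)
  n <- length(v)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}
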