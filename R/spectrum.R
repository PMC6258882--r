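#' Logarithmically spaced T2 grid
#'
#' `grid[k] = t2_min * (t2_max/t2_min)^((k-1)/(n-1))`, endpoints inclusive.
#' The default (40 points from 15 ms to 2 s) spans myelin water, intra- and
#' extracellular water, and CSF.
#'
#' @param t2_min,t2_max Grid endpoints in seconds.
#' @param n Number of grid points (>= 2).
#' @return Object of class `t2_grid`: numeric vector of T2 values.
#' @examples
#' g <- make_t2_grid()
#' range(g)   # 0.015 2
#' @export
make_t2_grid <- function(t2_min = 0.015, t2_max = 2.0, n = 40L) {
  stopifnot(is.numeric(t2_min), is.numeric(t2_max), length(t2_min) == 1,
            length(t2_max) == 1)
  if (!(t2_min > 0 && t2_max > t2_min))
    stop("t2 grid requires 0 < t2_min < t2_max", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("t2 grid requires n >= 2", call. = FALSE)
  k <- seq_len(n) - 1L
  structure(t2_min * (t2_max / t2_min)^(k / (n - 1L)), class = "t2_grid")
}

#' @export
print.t2_grid <- function(x, ...) {
  cat(sprintf("t2_grid: %d log-spaced T2 values, %g..%g s\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

#' Fit configuration for the stimulated-echo-corrected spectrum fit
#'
#' @param candidate_angles Candidate refocusing flip angles in degrees for
#'   the stimulated-echo correction; default 8 values linearly spaced on
#'   \[50, 180\] inclusive.
#' @param reg_lo,reg_hi Target band for the chi-square inflation ratio
#'   `chi2_reg / chi2_min` of the regularized fit (defaults 1.02, 1.025).
#' @param chi2_floor Relative floor: if `chi2_min < chi2_floor * ||b||^2`
#'   the data are treated as noiseless and regularization is skipped.
#' @param myelin_window Myelin water T2 window in seconds, endpoints
#'   inclusive (default 0.015-0.040 s).
#' @param t1 Assumed longitudinal relaxation time in seconds for all
#'   spectral components (default 1.0; not estimated).
#' @param angle_step Resolution in degrees of the continuous flip-angle
#'   search over the spline-interpolated chi-square profile.
#' @param bisect_max Maximum bisection iterations for the regularization
#'   parameter.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(candidate_angles = seq(50, 180, length.out = 8),
                       reg_lo = 1.02, reg_hi = 1.025,
                       chi2_floor = 1e-10,
                       myelin_window = c(0.015, 0.040),
                       t1 = 1.0, angle_step = 0.1, bisect_max = 60L) {
  stopifnot(length(candidate_angles) >= 2,
            all(diff(candidate_angles) > 0),
            all(candidate_angles > 0), all(candidate_angles <= 180))
  if (!(1 < reg_lo && reg_lo < reg_hi))
    stop("regularization band requires 1 < reg_lo < reg_hi", call. = FALSE)
  stopifnot(length(myelin_window) == 2, myelin_window[1] < myelin_window[2],
            t1 > 0, angle_step > 0)
  structure(list(candidate_angles = as.numeric(candidate_angles),
                 reg_lo = reg_lo, reg_hi = reg_hi,
                 chi2_floor = chi2_floor,
                 myelin_window = as.numeric(myelin_window),
                 t1 = t1, angle_step = angle_step,
                 bisect_max = as.integer(bisect_max)),
            class = "fit_config")
}

#' Theoretical decay basis at a refocusing flip angle
#'
#' Column j holds [epg_echo_amplitudes()] at `grid[j]` for the given angle;
#' the matrix maps a T2 amplitude distribution to its predicted decay curve.
#'
#' @param grid A [make_t2_grid()].
#' @param refocus_angle Refocusing flip angle in degrees.
#' @param train An [echo_train()].
#' @param t1 Assumed T1 in seconds.
#' @return `n_echoes x length(grid)` matrix with attribute `angle`.
#' @export
decay_basis <- function(grid, refocus_angle, train = echo_train(), t1 = 1.0) {
  A <- epg_train_matrix(as.numeric(grid), t1, refocus_angle, train)
  attr(A, "angle") <- refocus_angle
  A
}

#' Non-negative least squares
#'
#' Solves `argmin ||A x - b||^2` subject to `x >= 0` by the Lawson-Hanson
#' active-set method (compiled).
#'
#' @param A Numeric matrix.
#' @param b Numeric vector, `length(b) == nrow(A)`.
#' @return Nonnegative solution vector with attribute `chi2`, the residual
#'   sum of squares.
#' @examples
#' nnls_solve(diag(2), c(3, -1))   # c(3, 0)
#' @export
nnls_solve <- function(A, b) {
  A <- as.matrix(A)
  if (!is.numeric(A) || ncol(A) < 1) stop("A must be a numeric matrix")
  if (length(b) != nrow(A))
    stop("dimension mismatch: length(b) != nrow(A)", call. = FALSE)
  fit <- .nnls_cpp(A, as.numeric(b))
  structure(drop(fit$x), chi2 = fit$chi2)
}

#' Estimate the true refocusing flip angle of a decay curve
#'
#' For each candidate angle an EPG decay basis is built and the curve is
#' fit by unregularized NNLS; the residual chi-square profile over angle is
#' interpolated by a cubic spline and minimized on an `angle_step` grid
#' clamped to the candidate range. If some candidate already fits the curve
#' to (relative) machine residual, that candidate is returned directly.
#'
#' @param curve Numeric vector of echo amplitudes.
#' @param grid A [make_t2_grid()].
#' @param train An [echo_train()].
#' @param cfg A [fit_config()].
#' @param bases Optional precomputed list of candidate bases (one per
#'   candidate angle), as built by [candidate_bases()].
#' @return Estimated angle in degrees, with attribute `chi2` giving the
#'   per-candidate residuals; `NA` for an all-zero curve.
#' @export
estimate_flip_angle <- function(curve, grid, train = echo_train(),
                                cfg = fit_config(), bases = NULL) {
  curve <- as.numeric(curve)
  if (!all(is.finite(curve))) stop("curve must be finite", call. = FALSE)
  if (all(curve == 0)) return(NA_real_)
  if (is.null(bases)) bases <- candidate_bases(grid, train, cfg)
  angles <- cfg$candidate_angles
  chi2 <- vapply(bases, function(A) attr(nnls_solve(A, curve), "chi2"),
                 numeric(1))
  floor_ <- cfg$chi2_floor * sum(curve^2)
  if (min(chi2) < floor_) {
    est <- angles[which.min(chi2)]        # exact fit: no interpolation
  } else {
    sp <- stats::splinefun(angles, chi2, method = "fmm")
    ag <- seq(angles[1], angles[length(angles)], by = cfg$angle_step)
    est <- ag[which.min(sp(ag))]
  }
  structure(est, chi2 = chi2)
}

#' Precompute decay bases for all candidate flip angles
#' @inheritParams estimate_flip_angle
#' @return List of basis matrices, one per candidate angle.
#' @export
candidate_bases <- function(grid, train = echo_train(), cfg = fit_config()) {
  lapply(cfg$candidate_angles, function(a) decay_basis(grid, a, train, cfg$t1))
}

#' Regularized NNLS spectrum fit
#'
#' Solves `min ||A x - b||^2 + mu ||x||^2, x >= 0` by appending
#' `sqrt(mu) * I` rows to the basis and zeros to the data. The energy
#' penalty `mu` is chosen by bisection on `log(mu)` so that the misfit
#' inflation `chi2_reg / chi2_min` falls in `[cfg$reg_lo, cfg$reg_hi]`
#' (both chi-squares are misfit-only, i.e. evaluated on the data rows).
#' Near-noiseless curves (`chi2_min` below the floor) are returned
#' unregularized.
#'
#' @param curve Numeric vector of echo amplitudes.
#' @param basis A [decay_basis()] built at the voxel's estimated angle.
#' @param cfg A [fit_config()].
#' @return List with `distribution` (nonnegative amplitudes over the grid),
#'   `chi2_min`, `chi2_reg`, and the chosen `mu`.
#' @export
regularized_nnls <- function(curve, basis, cfg = fit_config()) {
  b <- as.numeric(curve)
  A <- as.matrix(basis)
  n_t2 <- ncol(A)
  x0 <- nnls_solve(A, b)
  chi2_min <- attr(x0, "chi2")
  if (chi2_min < cfg$chi2_floor * sum(b^2)) {
    return(list(distribution = as.numeric(x0), chi2_min = chi2_min,
                chi2_reg = chi2_min, mu = 0))
  }
  b_aug <- c(b, numeric(n_t2))
  solve_mu <- function(mu) {
    A_aug <- rbind(A, sqrt(mu) * diag(n_t2))
    x <- nnls_solve(A_aug, b_aug)
    r <- b - A %*% x
    list(x = as.numeric(x), chi2 = sum(r^2))
  }
  scale <- mean(colSums(A^2))
  llo <- log(1e-10 * scale); lhi <- log(1e4 * scale)
  f_lo <- solve_mu(exp(llo)); f_hi <- solve_mu(exp(lhi))
  ratio <- function(f) f$chi2 / chi2_min
  pick <- function(f) list(distribution = f$x, chi2_min = chi2_min,
                           chi2_reg = f$chi2, mu = f$mu)
  f_lo$mu <- exp(llo); f_hi$mu <- exp(lhi)
  if (ratio(f_lo) > cfg$reg_hi) {
    warning("regularization bracket too high at lower end; returning it")
    return(pick(f_lo))
  }
  if (ratio(f_hi) < cfg$reg_lo) {
    warning("regularization bracket cannot inflate chi2 enough; returning it")
    return(pick(f_hi))
  }
  # bisect toward the lower band edge: the least regularization that
  # satisfies the chi-square inflation criterion
  best <- NULL; last <- NULL
  for (i in seq_len(cfg$bisect_max)) {
    lm <- (llo + lhi) / 2
    f <- solve_mu(exp(lm)); f$mu <- exp(lm)
    rr <- ratio(f)
    last <- f
    if (rr >= cfg$reg_lo && rr <= cfg$reg_hi) {
      best <- f
      if (rr - cfg$reg_lo <= 0.2 * (cfg$reg_hi - cfg$reg_lo))
        return(pick(f))
    }
    if (rr < cfg$reg_lo) llo <- lm else lhi <- lm
  }
  if (!is.null(best)) return(pick(best))
  warning("regularization bisection did not converge; returning closest")
  pick(last)
}

#' Myelin water fraction of a T2 distribution
#'
#' Fraction of total spectral amplitude at grid points with T2 inside the
#' myelin window (both endpoints inclusive).
#'
#' @param dist Nonnegative amplitude vector on `grid`.
#' @param grid A [make_t2_grid()].
#' @param window Length-2 window in seconds; must lie within the grid range.
#' @return Fraction in \[0, 1\], or `NA` for an all-zero distribution.
#' @export
compute_mwf <- function(dist, grid, window = c(0.015, 0.040)) {
  grid <- as.numeric(grid)
  dist <- as.numeric(dist)
  stopifnot(length(dist) == length(grid), length(window) == 2)
  if (window[1] < grid[1] - 1e-12 || window[2] > grid[length(grid)] + 1e-12)
    stop("myelin window outside grid range", call. = FALSE)
  total <- sum(dist)
  if (total == 0) return(NA_real_)
  inw <- grid >= window[1] & grid <= window[2]
  sum(dist[inw]) / total
}

#' Fit a single voxel decay curve
#'
#' Full per-voxel chain: flip-angle estimation, basis rebuild at the
#' estimated angle, regularized NNLS, MWF extraction. Deterministic given
#' its inputs.
#'
#' @inheritParams estimate_flip_angle
#' @return List of class `voxel_fit`: `mwf`, `angle`, `chi2_min`,
#'   `chi2_reg`, `mu`, `distribution`.
#' @export
fit_voxel <- function(curve, grid, train = echo_train(), cfg = fit_config(),
                      bases = NULL) {
  curve <- as.numeric(curve)
  if (!all(is.finite(curve))) stop("curve must be finite", call. = FALSE)
  na_fit <- structure(list(mwf = NA_real_, angle = NA_real_,
                           chi2_min = NA_real_, chi2_reg = NA_real_,
                           mu = NA_real_,
                           distribution = rep(NA_real_, length(grid))),
                      class = "voxel_fit")
  if (all(curve == 0)) return(na_fit)
  ang <- estimate_flip_angle(curve, grid, train, cfg, bases)
  if (is.na(ang)) return(na_fit)
  basis <- decay_basis(grid, as.numeric(ang), train, cfg$t1)
  reg <- regularized_nnls(curve, basis, cfg)
  mwf <- compute_mwf(reg$distribution, grid, cfg$myelin_window)
  structure(list(mwf = mwf, angle = as.numeric(ang),
                 chi2_min = reg$chi2_min, chi2_reg = reg$chi2_reg,
                 mu = reg$mu, distribution = reg$distribution),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("voxel_fit: MWF %.4f, angle %.1f deg, chi2 %.3g -> %.3g\n",
              x$mwf, x$angle, x$chi2_min, x$chi2_reg))
  invisible(x)
}

#' Fit every in-mask voxel of a 4D decay volume
#'
#' Applies [fit_voxel()] independently to each voxel where `mask` is
#' nonzero. Candidate bases are computed once and shared.
#'
#' @param volume 4D array `(x, y, z, echo)`.
#' @param mask 3D array matching the spatial dimensions; nonzero = fit.
#' @param grid A [make_t2_grid()].
#' @param train An [echo_train()].
#' @param cfg A [fit_config()].
#' @param verbose Emit a progress message every 10000 voxels.
#' @return List of class `mwf_maps` with 3D arrays `mwf`, `angle`, `chi2`
#'   (`NA` outside the mask) and the number of voxels fit, `n_fit`.
#' @export
fit_volume <- function(volume, mask, grid = make_t2_grid(),
                       train = echo_train(), cfg = fit_config(),
                       verbose = FALSE) {
  dv <- dim(volume)
  if (length(dv) != 4L || dv[4] != train$n_echoes)
    stop("volume must be 4D with echo as 4th dimension matching the train",
         call. = FALSE)
  if (!identical(dim(mask), dv[1:3]))
    stop("mask dimensions must match the volume spatial dimensions",
         call. = FALSE)
  bases <- candidate_bases(grid, train, cfg)
  shape <- dv[1:3]
  mwf <- array(NA_real_, shape)
  ang <- array(NA_real_, shape)
  chi2 <- array(NA_real_, shape)
  idx <- which(mask != 0)
  vmat <- matrix(volume, prod(shape), dv[4])
  for (i in seq_along(idx)) {
    v <- idx[i]
    f <- fit_voxel(vmat[v, ], grid, train, cfg, bases)
    mwf[v] <- f$mwf; ang[v] <- f$angle; chi2[v] <- f$chi2_reg
    if (verbose && i %% 10000L == 0L)
      message(sprintf("fit %d / %d voxels", i, length(idx)))
  }
  structure(list(mwf = mwf, angle = ang, chi2 = chi2, n_fit = length(idx)),
            class = "mwf_maps")
}

#' @export
print.mwf_maps <- function(x, ...) {
  cat(sprintf("mwf_maps: %s grid, %d voxels fit, mean MWF %.4f\n",
              paste(dim(x$mwf), collapse = "x"), x$n_fit,
              mean(x$mwf, na.rm = TRUE)))
  invisible(x)
}
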