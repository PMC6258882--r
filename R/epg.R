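#' Multi-echo spin-echo train specification
#'
#' Describes a CPMG-style echo train: echoes are read at
#' `TE_i = i * echo_spacing`, with refocusing pulses midway between echoes.
#' The repetition time is recorded for provenance but does not enter the
#' decay model (TR saturation is absorbed into the voxel amplitude scale).
#'
#' @param echo_spacing Echo spacing in seconds (default 0.010).
#' @param n_echoes Number of echoes (default 32).
#' @param repetition_time Repetition time in seconds (default 1.0, unused).
#' @return An object of class `echo_train`.
#' @examples
#' echo_train()                      # 32 echoes, TE = 10..320 ms
#' echo_train(0.008, 48)
#' @export
echo_train <- function(echo_spacing = 0.010, n_echoes = 32L,
                       repetition_time = 1.0) {
  stopifnot(is.numeric(echo_spacing), length(echo_spacing) == 1,
            is.finite(echo_spacing), echo_spacing > 0)
  n_echoes <- as.integer(n_echoes)
  stopifnot(length(n_echoes) == 1, !is.na(n_echoes), n_echoes >= 1)
  structure(list(echo_spacing = echo_spacing, n_echoes = n_echoes,
                 repetition_time = repetition_time),
            class = "echo_train")
}

#' @export
print.echo_train <- function(x, ...) {
  cat(sprintf("echo_train: %d echoes, TE = %g..%g ms (ESP %g ms), TR %g ms\n",
              x$n_echoes, 1000 * x$echo_spacing,
              1000 * x$echo_spacing * x$n_echoes,
              1000 * x$echo_spacing, 1000 * x$repetition_time))
  invisible(x)
}

#' Echo times of a train
#' @param train An [echo_train()].
#' @return Numeric vector of echo times in seconds.
#' @export
echo_times <- function(train) {
  train$echo_spacing * seq_len(train$n_echoes)
}

check_relax <- function(t2, t1) {
  stopifnot(is.numeric(t2), is.numeric(t1),
            all(is.finite(t2)), all(is.finite(t1)))
  if (any(t2 <= 0) || any(t1 <= 0))
    stop("relaxation times must be positive", call. = FALSE)
  if (any(t2 > t1))
    warning("t2 > t1 is unphysical; proceeding anyway", call. = FALSE)
  invisible(TRUE)
}

# Core EPG recursion, vectorized over a vector of T2 values sharing one T1,
# flip angle and train. Configuration states advance by one order per
# half-interval (pulses sit midway between echoes), so orders up to
# 2*(n_echoes+1) are reachable; the state ladder is truncated there.
# Longitudinal relaxation omits the equilibrium regrowth term: pathways
# that were never excited cannot contribute to the echoes of a single
# excitation, and TR saturation is treated as an amplitude scale factor.
epg_train_matrix <- function(t2, t1, refocus_angle, train) {
  n_t2 <- length(t2)
  n_echoes <- train$n_echoes
  a <- refocus_angle * pi / 180
  K <- 2L * (n_echoes + 1L)      # highest reachable dephasing order

  # states: rows = order 0..K, cols = T2 values
  Fp <- matrix(0i, K + 1L, n_t2)
  Fm <- matrix(0i, K + 1L, n_t2)
  Z  <- matrix(0i, K + 1L, n_t2)
  Fp[1L, ] <- -1i                # instantaneous 90deg excitation about x

  E2h <- matrix(exp(-train$echo_spacing / 2 / t2), K + 1L, n_t2, byrow = TRUE)
  E1h <- exp(-train$echo_spacing / 2 / t1)

  # refocusing pulse of flip a about y (CPMG phase), acting on (F+, F-, Z)
  ca2 <- cos(a / 2)^2; sa2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  ephi <- exp(1i * pi / 2)
  T11 <- ca2;                T12 <- ephi^2 * sa2;  T13 <- -1i * ephi * sa
  T21 <- Conj(ephi^2) * sa2; T22 <- ca2;           T23 <- 1i * Conj(ephi) * sa
  T31 <- -0.5i * Conj(ephi) * sa; T32 <- 0.5i * ephi * sa; T33 <- ca

  out <- matrix(0, n_echoes, n_t2)
  for (e in seq_len(n_echoes)) {
    for (half in 1:2) {
      Fp <- Fp * E2h; Fm <- Fm * E2h; Z <- Z * E1h
      # dephase by +1 order: F(k) -> F(k+1); the old F(-1) state becomes F(0)
      Fp <- rbind(Conj(Fm[2L, , drop = FALSE]), Fp[seq_len(K), , drop = FALSE])
      Fm <- rbind(Conj(Fp[1L, , drop = FALSE]),
                  Fm[3:(K + 1L), , drop = FALSE],
                  matrix(0i, 1L, n_t2))
      if (half == 1L) {
        Fp2 <- T11 * Fp + T12 * Fm + T13 * Z
        Fm2 <- T21 * Fp + T22 * Fm + T23 * Z
        Z   <- T31 * Fp + T32 * Fm + T33 * Z
        Fp <- Fp2; Fm <- Fm2
        Fm[1L, ] <- Conj(Fp[1L, ])
      }
    }
    out[e, ] <- Mod(Fp[1L, ])
  }
  out
}

#' EPG echo amplitudes for an imperfect refocusing train
#'
#' Computes the echo-top amplitudes of a CPMG-style multi-echo train using
#' the extended phase graph (EPG) formalism. The excitation pulse is an
#' ideal 90 degrees; all refocusing pulses share the flip angle
#' `refocus_angle` about the CPMG axis. Below 180 degrees, stimulated-echo
#' pathways (stored as longitudinal configuration states between pulses)
#' contribute to later echoes, which is the signal shape exploited by
#' stimulated-echo correction.
#'
#' @param t2 Transverse relaxation time in seconds.
#' @param t1 Longitudinal relaxation time in seconds (default 1.0, the
#'   conventional white-matter assumption when T1 is not mapped).
#' @param refocus_angle Refocusing flip angle in degrees, in (0, 180].
#' @param train An [echo_train()].
#' @return Numeric vector of `n_echoes` nonnegative amplitudes (M0 = 1).
#' @examples
#' a <- epg_echo_amplitudes(0.1, 1.0, 180, echo_train())
#' all.equal(a, exp(-echo_times(echo_train()) / 0.1))  # ideal limit
#' @seealso [isochromat_reference()] for the brute-force Bloch oracle.
#' @export
epg_echo_amplitudes <- function(t2, t1 = 1.0, refocus_angle,
                                train = echo_train()) {
  check_relax(t2, t1)
  stopifnot(length(t2) == 1, length(refocus_angle) == 1)
  if (!is.finite(refocus_angle) || refocus_angle <= 0 || refocus_angle > 180)
    stop("refocus_angle must be in (0, 180] degrees", call. = FALSE)
  drop(epg_train_matrix(t2, t1, refocus_angle, train))
}

#' Isochromat (Bloch rotation) reference simulation
#'
#' Brute-force oracle for [epg_echo_amplitudes()]: simulates `n_spins`
#' isochromats whose per-echo-spacing dephasing angles uniformly cover
#' 2*pi, applying explicit rotation matrices for the 90-degree excitation
#' and every refocusing pulse, with T2/T1 relaxation (no equilibrium
#' regrowth) between events. The voxel signal is the modulus of the mean
#' transverse magnetization at each echo top. Converges to the EPG result
#' as `n_spins` grows; with uniformly spaced phases the quadrature is
#' exact once `n_spins` exceeds the highest reachable dephasing order.
#'
#' @inheritParams epg_echo_amplitudes
#' @param n_spins Number of isochromats (>= 1000).
#' @return Numeric vector of `n_echoes` amplitudes.
#' @export
isochromat_reference <- function(t2, t1 = 1.0, refocus_angle,
                                 train = echo_train(), n_spins = 10000L) {
  check_relax(t2, t1)
  if (!is.finite(refocus_angle) || refocus_angle < 0 || refocus_angle > 180)
    stop("refocus_angle must be in [0, 180] degrees", call. = FALSE)
  n_spins <- as.integer(n_spins)
  stopifnot(n_spins >= 1000L)

  a <- refocus_angle * pi / 180
  th <- 2 * pi * ((seq_len(n_spins) - 0.5) / n_spins) - pi  # dephasing per ESP
  c2 <- cos(th / 2); s2 <- sin(th / 2)
  E2h <- exp(-train$echo_spacing / 2 / t2)
  E1h <- exp(-train$echo_spacing / 2 / t1)
  ca <- cos(a); sa <- sin(a)

  # 90deg about x: (0, 0, 1) -> (0, -1, 0)
  Mx <- numeric(n_spins); My <- rep(-1, n_spins); Mz <- numeric(n_spins)
  out <- numeric(train$n_echoes)
  for (e in seq_len(train$n_echoes)) {
    # free precession + relaxation over ESP/2
    Mx2 <- Mx * c2 - My * s2; My2 <- Mx * s2 + My * c2
    Mx <- Mx2 * E2h; My <- My2 * E2h; Mz <- Mz * E1h
    # refocusing rotation about y
    Mx2 <- Mx * ca + Mz * sa; Mz <- -Mx * sa + Mz * ca; Mx <- Mx2
    # second half interval
    Mx2 <- Mx * c2 - My * s2; My2 <- Mx * s2 + My * c2
    Mx <- Mx2 * E2h; My <- My2 * E2h; Mz <- Mz * E1h
    out[e] <- Mod(complex(real = mean(Mx), imaginary = mean(My)))
  }
  out
}
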