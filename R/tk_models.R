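#' Brix II (two-compartment exchange) forward model
#'
#' The ROI is a well-mixed plasma compartment of relative volume `phi_P`
#' fed directly by the AIF with flow `F`, exchanging with an interstitial
#' compartment of volume `phi_I = 1 - phi_P` at rate `K_PS`:
#' \deqn{\frac{d(\phi_P C_P)}{dt} = \frac{F}{V}(C_A - C_P) -
#'       \frac{K_{PS}}{V}(C_P - C_I), \qquad
#'       \frac{d(\phi_I C_I)}{dt} = \frac{K_{PS}}{V}(C_P - C_I),}
#' integrated by implicit Euler (exact linear 2x2 update per substep) on
#' the measurement grid. The returned total concentration is
#' `C = phi_P C_P + phi_I C_I`. Degenerate volumes (`phi_P` of 0 or 1) are
#' handled by compartment elimination.
#'
#' @param phi_P Plasma volume fraction in `[0, 1]`.
#' @param F Flow in um^3/s (>= 0).
#' @param K_PS Exchange rate in um^3/s (>= 0).
#' @param aif An [aif_model()].
#' @param V ROI volume in um^3.
#' @param times Strictly increasing measurement times (s) starting at >= 0.
#' @param n_substeps Implicit-Euler substeps per measurement interval.
#' @return Total concentration `C(t)` in mM at `times`.
#' @export
brix2_forward <- function(phi_P, F, K_PS, aif, V, times, n_substeps = 8) {
  check_tk_times(times)
  if (V <= 0) stop_invalid("ROI volume must be > 0")
  if (phi_P < 0 || phi_P > 1 || F < 0 || K_PS < 0)
    stop_invalid("invalid Brix II parameters")
  phi_I <- 1 - phi_P
  eps <- 1e-9
  tg <- refine_grid(times, n_substeps)
  CAg <- aif_value(tg, aif)
  hs <- diff(tg)
  CP <- 0; CI <- 0
  CPg <- numeric(length(tg)); CIg <- numeric(length(tg))
  if (phi_P <= eps) {
    ki0 <- K_PS / (V * max(phi_I, eps))
    for (n in seq_along(hs)) {
      CA <- CAg[n + 1]
      CP <- if (F + K_PS > 0) (F * CA + K_PS * CI) / (F + K_PS) else 0
      CI <- (CI + hs[n] * ki0 * CP) / (1 + hs[n] * ki0)
      CPg[n + 1] <- CP; CIg[n + 1] <- CI
    }
  } else if (phi_I <= eps) {
    for (n in seq_along(hs)) {
      a <- hs[n] * F / (V * phi_P)
      CP <- (CP + a * CAg[n + 1]) / (1 + a)
      CPg[n + 1] <- CP; CIg[n + 1] <- CP
    }
    CIg <- CPg
  } else {
    aV <- hs * F / (V * phi_P)
    bV <- hs * K_PS / (V * phi_P)
    cV <- hs * K_PS / (V * phi_I)
    detV <- (1 + aV + bV) * (1 + cV) - bV * cV
    for (n in seq_along(hs)) {
      z <- CP + aV[n] * CAg[n + 1]
      CPn <- (z * (1 + cV[n]) + bV[n] * CI) / detV[n]
      CIn <- (CI * (1 + aV[n] + bV[n]) + cV[n] * z) / detV[n]
      CP <- CPn; CI <- CIn
      CPg[n + 1] <- CP; CIg[n + 1] <- CI
    }
  }
  sel <- match_times(tg, times)
  phi_P * CPg[sel] + phi_I * CIg[sel]
}

#' Delay-extended Tofts forward model
#'
#' Blood-pool plus leakage model with a bolus-arrival delay `t_0`:
#' \deqn{C(t) = \phi_P C_A(t - t_0) + K^{trans} \int_{-\infty}^{t}
#'   C_A(t' - t_0)\, e^{-K^{trans}/\phi_I (t - t')}\, dt',}
#' where `Ktrans = KtransV / V` and `phi_I = 1 - phi_P`. The convolution is
#' evaluated by the causal trapezoidal rule applied recursively to the
#' exponential kernel on a refined grid; the delayed AIF is interpolated
#' continuously, so sub-frame delays are resolved.
#'
#' @param phi_P Plasma volume fraction in `[0, 1]`.
#' @param KtransV Transfer constant times ROI volume, um^3/s (>= 0);
#'   comparable to `K_PS` of the Brix II model.
#' @param t0 Bolus arrival delay in s (>= 0).
#' @inheritParams brix2_forward
#' @return Total concentration `C(t)` in mM at `times`.
#' @export
detofts_forward <- function(phi_P, KtransV, t0, aif, V, times,
                            n_substeps = 8) {
  check_tk_times(times)
  if (V <= 0) stop_invalid("ROI volume must be > 0")
  if (phi_P < 0 || phi_P > 1 || KtransV < 0 || t0 < 0)
    stop_invalid("invalid DE-Tofts parameters")
  phi_I <- 1 - phi_P
  Ktrans <- KtransV / V
  blood <- phi_P * aif_value(times - t0, aif)
  if (Ktrans <= 0 || phi_I <= 1e-9) return(blood)
  k <- Ktrans / phi_I
  # refined grid for the convolution
  tg <- refine_grid(times, n_substeps)
  u <- aif_value(tg - t0, aif)
  J <- numeric(length(tg))
  for (n in 2:length(tg)) {
    d <- tg[n] - tg[n - 1]
    E <- exp(-k * d)
    J[n] <- J[n - 1] * E + d / 2 * (u[n] + E * u[n - 1])
  }
  leak <- Ktrans * J[match_times(tg, times)]
  blood + leak
}

check_tk_times <- function(times) {
  if (length(times) < 2) stop_invalid("need at least two measurement times")
  if (times[1] < 0 || any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing from >= 0")
}

refine_grid <- function(times, n_substeps) {
  if (n_substeps <= 1) return(times)
  out <- unlist(lapply(seq_len(length(times) - 1), function(n)
    seq(times[n], times[n + 1], length.out = n_substeps + 1)[-(n_substeps + 1)]))
  c(out, times[length(times)])
}

match_times <- function(grid, times) {
  vapply(times, function(t) which.min(abs(grid - t)), integer(1))
}
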