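# 15N backbone dynamics: R1/R2 exponential fitting, heteronuclear NOE,
# reduced spectral density mapping, and H/D exchange kinetics.

# Physical constants (SI)
.nmr_const <- list(
  mu0    = 4 * pi * 1e-7,        # vacuum permeability, T m / A
  hbar   = 1.054571817e-34,      # J s
  gamma_h = 2.6752218744e8,      # 1H gyromagnetic ratio, rad s^-1 T^-1
  gamma_n = -2.71261804e7        # 15N gyromagnetic ratio (negative)
)

#' Spectrometer field parameters for 15N relaxation
#'
#' Collects the Larmor frequencies and interaction constants needed for
#' reduced spectral density mapping. Defaults correspond to an 18.8 T
#' spectrometer (1H at 800.13 MHz), an N-H bond length of 1.02 Angstrom and a
#' 15N CSA of -160 ppm.
#'
#' @param b0 Static field (Tesla). Used only when `freq_h_mhz` is `NULL`.
#' @param freq_h_mhz Proton frequency in MHz; overrides `b0` when given.
#' @param r_nh N-H bond length (m).
#' @param csa 15N chemical shift anisotropy (dimensionless, e.g. -160e-6).
#' @return List of class `field_params`: `omega_h`, `omega_n` (rad/s, signed),
#'   `d2` (squared dipolar constant, rad^2/s^2), `c2` (squared CSA constant),
#'   `gamma_ratio` (gamma_H / gamma_N, signed).
#' @export
field_params <- function(b0 = 18.8, freq_h_mhz = 800.13,
                         r_nh = 1.02e-10, csa = -160e-6) {
  omega_h <- if (is.null(freq_h_mhz)) .nmr_const$gamma_h * b0 else
    2 * pi * freq_h_mhz * 1e6
  omega_n <- omega_h * .nmr_const$gamma_n / .nmr_const$gamma_h
  d <- .nmr_const$mu0 * .nmr_const$hbar * .nmr_const$gamma_h *
    .nmr_const$gamma_n / (4 * pi * r_nh^3)
  c2 <- (omega_n * csa)^2 / 3
  structure(list(omega_h = omega_h, omega_n = omega_n,
                 d2 = d^2, c2 = c2,
                 gamma_ratio = .nmr_const$gamma_h / .nmr_const$gamma_n),
            class = "field_params")
}

#' Lipari-Szabo spectral density
#'
#' `J(w) = 2/5 * (S2 tau_m / (1 + (w tau_m)^2) + (1 - S2) tau / (1 + (w tau)^2))`
#' with `1/tau = 1/tau_m + 1/tau_e`. `S2 = 1` gives the rigid single-Lorentzian
#' limit.
#'
#' @param omega Angular frequency (rad/s); vectorised.
#' @param tau_m Overall tumbling time (s).
#' @param s2 Generalised order parameter in \[0, 1\].
#' @param tau_e Effective internal correlation time (s); must be < `tau_m`.
#' @return J in s/rad.
#' @export
spectral_density_ls <- function(omega, tau_m, s2 = 1, tau_e = 0) {
  if (s2 < 0 || s2 > 1) stop("s2 must be in [0, 1]")
  if (tau_e >= tau_m) stop("tau_e must be smaller than tau_m")
  j <- s2 * tau_m / (1 + (omega * tau_m)^2)
  if (s2 < 1 && tau_e > 0) {
    tau <- tau_m * tau_e / (tau_m + tau_e)
    j <- j + (1 - s2) * tau / (1 + (omega * tau)^2)
  }
  0.4 * j
}

#' Forward relaxation observables from a spectral density
#'
#' Computes R1, R2 and the steady-state heteronuclear NOE for an amide 15N
#' from a spectral density function. `approx = "reduced"` evaluates the
#' high-frequency terms at 0.87 wH with the reduced-mapping coefficients
#' (7 for R1, 13 for R2, 5 for the cross-relaxation term), making the
#' mapping in [map_spectral_density()] an exact inverse; `approx = "full"`
#' evaluates J at wH - wN, wH and wH + wN separately.
#'
#' @param j A function of angular frequency returning J (s/rad).
#' @param field [field_params()].
#' @param approx `"reduced"` or `"full"`.
#' @param rex Additive chemical-exchange contribution to R2 (s^-1).
#' @return List with `r1`, `r2` (s^-1) and `noe` (ratio).
#' @export
forward_relaxation <- function(j, field = field_params(),
                               approx = c("reduced", "full"), rex = 0) {
  approx <- match.arg(approx)
  wn <- abs(field$omega_n); wh <- abs(field$omega_h)
  d2 <- field$d2; c2 <- field$c2
  j0 <- j(0); jn <- j(wn)
  if (approx == "reduced") {
    jh <- j(0.87 * wh)
    r1 <- (d2 / 4) * (3 * jn + 7 * jh) + c2 * jn
    r2 <- (d2 / 8) * (4 * j0 + 3 * jn + 13 * jh) +
      (c2 / 6) * (4 * j0 + 3 * jn) + rex
    sigma <- (d2 / 4) * 5 * jh
  } else {
    jmh <- j(wh - wn); jph <- j(wh + wn); jhh <- j(wh)
    r1 <- (d2 / 4) * (jmh + 3 * jn + 6 * jph) + c2 * jn
    r2 <- (d2 / 8) * (4 * j0 + jmh + 3 * jn + 6 * jhh + 6 * jph) +
      (c2 / 6) * (4 * j0 + 3 * jn) + rex
    sigma <- (d2 / 4) * (6 * jph - jmh)
  }
  noe <- 1 + field$gamma_ratio * sigma / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

#' Heteronuclear NOE from a peak-volume pair
#'
#' Ratio of the amide peak volume with proton saturation to the volume
#' without.
#'
#' @param vol_sat Saturated-spectrum peak volume.
#' @param vol_unsat Unsaturated-spectrum peak volume (non-zero).
#' @return NOE ratio.
#' @export
het_noe <- function(vol_sat, vol_unsat) {
  if (any(vol_unsat == 0)) stop("unsaturated peak volume must be non-zero")
  vol_sat / vol_unsat
}

#' Fit a mono-exponential relaxation decay
#'
#' Non-linear least-squares fit of `I(t) = I0 exp(-R t)` by Levenberg-
#' Marquardt, started from a log-linear regression. The rate standard
#' deviation comes from the curvature (inverse-Hessian) matrix of the fit and
#' a t-based 95% confidence interval is reported.
#'
#' @param delays Delay times (s), >= 3 distinct values.
#' @param intensities Peak intensities (same length).
#' @return Object of class `rate_fit`: `rate` (s^-1), `amplitude`, `sd`,
#'   `ci95` (length-2), `ok` (logical fit-success flag), `reason` when failed.
#' @export
fit_rate <- function(delays, intensities) {
  fail <- function(reason)
    structure(list(rate = NA_real_, amplitude = NA_real_, sd = NA_real_,
                   ci95 = c(NA_real_, NA_real_), ok = FALSE, reason = reason),
              class = "rate_fit")
  if (length(delays) != length(intensities))
    stop("delays and intensities must have equal length")
  if (length(unique(delays)) < 3) return(fail("fewer than 3 distinct delays"))
  if (!all(is.finite(intensities))) return(fail("non-finite intensities"))
  if (stats::sd(intensities) == 0) return(fail("constant intensities"))
  pos <- intensities > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(intensities[pos]) ~ delays[pos])
    r0 <- -unname(stats::coef(lf)[2]); i0 <- exp(unname(stats::coef(lf)[1]))
  } else {
    r0 <- 1 / max(delays); i0 <- max(abs(intensities))
  }
  if (!is.finite(r0) || r0 <= 0) return(fail("non-decaying data"))
  df <- data.frame(t = delays, y = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-r * t), data = df,
                      start = list(i0 = i0, r = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  est <- stats::coef(fit)
  if (!is.finite(est[["r"]]) || est[["r"]] <= 0)
    return(fail("fitted rate not positive"))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || !is.finite(vc["r", "r"]) || vc["r", "r"] < 0)
    return(fail("singular curvature matrix"))
  se <- sqrt(vc["r", "r"])
  dfree <- length(delays) - 2L
  tq <- stats::qt(0.975, dfree)
  structure(list(rate = unname(est[["r"]]), amplitude = unname(est[["i0"]]),
                 sd = se, ci95 = unname(est[["r"]]) + c(-1, 1) * tq * se,
                 ok = TRUE, reason = NULL),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<rate_fit> R = %.4g s^-1 (sd %.3g, 95%% CI [%.4g, %.4g])\n",
                x$rate, x$sd, x$ci95[1], x$ci95[2]))
  else
    cat(sprintf("<rate_fit> FAILED: %s\n", x$reason))
  invisible(x)
}

#' Reduced spectral density mapping
#'
#' Inverts the reduced-mapping relations to obtain J(0), J(wN) and
#' J(0.87 wH) from R1, R2 and the heteronuclear NOE:
#' \deqn{\sigma_{NH} = (NOE - 1) R_1 \gamma_N / \gamma_H}
#' \deqn{J(0.87\omega_H) = 4\sigma_{NH} / (5 d^2)}
#' \deqn{J(\omega_N) = (R_1 - 7 d^2 J(0.87\omega_H)/4) / (3 d^2/4 + c^2)}
#' \deqn{J(0) = (R_2 - d^2(3J(\omega_N) + 13J(0.87\omega_H))/8 -
#'   c^2 J(\omega_N)/2) / (d^2/2 + 2 c^2/3)}
#'
#' @param r1,r2 Relaxation rates (s^-1), positive; vectorised.
#' @param noe NOE ratio(s).
#' @param field [field_params()].
#' @param neg_tol J values below `-neg_tol` (s/rad) are flagged.
#' @return data.frame with `j0`, `jn`, `jh` (s/rad) and `flagged` (negative
#'   J beyond tolerance, indicating noise or exchange inconsistency).
#' @export
map_spectral_density <- function(r1, r2, noe, field = field_params(),
                                 neg_tol = 1e-12) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("rates must be positive")
  d2 <- field$d2; c2 <- field$c2
  sigma <- (noe - 1) * r1 / field$gamma_ratio
  jh <- 4 * sigma / (5 * d2)
  jn <- (r1 - (7 * d2 / 4) * jh) / (3 * d2 / 4 + c2)
  j0 <- (r2 - (d2 / 8) * (3 * jn + 13 * jh) - (c2 / 2) * jn) /
    (d2 / 2 + 2 * c2 / 3)
  data.frame(j0 = j0, jn = jn, jh = jh,
             flagged = j0 < -neg_tol | jn < -neg_tol | jh < -neg_tol)
}

#' Heuristic exchange-contribution estimate from J(0)
#'
#' Slow (us-ms) exchange inflates R2 and hence the apparent J(0). This
#' heuristic takes a robust per-protein baseline (10% trimmed mean of J(0))
#' and converts each residue's excess J(0) back to rate units.
#'
#' @param j0 Per-residue J(0) values (s/rad).
#' @param field [field_params()].
#' @param trim Trim fraction for the baseline mean.
#' @return Numeric vector of R_ex estimates (s^-1); negative excesses clip
#'   to zero.
#' @export
estimate_rex <- function(j0, field = field_params(), trim = 0.1) {
  baseline <- mean(j0, trim = trim)
  pmax(0, (j0 - baseline) * (field$d2 / 2 + 2 * field$c2 / 3))
}

#' Fit an H/D-exchange decay and half-life
#'
#' Fits `v = v0 exp(-k t)` to amide peak integrals versus time (hours) and
#' reports the half-life ln(2)/k. Residues with fewer than 3 observed points
#' are classified as exchanging too fast to measure.
#'
#' @param times Time points (h).
#' @param integrals Peak integrals.
#' @return Object of class `hdx_fit`: `half_life` (h), `k` (h^-1),
#'   `detectable` (logical), `fit` (the underlying `rate_fit`).
#' @export
fit_hdx_halflife <- function(times, integrals) {
  keep <- is.finite(integrals)
  times <- times[keep]; integrals <- integrals[keep]
  if (length(times) < 3) {
    return(structure(list(half_life = NA_real_, k = NA_real_,
                          detectable = FALSE, fit = NULL),
                     class = "hdx_fit"))
  }
  fit <- fit_rate(times, integrals)
  if (!fit$ok) {
    return(structure(list(half_life = NA_real_, k = NA_real_,
                          detectable = TRUE, fit = fit),
                     class = "hdx_fit"))
  }
  structure(list(half_life = log(2) / fit$rate, k = fit$rate,
                 detectable = TRUE, fit = fit),
            class = "hdx_fit")
}

#' @export
print.hdx_fit <- function(x, ...) {
  if (!x$detectable)
    cat("<hdx_fit> undetectable (fewer than 3 points: exchange too fast)\n")
  else if (is.na(x$half_life))
    cat("<hdx_fit> fit failed\n")
  else
    cat(sprintf("<hdx_fit> t1/2 = %.3g h (k = %.3g h^-1)\n",
                x$half_life, x$k))
  invisible(x)
}

#' Classify slow-exchanging amides
#'
#' Residues whose fitted exchange half-life strictly exceeds the threshold;
#' these are candidates for hydrogen bonding or burial. Undetectable residues
#' (no fit) are excluded.
#'
#' @param half_lives Named numeric vector (or data.frame with `residue`,
#'   `half_life`) of fitted half-lives in hours; `NA` = undetectable.
#' @param threshold_h Half-life threshold (h); default 2.5.
#' @return Character vector of residue ids with `t1/2 > threshold_h`.
#' @export
classify_slow_exchangers <- function(half_lives, threshold_h = 2.5) {
  if (is.data.frame(half_lives)) {
    hl <- stats::setNames(half_lives$half_life, half_lives$residue)
  } else hl <- half_lives
  names(hl)[!is.na(hl) & hl > threshold_h]
}
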