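#' Structural pharmacokinetic parameters
#'
#' Individual one-compartment parameters for oral dosing: first-order
#' absorption rate constant `ka`, apparent volume of distribution `V`
#' and apparent clearance `Cl`. Parameters are "apparent" (scaled by
#' bioavailability, F = 1): they are the quantities identifiable from
#' oral concentration data alone.
#'
#' @param ka absorption rate constant (1/h), > 0
#' @param V apparent volume of distribution (L), > 0
#' @param Cl apparent clearance (L/h), > 0
#' @return an object of class `pk_params`
#' @examples
#' p <- pk_params(ka = 0.18, V = 192.42, Cl = 9.3)
#' half_life(p)
#' @export
pk_params <- function(ka, V, Cl) {
  for (nm in c("ka", "V", "Cl")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("invalid parameter: '", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  structure(list(ka = ka, V = V, Cl = Cl), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("One-compartment oral PK parameters\n  ka = %.4g 1/h, V = %.4g L, Cl = %.4g L/h\n  ke = %.4g 1/h, t1/2 = %.3g h\n",
              x$ka, x$V, x$Cl, ke(x), half_life(x)))
  invisible(x)
}

#' Elimination rate constant
#'
#' @param p a [pk_params()] object
#' @return ke = Cl/V (1/h)
#' @export
ke <- function(p) p$Cl / p$V

#' Elimination half-life
#'
#' @param p a [pk_params()] object
#' @return ln(2) V / Cl, in hours
#' @export
half_life <- function(p) log(2) * p$V / p$Cl

#' Dosing regimen
#'
#' A fixed repeated-dose oral regimen: `dose` mg every `interval` hours,
#' for `n_doses` administrations (use `Inf` for continued dosing to
#' steady state). Doses are EC-MPS-equivalent milligrams; MMF doses must
#' be converted first (see [convert_mmf_dose()]).
#'
#' @param dose mg per administration, >= 0
#' @param interval h between doses, > 0
#' @param n_doses number of administrations (>= 1) or `Inf`
#' @return an object of class `regimen`
#' @export
regimen <- function(dose, interval = 12, n_doses = Inf) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop("invalid regimen: 'dose' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(interval) || length(interval) != 1L || !is.finite(interval) || interval <= 0)
    stop("invalid regimen: 'interval' must be a single positive number", call. = FALSE)
  if (!is.numeric(n_doses) || length(n_doses) != 1L || is.na(n_doses) || n_doses < 1)
    stop("invalid regimen: 'n_doses' must be >= 1 (or Inf for steady state)", call. = FALSE)
  structure(list(dose = dose, interval = interval, n_doses = n_doses), class = "regimen")
}

# relative tolerance below which ka and ke are treated as coincident
# (flip-flop degeneracy) and the analytic limit is used
.KA_KE_TOL <- 1e-8

#' Concentration after a single oral dose
#'
#' Closed-form one-compartment concentration with first-order absorption
#' and elimination:
#' C(t) = dose ka / (V (ka - ke)) (exp(-ke t) - exp(-ka t)), ke = Cl/V.
#' When |ka - ke| is below a small relative tolerance the analytic limit
#' dose ka t exp(-ka t) / V is used.
#'
#' @param p a [pk_params()] object
#' @param dose mg administered at t = 0
#' @param t time since the dose (h), vectorised, >= 0
#' @return concentration in mg/L at each `t`
#' @examples
#' p <- pk_params(0.18, 192.42, 9.3)
#' conc_single_dose(p, 720, c(0, 6, 12))
#' @export
conc_single_dose <- function(p, dose, t) {
  stopifnot(inherits(p, "pk_params"))
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop("'dose' must be a single non-negative number", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  kel <- ke(p)
  if (abs(p$ka - kel) < .KA_KE_TOL * kel) {
    dose * p$ka * t * exp(-p$ka * t) / p$V
  } else {
    dose * p$ka / (p$V * (p$ka - kel)) * (exp(-kel * t) - exp(-p$ka * t))
  }
}

#' Concentration under repeated dosing (superposition)
#'
#' Sum of [conc_single_dose()] contributions from every administration
#' at or before `t`. Linear kinetics make superposition exact.
#'
#' @param p a [pk_params()] object
#' @param r a [regimen()]; `n_doses = Inf` is truncated once remaining
#'   contributions are negligible (20 half-lives back)
#' @param t time since the first dose (h), vectorised
#' @return concentration in mg/L at each `t`
#' @export
conc_multi_dose <- function(p, r, t) {
  stopifnot(inherits(p, "pk_params"), inherits(r, "regimen"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  vapply(t, function(ti) {
    n_avail <- floor(ti / r$interval) + 1   # doses at 0, tau, 2 tau, ... <= ti
    n <- min(n_avail, r$n_doses)
    # doses older than 20 half-lives of both processes contribute nothing
    horizon <- 20 * log(2) / min(p$ka, ke(p))
    k0 <- max(0, ceiling((ti - horizon) / r$interval))
    kk <- k0:(n - 1)
    sum(conc_single_dose(p, r$dose, ti - kk * r$interval))
  }, numeric(1))
}

# fully vectorised steady-state concentration (all arguments recycled);
# used on the estimation/simulation hot path. tad in [0, ii].
.css_vec <- function(ka, V, Cl, dose, ii, tad) {
  kel <- Cl / V
  n <- max(length(ka), length(V), length(Cl), length(dose), length(ii), length(tad))
  ka <- rep_len(ka, n); V <- rep_len(V, n); kel <- rep_len(kel, n)
  dose <- rep_len(dose, n); ii <- rep_len(ii, n); tad <- rep_len(tad, n)
  out <- numeric(n)
  deg <- abs(ka - kel) < 1e-8 * kel
  if (any(!deg)) {
    i <- !deg
    coef <- dose[i] * ka[i] / (V[i] * (ka[i] - kel[i]))
    out[i] <- coef * (exp(-kel[i] * tad[i]) / (1 - exp(-kel[i] * ii[i])) -
                      exp(-ka[i] * tad[i]) / (1 - exp(-ka[i] * ii[i])))
  }
  if (any(deg)) {
    # ka -> ke limit of the steady-state superposition:
    # D ka/V e^(-ka t) [ t/(1-q) + ii q/(1-q)^2 ], q = e^(-ka ii)
    i <- deg
    q <- exp(-ka[i] * ii[i])
    out[i] <- dose[i] * ka[i] / V[i] * exp(-ka[i] * tad[i]) *
      (tad[i] / (1 - q) + ii[i] * q / (1 - q)^2)
  }
  out
}

#' Steady-state concentration within a dosing interval
#'
#' Closed-form steady-state profile of repeated dosing, evaluated at
#' times `t` after a dose (0 <= t <= interval). Near the ka = ke
#' degeneracy an explicit long-run superposition is used instead.
#'
#' @param p a [pk_params()] object
#' @param dose mg per administration
#' @param interval h between doses
#' @param t time after a dose (h), vectorised
#' @return concentration in mg/L at each `t`
#' @export
conc_ss <- function(p, dose, interval, t) {
  kel <- ke(p)
  if (abs(p$ka - kel) < 1e-6 * kel) {
    # near flip-flop degeneracy: explicit superposition over 30 half-lives
    n <- ceiling(30 * log(2) / (kel * interval)) + 1
    r <- regimen(dose, interval, n)
    return(conc_multi_dose(p, r, (n - 1) * interval + t))
  }
  coef <- dose * p$ka / (p$V * (p$ka - kel))
  coef * (exp(-kel * t) / (1 - exp(-kel * interval)) -
          exp(-p$ka * t) / (1 - exp(-p$ka * interval)))
}

#' Steady-state AUC over one dosing interval
#'
#' Under linear kinetics the steady-state AUC over a full dosing
#' interval equals dose/Cl regardless of ka and V. 1 mg.h/L is
#' numerically identical to 1 ug.h/mL, the unit of the therapeutic
#' window.
#'
#' @param p a [pk_params()] object
#' @param r a [regimen()]
#' @return AUC over one interval at steady state (mg.h/L)
#' @examples
#' auc_tau_ss(pk_params(0.18, 192.42, 9.3), regimen(720, 12))  # 77.42
#' @export
auc_tau_ss <- function(p, r) {
  stopifnot(inherits(p, "pk_params"), inherits(r, "regimen"))
  r$dose / p$Cl
}

#' Steady-state AUC over a sub-window of the dosing interval
#'
#' Analytic integral of the steady-state profile from `t1` to `t2`
#' (hours after a dose, both within one interval). Used to compute
#' AUC 0-12 for once-daily regimens, where the first 12 h hold slightly
#' more than half of the daily exposure.
#'
#' @param p a [pk_params()] object
#' @param dose mg per administration
#' @param interval h between doses
#' @param t1,t2 window bounds in h after a dose, 0 <= t1 < t2 <= interval
#' @return AUC over `[t1, t2]` at steady state (mg.h/L)
#' @export
auc_ss_window <- function(p, dose, interval, t1 = 0, t2 = interval) {
  stopifnot(inherits(p, "pk_params"))
  if (t1 < 0 || t2 > interval || t1 >= t2)
    stop("require 0 <= t1 < t2 <= interval", call. = FALSE)
  kel <- ke(p)
  if (abs(p$ka - kel) < 1e-6 * kel) {
    return(stats::integrate(function(t) conc_ss(p, dose, interval, t),
                            t1, t2, rel.tol = 1e-10)$value)
  }
  coef <- dose * p$ka / (p$V * (p$ka - kel))
  int_exp <- function(k) (exp(-k * t1) - exp(-k * t2)) / k
  coef * (int_exp(kel) / (1 - exp(-kel * interval)) -
          int_exp(p$ka) / (1 - exp(-p$ka * interval)))
}

#' Steady-state trough concentration
#'
#' Concentration immediately before a dose at steady state (the C0
#' measured in trough-only therapeutic drug monitoring). Equals the
#' limit of pre-dose values under continued dosing.
#'
#' @param p a [pk_params()] object
#' @param r a [regimen()]
#' @return trough concentration (mg/L)
#' @export
trough_ss <- function(p, r) {
  stopifnot(inherits(p, "pk_params"), inherits(r, "regimen"))
  conc_ss(p, r$dose, r$interval, r$interval)
}
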