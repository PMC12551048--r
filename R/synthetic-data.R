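#' Cohort design for the synthetic trough-only study
#'
#' Describes the monitoring design the generator emulates: adult renal
#' transplant recipients on twice-daily oral MPA, monthly visits with a
#' single steady-state pre-dose (trough) sample per visit, and a saliva
#' sample for a subset of patients at the first visit only. Defaults
#' reproduce the study scale: 76 patients (63 EC-MPS, 13 MMF), 209
#' plasma troughs over up to 6 monthly visits and 65 saliva samples.
#'
#' @param n_ecmps,n_mmf patients per formulation
#' @param target_samples total number of trough observations the visit
#'   draw is calibrated to
#' @param max_visits maximum monthly visits per patient
#' @param n_saliva patients with a first-visit saliva sample
#' @return an object of class `cohort_design`
#' @export
cohort_design <- function(n_ecmps = 63, n_mmf = 13, target_samples = 209,
                          max_visits = 6, n_saliva = 65) {
  n <- n_ecmps + n_mmf
  if (n < 1) stop("design needs at least one patient", call. = FALSE)
  if (n_saliva > n)
    stop("infeasible design: more saliva samples (", n_saliva,
         ") than patients (", n, ")", call. = FALSE)
  if (target_samples < n || target_samples > n * max_visits)
    stop("'target_samples' must lie in [n_patients, n_patients * max_visits]", call. = FALSE)
  structure(list(n_ecmps = n_ecmps, n_mmf = n_mmf, n_patients = n,
                 target_samples = target_samples, max_visits = max_visits,
                 n_saliva = n_saliva),
            class = "cohort_design")
}

# lognormal sdlog such that a median-m distribution has the given IQR:
# IQR = m (exp(q s) - exp(-q s)) with q = qnorm(0.75)
.sdlog_from_iqr <- function(median, iqr) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

.rlnorm_med_iqr <- function(n, median, iqr, lower = 0) {
  x <- stats::rlnorm(n, log(median), .sdlog_from_iqr(median, iqr))
  pmax(x, lower)
}

.rnorm_med_iqr <- function(n, median, iqr, lower) {
  x <- stats::rnorm(n, median, iqr / (2 * stats::qnorm(0.75)))
  pmax(x, lower)
}

# patient-level covariates; medians/IQRs follow the monitored cohort.
# urea and creatinine share a Gaussian copula (correlation 0.7) so the
# ML stages see the collinearity of renal markers.
.draw_covariates <- function(n) {
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  z[, 2] <- 0.7 * z[, 1] + sqrt(1 - 0.7^2) * z[, 2]
  urea  <- exp(log(7.8) + .sdlog_from_iqr(7.8, 5.4) * z[, 1])
  creat <- exp(log(136) + .sdlog_from_iqr(136, 60) * z[, 2])
  data.frame(
    AGE   = round(.rnorm_med_iqr(n, 51, 14, lower = 18)),
    SEX   = stats::rbinom(n, 1, 50 / 76),            # 1 = male
    PTP   = pmax(.rlnorm_med_iqr(n, 70, 84.3), 3),   # months, >= 3 by inclusion
    UREA  = urea,                                    # mmol/L
    CREAT = creat,                                   # umol/L
    WBC   = .rnorm_med_iqr(n, 7.9, 2.6, lower = 1),  # 10^9/L
    RBC   = .rnorm_med_iqr(n, 4.7, 0.9, lower = 2),  # 10^12/L
    HB    = .rnorm_med_iqr(n, 138, 32, lower = 60),  # g/L
    HT    = .rnorm_med_iqr(n, 41.4, 8.9, lower = 20),# %
    PLT   = .rnorm_med_iqr(n, 225, 88, lower = 30),  # 10^9/L
    DONOR = stats::rbinom(n, 1, 54 / 72)             # 1 = living donor
  )
}

# per-patient visit counts on 1..max_visits adjusted to an exact total
.draw_visit_counts <- function(n, total, max_visits) {
  lambda <- total / n
  probs <- stats::dpois(seq_len(max_visits), lambda)
  counts <- sample(seq_len(max_visits), n, replace = TRUE, prob = probs)
  while (sum(counts) != total) {
    if (sum(counts) < total) {
      i <- sample(which(counts < max_visits), 1)
      counts[i] <- counts[i] + 1
    } else {
      i <- sample(which(counts > 1), 1)
      counts[i] <- counts[i] - 1
    }
  }
  counts
}

# daily-dose grid: EC-MPS 360-1440 mg/day BID; MMF 500-2000 mg/day BID
# (recorded as the EC-MPS-equivalent after the 0.72 conversion)
.draw_tdd <- function(n, formulation) {
  if (formulation == "ecmps") {
    sample(c(360, 720, 1080, 1440), n, replace = TRUE)
  } else {
    convert_mmf_dose(sample(c(500, 1000, 1500, 2000), n, replace = TRUE))
  }
}

#' Generate a synthetic trough-only cohort
#'
#' Simulates a virtual cohort with the statistical structure of a
#' trough-only therapeutic drug monitoring study: patient covariates
#' drawn from lognormal/normal families calibrated to the cohort
#' medians and IQRs, daily doses from the permitted regimen grid,
#' monthly visits whose total observation count matches the design
#' exactly, and steady-state troughs simulated through the structural
#' and population layers with residual error. Each trough is taken 12 h
#' after the last dose of a twice-daily regimen after at least a week
#' of dosing (>= 10 half-lives, so steady state holds).
#'
#' Uses the current RNG state; seed with [set.seed()].
#'
#' @param design a [cohort_design()]
#' @param truth_ecmps,truth_mmf generating [population_model()]s per
#'   formulation (defaults: the fitted presets)
#' @return an object of class `pk_cohort`: list with `data` (the
#'   observation table: ID, TIME, DV, AMT, II, TAD, OCC, FORM and
#'   covariate columns), `truth` (generating models and random-effect
#'   draws) and `design`
#' @export
generate_cohort <- function(design = cohort_design(),
                            truth_ecmps = mpa_model("ecmps"),
                            truth_mmf = mpa_model("mmf")) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_patients
  form <- rep(c("ecmps", "mmf"), c(design$n_ecmps, design$n_mmf))
  cov <- .draw_covariates(n)
  cov$TDD <- numeric(n)
  cov$TDD[form == "ecmps"] <- .draw_tdd(sum(form == "ecmps"), "ecmps")
  cov$TDD[form == "mmf"] <- .draw_tdd(sum(form == "mmf"), "mmf")
  visits <- .draw_visit_counts(n, design$target_samples, design$max_visits)

  eff <- list(
    ecmps = sample_effects(truth_ecmps$random, n, design$max_visits),
    mmf   = sample_effects(truth_mmf$random, n, design$max_visits))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- if (form[i] == "ecmps") truth_ecmps else truth_mmf
    e <- eff[[form[i]]]
    occ <- seq_len(visits[i])
    ptp_occ <- cov$PTP[i] + (occ - 1)          # months advance by visit
    dose <- cov$TDD[i] / 2                     # BID administration
    dv_true <- vapply(occ, function(j) {
      ci <- as.list(cov[i, ])
      ci$PTP <- ptp_occ[j]
      p <- individual_params(m, ci, eta = e$eta[i, ], kappa = e$kappa[i, j, ])
      trough_ss(p, regimen(dose, 12))
    }, numeric(1))
    dv <- observe(dv_true, m$error)
    rows[[i]] <- data.frame(
      ID = i, OCC = occ, TIME = (occ - 1) * 730 + 180,
      DV = dv, AMT = dose, II = 12, TAD = 12,
      FORM = form[i], TDD = cov$TDD[i], PTP = ptp_occ,
      cov[i, setdiff(names(cov), c("TDD", "PTP"))],
      SALIVA = NA_real_, row.names = NULL)
  }
  data <- do.call(rbind, rows)
  structure(list(data = data,
                 truth = list(ecmps = truth_ecmps, mmf = truth_mmf,
                              eta = eff, formulation = form, visits = visits),
                 design = design),
            class = "pk_cohort")
}

#' Generate a rich-design cohort for parameter-recovery experiments
#'
#' A dense steady-state sampling variant of [generate_cohort()]: every
#' subject contributes several post-dose samples within one dosing
#' interval on a single occasion. Occasion-level (IOV) variability is
#' switched off so the experiment isolates the inter-individual layer;
#' recovery of the generating fixed effects, covariate coefficients and
#' IIV is the purpose of this design.
#'
#' @param n_subjects number of subjects
#' @param times sampling times after the dose (h), within one interval
#' @param truth generating [population_model()]
#' @return a `pk_cohort` (single formulation, one occasion per subject)
#' @export
generate_rich_cohort <- function(n_subjects = 100,
                                 times = c(0.5, 1, 2, 4, 6, 8, 10, 12),
                                 truth = mpa_model("ecmps")) {
  stopifnot(inherits(truth, "population_model"))
  if (any(times <= 0)) stop("'times' must be positive (h after a dose)", call. = FALSE)
  n <- n_subjects
  cov <- .draw_covariates(n)
  cov$TDD <- .draw_tdd(n, truth$formulation)
  eta <- sample_effects(random_effect_spec(omega = truth$random$omega), n, 1)$eta
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- individual_params(truth, as.list(cov[i, ]), eta = eta[i, ])
    dose <- cov$TDD[i] / 2
    ctrue <- conc_ss(p, dose, 12, times)
    rows[[i]] <- data.frame(
      ID = i, OCC = 1, TIME = 168 + times,
      DV = observe(ctrue, truth$error), AMT = dose, II = 12, TAD = times,
      FORM = truth$formulation, TDD = cov$TDD[i],
      cov[i, setdiff(names(cov), "TDD")],
      SALIVA = NA_real_, row.names = NULL)
  }
  data <- do.call(rbind, rows)
  structure(list(data = data,
                 truth = list(model = truth, eta = eta),
                 design = list(n_subjects = n, times = times)),
            class = "pk_cohort")
}

#' Add synthetic first-visit saliva concentrations
#'
#' Saliva MPA is generated as the plasma trough multiplied by a
#' lognormal saliva:plasma ratio (median `ratio_mean`, coefficient of
#' variation `ratio_cv`), at the first visit only and for a designated
#' patient subset. The ratio is a synthetic construction that creates a
#' correlated auxiliary signal for the covariate-exploration stage; it
#' is not a physiological estimate.
#'
#' @param cohort a `pk_cohort` from [generate_cohort()]
#' @param ratio_mean median saliva:plasma ratio, > 0
#' @param ratio_cv coefficient of variation of the ratio, >= 0
#' @param n_saliva subset size (default: the design's `n_saliva`)
#' @return the cohort with the `SALIVA` column filled at occasion 1
#' @export
generate_saliva <- function(cohort, ratio_mean = 0.01, ratio_cv = 0.3,
                            n_saliva = NULL) {
  stopifnot(inherits(cohort, "pk_cohort"))
  if (ratio_mean <= 0) stop("'ratio_mean' must be > 0", call. = FALSE)
  if (ratio_cv < 0) stop("'ratio_cv' must be >= 0", call. = FALSE)
  ids <- unique(cohort$data$ID)
  if (is.null(n_saliva)) n_saliva <- cohort$design$n_saliva
  if (is.null(n_saliva)) n_saliva <- length(ids)
  if (n_saliva > length(ids))
    stop("saliva subset larger than cohort", call. = FALSE)
  subset_ids <- sort(sample(ids, n_saliva))
  idx <- which(cohort$data$OCC == 1 & cohort$data$ID %in% subset_ids)
  sdlog <- sqrt(log(1 + ratio_cv^2))
  ratio <- stats::rlnorm(length(idx), log(ratio_mean), sdlog)
  cohort$data$SALIVA[idx] <- cohort$data$DV[idx] * ratio
  cohort
}
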