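#' Covariate effect on a PK parameter
#'
#' A single covariate term of the log-parameter model. Continuous
#' covariates enter as `beta * log(C_i / center)` with a fixed
#' normalisation constant `center`; categorical covariates enter as
#' `beta * G_i`, where the reference level (`G_i = 0`) contributes 0.
#'
#' @param name covariate column name (e.g. `"TDD"`, `"PTP"`)
#' @param beta effect coefficient
#' @param kind `"continuous"` or `"categorical"`
#' @param center normalisation constant for continuous covariates
#'   (same units as the covariate), > 0
#' @return an object of class `covariate_effect`
#' @export
covariate_effect <- function(name, beta, kind = c("continuous", "categorical"),
                             center = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (is.null(center) || !is.numeric(center) || center <= 0)
      stop("continuous covariate effect '", name, "' requires center > 0", call. = FALSE)
  } else {
    center <- NA_real_
  }
  structure(list(name = name, beta = beta, kind = kind, center = center),
            class = "covariate_effect")
}

#' Random-effect specification (IIV and IOV)
#'
#' Standard deviations of the lognormal random effects: `omega` for
#' inter-individual variability (one eta per subject) and `gamma` for
#' inter-occasion variability (one kappa per subject-occasion). Each is
#' a named vector over the structural parameters ka, V, Cl; zeros
#' switch the corresponding effect off.
#'
#' @param omega named numeric vector `c(ka=, V=, Cl=)`, all >= 0
#' @param gamma named numeric vector `c(ka=, V=, Cl=)`, all >= 0
#' @return an object of class `random_effect_spec`
#' @export
random_effect_spec <- function(omega = c(ka = 0, V = 0, Cl = 0),
                               gamma = c(ka = 0, V = 0, Cl = 0)) {
  fix <- function(x, what) {
    full <- c(ka = 0, V = 0, Cl = 0)
    if (is.null(names(x))) {
      if (length(x) != 3L) stop(what, " must be named or length 3", call. = FALSE)
      names(x) <- c("ka", "V", "Cl")
    }
    bad <- setdiff(names(x), names(full))
    if (length(bad)) stop("unknown parameter in ", what, ": ", bad[1], call. = FALSE)
    full[names(x)] <- x
    if (any(full < 0)) stop(what, " standard deviations must be >= 0", call. = FALSE)
    full
  }
  structure(list(omega = fix(omega, "omega"), gamma = fix(gamma, "gamma")),
            class = "random_effect_spec")
}

#' Residual-error model
#'
#' Maps a model prediction to an observed concentration:
#' additive `Cobs = Cpred + a e1`, proportional
#' `Cobs = Cpred (1 + b e2)`, or combined
#' `Cobs = Cpred (1 + b e2) + a e1`, with e1, e2 standard normal.
#'
#' @param kind `"additive"`, `"proportional"` or `"combined"`
#' @param a additive SD (mg/L), >= 0
#' @param b proportional coefficient (dimensionless), >= 0
#' @return an object of class `error_model`
#' @export
error_model <- function(kind = c("combined", "additive", "proportional"),
                        a = 0, b = 0) {
  kind <- match.arg(kind)
  if (a < 0 || b < 0) stop("error components must be >= 0", call. = FALSE)
  if (kind == "additive" && a <= 0) stop("additive error requires a > 0", call. = FALSE)
  if (kind == "proportional" && b <= 0) stop("proportional error requires b > 0", call. = FALSE)
  if (kind == "combined" && (a <= 0 || b <= 0))
    stop("combined error requires a > 0 and b > 0", call. = FALSE)
  structure(list(kind = kind, a = a, b = b), class = "error_model")
}

#' Residual standard deviation at a predicted concentration
#'
#' @param c_pred predicted concentration (mg/L), vectorised
#' @param e an [error_model()]
#' @return SD of the observation: `a` (additive), `b * c_pred`
#'   (proportional), `sqrt(a^2 + b^2 c_pred^2)` (combined)
#' @export
obs_sd <- function(c_pred, e) {
  stopifnot(inherits(e, "error_model"))
  switch(e$kind,
         additive     = rep_len(e$a, length(c_pred)),
         proportional = e$b * c_pred,
         combined     = sqrt(e$a^2 + e$b^2 * c_pred^2))
}

#' Draw noisy observations from the residual-error model
#'
#' Draws use the current RNG state; seed with [set.seed()] for
#' reproducibility. Negative draws are floored at a small positive
#' value (1e-6 mg/L) since concentrations are physical quantities.
#'
#' @param c_pred predicted concentrations (mg/L), >= 0
#' @param e an [error_model()]
#' @return one observation per prediction (mg/L)
#' @export
observe <- function(c_pred, e) {
  stopifnot(inherits(e, "error_model"))
  if (any(c_pred < 0)) stop("'c_pred' must be >= 0", call. = FALSE)
  n <- length(c_pred)
  out <- switch(e$kind,
                additive     = c_pred + e$a * stats::rnorm(n),
                proportional = c_pred * (1 + e$b * stats::rnorm(n)),
                combined     = c_pred * (1 + e$b * stats::rnorm(n)) + e$a * stats::rnorm(n))
  pmax(out, 1e-6)
}

#' Population pharmacokinetic model
#'
#' Fixed effects (population means of ka, V, Cl), covariate effects per
#' parameter, lognormal random-effect SDs and a residual-error model.
#' Individual parameters follow
#' `log P_i = log P_pop + sum(beta log(C_i/C_mean)) + eta_i + kappa_ij`.
#'
#' @param kapop,Vpop,Clpop population means (1/h, L, L/h), all > 0
#' @param effects named list of lists of [covariate_effect()]s, keyed by
#'   parameter (`ka`, `V`, `Cl`)
#' @param random a [random_effect_spec()]
#' @param error an [error_model()]
#' @param formulation `"ecmps"`, `"mmf"` or `"custom"`
#' @return an object of class `population_model`
#' @export
population_model <- function(kapop, Vpop, Clpop, effects = list(),
                             random = random_effect_spec(),
                             error = error_model("additive", a = 1e-3),
                             formulation = "custom") {
  if (kapop <= 0 || Vpop <= 0 || Clpop <= 0)
    stop("population means must be > 0", call. = FALSE)
  stopifnot(inherits(random, "random_effect_spec"), inherits(error, "error_model"))
  bad <- setdiff(names(effects), c("ka", "V", "Cl"))
  if (length(bad)) stop("effects keyed by unknown parameter: ", bad[1], call. = FALSE)
  structure(list(kapop = kapop, Vpop = Vpop, Clpop = Clpop,
                 effects = effects, random = random, error = error,
                 formulation = formulation),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population PK model (%s)\n", x$formulation))
  cat(sprintf("  kapop = %.4g 1/h, Vpop = %.4g L, Clpop = %.4g L/h\n",
              x$kapop, x$Vpop, x$Clpop))
  for (par in names(x$effects)) {
    for (ef in x$effects[[par]]) {
      cat(sprintf("  %s: beta(%s) = %.3g%s\n", par, ef$name, ef$beta,
                  if (ef$kind == "continuous") sprintf(" (center %.4g)", ef$center) else ""))
    }
  }
  cat(sprintf("  omega = (%.3g, %.3g, %.3g), gamma = (%.3g, %.3g, %.3g)\n",
              x$random$omega["ka"], x$random$omega["V"], x$random$omega["Cl"],
              x$random$gamma["ka"], x$random$gamma["V"], x$random$gamma["Cl"]))
  cat(sprintf("  error: %s (a = %.3g, b = %.3g)\n", x$error$kind, x$error$a, x$error$b))
  invisible(x)
}

# log-scale covariate contribution for one structural parameter
.cov_shift <- function(m, par, cov) {
  shift <- 0
  for (ef in m$effects[[par]]) {
    val <- cov[[ef$name]]
    if (is.null(val) || (length(val) == 1L && is.na(val)))
      stop("missing covariate '", ef$name, "' required by the model", call. = FALSE)
    if (ef$kind == "continuous") {
      if (val <= 0) stop("covariate '", ef$name, "' must be > 0", call. = FALSE)
      shift <- shift + ef$beta * log(val / ef$center)
    } else {
      shift <- shift + ef$beta * val
    }
  }
  shift
}

#' Individual parameters from the population model
#'
#' Applies covariate effects and random-effect draws on the log scale
#' and exponentiates, guaranteeing positive individual parameters. With
#' `eta = kappa = 0` and covariates at their normalisation constants the
#' population means are returned exactly.
#'
#' @param m a [population_model()]
#' @param cov named list or one-row data.frame of covariate values
#' @param eta named IIV draws `c(ka=, V=, Cl=)` (log scale)
#' @param kappa named IOV draws for the occasion, same layout
#' @return a [pk_params()] object
#' @examples
#' m <- mpa_model("ecmps")
#' individual_params(m, list(TDD = 1500, PTP = 67))  # Cl = 9.3 exactly
#' @export
individual_params <- function(m, cov = list(),
                              eta = c(ka = 0, V = 0, Cl = 0),
                              kappa = c(ka = 0, V = 0, Cl = 0)) {
  stopifnot(inherits(m, "population_model"))
  get_re <- function(x, par) if (is.null(names(x))) x[match(par, c("ka", "V", "Cl"))] else
    if (par %in% names(x)) x[[par]] else 0
  pop <- c(ka = m$kapop, V = m$Vpop, Cl = m$Clpop)
  out <- vapply(c("ka", "V", "Cl"), function(par) {
    # multiplicative form keeps the identity exact when all shifts vanish
    pop[[par]] * exp(.cov_shift(m, par, cov) +
                       get_re(eta, par) + get_re(kappa, par))
  }, numeric(1))
  pk_params(out[["ka"]], out[["V"]], out[["Cl"]])
}

#' Sample inter-individual and inter-occasion random effects
#'
#' Eta draws are N(0, omega^2) per subject and parameter; kappa draws
#' are N(0, gamma^2) per subject-occasion and parameter. Uses the
#' current RNG state; seed with [set.seed()].
#'
#' @param spec a [random_effect_spec()]
#' @param n_subjects number of subjects, >= 1
#' @param n_occasions occasions per subject, >= 1
#' @return list with `eta` (n_subjects x 3 matrix) and `kappa`
#'   (n_subjects x n_occasions x 3 array), dimnames over ka, V, Cl
#' @export
sample_effects <- function(spec, n_subjects, n_occasions = 1) {
  stopifnot(inherits(spec, "random_effect_spec"))
  if (n_subjects < 1 || n_occasions < 1)
    stop("'n_subjects' and 'n_occasions' must be >= 1", call. = FALSE)
  pars <- c("ka", "V", "Cl")
  eta <- sapply(pars, function(p) stats::rnorm(n_subjects, 0, spec$omega[[p]]))
  eta <- matrix(eta, nrow = n_subjects, dimnames = list(NULL, pars))
  kappa <- array(0, dim = c(n_subjects, n_occasions, 3),
                 dimnames = list(NULL, NULL, pars))
  for (p in pars) {
    kappa[, , p] <- stats::rnorm(n_subjects * n_occasions, 0, spec$gamma[[p]])
  }
  list(eta = eta, kappa = kappa)
}

#' Convert an MMF dose to its EC-MPS-equivalent
#'
#' MMF and EC-MPS are not bioequivalent; doses are normalised to
#' EC-MPS-equivalent milligrams with the standard 0.72 conversion
#' factor before entering the covariate model.
#'
#' @param mmf_mg MMF dose (mg), >= 0, vectorised
#' @return EC-MPS-equivalent dose: `mmf_mg * 0.72`
#' @export
convert_mmf_dose <- function(mmf_mg) {
  if (any(mmf_mg < 0)) stop("dose must be >= 0", call. = FALSE)
  mmf_mg * 0.72
}
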