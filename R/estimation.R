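# ---------------------------------------------------------------------------
# Nonlinear mixed-effects estimation for the steady-state oral PK model.
#
# The marginal likelihood is approximated subject-by-subject with the
# Laplace method: the joint negative log-density in the subject's random
# effects is minimised, and the Gaussian curvature at the mode supplies
# the integral. Random effects are the lognormal IIV terms on ka, V and
# Cl; fitting is IIV-only (occasion-level variability is a property of
# the generating design, see the vignette).
# ---------------------------------------------------------------------------

.PAR_ORDER <- c("ka", "V", "Cl")

# internal fit parameterisation extracted from a population_model
.par_template <- function(m) {
  betas <- numeric(0)
  meta <- list()
  for (par in names(m$effects)) {
    for (ef in m$effects[[par]]) {
      nm <- paste0("beta_", par, "_", ef$name)
      betas[nm] <- ef$beta
      meta[[nm]] <- list(par = par, cov = ef$name, center = ef$center, kind = ef$kind)
    }
  }
  list(pops = c(kapop = m$kapop, Vpop = m$Vpop, Clpop = m$Clpop),
       betas = betas, beta_meta = meta,
       omega = m$random$omega,
       gamma = m$random$gamma,   # carried through, never estimated here
       err_kind = m$error$kind, a = m$error$a, b = m$error$b,
       formulation = m$formulation)
}

.template_to_model <- function(tp) {
  effects <- list()
  for (nm in names(tp$betas)) {
    mt <- tp$beta_meta[[nm]]
    effects[[mt$par]] <- c(effects[[mt$par]],
                           list(covariate_effect(mt$cov, unname(tp$betas[nm]),
                                                 mt$kind, mt$center)))
  }
  err <- switch(tp$err_kind,
                additive     = error_model("additive", a = tp$a),
                proportional = error_model("proportional", b = tp$b),
                combined     = error_model("combined", a = tp$a, b = tp$b))
  population_model(tp$pops[["kapop"]], tp$pops[["Vpop"]], tp$pops[["Clpop"]],
                   effects = effects,
                   random = random_effect_spec(omega = tp$omega, gamma = tp$gamma),
                   error = err, formulation = tp$formulation)
}

.free_names <- function(tp) {
  c("kapop", "Vpop", "Clpop", names(tp$betas),
    "omega_ka", "omega_V", "omega_Cl", "a", "b")
}

# log transform for positivity-constrained parameters; identity for betas
.is_logscale <- function(nm) !startsWith(nm, "beta_")

.get_par <- function(tp, nm) {
  if (nm %in% names(tp$pops)) return(tp$pops[[nm]])
  if (nm %in% names(tp$betas)) return(unname(tp$betas[nm]))
  if (startsWith(nm, "omega_")) return(tp$omega[[sub("omega_", "", nm)]])
  if (nm %in% c("a", "b")) return(tp[[nm]])
  stop("unknown parameter: ", nm, call. = FALSE)
}

.set_par <- function(tp, nm, value) {
  if (nm %in% names(tp$pops)) tp$pops[[nm]] <- value
  else if (nm %in% names(tp$betas)) tp$betas[nm] <- value
  else if (startsWith(nm, "omega_")) tp$omega[[sub("omega_", "", nm)]] <- value
  else if (nm %in% c("a", "b")) tp[[nm]] <- value
  else stop("unknown parameter: ", nm, call. = FALSE)
  tp
}

.pack_theta <- function(tp, free) {
  vapply(free, function(nm) {
    v <- .get_par(tp, nm)
    if (.is_logscale(nm)) log(v) else v
  }, numeric(1))
}

.unpack_theta <- function(tp, free, theta) {
  for (k in seq_along(free)) {
    v <- if (.is_logscale(free[k])) exp(theta[k]) else theta[k]
    tp <- .set_par(tp, free[k], v)
  }
  tp
}

# split dataset by subject and precompute covariate design columns
.subject_data <- function(data, tp) {
  need <- c("ID", "DV", "AMT", "II", "TAD")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  lapply(split(data, data$ID), function(d) {
    X <- lapply(tp$beta_meta, function(mt) {
      val <- d[[mt$cov]]
      if (is.null(val)) stop("missing covariate '", mt$cov, "' in dataset", call. = FALSE)
      if (mt$kind == "continuous") log(val / mt$center) else as.numeric(val)
    })
    list(y = d$DV, amt = d$AMT, ii = d$II, tad = d$TAD, n = nrow(d), X = X)
  })
}

# row-wise predictions for one subject given parameters and random effects
.subj_pred <- function(sd_, tp, eta) {
  lp <- cbind(ka = rep(log(tp$pops[["kapop"]]) + eta[1], sd_$n),
              V  = rep(log(tp$pops[["Vpop"]]) + eta[2], sd_$n),
              Cl = rep(log(tp$pops[["Clpop"]]) + eta[3], sd_$n))
  for (nm in names(tp$betas)) {
    par <- tp$beta_meta[[nm]]$par
    lp[, par] <- lp[, par] + tp$betas[nm] * sd_$X[[nm]]
  }
  .css_vec(exp(lp[, "ka"]), exp(lp[, "V"]), exp(lp[, "Cl"]),
           sd_$amt, sd_$ii, sd_$tad)
}

.resid_sd <- function(pred, tp) {
  s <- switch(tp$err_kind,
              additive     = rep_len(tp$a, length(pred)),
              proportional = tp$b * pred,
              combined     = sqrt(tp$a^2 + tp$b^2 * pred^2))
  pmax(s, 1e-10)
}

# negative log joint density of (data, eta) for one subject;
# eta is the full length-3 vector, `active` indexes estimated components
.subj_joint_nll <- function(sd_, tp, eta, active) {
  pred <- .subj_pred(sd_, tp, eta)
  s <- .resid_sd(pred, tp)
  nll <- sum(0.5 * log(2 * pi) + log(s) + 0.5 * ((sd_$y - pred) / s)^2)
  for (p in active) {
    w <- tp$omega[[p]]
    j <- match(p, .PAR_ORDER)
    nll <- nll + 0.5 * log(2 * pi) + log(w) + 0.5 * (eta[j] / w)^2
  }
  nll
}

# central-difference Hessian of a scalar function
.num_hess <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

# Laplace-approximate marginal nll contribution of one subject
.subj_marginal_nll <- function(sd_, tp, active, eta_start = NULL) {
  d <- length(active)
  act_idx <- match(active, .PAR_ORDER)
  if (d == 0L) {
    return(list(nll = .subj_joint_nll(sd_, tp, numeric(3), character(0)),
                eta = numeric(3)))
  }
  fn <- function(ea) {
    eta <- numeric(3)
    eta[act_idx] <- ea
    .subj_joint_nll(sd_, tp, eta, active)
  }
  start <- if (is.null(eta_start)) numeric(d) else eta_start[act_idx]
  opt <- stats::nlminb(start, fn, control = list(rel.tol = 1e-10))
  if (!is.finite(opt$objective)) {
    opt <- stats::nlminb(numeric(d), fn, control = list(rel.tol = 1e-10))
  }
  H <- .num_hess(fn, opt$par)
  detH <- det(H)
  nll <- if (is.finite(detH) && detH > 0) {
    opt$objective - 0.5 * d * log(2 * pi) + 0.5 * log(detH)
  } else {
    opt$objective + 1e3   # curvature failure: strongly disfavoured
  }
  eta <- numeric(3)
  eta[act_idx] <- opt$par
  list(nll = nll, eta = eta)
}

#' Empirical Bayes (MAP) estimates of individual random effects
#'
#' Maximises the posterior density of one subject's random effects
#' given the population model: the residual-error likelihood of the
#' subject's observations times the lognormal random-effect priors.
#' With several occasions and non-zero occasion-level SDs (`gamma`),
#' per-occasion kappa terms are estimated jointly with eta.
#'
#' @param m a [population_model()]
#' @param data the subject's observation rows (columns ID, DV, AMT, II,
#'   TAD, OCC and any covariates the model requires)
#' @return list with `eta` (named length-3), `kappa` (occasions x 3
#'   matrix, zero rows when IOV is off) and `objective` (the joint
#'   negative log-density at the mode)
#' @export
map_individual <- function(m, data) {
  stopifnot(inherits(m, "population_model"))
  if (nrow(data) == 0L || all(is.na(data$DV)))
    stop("subject has no usable observations", call. = FALSE)
  tp <- .par_template(m)
  sd_ <- .subject_data(data, tp)[[1]]
  occ <- if ("OCC" %in% names(data)) as.integer(factor(data$OCC)) else rep(1L, nrow(data))
  n_occ <- max(occ)
  act_eta <- .PAR_ORDER[tp$omega > 0]
  act_kap <- .PAR_ORDER[m$random$gamma > 0]
  if (n_occ == 1L) act_kap <- character(0)   # one occasion: kappa not separable
  d_eta <- length(act_eta)
  d_kap <- length(act_kap)
  fn <- function(z) {
    eta <- numeric(3)
    eta[match(act_eta, .PAR_ORDER)] <- z[seq_len(d_eta)]
    kap <- matrix(0, n_occ, 3)
    if (d_kap) {
      kap[, match(act_kap, .PAR_ORDER)] <-
        matrix(z[-seq_len(d_eta)], n_occ, d_kap)
    }
    nll <- 0
    for (j in seq_len(n_occ)) {
      rows <- occ == j
      sdj <- list(y = sd_$y[rows], amt = sd_$amt[rows], ii = sd_$ii[rows],
                  tad = sd_$tad[rows], n = sum(rows),
                  X = lapply(sd_$X, function(x) x[rows]))
      pred <- .subj_pred(sdj, tp, eta + kap[j, ])
      s <- .resid_sd(pred, tp)
      nll <- nll + sum(0.5 * log(2 * pi) + log(s) + 0.5 * ((sdj$y - pred) / s)^2)
    }
    for (p in act_eta) {
      w <- tp$omega[[p]]
      nll <- nll + 0.5 * log(2 * pi) + log(w) +
        0.5 * (eta[match(p, .PAR_ORDER)] / w)^2
    }
    for (p in act_kap) {
      g <- m$random$gamma[[p]]
      for (j in seq_len(n_occ)) {
        nll <- nll + 0.5 * log(2 * pi) + log(g) +
          0.5 * (kap[j, match(p, .PAR_ORDER)] / g)^2
      }
    }
    nll
  }
  d <- d_eta + d_kap * n_occ
  if (d == 0L) {
    eta <- stats::setNames(numeric(3), .PAR_ORDER)
    return(list(eta = eta, kappa = matrix(0, n_occ, 3,
                                          dimnames = list(NULL, .PAR_ORDER)),
                objective = fn(numeric(0))))
  }
  opt <- stats::nlminb(numeric(d), fn, control = list(rel.tol = 1e-10))
  eta <- stats::setNames(numeric(3), .PAR_ORDER)
  eta[act_eta] <- opt$par[seq_len(d_eta)]
  kap <- matrix(0, n_occ, 3, dimnames = list(NULL, .PAR_ORDER))
  if (d_kap)
    kap[, act_kap] <- matrix(opt$par[-seq_len(d_eta)], n_occ, d_kap)
  list(eta = eta, kappa = kap, objective = opt$objective)
}

#' Marginal -2 log-likelihood of a population model
#'
#' Evaluates the Laplace-approximate marginal likelihood of a dataset
#' at a fixed [population_model()] without optimising anything — useful
#' for comparing parameter sets and for likelihood-surface checks.
#'
#' @param data observation table (see [fit_population()])
#' @param m a [population_model()]
#' @return the -2 log-likelihood (smaller is better)
#' @export
loglik_population <- function(data, m) {
  stopifnot(inherits(m, "population_model"))
  if (inherits(data, "pk_cohort")) data <- data$data
  tp <- .par_template(m)
  sdl <- .subject_data(data, tp)
  active <- .PAR_ORDER[tp$omega > 0]
  2 * sum(vapply(sdl, function(sd_) {
    .subj_marginal_nll(sd_, tp, active)$nll
  }, numeric(1)))
}

#' Fit a population PK model by Laplace-approximation NLME
#'
#' Maximises the marginal likelihood of the steady-state observations,
#' integrating the lognormal inter-individual effects out with the
#' Laplace approximation. The paper-style stepwise schedule is the
#' intended workflow: start from a model whose ka and V are held at
#' prior values, free clearance and its covariates, then progressively
#' release further parameters (see [fit_stepwise()]). Standard errors
#' come from the observed information matrix of the marginal
#' log-likelihood; AIC = -2LL + 2p and BIC = -2LL + p log(N) with N the
#' number of observations.
#'
#' @param data observation table with columns ID, DV, AMT (mg per
#'   administration), II (h), TAD (h after last dose) and the covariate
#'   columns the model requires; steady state is assumed
#' @param start a [population_model()] supplying structure and starting
#'   values (fixed parameters keep these values)
#' @param free character vector of parameters to estimate, from:
#'   `kapop`, `Vpop`, `Clpop`, `beta_<par>_<cov>`, `omega_ka`,
#'   `omega_V`, `omega_Cl`, `a`, `b`
#' @param se compute standard errors (numerical Hessian; set `FALSE`
#'   to save time in nested fits)
#' @param control passed to [stats::nlminb()]
#' @return an object of class `mpa_fit`: estimates, SE and RSE%, -2LL,
#'   AIC, BIC, per-subject empirical Bayes eta estimates, the fitted
#'   [population_model()] and a convergence report
#' @export
fit_population <- function(data, start, free = c("Clpop", "omega_Cl"),
                           se = TRUE,
                           control = list(rel.tol = 1e-8, iter.max = 400)) {
  stopifnot(inherits(start, "population_model"))
  if (inherits(data, "pk_cohort")) data <- data$data
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  free <- unname(free)
  tp0 <- .par_template(start)
  unknown <- setdiff(free, .free_names(tp0))
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!length(free)) stop("free-parameter set is empty", call. = FALSE)

  obs_per_subject <- table(data$ID)
  if (all(obs_per_subject == 1L) &&
      all(c("kapop", "Vpop", "Clpop") %in% free)) {
    warning("all structural parameters free with one observation per subject is ",
            "unidentifiable; consider the stepwise schedule (fit_stepwise)")
  }

  sdl <- .subject_data(data, tp0)
  n_subj <- length(sdl)
  ebe_cache <- matrix(0, n_subj, 3)

  nll_total <- function(theta) {
    tp <- .unpack_theta(tp0, free, theta)
    active <- .PAR_ORDER[tp$omega > 0]
    total <- 0
    for (i in seq_len(n_subj)) {
      res <- .subj_marginal_nll(sdl[[i]], tp, active, eta_start = ebe_cache[i, ])
      ebe_cache[i, ] <<- res$eta
      total <- total + res$nll
    }
    if (!is.finite(total)) total <- 1e10
    total
  }

  theta0 <- .pack_theta(tp0, free)
  opt <- stats::nlminb(theta0, nll_total, control = control)
  tp_hat <- .unpack_theta(tp0, free, opt$par)

  # refresh EBEs at the optimum
  active <- .PAR_ORDER[tp_hat$omega > 0]
  ebe <- matrix(0, n_subj, 3, dimnames = list(names(sdl), .PAR_ORDER))
  for (i in seq_len(n_subj)) {
    ebe[i, ] <- .subj_marginal_nll(sdl[[i]], tp_hat, active,
                                   eta_start = ebe_cache[i, ])$eta
  }

  est <- vapply(free, function(nm) .get_par(tp_hat, nm), numeric(1))
  se_vec <- rep(NA_real_, length(free))
  if (se) {
    H <- tryCatch(stats::optimHess(opt$par, nll_total), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        sd_trans <- sqrt(pmax(diag(V), 0))
        se_vec <- ifelse(vapply(free, .is_logscale, logical(1)),
                         sd_trans * est, sd_trans)   # delta method for log scale
      }
    }
  }
  names(se_vec) <- free
  p <- length(free)
  N <- nrow(data)
  m2ll <- 2 * opt$objective
  structure(list(
    estimates = est,
    se = se_vec,
    rse = 100 * se_vec / abs(est),
    ofv = m2ll, aic = m2ll + 2 * p, bic = m2ll + p * log(N),
    n_obs = N, n_subjects = n_subj, n_free = p,
    free = free, model = .template_to_model(tp_hat),
    ebe = ebe,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations),
    method = "Laplace approximation (IIV integrated per subject)"),
    class = "mpa_fit")
}

#' @export
print.mpa_fit <- function(x, ...) {
  cat("Population PK fit —", x$method, "\n")
  cat(sprintf("  %d subjects, %d observations, %d free parameters\n",
              x$n_subjects, x$n_obs, x$n_free))
  cat(sprintf("  -2LL = %.2f, AIC = %.2f, BIC = %.2f\n", x$ofv, x$aic, x$bic))
  tab <- data.frame(estimate = x$estimates, se = x$se, `rse%` = x$rse,
                    check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Stepwise release of structural parameters
#'
#' Runs a sequence of [fit_population()] stages in which progressively
#' more parameters are freed, warm-starting each stage at the previous
#' estimates — the estimation schedule appropriate for sparse designs
#' where freeing everything at once is not identifiable. The -2LL is
#' non-increasing across stages by construction (each stage can at
#' least reproduce its warm start).
#'
#' @param data observation table (see [fit_population()])
#' @param start prior/starting [population_model()]
#' @param stages list of free-parameter character vectors, one per
#'   stage; each stage should contain the previous one
#' @param se compute standard errors for the final stage
#' @return list of `mpa_fit` objects, one per stage
#' @export
fit_stepwise <- function(data, start,
                         stages = list(
                           c("Clpop", "omega_Cl", "a", "b"),
                           c("Clpop", "omega_Cl", "kapop", "omega_ka", "a", "b"),
                           c("Clpop", "omega_Cl", "kapop", "omega_ka",
                             "Vpop", "omega_V", "a", "b")),
                         se = TRUE) {
  fits <- vector("list", length(stages))
  current <- start
  for (k in seq_along(stages)) {
    fits[[k]] <- fit_population(data, current, free = stages[[k]],
                                se = se && k == length(stages))
    current <- fits[[k]]$model
  }
  fits
}

#' Stepwise covariate selection on clearance
#'
#' Forward inclusion / backward elimination of continuous covariates on
#' clearance. At each forward step every remaining candidate is added
#' to the model, the extended model is refitted, and the candidate with
#' the smallest Wald p-value below `alpha` enters (ties broken by the
#' larger drop in -2LL). Backward elimination then removes retained
#' covariates whose Wald p rises above `alpha`. Centering constants are
#' the covariate medians of the dataset.
#'
#' @param data observation table (see [fit_population()])
#' @param base a [population_model()] without the candidate effects
#' @param candidates character vector of covariate column names
#' @param free_base parameters re-estimated alongside each beta
#' @param alpha Wald significance level (default 0.05)
#' @return list with `model` (selected [population_model()]), `fit`
#'   (final `mpa_fit`) and `log` (a data.frame: step, covariate, beta,
#'   Wald z, p, delta -2LL, decision)
#' @export
covariate_search <- function(data, base, candidates,
                             free_base = c("Clpop", "omega_Cl"),
                             alpha = 0.05) {
  if (inherits(data, "pk_cohort")) data <- data$data
  if (!length(candidates)) {
    fit <- fit_population(data, base, free = free_base)
    return(list(model = base, fit = fit, log = data.frame()))
  }
  # collinearity advisory among candidates
  if (length(candidates) > 1) {
    cc <- stats::cor(log(data[candidates]))
    hi <- which(abs(cc) > 0.8 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hi)) {
      warning("collinear candidate pair(s): ",
              paste(candidates[hi[, 1]], candidates[hi[, 2]],
                    sep = "~", collapse = ", "),
              "; both are tested")
    }
  }
  centers <- vapply(candidates, function(nm) stats::median(data[[nm]]), numeric(1))
  add_effect <- function(m, nm, beta = 0) {
    m$effects$Cl <- c(m$effects$Cl,
                      list(covariate_effect(nm, beta, "continuous", centers[[nm]])))
    m
  }
  drop_effect <- function(m, nm) {
    keep <- vapply(m$effects$Cl, function(ef) ef$name != nm, logical(1))
    m$effects$Cl <- m$effects$Cl[keep]
    if (!length(m$effects$Cl)) m$effects$Cl <- NULL
    m
  }
  beta_name <- function(nm) paste0("beta_Cl_", nm, recycle0 = TRUE)
  fit_with <- function(m, in_model) {
    fit_population(data, m, free = c(free_base, beta_name(in_model)))
  }

  in_model <- character(0)
  remaining <- candidates
  current <- base
  log_rows <- list()
  step <- 0L
  base_fit <- fit_with(current, in_model)

  repeat {                                   # forward
    if (!length(remaining)) break
    trials <- lapply(remaining, function(nm) {
      m_try <- add_effect(current, nm)
      f <- fit_with(m_try, c(in_model, nm))
      b <- f$estimates[[beta_name(nm)]]
      s <- f$se[[beta_name(nm)]]
      z <- b / s
      list(nm = nm, fit = f, beta = b, z = z,
           p = 2 * stats::pnorm(-abs(z)), d2ll = base_fit$ofv - f$ofv)
    })
    ps <- vapply(trials, `[[`, numeric(1), "p")
    d2 <- vapply(trials, `[[`, numeric(1), "d2ll")
    ord <- order(ps, -d2)
    best <- trials[[ord[1]]]
    step <- step + 1L
    accepted <- is.finite(best$p) && best$p < alpha
    for (tr in trials) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, phase = "forward", covariate = tr$nm, beta = tr$beta,
        wald_z = tr$z, p = tr$p, delta_m2ll = tr$d2ll,
        decision = if (accepted && tr$nm == best$nm) "enter" else "hold")
    }
    if (!accepted) break
    in_model <- c(in_model, best$nm)
    remaining <- setdiff(remaining, best$nm)
    current <- add_effect(current, best$nm, best$beta)
    base_fit <- best$fit
  }

  repeat {                                   # backward
    if (!length(in_model)) break
    f <- base_fit
    zs <- vapply(in_model, function(nm) {
      f$estimates[[beta_name(nm)]] / f$se[[beta_name(nm)]]
    }, numeric(1))
    ps <- 2 * stats::pnorm(-abs(zs))
    worst <- which.max(ps)
    if (ps[worst] < alpha) break
    nm <- in_model[worst]
    step <- step + 1L
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, phase = "backward", covariate = nm,
      beta = f$estimates[[beta_name(nm)]], wald_z = zs[worst], p = ps[worst],
      delta_m2ll = NA_real_, decision = "remove")
    in_model <- setdiff(in_model, nm)
    current <- drop_effect(current, nm)
    base_fit <- fit_with(current, in_model)
  }

  list(model = base_fit$model, fit = base_fit,
       log = if (length(log_rows)) do.call(rbind, log_rows) else data.frame())
}
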