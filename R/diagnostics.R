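# shared row-wise prediction machinery for a whole dataset -------------------

.dataset_design <- function(data, tp) {
  X <- lapply(tp$beta_meta, function(mt) {
    val <- data[[mt$cov]]
    if (is.null(val)) stop("missing covariate '", mt$cov, "' in dataset", call. = FALSE)
    if (mt$kind == "continuous") log(val / mt$center) else as.numeric(val)
  })
  ids <- unique(data$ID)
  list(X = X, id_idx = match(data$ID, ids), ids = ids,
       occ = if ("OCC" %in% names(data)) as.integer(data$OCC) else rep(1L, nrow(data)))
}

# predictions for every row of `data` under `m`, with optional per-subject
# eta (n_subj x 3, ordered as unique(data$ID)) and per-row kappa (n x 3)
.predict_rows <- function(m, data, eta = NULL, kappa_rows = NULL) {
  tp <- .par_template(m)
  dg <- .dataset_design(data, tp)
  n <- nrow(data)
  lp <- cbind(ka = rep(log(tp$pops[["kapop"]]), n),
              V  = rep(log(tp$pops[["Vpop"]]), n),
              Cl = rep(log(tp$pops[["Clpop"]]), n))
  for (nm in names(tp$betas)) {
    par <- tp$beta_meta[[nm]]$par
    lp[, par] <- lp[, par] + tp$betas[nm] * dg$X[[nm]]
  }
  if (!is.null(eta)) lp <- lp + eta[dg$id_idx, , drop = FALSE]
  if (!is.null(kappa_rows)) lp <- lp + kappa_rows
  .css_vec(exp(lp[, "ka"]), exp(lp[, "V"]), exp(lp[, "Cl"]),
           data$AMT, data$II, data$TAD)
}

#' Visual and numerical predictive checks
#'
#' Simulates `n_sim` replicate datasets at the observed design under
#' the model (inter-individual and inter-occasion effects plus residual
#' error), then compares observed percentiles with the simulation
#' distribution. The VPC table reports, per occasion bin, the observed
#' 5th/50th/95th percentiles against the corresponding simulated
#' confidence bands; the NPC reports the fraction of observations
#' falling inside centred prediction intervals.
#'
#' Uses the current RNG state; seed with [set.seed()].
#'
#' @param m a [population_model()] or an `mpa_fit` (its fitted model is
#'   used)
#' @param data observed dataset (ID, DV, AMT, II, TAD, OCC, covariates)
#' @param n_sim number of Monte Carlo replicates (default 1000; fewer
#'   than 100 triggers a warning)
#' @param ci confidence level of the simulated bands (default 0.90)
#' @param pi_levels prediction-interval levels for the NPC
#' @return list with `vpc` (per-bin percentile table), `npc`
#'   (data.frame of level, nominal and observed coverage) and `n_sim`
#' @export
vpc_npc <- function(m, data, n_sim = 1000, ci = 0.90,
                    pi_levels = c(0.5, 0.8, 0.9)) {
  if (inherits(m, "mpa_fit")) m <- m$model
  stopifnot(inherits(m, "population_model"))
  if (inherits(data, "pk_cohort")) data <- data$data
  if (n_sim < 100) warning("n_sim < 100 gives unstable predictive-check bands")
  tp <- .par_template(m)
  dg <- .dataset_design(data, tp)
  n <- nrow(data)
  n_subj <- length(dg$ids)
  n_occ <- max(dg$occ)

  kap_idx <- lapply(1:3, function(p) cbind(dg$id_idx, dg$occ, p))
  sims <- matrix(NA_real_, n, n_sim)
  for (s in seq_len(n_sim)) {
    eff <- sample_effects(m$random, n_subj, n_occ)
    kap_rows <- vapply(kap_idx, function(ix) eff$kappa[ix], numeric(n))
    pred <- .predict_rows(m, data, eta = eff$eta, kappa_rows = kap_rows)
    sims[, s] <- observe(pred, m$error)
  }

  qs <- c(0.05, 0.5, 0.95)
  alpha <- (1 - ci) / 2
  vpc <- do.call(rbind, lapply(sort(unique(dg$occ)), function(b) {
    rows <- dg$occ == b
    obs_q <- stats::quantile(data$DV[rows], qs, names = FALSE)
    sim_q <- apply(sims[rows, , drop = FALSE], 2, stats::quantile,
                   probs = qs, names = FALSE)          # 3 x n_sim
    lo <- apply(sim_q, 1, stats::quantile, probs = alpha)
    md <- apply(sim_q, 1, stats::median)
    hi <- apply(sim_q, 1, stats::quantile, probs = 1 - alpha)
    data.frame(bin = b, n = sum(rows), percentile = 100 * qs,
               observed = obs_q, sim_median = md, sim_lo = lo, sim_hi = hi)
  }))
  in_band <- with(vpc, observed >= sim_lo & observed <= sim_hi)

  npc <- do.call(rbind, lapply(pi_levels, function(lv) {
    a <- (1 - lv) / 2
    lo <- apply(sims, 1, stats::quantile, probs = a)
    hi <- apply(sims, 1, stats::quantile, probs = 1 - a)
    data.frame(level = lv, nominal = lv,
               observed = mean(data$DV >= lo & data$DV <= hi))
  }))
  list(vpc = vpc, vpc_in_band = mean(in_band), npc = npc, n_sim = n_sim)
}

#' Goodness-of-fit diagnostics
#'
#' Population predictions (random effects at zero), individual
#' predictions (empirical Bayes eta estimates) and individual weighted
#' residuals IWRES = (Cobs - Cpred_ind) / sd(Cpred_ind), where sd is
#' the residual-error SD at the individual prediction. At the true
#' model with noise, IWRES is approximately standard normal.
#'
#' @param fit an `mpa_fit` from [fit_population()], or a
#'   [population_model()] (empirical Bayes etas are then computed with
#'   [map_individual()])
#' @param data the dataset the model was fitted to
#' @return data.frame with ID, DV, PRED (population), IPRED
#'   (individual), RES, IWRES
#' @export
gof <- function(fit, data) {
  if (inherits(data, "pk_cohort")) data <- data$data
  ids <- unique(data$ID)
  if (inherits(fit, "population_model")) {
    m <- fit
    eta <- t(vapply(ids, function(id) {
      map_individual(m, data[data$ID == id, ])$eta
    }, numeric(3)))
  } else {
    stopifnot(inherits(fit, "mpa_fit"))
    m <- fit$model
    eta <- fit$ebe[match(as.character(ids), rownames(fit$ebe)), , drop = FALSE]
  }
  pred_pop <- .predict_rows(m, data)
  pred_ind <- .predict_rows(m, data, eta = eta)
  s <- obs_sd(pred_ind, m$error)
  data.frame(ID = data$ID, DV = data$DV, PRED = pred_pop, IPRED = pred_ind,
             RES = data$DV - pred_pop, IWRES = (data$DV - pred_ind) / pmax(s, 1e-10))
}
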