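.REQUIRED_COLS <- c("ID", "TIME", "DV", "AMT", "OCC")

#' Write a dataset in the plain CSV monitoring dialect
#'
#' Comma-separated, dot decimal, header row: columns ID, TIME (h since
#' first dose), DV (mg/L), AMT (mg per administration), II (h), TAD (h
#' after last dose), OCC and the covariate columns. When given a
#' `pk_cohort`, the generating truth (models and random-effect draws)
#' can be written alongside as a JSON sidecar for recovery tests.
#'
#' @param x a `pk_cohort` or an observation data.frame
#' @param path output CSV path
#' @param truth_path optional path for the truth JSON sidecar
#' @return `path`, invisibly
#' @export
write_pk_dataset <- function(x, path, truth_path = NULL) {
  d <- if (inherits(x, "pk_cohort")) x$data else x
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    if (!inherits(x, "pk_cohort"))
      stop("truth sidecar requires a pk_cohort", call. = FALSE)
    serialize_model <- function(m) {
      tp <- .par_template(m)
      list(pops = as.list(tp$pops), betas = as.list(tp$betas),
           omega = as.list(tp$omega),
           gamma = as.list(m$random$gamma),
           error = list(kind = tp$err_kind, a = tp$a, b = tp$b),
           formulation = tp$formulation)
    }
    truth <- list(
      models = lapply(Filter(function(z) inherits(z, "population_model"),
                             x$truth), serialize_model),
      eta = lapply(x$truth$eta, function(e) e$eta))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a dataset in the plain CSV monitoring dialect
#'
#' Strict reader: required columns must be present, occasion indices
#' are 1-based integers, DV must be non-negative. Violations name the
#' offending column or data line.
#'
#' @param path CSV path
#' @return validated data.frame
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.REQUIRED_COLS, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(d$DV) & d$DV < 0)
  if (length(bad))
    stop("negative DV at data line ", bad[1] + 1L, call. = FALSE)
  if (any(d$OCC < 1 | d$OCC != floor(d$OCC)))
    stop("OCC must contain 1-based integer occasion indices", call. = FALSE)
  message(sprintf("read %d rows, %d columns, %d subjects from %s",
                  nrow(d), ncol(d), length(unique(d$ID)), basename(path)))
  d
}

#' Pipeline configuration
#'
#' @param preset model preset name (`"ecmps"` or `"mmf"`)
#' @param stages character vector of stages to run, in order, from
#'   `generate`, `fit`, `vpc`, `dose_sim`, `ml`
#' @param seed integer seed stamped into every artifact
#' @param out_dir output directory (created if needed)
#' @param n_sim_vpc Monte Carlo replicates for the predictive check
#' @param n_subjects_sim subjects per dosing scenario
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(preset = "ecmps",
                            stages = c("generate", "fit", "vpc", "dose_sim", "ml"),
                            seed = 1, out_dir = tempfile("mpapk-run-"),
                            n_sim_vpc = 300, n_subjects_sim = 1000) {
  if (length(stages)) {
    stages <- match.arg(stages, c("generate", "fit", "vpc", "dose_sim", "ml"),
                        several.ok = TRUE)
  }
  preset <- match.arg(preset, c("ecmps", "mmf"))
  structure(list(preset = preset, stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, n_sim_vpc = n_sim_vpc,
                 n_subjects_sim = n_subjects_sim),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order generate, fit, vpc, dose_sim,
#' ml, writing CSV/JSON artifacts stamped with the seed, preset and
#' package version. All randomness flows from the configured seed. A
#' stage failure stops downstream stages; artifacts already written are
#' retained.
#'
#' @param config a [pipeline_config()]
#' @return named list of stage results (also written under
#'   `config$out_dir`), invisibly
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(config$stages)) {
    warning("no stages enabled; returning an empty bundle")
    return(invisible(list()))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = config$seed, preset = config$preset,
                package = "mpapk",
                version = as.character(utils::packageVersion("mpapk")))
  set.seed(config$seed)
  out <- list(stamp = stamp)
  m <- mpa_model(config$preset)
  cohort <- NULL
  fit <- NULL
  write_json_artifact <- function(x, name) {
    jsonlite::write_json(c(stamp, x), file.path(config$out_dir, name),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  for (stage in c("generate", "fit", "vpc", "dose_sim", "ml")) {
    if (!stage %in% config$stages) next
    message("stage: ", stage)
    switch(stage,
      generate = {
        cohort <- generate_cohort()
        cohort <- generate_saliva(cohort)
        write_pk_dataset(cohort, file.path(config$out_dir, "cohort.csv"),
                         truth_path = file.path(config$out_dir, "cohort-truth.json"))
        out$generate <- cohort
      },
      fit = {
        if (is.null(cohort)) stop("fit stage requires the generate stage", call. = FALSE)
        d <- cohort$data[cohort$data$FORM == config$preset, ]
        fit <- fit_population(d, m, free = c("Clpop", "omega_Cl"))
        write_json_artifact(list(estimates = as.list(fit$estimates),
                                 se = as.list(fit$se), ofv = fit$ofv,
                                 aic = fit$aic, bic = fit$bic,
                                 method = fit$method), "fit.json")
        out$fit <- fit
      },
      vpc = {
        mdl <- if (!is.null(fit)) fit$model else m
        d <- cohort$data[cohort$data$FORM == config$preset, ]
        pc <- vpc_npc(mdl, d, n_sim = config$n_sim_vpc)
        utils::write.csv(pc$vpc, file.path(config$out_dir, "vpc.csv"),
                         row.names = FALSE)
        write_json_artifact(list(npc = pc$npc, vpc_in_band = pc$vpc_in_band),
                            "npc.json")
        out$vpc <- pc
      },
      dose_sim = {
        scen <- expand.grid(dose = c(360, 720), cl_scale = c(1, 0.5, 0.25))
        res <- lapply(seq_len(nrow(scen)), function(i) {
          s <- regimen_scenario(regimen(scen$dose[i], 12),
                                cl_scale = scen$cl_scale[i],
                                n_subjects = config$n_subjects_sim)
          sim <- simulate_scenario(m, s)
          c(list(dose = scen$dose[i], cl_scale = scen$cl_scale[i]),
            sim$summary)
        })
        adj_grid <- expand.grid(reference_dose = c(360, 720),
                                cl_scale = c(0.5, 0.25))
        adj <- do.call(rbind, lapply(seq_len(nrow(adj_grid)), function(i) {
          pr <- propose_regimen(m, regimen(adj_grid$reference_dose[i], 12),
                                adj_grid$cl_scale[i])
          cbind(adj_grid[i, ], dose = pr$regimen$dose,
                interval = pr$regimen$interval)
        }))
        write_json_artifact(list(scenarios = res, adjustments = adj),
                            "dose-sim.json")
        out$dose_sim <- list(scenarios = res, adjustments = adj)
      },
      ml = {
        if (is.null(cohort)) stop("ml stage requires the generate stage", call. = FALSE)
        tab <- feature_table(cohort)
        rep_plasma <- fit_boosted(tab)
        pca <- run_pca(tab)
        tab_sal <- feature_table(cohort, include_saliva = TRUE)
        paired <- compare_with_saliva(tab_sal)
        write_json_artifact(list(
          plasma = list(mse = rep_plasma$mse, r2 = rep_plasma$r2,
                        ranking = rep_plasma$ranking,
                        importance = as.list(rep_plasma$importance)),
          paired = list(delta_r2 = paired$delta_r2,
                        ranking_with = paired$ranking_with,
                        ranking_without = paired$ranking_without),
          pca = list(var_explained = pca$var_explained,
                     loadings = as.data.frame(pca$loadings))), "ml.json")
        out$ml <- list(plasma = rep_plasma, paired = paired, pca = pca)
      })
  }
  invisible(out)
}
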