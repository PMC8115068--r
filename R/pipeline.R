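#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: cohort design, frame
#' schedule, Patlak settings, SUVR windows, classifier zoo and economic
#' scenario.  One master seed drives all randomness; per-stage seeds are
#' derived from it deterministically.
#'
#' @param design A [cohort_design()].
#' @param schedule `"dataset1"`, `"dataset2"` or a [frame_schedule()].
#' @param n_retest Subjects in the test-retest arm (default 8).
#' @param t_star Patlak start time, minutes (default 30).
#' @param patlak_weights `"uniform"` or `"duration"`.
#' @param suvr_window_starts_min SUVR window start times (default 60, 75,
#'   90 min).
#' @param suvr_window_length_min SUVR window length (default 10 min).
#' @param classifier_families Families evaluated by the voxel stage
#'   (default the deterministic trio; see [model_spec()]).
#' @param classifier_seeds Seeds per stochastic family (default 5 here to
#'   keep the default run fast; raise to 100 for full runs).
#' @param econ An [econ_scenario()].
#' @param stages Character subset of
#'   `c("simulate", "patlak", "suvr", "reliability", "correlation",
#'   "effectsize", "roc", "classify", "econ")`.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(design = cohort_design(),
                       schedule = "dataset1",
                       n_retest = 8L,
                       t_star = 30,
                       patlak_weights = "uniform",
                       suvr_window_starts_min = c(60, 75, 90),
                       suvr_window_length_min = 10,
                       classifier_families = c("bernoulli_logistic",
                                               "linear_svm", "knn"),
                       classifier_seeds = 5L,
                       econ = econ_scenario(),
                       stages = c("patlak", "suvr", "reliability",
                                  "correlation", "effectsize", "roc",
                                  "classify", "econ"),
                       seed = 1L) {
  sched <- if (inherits(schedule, "frame_schedule")) schedule
           else switch(schedule,
                       dataset1 = frame_schedule_dataset1(),
                       dataset2 = frame_schedule_dataset2(),
                       stop("unknown schedule: ", schedule))
  structure(list(design = design, schedule = sched, n_retest = n_retest,
                 t_star = t_star, patlak_weights = patlak_weights,
                 suvr_window_starts_min = suvr_window_starts_min,
                 suvr_window_length_min = suvr_window_length_min,
                 classifier_families = classifier_families,
                 classifier_seeds = as.integer(classifier_seeds),
                 econ = econ, stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_regions <- function() {
  c("striatum", striatal_region_names())
}

# per-subject, per-region Patlak table for a list of scans
cohort_ki_table <- function(scans, t_star, weights) {
  do.call(rbind, lapply(scans, function(s) {
    do.call(rbind, lapply(pipeline_regions(), function(r) {
      f <- roi_ki(s, r, t_star = t_star, weights = weights)
      data.frame(subject_id = s$subject_id, group = s$group,
                 session = s$session, region = r,
                 ki_cer_per_min = f$ki_cer, intercept = f$intercept,
                 r_squared = f$r_squared, t_star_min = f$t_star)
    }))
  }))
}

cohort_suvr_table <- function(scans, starts, len) {
  do.call(rbind, lapply(scans, function(s) {
    do.call(rbind, lapply(starts, function(w0) {
      do.call(rbind, lapply(pipeline_regions(), function(r) {
        res <- compute_suvrc(s, r, w0, len)
        data.frame(subject_id = s$subject_id, group = s$group,
                   session = s$session, region = r,
                   window_start_min = w0, window_length_min = len,
                   suvrc = res$suvrc)
      }))
    }))
  }))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cross-sectional cohort and a test-retest arm, then executes
#' the configured stages in sequence: region Patlak Ki, SUVR windows,
#' test-retest reliability (both ICC variants + %VAR for Ki and SUVR),
#' normality-gated SUVR-vs-Ki correlations, responder/non-responder effect
#' sizes, ROC analyses (Ki and SUVR; whole striatum and associative
#' subdivision), voxel-wise LOOCV classification, and the economic model.
#' Every stage writes a CSV into `out_dir`; a run-report JSON records the
#' config echo, package version, per-stage wall-clock and output paths.
#' Given one master seed the CSV outputs are byte-identical across runs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return A `run_report` list (invisible): `outputs`, `timings_s`,
#'   `seed`, `version`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("fdopa_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4L)
  outputs <- character(0)
  timings <- numeric(0)
  mask <- make_striatal_mask()

  # drop SUVR windows that would run past the end of the acquisition
  scan_min <- sum(config$schedule$duration_s) / 60
  fits <- config$suvr_window_starts_min + config$suvr_window_length_min <=
    scan_min + 1e-9
  if (!all(fits))
    message("dropping SUVR window start(s) ",
            paste(config$suvr_window_starts_min[!fits], collapse = ", "),
            " min: window exceeds the ", scan_min, "-min acquisition")
  config$suvr_window_starts_min <- config$suvr_window_starts_min[fits]

  run_stage <- function(name, fun) {
    if (!name %in% c(config$stages, "setup")) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  save_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    outputs[[file]] <<- path
    path
  }

  cohort <- run_stage("setup", function()
    simulate_cohort(config$design, config$schedule, mask,
                    seed = stage_seed[1L]))
  rt_design <- config$design
  rt_design$n <- c(control = config$n_retest, responder = 1L,
                   nonresponder = 1L)  # reliability arm is control-based
  retest <- run_stage("setup", function()
    simulate_test_retest(rt_design, config$schedule, mask,
                         seed = stage_seed[2L]))

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      scan_dir <- file.path(out_dir, "scans")
      for (s in cohort) write_scan(s, scan_dir)
      outputs[["cohort_manifest.csv"]] <<-
        write_cohort_manifest(cohort, scan_dir)
    })
  }

  ki_tab <- run_stage("patlak", function()
    save_csv(cohort_ki_table(cohort, config$t_star, config$patlak_weights),
             "ki.csv"))
  ki_df <- if (!is.null(ki_tab)) utils::read.csv(ki_tab)

  suvr_tab <- run_stage("suvr", function()
    save_csv(cohort_suvr_table(cohort, config$suvr_window_starts_min,
                               config$suvr_window_length_min), "suvr.csv"))
  suvr_df <- if (!is.null(suvr_tab)) utils::read.csv(suvr_tab)

  run_stage("reliability", function() {
    ki_t <- cohort_ki_table(retest$test, config$t_star, config$patlak_weights)
    ki_r <- cohort_ki_table(retest$retest, config$t_star,
                            config$patlak_weights)
    sv_t <- cohort_suvr_table(retest$test, 75, config$suvr_window_length_min)
    sv_r <- cohort_suvr_table(retest$retest, 75,
                              config$suvr_window_length_min)
    rows <- do.call(rbind, lapply(pipeline_regions(), function(r) {
      do.call(rbind, lapply(c("ki_cer", "suvrc_75"), function(metric) {
        if (metric == "ki_cer") {
          te <- ki_t$ki_cer_per_min[ki_t$region == r]
          re <- ki_r$ki_cer_per_min[ki_r$region == r]
        } else {
          te <- sv_t$suvrc[sv_t$region == r]
          re <- sv_r$suvrc[sv_r$region == r]
        }
        pm <- paired_measurements(te, re)
        icc <- icc_two_way(pm)
        pv <- percent_var(pm)
        data.frame(region = r, metric = metric, n = length(te),
                   icc_consistency = icc$icc_consistency,
                   icc_agreement = icc$icc_agreement,
                   var_subject = icc$variance_components[["subject"]],
                   var_session = icc$variance_components[["session"]],
                   var_residual = icc$variance_components[["residual"]],
                   mean_var_percent = pv$mean_var)
      }))
    }))
    save_csv(rows, "reliability.csv")
  })

  run_stage("correlation", function() {
    stopifnot(!is.null(ki_df), !is.null(suvr_df))
    rows <- do.call(rbind, lapply(pipeline_regions(), function(r) {
      ki_r <- ki_df[ki_df$region == r, ]
      do.call(rbind, lapply(config$suvr_window_starts_min, function(w0) {
        sv <- suvr_df[suvr_df$region == r & suvr_df$window_start_min == w0, ]
        m <- merge(ki_r, sv, by = "subject_id")
        g <- gated_correlation(m$ki_cer_per_min, m$suvrc)
        data.frame(region = r, window_start_min = w0, n = nrow(m),
                   coefficient = g$coefficient, method = g$method,
                   p_value = g$p_value)
      }))
    }))
    save_csv(rows, "correlations.csv")
  })

  run_stage("effectsize", function() {
    stopifnot(!is.null(ki_df), !is.null(suvr_df))
    grab <- function(df, col, r, grp, w0 = NULL) {
      sel <- df$region == r & df$group == grp
      if (!is.null(w0)) sel <- sel & df$window_start_min == w0
      df[[col]][sel]
    }
    rows <- do.call(rbind, lapply(pipeline_regions(), function(r) {
      d_ki <- cohens_d(grab(ki_df, "ki_cer_per_min", r, "responder"),
                       grab(ki_df, "ki_cer_per_min", r, "nonresponder"))
      out <- data.frame(region = r, metric = "ki_cer",
                        window_start_min = NA_real_,
                        cohens_d = d_ki$cohens_d)
      for (w0 in config$suvr_window_starts_min) {
        d_sv <- cohens_d(grab(suvr_df, "suvrc", r, "responder", w0),
                         grab(suvr_df, "suvrc", r, "nonresponder", w0))
        out <- rbind(out, data.frame(region = r, metric = "suvrc",
                                     window_start_min = w0,
                                     cohens_d = d_sv$cohens_d))
      }
      out
    }))
    save_csv(rows, "effect_sizes.csv")
  })

  roc_df <- run_stage("roc", function() {
    stopifnot(!is.null(ki_df), !is.null(suvr_df))
    one_roc <- function(values, groups, label, region, w0 = NA_real_) {
      keep <- groups %in% c("responder", "nonresponder")
      rc <- roc_curve(labelled_scores(values[keep],
                                      groups[keep] == "nonresponder",
                                      positive_low = TRUE))
      data.frame(metric = label, region = region, window_start_min = w0,
                 auc = rc$auc, p_value = rc$p_value,
                 sens_at_100spec = rc$sens_at_full_spec)
    }
    rows <- do.call(rbind, lapply(c("striatum", "associative"), function(r) {
      ki_r <- ki_df[ki_df$region == r, ]
      out <- one_roc(ki_r$ki_cer_per_min, ki_r$group, "ki_cer", r)
      for (w0 in config$suvr_window_starts_min) {
        sv <- suvr_df[suvr_df$region == r & suvr_df$window_start_min == w0, ]
        out <- rbind(out, one_roc(sv$suvrc, sv$group, "suvrc", r, w0))
      }
      out
    }))
    save_csv(rows, "roc.csv")
    rows
  })

  run_stage("classify", function() {
    fm <- extract_feature_matrix(cohort, t_star = config$t_star,
                                 weights = config$patlak_weights)
    rows <- do.call(rbind, lapply(config$classifier_families, function(fam) {
      spec <- model_spec(fam)
      seeds <- if (spec$stochastic)
        stage_seed[3L] + seq_len(config$classifier_seeds) else 1L
      cv <- loocv_evaluate(spec, fm, seeds = seeds)
      data.frame(model = fam, mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
                 n_seeds = cv$n_seeds)
    }))
    save_csv(rows, "classifiers.csv")
  })

  run_stage("econ", function() {
    sc <- config$econ
    # feed the observed Ki whole-striatum operating point into the scenario
    if (!is.null(roc_df)) {
      sens <- roc_df$sens_at_100spec[roc_df$metric == "ki_cer" &
                                       roc_df$region == "striatum"][1L]
      if (is.finite(sens)) sc$sensitivity <- sens
    }
    out <- econ_outcome(sc)
    be <- tryCatch(breakeven_sensitivity(sc), error = function(e) NA_real_)
    save_csv(data.frame(sensitivity = sc$sensitivity,
                        specificity = sc$specificity,
                        net_per_patient_gbp = out$net_per_patient,
                        total_benefit_gbp = out$total_benefit,
                        total_cost_gbp = out$total_cost,
                        breakeven_sensitivity = be),
             "econ.csv")
    save_csv(savings_surface(sc, seq(0, 1, by = 0.1), seq(0, 1, by = 0.1)),
             "econ_surface.csv")
  })

  report <- list(outputs = outputs, timings_s = timings, seed = config$seed,
                 version = as.character(utils::packageVersion("fdopa")),
                 stages = config$stages)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  class(report) <- "run_report"
  invisible(report)
}
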