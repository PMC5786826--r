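#' Run the full ISC analysis pipeline
#'
#' Orchestrates every stage over a simulated or on-disk cohort:
#' (optional) simulation, preprocessing (resample, filter, EOG regression),
#' robust-PCA outlier removal, cohort assembly per condition, CorrCA model
#' fitting per configured subject group, per-subject ISC, SSVEP band power,
#' eigenvalue spectra, and the group statistics (age correlation with BH
#' FDR across the stimulus family, median-split two-way ANOVAs, Tukey post
#' hocs, SSVEP-residualized ISC, topography similarity across group
#' models). Results are written as CSV/JSON files under `out_dir`.
#'
#' @param config path to a YAML/JSON config file, or an equivalent named
#'   list. Recognized keys: `simulation` (arguments to [sim_config()]),
#'   `conditions` (character vector; must include at least one stimulus),
#'   `fit_groups` (subset of `all`, `age`, `sex`, `age_sex`),
#'   `preprocess` (`fs_target`, `hp_hz`, `notch`, `butter_order`),
#'   `rpca` (`enabled`, `lambda`, `tol`, `max_iter`),
#'   `ssvep` (`enabled`, `f0`, `bw`, `n_trials`, `electrodes`),
#'   `split_boundary` (fixed age boundary, optional), `n_components`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the per-stage results (`isc`, `models`,
#'   `ssvep`, `spectrum`, `stats`).
#' @export
run_pipeline <- function(config, out_dir = "isc_results") {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  log_line("isceeg pipeline, seed ", cfg$simulation$seed,
           ", conditions: ", paste(cfg$conditions, collapse = ", "))

  sim_cfg <- do.call(sim_config, cfg$simulation)
  conditions <- cfg$conditions
  stimuli <- setdiff(conditions, c("Rest", "Flash"))
  if (length(stimuli) < 1L)
    stop("config must name at least one stimulus condition")

  # --- simulate + preprocess + clean + assemble, per condition ----------
  cohorts <- list()
  subject_meta <- NULL
  for (cond in conditions) {
    log_line("condition ", cond, ": simulating N=", sim_cfg$n_subjects)
    sim <- simulate_cohort(sim_cfg, cond)
    recs <- lapply(sim$recordings, function(r) {
      r <- preprocess_recording(r, fs_target = cfg$preprocess$fs_target,
                                hp_hz = cfg$preprocess$hp_hz,
                                notch = cfg$preprocess$notch,
                                order = cfg$preprocess$butter_order)
      if (isTRUE(cfg$rpca$enabled))
        r <- clean_recording(r, lambda = cfg$rpca$lambda,
                             tol = cfg$rpca$tol,
                             max_iter = cfg$rpca$max_iter)
      r
    })
    cohorts[[cond]] <- build_cohort(recs, cond)
    if (is.null(subject_meta))
      subject_meta <- data.frame(subject_id = cohorts[[cond]]$subjects,
                                 age = cohorts[[cond]]$ages,
                                 sex = cohorts[[cond]]$sexes,
                                 stringsAsFactors = FALSE)
  }
  subject_meta <- median_split(subject_meta, cfg$split_boundary)

  # --- CorrCA / ISC per fit group ---------------------------------------
  log_line("fitting CorrCA models (groups: ",
           paste(cfg$fit_groups, collapse = ", "), ")")
  isc_all <- list(); models <- list()
  for (cond in conditions) {
    cohort <- cohorts[[cond]]
    covs <- assemble_covariances(cohort)
    for (fg in cfg$fit_groups) {
      groups <- fit_group_labels(fg, subject_meta, cohort$subjects)
      for (g in unique(groups)) {
        members <- which(groups == g)
        if (length(members) < 2L) next
        sub <- subset_cohort(cohort, members)
        covs_g <- if (identical(members, seq_along(cohort$subjects)))
          covs else assemble_covariances(sub)
        model <- fit_corrca(covs_g, k = cfg$n_components, fit_group = g)
        models[[paste(cond, g, sep = ".")]] <- model
        isc_all[[paste(cond, g, sep = ".")]] <-
          subject_isc(sub, model, covs_g)
      }
    }
  }
  isc_df <- do.call(rbind, isc_all)
  rownames(isc_df) <- NULL
  utils::write.csv(isc_df, file.path(out_dir, "isc_per_subject.csv"),
                   row.names = FALSE)

  # --- SSVEP -------------------------------------------------------------
  ssvep_df <- NULL
  if (isTRUE(cfg$ssvep$enabled)) {
    log_line("SSVEP stage: ", cfg$ssvep$n_trials, " trials per subject")
    fl <- simulate_flicker_trials(sim_cfg, n_trials = cfg$ssvep$n_trials,
                                  f0 = cfg$ssvep$f0)
    electrodes <- cfg$ssvep$electrodes
    if (is.null(electrodes)) electrodes <- sim_cfg$occipital
    ssvep_df <- do.call(rbind, lapply(names(fl$trial_sets), function(id) {
      ts <- reject_trials(fl$trial_sets[[id]], z = 3)
      ts <- trim_onset(ts, 200)
      data.frame(subject_id = id,
                 n_trials_used = dim(ts$trials)[1L],
                 band_power = band_power(ts, f0 = cfg$ssvep$f0,
                                         bw = cfg$ssvep$bw,
                                         electrodes = electrodes),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(ssvep_df, file.path(out_dir, "ssvep_power.csv"),
                     row.names = FALSE)
  }

  # --- eigenvalue spectra ------------------------------------------------
  spectrum_df <- do.call(rbind, lapply(conditions, function(cond) {
    cohort <- cohorts[[cond]]
    do.call(rbind, lapply(seq_along(cohort$data), function(k) {
      sf <- fit_loglog_slope(eigenspectrum(cohort$data[[k]]))
      data.frame(subject_id = cohort$subjects[k], condition = cond,
                 total_power = sf$total_power, slope = sf$slope,
                 n_used = sf$n_used, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(spectrum_df, file.path(out_dir, "spectrum.csv"),
                   row.names = FALSE)

  # --- group statistics --------------------------------------------------
  log_line("group statistics")
  stats_out <- pipeline_stats(isc_df, ssvep_df, spectrum_df, subject_meta,
                              stimuli, models, cfg)
  jsonlite::write_json(stats_out, file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done; outputs in ", normalizePath(out_dir))
  invisible(list(isc = isc_df, models = models, ssvep = ssvep_df,
                 spectrum = spectrum_df, stats = stats_out,
                 subjects = subject_meta))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  defaults <- list(
    simulation = list(),
    conditions = c("Wimpy", "Rest"),
    fit_groups = c("all"),
    n_components = 3L,
    split_boundary = NULL,
    preprocess = list(fs_target = 125, hp_hz = 1, notch = c(59, 61),
                      butter_order = 4L),
    rpca = list(enabled = TRUE, lambda = NULL, tol = 1e-7, max_iter = 500L),
    ssvep = list(enabled = TRUE, f0 = 25, bw = 0.5, n_trials = 128L,
                 electrodes = NULL))
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$conditions) < 1L) stop("config names no conditions")
  for (blk in c("preprocess", "rpca", "ssvep"))
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], as.list(cfg[[blk]]))
  if (is.null(cfg$simulation$seed)) cfg$simulation$seed <- 1L
  cfg
}

fit_group_labels <- function(fg, meta, subjects) {
  m <- meta[match(subjects, meta$subject_id), ]
  switch(fg,
    all = rep("all", length(subjects)),
    age = as.character(m$age_group),
    sex = m$sex,
    age_sex = paste(m$age_group, m$sex, sep = "-"),
    stop("unknown fit group: ", fg))
}

subset_cohort <- function(cohort, idx) {
  cohort$data <- cohort$data[idx]
  cohort$subjects <- cohort$subjects[idx]
  cohort$ages <- cohort$ages[idx]
  cohort$sexes <- cohort$sexes[idx]
  cohort
}

pipeline_stats <- function(isc_df, ssvep_df, spectrum_df, meta, stimuli,
                           models, cfg) {
  out <- list()
  # age correlation per stimulus (all-subject models), BH across the family
  all_rows <- isc_df[isc_df$model_group == "all" &
                       isc_df$condition %in% stimuli, ]
  if (nrow(all_rows)) {
    fam <- vapply(stimuli, function(s) {
      r <- all_rows[all_rows$condition == s, ]
      correlate_with_age(r$isc, r$age)$p
    }, numeric(1))
    out$age_correlation <- lapply(stimuli, function(s) {
      r <- all_rows[all_rows$condition == s, ]
      correlate_with_age(r$isc, r$age, family = fam)
    })
    names(out$age_correlation) <- stimuli
  }
  # median-split ANOVA: ISC ~ age_group + stimulus on within-group models
  grp_rows <- isc_df[isc_df$condition %in% stimuli, ]
  if ("age" %in% cfg$fit_groups) {
    r <- grp_rows[grp_rows$model_group %in% c("young", "old"), ]
    if (length(unique(r$condition)) >= 2L)
      out$anova_age_stimulus <-
        two_way_anova(r$isc, r$model_group, r$condition)
    else
      out$anova_age_stimulus <- two_way_anova(r$isc, r$model_group)
  }
  if ("sex" %in% cfg$fit_groups) {
    r <- grp_rows[grp_rows$model_group %in% c("male", "female"), ]
    if (length(unique(r$condition)) >= 2L)
      out$anova_sex_stimulus <-
        two_way_anova(r$isc, r$model_group, r$condition)
    else
      out$anova_sex_stimulus <- two_way_anova(r$isc, r$model_group)
  }
  # age-sex groups, ISC averaged across stimuli
  if ("age_sex" %in% cfg$fit_groups) {
    r <- grp_rows[grepl("-", grp_rows$model_group), ]
    if (nrow(r)) {
      avg <- stats::aggregate(isc ~ subject_id + model_group, r, mean)
      parts <- strsplit(avg$model_group, "-", fixed = TRUE)
      avg$age_group <- vapply(parts, `[[`, character(1), 1L)
      avg$sex <- vapply(parts, `[[`, character(1), 2L)
      if (all(table(avg$age_group, avg$sex) > 0))
        out$anova_age_sex <- two_way_anova(avg$isc, avg$age_group, avg$sex)
      if (!is.null(ssvep_df)) {
        res <- residualize_isc(avg[, c("subject_id", "isc")], ssvep_df)
        res <- merge(res, avg[, c("subject_id", "age_group", "sex")],
                     by = "subject_id")
        out$anova_residual_isc <-
          two_way_anova(res$residual, res$age_group, res$sex)
      }
    }
  }
  # stimulus Tukey comparisons on all-subject ISC
  if (length(stimuli) >= 2L && nrow(all_rows))
    out$tukey_stimulus <- tukey_hsd(all_rows$isc, all_rows$condition)
  # SSVEP vs age
  if (!is.null(ssvep_df)) {
    m <- merge(ssvep_df, meta, by = "subject_id")
    out$ssvep_age_correlation <- correlate_with_age(m$band_power, m$age)
  }
  # spectrum: power and slope by age group across stimuli
  sp <- merge(spectrum_df[spectrum_df$condition %in% stimuli, ], meta,
              by = "subject_id")
  if (nrow(sp) && length(unique(sp$age_group)) == 2L) {
    if (length(unique(sp$condition)) >= 2L) {
      out$anova_power_age <- two_way_anova(sp$total_power, sp$age_group,
                                           sp$condition)
      out$anova_slope_age <- two_way_anova(sp$slope, sp$age_group,
                                           sp$condition)
    } else {
      out$anova_power_age <- two_way_anova(sp$total_power, sp$age_group)
      out$anova_slope_age <- two_way_anova(sp$slope, sp$age_group)
    }
  }
  # topography similarity between group models, per condition
  if ("age" %in% cfg$fit_groups) {
    sims <- list()
    for (cond in unique(grp_rows$condition)) {
      a <- models[[paste(cond, "young", sep = ".")]]
      b <- models[[paste(cond, "old", sep = ".")]]
      if (!is.null(a) && !is.null(b))
        sims[[cond]] <- topography_similarity(a, b)
    }
    if (length(sims)) out$topography_similarity_age <- sims
  }
  out
}
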