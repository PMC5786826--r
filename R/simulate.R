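#' Configuration for the synthetic multi-subject EEG cohort
#'
#' The generator emulates the statistical structure the ISC analysis
#' assumes: a few shared stimulus-locked source time courses mixed to scalp
#' channels with a per-subject gain that decreases with age and is offset
#' by sex, spatially correlated 1/f background noise, EOG channels leaking
#' into the scalp, sparse gross outliers, a Rest condition with no shared
#' signal, and 25 Hz flicker trials for the SSVEP stage.
#'
#' The per-subject shared-signal gain is
#' `max(0, baseline + age_slope * (age - min(age_range)) + male_offset * is_male)`,
#' so with the defaults the youngest subjects sit at signal-to-noise ratio
#' about 1 and gain declines linearly with age.
#'
#' @param n_subjects cohort size (default 12).
#' @param n_channels number of scalp EEG channels (default 16).
#' @param n_eog number of EOG channels (default 2).
#' @param duration_s recording length in seconds (default 60).
#' @param fs sampling rate in Hz (default 125).
#' @param n_sources number of shared band-limited sources (default 3).
#' @param source_band shared-source band in Hz (default 0.5-15).
#' @param gain_baseline shared-signal gain at the youngest age (default 1).
#' @param age_slope gain change per year, non-positive (default -0.02).
#' @param male_offset additive gain for males, non-negative (default 0.2).
#' @param noise_exponent background-noise spectral exponent a in 1/f^a
#'   (default 1).
#' @param noise_sd background-noise standard deviation per channel
#'   (default 1).
#' @param spatial_scale channel-index smoothing scale of the noise spatial
#'   correlation (default 2).
#' @param eog_leak scale of EOG leakage into scalp channels (default 0.3).
#' @param artifact_rate expected gross-outlier spikes per minute
#'   (default 4).
#' @param spike_amp spike amplitude in multiples of channel RMS
#'   (default 20).
#' @param ssvep_scale flicker-drive amplitude multiplier applied to the
#'   subject gain (default 1).
#' @param occipital names of the channels carrying the flicker drive
#'   (default the last 3 scalp channels).
#' @param ages,sexes optional explicit per-subject values; by default ages
#'   are drawn uniformly over `age_range` and sexes are balanced.
#' @param age_range age span in years (default 6-44).
#' @param seed integer seed making the cohort fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, n_channels = 16L, n_eog = 2L,
                       duration_s = 60, fs = 125, n_sources = 3L,
                       source_band = c(0.5, 15),
                       gain_baseline = 1, age_slope = -0.02,
                       male_offset = 0.2,
                       noise_exponent = 1, noise_sd = 1,
                       spatial_scale = 2, eog_leak = 0.3,
                       artifact_rate = 4, spike_amp = 20,
                       ssvep_scale = 1, occipital = NULL,
                       ages = NULL, sexes = NULL, age_range = c(6, 44),
                       seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (age_slope > 0) stop("age_slope must be <= 0")
  if (male_offset < 0) stop("male_offset must be >= 0")
  if (fs <= 2 * source_band[2L])
    stop("fs must exceed twice the highest source frequency")
  if (!is.null(ages) && length(ages) != n_subjects)
    stop("ages length must equal n_subjects")
  if (!is.null(sexes) && length(sexes) != n_subjects)
    stop("sexes length must equal n_subjects")
  if (is.null(occipital))
    occipital <- paste0("E", (n_channels - 2L):n_channels)
  structure(as.list(environment()), class = "sim_config")
}

# one draw per cfg seed, shared by every condition and the flicker stage,
# so subject k keeps one age/sex across the whole simulated study
sim_demographics <- function(cfg) {
  set.seed(cfg$seed)
  ages <- if (is.null(cfg$ages))
    stats::runif(cfg$n_subjects, cfg$age_range[1L], cfg$age_range[2L])
  else cfg$ages
  sexes <- cfg$sexes
  if (is.null(sexes)) {
    # balanced, and crossed with age: alternate along the age order so
    # every age-by-sex cell of a median split is populated
    sexes <- character(cfg$n_subjects)
    sexes[order(ages)] <- rep(c("male", "female"),
                              length.out = cfg$n_subjects)
  }
  list(ages = ages, sexes = sexes)
}

sim_gain <- function(cfg, age, sex) {
  pmax(0, cfg$gain_baseline + cfg$age_slope * (age - cfg$age_range[1L]) +
         cfg$male_offset * (sex == "male"))
}

# 1/f^a noise via frequency-domain synthesis, unit variance
pink_noise <- function(n, exponent, fs) {
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  as.numeric(x / stats::sd(x))
}

# smooth spatial mixing: Gaussian kernel over channel index
spatial_kernel <- function(d, scale) {
  K <- outer(seq_len(d), seq_len(d),
             function(i, j) exp(-(i - j)^2 / (2 * scale^2)))
  K / sqrt(rowSums(K^2))
}

sim_sources <- function(cfg, n_samples) {
  nyq <- cfg$fs / 2
  bp <- signal::butter(4, cfg$source_band / nyq, type = "pass")
  t(vapply(seq_len(cfg$n_sources), function(i) {
    s <- signal::filtfilt(bp, stats::rnorm(n_samples))
    s / stats::sd(s)
  }, numeric(n_samples)))
}

sim_eog <- function(cfg, n_samples) {
  nyq <- cfg$fs / 2
  lp <- signal::butter(2, 3 / nyq, type = "low")
  t(vapply(seq_len(cfg$n_eog), function(i) {
    drift <- signal::filtfilt(lp, stats::rnorm(n_samples)) * 3
    # saccade-like steps
    nstep <- max(1L, round(n_samples / cfg$fs / 2))
    at <- sample.int(n_samples, nstep)
    steps <- numeric(n_samples)
    steps[at] <- stats::rnorm(nstep, sd = 4)
    drift + signal::filtfilt(lp, cumsum(steps) - mean(cumsum(steps)))
  }, numeric(n_samples)))
}

#' Simulate a multi-subject cohort for one condition
#'
#' Each subject's scalp data are
#' `gain(age, sex) * mixing %*% sources + spatially correlated 1/f noise +
#' eog_leak * leakage %*% eog + sparse spikes`. The shared sources are
#' common to every subject (they stand for stimulus-locked activity);
#' condition `"Rest"` forces the shared gain to zero, and `"Flash"`
#' additionally drives the occipital channels with a 25 Hz sinusoid gated
#' in 2.4 s on / 1 s off trials.
#'
#' @param cfg a [sim_config()].
#' @param condition condition label (`"Rest"` and `"Flash"` are special,
#'   any other label is a generic stimulus).
#' @return A list with `recordings` (list of `eeg_recording` including the
#'   EOG channels) and `truth` (mixing matrix, per-subject gains, ages,
#'   sexes, spike positions, source time courses).
#' @export
simulate_cohort <- function(cfg, condition = "Stim") {
  stopifnot(inherits(cfg, "sim_config"))
  demo <- sim_demographics(cfg)
  ages <- demo$ages; sexes <- demo$sexes
  set.seed(cfg$seed + sum(utf8ToInt(condition)) %% 1000L)
  n <- cfg$n_subjects
  d <- cfg$n_channels
  nt <- round(cfg$duration_s * cfg$fs)
  gains <- sim_gain(cfg, ages, sexes)
  if (condition == "Rest") gains <- rep(0, n)
  mixing <- spatial_kernel(d, cfg$spatial_scale) %*%
    matrix(stats::rnorm(d * cfg$n_sources), d, cfg$n_sources)
  mixing <- apply(mixing, 2L, function(m)
    m / sqrt(sum(m^2)) * sqrt(d / cfg$n_sources))
  mixing <- matrix(mixing, nrow = d)
  sources <- sim_sources(cfg, nt)
  Ksp <- spatial_kernel(d, cfg$spatial_scale)
  flash_drive <- if (condition == "Flash") {
    gate <- rep(c(rep(1, round(2.4 * cfg$fs)), rep(0, round(1 * cfg$fs))),
                length.out = nt)
    sin(2 * pi * 25 * seq_len(nt) / cfg$fs) * gate
  }
  ch_names <- c(paste0("E", seq_len(d)), paste0("EOG", seq_len(cfg$n_eog)))
  roles <- c(rep("EEG", d), rep("EOG", cfg$n_eog))
  spike_log <- list()
  recordings <- vector("list", n)
  for (k in seq_len(n)) {
    noise <- Ksp %*% t(vapply(seq_len(d), function(i)
      pink_noise(nt, cfg$noise_exponent, cfg$fs), numeric(nt)))
    noise <- noise / stats::sd(as.numeric(noise)) * cfg$noise_sd
    x <- gains[k] * (mixing %*% sources) + noise
    eog <- sim_eog(cfg, nt)
    leak <- matrix(stats::rnorm(d * cfg$n_eog, sd = cfg$eog_leak),
                   d, cfg$n_eog)
    x <- x + leak %*% eog
    if (condition == "Flash") {
      occ <- match(cfg$occipital, ch_names[seq_len(d)])
      x[occ, ] <- x[occ, ] +
        rep(cfg$ssvep_scale * gains_flash(cfg, ages[k], sexes[k]),
            each = 1) * matrix(flash_drive, length(occ), nt, byrow = TRUE)
    }
    nspk <- stats::rpois(1L, cfg$artifact_rate * cfg$duration_s / 60)
    spk <- NULL
    if (nspk > 0) {
      spk <- cbind(channel = sample.int(d, nspk, replace = TRUE),
                   sample = sample.int(nt, nspk, replace = TRUE))
      rms <- sqrt(rowMeans(x^2))
      for (s in seq_len(nspk))
        x[spk[s, 1L], spk[s, 2L]] <- x[spk[s, 1L], spk[s, 2L]] +
          sample(c(-1, 1), 1L) * cfg$spike_amp * rms[spk[s, 1L]]
    }
    spike_log[[k]] <- spk
    recordings[[k]] <- new_recording(rbind(x, eog), cfg$fs, roles,
                                     subject_id = sprintf("S%02d", k),
                                     condition = condition,
                                     age = ages[k], sex = sexes[k],
                                     channel_names = ch_names)
  }
  list(recordings = recordings,
       truth = list(mixing = mixing, gains = gains, ages = ages,
                    sexes = sexes, spikes = spike_log, sources = sources))
}

# flicker-drive amplitude shares the gain model with the shared sources
gains_flash <- function(cfg, age, sex) sim_gain(cfg, age, sex)

#' Simulate flicker trials for the SSVEP stage
#'
#' Generates `n_trials` trials of 2.4 s per subject: white background noise
#' on every channel plus an `f0` sinusoid on the configured occipital
#' channels whose amplitude follows the subject's gain model (so planted
#' amplitude declines with age).
#'
#' @param cfg a [sim_config()].
#' @param n_trials trials per subject (default 128, i.e. the full flicker
#'   session).
#' @param f0 flicker frequency in Hz (default 25).
#' @param trial_s trial duration in seconds (default 2.4).
#' @param noise_sd in-trial noise standard deviation (default
#'   `cfg$noise_sd`).
#' @return A list with `trial_sets` (named list of `trial_set`, one per
#'   subject), `amplitudes` (planted per-subject drive amplitude), `ages`,
#'   `sexes`.
#' @export
simulate_flicker_trials <- function(cfg, n_trials = 128L, f0 = 25,
                                    trial_s = 2.4, noise_sd = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (f0 >= cfg$fs / 2) stop("f0 must be below the Nyquist frequency")
  if (is.null(noise_sd)) noise_sd <- cfg$noise_sd
  demo <- sim_demographics(cfg)
  ages <- demo$ages; sexes <- demo$sexes
  set.seed(cfg$seed + 101L)
  n <- cfg$n_subjects
  d <- cfg$n_channels
  nt <- round(trial_s * cfg$fs)
  amps <- cfg$ssvep_scale * sim_gain(cfg, ages, sexes)
  ch_names <- paste0("E", seq_len(d))
  occ <- match(cfg$occipital, ch_names)
  if (any(is.na(occ))) stop("occipital channels not among scalp channels")
  drive <- sin(2 * pi * f0 * seq_len(nt) / cfg$fs)
  labels <- rep(paste0("cond", seq_len(12L)), length.out = n_trials)
  ids <- sprintf("S%02d", seq_len(n))
  trial_sets <- lapply(seq_len(n), function(k) {
    arr <- array(stats::rnorm(n_trials * d * nt, sd = noise_sd),
                 c(n_trials, d, nt))
    for (tr in seq_len(n_trials))
      arr[tr, occ, ] <- arr[tr, occ, ] +
        matrix(amps[k] * drive, length(occ), nt, byrow = TRUE)
    new_trial_set(arr, cfg$fs, ch_names, condition_labels = labels,
                  subject_id = ids[k])
  })
  names(trial_sets) <- ids
  list(trial_sets = trial_sets, amplitudes = stats::setNames(amps, ids),
       ages = stats::setNames(ages, ids), sexes = stats::setNames(sexes, ids))
}
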