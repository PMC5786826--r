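#' Resample a recording with anti-alias filtering
#'
#' Polyphase rational-rate resampling of every channel to a lower rate
#' (typically 500 Hz -> 125 Hz): zero stuffing by the numerator `p` of the
#' reduced rate ratio, a zero-phase (forward-backward) FIR anti-alias
#' low-pass at 0.9 of the target Nyquist frequency, then decimation by the
#' denominator `q`. The zero-phase filter keeps samples aligned in time,
#' which matters because ISC compares fine temporal structure across
#' subjects.
#'
#' @param rec an `eeg_recording`.
#' @param fs_target target sampling rate in Hz, at most `rec$fs`.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, fs_target) {
  if (fs_target > rec$fs)
    stop("fs_target (", fs_target, ") exceeds recording rate (", rec$fs, ")")
  if (isTRUE(all.equal(fs_target, rec$fs))) return(rec)
  frac <- ratio_approx(fs_target / rec$fs)
  p <- frac[1L]; q <- frac[2L]
  f <- max(p, q)
  h <- signal::fir1(20L * f, 0.9 / f)
  nt <- ncol(rec$data)
  out <- t(apply(rec$data, 1L, function(ch) {
    up <- numeric(nt * p)
    up[seq(1L, nt * p, p)] <- ch
    y <- signal::filtfilt(signal::Ma(h), up) * p
    y[seq(1L, length(y), q)]
  }))
  new_recording(out, rec$fs * p / q, rec$channel_roles,
                subject_id = rec$subject_id, condition = rec$condition,
                age = rec$age, sex = rec$sex,
                channel_names = rec$channel_names)
}

# smallest p/q with |p/q - x| < tol (continued fractions)
ratio_approx <- function(x, tol = 1e-9, max_den = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol) break
    if (abs(r - a) < .Machine$double.eps) break
    r <- 1 / (r - a)
  }
  c(p1, q1)
}

#' High-pass and notch filter a recording
#'
#' High-pass at `hp_hz` (default 1 Hz) followed by a band-stop notch
#' (default 59-61 Hz), both Butterworth of prototype order `order`
#' (default 4), applied zero phase by forward-backward filtering
#' ([signal::filtfilt()]); the effective magnitude response is therefore
#' that of order `2 * order`. Zero-phase filtering is used because ISC
#' compares fine temporal structure across subjects and phase distortion
#' would deflate correlations.
#'
#' @param rec an `eeg_recording`.
#' @param hp_hz high-pass corner in Hz.
#' @param notch length-2 numeric, band-stop edges in Hz; `NULL` skips the
#'   notch (e.g. when the Nyquist rate is below the band).
#' @param order Butterworth prototype order.
#' @return The filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, hp_hz = 1, notch = c(59, 61), order = 4L) {
  nyq <- rec$fs / 2
  if (hp_hz <= 0 || hp_hz >= nyq)
    stop("high-pass corner must lie in (0, fs/2)")
  if (!is.null(notch)) {
    if (length(notch) != 2L || notch[1L] >= notch[2L] ||
        notch[1L] <= hp_hz || notch[2L] >= nyq)
      stop("notch band must satisfy hp < lo < hi < fs/2")
  }
  hp <- signal::butter(order, hp_hz / nyq, type = "high")
  bs <- if (!is.null(notch))
    signal::butter(order, notch / nyq, type = "stop")
  # odd-reflection padding keeps the forward-backward transient (whose time
  # scale is set by the high-pass corner) away from the retained samples
  nt <- ncol(rec$data)
  npad <- min(nt - 1L, round(6 * rec$fs / hp_hz))
  out <- t(apply(rec$data, 1L, function(ch) {
    xp <- c(2 * ch[1L] - rev(ch[2L:(npad + 1L)]),
            ch,
            2 * ch[nt] - rev(ch[(nt - npad):(nt - 1L)]))
    y <- signal::filtfilt(hp, xp)
    if (!is.null(bs)) y <- signal::filtfilt(bs, y)
    y[(npad + 1L):(npad + nt)]
  }))
  rec$data <- out
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Regress EOG channels out of scalp EEG
#'
#' Removes ocular artifacts by ordinary least squares: all EEG channels are
#' jointly regressed on the EOG channels (temporal means removed first) and
#' the residual is returned. The residual is zero-mean per channel and
#' orthogonal in time to every EOG channel.
#'
#' @param eeg numeric matrix, EEG channels x samples.
#' @param eog numeric matrix, EOG channels x samples (same sample count).
#' @return Residual matrix of the same shape as `eeg`, zero-mean per channel.
#' @export
regress_out_eog <- function(eeg, eog) {
  eeg <- as.matrix(eeg); eog <- as.matrix(eog)
  if (ncol(eeg) != ncol(eog))
    stop("EEG and EOG must have the same number of samples")
  if (nrow(eog) < 1L) stop("at least one EOG channel required")
  eegc <- eeg - rowMeans(eeg)
  eogc <- eog - rowMeans(eog)
  if (all(abs(eogc) < .Machine$double.eps)) {
    warning("EOG channels carry no variance; returning EEG unchanged")
    return(eeg)
  }
  # residual of eegc' ~ eogc' via QR; B = eegc eogc' (eogc eogc')^-1
  fit <- qr(t(eogc))
  res <- t(qr.resid(fit, t(eegc)))
  dimnames(res) <- dimnames(eeg)
  res
}

#' Run the full signal-conditioning chain on one recording
#'
#' Downsample, high-pass + notch filter, regress EOG out of the scalp
#' channels, then drop the EOG channels (their job is done). Stage order
#' matches the acquisition-processing chain the analysis assumes.
#'
#' @param rec an `eeg_recording` containing EEG (and optionally EOG) rows.
#' @param fs_target target rate in Hz (default 125).
#' @param hp_hz high-pass corner (default 1 Hz).
#' @param notch notch band (default 59-61 Hz), `NULL` to skip.
#' @param order Butterworth prototype order (default 4).
#' @return An `eeg_recording` with EEG (and BAD) channels only.
#' @export
preprocess_recording <- function(rec, fs_target = 125, hp_hz = 1,
                                 notch = c(59, 61), order = 4L) {
  rec <- resample_recording(rec, fs_target)
  if (!is.null(notch) && notch[2L] >= fs_target / 2) notch <- NULL
  rec <- filter_recording(rec, hp_hz = hp_hz, notch = notch, order = order)
  is_eog <- rec$channel_roles == "EOG"
  keep <- !is_eog & rec$channel_roles != "DISCARD"
  out <- rec$data[keep, , drop = FALSE]
  if (any(is_eog)) {
    scalp <- rec$channel_roles[keep] == "EEG"
    out[scalp, ] <- regress_out_eog(out[scalp, , drop = FALSE],
                                    rec$data[is_eog, , drop = FALSE])
  }
  new_recording(out, rec$fs, rec$channel_roles[keep],
                subject_id = rec$subject_id, condition = rec$condition,
                age = rec$age, sex = rec$sex,
                channel_names = rec$channel_names[keep])
}
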