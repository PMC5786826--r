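#' Construct an EEG recording object
#'
#' A recording holds one subject's channels-by-samples voltage matrix for one
#' stimulus condition, together with the sampling rate, per-channel roles and
#' subject metadata. It is the unit every preprocessing stage consumes.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_roles character vector, one of `"EEG"`, `"EOG"`,
#'   `"DISCARD"`, `"BAD"` per row of `data`. `BAD` channels are retained but
#'   zeroed at cohort assembly so they contribute nothing to covariances.
#' @param subject_id subject identifier string.
#' @param condition stimulus condition label (e.g. `"Wimpy"`, `"Rest"`,
#'   `"Flash"`).
#' @param age subject age in years.
#' @param sex `"male"` or `"female"`.
#' @param channel_names optional character vector of channel names; defaults
#'   to `"E1"`, `"E2"`, ...
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_roles,
                          subject_id = "S1", condition = "Stim",
                          age = NA_real_, sex = NA_character_,
                          channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (length(channel_roles) != nrow(data))
    stop("channel_roles length (", length(channel_roles),
         ") does not match channel count (", nrow(data), ")")
  channel_roles <- toupper(as.character(channel_roles))
  bad_lab <- setdiff(unique(channel_roles), c("EEG", "EOG", "DISCARD", "BAD"))
  if (length(bad_lab))
    stop("unknown channel roles: ", paste(bad_lab, collapse = ", "))
  if (!any(channel_roles == "EEG"))
    stop("recording must contain at least one EEG channel")
  if (any(!is.finite(data)))
    stop("recording contains non-finite samples")
  if (is.null(channel_names))
    channel_names <- paste0("E", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length does not match channel count")
  rownames(data) <- channel_names
  structure(list(
    subject_id = as.character(subject_id),
    condition = as.character(condition),
    fs = as.numeric(fs),
    data = data,
    channel_roles = channel_roles,
    channel_names = as.character(channel_names),
    age = as.numeric(age),
    sex = as.character(sex)
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, condition %s\n",
              x$subject_id, x$condition))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$channel_roles)),
                            table(x$channel_roles)), collapse = " ")))
  invisible(x)
}

#' Number of EEG channels and samples
#' @param rec an `eeg_recording`.
#' @return integer vector `c(channels, samples)`.
#' @export
dim_recording <- function(rec) dim(rec$data)

# --- role / metadata tables ---------------------------------------------

#' Read a channel-role table
#'
#' CSV with header `channel,role`; roles in EEG/EOG/DISCARD/BAD.
#' @param path CSV file path.
#' @return data.frame with columns `channel`, `role`.
#' @export
read_roles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "role") %in% names(df)))
    stop("role table must have columns 'channel' and 'role'")
  df$role <- toupper(df$role)
  df
}

#' Read a subject-metadata table
#'
#' CSV with header `subject_id,age,sex`.
#' @param path CSV file path.
#' @return data.frame with one row per subject.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex")
  if (!all(need %in% names(df)))
    stop("subject table must have columns subject_id, age, sex")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subject table")
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("ages must be positive")
  df
}

# --- reading / writing recordings ---------------------------------------

#' Read a recording from disk
#'
#' Dispatches on the file extension: `.edf` is read with the built-in
#' EDF/EDF+ codec (annotations ignored), `.rds` with the native matrix
#' layout written by [write_recording()]. Channels whose role is `DISCARD`
#' are dropped; `BAD` channels are kept (they are zeroed later, at cohort
#' assembly).
#'
#' @param path file path (`.edf` or `.rds`).
#' @param roles data.frame with columns `channel`, `role` covering every
#'   channel in the file (see [read_roles()]).
#' @param meta one-row data.frame (or list) with `subject_id`, `age`, `sex`;
#'   if the file stores a subject id they must agree.
#' @param condition condition label; overrides anything stored in the file
#'   when non-NULL.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, roles, meta, condition = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    edf = read_edf(path),
    rds = read_rds_recording(path),
    stop("unsupported recording format: .", ext))
  if (is.null(condition)) condition <- raw$condition
  if (is.null(condition)) condition <- "Stim"
  if (nrow(roles) != length(raw$channel_names))
    stop("role table has ", nrow(roles), " rows but file has ",
         length(raw$channel_names), " channels")
  idx <- match(raw$channel_names, roles$channel)
  if (any(is.na(idx)))
    stop("channels missing from role table: ",
         paste(raw$channel_names[is.na(idx)], collapse = ", "))
  role <- roles$role[idx]
  if (is.null(meta) || !all(c("subject_id", "age", "sex") %in% names(meta)))
    stop("missing subject metadata (subject_id, age, sex)")
  keep <- role != "DISCARD"
  new_recording(raw$data[keep, , drop = FALSE], raw$fs, role[keep],
                subject_id = meta$subject_id, condition = condition,
                age = meta$age, sex = meta$sex,
                channel_names = raw$channel_names[keep])
}

#' Write a recording to disk
#'
#' `.edf` writes 16-bit EDF (physical range set per channel from the data,
#' so values are quantized to (max-min)/65535); `.rds` writes the native
#' layout, bit-exact for doubles.
#'
#' @param rec an `eeg_recording`.
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    edf = write_edf(rec, path),
    rds = write_rds_recording(rec, path),
    stop("unsupported recording format: .", ext))
  invisible(path)
}

# Native layout: plain list mirroring the on-disk dataset/attribute layout
# (data matrix + fs/subject_id/condition + channel names).
write_rds_recording <- function(rec, path) {
  saveRDS(list(data = rec$data, fs = rec$fs, subject_id = rec$subject_id,
               condition = rec$condition, channels = rec$channel_names),
          path)
}

read_rds_recording <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !all(c("data", "fs", "channels") %in% names(x)))
    stop("not a recording layout: ", path)
  list(data = as.matrix(x$data), fs = x$fs, channel_names = x$channels,
       condition = x$condition)
}

# --- cohort assembly ----------------------------------------------------

#' Stack cleaned recordings of one condition into a cohort
#'
#' Subjects are stacked in input order; EEG channels are ordered by
#' `channel_order` (default: the channel order of the first recording).
#' Assembly fails if any recording lacks a requested channel name — silent
#' reordering or dropping would misalign the covariance matrices downstream.
#' Recordings are truncated to the minimum common length, and `BAD` channels
#' are zeroed so they contribute nothing to any covariance.
#'
#' @param recordings list of `eeg_recording` objects, all of `condition`.
#' @param condition condition label the cohort represents.
#' @param channel_order optional character vector of EEG channel names fixing
#'   the row order.
#' @return An object of class `eeg_cohort` with elements `condition`,
#'   `subjects`, `data` (list of D x T matrices, one per subject), `fs`,
#'   `channel_names`, `ages`, `sexes`.
#' @export
build_cohort <- function(recordings, condition, channel_order = NULL) {
  recordings <- Filter(function(r) identical(r$condition, condition),
                       recordings)
  if (length(recordings) < 2L)
    stop("cohort for condition '", condition,
         "' needs at least 2 recordings, got ", length(recordings))
  fs <- vapply(recordings, `[[`, numeric(1), "fs")
  if (length(unique(fs)) != 1L)
    stop("sampling rates differ across recordings: ",
         paste(unique(fs), collapse = ", "))
  if (is.null(channel_order)) {
    r1 <- recordings[[1L]]
    channel_order <- r1$channel_names[r1$channel_roles %in% c("EEG", "BAD")]
  }
  tmin <- min(vapply(recordings, function(r) ncol(r$data), integer(1)))
  slabs <- lapply(recordings, function(r) {
    idx <- match(channel_order, r$channel_names)
    if (any(is.na(idx)))
      stop("subject ", r$subject_id, " is missing channels: ",
           paste(channel_order[is.na(idx)], collapse = ", "))
    x <- r$data[idx, seq_len(tmin), drop = FALSE]
    x[r$channel_roles[idx] == "BAD", ] <- 0
    x
  })
  structure(list(
    condition = condition,
    subjects = vapply(recordings, `[[`, character(1), "subject_id"),
    data = slabs,
    fs = fs[1L],
    channel_names = channel_order,
    ages = vapply(recordings, `[[`, numeric(1), "age"),
    sexes = vapply(recordings, `[[`, character(1), "sex")
  ), class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> condition %s: N=%d subjects, D=%d channels, T=%d samples @ %g Hz\n",
              x$condition, length(x$data), nrow(x$data[[1L]]),
              ncol(x$data[[1L]]), x$fs))
  invisible(x)
}
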