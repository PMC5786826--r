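# Minimal EDF/EDF+ codec: 16-bit little-endian samples, fixed-width ASCII
# header. Annotation signals ("EDF Annotations") are skipped on read; all
# signals must share one sampling rate. Physical scaling follows the header
# calibration (phys range mapped onto dig range per channel).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  x <- rec$data
  ns <- nrow(x)
  nt <- ncol(x)
  # one data record holding the whole signal keeps lengths exact
  pmin <- apply(x, 1L, min)
  pmax <- apply(x, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (pmax - pmin) / (dmax - dmin)
  dig <- round((x - pmin) / scale + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(rec$subject_id, 80L),
    edf_pad(rec$condition, 80L),
    "01.01.00", "00.00.00",
    edf_pad(256L + ns * 256L, 8L),
    edf_pad("", 44L),
    edf_pad(1L, 8L),
    edf_num(nt / rec$fs, 8L),
    edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  pern <- function(vals, width)
    writeChar(paste(vapply(vals, edf_num, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  per(rec$channel_names, 16L)
  per(rep("", ns), 80L)
  per(rep("uV", ns), 8L)
  pern(pmin, 8L)
  pern(pmax, 8L)
  pern(rep(dmin, ns), 8L)
  pern(rep(dmax, ns), 8L)
  per(rep("", ns), 80L)
  per(rep(nt, ns), 8L)
  per(rep("", ns), 32L)
  writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8L)
  subject_id <- rd(80L)
  condition <- rd(80L)
  rd(8L); rd(8L)                       # start date / time
  rd(8L)                               # header bytes
  reserved <- rd(44L)                  # "EDF+C"/"EDF+D" for EDF+
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width),
                                character(1))
  labels <- rdv(16L)
  rdv(80L); rdv(8L)                    # transducer, unit
  pmin <- as.numeric(rdv(8L))
  pmax <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L))
  dmax <- as.numeric(rdv(8L))
  rdv(80L)                             # prefilter
  spr <- as.integer(rdv(8L))
  rdv(32L)
  keep <- labels != "EDF Annotations"
  out <- vector("list", ns)
  for (i in which(keep)) out[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                      endian = "little")
      if (keep[i]) out[[i]][[r]] <- vals
    }
  }
  spr_eeg <- unique(spr[keep])
  if (length(spr_eeg) != 1L)
    stop("EDF signals with mixed sampling rates are not supported")
  fs <- spr_eeg / rec_dur
  data <- do.call(rbind, lapply(which(keep), function(i) {
    dig <- unlist(out[[i]])
    pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  }))
  rownames(data) <- labels[keep]
  list(data = data, fs = fs, channel_names = labels[keep],
       condition = if (nzchar(condition)) condition else NULL,
       subject_id = if (nzchar(subject_id)) subject_id else NULL)
}
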