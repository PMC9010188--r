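# On-disk formats. Three families:
#  * delimited text (.csv): recordings (pinned fixture format), manifests,
#    questionnaires, reports, training logs;
#  * EDF (.edf): standard 16-bit multichannel biosignal interchange;
#  * a versioned RDS array container (.rds): tensors, feature images and
#    checkpoints, with bit-exact round-trips.
# Every serialized object embeds a format-version string and readers reject
# unknown versions rather than guessing.

RECORDING_FORMAT_VERSION <- "eegaffect-recording/1"
CONTAINER_VERSION <- "eegaffect-container/1"

#' Write a recording as delimited text
#'
#' Pinned fixture format: a comment line with the format version, sampling
#' rate and label; a header row listing the channel names in row order;
#' then one comma-separated row of samples per channel.
#'
#' @param rec a \code{raw_recording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s sample_rate=%.10g label=%s", RECORDING_FORMAT_VERSION,
                     rec$sample_rate,
                     if (is.null(rec$label)) "NA" else rec$label), con)
  writeLines(paste(rec$channel_names, collapse = ","), con)
  utils::write.table(rec$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' @param path file written by \code{write_recording_csv}.
#' @return A \code{raw_recording}.
#' @export
read_recording_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed recording file: fewer than 3 lines")
  hdr <- lines[[1]]
  if (!startsWith(hdr, paste0("# ", RECORDING_FORMAT_VERSION))) {
    stop("unknown recording format version in header: ", hdr)
  }
  rate <- as.numeric(sub(".*sample_rate=([0-9.eE+-]+).*", "\\1", hdr))
  lab <- sub(".*label=([^ ]+).*", "\\1", hdr)
  label <- if (lab == "NA") NULL else as.integer(lab)
  channels <- strsplit(lines[[2]], ",", fixed = TRUE)[[1]]
  rows <- lines[-(1:2)]
  if (length(rows) != length(channels)) {
    stop("channel-count mismatch: header declares ", length(channels),
         " channels but file has ", length(rows), " data rows")
  }
  parsed <- lapply(seq_along(rows), function(i) {
    cells <- strsplit(rows[[i]], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1]
      stop("non-numeric cell at data row ", i, ", column ", bad,
           " (channel ", channels[i], "): '", cells[bad], "'")
    }
    vals
  })
  ns <- unique(lengths(parsed))
  if (length(ns) != 1L) stop("ragged rows: sample counts ", paste(ns, collapse = ", "))
  data <- do.call(rbind, parsed)
  raw_recording(data, rate, channel_names = channels, label = label)
}

# ---- EDF ----------------------------------------------------------------

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  if (nchar(s) > width) stop("numeric field too wide for EDF header: ", x)
  edf_field(s, width)
}

#' Write a recording as an EDF file
#'
#' Standard EDF: 16-bit integers with per-signal physical scaling, 1 s data
#' records. Requires a whole number of seconds and an integer sampling
#' rate. The emotion label, if any, is carried in the header's reserved
#' field (\code{label=<l>}) since EDF has no native slot for it. EDF
#' quantizes to 16 bits, so round-trips are close but not bit-exact (use
#' the array container for bit-exact storage).
#'
#' @param rec a \code{raw_recording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sample_rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  n <- ncol(rec$data)
  if (n %% fs != 0) stop("EDF export requires a whole number of seconds")
  n_rec <- n %/% fs
  n_sig <- nrow(rec$data)
  pmin_ <- apply(rec$data, 1L, min)
  pmax_ <- apply(rec$data, 1L, max)
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_field("0", 8))
  wr(edf_field("X X X X", 80))                  # patient id
  wr(edf_field("Startdate X X X X", 80))        # recording id
  wr(edf_field("01.01.00", 8)); wr(edf_field("00.00.00", 8))
  wr(edf_field(256 + 256 * n_sig, 8))
  wr(edf_field(if (is.null(rec$label)) "" else paste0("label=", rec$label), 44))
  wr(edf_field(n_rec, 8)); wr(edf_field(1, 8)); wr(edf_field(n_sig, 4))
  for (ch in rec$channel_names) wr(edf_field(ch, 16))
  for (i in seq_len(n_sig)) wr(edf_field("", 80))        # transducer
  for (i in seq_len(n_sig)) wr(edf_field("uV", 8))
  for (i in seq_len(n_sig)) wr(edf_num(pmin_[i]))
  for (i in seq_len(n_sig)) wr(edf_num(pmax_[i]))
  for (i in seq_len(n_sig)) wr(edf_field(-32768L, 8))
  for (i in seq_len(n_sig)) wr(edf_field(32767L, 8))
  for (i in seq_len(n_sig)) wr(edf_field("", 80))        # prefilter
  for (i in seq_len(n_sig)) wr(edf_field(as.integer(fs), 8))
  for (i in seq_len(n_sig)) wr(edf_field("", 32))
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(n_sig)) {
      dig <- as.integer(round((rec$data[s, idx] - pmin_[s]) * scale[s]) - 32768)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' @param path an EDF file; all signals must share one sampling rate.
#' @return A \code{raw_recording} (label recovered from the reserved header
#'   field when present).
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  ver <- trimws(rd(8))
  if (ver != "0") stop("not an EDF file (version field '", ver, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  reserved <- trimws(rd(44))
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  n_sig <- as.integer(trimws(rd(4)))
  labels <- trimws(vapply(seq_len(n_sig), function(i) rd(16), ""))
  for (i in seq_len(n_sig)) rd(80)
  for (i in seq_len(n_sig)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) trimws(rd(8)), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) trimws(rd(8)), ""))
  dmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) trimws(rd(8)), ""))
  dmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) trimws(rd(8)), ""))
  for (i in seq_len(n_sig)) rd(80)
  spr <- as.integer(vapply(seq_len(n_sig), function(i) trimws(rd(8)), ""))
  for (i in seq_len(n_sig)) rd(32)
  if (length(unique(spr)) != 1L) stop("EDF signals with mixed sampling rates are not supported")
  fs <- spr[1] / dur
  data <- matrix(NA_real_, n_sig, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, endian = "little")
      phys <- pmin_[s] + (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  lab <- if (grepl("label=", reserved)) {
    as.integer(sub(".*label=(-?[01]).*", "\\1", reserved))
  }
  raw_recording(data, fs, channel_names = labels, label = lab)
}

# ---- versioned RDS array container --------------------------------------

#' Save / load objects through the versioned array container
#'
#' Tensors, feature images and checkpoints are stored as an RDS-serialized
#' list carrying a container version string and the object's class; loading
#' validates both. Round-trips are bit-exact.
#'
#' @param x object to store (\code{de_tensor}, \code{feature_image},
#'   checkpoint list, ...).
#' @param path file path (.rds).
#' @return \code{path} invisibly for save; the object for load.
#' @export
save_container <- function(x, path) {
  saveRDS(list(version = CONTAINER_VERSION, class = class(x)[1], payload = x),
          path)
  invisible(path)
}

#' @rdname save_container
#' @param expected_class optional class name the payload must have.
#' @export
load_container <- function(path, expected_class = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$version, CONTAINER_VERSION)) {
    stop("unknown container version; refusing to guess (expected ",
         CONTAINER_VERSION, ")")
  }
  if (!is.null(expected_class) && !identical(obj$class, expected_class)) {
    stop("container holds a '", obj$class, "', expected '", expected_class, "'")
  }
  obj$payload
}

#' Write / read a model checkpoint
#'
#' A checkpoint embeds the parameters, architecture config, training config,
#' seed, epoch and that epoch's held-out accuracy, so a run is re-creatable
#' from its artifacts.
#'
#' @param path .rds path.
#' @param net a \code{resnet_classifier}.
#' @param config a \code{training_config} (or NULL).
#' @param epoch,accuracy epoch number and its test accuracy (or NA).
#' @return \code{path} invisibly for write; a \code{resnet_classifier}
#'   (with \code{$checkpoint} metadata) for read.
#' @export
write_checkpoint <- function(path, net, config = NULL, epoch = NA,
                             accuracy = NA) {
  stopifnot(inherits(net, "resnet_classifier"))
  ck <- structure(list(net = net, training_config = config, epoch = epoch,
                       accuracy = accuracy), class = "model_checkpoint")
  save_container(ck, path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- load_container(path, "model_checkpoint")
  net <- ck$net
  net$checkpoint <- list(epoch = ck$epoch, accuracy = ck$accuracy,
                         training_config = ck$training_config)
  net
}

# ---- manifests and logs -------------------------------------------------

#' Write / read / validate a dataset manifest
#'
#' A manifest maps recording files to (subject, session, trial, label).
#' Labels must lie in \{-1, 0, +1\} and (subject, session, trial) must be
#' unique.
#'
#' @param manifest data.frame with columns file, subject, session, trial,
#'   label.
#' @param path .csv path.
#' @return \code{path} invisibly for write; the validated data.frame for
#'   read.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  validate_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_manifest <- function(manifest) {
  need <- c("file", "subject", "session", "trial", "label")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!manifest$label %in% c(-1, 0, 1))) {
    stop("manifest labels must be in {-1, 0, +1}")
  }
  key <- paste(manifest$subject, manifest$session, manifest$trial)
  if (anyDuplicated(key)) stop("duplicate (subject, session, trial) in manifest")
  manifest
}

#' Write a training log as delimited text
#'
#' One row per epoch: epoch, train_loss, test_accuracy (the held-out
#' accuracy curve).
#'
#' @param records the \code{records} data.frame from
#'   \code{train_classifier}.
#' @param path .csv path.
#' @return \code{path}, invisibly.
#' @export
write_training_log <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# ---- generic recording reader/writer ------------------------------------

#' Read / write a recording, dispatching on format
#'
#' Formats: \code{"edf"}, \code{"delimited"} (.csv), \code{"container"}
#' (.rds); \code{"auto"} dispatches on the file extension.
#'
#' @param path file path.
#' @param format one of "auto", "edf", "delimited", "container".
#' @return A \code{raw_recording}.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited",
                                            "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "delimited", rds = "container",
                     stop("cannot infer format from extension of ", path))
  }
  switch(format,
         edf = read_recording_edf(path),
         delimited = read_recording_csv(path),
         container = {
           rec <- load_container(path, "raw_recording")
           assert_pipeline_recording(rec, require_62 = FALSE)
         })
}

#' @rdname read_recording
#' @param rec a \code{raw_recording}.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "delimited",
                                                  "container")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "delimited", rds = "container",
                     stop("cannot infer format from extension of ", path))
  }
  switch(format,
         edf = write_recording_edf(rec, path),
         delimited = write_recording_csv(rec, path),
         container = save_container(rec, path))
  invisible(path)
}

# ---- SEED-style session adapter -----------------------------------------

#' Read a SEED-style preprocessed session
#'
#' Adapter for the reference corpus layout: one session file holding 15
#' channel x time trial arrays plus a 15-entry label vector in \{-1, 0,
#' +1\}, preprocessed at 200 Hz. Two storages are accepted: an RDS file
#' containing \code{list(trials = <list of matrices>, labels = <vector>)},
#' or a directory with \code{trial_NN.csv} recordings and a
#' \code{labels.csv} (column \code{label}). Converting original MATLAB
#' session files into either layout is a one-line external step; the
#' adapter validates shape and labels rather than array names, and is
#' never required by the test pipeline.
#'
#' @param path .rds file or directory.
#' @param relaxed allow other trial counts than 15 (test mode).
#' @param sample_rate assumed rate (default 200 Hz).
#' @return List of labeled \code{raw_recording}s.
#' @export
read_seed_session <- function(path, relaxed = FALSE, sample_rate = 200) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^trial_\\d+\\.csv$",
                             full.names = TRUE))
    labfile <- file.path(path, "labels.csv")
    if (!file.exists(labfile)) stop("missing label vector (labels.csv) in ", path)
    labels <- utils::read.csv(labfile)$label
    trials <- lapply(files, function(f) read_recording_csv(f)$data)
  } else {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$trials) || is.null(obj$labels)) {
      stop("SEED-style session must contain `trials` and a `labels` vector")
    }
    trials <- obj$trials
    labels <- obj$labels
  }
  if (length(trials) != length(labels)) {
    stop("trial count (", length(trials), ") does not match label count (",
         length(labels), ")")
  }
  if (!relaxed && length(trials) != 15L) {
    stop("a session must contain exactly 15 trials (got ", length(trials),
         "); use relaxed = TRUE for test fixtures")
  }
  if (any(!labels %in% c(-1, 0, 1))) {
    stop("session labels must be in {-1, 0, +1}")
  }
  mapply(function(m, l) raw_recording(as.matrix(m), sample_rate, label = l),
         trials, labels, SIMPLIFY = FALSE)
}
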