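#' Movement label set
#'
#' The four lower-limb movement classes and their integer codes. Codes are
#' 0-based so they can be used directly as class indices in the network head
#' and in class-weight computations.
#'
#' @return Named integer vector mapping label names to codes 0..3.
#' @export
movement_labels <- function() {
  c(SIT = 0L, STAND = 1L, WALK = 2L, UPSTAIRS = 3L)
}

label_code <- function(label, labels = movement_labels()) {
  if (is.numeric(label)) {
    code <- as.integer(label)
    if (!code %in% labels) stop("unknown movement code: ", label)
    return(code)
  }
  if (!label %in% names(labels)) {
    stop("unknown movement label '", label, "'; expected one of: ",
         paste(names(labels), collapse = ", "))
  }
  unname(labels[[label]])
}

label_name <- function(code, labels = movement_labels()) {
  names(labels)[match(as.integer(code), labels)]
}

#' Construct a surface-EMG recording
#'
#' A recording is one subject/trial multichannel sEMG time series. Samples are
#' stored channels-by-time (`C x T`). Channels `1..C/2` are the left-side
#' muscles and channel `k + C/2` is the right-side mirror of channel `k`; this
#' pairing is what the symmetric weight tying in the network relies on.
#' Annotations are named half-open sample intervals `[start, end)`, 1-based on
#' start (so `[1, T+1)` spans the whole trial).
#'
#' @param samples numeric matrix, channels x time.
#' @param rate_hz sampling rate in Hz (default 1500).
#' @param channel_names optional character vector of length `C`.
#' @param subject_id,trial_id identifier strings.
#' @param label movement label name or code (see [movement_labels()]).
#' @param annotations optional named list of `c(start, end)` sample intervals.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, rate_hz = 1500, channel_names = NULL,
                          subject_id = "S1", trial_id = "T1",
                          label = "SIT", annotations = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples), arr.ind = TRUE)[1, ]
    stop("non-finite sample at channel ", bad[1], ", sample ", bad[2])
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  C <- nrow(samples)
  if (C < 2) stop("need at least 2 channels, got ", C)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  if (length(channel_names) != C) stop("channel_names must have length ", C)
  Tn <- ncol(samples)
  if (!is.null(annotations)) {
    if (is.null(names(annotations)) || any(names(annotations) == "")) {
      stop("annotations must be a named list")
    }
    for (nm in names(annotations)) {
      iv <- annotations[[nm]]
      if (length(iv) != 2 || iv[2] <= iv[1]) {
        stop("annotation '", nm, "' must be a non-empty interval c(start, end)")
      }
      if (iv[1] < 1 || iv[2] > Tn + 1) {
        stop("annotation '", nm, "' [", iv[1], ", ", iv[2],
             ") outside the recording (T = ", Tn, ")")
      }
      annotations[[nm]] <- as.integer(iv)
    }
  }
  structure(
    list(samples = samples, rate_hz = rate_hz, channel_names = channel_names,
         subject_id = subject_id, trial_id = trial_id,
         label = label_name(label_code(label)), annotations = annotations),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s/%s  %s  %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$label,
              nrow(x$samples), ncol(x$samples), x$rate_hz))
  if (!is.null(x$annotations)) {
    for (nm in names(x$annotations)) {
      iv <- x$annotations[[nm]]
      cat(sprintf("  annotation %s: [%d, %d)\n", nm, iv[1], iv[2]))
    }
  }
  invisible(x)
}

n_channels <- function(rec) nrow(rec$samples)
n_samples <- function(rec) ncol(rec$samples)

#' Write a recording to CSV + JSON sidecar
#'
#' The CSV holds the numeric matrix with one row per time sample and one
#' column per channel (header = channel names). Values are printed with 17
#' significant digits so a write/read round trip reproduces doubles exactly.
#' The sidecar `<path without extension>.json` carries rate, channel names,
#' identifiers, label, and annotations.
#'
#' @param rec an [emg_recording()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  m <- t(rec$samples)                       # rows = samples on disk
  header <- paste(rec$channel_names, collapse = ",")
  body <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(c(header, body), path)
  meta <- list(rate_hz = rec$rate_hz, channel_names = rec$channel_names,
               subject_id = rec$subject_id, trial_id = rec$trial_id,
               label = rec$label, annotations = rec$annotations)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a recording from CSV + JSON sidecar
#'
#' @param path CSV file path (sidecar found next to it).
#' @param meta optional list overriding/supplying sidecar fields
#'   (`rate_hz`, `label`, `subject_id`, `trial_id`, `channel_names`,
#'   `annotations`) when no sidecar exists.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  side <- sidecar_path(path)
  info <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (!is.null(meta)) info[names(meta)] <- meta
  if (is.null(info$rate_hz)) {
    stop("no sampling rate for ", path, ": provide a JSON sidecar or meta$rate_hz")
  }
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) m <- matrix(m, 1, ncol(df), dimnames = list(NULL, names(df)))
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-numeric or non-finite cell in ", path,
         " at data row ", bad[1], ", column ", bad[2])
  }
  ann <- info$annotations
  if (!is.null(ann)) ann <- lapply(ann, function(iv) as.integer(unlist(iv)))
  emg_recording(t(m), rate_hz = info$rate_hz,
                channel_names = if (!is.null(info$channel_names)) info$channel_names else colnames(m),
                subject_id = if (!is.null(info$subject_id)) info$subject_id else "S1",
                trial_id = if (!is.null(info$trial_id)) info$trial_id else
                  tools::file_path_sans_ext(basename(path)),
                label = if (!is.null(info$label)) info$label else "SIT",
                annotations = ann)
}

#' Write a dataset manifest
#'
#' The manifest is a single JSON file listing, per subject, the recording
#' files with their trial identifiers and labels.
#'
#' @param entries data frame with columns `subject_id`, `path`, `trial_id`,
#'   `label`.
#' @param path output JSON path.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(all(c("subject_id", "path", "trial_id", "label") %in% names(entries)))
  jsonlite::write_json(list(entries = entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path JSON manifest path.
#' @return Data frame of entries.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- obj$entries
  if (is.null(entries) || NROW(entries) == 0) {
    return(data.frame(subject_id = character(), path = character(),
                      trial_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  as.data.frame(entries, stringsAsFactors = FALSE)
}

#' Load all recordings listed in a manifest, grouped by subject
#'
#' Recording paths are resolved relative to the manifest's directory unless
#' absolute. Output is deterministically ordered (subject, then trial) and is
#' therefore stable under permutation of manifest rows.
#'
#' @param manifest path to a manifest JSON, or the entries data frame.
#' @param base_dir directory against which relative paths resolve.
#' @return Named list (one element per subject) of lists of recordings.
#' @export
load_dataset <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (nrow(manifest) == 0) {
    warning("empty manifest: no recordings to load")
    return(list())
  }
  manifest <- manifest[order(manifest$subject_id, manifest$trial_id), , drop = FALSE]
  dup <- duplicated(manifest[, c("subject_id", "trial_id")])
  if (any(dup)) {
    stop("duplicate trial_id within subject: ",
         paste(unique(manifest$trial_id[dup]), collapse = ", "))
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path),
                  manifest$path, file.path(base_dir, manifest$path))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("manifest references missing file(s): ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- read_recording(paths[i],
                          meta = list(subject_id = manifest$subject_id[i],
                                      trial_id = manifest$trial_id[i],
                                      label = manifest$label[i]))
    out[[rec$subject_id]] <- c(out[[rec$subject_id]], list(rec))
  }
  out
}

#' Construct a window set
#'
#' Segmented analysis windows plus their labels and provenance. `windows` is
#' an `N x C x L` array; `window_order` is each window's temporal index within
#' its source trial (strictly increasing per trial).
#'
#' @param windows numeric array `[N, C, L]`.
#' @param labels integer class codes, length `N`.
#' @param subject_ids,trial_ids character vectors, length `N`.
#' @param window_order integer vector, length `N`.
#' @param meta provenance list (filter settings, window length, step, ...).
#' @param check_order verify that `window_order` is strictly increasing within
#'   each trial (disable for deliberately permuted subsets).
#' @return An object of class `emg_windows`.
#' @export
window_set <- function(windows, labels, subject_ids, trial_ids,
                       window_order, meta = list(), check_order = TRUE) {
  stopifnot(length(dim(windows)) == 3)
  n <- dim(windows)[1]
  stopifnot(length(labels) == n, length(subject_ids) == n,
            length(trial_ids) == n, length(window_order) == n)
  if (check_order) {
    for (tr in unique(trial_ids)) {
      ord <- window_order[trial_ids == tr]
      if (any(diff(ord) <= 0)) stop("window_order not increasing within trial ", tr)
    }
  }
  structure(list(windows = windows, labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 trial_ids = as.character(trial_ids),
                 window_order = as.integer(window_order), meta = meta),
            class = "emg_windows")
}

#' @export
print.emg_windows <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<emg_windows> %d windows of %d ch x %d samples, %d subject(s), %d trial(s)\n",
              d[1], d[2], d[3], length(unique(x$subject_ids)),
              length(unique(x$trial_ids))))
  print(table(label = label_name(x$labels)))
  invisible(x)
}

#' Concatenate window sets
#'
#' @param ws_list list of [window_set()] objects with matching `C` and `L`.
#' @return A single `emg_windows` object.
#' @export
bind_windows <- function(ws_list) {
  ws_list <- Filter(function(w) dim(w$windows)[1] > 0, ws_list)
  if (length(ws_list) == 0) stop("no windows to bind")
  dims <- vapply(ws_list, function(w) dim(w$windows)[2:3], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("window sets have inconsistent channel count or length")
  }
  n <- sum(vapply(ws_list, function(w) dim(w$windows)[1], integer(1)))
  out <- array(0, c(n, dims[1, 1], dims[2, 1]))
  at <- 1
  for (w in ws_list) {
    k <- dim(w$windows)[1]
    out[at:(at + k - 1), , ] <- w$windows
    at <- at + k
  }
  window_set(out,
             unlist(lapply(ws_list, `[[`, "labels")),
             unlist(lapply(ws_list, `[[`, "subject_ids")),
             unlist(lapply(ws_list, `[[`, "trial_ids")),
             unlist(lapply(ws_list, `[[`, "window_order")),
             meta = ws_list[[1]]$meta)
}

#' Subset a window set
#'
#' @param ws an `emg_windows` object.
#' @param idx integer or logical index over windows.
#' @return The subset as an `emg_windows` object.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$subject_ids[idx], ws$trial_ids[idx], ws$window_order[idx],
             meta = ws$meta, check_order = FALSE)
}
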