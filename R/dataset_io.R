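#' Construct a single-subject waveform record
#'
#' A `waveform_record` holds one virtual subject's multichannel hemodynamic
#' signals: pressure (mmHg) at the brachial, radial and abdominal-aortic
#' sites plus the abdominal-aortic luminal area, together with the sampling
#' frequency and the duration of one cardiac cycle.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param fs Sampling frequency in Hz (positive).
#' @param p_brachial,p_radial,p_abdominal Numeric pressure series in mmHg.
#' @param a_abdominal Numeric luminal-area series, in m^2 (`units_area =
#'   "m2"`, as distributed) or cm^2 (`"cm2"`, after [convert_area_to_cm2()]).
#' @param pulse_period Duration of one cardiac cycle in seconds.
#' @param units_area Either `"m2"` or `"cm2"`.
#' @return An object of class `waveform_record`.
#' @seealso [cohort()], [load_database()], [convert_area_to_cm2()]
#' @export
waveform_record <- function(subject_id, fs, p_brachial, p_radial,
                            p_abdominal, a_abdominal, pulse_period,
                            units_area = c("m2", "cm2")) {
  units_area <- match.arg(units_area)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.numeric(fs), length(fs) == 1L,
            is.numeric(pulse_period), length(pulse_period) == 1L)
  if (fs <= 0) stop("`fs` must be positive")
  if (pulse_period <= 0) stop("`pulse_period` must be positive")
  n <- length(p_brachial)
  if (length(p_radial) != n || length(p_abdominal) != n ||
      length(a_abdominal) != n)
    stop("all four signal series must have equal length")
  if (round(pulse_period * fs) > n)
    stop("`pulse_period` longer than the recorded series")
  if (any(!is.finite(p_brachial)) || any(!is.finite(p_radial)) ||
      any(!is.finite(p_abdominal)) || any(!is.finite(a_abdominal)))
    stop("signals must be finite")
  if (any(p_brachial <= 0) || any(p_radial <= 0) || any(p_abdominal <= 0))
    stop("pressure values must be positive")
  if (any(a_abdominal <= 0)) stop("area values must be positive")
  structure(
    list(subject_id = subject_id, fs = fs,
         p_brachial = as.numeric(p_brachial),
         p_radial = as.numeric(p_radial),
         p_abdominal = as.numeric(p_abdominal),
         a_abdominal = as.numeric(a_abdominal),
         pulse_period = pulse_period, units_area = units_area),
    class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s: %d samples @ %g Hz, pulse %.4g s, area in %s\n",
              x$subject_id, length(x$p_brachial), x$fs, x$pulse_period,
              x$units_area))
  invisible(x)
}

#' Construct a cohort of waveform records
#'
#' @param records List of [waveform_record()] objects with unique subject ids.
#' @param role One of `"full"`, `"train"`, `"test"`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(records, role = c("full", "train", "test")) {
  role <- match.arg(role)
  stopifnot(is.list(records))
  if (!all(vapply(records, inherits, logical(1), "waveform_record")))
    stop("`records` must be a list of waveform_record objects")
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("subject_ids must be unique within a cohort")
  structure(list(records = records, role = role), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> role=%s, %d subjects\n", x$role, length(x$records)))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$records)

cohort_ids <- function(x) vapply(x$records, `[[`, character(1), "subject_id")

# Canonical channel names used throughout the package.
.channels <- c("p_brachial", "p_radial", "p_abdominal", "a_abdominal")

#' Read a processed waveform archive into a cohort
#'
#' The archive layout is a directory with a `manifest.json` listing one entry
#' per subject (`subject_id`, `fs`, `pulse_period`, `units_area`, `file`) and
#' one CSV per subject with a header row of channel names and one sample per
#' row. `site_map` maps the four canonical channels to the column names used
#' in the archive, so deposits exported with different channel labels can be
#' read after a thin conversion.
#'
#' When `pulse_period` is absent from the manifest it is estimated from the
#' abdominal pressure channel as the spacing of the first two detected pulse
#' feet (see [detect_first_pulse()]).
#'
#' @param path Directory containing `manifest.json` and the per-subject CSVs.
#' @param site_map Named character vector mapping canonical channel names
#'   (`p_brachial`, `p_radial`, `p_abdominal`, `a_abdominal`) to archive
#'   column names.
#' @return A [cohort()] with `role = "full"`.
#' @export
load_database <- function(path, site_map = setNames(.channels, .channels)) {
  if (!dir.exists(path)) stop("archive path does not exist: ", path)
  missing_map <- setdiff(.channels, names(site_map))
  if (length(missing_map))
    stop("`site_map` must name all four channels; missing: ",
         paste(missing_map, collapse = ", "))
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop("not a waveform archive (no manifest.json): ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (is.null(mf$subjects)) stop("malformed manifest: no `subjects` entry")
  records <- lapply(mf$subjects, function(s) {
    f <- file.path(path, s$file)
    if (!file.exists(f)) stop("missing subject file: ", f)
    dt <- data.table::fread(f, colClasses = "numeric", showProgress = FALSE)
    for (ch in .channels) {
      if (!site_map[[ch]] %in% names(dt))
        stop("channel not found in ", s$file, ": ", ch,
             " (expected column '", site_map[[ch]], "')")
    }
    fs <- as.numeric(s$fs)
    pp <- if (!is.null(s$pulse_period)) as.numeric(s$pulse_period) else {
      w <- detect_first_pulse(dt[[site_map[["p_abdominal"]]]], fs)
      (w$end - w$start) / fs
    }
    waveform_record(
      subject_id = as.character(s$subject_id), fs = fs,
      p_brachial = dt[[site_map[["p_brachial"]]]],
      p_radial = dt[[site_map[["p_radial"]]]],
      p_abdominal = dt[[site_map[["p_abdominal"]]]],
      a_abdominal = dt[[site_map[["a_abdominal"]]]],
      pulse_period = pp,
      units_area = if (!is.null(s$units_area)) s$units_area else "m2")
  })
  cohort(records, role = "full")
}

#' Write a cohort to the processed-archive format
#'
#' Signals are serialized with 17 significant digits so that a write/read
#' round trip reproduces every sample bit-exactly.
#'
#' @param x A [cohort()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_archive <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  subjects <- lapply(x$records, function(r) {
    file <- paste0(r$subject_id, ".csv")
    cols <- lapply(.channels, function(ch) sprintf("%.17g", r[[ch]]))
    names(cols) <- .channels
    data.table::fwrite(data.table::as.data.table(cols),
                       file.path(path, file), quote = FALSE)
    list(subject_id = r$subject_id, fs = r$fs, pulse_period = r$pulse_period,
         units_area = r$units_area, n_samples = length(r$p_brachial),
         file = file)
  })
  manifest <- list(format = "cyclepw-archive", version = 1L,
                   role = x$role, subjects = subjects)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Split a cohort into train and test subsets
#'
#' Subjects are assigned at random (by subject, unstratified); the training
#' set receives `round(n * (1 - test_fraction))` subjects and the test set
#' the remainder, so the two parts are disjoint and their union is the input.
#'
#' @param x A [cohort()].
#' @param test_fraction Proportion of subjects assigned to the test set,
#'   strictly between 0 and 1 (default 0.15).
#' @param seed Integer seed making the split deterministic.
#' @return A list with elements `train` and `test`, both [cohort()]s.
#' @export
split_cohort <- function(x, test_fraction = 0.15, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("`test_fraction` must be strictly between 0 and 1")
  n <- length(x$records)
  if (n < 2L) stop("cannot split a cohort with fewer than 2 records")
  n_train <- round(n * (1 - test_fraction))
  perm <- with_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[-seq_len(n_train)])
  list(train = cohort(x$records[idx_train], role = "train"),
       test = cohort(x$records[idx_test], role = "test"))
}
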