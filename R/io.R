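#' Write a recording to disk
#'
#' The container is plain CSV — one column per channel, header row of channel
#' ids, one sample per line, `%.17g` formatting so that doubles round-trip
#' bitwise — plus a JSON metadata sidecar `<path>.meta.json` holding `fs`,
#' `channel_ids` and any free-form `meta`.
#'
#' @param rec a [recording()].
#' @param path destination CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_ids, collapse = ","), con)
  # one sample (time point) per line, full precision
  lines <- apply(rec$data, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ","))
  writeLines(lines, con)
  jsonlite::write_json(
    list(fs = rec$fs, channel_ids = rec$channel_ids, meta = rec$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a recording from disk
#'
#' Reads the CSV container written by [write_recording()] together with its
#' JSON metadata sidecar. A missing sidecar, or a sidecar without an `fs`
#' entry, is a format error; non-finite samples are a data error.
#'
#' @param path CSV path (sidecar `<path>.meta.json` must exist).
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("format error: missing metadata sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop("format error: sidecar lacks sampling frequency `fs`")
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "numeric")
  data <- t(as.matrix(tab))   # file is samples x channels
  if (!all(is.finite(data))) stop("data error: non-finite samples in ", path)
  recording(data, fs = meta$fs,
            channel_ids = if (!is.null(meta$channel_ids)) meta$channel_ids
                          else colnames(tab),
            meta = if (is.null(meta$meta)) list() else as.list(meta$meta))
}

#' Write state-interval labels as JSON
#' @param intervals a [state_intervals()] object.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(intervals, path) {
  stopifnot(inherits(intervals, "state_intervals"))
  jsonlite::write_json(
    list(intervals = as.data.frame(unclass(intervals))),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read state-interval labels from JSON
#' @param path JSON path written by [write_labels()].
#' @return a [state_intervals()] object.
#' @export
read_labels <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)$intervals
  state_intervals(x$label, x$start_s, x$end_s, x$trim_s)
}

#' Feature-set container
#'
#' A labeled set of fixed-length feature vectors (DS or FFT) drawn from the
#' state intervals of one recording, plus the provenance needed to reproduce
#' it.
#'
#' @param vectors numeric matrix, one row per vector.
#' @param labels character/factor of per-vector states
#'   (`"awake"`/`"anesthetized"`).
#' @param window_s segment length Delta (seconds) each vector summarizes.
#' @param source `"ds"` or `"fft"`.
#' @param surrogate `"none"`, `"phase"`, `"stagger"` or `"global_stagger"`.
#' @param seed integer seed used when building the set.
#' @param extra optional named list of additional provenance.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(vectors, labels, window_s, source = c("ds", "fft"),
                        surrogate = c("none", "phase", "stagger",
                                      "global_stagger"),
                        seed = NA_integer_, extra = list()) {
  source <- match.arg(source)
  surrogate <- match.arg(surrogate)
  vectors <- as.matrix(vectors)
  labels <- factor(as.character(labels), levels = c("awake", "anesthetized"))
  if (nrow(vectors) < 1L) stop("feature set must contain at least one vector")
  if (length(labels) != nrow(vectors))
    stop("`labels` length must match the number of vectors")
  if (anyNA(labels)) stop("labels must be 'awake' or 'anesthetized'")
  structure(list(vectors = unname(vectors), labels = labels,
                 window_s = window_s, source = source, surrogate = surrogate,
                 seed = seed, extra = extra),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d x %d (%s, surrogate=%s, Delta=%g s)\n",
              nrow(x$vectors), ncol(x$vectors), x$source, x$surrogate,
              x$window_s))
  print(table(x$labels))
  invisible(x)
}

#' Write a feature set as CSV plus JSON header sidecar
#'
#' One row per vector, trailing `label` column; Delta, source, surrogate and
#' seed go to `<path>.meta.json`.
#'
#' @param fset a [feature_set()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fset, path) {
  stopifnot(inherits(fset, "feature_set"))
  df <- as.data.frame(fset$vectors)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$label <- as.character(fset$labels)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(window_s = fset$window_s, source = fset$source,
         surrogate = fset$surrogate, seed = fset$seed),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature set written by [write_feature_set()]
#' @param path CSV path.
#' @return a [feature_set()].
#' @export
read_feature_set <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path, header = TRUE)
  lab <- df$label
  df$label <- NULL
  feature_set(as.matrix(df), lab, window_s = meta$window_s,
              source = meta$source, surrogate = meta$surrogate,
              seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report` from [evaluate()].
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read an evaluation report written by [write_eval_report()]
#' @param path JSON path.
#' @return an `eval_report`.
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$roc <- as.data.frame(x$roc)
  structure(x, class = "eval_report")
}
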