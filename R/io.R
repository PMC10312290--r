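#' Parcellated BOLD container
#'
#' Wraps a frames-by-parcels signal matrix together with the repetition time
#' and the parcel atlas it was extracted with.
#'
#' @param data Numeric matrix, frames x parcels, finite, at least 2 frames.
#' @param tr Repetition time in seconds.
#' @param atlas A [parcel_atlas()] whose size matches `ncol(data)`.
#' @return An object of class `cc_bold` (list with `data`, `tr`, `atlas`).
#' @export
parcellated_bold <- function(data, tr, atlas) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_invalid("data must be a numeric matrix")
  if (nrow(data) < 2) stop_invalid("at least 2 frames are required")
  if (!all(is.finite(data))) stop_invalid("BOLD data must be finite")
  check_scalar_number(tr, "tr", positive = TRUE)
  validate_atlas(atlas)
  if (ncol(data) != nrow(atlas))
    stop_invalid("parcel count (", ncol(data), ") does not match atlas size (",
                 nrow(atlas), ")")
  colnames(data) <- atlas$name
  structure(list(data = data, tr = tr, atlas = atlas), class = "cc_bold")
}

#' @export
print.cc_bold <- function(x, ...) {
  cat(sprintf("<cc_bold> %d frames x %d parcels, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

# ---- delimited text I/O -----------------------------------------------------
# All numeric output is written with 17 significant digits so that
# read(write(x)) round-trips doubles exactly.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1) stop_format("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != n[1]))
    stop_format("ragged rows in ", path, ": row ", which(n != n[1])[1],
                " has ", n[n != n[1]][1], " fields, expected ", n[1])
  fields
}

parse_numeric_cells <- function(fields, path, skip_cols = integer(0)) {
  header <- fields[[1]]
  body <- fields[-1]
  ncol <- length(header)
  out <- matrix(NA_real_, nrow = length(body), ncol = ncol)
  for (j in setdiff(seq_len(ncol), skip_cols)) {
    cells <- vapply(body, `[[`, "", j)
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !(cells %in% c("NA", "")))
    if (length(bad))
      stop_format("non-numeric cell in ", path, " at row ", bad[1],
                  ", column ", j, " ('", header[j], "'): '", cells[bad[1]], "'")
    out[, j] <- vals
  }
  colnames(out) <- header
  out
}

#' Write / read a parcellated BOLD time series
#'
#' Tab-delimited, one header row of parcel names, one row per frame, full
#' double precision. The repetition time is not stored in the file and must be
#' supplied on read.
#'
#' @param bold A `cc_bold` object.
#' @param path File path.
#' @param tr Repetition time (seconds) of the stored series.
#' @param atlas Atlas the parcel columns must match.
#' @return `read_timeseries` returns a `cc_bold`; `write_timeseries` returns
#'   `path` invisibly.
#' @export
write_timeseries <- function(bold, path) {
  stopifnot(inherits(bold, "cc_bold"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(bold$data), collapse = "\t"), con)
  writeLines(apply(bold$data, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
             con)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, tr, atlas) {
  fields <- read_tsv_table(path)
  mat <- parse_numeric_cells(fields, path)
  header <- colnames(mat)
  if (length(header) != nrow(atlas))
    stop_format("header of ", path, " names ", length(header),
                " parcels but atlas has ", nrow(atlas))
  mism <- which(header != atlas$name)
  if (length(mism))
    stop_format("parcel name mismatch in ", path, " at column ", mism[1],
                ": '", header[mism[1]], "' vs atlas '", atlas$name[mism[1]], "'")
  parcellated_bold(mat, tr = tr, atlas = atlas)
}

#' Write / read a task event table
#'
#' BIDS-events-style tab-delimited table with columns `onset`, `duration`,
#' `trial_type`, `rms_error`, `calc_correct`. Missing behavioural outcomes are
#' stored as `NA`.
#'
#' @param events Data frame of events.
#' @param path File path.
#' @return `read_events` returns the events data.frame.
#' @export
write_events <- function(events, path) {
  cols <- c("onset", "duration", "trial_type", "rms_error", "calc_correct")
  missing_cols <- setdiff(cols, names(events))
  if (length(missing_cols))
    stop_invalid("events table lacks column(s): ",
                 paste(missing_cols, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  rows <- paste(fmt_num(events$onset), fmt_num(events$duration),
                events$trial_type, fmt_num(events$rms_error),
                ifelse(is.na(events$calc_correct), "NA",
                       ifelse(events$calc_correct, "1", "0")),
                sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  fields <- read_tsv_table(path)
  header <- fields[[1]]
  expect <- c("onset", "duration", "trial_type", "rms_error", "calc_correct")
  if (!identical(header, expect))
    stop_format("events header of ", path, " must be: ",
                paste(expect, collapse = ", "))
  mat <- parse_numeric_cells(fields, path, skip_cols = 3L)
  body <- fields[-1]
  data.frame(
    onset = mat[, 1], duration = mat[, 2],
    trial_type = vapply(body, `[[`, "", 3L),
    rms_error = mat[, 4],
    calc_correct = ifelse(is.na(mat[, 5]), NA, mat[, 5] != 0),
    stringsAsFactors = FALSE
  )
}

#' Motion trace container and I/O
#'
#' Six rigid-body realignment parameters per frame: three translations (mm)
#' and three rotations (radians), tab-delimited with a header row.
#'
#' @param translations Frames x 3 matrix (mm).
#' @param rotations Frames x 3 matrix (radians).
#' @param motion A `cc_motion` object.
#' @param path File path.
#' @return `motion_trace`/`read_motion` return a `cc_motion` object.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations); rotations <- as.matrix(rotations)
  if (ncol(translations) != 3 || ncol(rotations) != 3)
    stop_invalid("translations and rotations must each have 3 columns")
  if (nrow(translations) != nrow(rotations))
    stop_invalid("translations and rotations must cover the same frames")
  if (!all(is.finite(translations)) || !all(is.finite(rotations)))
    stop_invalid("motion parameters must be finite")
  colnames(translations) <- c("trans_x", "trans_y", "trans_z")
  colnames(rotations) <- c("rot_x", "rot_y", "rot_z")
  structure(list(translations = translations, rotations = rotations),
            class = "cc_motion")
}

#' @rdname motion_trace
#' @export
write_motion <- function(motion, path) {
  stopifnot(inherits(motion, "cc_motion"))
  m <- cbind(motion$translations, motion$rotations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  writeLines(apply(m, 1L, function(r) paste(fmt_num(r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname motion_trace
#' @export
read_motion <- function(path) {
  fields <- read_tsv_table(path)
  mat <- parse_numeric_cells(fields, path)
  if (ncol(mat) != 6)
    stop_format("motion file ", path, " must have 6 columns, found ", ncol(mat))
  motion_trace(mat[, 1:3, drop = FALSE], mat[, 4:6, drop = FALSE])
}

#' Write / read a labelled numeric matrix
#'
#' Tab-delimited with row and column parcel names; used for structural
#' connectomes, connectivity matrices and summary grids.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_matrix` returns the labelled matrix.
#' @export
write_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_invalid("matrix must carry row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("row", colnames(mat)), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t"), ""), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  fields <- read_tsv_table(path)
  mat <- parse_numeric_cells(fields, path, skip_cols = 1L)
  rn <- vapply(fields[-1], `[[`, "", 1L)
  out <- mat[, -1, drop = FALSE]
  rownames(out) <- rn
  out
}
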