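#' Construct a realignment-parameter series
#'
#' Canonical container for per-frame rigid-body head position: three
#' translations (mm) followed by three rotations (radians), regardless of
#' the file dialect the values came from.
#'
#' @param params Numeric matrix, frames x 6, canonical column order
#'   `dx, dy, dz, alpha, beta, gamma` (translations mm, rotations radians).
#' @param tr_seconds Repetition time of the run.
#' @param dialect Source dialect tag.
#' @param run_id Text label for the run.
#' @return Object of class `realignment_series`.
#' @export
realignment_series <- function(params, tr_seconds = 2.5,
                               dialect = "generic", run_id = "run1") {
  params <- as.matrix(params)
  if (ncol(params) != 6)
    stop("realignment series must have exactly 6 columns, got ", ncol(params))
  if (!all(is.finite(params)))
    stop("realignment series contains non-finite values")
  colnames(params) <- c("dx", "dy", "dz", "alpha", "beta", "gamma")
  structure(list(params = params, tr_seconds = tr_seconds,
                 dialect = dialect, run_id = run_id),
            class = "realignment_series")
}

#' @export
print.realignment_series <- function(x, ...) {
  cat(sprintf("<realignment_series> %s: %d frames, TR = %gs (dialect %s)\n",
              x$run_id, nrow(x$params), x$tr_seconds, x$dialect))
  invisible(x)
}

# column order and rotation unit per supported dialect; canonical order is
# translations (mm) then rotations (radians)
.dialects <- list(
  generic = list(order = 1:6, rot_unit = "rad"),
  spm     = list(order = 1:6, rot_unit = "rad"),
  fsl     = list(order = c(4:6, 1:3), rot_unit = "rad"),  # rotations first
  afni    = list(order = 1:6, rot_unit = "deg")
)

#' Read rigid-body realignment parameters
#'
#' Parses the 6-column motion-parameter text files emitted by the common
#' realignment tools and converts them to the canonical representation
#' (translations in mm first, rotations in radians). The dialect must be
#' declared by the caller; it is never guessed from the file.
#'
#' Dialect conventions: `spm`/`generic` are translations-first with
#' rotations in radians; `fsl` stores rotations (radians) in the first
#' three columns; `afni` is translations-first with rotations in degrees.
#'
#' @param path Whitespace- or comma-delimited numeric text file, 6 columns.
#' @param dialect One of `"generic"`, `"spm"`, `"fsl"`, `"afni"`.
#' @param tr_seconds Repetition time to attach.
#' @param run_id Run label (defaults to the file name).
#' @return A [realignment_series()].
#' @export
read_realignment <- function(path, dialect = c("generic", "spm", "fsl", "afni"),
                             tr_seconds = 2.5, run_id = basename(path)) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(ln) {
    fields <- strsplit(trimws(lines[[ln]]), "[,[:space:]]+")[[1]]
    if (length(fields) != 6)
      stop(sprintf("line %d of '%s': expected 6 columns, found %d",
                   ln, path, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("line %d of '%s': non-numeric value '%s'",
                   ln, path, fields[which(is.na(vals))[1]]))
    vals
  })
  m <- do.call(rbind, rows)
  spec <- .dialects[[dialect]]
  m <- m[, spec$order, drop = FALSE]
  if (spec$rot_unit == "deg") m[, 4:6] <- m[, 4:6] * pi / 180
  realignment_series(m, tr_seconds = tr_seconds, dialect = dialect,
                     run_id = run_id)
}

#' Write realignment parameters in a given dialect
#'
#' Inverse of [read_realignment()]: converts the canonical representation
#' back to the dialect's column order and rotation unit, so a write/read
#' round trip reproduces the canonical values.
#'
#' @param series A [realignment_series()].
#' @param path Output file.
#' @param dialect Target dialect.
#' @export
write_realignment <- function(series, path,
                              dialect = c("generic", "spm", "fsl", "afni")) {
  dialect <- match.arg(dialect)
  spec <- .dialects[[dialect]]
  m <- series$params
  if (spec$rot_unit == "deg") m[, 4:6] <- m[, 4:6] * 180 / pi
  out <- matrix(NA_real_, nrow(m), 6)
  out[, spec$order] <- m
  utils::write.table(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ROI table
#'
#' Tab-separated table of ROI centers in a Talairach-like millimetre space
#' with a functional-network label per ROI (e.g. default, cerebellum,
#' fronto-parietal, cingulo-opercular, occipital, sensorimotor). Row order
#' defines the canonical ROI ordering used for every downstream edge index.
#'
#' @param path TSV with header `id, x, y, z, network`.
#' @return `data.frame` of class `roi_set`.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  roi_set(df)
}

#' Construct / validate an ROI set
#' @param df Data frame with columns `id, x, y, z, network`.
#' @return Validated `roi_set` data frame.
#' @export
roi_set <- function(df) {
  need <- c("id", "x", "y", "z", "network")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate ROI id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("ROI table has missing or non-finite coordinates")
  if (any(!nzchar(df$network)) || anyNA(df$network))
    stop("ROI table has empty network labels")
  rownames(df) <- NULL
  class(df) <- c("roi_set", "data.frame")
  df
}

#' Write an ROI table
#' @param rois `roi_set`.
#' @param path Output TSV.
#' @export
write_roi_table <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI-by-time series matrix
#'
#' @param path Numeric TSV/CSV. Rows are ROIs in the canonical ROI order
#'   unless `orientation = "time_by_roi"`, in which case the file is
#'   transposed on read.
#' @param rois Optional `roi_set`; if given, the ROI dimension must match.
#' @param orientation `"roi_by_time"` (default) or `"time_by_roi"`.
#' @param sep Field separator (default tab).
#' @return Numeric matrix, ROI x time.
#' @export
read_timeseries <- function(path, rois = NULL,
                            orientation = c("roi_by_time", "time_by_roi"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  storage.mode(m) <- "double"
  if (orientation == "time_by_roi") m <- t(m)
  dimnames(m) <- NULL
  if (!is.null(rois) && nrow(m) != nrow(rois))
    stop(sprintf("time series has %d ROIs but the ROI set has %d",
                 nrow(m), nrow(rois)))
  m
}

#' Write an ROI-by-time series matrix
#' @param ts ROI x time matrix.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  utils::write.table(format(ts, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a censor mask
#'
#' Frame-retention mask in the 1 = keep convention, so the mask can
#' multiply a design and `fraction_removed` is `1 - mean(keep)`.
#'
#' @param keep Logical (or 0/1) vector, `TRUE` = frame retained.
#' @param source_metric `"fd"`, `"dvars"`, or `"none"`.
#' @param threshold Threshold that produced the mask.
#' @return Logical vector of class `censor_mask` with attributes
#'   `source_metric` and `threshold`.
#' @export
censor_mask <- function(keep, source_metric = "none", threshold = NA_real_) {
  keep <- as.logical(keep)
  if (anyNA(keep)) stop("censor mask values must be 0/1")
  structure(keep, source_metric = source_metric, threshold = threshold,
            class = "censor_mask")
}

#' Fraction of frames removed by a censor mask
#' @param mask `censor_mask` or logical vector (TRUE = keep).
#' @return Scalar in `[0, 1]`.
#' @export
fraction_removed <- function(mask) 1 - mean(as.logical(mask))

#' Read a censor mask file
#' @param path Text file, one 0/1 value per line (1 = keep).
#' @param source_metric,threshold Metadata to attach.
#' @return A [censor_mask()].
#' @export
read_censor_mask <- function(path, source_metric = "none",
                             threshold = NA_real_) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (!all(v %in% c(0, 1)))
    stop("censor mask file must contain only 0/1 values; found ",
         paste(utils::head(setdiff(v, c(0, 1))), collapse = ", "))
  censor_mask(v == 1, source_metric = source_metric, threshold = threshold)
}

#' Write a censor mask file
#' @param mask A [censor_mask()] or logical vector.
#' @param path Output file (one 0/1 per line, 1 = keep).
#' @export
write_censor_mask <- function(mask, path) {
  writeLines(as.character(as.integer(as.logical(mask))), path)
  invisible(path)
}

.diagnoses <- c("TDC", "ADHD-I", "ADHD-C")

#' Read a phenotype table
#'
#' @param path CSV with columns `id, age, diagnosis, site, sex, IQ`
#'   (optionally `mean_fd_pre`, `mean_fd_post`). Diagnosis must be one of
#'   `TDC`, `ADHD-I`, `ADHD-C`. Missing IQ is permitted and flagged in the
#'   logical `iq_missing` column.
#' @return `data.frame` of class `cohort_table`.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(df)
}

#' Construct / validate a cohort table
#' @param df Data frame with at least `id, age, diagnosis, site, sex, IQ`.
#' @return Validated `cohort_table` data frame with an `iq_missing` flag.
#' @export
cohort_table <- function(df) {
  need <- c("id", "age", "diagnosis", "site", "sex", "IQ")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate subject id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("ages must be positive and finite")
  bad <- setdiff(unique(df$diagnosis), .diagnoses)
  if (length(bad))
    stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.diagnoses, collapse = "/"), ")")
  df$iq_missing <- is.na(df$IQ)
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a phenotype table
#' @param cohort `cohort_table`.
#' @param path Output CSV.
#' @export
write_phenotype <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$iq_missing <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
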