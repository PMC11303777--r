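# Long-format germination data container and its validation.
#
# A "germination_data" object is a plain data.frame, one row per
# dish-observation, with the canonical columns
#   temperature_C, psi_MPa, nacl_M, replicate, time_h, cum_germinated, n_sown
# and, optionally, seedling_length_cm and seedling_dry_weight_mg.
# Times are carried in hours internally; day-indexed indices bin them.

.GERM_REQUIRED <- c("temperature_C", "replicate", "time_h", "cum_germinated", "n_sown")
.GERM_MORPH <- c("seedling_length_cm", "seedling_dry_weight_mg")

#' Construct and validate a germination dataset
#'
#' Validates a long-format table of cumulative germination counts (one row
#' per dish and observation time) and returns it as a `germination_data`
#' object used by the fitting, index and reporting functions.
#'
#' Either `psi_MPa` or `nacl_M` must be present. A missing one is derived
#' from the other through the Van't Hoff relation at the dish temperature.
#' When both are present, `psi_MPa` is taken as the modelled variable and
#' `nacl_M` is cross-checked against it (warning beyond `nacl_tol` relative
#' disagreement).
#'
#' @param x data.frame with columns `temperature_C`, `psi_MPa` and/or
#'   `nacl_M`, `replicate`, `time_h`, `cum_germinated`, `n_sown`, and
#'   optionally `seedling_length_cm`, `seedling_dry_weight_mg`.
#' @param time_unit unit of the incoming time column: `"h"` (default) or
#'   `"d"`; days are converted to hours (x 24).
#' @param nacl_tol relative tolerance for the psi/NaCl consistency check.
#' @param ions Van't Hoff dissociation number used for derivations.
#' @return `x`, coerced, sorted by course and time, with class
#'   `c("germination_data", "data.frame")`.
#' @details Validation enforces: counts are integers, non-decreasing within
#'   each course, and never exceed `n_sown`; observation times are positive
#'   and strictly increasing within a course; `psi_MPa <= 0`; `nacl_M >= 0`.
#'   A ragged treatment grid (unequal replicate counts across treatments)
#'   produces a warning, not an error.
#' @examples
#' df <- data.frame(temperature_C = 25, psi_MPa = 0, replicate = 1,
#'                  time_h = c(24, 48, 72), cum_germinated = c(5, 10, 15),
#'                  n_sown = 30)
#' gd <- germination_data(df)
#' @export
germination_data <- function(x, time_unit = c("h", "d"), nacl_tol = 0.1, ions = 2) {
  time_unit <- match.arg(time_unit)
  x <- as.data.frame(x)

  has_psi <- "psi_MPa" %in% names(x)
  has_nacl <- "nacl_M" %in% names(x)
  if (!has_psi && !has_nacl)
    stop("missing column: 'psi_MPa' (or 'nacl_M')")
  missing_cols <- setdiff(.GERM_REQUIRED, names(x))
  if (length(missing_cols))
    stop("missing column: ", paste(sQuote(missing_cols), collapse = ", "))

  if (time_unit == "d") x$time_h <- x$time_h * 24

  if (has_psi && any(x$psi_MPa > 0)) stop("psi_MPa must be <= 0")
  if (has_nacl && any(x$nacl_M < 0)) stop("nacl_M must be >= 0")
  if (!has_psi) x$psi_MPa <- vant_hoff_psi(x$nacl_M, x$temperature_C, ions)
  if (!has_nacl) x$nacl_M <- vant_hoff_conc(x$psi_MPa, x$temperature_C, ions)
  if (has_psi && has_nacl) {
    implied <- vant_hoff_psi(x$nacl_M, x$temperature_C, ions)
    off <- abs(implied - x$psi_MPa) > nacl_tol * pmax(abs(x$psi_MPa), 1e-12) &
      !(x$psi_MPa == 0 & x$nacl_M == 0)
    if (any(off))
      warning(sum(off), " row(s) where nacl_M disagrees with psi_MPa beyond ",
              nacl_tol * 100, "%; psi_MPa is used as the modelled variable")
  }

  if (any(!is.finite(x$temperature_C))) stop("non-finite temperature_C")
  if (any(x$psi_MPa > 0)) stop("psi_MPa must be <= 0")
  if (any(x$nacl_M < 0)) stop("nacl_M must be >= 0")
  if (any(x$time_h <= 0)) stop("time_h must be > 0")
  if (any(x$n_sown <= 0)) stop("n_sown must be > 0")

  x$cum_germinated <- as.integer(round(x$cum_germinated))
  x$n_sown <- as.integer(round(x$n_sown))
  if (any(x$cum_germinated < 0 | x$cum_germinated > x$n_sown))
    stop("cum_germinated must lie in [0, n_sown]; offending row(s): ",
         paste(utils::head(which(x$cum_germinated < 0 | x$cum_germinated > x$n_sown), 5),
               collapse = ", "))

  canon <- c("temperature_C", "psi_MPa", "nacl_M", "replicate", "time_h",
             "cum_germinated", "n_sown")
  x <- x[, c(canon, setdiff(names(x), canon)), drop = FALSE]

  key <- .course_key(x)
  ord <- order(key, x$time_h)
  x <- x[ord, , drop = FALSE]
  key <- key[ord]
  rownames(x) <- NULL

  for (k in unique(key)) {
    idx <- which(key == k)
    tt <- x$time_h[idx]
    if (anyDuplicated(tt))
      stop("duplicated observation times in course ", k)
    cc <- x$cum_germinated[idx]
    bad <- which(diff(cc) < 0)
    if (length(bad))
      stop("decreasing cumulative count in course ", k,
           " at row ", idx[bad[1] + 1])
    if (length(unique(x$n_sown[idx])) != 1L)
      stop("n_sown varies within course ", k)
  }

  treat <- unique(data.frame(temperature_C = x$temperature_C, psi_MPa = x$psi_MPa))
  reps_per <- tapply(key, paste(x$temperature_C, x$psi_MPa), function(k) length(unique(k)))
  if (nrow(treat) > 1 && length(unique(reps_per)) > 1)
    warning("ragged treatment grid: replicate counts differ across treatments")

  class(x) <- c("germination_data", "data.frame")
  x
}

# course identifier: treatment x replicate
.course_key <- function(x) {
  paste(format(x$temperature_C), format(x$psi_MPa), x$replicate, sep = "/")
}

# split a germination_data into per-course data.frames (sorted by time)
.courses <- function(x) {
  split(as.data.frame(x), .course_key(x))
}

#' Read a germination dataset from CSV
#'
#' Reads a long-format CSV (RFC 4180, header row required) and validates it
#' through [germination_data()]. Non-standard column names are handled by
#' `dialect`, a named character vector mapping canonical names to the names
#' used in the file, e.g. `c(temperature_C = "temp", time_h = "hours")`.
#'
#' @param path CSV file path.
#' @param dialect optional named character vector of column-name mappings.
#' @inheritParams germination_data
#' @return A [germination_data] object.
#' @export
read_germination <- function(path, dialect = NULL, time_unit = "h",
                             nacl_tol = 0.1, ions = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(x))
      if (!is.na(j)) names(x)[j] <- canon
    }
  }
  germination_data(x, time_unit = time_unit, nacl_tol = nacl_tol, ions = ions)
}

#' Write a germination dataset to CSV
#'
#' Writes the long format back out with a stable column order, so that
#' `read_germination(write_germination(x, f))` round-trips losslessly.
#'
#' @param data a [germination_data] object (or coercible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_germination <- function(data, path) {
  data <- as.data.frame(data)
  cols <- c("temperature_C", "psi_MPa", "nacl_M", "replicate", "time_h",
            "cum_germinated", "n_sown", intersect(.GERM_MORPH, names(data)))
  cols <- intersect(cols, names(data))
  utils::write.csv(data[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.germination_data <- function(x, ...) {
  n_course <- length(unique(.course_key(x)))
  treat <- unique(paste(x$temperature_C, x$psi_MPa))
  cat(sprintf("Germination dataset: %d observations, %d courses, %d treatments\n",
              nrow(x), n_course, length(treat)))
  cat(sprintf("  temperatures (C): %s\n",
              paste(sort(unique(x$temperature_C)), collapse = ", ")))
  cat(sprintf("  osmotic potentials (MPa): %s\n",
              paste(sort(unique(x$psi_MPa)), collapse = ", ")))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
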