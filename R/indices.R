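# Classical germination and vigour indices computed from a cumulative
# time course, plus the two enzyme-activity unit conversions.
#
# Day-indexed indices (GE, GI, GRI, TGI, MGT, MGR, CVG) bin observation
# times to integer days, day = ceiling(hours / 24); a seed is credited to
# the first scoring day on which it was seen germinated.

# daily-binned cumulative counts: returns data.frame(day, cum, new)
.daily_counts <- function(times_h, cum_counts) {
  stopifnot(length(times_h) == length(cum_counts))
  day <- ceiling(times_h / 24)
  cum <- tapply(cum_counts, day, max)
  day <- as.numeric(names(cum))
  cum <- as.numeric(cum)
  data.frame(day = day, cum = cum, new = diff(c(0, cum)))
}

#' Final germination percentage (GP)
#'
#' @param cum_counts cumulative germinated counts over time (one course).
#' @param n_sown number of seeds sown.
#' @return Percentage of sown seeds germinated by the last observation.
#' @export
germination_percentage <- function(cum_counts, n_sown) {
  if (n_sown <= 0) stop("n_sown must be > 0")
  100 * cum_counts[length(cum_counts)] / n_sown
}

#' Germination energy (GE, Maguire's speed of germination)
#'
#' Sum over scoring days of the newly germinated seeds divided by the day
#' number: X1/Y1 + (X2 - X1)/Y2 + ... with X the cumulative count on day Y.
#'
#' @param times_h observation times, hours.
#' @inheritParams germination_percentage
#' @return seeds/day.
#' @export
germination_energy <- function(times_h, cum_counts) {
  d <- .daily_counts(times_h, cum_counts)
  sum(d$new / d$day)
}

#' Germination index (GI)
#'
#' Weighted count giving day-1 germinations weight `horizon` down to weight
#' 1 on day `horizon`: GI = (10 x n1) + (9 x n2) + ... + (1 x n10) for the
#' default 10-day horizon. Germinations after the horizon get weight 0
#' (with a warning).
#'
#' @inheritParams germination_energy
#' @param horizon highest weighted day (default 10).
#' @export
germination_index <- function(times_h, cum_counts, horizon = 10) {
  if (horizon < 1) stop("horizon must be >= 1")
  d <- .daily_counts(times_h, cum_counts)
  late <- d$day > horizon
  if (any(late & d$new > 0))
    warning("germinations after the ", horizon, "-day horizon get weight 0")
  w <- pmax(horizon + 1 - d$day, 0)
  sum(w * d$new)
}

#' Germination rate index (GRI)
#'
#' GRI = G1/1 + G2/2 + ... with Gd the day-d germination as a percentage of
#' seeds sown.
#'
#' @inheritParams germination_energy
#' @inheritParams germination_percentage
#' @return percent/day.
#' @export
germination_rate_index <- function(times_h, cum_counts, n_sown) {
  if (n_sown <= 0) stop("n_sown must be > 0")
  d <- .daily_counts(times_h, cum_counts)
  sum(100 * d$new / n_sown / d$day)
}

#' Timson germination index (TGI)
#'
#' Mean of the cumulative germination percentages over the scoring days:
#' TGI = sum(cumulative % on each day) / T, with T the number of scoring
#' days.
#'
#' @inheritParams germination_rate_index
#' @return percent/day.
#' @export
timson_index <- function(times_h, cum_counts, n_sown) {
  if (n_sown <= 0) stop("n_sown must be > 0")
  d <- .daily_counts(times_h, cum_counts)
  sum(100 * d$cum / n_sown) / nrow(d)
}

#' Mean germination time (MGT)
#'
#' Count-weighted mean day of germination, MGT = sum(f d)/sum(f) with f the
#' per-day germinations. Undefined (NA) when nothing germinates.
#'
#' @inheritParams germination_energy
#' @return days, or `NA_real_` if no seed germinated.
#' @export
mean_germination_time <- function(times_h, cum_counts) {
  d <- .daily_counts(times_h, cum_counts)
  if (sum(d$new) == 0) return(NA_real_)
  sum(d$new * d$day) / sum(d$new)
}

#' Mean germination rate (MGR)
#'
#' Exactly 1/MGT; undefined when MGT is.
#'
#' @inheritParams mean_germination_time
#' @return 1/days.
#' @export
mean_germination_rate <- function(times_h, cum_counts) {
  1 / mean_germination_time(times_h, cum_counts)
}

#' Coefficient of velocity of germination (CVG)
#'
#' CVG = 100 x sum(Nd) / sum(Nd Td), reaching its theoretical maximum of
#' 100 exactly when every germinated seed germinates on day 1.
#'
#' @inheritParams mean_germination_time
#' @return percent/day, or `NA_real_` if no seed germinated.
#' @export
coefficient_of_velocity <- function(times_h, cum_counts) {
  d <- .daily_counts(times_h, cum_counts)
  if (sum(d$new) == 0) return(NA_real_)
  100 * sum(d$new) / sum(d$new * d$day)
}

#' Time to a germination fraction (T50 and friends)
#'
#' Linear interpolation of the cumulative curve between the observations
#' bracketing the target count `fraction * n_total`:
#' `Ti + (target - ni) (Tj - Ti) / (nj - ni)`. The curve starts at the
#' origin (0, 0). Returns `NA_real_` when the target is never reached;
#' returns `Ti` when the bracketing counts are tied.
#'
#' @inheritParams germination_energy
#' @param n_total reference population: the final germinated count for the
#'   median of the germinated subpopulation (default), or seeds sown.
#' @param fraction target fraction of `n_total` (default 0.5).
#' @return time in hours (same unit as `times_h`).
#' @export
time_to_fraction <- function(times_h, cum_counts, n_total = NULL, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(n_total)) n_total <- cum_counts[length(cum_counts)]
  target <- fraction * n_total
  if (target == 0 || max(cum_counts) < target) return(NA_real_)
  tt <- c(0, times_h)
  cc <- c(0, cum_counts)
  j <- which(cc >= target)[1]
  i <- j - 1
  if (cc[j] == cc[i]) return(tt[i])
  tt[i] + (target - cc[i]) * (tt[j] - tt[i]) / (cc[j] - cc[i])
}

#' Seed vigour index I (length basis)
#'
#' @param gp germination percentage, 0-100.
#' @param seedling_length seedling length, cm.
#' @return cm times percent.
#' @export
seed_vigor_index_i <- function(gp, seedling_length) {
  if (any(gp < 0) || any(seedling_length < 0)) stop("inputs must be >= 0")
  gp * seedling_length
}

#' Seed vigour index II (dry-weight basis)
#'
#' @inheritParams seed_vigor_index_i
#' @param dry_weight seedling dry weight, mg.
#' @return mg times percent.
#' @export
seed_vigor_index_ii <- function(gp, dry_weight) {
  if (any(gp < 0) || any(dry_weight < 0)) stop("inputs must be >= 0")
  gp * dry_weight
}

#' Superoxide dismutase activity
#'
#' Literal evaluation of the NBT-inhibition unit conversion
#' SOD = (ODcontrol - ODtest)/ODcontrol x 1/50 x Vt/SQ x FW.
#' Note the trailing multiplication by fresh weight is as the source
#' formula prints it; per-gram activities conventionally divide by FW.
#'
#' @param od_control,od_test absorbances of control and test reactions.
#' @param vt total extract volume, ml.
#' @param sq sample quantity used, ml.
#' @param fw fresh weight of the homogenized tissue, g.
#' @return units/g FW.
#' @export
sod_activity <- function(od_control, od_test, vt, sq, fw) {
  if (any(od_control <= 0)) stop("od_control must be > 0")
  if (any(c(vt, sq, fw) <= 0)) stop("volumes and weight must be > 0")
  (od_control - od_test) / od_control * (1 / 50) * (vt / sq) * fw
}

#' Peroxidase activity
#'
#' POD = (change in OD / time) x 1/EC x TV/UV x 1/FW x 100.
#'
#' @param delta_od change in absorbance over the assay.
#' @param time_min assay time, minutes.
#' @param ec extinction coefficient.
#' @param tv total volume, ml.
#' @param uv used volume, ml.
#' @param fw fresh weight, g.
#' @return units/g FW/min.
#' @export
pod_activity <- function(delta_od, time_min, ec, tv, uv, fw) {
  if (any(c(time_min, ec, tv, uv, fw) <= 0)) stop("assay quantities must be > 0")
  delta_od / time_min * (1 / ec) * (tv / uv) * (1 / fw) * 100
}

#' Per-course germination index report
#'
#' Computes every index for each course (treatment x replicate) of a
#' dataset: GP, GE, GI, GRI, TGI, MGT, MGR, CVG, T50 and, when morphology
#' columns are present, SVI-I and SVI-II. Indices that are undefined for a
#' course (e.g. MGT with zero germination) are `NA` and named in the
#' `undefined_flags` column.
#'
#' @param data a [germination_data] object.
#' @param horizon GI horizon in days (default 10).
#' @param t50_of reference population for T50: `"germinated"` (median of
#'   the germinated subpopulation, default) or `"sown"`.
#' @return data.frame, one row per course.
#' @export
germination_indices <- function(data, horizon = 10,
                                t50_of = c("germinated", "sown")) {
  t50_of <- match.arg(t50_of)
  data <- as_germination_data(data)
  has_morph <- all(.GERM_MORPH %in% names(data))
  out <- lapply(.courses(data), function(cs) {
    tt <- cs$time_h
    cc <- cs$cum_germinated
    n <- cs$n_sown[1]
    gp <- germination_percentage(cc, n)
    n_ref <- if (t50_of == "sown") n else cc[length(cc)]
    t50_h <- time_to_fraction(tt, cc, n_total = n_ref)
    r <- data.frame(
      temperature_C = cs$temperature_C[1], psi_MPa = cs$psi_MPa[1],
      replicate = cs$replicate[1],
      gp = gp,
      ge = germination_energy(tt, cc),
      gi = suppressWarnings(germination_index(tt, cc, horizon)),
      gri = germination_rate_index(tt, cc, n),
      tgi = timson_index(tt, cc, n),
      mgt = mean_germination_time(tt, cc),
      mgr = mean_germination_rate(tt, cc),
      cvg = coefficient_of_velocity(tt, cc),
      t50 = t50_h / 24
    )
    if (has_morph) {
      r$svi_i <- seed_vigor_index_i(gp, mean(cs$seedling_length_cm))
      r$svi_ii <- seed_vigor_index_ii(gp, mean(cs$seedling_dry_weight_mg))
    }
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  idx_cols <- setdiff(names(out), c("temperature_C", "psi_MPa", "replicate"))
  out$undefined_flags <- apply(out[, idx_cols, drop = FALSE], 1, function(v) {
    paste(idx_cols[is.na(v)], collapse = ";")
  })
  out
}

# coerce plain data.frames on entry to user-facing functions
as_germination_data <- function(x, ...) {
  if (inherits(x, "germination_data")) x else germination_data(x, ...)
}
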