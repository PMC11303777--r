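# Assembled reporting: the per-temperature / global / derived-quantity
# table flow, and the index correlation matrix.

#' Run the full analysis pipeline and write report tables
#'
#' Fits the halothermal-time model, computes the germination indices and
#' writes four CSVs to `out_dir`:
#' \describe{
#'   \item{table1.csv}{per-temperature halotime fits (psi_b50, sigma_psib,
#'     theta_halo, R2, SE, F, p).}
#'   \item{table2.csv}{global model parameters, cardinal temperatures and
#'     fit diagnostics.}
#'   \item{table3.csv}{derived threshold-time quantities per treatment
#'     (tg, TTsub, TTsupra, theta_halo, theta_halott, GR).}
#'   \item{indices.csv}{per-course germination indices with undefined
#'     flags.}
#' }
#' plus `run_log.txt` recording the configuration and versions. Outputs
#' are deterministic: rerunning with the same inputs reproduces the files
#' byte for byte. Floats are written at 6 significant digits;
#' `paper_rounding = TRUE` additionally rounds table3 to 2 decimals.
#'
#' @param data a [germination_data] object (or coercible data.frame).
#' @param out_dir output directory (created if missing).
#' @param g reference percentile for derived quantities.
#' @param t_opt optional optimum temperature passed to [halott()].
#' @param derive_params optional [halott_params] used for table3 instead
#'   of the fitted ones (e.g. alternative cardinal temperatures).
#' @param paper_rounding round table3 to 2 decimals.
#' @param horizon GI horizon (days) for the index report.
#' @return Invisibly, a list with the fitted model, the four tables and
#'   their file paths.
#' @export
halott_pipeline <- function(data, out_dir, g = 0.5, t_opt = NULL,
                            derive_params = NULL, paper_rounding = FALSE,
                            horizon = 10) {
  data <- as_germination_data(data)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- "fit"
  fit <- tryCatch(halott(data, g = g, t_opt = t_opt),
                  error = function(e) stop("pipeline stage '", stage,
                                           "' failed: ", conditionMessage(e)))

  stage <- "table1"
  temps <- sort(unique(data$temperature_C))
  table1 <- do.call(rbind, lapply(temps, function(Tt) {
    f <- tryCatch(fit_halo_temperature(data, Tt), error = function(e) NULL)
    if (is.null(f)) {
      warning("per-temperature fit failed at ", Tt, " C; row omitted from table1")
      return(NULL)
    }
    data.frame(temperature_C = Tt, psi_b50 = f$psi_b50,
               sigma_psib = f$sigma_psib, theta_halo = f$theta_halo,
               r2 = f$diagnostics$r2, se = f$diagnostics$se,
               f_stat = f$diagnostics$f_stat, sig = f$diagnostics$sig)
  }))

  stage <- "table2"
  co <- coef(fit)
  table2 <- data.frame(parameter = names(co), value = unname(co))
  table2 <- rbind(table2,
                  data.frame(parameter = "r2", value = fit$diagnostics$r2))

  stage <- "table3"
  dp <- if (is.null(derive_params)) fit$params else derive_params
  table3 <- derive_cells(data, dp, g = g)

  stage <- "indices"
  indices <- germination_indices(data, horizon = horizon)

  num6 <- function(d) {
    for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], 6)
    d
  }
  table1 <- num6(table1)
  table2 <- num6(table2)
  indices <- num6(indices)
  table3 <- if (paper_rounding) {
    for (j in seq_along(table3)) if (is.numeric(table3[[j]]))
      table3[[j]] <- round(table3[[j]], 2)
    table3
  } else num6(table3)

  paths <- file.path(out_dir, c("table1.csv", "table2.csv", "table3.csv",
                                "indices.csv"))
  utils::write.csv(table1, paths[1], row.names = FALSE)
  utils::write.csv(table2, paths[2], row.names = FALSE)
  utils::write.csv(table3, paths[3], row.names = FALSE)
  utils::write.csv(indices, paths[4], row.names = FALSE)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("halott version: %s", as.character(utils::packageVersion("halott"))),
    sprintf("R version: %s", R.version.string),
    sprintf("courses: %d", length(unique(.course_key(data)))),
    sprintf("g: %g", g),
    sprintf("t_opt: %s", if (is.null(t_opt)) "estimated" else format(t_opt)),
    sprintf("paper_rounding: %s", paper_rounding)
  ), log_path)

  invisible(list(fit = fit, table1 = table1, table2 = table2, table3 = table3,
                 indices = indices, paths = c(paths, log_path)))
}

#' Correlation matrix of germination indices
#'
#' Product-moment correlations between index columns of a
#' [germination_indices()] report, computed on pairwise-complete
#' observations. Cells backed by fewer than `min_pairs` complete pairs, or
#' by a constant column, are `NA`.
#'
#' @param reports output of [germination_indices()] (>= 3 rows).
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return A symmetric correlation matrix.
#' @export
index_correlation <- function(reports, min_pairs = 3) {
  if (nrow(reports) < 3) stop("need at least 3 reports")
  drop <- c("temperature_C", "psi_MPa", "replicate", "undefined_flags")
  m <- as.matrix(reports[, setdiff(names(reports), drop), drop = FALSE])
  storage.mode(m) <- "double"
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < min_pairs) next
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) next
    out[i, j] <- stats::cor(m[ok, i], m[ok, j])
  }
  out
}
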