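#' Fit the linear elongation model to a length series
#'
#' Crown-root length (and shoot pixel count) is modelled as a straight line
#' in time, `L(t) = a + b t`, with `t = 0` anchored at the solution change so
#' that the intercept `a` is the length at treatment start and the slope `b`
#' is the elongation rate. Fitting is ordinary least squares via `lm()`.
#' Residual QC flags observations with |studentized residual| > 4; nothing is
#' removed automatically.
#'
#' @param series data frame with columns `t` (days since solution change) and
#'   `length` (cm, or pixels for shoot series), or a two-column matrix.
#' @return A `growth_fit`: list with `a`, `b`, `n_points`, `r2` (NA for a
#'   zero-variance response), `residual_sd`, and `flags` (QC messages).
#' @export
#' @examples
#' fit_linear(data.frame(t = c(0, 2, 4), length = c(10, 13, 16)))  # a=10, b=1.5
fit_linear <- function(series) {
  if (is.matrix(series)) series <- data.frame(t = series[, 1], length = series[, 2])
  t <- series$t; y <- series$length
  ok <- stats::complete.cases(t, y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n < 2L)
    stop("insufficient data: linear fit needs at least 2 observations",
         call. = FALSE)
  if (length(unique(t)) < 2L)
    stop("singular fit: all time values identical", call. = FALSE)
  fit <- stats::lm(y ~ t)
  cf <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst <= .Machine$double.eps * sum(y^2) + 1e-300) NA_real_ else 1 - sse / sst
  flags <- character(0)
  if (n > 3L) {
    rs <- stats::rstudent(fit)
    big <- which(is.finite(rs) & abs(rs) > 4)
    if (length(big))
      flags <- sprintf("studentized residual > 4 at t = %s",
                       paste(t[big], collapse = ", "))
  }
  structure(list(a = unname(cf[1]), b = unname(cf[2]), n_points = n,
                 r2 = r2,
                 residual_sd = if (n > 2L) sqrt(sse / (n - 2L)) else NA_real_,
                 flags = flags),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit: a = %.4g, b = %.4g (n = %d, r2 = %.3f)\n",
              x$a, x$b, x$n_points, x$r2))
  invisible(x)
}

#' Fit growth models to all eligible root and shoot series
#'
#' Bookkeeping layer over [fit_linear]: one elongation-rate/intercept pair
#' per eligible crown root (`ER_Cr`, `IC_Cr`, carrying its nitrogen level and
#' slide side) and per plant shoot (`ER_S`, `IC_S`). Root fits exclude
#' pre-treatment observations (`t < 0`) by default, since the model describes
#' the response to the nitrogen split; shoot fits use observations up to
#' `shoot_cutoff_day` (leaves outgrowing the imaging area end the usable
#' series). Roots first observed after the solution change get a slope but no
#' intercept (`IC_Cr` is not extrapolated backwards). Inestimable fits are
#' skipped with a QC entry, never imputed.
#'
#' @param root_series list of entries `list(genotype, replicate, side,
#'   n_level, series)`, one per eligible crown root.
#' @param shoot_series list of entries `list(genotype, replicate, series)`,
#'   one per plant; series in pixels.
#' @param include_pretreatment keep `t < 0` points in root fits.
#' @param shoot_cutoff_day last day (relative to solution change) usable for
#'   shoot fits, or `NULL` for no truncation.
#' @return List with `traits` (a [trait_table] of ER/IC records), `fits`
#'   (the underlying `growth_fit`s) and `qc` (data frame of skipped units).
#' @export
fit_all <- function(root_series = list(), shoot_series = list(),
                    include_pretreatment = FALSE, shoot_cutoff_day = NULL) {
  recs <- list(); fits <- list()
  qc <- data.frame(unit = character(0), reason = character(0))
  add_qc <- function(unit, reason)
    qc <<- rbind(qc, data.frame(unit = unit, reason = reason))

  for (rs in root_series) {
    s <- rs$series
    if (!include_pretreatment) s <- s[s$t >= 0, , drop = FALSE]
    unit <- sprintf("%s/rep%s/%s/%s-N", rs$genotype, rs$replicate, rs$side, rs$n_level)
    fit <- tryCatch(fit_linear(s), error = function(e) e)
    if (inherits(fit, "error")) { add_qc(unit, conditionMessage(fit)); next }
    fits[[length(fits) + 1L]] <- fit
    recs[[length(recs) + 1L]] <- trait_table(
      genotype = rs$genotype, n_level = rs$n_level, replicate = rs$replicate,
      side = rs$side, trait = "ER_Cr", value = fit$b, units = "cm/d")
    first_after_change <- min(rs$series$t) > 0
    if (!first_after_change) {
      recs[[length(recs) + 1L]] <- trait_table(
        genotype = rs$genotype, n_level = rs$n_level, replicate = rs$replicate,
        side = rs$side, trait = "IC_Cr", value = fit$a, units = "cm")
    } else {
      add_qc(unit, "root first observed after solution change: intercept not extrapolated")
    }
  }

  for (ss in shoot_series) {
    s <- ss$series
    if (!is.null(shoot_cutoff_day)) s <- s[s$t <= shoot_cutoff_day, , drop = FALSE]
    unit <- sprintf("%s/rep%s/shoot", ss$genotype, ss$replicate)
    fit <- tryCatch(fit_linear(s), error = function(e) e)
    if (inherits(fit, "error")) { add_qc(unit, conditionMessage(fit)); next }
    fits[[length(fits) + 1L]] <- fit
    recs[[length(recs) + 1L]] <- trait_table(
      genotype = ss$genotype, n_level = "none", replicate = ss$replicate,
      side = "none", trait = "ER_S", value = fit$b, units = "pixel/d")
    recs[[length(recs) + 1L]] <- trait_table(
      genotype = ss$genotype, n_level = "none", replicate = ss$replicate,
      side = "none", trait = "IC_S", value = fit$a, units = "pixel")
  }

  traits <- if (length(recs)) merge_trait_tables(recs) else trait_table()
  list(traits = traits, fits = fits, qc = qc)
}
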