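# Thermal-time phenology: growing-degree-day flowering traits, vegetative
# period length, and plot-level sex-determination scores aggregated to
# accession-by-location means.

#' Daily mean-temperature series
#'
#' @param location_id Location identifier.
#' @param dates Strictly consecutive calendar days.
#' @param tmean Finite daily mean air temperatures, degrees C.
#' @return A data frame with columns `date`, `tmean_c` and a `location_id`
#'   attribute, of class `temperature_series`.
#' @export
temperature_series <- function(location_id, dates, tmean) {
  dates <- as.Date(dates)
  if (length(dates) != length(tmean)) stop("dates and tmean differ in length")
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
    stop("dates must be strictly consecutive with no gaps")
  if (any(!is.finite(tmean))) stop("temperatures must be finite")
  structure(data.frame(date = dates, tmean_c = as.numeric(tmean)),
            location_id = as.character(location_id),
            class = c("temperature_series", "data.frame"))
}

#' Accumulated thermal time (degree-days)
#'
#' Sums `max(0, tmean - base_temp)` over the half-open day interval
#' `[from_date, to_date)`: the start day contributes, the end day does not,
#' which makes accumulation exactly additive over abutting intervals.
#' Optionally caps the daily mean at `ceiling_temp` before subtracting the
#' base.
#'
#' @param series A [temperature_series()].
#' @param from_date,to_date Interval bounds, `from_date <= to_date`, both
#'   within the series (`to_date` may be one day past its end).
#' @param base_temp Base temperature, degrees C (default 1).
#' @param ceiling_temp Optional upper cap on the daily mean, degrees C.
#' @return Accumulated thermal time in degree-days; 0 when the interval is
#'   empty.
#' @export
accumulate_thermal_time <- function(series, from_date, to_date, base_temp = 1,
                                    ceiling_temp = NULL) {
  stopifnot(inherits(series, "temperature_series"))
  from_date <- as.Date(from_date); to_date <- as.Date(to_date)
  if (from_date > to_date) stop("from_date must be <= to_date")
  if (from_date < series$date[1] || from_date > series$date[nrow(series)] + 1)
    stop("date ", format(from_date), " outside the temperature series")
  if (to_date > series$date[nrow(series)] + 1)
    stop("date ", format(to_date), " outside the temperature series")
  if (from_date == to_date) return(0)
  sel <- series$date >= from_date & series$date < to_date
  tm <- series$tmean_c[sel]
  if (!is.null(ceiling_temp)) tm <- pmin(tm, ceiling_temp)
  sum(pmax(tm - base_temp, 0))
}

#' Thermal-time flowering traits of plot records
#'
#' For each plot record computes `FL_Begin` and `FL_Full` as the thermal time
#' accumulated from emergence to, respectively, the beginning of flowering
#' and full flowering, and `VEG` as the number of calendar days from
#' emergence to the beginning of flowering.  Missing flowering dates
#' (plots that stayed vegetative) propagate as `NA`.
#'
#' @param records Plot phenology data frame with columns `location_id`,
#'   `accession_id`, `plot_id`, `sowing_date`, `emergence_date`,
#'   `begin_flowering_date`, `full_flowering_date`, `sex_score`.
#' @param temps Named list of [temperature_series()] keyed by location.
#' @param base_temp,ceiling_temp Passed to [accumulate_thermal_time()].
#' @return `records` with added numeric columns `FL_Begin`, `FL_Full` (both
#'   degree-days) and `VEG` (days).
#' @export
compute_flowering_traits <- function(records, temps, base_temp = 1,
                                     ceiling_temp = NULL) {
  temps <- as_series_list(temps)
  validate_phenology(records)
  n <- nrow(records)
  fl_b <- fl_f <- veg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- temps[[records$location_id[i]]]
    if (is.null(s)) stop("no temperature series for location ",
                         records$location_id[i])
    em <- records$emergence_date[i]
    bf <- records$begin_flowering_date[i]
    ff <- records$full_flowering_date[i]
    if (!is.na(bf)) {
      fl_b[i] <- accumulate_thermal_time(s, em, bf, base_temp, ceiling_temp)
      veg[i] <- as.numeric(as.Date(bf) - as.Date(em))
    }
    if (!is.na(ff))
      fl_f[i] <- accumulate_thermal_time(s, em, ff, base_temp, ceiling_temp)
  }
  records$FL_Begin <- fl_b
  records$FL_Full <- fl_f
  records$VEG <- veg
  records
}

validate_phenology <- function(records) {
  need <- c("location_id", "accession_id", "plot_id", "emergence_date",
            "begin_flowering_date", "full_flowering_date", "sex_score")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("phenology records lack columns: ",
                             paste(miss, collapse = ", "))
  if (!all(records$sex_score %in% c(1L, 2L, 3L)))
    stop("sex_score must be 1, 2 or 3")
  b <- as.Date(records$begin_flowering_date)
  f <- as.Date(records$full_flowering_date)
  e <- as.Date(records$emergence_date)
  both <- !is.na(b) & !is.na(f)
  if (any(b[both] > f[both]))
    stop("begin_flowering_date after full_flowering_date in some plots")
  if (any(!is.na(b) & b < e) ||
      ("sowing_date" %in% names(records) &&
       any(e < as.Date(records$sowing_date))))
    stop("dates violate sowing <= emergence <= begin flowering")
  invisible(records)
}

as_series_list <- function(temps) {
  if (inherits(temps, "temperature_series")) temps <- list(temps)
  if (is.null(names(temps)) || any(!nzchar(names(temps))))
    names(temps) <- vapply(temps, function(s) attr(s, "location_id"), character(1))
  temps
}

#' Aggregate plot records to accession-by-location trait means
#'
#' Computes [compute_flowering_traits()] per plot and averages each trait
#' over the plots of an accession at a location, using only plots with a
#' non-missing value; `Sex_det` is the mean plot sex score.  A cell whose
#' plots are all missing stays `NA` and is reported via a message.
#'
#' @inheritParams compute_flowering_traits
#' @return A `trait_table` data frame keyed by `(accession_id, location_id)`
#'   with columns `FL_Begin`, `FL_Full` (degree-days), `VEG` (days) and
#'   `Sex_det` (in `[1, 3]`).
#' @export
aggregate_plots <- function(records, temps, base_temp = 1, ceiling_temp = NULL) {
  r <- compute_flowering_traits(records, temps, base_temp, ceiling_temp)
  key <- list(accession_id = r$accession_id, location_id = r$location_id)
  mean_nn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- aggregate(cbind(FL_Begin, FL_Full, VEG) ~ accession_id + location_id,
                   data = r, FUN = mean_nn, na.action = NULL)
  sx <- aggregate(list(Sex_det = as.numeric(r$sex_score)), by = key, FUN = mean)
  out <- merge(out, sx, by = c("accession_id", "location_id"), sort = TRUE)
  n_missing <- sum(is.na(out$FL_Begin)) + sum(is.na(out$FL_Full))
  if (n_missing > 0)
    message(n_missing, " accession-by-location trait cells have no flowering ",
            "plots and stay missing")
  out <- out[order(out$location_id, out$accession_id), ]
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}
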