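# day-of-year windows on the 365-day model calendar
.AUGUST_DAYS <- 213:243
.SUMMER_DAYS <- 121:274   # 1 May - 1 Oct

.check_daily <- function(x, min_years = 1) {
  if (length(x) == 0 || length(x) %% 365 != 0)
    stop("series length must be a positive multiple of 365 (whole years)",
         call. = FALSE)
  n <- length(x) %/% 365
  if (n < min_years)
    stop(sprintf("need at least %d complete year(s)", min_years), call. = FALSE)
  n
}

#' Mean annual cycle (daily climatology)
#'
#' Averages a daily series across years into a 365-day mean yearly cycle.
#'
#' @param x Daily values over one or more whole 365-day years.
#' @return Numeric vector of length 365.
#' @export
climatology <- function(x) {
  .check_daily(x)
  rowMeans(matrix(x, nrow = 365))
}

#' Annual means of a daily series
#'
#' @inheritParams climatology
#' @return One mean per year.
#' @export
annual_means <- function(x) {
  .check_daily(x)
  colMeans(matrix(x, nrow = 365))
}

#' Within-year coefficient of variation
#'
#' Seasonal variability: the CV computed over the 365 days of the average
#' yearly cycle (population standard deviation over the mean, the 365 days
#' being the complete cycle rather than a sample).
#'
#' @inheritParams climatology
#' @return Non-negative scalar.
#' @export
within_year_cv <- function(x) {
  clim <- climatology(x)
  m <- mean(clim)
  if (m == 0) stop("zero-mean series: CV undefined", call. = FALSE)
  sqrt(mean((clim - m)^2)) / m
}

#' Between-year coefficient of variation
#'
#' Interannual variability: the CV of the annual means (sample standard
#' deviation, n - 1 denominator). Requires at least two whole years.
#'
#' @inheritParams climatology
#' @return Non-negative scalar.
#' @export
between_year_cv <- function(x) {
  .check_daily(x, min_years = 2)
  am <- annual_means(x)
  m <- mean(am)
  if (m == 0) stop("zero-mean series: CV undefined", call. = FALSE)
  stats::sd(am) / m
}

#' Seasonal food-web metrics of a scenario
#'
#' Computes, over the analysis window of a run, the four summary metrics
#' used to characterize the response of the food web to nutrient loading:
#' mean August (days 213-243) omnivorous fish biomass; mean August predator
#' fraction of total fish biomass; mean summer (1 May-1 Oct, days 121-274)
#' zooplankton-to-phytoplankton biomass ratio; and mean summer chlorophyll
#' proxy (phytoplankton biomass times the configured conversion factor).
#' Normalization of the omnivore index across model configurations is left
#' to the caller.
#'
#' @param result A `"scenario_result"` from [foodweb_run()].
#' @return A data frame with columns `metric` and `value`.
#' @export
scenario_metrics <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  s <- result$series[result$series$year %in% result$analysis_years, ]
  if (nrow(s) < 365) stop("analysis window must cover >= 1 full year", call. = FALSE)
  aug <- s$doy %in% .AUGUST_DAYS
  sm <- s$doy %in% .SUMMER_DAYS
  if (!any(aug) || !any(sm)) stop("empty seasonal window", call. = FALSE)
  fish_tot <- s$omnivore[aug] + s$predator[aug]
  pred_frac <- ifelse(fish_tot > 0, s$predator[aug] / fish_tot, 0)
  zp <- ifelse(s$phytoplankton[sm] > 0,
               s$zooplankton[sm] / s$phytoplankton[sm], NA_real_)
  chl <- result$cfg$chl_conversion * s$phytoplankton[sm]
  data.frame(
    metric = c("august_omnivore_biomass", "august_predator_fraction",
               "summer_zoo_phyto_ratio", "summer_chlorophyll"),
    value = c(mean(s$omnivore[aug]), mean(pred_frac),
              mean(zp, na.rm = TRUE), mean(chl))
  )
}

#' Pool-wise means and variability decomposition of a scenario
#'
#' Mean, within-year CV and between-year CV of every pool over the
#' analysis window, plus the share of days each fish group spent in each
#' behavioral regime.
#'
#' @param result A `"scenario_result"`.
#' @return A list with `pools` (data frame: pool, mean, within_cv,
#'   between_cv) and `regimes` (data frame of regime occupancy fractions
#'   per fish group).
#' @export
scenario_summary <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  pools <- lapply(.POOLS, function(p) {
    x <- analysis_series(result, p)
    data.frame(pool = p, mean = mean(x),
               within_cv = tryCatch(within_year_cv(x), error = function(e) NA_real_),
               between_cv = tryCatch(between_year_cv(x), error = function(e) NA_real_))
  })
  reg <- lapply(c(omnivore = "regime_omn", predator = "regime_prd"),
                function(col) {
                  r <- analysis_series(result, col)
                  c(normal = mean(r == 1), starvation_feed = mean(r == 2),
                    starvation_stop = mean(r == 3))
                })
  list(pools = do.call(rbind, pools),
       regimes = data.frame(group = names(reg), do.call(rbind, reg),
                            row.names = NULL))
}
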