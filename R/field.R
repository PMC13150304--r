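#' Root-water-uptake proxy from a soil-moisture series
#'
#' The negative time-derivative of volumetric soil water content (uptake
#' positive while the soil dries), smoothed by a centered moving average of
#' `window_h` hours applied `passes` times. Derivatives use central
#' differences on the native grid; the averaging window shrinks to the
#' valid range at the series edges.
#'
#' @param t time stamps (s), strictly increasing
#' @param theta volumetric water content (fraction)
#' @param window_h moving-average window (h)
#' @param passes number of smoothing passes
#' @param resample resample an irregular grid to its median spacing by
#'   linear interpolation; if `FALSE` an irregular grid is an error
#' @return data frame with columns `t` (s) and `rwu` (fraction s-1)
#' @export
rwu_series <- function(t, theta, window_h = 2, passes = 2,
                       resample = FALSE) {
  stopifnot(length(t) == length(theta), length(t) >= 3, !is.unsorted(t))
  dts <- diff(t)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts)) {
    if (!resample)
      stop("irregular time grid: resample first (or set resample = TRUE)")
    dt <- stats::median(dts)
    tg <- seq(t[1], t[length(t)], by = dt)
    theta <- stats::approx(t, theta, xout = tg)$y
    t <- tg
  }
  n <- length(t)
  d <- numeric(n)
  d[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (theta[2] - theta[1]) / (t[2] - t[1])
  d[n] <- (theta[n] - theta[n - 1]) / (t[n] - t[n - 1])
  rwu <- -d
  w <- max(1L, round(window_h * 3600 / (t[2] - t[1])))
  for (i in seq_len(passes)) rwu <- moving_average(rwu, w)
  data.frame(t = t, rwu = rwu)
}

# Centered moving average of total window width `w` samples, shrinking to
# the valid range at the edges.
moving_average <- function(x, w) {
  n <- length(x)
  k <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Mask wet days and the days following them
#'
#' Soil-moisture fluctuations after rewetting reflect percolation rather
#' than uptake, so days with precipitation above the threshold -- by default
#' the series' first quartile, the field analysis used 0.15 mm per day --
#' and the single day after each such day are excluded.
#'
#' @param precip daily precipitation totals (mm d-1)
#' @param threshold exclusion threshold (mm d-1); `NULL` uses the first
#'   quartile of `precip`
#' @return logical vector, `TRUE` where the day is excluded
#' @export
wet_day_mask <- function(precip, threshold = NULL) {
  precip <- as.vector(precip)   # accept tapply-style 1-d arrays
  if (is.null(threshold)) threshold <- stats::quantile(precip, 0.25,
                                                       names = FALSE)
  wet <- precip > threshold
  after <- c(FALSE, wet[-length(wet)])
  wet | after
}

#' Clock time of the daily maximum of a diel series
#'
#' Per retained day, the clock hour at which the series attains its maximum
#' within the daylight window (ties to the earliest sample). Days with no
#' finite data are skipped with a message.
#'
#' @param t time stamps (s from the series origin; days are 86400 s)
#' @param value the series (e.g. sap-flux density or smoothed uptake)
#' @param exclude_days logical per-day exclusion mask (e.g. from
#'   [wet_day_mask()]), indexed by day number starting at the first day
#' @param daylight length-2 clock-hour window searched for the maximum
#' @return data frame with columns `day` (0-based) and `peak_hour`
#' @export
daily_peak_times <- function(t, value, exclude_days = NULL,
                             daylight = c(5, 21)) {
  day <- t %/% 86400
  hour <- (t %% 86400) / 3600
  in_window <- hour >= daylight[1] & hour <= daylight[2]
  days <- sort(unique(day))
  rows <- lapply(days, function(dd) {
    if (!is.null(exclude_days)) {
      j <- dd - days[1] + 1
      if (j <= length(exclude_days) && isTRUE(exclude_days[j])) return(NULL)
    }
    idx <- which(day == dd & in_window & is.finite(value))
    if (length(idx) == 0) {
      message("day ", dd, ": no finite data, skipped")
      return(NULL)
    }
    i <- idx[which.max(value[idx])]
    data.frame(day = dd, peak_hour = hour[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(day = integer(), peak_hour = numeric())
  out
}

#' Fit a distribution to daily peak times
#'
#' Gamma by maximum likelihood (a natural model for time durations;
#' requires >= 10 values) or a nonparametric kernel density estimate with
#' rule-of-thumb bandwidth on a 24-h grid (for bimodal timings such as
#' beech sap flow; requires >= 20 values). KDE modes are local maxima of
#' the density reaching at least 10 percent of its peak.
#'
#' @param times peak clock hours (>= 0)
#' @param kind `"gamma"` or `"kde"`
#' @return for gamma: list with `kind`, `shape`, `rate`, `scale`, `mean`;
#'   for kde: list with `kind`, `x`, `density`, `modes`, `mean`, `bw`
#' @export
fit_timing_distribution <- function(times, kind = c("gamma", "kde")) {
  kind <- match.arg(kind)
  if (any(times < 0)) stop("negative times")
  if (kind == "gamma") {
    if (length(times) < 10) stop("need >= 10 timing values for a gamma fit")
    fit <- MASS::fitdistr(times, "gamma")
    shape <- unname(fit$estimate["shape"])
    rate <- unname(fit$estimate["rate"])
    list(kind = "gamma", shape = shape, rate = rate, scale = 1 / rate,
         mean = shape / rate)
  } else {
    if (length(times) < 20) stop("need >= 20 timing values for a KDE fit")
    den <- stats::density(times, bw = "nrd0", from = 0, to = 24, n = 481)
    y <- den$y
    n <- length(y)
    is_mode <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                        y[2:(n - 1)] >= y[3:n], FALSE)
    modes <- den$x[is_mode & y >= 0.1 * max(y)]
    list(kind = "kde", x = den$x, density = y, modes = modes,
         mean = sum(den$x * y) / sum(y), bw = den$bw)
  }
}

#' Mean lag between daily sap-flow and root-water-uptake peaks
#'
#' Two lag estimates: the mean of the day-matched pairwise differences
#' (uptake peak minus sap-flow peak; positive when uptake peaks later), and
#' the difference of the means of distributions fitted to all timings of
#' each series.
#'
#' @param sap_times data frame from [daily_peak_times()] for sap flow
#' @param rwu_times data frame from [daily_peak_times()] for uptake
#' @param sap_kind,rwu_kind distribution kinds for the fitted-mean lag;
#'   `NULL` skips the distribution route (e.g. too few days)
#' @return list with `mean_pairwise` (h), `mean_dist_diff` (h or `NA`),
#'   `n_days`
#' @export
mean_lag <- function(sap_times, rwu_times, sap_kind = "gamma",
                     rwu_kind = "gamma") {
  m <- merge(sap_times, rwu_times, by = "day",
             suffixes = c("_sap", "_rwu"))
  if (nrow(m) == 0) stop("no day-matched timing pairs")
  pairwise <- mean(m$peak_hour_rwu - m$peak_hour_sap)
  dist_diff <- NA_real_
  if (!is.null(sap_kind) && !is.null(rwu_kind)) {
    dist_diff <- tryCatch(
      fit_timing_distribution(rwu_times$peak_hour, rwu_kind)$mean -
        fit_timing_distribution(sap_times$peak_hour, sap_kind)$mean,
      error = function(e) NA_real_)
  }
  list(mean_pairwise = pairwise, mean_dist_diff = dist_diff, n_days = nrow(m))
}
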