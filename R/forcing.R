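#' Hourly meteorological forcing
#'
#' A `meteo_forcing` is a data frame with one row per hour on a 365-day
#' calendar (leap days are dropped throughout the package so that hourly,
#' 10-minute and daily clocks always align). Columns:
#' \describe{
#'   \item{timestamp}{ISO-8601 character, strictly hourly, no gaps}
#'   \item{air_temp}{air temperature, degC}
#'   \item{precip}{precipitation, mm h-1, >= 0}
#'   \item{rel_humidity}{relative humidity, \%}
#'   \item{sw_down}{downwelling shortwave, W m-2}
#'   \item{wind}{wind speed, m s-1}
#'   \item{pressure}{air pressure, kPa}
#'   \item{co2_atm}{atmospheric CO2, ppm (daily value repeated hourly)}
#' }
#' @name meteo_forcing
NULL

.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_start <- c(0L, cumsum(.month_days))[1:12]  # day-of-year offset

# ISO timestamp for hour index h (0-based) after year0-01-01 00:00, 365-d year
.hour_to_timestamp <- function(h, year0) {
  yr <- year0 + h %/% 8760L
  rem <- h %% 8760L
  doy <- rem %/% 24L            # 0-based
  hod <- rem %% 24L
  mon <- findInterval(doy, .month_start)
  dom <- doy - .month_start[mon] + 1L
  sprintf("%04d-%02d-%02d %02d:00:00", yr, mon, dom, hod)
}

# inverse: ISO timestamp -> hour index on the 365-day calendar (NA if invalid)
.timestamp_to_hour <- function(ts, year0) {
  m <- regmatches(ts, regexec(
    "^(\\d{4})-(\\d{2})-(\\d{2})[ T](\\d{2}):(\\d{2})(:(\\d{2}))?$", ts))
  out <- rep(NA_real_, length(ts))
  for (i in seq_along(ts)) {
    g <- m[[i]]
    if (length(g) == 0) next
    yr <- as.integer(g[2]); mo <- as.integer(g[3]); dd <- as.integer(g[4])
    hh <- as.integer(g[5]); mi <- as.integer(g[6])
    if (mo < 1 || mo > 12 || dd < 1 || dd > .month_days[mo] || hh > 23 ||
        mi != 0L)
      next
    doy <- .month_start[mo] + dd - 1L
    out[i] <- (yr - year0) * 8760 + doy * 24 + hh
  }
  out
}

.forcing_cols <- c("timestamp", "air_temp", "precip", "rel_humidity",
                   "sw_down", "wind", "pressure", "co2_atm")

.new_meteo_forcing <- function(df, year0) {
  stopifnot(identical(names(df), .forcing_cols))
  attr(df, "year0") <- year0
  class(df) <- c("meteo_forcing", "data.frame")
  df
}

#' Validate a meteo_forcing object
#'
#' Checks the type invariants: strictly hourly timestamps with no gaps,
#' non-negative precipitation, relative humidity in \[0, 100\], positive CO2.
#'
#' @param forcing a `meteo_forcing`
#' @return `forcing`, invisibly; stops with an informative error otherwise.
#' @export
validate_forcing <- function(forcing) {
  if (!inherits(forcing, "meteo_forcing"))
    stop("not a meteo_forcing object")
  year0 <- attr(forcing, "year0")
  h <- .timestamp_to_hour(forcing$timestamp, year0)
  bad <- which(is.na(h))
  if (length(bad))
    stop("invalid timestamp at row ", bad[1], ": ", forcing$timestamp[bad[1]])
  dh <- diff(h)
  if (any(dh == 0)) {
    i <- which(dh == 0)[1]
    stop("duplicated timestamp at row ", i + 1, ": ", forcing$timestamp[i + 1])
  }
  if (any(dh != 1)) {
    i <- which(dh != 1)[1]
    stop("non-hourly or non-monotone timestamps at row ", i + 1, ": ",
         forcing$timestamp[i + 1])
  }
  if (any(forcing$precip < 0)) stop("negative precipitation")
  if (any(forcing$rel_humidity < 0 | forcing$rel_humidity > 100))
    stop("relative humidity outside [0, 100]")
  if (any(forcing$co2_atm <= 0)) stop("non-positive atmospheric CO2")
  if (anyNA(forcing[.forcing_cols[-1]])) stop("NA in forcing values")
  invisible(forcing)
}

#' Generate statistically plausible synthetic hourly forcing
#'
#' Produces an hourly forcing record with an annual and diurnal sinusoidal
#' temperature cycle plus bounded AR(1) noise, and rainfall as a marked
#' Poisson process: storm arrivals at `storm_freq` per day, depths
#' exponentially distributed so the expected annual total equals
#' `annual_rain_mm`. Shortwave radiation follows a day-length modulated
#' clear-sky curve attenuated on rainy hours; humidity is anticorrelated with
#' the temperature anomaly. Identical seeds give bit-identical output.
#'
#' @param mean_temp mean annual air temperature, degC
#' @param seasonal_amp amplitude of the annual temperature cycle, degC
#' @param diurnal_amp amplitude of the diurnal temperature cycle, degC
#' @param annual_rain_mm expected annual rainfall, mm
#' @param storm_freq mean storm arrivals per day (> 0)
#' @param seed integer seed; the generator uses a private RNG stream
#' @param n_years integer number of 365-day years (>= 1)
#' @param temp_noise_sd std. dev. of the AR(1) temperature noise, degC
#' @param co2_ppm atmospheric CO2 mixing ratio, ppm
#' @param year0 calendar year label of the first record
#' @return a [meteo_forcing] data frame of `8760 * n_years` rows
#' @export
generate_synthetic_forcing <- function(mean_temp, seasonal_amp, diurnal_amp,
                                       annual_rain_mm, storm_freq,
                                       seed = 1L, n_years = 1L,
                                       temp_noise_sd = 1.5,
                                       co2_ppm = 420, year0 = 2001L) {
  if (n_years < 1) stop("n_years must be >= 1")
  if (annual_rain_mm < 0) stop("annual rainfall must be non-negative")
  if (storm_freq <= 0) stop("storm frequency must be positive")
  prm <- c(mean_temp, seasonal_amp, diurnal_amp, annual_rain_mm, storm_freq,
           temp_noise_sd, co2_ppm)
  if (!all(is.finite(prm))) stop("all climate parameters must be finite")

  n <- 8760L * as.integer(n_years)
  h <- seq_len(n) - 1L
  doy <- (h %/% 24L) %% 365L          # 0-based
  hod <- h %% 24L

  # private RNG stream so callers' RNG state is untouched
  rng <- .with_private_seed(seed, {
    eps <- stats::rnorm(n, 0, temp_noise_sd)
    u_storm <- stats::runif(n)
    depth <- stats::rexp(n)
    rh_eps <- stats::rnorm(n, 0, 5)
    wind_eps <- stats::rnorm(n, 0, 0.5)
    list(eps = eps, u_storm = u_storm, depth = depth, rh_eps = rh_eps,
         wind_eps = wind_eps)
  })

  # bounded AR(1) noise (clipped at 3 marginal sd)
  ar <- 0.9
  noise <- stats::filter(rng$eps * sqrt(1 - ar^2), ar, method = "recursive")
  noise <- pmin(pmax(as.numeric(noise), -3 * temp_noise_sd),
                3 * temp_noise_sd)
  seas <- -cos(2 * pi * (doy + 15) / 365)   # minimum in mid-January
  diur <- -cos(2 * pi * (hod - 3) / 24)     # minimum ~03:00, max ~15:00
  air_temp <- mean_temp + seasonal_amp * seas + diurnal_amp * diur + noise

  # marked Poisson rainfall: per-hour arrival prob, exponential depths
  p_hour <- storm_freq / 24
  mean_depth <- annual_rain_mm / (storm_freq * 365)
  precip <- ifelse(rng$u_storm < p_hour, rng$depth * mean_depth, 0)

  # clear-sky-ish shortwave: half-sine day shaped by seasonal day length
  decl <- 0.41 * seas                        # crude declination proxy, rad
  daylen <- 12 + 8 * decl / 0.41 * 0.35      # hours, 9.2..14.8 at mid-lat
  x <- (hod + 0.5 - 12) / (daylen / 2)
  sw_clear <- 900 * pmax(0, cos(pi / 2 * pmin(abs(x), 1.5)))
  sw_clear[abs(x) >= 1] <- 0
  cloud <- ifelse(precip > 0, 0.25, 1)
  sw_down <- sw_clear * cloud * (0.75 + 0.25 * seas * 0)  # keep deterministic

  rh <- 70 - 1.5 * (air_temp - (mean_temp + seasonal_amp * seas)) + rng$rh_eps
  rh[precip > 0] <- 96
  rh <- pmin(pmax(rh, 5), 100)

  wind <- pmax(0.1, 2.5 + rng$wind_eps)
  pressure <- rep(101.325, n)
  co2 <- rep(co2_ppm, n)

  df <- data.frame(timestamp = .hour_to_timestamp(h, year0),
                   air_temp = air_temp, precip = precip, rel_humidity = rh,
                   sw_down = sw_down, wind = wind, pressure = pressure,
                   co2_atm = co2, stringsAsFactors = FALSE)
  validate_forcing(.new_meteo_forcing(df, year0))
}

# run expr with a private RNG state derived from seed; restores caller state
.with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Read an hourly forcing table
#'
#' Reads the documented forcing dialect: UTF-8 delimited text with header
#' `timestamp,air_temp_C,precip_mm,rh_pct,sw_Wm2,wind_ms,pressure_kPa,co2_ppm`
#' and ISO-8601 timestamps on a 365-day calendar. Gaps of up to 3 hours are
#' filled by linear interpolation (precipitation filled with 0); longer gaps,
#' duplicated or non-monotone timestamps are rejected with the offending
#' timestamp named.
#'
#' @param path path to the file
#' @return a [meteo_forcing]
#' @export
read_forcing_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  dialect <- c("timestamp", "air_temp_C", "precip_mm", "rh_pct", "sw_Wm2",
               "wind_ms", "pressure_kPa", "co2_ppm")
  missing_cols <- setdiff(dialect, names(raw))
  if (length(missing_cols))
    stop("forcing file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[dialect]
  year0 <- as.integer(substr(raw$timestamp[1], 1, 4))
  h <- .timestamp_to_hour(raw$timestamp, year0)
  bad <- which(is.na(h))
  if (length(bad))
    stop("invalid timestamp at row ", bad[1], ": ", raw$timestamp[bad[1]])
  dh <- diff(h)
  if (any(dh <= 0)) {
    i <- which(dh <= 0)[1]
    stop(if (dh[i] == 0) "duplicated" else "non-monotone",
         " timestamp at row ", i + 1, ": ", raw$timestamp[i + 1])
  }
  if (any(dh > 4)) {
    i <- which(dh > 4)[1]
    stop("gap longer than 3 h after ", raw$timestamp[i],
         " (", dh[i] - 1, " missing hours)")
  }
  hh <- seq(h[1], h[length(h)])
  vals <- vapply(dialect[-1], function(cn) {
    v <- as.numeric(raw[[cn]])
    if (cn == "precip_mm") {
      out <- rep(0, length(hh)); out[match(h, hh)] <- v; out
    } else stats::approx(h, v, xout = hh)$y
  }, numeric(length(hh)))
  df <- data.frame(timestamp = .hour_to_timestamp(hh, year0),
                   air_temp = vals[, "air_temp_C"],
                   precip = vals[, "precip_mm"],
                   rel_humidity = vals[, "rh_pct"],
                   sw_down = vals[, "sw_Wm2"],
                   wind = vals[, "wind_ms"],
                   pressure = vals[, "pressure_kPa"],
                   co2_atm = vals[, "co2_ppm"], stringsAsFactors = FALSE)
  validate_forcing(.new_meteo_forcing(df, year0))
}

#' Write an hourly forcing table
#'
#' Writes the same dialect [read_forcing_table()] reads. Numbers are written
#' with 17 significant digits so a read/write round trip reproduces the
#' numeric content exactly.
#'
#' @param forcing a [meteo_forcing]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_forcing <- function(forcing, path) {
  validate_forcing(forcing)
  fmt <- function(x) sprintf("%.17g", x)
  out <- data.frame(timestamp = forcing$timestamp,
                    air_temp_C = fmt(forcing$air_temp),
                    precip_mm = fmt(forcing$precip),
                    rh_pct = fmt(forcing$rel_humidity),
                    sw_Wm2 = fmt(forcing$sw_down),
                    wind_ms = fmt(forcing$wind),
                    pressure_kPa = fmt(forcing$pressure),
                    co2_ppm = fmt(forcing$co2_atm),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.meteo_forcing <- function(x, ...) {
  cat("<meteo_forcing> ", nrow(x), " hourly records (",
      sprintf("%.2f", nrow(x) / 8760), " yr), ",
      x$timestamp[1], " .. ", x$timestamp[nrow(x)], "\n", sep = "")
  cat(sprintf("  mean T %.1f degC | total precip %.0f mm | mean CO2 %.0f ppm\n",
              mean(x$air_temp), sum(x$precip), mean(x$co2_atm)))
  invisible(x)
}
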