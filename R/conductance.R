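# Eggshell water-vapor conductance from daily mass-loss series, with
# regression QC, species aggregation, egg-volume allometry and elevation
# banding. Conductance G_H2O (mg d^-1 torr^-1) is the daily water-loss rate
# divided by the vapor-pressure difference across the shell; in a silica-gel
# desiccator the ambient humidity is ~0, so dP equals the saturation vapor
# pressure at the egg's temperature.

TORR_PER_HPA <- 0.7500616827

#' Saturation vapor pressure of water, in torr
#'
#' Arden Buck equation over liquid water, converted from hPa to torr.
#' At 25 C this evaluates to ~23.77 torr.
#'
#' @param temp_c Temperature in Celsius, in `[-10, 60]`.
#' @return Saturation vapor pressure (torr); strictly increasing in `temp_c`.
#' @export
#' @examples
#' saturation_vapor_pressure(25)
saturation_vapor_pressure <- function(temp_c) {
  if (any(!is.finite(temp_c)) || any(temp_c < -10) || any(temp_c > 60))
    stop("temperature out of supported range [-10, 60] C")
  hpa <- 6.1121 * exp((18.678 - temp_c / 234.5) * (temp_c / (257.14 + temp_c)))
  hpa * TORR_PER_HPA
}

#' Daily mass-loss rate of an egg by ordinary least squares
#'
#' Regresses mass (converted g -> mg) on day. The slope is kept signed
#' (mass loss gives a negative slope); `M_H2O` downstream is its magnitude.
#'
#' @param day Numeric day indices, strictly increasing, length >= 4.
#' @param mass_g Masses in grams (> 0).
#' @return List: `slope_mg_day` (signed), `intercept_mg`, `r_squared`.
#' @export
mass_loss_rate <- function(day, mass_g) {
  if (length(day) < 4) stop("need >= 4 time points")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(mass_g <= 0)) stop("masses must be positive")
  if (stats::var(day) == 0) stop("zero variance in day")
  mg <- mass_g * 1000
  fit <- stats::lm(mg ~ day)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mg - mean(mg))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < 1e-9 * mean(mg)) slope <- 0   # flat series: exact zero
  list(slope_mg_day = slope,
       intercept_mg = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Water-vapor conductance from a fitted mass-loss slope
#'
#' `G_H2O = |slope| / dP` for a mass-losing egg (negative slope). `dP`
#' (torr) is taken from [saturation_vapor_pressure()] at `temp_c` unless
#' `delta_p_torr` overrides it (e.g. the 23.77-torr standard used for
#' cross-study comparability).
#'
#' @param slope_mg_day Signed OLS slope in mg/day; must be negative.
#' @param temp_c Egg/chamber temperature in C.
#' @param delta_p_torr Optional explicit vapor-pressure difference (torr).
#' @return Conductance in mg day^-1 torr^-1.
#' @export
water_vapor_conductance <- function(slope_mg_day, temp_c = NULL,
                                    delta_p_torr = NULL) {
  if (!is.finite(slope_mg_day)) stop("slope must be finite")
  if (slope_mg_day >= 0) stop("egg not losing mass (slope >= 0)")
  dp <- if (!is.null(delta_p_torr)) delta_p_torr
        else if (!is.null(temp_c)) saturation_vapor_pressure(temp_c)
        else stop("supply temp_c or delta_p_torr")
  if (dp <= 0) stop("delta_p must be positive")
  abs(slope_mg_day) / dp
}

#' Quality control for one egg's mass-loss regression
#'
#' An egg passes QC when the mass-on-day regression has R^2 > 0.8, the raw
#' slope is negative, and no single between-day drop exceeds
#' `max_drop_mult` times the typical daily loss (a proxy for unusual weight
#' loss from eggshell fracture). The typical daily loss is the median of the
#' per-interval drops: a fracture step inflates the OLS slope itself, so the
#' regression slope would under-flag mid-series fractures, while the median
#' drop is resistant to a single step.
#'
#' @param day,mass_g Series as in [mass_loss_rate()].
#' @param r2_min Minimum R^2 (default 0.8, exclusive).
#' @param max_drop_mult Fracture-proxy multiple of the typical daily loss.
#' @return List: `pass` (logical), `reasons` (character vector of codes among
#'   "low_r2", "nonnegative_slope", "fracture_suspect"), plus the regression
#'   fields of [mass_loss_rate()].
#' @export
qc_egg <- function(day, mass_g, r2_min = 0.8, max_drop_mult = 5) {
  reg <- mass_loss_rate(day, mass_g)
  reasons <- character(0)
  if (reg$r_squared <= r2_min) reasons <- c(reasons, "low_r2")
  if (reg$slope_mg_day >= 0) reasons <- c(reasons, "nonnegative_slope")
  daily_drop <- -diff(mass_g * 1000) / diff(day)   # positive = loss, mg/day
  typical_loss <- stats::median(daily_drop)
  if (typical_loss > 0 && any(daily_drop > max_drop_mult * typical_loss))
    reasons <- c(reasons, "fracture_suspect")
  c(list(pass = length(reasons) == 0, reasons = reasons), reg)
}

#' Per-egg conductance table from a long-format mass-series data.frame
#'
#' Expects columns `egg_id`, `species`, `station`, `elevation_m`, `temp_c`,
#' `day`, `mass_g`. Computes the regression, QC, and conductance per egg.
#'
#' @param mass_df Long-format data.frame of daily masses.
#' @param delta_p_mode "temperature" (per-egg saturation pressure at its
#'   chamber temperature) or "standard" (fixed `standard_delta_p`).
#' @param standard_delta_p Fixed dP in torr for `"standard"` mode.
#' @param r2_min,max_drop_mult QC settings, see [qc_egg()].
#' @return data.frame with one row per egg: species, station, elevation_m,
#'   m_h2o_mg_day (positive loss rate), delta_p_torr, g_h2o, r_squared,
#'   qc_pass, qc_reasons.
#' @export
conductance_table <- function(mass_df,
                              delta_p_mode = c("temperature", "standard"),
                              standard_delta_p = 23.77,
                              r2_min = 0.8, max_drop_mult = 5) {
  delta_p_mode <- match.arg(delta_p_mode)
  need <- c("egg_id", "species", "station", "elevation_m", "temp_c", "day", "mass_g")
  miss <- setdiff(need, colnames(mass_df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(split(mass_df, mass_df$egg_id), function(d) {
    d <- d[order(d$day), ]
    qc <- qc_egg(d$day, d$mass_g, r2_min = r2_min, max_drop_mult = max_drop_mult)
    dp <- if (delta_p_mode == "standard") standard_delta_p
          else saturation_vapor_pressure(d$temp_c[1])
    g <- if (qc$slope_mg_day < 0) abs(qc$slope_mg_day) / dp else NA_real_
    data.frame(egg_id = d$egg_id[1], species = d$species[1],
               station = d$station[1], elevation_m = d$elevation_m[1],
               temp_c = d$temp_c[1],
               m_h2o_mg_day = abs(qc$slope_mg_day),
               delta_p_torr = dp, g_h2o = g, r_squared = qc$r_squared,
               qc_pass = qc$pass,
               qc_reasons = paste(qc$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-mean conductance from per-egg records
#'
#' Averages QC-passing conductance values per species, using at most the
#' first `max_eggs` passing eggs in stable input order. Species with no
#' passing egg are dropped with a message.
#'
#' @param records Per-egg data.frame from [conductance_table()].
#' @param max_eggs Cap on eggs per species (default 3).
#' @return data.frame: species, station, elevation_m, g_h2o (mean),
#'   n_eggs (used).
#' @export
species_conductance <- function(records, max_eggs = 3) {
  keep <- records[records$qc_pass & is.finite(records$g_h2o), , drop = FALSE]
  dropped <- setdiff(unique(records$species), unique(keep$species))
  if (length(dropped))
    message("species with zero QC-passing eggs dropped: ",
            paste(dropped, collapse = ", "))
  rows <- lapply(split(keep, keep$species), function(d) {
    d <- utils::head(d, max_eggs)
    data.frame(species = d$species[1], station = d$station[1],
               elevation_m = d$elevation_m[1], g_h2o = mean(d$g_h2o),
               n_eggs = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Egg volume from external dimensions (Hoyt's formula)
#'
#' `V = 0.51 L W^2`, with length `L` and width `W` in centimeters and the
#' volume in cubic centimeters.
#'
#' @param length_cm Egg length (cm), `>= width_cm`.
#' @param width_cm Egg width (cm), `> 0`.
#' @export
egg_volume <- function(length_cm, width_cm) {
  if (any(width_cm <= 0) || any(length_cm < width_cm))
    stop("require L >= W > 0")
  0.51 * length_cm * width_cm^2
}

#' Size-correction by regression residuals on the log-log scale
#'
#' OLS of `y` on `x` (both expected already log-transformed); returns the
#' residuals keyed by species. When the slope is not significant at
#' `alpha`, `significant = FALSE` advises using absolute trait values
#' instead of residuals.
#'
#' @param y,x Named numeric vectors (same species set).
#' @param alpha Significance level for the slope.
#' @return List: `residuals` (named), `slope`, `intercept`, `r_squared`,
#'   `p_value`, `significant`.
#' @export
allometric_residuals <- function(y, x, alpha = 0.05) {
  labs <- intersect(names(y), names(x))
  if (length(labs) < 3) stop("need >= 3 shared species")
  y <- y[labs]; x <- x[labs]
  if (stats::var(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- sm$coefficients[2, 4]
  res <- stats::residuals(fit)
  names(res) <- labs
  list(residuals = res, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, significant = p < alpha)
}

#' Default elevation bands (m) for the Andean study design
#' @export
default_elevation_bands <- function() {
  list(lowland = c(340, 850), mid = c(1200, 2000), highland = c(2500, 3000))
}

#' Classify elevations into lowland / mid / highland bands
#'
#' Values inside a band take its label; values falling in the gaps between
#' bands are assigned to the nearest band boundary, with a warning.
#'
#' @param elevation_m Elevations in meters (>= 0).
#' @param bands Named list of `c(lower, upper)` bounds; must not overlap.
#' @return Factor of band labels, level order as in `bands`.
#' @export
elevation_category <- function(elevation_m, bands = default_elevation_bands()) {
  if (any(elevation_m < 0)) stop("elevation must be >= 0")
  nm <- names(bands)
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  if (any(hi[-length(hi)] >= lo[-1])) stop("bands overlap or are unordered")
  lab <- character(length(elevation_m))
  warned <- FALSE
  for (i in seq_along(elevation_m)) {
    e <- elevation_m[i]
    inside <- which(e >= lo & e <= hi)
    if (length(inside)) lab[i] <- nm[inside[1]]
    else {
      dist <- pmin(abs(e - lo), abs(e - hi))
      lab[i] <- nm[which.min(dist)]
      warned <- TRUE
    }
  }
  if (warned) warning("elevation(s) outside the defined bands assigned to the nearest band")
  factor(lab, levels = nm)
}
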