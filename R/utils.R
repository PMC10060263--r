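# Internal helpers: unit conversions and interval plumbing.

CM_PER_M <- 100
SECONDS_PER_YEAR <- 31557600  # Julian year, 365.25 d

# 1e-6 cm^2/s -> m^2/yr
D0_UNIT_TO_M2YR <- 1e-10 * SECONDS_PER_YEAR

.naInterval <- function() c(NA_real_, NA_real_)

.isInterval <- function(x) length(x) == 2L && all(is.finite(x))

.cm2m <- function(z) z / CM_PER_M

#' Dynamic viscosity of seawater
#'
#' Kukulka et al. (1987) polynomial for the dynamic viscosity of seawater as
#' a function of temperature, salinity and pressure, in centipoise. Used for
#' the Stokes-Einstein correction of infinite-dilution diffusivities from
#' pure water to in-situ seawater conditions.
#'
#' @param temperature degrees Celsius.
#' @param salinity practical salinity.
#' @param pressure bar.
#' @return dynamic viscosity, centipoise.
#' @examples
#' seawaterViscosity(25, 0, 1.013253)  # ~0.9 cP, pure water at 25 C
#' @export
seawaterViscosity <- function(temperature, salinity = 35, pressure = 1.013253) {
  t <- temperature; S <- salinity; P <- pressure
  1.7910 -
    t * (6.144e-02 - t * (1.4510e-03 - t * 1.6826e-05)) -
    1.5290e-04 * P + 8.3885e-08 * P^2 + 2.4727e-03 * S +
    (6.0574e-06 * P - 2.6760e-09 * P^2) * t +
    (t * (4.8429e-05 - t * (4.7172e-06 - t * 7.5986e-08))) * S
}

# Clamp an interval to [lo, hi]; returns NA pair if empty after clamping.
.clampInterval <- function(iv, lo, hi) {
  if (!.isInterval(iv)) return(.naInterval())
  out <- c(max(iv[1], lo), min(iv[2], hi))
  if (out[1] > out[2]) .naInterval() else out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
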