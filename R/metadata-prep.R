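#' @include AllClasses.R
NULL

#' Indoor reference constants for environmental variables
#'
#' Standard indoor climate values used to fill the weather variables on
#' days without outdoor activity: 20 degrees C, 40 % relative humidity,
#' 1013 hPa, 0 m/s wind speed, 0 degrees wind direction (NIST indoor
#' reference conditions).
#'
#' @return Named numeric vector over [envVariables()].
#' @export
#' @examples
#' indoorConstants()
indoorConstants <- function() {
  c(temperature = 20, relative_humidity = 40, pressure = 1013,
    wind_speed = 0, wind_direction = 0)
}

#' Impute indoor reference constants
#'
#' For every sample whose `outdoor` flag is `FALSE`, all five environmental
#' variables are *set* to the indoor constants — any recorded value is
#' overridden (overrides are reported via a message). Outdoor samples are
#' untouched. The operation is total and idempotent.
#'
#' @param env environmental data.frame with columns `sample_id`, `outdoor`
#'   and the five [envVariables()] (as from [environmentTable()] or
#'   [readEnvironmentTable()]).
#' @param constants named replacement values; defaults to
#'   [indoorConstants()].
#' @param quiet suppress the per-override messages.
#' @return `env` with indoor rows filled.
#' @export
imputeIndoorConstants <- function(env, constants = indoorConstants(),
                                  quiet = TRUE) {
  stopifnot(all(c("outdoor", .ENV_VARS) %in% colnames(env)))
  if (anyNA(env$outdoor))
    stop("outdoor flag must be defined for every sample")
  idx <- which(!env$outdoor)
  for (v in .ENV_VARS) {
    overridden <- idx[!is.na(env[[v]][idx]) & env[[v]][idx] != constants[[v]]]
    if (length(overridden) && !quiet)
      message("indoor constant overrides recorded ", v, " for ",
              length(overridden), " sample(s): ",
              paste(env$sample_id[overridden], collapse = ", "))
    env[[v]][idx] <- constants[[v]]
  }
  env
}

#' Fill remaining environmental gaps by interpolation
#'
#' Missing values are filled by linear interpolation against the calendar
#' day, independently per host and per variable; leading/trailing gaps take
#' the nearest observed value. Interpolation therefore never leaves the
#' observed value range of a variable within a host. A variable with no
#' observation at all for some host is an error naming both.
#'
#' @param env environmental data.frame with `host_id`, `day` and the five
#'   [envVariables()].
#' @return `env` with no missing values.
#' @export
interpolateMissing <- function(env) {
  stopifnot(all(c("host_id", "day", .ENV_VARS) %in% colnames(env)))
  for (h in unique(env$host_id)) {
    rows <- which(env$host_id == h)
    ord <- rows[order(env$day[rows])]
    for (v in .ENV_VARS) {
      y <- env[[v]][ord]
      obs <- !is.na(y)
      if (!any(obs))
        stop("variable '", v, "' is entirely missing for host '", h, "'")
      if (all(obs)) next
      if (sum(obs) == 1L) {
        env[[v]][ord] <- y[obs]   # single observation: nearest fill
        next
      }
      filled <- stats::approx(x = env$day[ord][obs], y = y[obs],
                              xout = env$day[ord], method = "linear",
                              rule = 2, ties = mean)$y
      env[[v]][ord] <- filled
    }
  }
  env
}

#' Standard-scale environmental variables
#'
#' Transforms each environmental variable to zero mean and unit standard
#' deviation (population convention by default, matching the common
#' machine-learning scaler), storing the per-variable centre and spread so
#' the transform is exactly invertible with [unscaleEnvironment()].
#' Zero-variance variables are mapped to all zeros and flagged rather than
#' raising an error.
#'
#' @param env environmental data.frame with the five [envVariables()]
#'   columns, no missing values (run [imputeIndoorConstants()] and
#'   [interpolateMissing()] first).
#' @param population logical; use the population (divide by n) rather than
#'   the sample standard deviation.
#' @return `env` with scaled variable columns and an attribute `"scaling"`:
#'   a data.frame with `variable`, `mean`, `sd` and `constant` (flag for
#'   zero-variance columns).
#' @export
standardScale <- function(env, population = TRUE) {
  stopifnot(all(.ENV_VARS %in% colnames(env)))
  scaling <- data.frame(variable = .ENV_VARS, mean = NA_real_,
                        sd = NA_real_, constant = FALSE)
  for (k in seq_along(.ENV_VARS)) {
    v <- .ENV_VARS[k]
    x <- env[[v]]
    if (anyNA(x))
      stop("variable '", v, "' still has missing values; impute and ",
           "interpolate before scaling")
    n <- length(x)
    m <- mean(x)
    s <- stats::sd(x)
    if (population && !is.na(s)) s <- s * sqrt((n - 1) / n)
    scaling$mean[k] <- m
    if (is.na(s) || s == 0) {
      scaling$sd[k] <- 1
      scaling$constant[k] <- TRUE
      env[[v]] <- rep(0, n)
    } else {
      scaling$sd[k] <- s
      env[[v]] <- (x - m) / s
    }
  }
  attr(env, "scaling") <- scaling
  env
}

#' Invert standard scaling
#'
#' @param env a data.frame produced by [standardScale()] (carrying its
#'   `"scaling"` attribute), or any data.frame plus an explicit `scaling`
#'   table.
#' @param scaling per-variable mean/sd table; defaults to the attribute.
#' @return data.frame on the original measurement scale.
#' @export
unscaleEnvironment <- function(env, scaling = attr(env, "scaling")) {
  if (is.null(scaling))
    stop("no scaling parameters supplied or attached")
  for (k in seq_len(nrow(scaling))) {
    v <- scaling$variable[k]
    env[[v]] <- if (scaling$constant[k]) rep(scaling$mean[k], nrow(env))
                else env[[v]] * scaling$sd[k] + scaling$mean[k]
  }
  attr(env, "scaling") <- NULL
  env
}

#' Run the full environmental preparation chain
#'
#' Convenience wrapper: indoor-constant imputation, then per-host linear
#' interpolation of remaining gaps, then standard scaling.
#'
#' @inheritParams imputeIndoorConstants
#' @inheritParams standardScale
#' @return Scaled environmental data.frame (see [standardScale()]).
#' @export
prepareEnvironment <- function(env, constants = indoorConstants(),
                               population = TRUE) {
  standardScale(interpolateMissing(imputeIndoorConstants(env, constants)),
                population = population)
}
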