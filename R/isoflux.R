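#' Estimate daily soil end-members from unamended control jars
#'
#' The soil end-member delta_soil for each soil and calendar day (day =
#' `floor(time_h / 24)`) is the arithmetic mean of all delta13C values
#' measured that day in that soil's unamended control jars. Days inside
#' the observed range with no control measurement are filled by linear
#' interpolation between the nearest bracketing days; days outside the
#' range take the nearest endpoint. Amendment end-members are bulk
#' constants passed through unchanged.
#'
#' @param measurements Tibble with `jar_id`, `time_h`, `flux`, `delta`.
#' @param jars Tibble with `jar_id`, `soil`, `amendment`, `replicate`.
#' @param amendment_deltas Named numeric vector of bulk amendment
#'   end-members (permil), e.g. `c(OM = 500, PyOM = 500)`.
#' @param min_separation Minimum |delta_soil - delta_amendment| (permil)
#'   tolerated on any day; smaller separations make the mixing model
#'   ill-conditioned and raise an error naming the soil and day.
#' @param gap_fill `"interpolate"` (default) or `"none"` (error on gaps).
#' @return An `end_member_series`: list with `table` (soil, day,
#'   delta_soil), `amendment_deltas`, `min_separation`.
#' @export
estimate_end_members <- function(measurements, jars, amendment_deltas,
                                 min_separation = 50,
                                 gap_fill = c("interpolate", "none")) {
  gap_fill <- match.arg(gap_fill)
  if (is.null(names(amendment_deltas)) || !all(nzchar(names(amendment_deltas)))) {
    stop("`amendment_deltas` must be a named numeric vector")
  }
  m <- dplyr::inner_join(measurements, jars, by = "jar_id")
  m$day <- floor(m$time_h / 24)
  out <- list()
  for (s in unique(jars$soil)) {
    ms <- m[m$soil == s, ]
    ctrl <- ms[ms$amendment == "soil", ]
    if (nrow(ctrl) == 0L) {
      stop("no unamended control jars for soil \"", s, "\"")
    }
    grid <- seq(min(ms$day), max(ms$day))
    daily <- dplyr::summarise(dplyr::group_by(ctrl, .data$day),
                              delta_soil = mean(.data$delta),
                              .groups = "drop")
    if (!all(grid %in% daily$day)) {
      if (gap_fill == "none") {
        stop("soil \"", s, "\" has days without control measurements: ",
             paste(setdiff(grid, daily$day), collapse = ", "))
      }
      filled <- stats::approx(daily$day, daily$delta_soil, xout = grid,
                              rule = 2)$y
    } else {
      filled <- daily$delta_soil[match(grid, daily$day)]
    }
    out[[s]] <- tibble::tibble(soil = s, day = grid, delta_soil = filled)
  }
  tab <- dplyr::bind_rows(out)
  for (a in names(amendment_deltas)) {
    sep <- abs(tab$delta_soil - amendment_deltas[[a]])
    bad <- which(sep < min_separation)
    if (length(bad) > 0L) {
      stop("end-member separation below ", min_separation,
           " permil for amendment \"", a, "\" in soil \"",
           tab$soil[bad[1]], "\" on day ", tab$day[bad[1]])
    }
  }
  structure(list(table = tab, amendment_deltas = amendment_deltas,
                 min_separation = min_separation),
            class = "end_member_series")
}

#' Two end-member mixing-model partition of a CO2 flux
#'
#' Solves `delta_measured = delta_soil * f_soil + delta_amendment *
#' f_amendment` with `f_soil + f_amendment = 1`:
#' `f_soil = (delta_measured - delta_amendment) /
#' (delta_soil - delta_amendment)`. The component fluxes satisfy
#' `flux_soil + flux_amendment = flux` exactly.
#'
#' @param delta_measured,flux Measured delta13C (permil) and total CO2-C
#'   flux; vectors recycle per R rules.
#' @param delta_soil,delta_amendment End-members (permil).
#' @param clip If `TRUE` (default), `f_soil` outside [0, 1] (possible
#'   under measurement noise) is truncated and the truncation counted in
#'   attribute `"n_clipped"`; never silent.
#' @param min_separation Minimum end-member separation (permil).
#' @return Tibble with `f_soil`, `flux_soil`, `flux_amendment`,
#'   `clipped`; attribute `n_clipped`.
#' @export
partition_flux <- function(delta_measured, flux, delta_soil,
                           delta_amendment, clip = TRUE,
                           min_separation = 50) {
  if (!all(is.finite(delta_measured)) || !all(is.finite(delta_soil)) ||
      !all(is.finite(delta_amendment))) {
    stop("non-finite delta13C value in mixing model inputs")
  }
  if (any(abs(delta_soil - delta_amendment) < min_separation)) {
    stop("end-members separated by less than ", min_separation,
         " permil; partitioning is ill-conditioned")
  }
  f <- (delta_measured - delta_amendment) / (delta_soil - delta_amendment)
  clipped <- f < 0 | f > 1
  if (clip) {
    f <- pmin(pmax(f, 0), 1)
  }
  fs <- f * flux
  out <- tibble::tibble(f_soil = f, flux_soil = fs,
                        flux_amendment = flux - fs,
                        clipped = clipped & clip)
  attr(out, "n_clipped") <- sum(out$clipped)
  out
}

#' Partition a full measurement set against estimated end-members
#'
#' Amended jars are partitioned against their soil's daily end-member and
#' their amendment's bulk end-member. Unamended control jars are assigned
#' `f_soil = 1` by construction (all their respiration is soil-derived).
#'
#' @param measurements,jars As in [estimate_end_members()].
#' @param end_members An `end_member_series`.
#' @param clip Passed to [partition_flux()].
#' @return Tibble: jar_id, soil, amendment, replicate, time_h, flux,
#'   delta, f_soil, flux_soil, flux_amendment, clipped; attribute
#'   `n_clipped` reports the clipping count.
#' @export
partition_measurements <- function(measurements, jars, end_members,
                                   clip = TRUE) {
  stopifnot(inherits(end_members, "end_member_series"))
  m <- dplyr::inner_join(measurements, jars, by = "jar_id")
  if (nrow(m) < nrow(measurements)) {
    stop("measurements reference jar ids missing from `jars`")
  }
  if (any(m$flux < 0)) stop("negative total flux in measurements")
  m$day <- floor(m$time_h / 24)
  m <- dplyr::left_join(m, end_members$table, by = c("soil", "day"))
  if (anyNA(m$delta_soil)) {
    stop("no soil end-member available for some (soil, day) cells")
  }
  is_ctrl <- m$amendment == "soil"
  m$f_soil <- NA_real_
  m$flux_soil <- NA_real_
  m$flux_amendment <- NA_real_
  m$clipped <- FALSE
  m$f_soil[is_ctrl] <- 1
  m$flux_soil[is_ctrl] <- m$flux[is_ctrl]
  m$flux_amendment[is_ctrl] <- 0
  n_clip <- 0L
  for (a in unique(m$amendment[!is_ctrl])) {
    if (!a %in% names(end_members$amendment_deltas)) {
      stop("no amendment end-member provided for \"", a, "\"")
    }
    idx <- which(m$amendment == a)
    part <- partition_flux(m$delta[idx], m$flux[idx], m$delta_soil[idx],
                           end_members$amendment_deltas[[a]], clip = clip,
                           min_separation = end_members$min_separation)
    m$f_soil[idx] <- part$f_soil
    m$flux_soil[idx] <- part$flux_soil
    m$flux_amendment[idx] <- part$flux_amendment
    m$clipped[idx] <- part$clipped
    n_clip <- n_clip + attr(part, "n_clipped")
  }
  out <- m[, c("jar_id", "soil", "amendment", "replicate", "time_h",
               "flux", "delta", "f_soil", "flux_soil", "flux_amendment",
               "clipped")]
  attr(out, "n_clipped") <- n_clip
  out
}

# cumulative trapezoid from t = 0, extending the first flux back to 0
cumtrapz0 <- function(time_h, flux) {
  t <- c(0, time_h)
  f <- c(flux[1], flux)
  cumsum(diff(t) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' Accumulate partitioned fluxes per jar
#'
#' Trapezoidal integration of each flux component over time, starting at
#' `t = 0` with the first measured flux extended backward (the first
#' measurement typically occurs up to a day after wet-up). Units: ug C
#' per g soil.
#'
#' @param partitioned Output of [partition_measurements()].
#' @param normalize_c0 Optional initial soil C content (ug C / g soil);
#'   when given, cumulative values are divided by it (per-g-initial-C
#'   normalization).
#' @return Input tibble with `cum_soil`, `cum_amendment`, `cum_total`
#'   columns added; each jar's series is non-decreasing.
#' @export
cumulate <- function(partitioned, normalize_c0 = NULL) {
  if (!is.null(normalize_c0) && normalize_c0 <= 0) {
    stop("`normalize_c0` must be > 0")
  }
  if (any(partitioned$flux_soil < 0) || any(partitioned$flux_amendment < 0)) {
    stop("negative component flux; partition with clip = TRUE first")
  }
  one <- function(df) {
    o <- order(df$time_h)
    df <- df[o, ]
    if (anyDuplicated(df$time_h)) {
      stop("duplicate time points for jar \"", df$jar_id[1], "\"")
    }
    df$cum_soil <- cumtrapz0(df$time_h, df$flux_soil)
    df$cum_amendment <- cumtrapz0(df$time_h, df$flux_amendment)
    df$cum_total <- df$cum_soil + df$cum_amendment
    if (!is.null(normalize_c0)) {
      df$cum_soil <- df$cum_soil / normalize_c0
      df$cum_amendment <- df$cum_amendment / normalize_c0
      df$cum_total <- df$cum_total / normalize_c0
    }
    df
  }
  dplyr::bind_rows(lapply(split(partitioned, partitioned$jar_id), one))
}

#' Summarize cumulative emissions per treatment
#'
#' Mean, standard error, and 95% CI (mean +/- 1.96 SE, the convention of
#' incubation figure legends) of a cumulative variable across replicate
#' jars, per (soil, amendment, time). Jars harvested before a time point
#' simply have no rows there and are excluded automatically. Groups with
#' a single jar return the mean with `se = NA` (flagged undefined).
#'
#' @param cumulated Output of [cumulate()].
#' @param value Column to summarize (default `"cum_soil"`, the
#'   nSOC-derived cumulative CO2-C).
#' @param conf_z Normal quantile for the per-group CI (default 1.96).
#' @return Tibble: soil, amendment, time_h, n, mean, se, ci_low, ci_high.
#' @export
summarize_treatment <- function(cumulated, value = "cum_soil",
                                conf_z = 1.96) {
  stopifnot(value %in% names(cumulated))
  out <- dplyr::summarise(
    dplyr::group_by(cumulated, .data$soil, .data$amendment, .data$time_h),
    n = dplyr::n(),
    mean = mean(.data[[value]]),
    se = ifelse(dplyr::n() >= 2,
                stats::sd(.data[[value]]) / sqrt(dplyr::n()), NA_real_),
    .groups = "drop")
  out$ci_low <- out$mean - conf_z * out$se
  out$ci_high <- out$mean + conf_z * out$se
  out
}
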