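# Trace container and slope/binning machinery.
#
# A trace is the probe record of one trial: a strictly increasing time base,
# an oxygen series in either % air saturation or kPa, the water conditions,
# and a phase label per sample (sealed_k / flush_k) marking the sealed
# measurement segments that slopes may be fitted to.

#' Construct an oxygen trace
#'
#' @param time_s numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param o2_value oxygen readings, all >= 0.
#' @param unit `"percent_sat"` or `"kpa"`.
#' @param cond a [water_conditions()] object.
#' @param phase optional character vector of phase labels per sample
#'   (`"sealed_1"`, `"flush_1"`, ...); may be added later with
#'   [label_phases()].
#' @return An object of class `o2_trace`: a data frame with columns
#'   `time_s`, `o2_value` and (if given) `phase`, plus `unit` and `cond`
#'   attributes.
#' @export
o2_trace <- function(time_s, o2_value, unit = c("percent_sat", "kpa"),
                     cond, phase = NULL) {
  unit <- match.arg(unit)
  if (length(time_s) != length(o2_value))
    stop("time_s and o2_value lengths differ", call. = FALSE)
  d <- diff(time_s)
  if (length(d) && any(d <= 0))
    stop(sprintf("time_s must be strictly increasing (first offence at row %d)",
                 which(d <= 0)[1] + 1L), call. = FALSE)
  if (any(!is.finite(o2_value)) || any(o2_value < 0))
    stop("o2_value must be finite and >= 0", call. = FALSE)
  df <- data.frame(time_s = as.numeric(time_s), o2_value = as.numeric(o2_value))
  if (!is.null(phase)) {
    stopifnot(length(phase) == nrow(df))
    df$phase <- as.character(phase)
  }
  structure(df, unit = unit, cond = as_water_conditions(cond),
            class = c("o2_trace", "data.frame"))
}

#' @export
print.o2_trace <- function(x, ...) {
  cat(sprintf("o2_trace: %d samples over %.1f s, unit=%s\n",
              nrow(x), diff(range(x$time_s)), attr(x, "unit")))
  invisible(x)
}

trace_unit <- function(trace) attr(trace, "unit")
trace_cond <- function(trace) attr(trace, "cond")

#' Oxygen series of a trace in kPa
#'
#' @param trace an [o2_trace()].
#' @return Numeric vector of PO2 in kPa (conversion skipped when the trace
#'   is already in kPa).
#' @export
trace_po2_kpa <- function(trace) {
  if (trace_unit(trace) == "kpa") trace$o2_value
  else percent_sat_to_kpa(trace$o2_value, trace_cond(trace))
}

#' Label sealed and flush phases from protocol timing
#'
#' Trace CSV files carry no phase column; the sealed/flush structure is
#' reconstructed from the trial protocol: `n` measurement periods of
#' `measure_duration` separated by flushes of `flush_duration`, with the
#' final sealed segment open-ended for hypoxia trials and a single sealed
#' segment for blanks.
#'
#' @param trace an [o2_trace()].
#' @param protocol a [trial_protocol()].
#' @return The trace with a `phase` column filled in.
#' @export
label_phases <- function(trace, protocol) {
  t <- trace$time_s
  phase <- character(length(t))
  if (protocol$trial_type == "blank") {
    phase[] <- "sealed_1"
  } else {
    meas <- protocol$measure_duration_min * 60
    flsh <- protocol$flush_duration_min * 60
    n <- protocol$n_measure_periods
    phase[] <- sprintf("sealed_%d", n)  # open-ended final segment
    start <- 0
    for (k in seq_len(n)) {
      in_meas <- t >= start & t < start + meas
      phase[in_meas] <- sprintf("sealed_%d", k)
      if (k < n) {
        in_flush <- t >= start + meas & t < start + meas + flsh
        phase[in_flush] <- sprintf("flush_%d", k)
      } else if (protocol$trial_type == "mmr") {
        phase[t >= start + meas] <- "end"
      }
      start <- start + meas + flsh
    }
  }
  trace$phase <- phase
  trace
}

sealed_segment <- function(trace, segment) {
  if (is.null(trace$phase))
    stop("trace has no phase labels; call label_phases() first", call. = FALSE)
  lab <- if (is.numeric(segment)) sprintf("sealed_%d", segment) else segment
  out <- trace[trace$phase == lab, , drop = FALSE]
  if (nrow(out) < 2)
    stop(sprintf("sealed segment '%s' has fewer than 2 samples", lab),
         call. = FALSE)
  out
}

#' Split a sealed segment into consecutive time bins
#'
#' Bins are consecutive, non-overlapping, left-closed intervals of `width`
#' seconds covering the segment from its first sample.  A trailing partial
#' bin shorter than `width/2` is dropped so bin counts are deterministic.
#'
#' @param trace an [o2_trace()] with phase labels.
#' @param width bin width in seconds; must be at least 3 sample intervals.
#' @param segment sealed segment id (integer) or phase label.
#' @return A list of data frames (one per bin) with columns `time_s`,
#'   `po2_kpa`; empty list with a warning if the segment is shorter than
#'   one bin.
#' @export
bin_trace <- function(trace, width, segment = 1L) {
  seg <- sealed_segment(trace, segment)
  dt <- stats::median(diff(seg$time_s))
  if (width < 3 * dt)
    stop("bin width must be at least 3 sample intervals", call. = FALSE)
  t0 <- seg$time_s[1]
  span <- seg$time_s[nrow(seg)] - t0
  if (span < width) {
    warning("segment shorter than one bin; returning no bins")
    return(list())
  }
  idx <- floor((seg$time_s - t0) / width)
  seg$po2_kpa <- trace_po2_kpa(seg)
  last <- max(idx)
  # trailing partial bin: keep if it spans at least width/2
  tail_span <- span - last * width
  keep_last <- tail_span >= width / 2
  bins <- split(seg[, c("time_s", "po2_kpa")], idx)
  if (!keep_last && length(bins) == last + 1) bins <- bins[-length(bins)]
  bins <- bins[vapply(bins, nrow, 1L) >= 3L]
  unname(bins)
}

#' Least-squares O2 decline slope and mass-specific uptake for one bin
#'
#' Ordinary least squares of PO2 (kPa) on time; the negative slope is scaled
#' to a whole-chamber uptake with the solubility `beta` and effective volume
#' (chamber volume minus animal volume at tissue density 1 g/mL), then
#' divided by mass:
#' `mo2 = -slope * beta * V_eff / mass` (umol O2 g^-1 h^-1).
#'
#' Bins whose slope is positive beyond noise tolerance (more than 2 standard
#' errors above zero, or exactly positive when noiseless) are flagged rather
#' than dropped; downstream alpha estimation ignores flagged bins.
#'
#' @param bin data frame with columns `time_s` and `po2_kpa` (>= 3 rows).
#' @param chamber a [chamber_spec()].
#' @param mass animal mass in g (use 0 for a blank).
#' @param cond a [water_conditions()] object.
#' @return A one-row data frame (`t_mid_s`, `po2_kpa`, `slope_kpa_h`,
#'   `mo2_umol_g_h`, `n`, `r2`, `flag`).
#' @export
slope_mo2 <- function(bin, chamber, mass, cond) {
  if (nrow(bin) < 3) stop("need at least 3 points per bin", call. = FALSE)
  fit <- ols_slope(bin$time_s / 3600, bin$po2_kpa)  # slope in kPa/h
  beta <- solubility_per_kpa(cond)
  v_eff <- effective_volume(chamber, mass)
  mo2 <- -fit$slope * beta * v_eff / max(mass, .Machine$double.eps)
  flagged <- fit$slope > 0 && (fit$se == 0 || fit$slope > 2 * fit$se)
  data.frame(t_mid_s = mean(range(bin$time_s)),
             po2_kpa = mean(bin$po2_kpa),
             slope_kpa_h = fit$slope,
             mo2_umol_g_h = mo2,
             n = nrow(bin),
             r2 = fit$r2,
             flag = flagged)
}

# closed-form simple OLS; avoids lm() overhead in per-bin loops
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  res <- y - my - slope * (x - mx)
  sst <- sum((y - my)^2)
  sse <- sum(res^2)
  se <- if (n > 2) sqrt(sse / (n - 2) / sxx) else 0
  r2 <- if (sst > 0) 1 - sse / sst else 1
  list(slope = slope, intercept = my - slope * mx, se = se, r2 = r2)
}

effective_volume <- function(chamber, mass_g) {
  v <- chamber$volume_L - mass_g / 1000  # tissue density 1 g/mL
  if (v <= 0) stop("animal volume exceeds chamber volume", call. = FALSE)
  v
}

#' Bin slopes for a whole sealed segment
#'
#' Equivalent to [bin_trace()] followed by [slope_mo2()] on every bin, but
#' computed with grouped sums so that bin-width scans over long hypoxia
#' segments stay fast.
#'
#' @inheritParams bin_trace
#' @inheritParams slope_mo2
#' @return Data frame of per-bin rows (possibly 0 rows).
#' @export
segment_bin_slopes <- function(trace, width, segment, chamber, mass, cond) {
  empty <- data.frame(t_mid_s = numeric(), po2_kpa = numeric(),
                      slope_kpa_h = numeric(), mo2_umol_g_h = numeric(),
                      n = integer(), r2 = numeric(), flag = logical())
  seg <- sealed_segment(trace, segment)
  dt <- stats::median(diff(seg$time_s))
  if (width < 3 * dt)
    stop("bin width must be at least 3 sample intervals", call. = FALSE)
  t0 <- seg$time_s[1]
  span <- seg$time_s[nrow(seg)] - t0
  if (span < width) {
    warning("segment shorter than one bin; returning no bins")
    return(empty)
  }
  idx <- floor((seg$time_s - t0) / width)
  last <- max(idx)
  if (span - last * width < width / 2) idx[idx == last] <- -1L  # drop tail
  keep <- idx >= 0L
  x <- seg$time_s[keep] / 3600
  y_all <- if (trace_unit(trace) == "kpa") seg$o2_value
           else percent_sat_to_kpa(seg$o2_value, trace_cond(trace))
  y <- y_all[keep]
  g <- idx[keep] + 1L
  n <- as.vector(rowsum(rep(1, length(g)), g))
  sx <- as.vector(rowsum(x, g)); sy <- as.vector(rowsum(y, g))
  sxx <- as.vector(rowsum(x * x, g)); sxy <- as.vector(rowsum(x * y, g))
  syy <- as.vector(rowsum(y * y, g))
  Sxx <- sxx - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- syy - sy^2 / n
  slope <- Sxy / Sxx
  sse <- pmax(Syy - slope * Sxy, 0)
  se <- ifelse(n > 2, sqrt(sse / (n - 2) / Sxx), 0)
  r2 <- ifelse(Syy > 0, 1 - sse / Syy, 1)
  tmn <- tapply(x * 3600, g, function(v) mean(range(v)))
  beta <- solubility_per_kpa(cond)
  v_eff <- effective_volume(chamber, mass)
  mo2 <- -slope * beta * v_eff / max(mass, .Machine$double.eps)
  out <- data.frame(t_mid_s = as.vector(tmn),
                    po2_kpa = sy / n,
                    slope_kpa_h = slope,
                    mo2_umol_g_h = mo2,
                    n = as.integer(n),
                    r2 = r2,
                    flag = slope > 0 & (se == 0 | slope > 2 * se))
  out[out$n >= 3L, , drop = FALSE]
}

#' Microbial background rate from a blank trace
#'
#' One least-squares slope over the whole blank period.  Returned both in
#' the nominal-mass convention (rate referenced to W = 0.0001 g, the
#' convention used when a blank is pushed through mass-specific software)
#' and as a whole-chamber rate in umol O2/h, which is the dimensionally
#' meaningful quantity used for subtraction.
#'
#' @param blank an [o2_trace()] of the empty sealed chamber; a warning is
#'   issued if it is shorter than 10 minutes.
#' @param chamber a [chamber_spec()].
#' @param cond a [water_conditions()] object.
#' @return List with `rate_chamber_umol_h`, `rate_nominal_mass_umol_g_h`
#'   (whole-chamber rate / 0.0001 g), `slope_kpa_h` and `r2`.
#' @export
microbial_rate <- function(blank, chamber, cond) {
  if (diff(range(blank$time_s)) < 600)
    warning("blank trace shorter than 10 min; background estimate unstable")
  po2 <- trace_po2_kpa(blank)
  fit <- ols_slope(blank$time_s / 3600, po2)
  beta <- solubility_per_kpa(cond)
  rate <- -fit$slope * beta * chamber$volume_L  # empty chamber: V_eff = V
  list(rate_chamber_umol_h = rate,
       rate_nominal_mass_umol_g_h = rate / 1e-4,
       slope_kpa_h = fit$slope,
       r2 = fit$r2)
}

#' Subtract microbial background from bin rates
#'
#' The whole-chamber microbial rate is divided by animal mass and removed
#' from every bin's mass-specific rate.  Corrected rates that would go
#' negative are floored at zero and flagged.
#'
#' @param bins data frame from [segment_bin_slopes()].
#' @param microbial_chamber_umol_h whole-chamber background rate, umol/h
#'   (>= 0).
#' @param mass animal mass, g.
#' @return `bins` with `mo2_umol_g_h` corrected and the flag column updated.
#' @export
subtract_background <- function(bins, microbial_chamber_umol_h, mass) {
  stopifnot(microbial_chamber_umol_h >= 0)
  if (!nrow(bins)) return(bins)
  corr <- bins$mo2_umol_g_h - microbial_chamber_umol_h / mass
  neg <- corr < 0
  corr[neg] <- 0
  bins$mo2_umol_g_h <- corr
  bins$flag <- bins$flag | neg
  bins
}
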