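# Per-animal endpoints: MMR, oxygen supply capacity (alpha) and PcMax.
#
# alpha is estimated from the hypoxia trial as the mean of the three
# largest per-bin supply ratios alpha0 = MO2/PO2, after scanning a grid of
# bin widths and selecting, within the stable region of the scan, the
# width that jointly minimises alpha and the spread of its top three
# alpha0 values.  PcMax = MMR/alpha.

#' Maximum metabolic rate from one trial
#'
#' Each sealed measurement period yields one rate; MMR is the rate of the
#' period in which PO2 declined most rapidly.  Two granularities are
#' offered: `period_regression` (default) fits one least-squares slope to
#' the period's bin-mean PO2 values; `max_bin` takes the single largest
#' per-bin rate across all periods.  For hypoxia trials only the first
#' `measure_duration` of the final sealed segment counts as a measurement
#' period.
#'
#' @param trace an [o2_trace()] with phase labels (see [label_phases()]).
#' @param protocol the [trial_protocol()] of the trial.
#' @param chamber a [chamber_spec()].
#' @param mass animal mass, g.
#' @param cond a [water_conditions()] object.
#' @param width bin width, s (default 45).
#' @param microbial_chamber_umol_h whole-chamber background rate for
#'   subtraction, umol/h.
#' @param mode `"period_regression"` or `"max_bin"`.
#' @return List with `mmr` (umol O2 g^-1 h^-1), `per_period` (one rate per
#'   measurement period), `mode` and `width`.
#' @export
mmr_from_trial <- function(trace, protocol, chamber, mass, cond, width = 45,
                           microbial_chamber_umol_h = 0,
                           mode = c("period_regression", "max_bin")) {
  mode <- match.arg(mode)
  n_per <- protocol$n_measure_periods
  meas_s <- protocol$measure_duration_min * 60
  beta <- solubility_per_kpa(cond)
  v_eff <- effective_volume(chamber, mass)
  per_period <- rep(NA_real_, n_per)
  any_usable <- FALSE
  for (k in seq_len(n_per)) {
    bins <- segment_bin_slopes(trace, width, k, chamber, mass, cond)
    if (!nrow(bins)) next
    # hypoxia continuation: restrict the final segment to its measurement
    # period so MMR is not diluted by the long depletion tail
    if (k == n_per && protocol$trial_type == "hypoxia") {
      t0 <- min(bins$t_mid_s) - width / 2
      bins <- bins[bins$t_mid_s <= t0 + meas_s, , drop = FALSE]
    }
    bins <- subtract_background(bins, microbial_chamber_umol_h, mass)
    usable <- bins[!bins$flag, , drop = FALSE]
    if (!nrow(usable)) next
    any_usable <- TRUE
    if (mode == "period_regression") {
      fit <- ols_slope(usable$t_mid_s / 3600, usable$po2_kpa)
      per_period[k] <- -fit$slope * beta * v_eff / mass -
        microbial_chamber_umol_h / mass
    } else {
      per_period[k] <- max(usable$mo2_umol_g_h)
    }
  }
  if (!any_usable)
    stop("no usable (unflagged) bins in any measurement period", call. = FALSE)
  list(mmr = max(per_period, na.rm = TRUE), per_period = per_period,
       mode = mode, width = width)
}

#' Fit the allometric mass-scaling relation MO2 = c * W^b
#'
#' Nonlinear least squares in the original (not log) scale, so large
#' animals are not down-weighted.  Levenberg-Marquardt iteration
#' initialised from the log-log OLS fit; convergence when the relative
#' change in the residual sum of squares falls below 1e-10 (at most 500
#' iterations).
#'
#' @param mass_g body masses, g (>= 3 distinct values).
#' @param mo2 mass-specific rates, umol O2 g^-1 h^-1.
#' @param common_mass_g reference mass for later correction, g
#'   (default 594.1).
#' @return An object of class `scaling_fit`: list with `c`, `b`,
#'   `common_mass_g`, `rss`, `n`, `iterations`, `converged`.
#' @export
fit_mass_scaling <- function(mass_g, mo2, common_mass_g = 594.1) {
  stopifnot(length(mass_g) == length(mo2))
  if (length(mass_g) < 3) stop("need at least 3 animals", call. = FALSE)
  if (length(unique(mass_g)) < 2)
    stop("masses must not all be identical", call. = FALSE)
  if (any(mass_g <= 0) || any(mo2 <= 0))
    stop("masses and rates must be positive", call. = FALSE)
  # init from log-log OLS (exact for noiseless power-law data)
  lf <- ols_slope(log(mass_g), log(mo2))
  theta <- c(c = exp(lf$intercept), b = lf$slope)
  rss_of <- function(th) sum((mo2 - th[1] * mass_g^th[2])^2)
  rss <- rss_of(theta)
  lambda <- 1e-3
  it <- 0L
  converged <- FALSE
  while (it < 500L) {
    it <- it + 1L
    f <- theta[1] * mass_g^theta[2]
    r <- mo2 - f
    J <- cbind(mass_g^theta[2], f * log(mass_g))
    A <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (try in 1:30) {
      delta <- tryCatch(solve(A + lambda * diag(diag(A)), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        if (cand[1] > 0 && abs(cand[2]) <= 1) {
          rss_new <- rss_of(cand)
          if (rss_new <= rss) { step_ok <- TRUE; break }
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # no improving step: at a minimum
    lambda <- max(lambda / 10, 1e-12)
    rel <- (rss - rss_new) / max(rss, .Machine$double.eps)
    theta <- cand
    rss <- rss_new
    if (rel < 1e-10) { converged <- TRUE; break }
  }
  if (!converged && it >= 500L)
    stop(sprintf(
      "mass-scaling fit did not converge (last iterate c=%.6g, b=%.6g, rss=%.6g)",
      theta[1], theta[2], rss), call. = FALSE)
  structure(list(c = unname(theta[1]), b = unname(theta[2]),
                 common_mass_g = common_mass_g, rss = rss,
                 n = length(mass_g), iterations = it, converged = TRUE),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: MO2 = %.4g * W^%.4g (n=%d, rss=%.3g, common mass %.1f g)\n",
              x$c, x$b, x$n, x$rss, x$common_mass_g))
  invisible(x)
}

#' Mass-correct a mass-specific rate to the common mass
#'
#' Mass-specific convention: `mo2 * (common_mass / mass)^b`.  Identity when
#' `b = 0` or `mass == common_mass`.  (The whole-animal convention would
#' use exponent `b - 1`; this package works throughout in mass-specific
#' rates.)
#'
#' @param mo2 mass-specific rate(s), umol O2 g^-1 h^-1.
#' @param mass_g body mass, g (> 0).
#' @param fit a [fit_mass_scaling()] result (or any list with `b` and
#'   `common_mass_g`).
#' @return Corrected rate(s).
#' @export
mass_correct <- function(mo2, mass_g, fit) {
  stopifnot(all(mass_g > 0))
  mo2 * (fit$common_mass_g / mass_g)^fit$b
}

#' Per-bin instantaneous supply ratios alpha0 = MO2 / PO2
#'
#' @param bins background-subtracted bin table from
#'   [segment_bin_slopes()]; flagged bins are ignored.
#' @param po2_floor_kpa bins with mean PO2 below this are excluded
#'   (guards the ratio near anoxia; default 0.5 kPa).
#' @return Data frame with `t_mid_s`, `po2_kpa`, `alpha0`.
#' @export
alpha0_series <- function(bins, po2_floor_kpa = 0.5) {
  if (!nrow(bins)) stop("empty bin table", call. = FALSE)
  use <- !bins$flag & bins$po2_kpa >= po2_floor_kpa
  out <- bins[use, , drop = FALSE]
  if (!nrow(out)) stop("no usable bins above the PO2 floor", call. = FALSE)
  data.frame(t_mid_s = out$t_mid_s, po2_kpa = out$po2_kpa,
             alpha0 = out$mo2_umol_g_h / out$po2_kpa)
}

#' Oxygen supply capacity from the top three alpha0 values
#'
#' @param alpha0 numeric vector of per-bin supply ratios (>= 3 values).
#' @return List with `alpha` (mean of the three largest alpha0), `top3`
#'   and `sd_top3`.
#' @export
estimate_alpha <- function(alpha0) {
  if (length(alpha0) < 3) stop("need at least 3 alpha0 values", call. = FALSE)
  top3 <- sort(alpha0, decreasing = TRUE)[1:3]
  list(alpha = mean(top3), top3 = top3, sd_top3 = stats::sd(top3))
}

#' Bin-width sensitivity scan for the alpha estimator
#'
#' Runs the full binned-slope -> background subtraction -> alpha0 -> top-3
#' pipeline on the hypoxia segment at each candidate width.
#'
#' @param trace labelled hypoxia [o2_trace()].
#' @param widths ascending bin widths, s
#'   (default `c(30, 45, 60, 90, 120, 180, 240, 300, 450, 600)`).
#' @param segment sealed segment holding the hypoxia data (default the
#'   final one).
#' @param chamber,mass,cond as elsewhere.
#' @param microbial_chamber_umol_h whole-chamber background rate, umol/h.
#' @param po2_floor_kpa passed to [alpha0_series()].
#' @return Data frame with one row per width: `width_s`, `alpha`,
#'   `sd_top3`, `n_bins`, `n_alpha0` (NA alpha where fewer than 3 usable
#'   bins).
#' @export
bin_width_scan <- function(trace, widths = default_scan_widths(),
                           segment = NULL, chamber, mass, cond,
                           microbial_chamber_umol_h = 0,
                           po2_floor_kpa = 0.5) {
  stopifnot(!is.unsorted(widths))
  if (is.null(segment)) {
    labs <- unique(trace$phase[startsWith(trace$phase, "sealed_")])
    segment <- labs[length(labs)]
  }
  rows <- lapply(widths, function(w) {
    bins <- segment_bin_slopes(trace, w, segment, chamber, mass, cond)
    bins <- subtract_background(bins, microbial_chamber_umol_h, mass)
    a <- tryCatch({
      a0 <- alpha0_series(bins, po2_floor_kpa)
      if (nrow(a0) >= 3) estimate_alpha(a0$alpha0) else NULL
    }, error = function(e) NULL)
    data.frame(width_s = w,
               alpha = if (is.null(a)) NA_real_ else a$alpha,
               sd_top3 = if (is.null(a)) NA_real_ else a$sd_top3,
               n_bins = nrow(bins),
               n_alpha0 = if (is.null(a)) 0L else
                 sum(!bins$flag & bins$po2_kpa >= po2_floor_kpa))
  })
  do.call(rbind, rows)
}

#' @rdname bin_width_scan
#' @export
default_scan_widths <- function() c(30, 45, 60, 90, 120, 180, 240, 300, 450, 600)

#' Select a bin width from a sensitivity scan
#'
#' The stable region is the longest contiguous run of widths over which
#' alpha changes by less than `plateau_tol` (relative) between neighbours.
#' Within it each width is scored by `rank(alpha) + rank(sd_top3)` and the
#' smallest rank sum wins, ties going to the smallest width, making
#' concrete the rule of minimising both alpha and the spread of its top
#' three alpha0.  If no two neighbouring widths agree to `plateau_tol`,
#' the global rank-sum minimum is used with a warning.
#'
#' @param scan data frame from [bin_width_scan()] (>= 3 non-NA widths).
#' @param plateau_tol relative change defining the plateau (default 0.02).
#' @return The selected width in seconds.
#' @export
select_bin_width <- function(scan, plateau_tol = 0.02) {
  scan <- scan[!is.na(scan$alpha), , drop = FALSE]
  if (nrow(scan) < 3) stop("need at least 3 widths with alpha estimates",
                           call. = FALSE)
  a <- scan$alpha
  ok <- abs(diff(a)) / a[-length(a)] < plateau_tol
  runs <- rle(ok)
  pick <- function(idx) {
    sub <- scan[idx, , drop = FALSE]
    score <- rank(sub$alpha, ties.method = "min") +
      rank(sub$sd_top3, ties.method = "min")
    sub$width_s[order(score, sub$width_s)][1]
  }
  if (!any(ok)) {
    warning("no stable region in bin-width scan; using global rank-sum minimum")
    return(pick(seq_len(nrow(scan))))
  }
  # all maximal-length stable runs; when several tie, score their union so
  # the minimise-alpha-and-spread rule decides between them
  best_len <- max(runs$lengths[runs$values])
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths == best_len)
  idx <- sort(unique(unlist(lapply(hit, function(i) {
    first_pair <- ends[i] - runs$lengths[i] + 1L
    first_pair:(ends[i] + 1L)  # pairs i..j cover widths i..j+1
  }))))
  pick(idx)
}

#' Critical oxygen partial pressure for maximum metabolism
#'
#' `pcmax = mmr_max / alpha`: the PO2 below which the highest observed
#' metabolic rate can no longer be supplied.
#'
#' @param mmr_max highest (mass-corrected) MMR across trials,
#'   umol O2 g^-1 h^-1 (> 0).
#' @param alpha oxygen supply capacity, umol O2 g^-1 h^-1 kPa^-1 (> 0).
#' @return PcMax in kPa.
#' @export
pcmax <- function(mmr_max, alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(mmr_max <= 0)) stop("mmr_max must be > 0", call. = FALSE)
  mmr_max / alpha
}

#' Full alpha estimate for one hypoxia trial
#'
#' Convenience driver: bin-width scan, width selection, then the top-3
#' estimate at the selected width.
#'
#' @inheritParams bin_width_scan
#' @param widths candidate widths for the scan.
#' @param plateau_tol passed to [select_bin_width()].
#' @return List with `alpha`, `top3`, `sd_top3`, `selected_width_s` and
#'   the full `scan` table.
#' @export
alpha_from_hypoxia <- function(trace, chamber, mass, cond,
                               microbial_chamber_umol_h = 0,
                               widths = default_scan_widths(),
                               po2_floor_kpa = 0.5, plateau_tol = 0.02,
                               segment = NULL) {
  scan <- bin_width_scan(trace, widths, segment, chamber, mass, cond,
                         microbial_chamber_umol_h, po2_floor_kpa)
  w <- select_bin_width(scan, plateau_tol)
  if (is.null(segment)) {
    labs <- unique(trace$phase[startsWith(trace$phase, "sealed_")])
    segment <- labs[length(labs)]
  }
  bins <- segment_bin_slopes(trace, w, segment, chamber, mass, cond)
  bins <- subtract_background(bins, microbial_chamber_umol_h, mass)
  a0 <- alpha0_series(bins, po2_floor_kpa)
  est <- estimate_alpha(a0$alpha0)
  c(est, list(selected_width_s = w, scan = scan))
}
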