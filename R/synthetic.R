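# Mechanistic trace simulator with known ground truth.
#
# The generating model: a chased animal sealed in a chamber removes oxygen
# at the lesser of its metabolic demand and its oxygen supply capacity,
#   uptake(t) = min(demand(t), alpha * PO2(t))        [umol O2 g^-1 h^-1]
#   demand(t) = smr + (mmr0 - smr) * exp(-t / tau)    [EPOC decay]
# Sealed-phase chamber dynamics:
#   dPO2/dt = -(uptake * mass + microbial * V_eff) / (beta * V_eff)
# with beta the solubility (umol L^-1 kPa^-1) and V_eff the chamber volume
# minus animal volume.  Flush phases relax PO2 exponentially toward the
# trial's start PO2 (time constant 60 s).  Sensor noise is additive
# Gaussian in % air-saturation space, the probe's native unit.

FLUSH_TAU_S <- 60

#' Animal model for trace simulation
#'
#' @param mass_g wet mass, g (> 0).
#' @param smr resting demand floor, umol O2 g^-1 h^-1 (0 < smr < mmr0).
#' @param mmr0 post-chase peak demand, umol O2 g^-1 h^-1.
#' @param alpha_true oxygen supply capacity, umol O2 g^-1 h^-1 kPa^-1 (> 0).
#' @param recovery_tau_h time constant of the exponential decay of excess
#'   post-exercise demand toward `smr`, hours (> 0). `Inf` gives constant
#'   demand `mmr0`.
#' @return An object of class `animal_model`.
#' @export
animal_model <- function(mass_g, smr, mmr0, alpha_true, recovery_tau_h = 1.5) {
  stopifnot(mass_g > 0, smr > 0, mmr0 > smr, alpha_true > 0,
            recovery_tau_h > 0)
  structure(list(mass_g = mass_g, smr = smr, mmr0 = mmr0,
                 alpha_true = alpha_true, recovery_tau_h = recovery_tau_h),
            class = "animal_model")
}

#' Trial protocol for simulation and phase labelling
#'
#' Defaults follow the chase/seal protocol: three 15-min sealed measurement
#' periods separated by ~4-min flushes; hypoxia trials stay sealed after the
#' last period until PO2 falls below 2 kPa; blanks are a single sealed hour.
#'
#' @param trial_type `"mmr"`, `"hypoxia"` or `"blank"`.
#' @param start_po2_kpa PO2 at the start of the trial and flush target, kPa.
#' @param n_measure_periods number of sealed measurement periods.
#' @param measure_duration_min minutes per sealed measurement period.
#' @param flush_duration_min minutes per flush.
#' @param end_po2_floor_kpa hypoxia stop threshold, kPa.
#' @param sample_interval_s probe sampling interval, s.
#' @param noise_sd_pct sensor noise SD in % air saturation.
#' @param dt_s integrator step, s (reduced to divide `sample_interval_s`
#'   evenly).
#' @return An object of class `trial_protocol`.
#' @export
trial_protocol <- function(trial_type = c("mmr", "hypoxia", "blank"),
                           start_po2_kpa = 21,
                           n_measure_periods = 3,
                           measure_duration_min = 15,
                           flush_duration_min = 4,
                           end_po2_floor_kpa = 2,
                           sample_interval_s = 1,
                           noise_sd_pct = 0.1,
                           dt_s = 0.2) {
  trial_type <- match.arg(trial_type)
  stopifnot(start_po2_kpa > end_po2_floor_kpa, end_po2_floor_kpa >= 0,
            n_measure_periods >= 1, measure_duration_min > 0,
            flush_duration_min > 0, sample_interval_s > 0,
            noise_sd_pct >= 0, dt_s > 0)
  structure(list(trial_type = trial_type, start_po2_kpa = start_po2_kpa,
                 n_measure_periods = n_measure_periods,
                 measure_duration_min = measure_duration_min,
                 flush_duration_min = flush_duration_min,
                 end_po2_floor_kpa = end_po2_floor_kpa,
                 sample_interval_s = sample_interval_s,
                 noise_sd_pct = noise_sd_pct, dt_s = dt_s),
            class = "trial_protocol")
}

#' Chamber specification
#'
#' @param volume_L chamber volume, litres (> 0).
#' @param microbial_rate_umol_L_h volumetric microbial background uptake,
#'   umol O2 L^-1 h^-1 (>= 0).
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(volume_L, microbial_rate_umol_L_h = 2) {
  stopifnot(volume_L > 0, microbial_rate_umol_L_h >= 0)
  structure(list(volume_L = volume_L,
                 microbial_rate_umol_L_h = microbial_rate_umol_L_h),
            class = "chamber_spec")
}

# Euler integration of one sealed phase.  Returns po2 and per-gram uptake
# at every integrator step (step k uses the state at its left endpoint, so
# sum(rate_k)*dt is an exact discrete mass balance against the PO2 drop).
integrate_sealed <- function(po2_0, t0_s, duration_s, animal, chamber, beta,
                             dt_s, stop_floor = NULL, max_s = 6 * 3600) {
  mass <- if (is.null(animal)) 0 else animal$mass_g
  v_eff <- chamber$volume_L - mass / 1000
  micro <- chamber$microbial_rate_umol_L_h * v_eff      # umol/h
  denom <- beta * v_eff                                 # umol/kPa
  dt_h <- dt_s / 3600
  n_max <- if (is.null(stop_floor)) ceiling(duration_s / dt_s)
           else ceiling(max_s / dt_s)
  t <- numeric(n_max); po2 <- numeric(n_max); up <- numeric(n_max)
  p <- po2_0
  for (k in seq_len(n_max)) {
    tk <- t0_s + (k - 1) * dt_s
    u <- 0
    if (!is.null(animal)) {
      dem <- animal$smr + (animal$mmr0 - animal$smr) *
        exp(-(tk / 3600) / animal$recovery_tau_h)
      u <- min(dem, animal$alpha_true * p)
    }
    t[k] <- tk; po2[k] <- p; up[k] <- u
    p <- p - dt_h * (u * mass + micro) / denom
    if (p < 0) p <- 0
    if (!is.null(stop_floor) && p <= stop_floor) {
      t <- t[seq_len(k)]; po2 <- po2[seq_len(k)]; up <- up[seq_len(k)]
      break
    }
  }
  list(time_s = t, po2_kpa = po2, uptake_umol_g_h = up, po2_end = p)
}

#' Simulate one respirometry trial
#'
#' Integrates the sealed/flush protocol for one animal in one chamber and
#' returns the noisy probe trace (in % air saturation) together with a
#' noiseless ground-truth record.
#'
#' @param animal an [animal_model()], or `NULL` for an empty chamber.
#' @param protocol a [trial_protocol()].
#' @param chamber a [chamber_spec()].
#' @param cond a [water_conditions()] object.
#' @param seed integer seed; identical seeds give identical traces.
#' @return List with elements `trace` (an [o2_trace()] with phase labels)
#'   and `truth` (data frame `time_s`, `po2_kpa` noiseless,
#'   `demand_umol_g_h`, `mo2_umol_g_h`, `supply_limited`, `phase`), the
#'   latter carrying attributes `onset_po2_kpa`/`onset_time_s` (first
#'   supply-limited sample) and `params`.
#' @export
simulate_trial <- function(animal, protocol, chamber, cond, seed) {
  if (!is.null(animal) && animal$mass_g / 1000 >= chamber$volume_L)
    stop("animal volume exceeds chamber volume", call. = FALSE)
  if (protocol$trial_type == "blank") animal <- NULL
  beta <- solubility_per_kpa(cond)
  n_sub <- max(1L, as.integer(round(protocol$sample_interval_s / protocol$dt_s)))
  dt <- protocol$sample_interval_s / n_sub

  meas_s <- protocol$measure_duration_min * 60
  flush_s <- protocol$flush_duration_min * 60
  n_per <- if (protocol$trial_type == "blank") 1L else protocol$n_measure_periods

  time_all <- list(); po2_all <- list(); up_all <- list(); phase_all <- list()
  p <- protocol$start_po2_kpa
  t_cursor <- 0
  for (k in seq_len(n_per)) {
    last <- k == n_per
    stop_floor <- if (last && protocol$trial_type == "hypoxia")
      protocol$end_po2_floor_kpa else NULL
    dur <- if (protocol$trial_type == "blank") meas_s else meas_s
    seg <- integrate_sealed(p, t_cursor, dur, animal, chamber, beta, dt,
                            stop_floor = stop_floor)
    time_all[[length(time_all) + 1L]] <- seg$time_s
    po2_all[[length(po2_all) + 1L]] <- seg$po2_kpa
    up_all[[length(up_all) + 1L]] <- seg$uptake_umol_g_h
    phase_all[[length(phase_all) + 1L]] <- rep(sprintf("sealed_%d", k),
                                               length(seg$time_s))
    t_cursor <- seg$time_s[length(seg$time_s)] + dt
    p <- seg$po2_end
    if (!last) {
      # flush: exponential relaxation toward the trial's start PO2
      tf <- seq(t_cursor, t_cursor + flush_s - dt, by = dt)
      pf <- protocol$start_po2_kpa +
        (p - protocol$start_po2_kpa) * exp(-(tf - t_cursor) / FLUSH_TAU_S)
      time_all[[length(time_all) + 1L]] <- tf
      po2_all[[length(po2_all) + 1L]] <- pf
      up_all[[length(up_all) + 1L]] <- rep(NA_real_, length(tf))
      phase_all[[length(phase_all) + 1L]] <- rep(sprintf("flush_%d", k),
                                                 length(tf))
      t_cursor <- tf[length(tf)] + dt
      p <- pf[length(pf)]
    }
  }
  time_s <- unlist(time_all); po2 <- unlist(po2_all)
  uptake <- unlist(up_all); phase <- unlist(phase_all)

  # demand trajectory and supply-limitation bookkeeping
  if (!is.null(animal)) {
    demand <- animal$smr + (animal$mmr0 - animal$smr) *
      exp(-(time_s / 3600) / animal$recovery_tau_h)
    limited <- !is.na(uptake) & (animal$alpha_true * po2 < demand)
  } else {
    demand <- rep(0, length(time_s))
    limited <- rep(FALSE, length(time_s))
  }

  keep <- seq(1L, length(time_s), by = n_sub)  # record at sample interval
  truth <- data.frame(time_s = time_s[keep], po2_kpa = po2[keep],
                      demand_umol_g_h = demand[keep],
                      mo2_umol_g_h = uptake[keep],
                      supply_limited = limited[keep],
                      phase = phase[keep])
  onset <- which(truth$supply_limited)[1]
  attr(truth, "onset_po2_kpa") <- if (is.na(onset)) NA_real_ else truth$po2_kpa[onset]
  attr(truth, "onset_time_s") <- if (is.na(onset)) NA_real_ else truth$time_s[onset]
  attr(truth, "params") <- list(animal = animal, protocol = protocol,
                                chamber = chamber, cond = cond, seed = seed,
                                beta_umol_L_kpa = beta, dt_s = dt)
  # full-resolution record for discrete mass-balance checks
  attr(truth, "steps") <- data.frame(time_s = time_s, po2_kpa = po2,
                                     mo2_umol_g_h = uptake, phase = phase)

  pct_clean <- kpa_to_percent_sat(truth$po2_kpa, cond)
  pct <- pct_clean + with_seed(seed, stats::rnorm(length(pct_clean), 0,
                                                  protocol$noise_sd_pct))
  pct[pct < 0] <- 0
  trace <- o2_trace(truth$time_s, pct, unit = "percent_sat", cond = cond,
                    phase = truth$phase)
  list(trace = trace, truth = truth)
}

#' Simulate a microbial background check (blank trial)
#'
#' One sealed hour (by default) in the empty chamber; the decline reflects
#' the volumetric microbial rate only.
#'
#' @param chamber a [chamber_spec()].
#' @param cond a [water_conditions()] object.
#' @param duration_h sealed duration, hours (> 0).
#' @param start_po2_kpa initial PO2, kPa.
#' @param seed integer seed.
#' @param sample_interval_s probe sampling interval, s.
#' @param noise_sd_pct sensor noise SD in % air saturation.
#' @return As [simulate_trial()].
#' @export
simulate_microbial_check <- function(chamber, cond, duration_h = 1,
                                     start_po2_kpa = 20.5, seed = 1,
                                     sample_interval_s = 1,
                                     noise_sd_pct = 0.1) {
  stopifnot(duration_h > 0)
  proto <- trial_protocol(trial_type = "blank", start_po2_kpa = start_po2_kpa,
                          n_measure_periods = 1,
                          measure_duration_min = duration_h * 60,
                          sample_interval_s = sample_interval_s,
                          noise_sd_pct = noise_sd_pct,
                          dt_s = sample_interval_s)
  simulate_trial(NULL, proto, chamber, cond, seed)
}

# deterministic per-trial seed stream from one master seed
seed_stream <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max, n))
}

#' Default cohort configuration
#'
#' The stated world emulated by [simulate_cohort()]: three salinity groups
#' (32, 16, 6 psu) of six animals each at 26 degC; per-group true supply
#' capacity means 0.56 / 0.60 / 0.68 (SD 0.05) umol O2 g^-1 h^-1 kPa^-1;
#' peak post-chase demand equal across groups (mean 8, SD 1 umol O2 g^-1
#' h^-1 at the 594.1 g reference mass, scaled as mass^-0.1); resting demand
#' a third of peak; masses lognormal truncated to the observed 160-1036 g
#' range; chambers of 9/25/40 L assigned by body size; microbial background
#' 2 umol O2 L^-1 h^-1.  Each animal receives MMR trials at 21.0 and 27.0
#' kPa, a hypoxia trial starting at 11.7 kPa (whose first three measurement
#' periods double as the low-PO2 MMR trial), and a blank.
#'
#' @param ... named overrides of any top-level element.
#' @return A nested list of generator parameters.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    groups = data.frame(salinity_psu = c(32, 16, 6), n = c(6L, 6L, 6L),
                        alpha_mean = c(0.56, 0.60, 0.68), alpha_sd = 0.05),
    temperature_C = 26,
    mmr0_mean = 8, mmr0_sd = 1,
    smr_fraction = 1 / 3,
    recovery_tau_h = 1.5,
    scaling_b = -0.1,
    common_mass_g = 594.1,
    mass_meanlog = log(500), mass_sdlog = 0.45,
    mass_range_g = c(160, 1036),
    chamber_breaks_g = c(300, 600),   # <=300 g: 9 L, <=600 g: 25 L, else 40 L
    chamber_volumes_L = c(9, 25, 40),
    microbial_rate_umol_L_h = 2,
    start_po2_kpa = c(21, 27, 11.7),  # last continues into hypoxia
    noise_sd_pct = 0.1,
    sample_interval_s = 1,
    dt_s = 0.2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown cohort_config fields: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  if (any(cfg$groups$alpha_mean <= 0) || any(cfg$groups$alpha_sd < 0) ||
      cfg$mmr0_mean <= 0 || cfg$mmr0_sd < 0 ||
      cfg$smr_fraction <= 0 || cfg$smr_fraction >= 1)
    stop("invalid cohort distribution parameters", call. = FALSE)
  cfg
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= lower)) x[x <= lower] <- stats::rnorm(sum(x <= lower), mean, sd)
  x
}

rlnorm_range <- function(n, meanlog, sdlog, range) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  while (any(x < range[1] | x > range[2])) {
    bad <- x < range[1] | x > range[2]
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  x
}

#' Simulate a full cohort with ground truth
#'
#' Draws animals per group from [cohort_config()] distributions, simulates
#' every trial, and (optionally) writes the trace/manifest/truth files in
#' the dialects read by the pipeline.
#'
#' @param config a [cohort_config()] list.
#' @param seed master integer seed; per-trial seeds are derived from it.
#' @param outdir optional directory; when given, writes `manifest.csv`,
#'   `truth.csv`, `generator_config.json` and one `trace_<trial_id>.csv`
#'   per trial.
#' @return List with `manifest` (data frame), `traces` (named list of
#'   [o2_trace()]), `truths` (named list), `truth_table` (per-animal ground
#'   truth) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1, outdir = NULL) {
  groups <- config$groups
  n_tot <- sum(groups$n)
  grp <- rep(groups$salinity_psu, groups$n)
  draws <- with_seed(seed, list(
    mass = rlnorm_range(n_tot, config$mass_meanlog, config$mass_sdlog,
                        config$mass_range_g),
    alpha = rnorm_trunc(n_tot, rep(groups$alpha_mean, groups$n),
                        rep(groups$alpha_sd, groups$n), lower = 0.1),
    mmr0_ref = rnorm_trunc(n_tot, config$mmr0_mean, config$mmr0_sd, lower = 1)))
  mass <- draws$mass; alpha <- draws$alpha; mmr0_ref <- draws$mmr0_ref
  mmr0 <- mmr0_ref * (mass / config$common_mass_g)^config$scaling_b
  smr <- mmr0 * config$smr_fraction
  vol <- config$chamber_volumes_L[
    findInterval(mass, config$chamber_breaks_g) + 1L]

  animal_id <- sprintf("A%02d", seq_len(n_tot))
  truth_table <- data.frame(
    animal_id = animal_id, group_psu = grp, mass_g = mass,
    chamber_volume_L = vol, alpha_true = alpha, mmr0_true = mmr0,
    smr_true = smr, pc_true_kpa = mmr0 / alpha)

  trial_types <- c("mmr", "mmr", "hypoxia", "blank")
  start_po2 <- c(config$start_po2_kpa[1], config$start_po2_kpa[2],
                 config$start_po2_kpa[3], NA)
  n_trials <- n_tot * length(trial_types)
  seeds <- seed_stream(seed, n_trials)

  manifest <- vector("list", n_trials)
  traces <- list(); truths <- list()
  idx <- 0L
  for (i in seq_len(n_tot)) {
    cond <- water_conditions(config$temperature_C, grp[i])
    chamber <- chamber_spec(vol[i], config$microbial_rate_umol_L_h)
    ani <- animal_model(mass[i], smr[i], mmr0[i], alpha[i],
                        config$recovery_tau_h)
    for (j in seq_along(trial_types)) {
      idx <- idx + 1L
      tt <- trial_types[j]
      trial_id <- sprintf("%s_%s", animal_id[i],
                          if (tt == "mmr") sprintf("mmr%g", start_po2[j]) else tt)
      if (tt == "blank") {
        sim <- simulate_microbial_check(
          chamber, cond, duration_h = 1,
          start_po2_kpa = po2_at_saturation(cond), seed = seeds[idx],
          sample_interval_s = config$sample_interval_s,
          noise_sd_pct = config$noise_sd_pct)
        sp <- po2_at_saturation(cond)
      } else {
        proto <- trial_protocol(trial_type = tt, start_po2_kpa = start_po2[j],
                                sample_interval_s = config$sample_interval_s,
                                noise_sd_pct = config$noise_sd_pct,
                                dt_s = config$dt_s)
        sim <- simulate_trial(ani, proto, chamber, cond, seeds[idx])
        sp <- start_po2[j]
      }
      traces[[trial_id]] <- sim$trace
      truths[[trial_id]] <- sim$truth
      manifest[[idx]] <- data.frame(
        trial_id = trial_id, animal_id = animal_id[i], group_psu = grp[i],
        salinity_psu = grp[i], temp_C = config$temperature_C,
        chamber_volume_L = vol[i], animal_mass_g = mass[i], trial_type = tt,
        start_po2_kpa = sp, trace_file = sprintf("trace_%s.csv", trial_id))
    }
  }
  manifest <- do.call(rbind, manifest)
  out <- list(manifest = manifest, traces = traces, truths = truths,
              truth_table = truth_table, config = config, seed = seed)
  if (!is.null(outdir)) write_cohort(out, outdir)
  invisible(out)
}
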