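# Pipeline driver: process traces, compute per-animal metrics, run the
# statistical layer, and write the fixed output files with a checksum
# manifest and a log of every default in force.

#' Run configuration
#'
#' @param input_dir directory holding `manifest.csv` and the trace CSVs.
#' @param outdir output directory for run artifacts.
#' @param seed master seed; per-stage seeds are derived from it and logged.
#' @param n_perm permutations for the statistical layer (default 10000).
#' @param mmr_mode `"period_regression"` or `"max_bin"`.
#' @param width fixed bin width for MMR slopes, s (default 45).
#' @param scan_widths candidate bin widths for the alpha scan.
#' @param common_mass_g reference mass for mass correction (default 594.1).
#' @param po2_floor_kpa alpha0 PO2 floor, kPa.
#' @param plateau_tol stable-region tolerance for bin-width selection.
#' @param alpha_mass_correct logical; also report the mass-corrected alpha
#'   (the raw per-gram alpha is always reported).
#' @param protocol named list of protocol defaults overriding
#'   [trial_protocol()] arguments (trial type and start PO2 always come
#'   from the manifest).
#' @param water named list of water defaults (`pressure_kPa`,
#'   `o2_fraction`); temperature and salinity always come from the
#'   manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, outdir, seed = 1, n_perm = 10000,
                       mmr_mode = c("period_regression", "max_bin"),
                       width = 45, scan_widths = default_scan_widths(),
                       common_mass_g = 594.1, po2_floor_kpa = 0.5,
                       plateau_tol = 0.02, alpha_mass_correct = TRUE,
                       protocol = list(), water = list()) {
  structure(list(input_dir = input_dir, outdir = outdir, seed = seed,
                 n_perm = n_perm, mmr_mode = match.arg(mmr_mode),
                 width = width, scan_widths = scan_widths,
                 common_mass_g = common_mass_g,
                 po2_floor_kpa = po2_floor_kpa, plateau_tol = plateau_tol,
                 alpha_mass_correct = alpha_mass_correct,
                 protocol = protocol, water = water),
            class = "run_config")
}

row_conditions <- function(row, config) {
  water_conditions(row$temp_C, row$salinity_psu,
                   pressure_kPa = config$water$pressure_kPa %||% 101.325,
                   o2_fraction = config$water$o2_fraction %||% 0.2095)
}

row_protocol <- function(row, config) {
  args <- config$protocol
  args$trial_type <- row$trial_type
  if (row$trial_type != "blank") args$start_po2_kpa <- row$start_po2_kpa
  do.call(trial_protocol, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the processing + metrics + statistics pipeline
#'
#' Reads the trial manifest and traces, estimates per-chamber microbial
#' background from blank trials, computes per-trial MMR and per-animal
#' alpha (with bin-width scan diagnostics), fits the cohort mass-scaling
#' relation, applies mass correction, computes PcMax, runs the group
#' summaries and permutation tests, and writes:
#' `metrics.csv`, `trials.csv`, `group_stats.csv`, `stats_report.json`,
#' `scan_<trial>.csv` per hypoxia trial, `run.log`, and
#' `output_manifest.csv` with an MD5 checksum per produced file.
#'
#' @param config a [run_config()].
#' @param stages subset of `c("process", "metrics", "stats")` to run
#'   (later stages require earlier ones and are run cumulatively).
#' @return Invisibly, a list with `metrics`, `trials`, `group_stats`,
#'   `stats_report`, `scans` and `files`.
#' @export
run_pipeline <- function(config, stages = c("process", "metrics", "stats")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("o2supply run at %s", format(Sys.time())),
                 sprintf("seed: %d", config$seed),
                 sprintf("mmr_mode: %s (defaults: period_regression over %g-s bin means)",
                         config$mmr_mode, config$width),
                 sprintf("common_mass_g: %g", config$common_mass_g),
                 sprintf("alpha0 PO2 floor: %g kPa; plateau tolerance: %g",
                         config$po2_floor_kpa, config$plateau_tol),
                 sprintf("n_perm: %d", config$n_perm),
                 "background subtraction: whole-chamber blank rate / animal mass",
                 "effective volume: chamber volume - mass/1000 (tissue density 1 g/mL)")
  manifest <- read_manifest(file.path(config$input_dir, "manifest.csv"),
                            dir = config$input_dir)

  ## ---- process: read traces, label phases, microbial background ----
  trials <- split(manifest, seq_len(nrow(manifest)))
  names(trials) <- manifest$trial_id
  traces <- list(); protos <- list()
  for (id in names(trials)) {
    row <- trials[[id]]
    cond <- row_conditions(row, config)
    tr <- read_trace(file.path(config$input_dir, row$trace_file), cond)
    proto <- row_protocol(row, config)
    traces[[id]] <- label_phases(tr, proto)
    protos[[id]] <- proto
  }
  # microbial background per animal (blank trial in the same chamber)
  animals <- unique(manifest$animal_id)
  micro <- stats::setNames(rep(0, length(animals)), animals)
  for (a in animals) {
    brow <- manifest[manifest$animal_id == a & manifest$trial_type == "blank", ]
    if (!nrow(brow)) {
      warning(sprintf(
        "animal %s has no blank trial: proceeding with ZERO background", a))
      log_lines <- c(log_lines, sprintf(
        "WARNING: no blank for %s; background set to 0", a))
      next
    }
    id <- brow$trial_id[1]
    mr <- microbial_rate(traces[[id]],
                         chamber_spec(brow$chamber_volume_L[1], 0),
                         row_conditions(brow[1, ], config))
    micro[a] <- max(0, mr$rate_chamber_umol_h)
  }
  out <- list(files = character())
  if (!"metrics" %in% stages && !"stats" %in% stages) {
    writeLines(log_lines, file.path(config$outdir, "run.log"))
    return(invisible(out))
  }

  ## ---- metrics: per-trial MMR, per-animal alpha, scaling, PcMax ----
  trial_rows <- list(); scans <- list()
  animal_rows <- list()
  for (a in animals) {
    arows <- manifest[manifest$animal_id == a & manifest$trial_type != "blank", ]
    if (!nrow(arows)) next
    mass <- arows$animal_mass_g[1]
    chamber <- chamber_spec(arows$chamber_volume_L[1], 0)
    mmr_by_trial <- list()
    alpha_est <- NULL
    for (i in seq_len(nrow(arows))) {
      row <- arows[i, ]
      id <- row$trial_id
      cond <- row_conditions(row, config)
      tr <- traces[[id]]
      proto <- protos[[id]]
      m <- mmr_from_trial(tr, proto, chamber, mass, cond,
                          width = config$width,
                          microbial_chamber_umol_h = micro[a],
                          mode = config$mmr_mode)
      # trial-mean animal rate over unflagged 45-s bins, for the share
      segs <- unique(tr$phase[startsWith(tr$phase, "sealed_")])
      allbins <- do.call(rbind, lapply(segs, function(s)
        segment_bin_slopes(tr, config$width, s, chamber, mass, cond)))
      allbins <- subtract_background(allbins, micro[a], mass)
      mean_rate <- mean(allbins$mo2_umol_g_h[!allbins$flag])
      share <- micro[a] / (mean_rate * mass + micro[a])
      trial_rows[[id]] <- data.frame(
        trial_id = id, animal_id = a, group_psu = row$group_psu,
        trial_type = row$trial_type, start_po2_kpa = row$start_po2_kpa,
        mmr_umol_g_h = m$mmr, mmr_mode = m$mode,
        microbial_chamber_umol_h = unname(micro[a]),
        microbial_share = share)
      mmr_by_trial[[sprintf("%g", row$start_po2_kpa)]] <- m$mmr
      if (row$trial_type == "hypoxia") {
        alpha_est <- alpha_from_hypoxia(
          tr, chamber, mass, cond, microbial_chamber_umol_h = micro[a],
          widths = config$scan_widths, po2_floor_kpa = config$po2_floor_kpa,
          plateau_tol = config$plateau_tol)
        scans[[id]] <- alpha_est$scan
      }
    }
    if (is.null(alpha_est)) {
      warning(sprintf("animal %s has no hypoxia trial; skipped", a))
      next
    }
    animal_rows[[a]] <- data.frame(
      animal_id = a, group_psu = arows$group_psu[1], mass_g = mass,
      mmr_raw_max = max(unlist(mmr_by_trial)),
      t(unlist(stats::setNames(
        mmr_by_trial, sprintf("mmr_%s", names(mmr_by_trial))))),
      alpha_raw = alpha_est$alpha, sd_top3 = alpha_est$sd_top3,
      selected_bin_width_s = alpha_est$selected_width_s)
  }
  trials_df <- do.call(rbind, trial_rows)
  metrics <- do.call(rbind, animal_rows)
  rownames(metrics) <- NULL

  # cohort mass scaling from all per-trial raw MMR values
  fit_df <- merge(trials_df, metrics[, c("animal_id", "mass_g")],
                  by = "animal_id")
  scaling <- fit_mass_scaling(fit_df$mass_g, fit_df$mmr_umol_g_h,
                              common_mass_g = config$common_mass_g)
  log_lines <- c(log_lines, sprintf(
    "mass scaling: c=%.4g b=%.4g (n=%d trials)", scaling$c, scaling$b,
    scaling$n))
  metrics$mmr_max_corrected <- mass_correct(metrics$mmr_raw_max,
                                            metrics$mass_g, scaling)
  metrics$alpha <- if (config$alpha_mass_correct)
    mass_correct(metrics$alpha_raw, metrics$mass_g, scaling)
  else metrics$alpha_raw
  metrics$pcmax_kpa <- pcmax(metrics$mmr_max_corrected, metrics$alpha)

  files <- character()
  wf <- function(fn, writer) { p <- file.path(config$outdir, fn)
    writer(p); files <<- c(files, p); p }
  wf("metrics.csv", function(p) write_metrics(metrics, p))
  wf("trials.csv", function(p) write_metrics(trials_df, p))
  for (id in names(scans))
    wf(sprintf("scan_%s.csv", id),
       function(p) utils::write.csv(scans[[id]], p, row.names = FALSE))

  out <- list(metrics = metrics, trials = trials_df, scaling = scaling,
              scans = scans, files = files)
  if (!"stats" %in% stages) {
    writeLines(log_lines, file.path(config$outdir, "run.log"))
    return(invisible(out))
  }

  ## ---- stats: summaries and permutation tests ----
  seeds <- seed_stream(config$seed, 64)
  si <- 0L; next_seed <- function() { si <<- si + 1L; seeds[si] }
  summ <- summarize_groups(
    metrics, endpoints = intersect(
      c("mmr_11.7", "mmr_21", "mmr_27", "mmr_max_corrected", "alpha",
        "pcmax_kpa"), names(metrics)))
  report <- list(config = list(seed = config$seed, n_perm = config$n_perm,
                               mmr_mode = config$mmr_mode,
                               common_mass_g = config$common_mass_g),
                 effects = summ$effects)
  # per-salinity ANOVA of trial MMR across PO2 treatments (+ Tukey)
  anovas <- list()
  for (g in unique(trials_df$group_psu)) {
    sub <- trials_df[trials_df$group_psu == g, ]
    mmr_c <- mass_correct(sub$mmr_umol_g_h,
                          fit_df$mass_g[match(sub$trial_id, fit_df$trial_id)],
                          scaling)
    po2 <- factor(sub$start_po2_kpa)
    if (nlevels(po2) < 2 || any(table(po2) < 2)) next
    an <- perm_anova_oneway(mmr_c, po2, n_perm = config$n_perm,
                            seed = next_seed())
    tk <- tukey_posthoc(mmr_c, po2, n_perm = min(config$n_perm, 2000),
                        seed = next_seed())
    lil <- lilliefors(mmr_c, n_mc = min(config$n_perm, 5000),
                      seed = next_seed())
    lev <- levene(mmr_c, po2, n_perm = min(config$n_perm, 2000),
                  seed = next_seed())
    anovas[[as.character(g)]] <- list(
      anova = unclass(an), tukey = tk, lilliefors = unclass(lil),
      levene = unclass(lev))
  }
  report$mmr_by_po2 <- anovas
  # regressions of endpoints on salinity across animals
  regs <- list()
  for (e in c("mmr_max_corrected", "alpha", "pcmax_kpa")) {
    if (!e %in% names(metrics)) next
    r <- perm_linreg(metrics$group_psu, metrics[[e]],
                     n_perm = config$n_perm, seed = next_seed())
    regs[[e]] <- unclass(r)
  }
  report$salinity_regressions <- regs

  gs <- summ$groups
  wf("group_stats.csv", function(p)
    utils::write.csv(gs, p, row.names = FALSE))
  wf("stats_report.json", function(p) write_report(report, p))
  out$group_stats <- gs
  out$stats_report <- report
  out$files <- files

  log_lines <- c(log_lines,
                 sprintf("stage seeds used: %s",
                         paste(seeds[seq_len(si)], collapse = " ")))
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  sums <- tools::md5sum(files)
  utils::write.csv(data.frame(file = basename(names(sums)), md5 = sums,
                              row.names = NULL),
                   file.path(config$outdir, "output_manifest.csv"),
                   row.names = FALSE)
  invisible(out)
}
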