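# End-to-end orchestration: simulate -> detect -> behavioural metrics ->
# EEG preprocessing -> time-frequency -> cell table -> hierarchical model ->
# contrasts, with one root seed split per stage and per participant.

#' Pipeline configuration
#'
#' Defaults follow the study design this pipeline models: 15-s baseline,
#' five 16-beat (1 Hz) or 51-beat (3.2 Hz) sequences with 5-s breaks,
#' 1-35 Hz EEG band-pass at 256 Hz, 11 Morlet wavelets over 12-32 Hz with
#' 3-5 cycles, 2/10/20-SD artefact rules, 30/70 epoch split, 99% HDI and a
#' 0.4-dB effect floor.
#'
#' @param conditions Condition labels to run (default all 8).
#' @param n_participants Number of simulated participants (default 5; the
#'   full study design has 17).
#' @param n_sequences Sequences per condition (default 5).
#' @param seed Root seed; all stage seeds derive from it.
#' @param truth A `tap_ground_truth` shared by all participants.
#' @param effect_specs Named list (by condition label) of
#'   `beta_effect_spec`s; unnamed conditions get a frequency-dependent
#'   default (slow: suppression then rebound at C3; fast: sustained
#'   suppression).
#' @param reference "laplacian" (default) or "average" for the power maps.
#' @param model_electrodes Electrode labels entering the hierarchical model
#'   (default: all montage channels).
#' @param mcmc list(chains, warmup, draws) for [fit_model()].
#' @param hdi_mass,floor_db Significance rule parameters (0.99, 0.4).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = names(build_condition_set()),
                            n_participants = 5, n_sequences = 5, seed = 1,
                            truth = tap_ground_truth(mean_phase_deg = 350,
                                                     iti_cv_target = 6),
                            effect_specs = list(),
                            reference = c("laplacian", "average"),
                            model_electrodes = NULL,
                            mcmc = list(chains = 2, warmup = 300, draws = 500),
                            hdi_mass = 0.99, floor_db = 0.4) {
  structure(
    list(conditions = conditions, n_participants = n_participants,
         n_sequences = n_sequences, seed = seed, truth = truth,
         effect_specs = effect_specs, reference = match.arg(reference),
         model_electrodes = model_electrodes, mcmc = mcmc,
         hdi_mass = hdi_mass, floor_db = floor_db),
    class = "pipeline_config"
  )
}

default_effect_spec <- function(condition) {
  if (condition$frequency_class == "slow") {
    beta_effect_spec(around_db = -1, after_db = 1, focus = "C3")
  } else {
    beta_effect_spec(around_db = -1, after_db = -1, focus = "C3")
  }
}

#' Process one synthetic participant-condition recording into cells
#'
#' Runs the complete single-recording chain: tap simulation, accelerometer
#' detection, retention rules, behavioural summary, EEG simulation,
#' band-pass, channel QC + interpolation, average reference (for artefact
#' masks), Laplacian (or average) power maps, baseline spectrum, tap-locked
#' epochs, dB normalization and window averaging.
#'
#' @param condition A `cue_condition`.
#' @param config A `pipeline_config`.
#' @param participant Participant index (used to derive seeds).
#' @return list(behaviour, cells, series, n_epochs) or NULL when the
#'   condition is excluded by the retention rules.
#' @export
process_participant_condition <- function(condition, config, participant) {
  seed_base <- config$seed * 10000L + participant * 100L +
    match(condition$label, names(build_condition_set()))
  schedule <- generate_cue_schedule(condition, config$n_sequences)
  sim <- simulate_taps(schedule, config$truth, seed = seed_base)

  mag <- accel_magnitude(sim$accel)
  prep <- preprocess_accel(mag, sim$accel$sample_rate)
  det <- detect_taps_by_sequence(prep$x, prep$fs, schedule)
  series <- apply_retention_rules(det, condition$cues_per_sequence,
                                  config$n_sequences)
  if (!series$condition_retained) return(NULL)
  keep_seqs <- which(series$retained)
  behaviour <- behaviour_summary(series$tap_times[keep_seqs],
                                 within_schedule(schedule, keep_seqs))
  behaviour$participant <- paste0("P", participant)
  behaviour$condition <- condition$label

  spec <- config$effect_specs[[condition$label]]
  if (is.null(spec)) spec <- default_effect_spec(condition)
  rec <- simulate_eeg(schedule, sim$tap_times, spec, seed = seed_base + 1L)
  rec <- bandpass_eeg(rec, downsample_to = NULL)
  flags <- flag_bad_channels(rec)
  if (any(flags)) rec <- interpolate_channels(rec, flags)
  rec_avg <- rereference_average(rec)
  rec_pow <- if (config$reference == "laplacian") {
    surface_laplacian(rec_avg)
  } else {
    rec_avg
  }
  fam <- build_wavelet_family(rec$sample_rate)
  tf_avg <- tf_power(rec_avg, fam)
  tf_use <- if (config$reference == "laplacian") tf_power(rec_pow, fam) else tf_avg

  isi <- condition$isi
  taps_used <- sort(unlist(series$tap_times[keep_seqs]))
  bl_defs <- baseline_epoch_defs(rec$sample_rate, schedule$baseline_window)
  tp_defs <- tap_epoch_defs(rec$sample_rate, taps_used, isi)
  defs <- rbind(bl_defs[c("i0", "i1", "type")], tp_defs[c("i0", "i1", "type")])
  keep <- reject_artefact_epochs(rec_avg, tf_avg, defs)
  keep_bl <- keep[defs$type == "baseline"]
  keep_tp <- keep[defs$type == "tap"]

  baseline <- segment_baseline(tf_use, bl_defs, keep_bl)
  epochs <- epoch_around_taps(tf_use, taps_used, isi, keep = keep_tp)
  epochs_db <- db_normalize(epochs, baseline)
  cells <- window_average(epochs_db, isi)
  cells$participant <- paste0("P", participant)
  cells$condition <- condition$label
  list(behaviour = behaviour, cells = cells, series = series,
       n_epochs = dim(epochs$power)[1])
}

# restrict a schedule to a subset of sequences (for behavioural pooling)
within_schedule <- function(schedule, seqs) {
  out <- schedule
  out$main_beats <- schedule$main_beats[seqs]
  out$secondary_beats <- schedule$secondary_beats[seqs]
  out$sequence_windows <- schedule$sequence_windows[seqs, , drop = FALSE]
  out
}

split_condition_label <- function(labels) {
  parts <- strsplit(labels, "-", fixed = TRUE)
  data.frame(
    modality = vapply(parts, `[`, character(1), 1),
    rhythmicity = vapply(parts, `[`, character(1), 2),
    frequency = vapply(parts, `[`, character(1), 3)
  )
}

#' Run the full synthetic pipeline
#'
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_bundle`: behavioural table, cell
#'   table, fitted models per window and per behavioural metric, contrast
#'   tables, circular-test table, manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  set <- build_condition_set()
  unknown <- setdiff(config$conditions, names(set))
  if (length(unknown)) stop("unknown conditions: ", paste(unknown, collapse = ", "))

  behaviour <- list(); cells <- list(); excluded <- character(0)
  for (p in seq_len(config$n_participants)) {
    for (lab in config$conditions) {
      res <- process_participant_condition(set[[lab]], config, p)
      if (is.null(res)) {
        excluded <- c(excluded, paste0("P", p, ":", lab))
        next
      }
      behaviour[[length(behaviour) + 1]] <- res$behaviour
      cells[[length(cells) + 1]] <- res$cells
    }
  }
  behaviour <- do.call(rbind, behaviour)
  cells <- do.call(rbind, cells)

  # cell tables per window -> Model 1 fits and contrasts
  if (!is.null(config$model_electrodes)) {
    cells_model <- cells[cells$channel %in% config$model_electrodes, ]
  } else {
    cells_model <- cells
  }
  fits_power <- list(); contrasts_power <- list()
  for (win in c("around", "after")) {
    tab <- cells_model[cells_model$window == win, ]
    tab <- cbind(split_condition_label(tab$condition),
                 data.frame(participant = tab$participant,
                            electrode = tab$channel, value = tab$value_db))
    fit <- fit_model(build_design(tab), chains = config$mcmc$chains,
                     warmup = config$mcmc$warmup, draws = config$mcmc$draws,
                     seed = config$seed + 7L)
    cmp_present <- comparisons_of_interest()
    fits_power[[win]] <- fit
    ok <- cmp_ok(cmp_present, unique(paste(tab$modality, tab$rhythmicity,
                                           tab$frequency, sep = "-")))
    contrasts_power[[win]] <- if (any(ok)) {
      do.call(rbind, lapply(which(ok), function(i) {
        ctab <- contrast_table_rows(fit, cmp_present[i, ],
                                    unique(tab$electrode),
                                    mass = config$hdi_mass,
                                    floor_db = config$floor_db)
        ctab
      }))
    }
  }

  # Model 2: behavioural metrics
  fits_behaviour <- list(); contrasts_behaviour <- list()
  for (metric in c("iti_d", "iti_cv")) {
    tab <- cbind(split_condition_label(behaviour$condition),
                 data.frame(participant = behaviour$participant,
                            value = behaviour[[metric]]))
    fit <- fit_model(build_design(tab), chains = config$mcmc$chains,
                     warmup = config$mcmc$warmup, draws = config$mcmc$draws,
                     seed = config$seed + 11L)
    fits_behaviour[[metric]] <- fit
    ok <- cmp_ok(comparisons_of_interest(),
                 unique(paste(tab$modality, tab$rhythmicity, tab$frequency,
                              sep = "-")))
    contrasts_behaviour[[metric]] <- if (any(ok)) {
      do.call(rbind, lapply(which(ok), function(i) {
        cmp <- comparisons_of_interest()[i, ]
        ct <- contrast(fit, cmp$condition_a, cmp$condition_b,
                       mass = config$hdi_mass)
        data.frame(metric = metric, characteristic = cmp$characteristic,
                   condition_a = cmp$condition_a,
                   condition_b = cmp$condition_b, diff_mean = ct$diff_mean,
                   hdi_low = ct$hdi_low, hdi_high = ct$hdi_high,
                   significant = ct$significant)
      }))
    }
  }

  # circular phase statistics across participants
  circ <- circular_report(behaviour)

  structure(
    list(behaviour = behaviour, cells = cells,
         fits_power = fits_power, contrasts_power = contrasts_power,
         fits_behaviour = fits_behaviour,
         contrasts_behaviour = contrasts_behaviour,
         circular = circ, excluded = excluded,
         manifest = list(seed = config$seed,
                         conditions = config$conditions,
                         n_participants = config$n_participants,
                         reference = config$reference,
                         timestamp = NA)),
    class = "pipeline_bundle"
  )
}

cmp_ok <- function(cmp, present) {
  cmp$condition_a %in% present & cmp$condition_b %in% present
}

contrast_table_rows <- function(fit, cmp_row, electrodes, mass, floor_db) {
  do.call(rbind, lapply(electrodes, function(el) {
    ct <- contrast(fit, cmp_row$condition_a, cmp_row$condition_b,
                   electrode = el, mass = mass, floor_db = floor_db)
    data.frame(characteristic = cmp_row$characteristic,
               condition_a = cmp_row$condition_a,
               condition_b = cmp_row$condition_b, electrode = el,
               diff_mean = ct$diff_mean, hdi_low = ct$hdi_low,
               hdi_high = ct$hdi_high, significant = ct$significant,
               blacklisted = ct$blacklisted)
  }))
}

circular_report <- function(behaviour) {
  conds <- unique(behaviour$condition)
  per_cond <- do.call(rbind, lapply(conds, function(lab) {
    ph <- behaviour$mean_phase_deg[behaviour$condition == lab]
    row <- data.frame(condition = lab, n = length(ph))
    if (length(ph) >= 3) {
      mi <- circular_median_iqr(ph)
      row$median_deg <- mi$median_deg
      row$iqr_lo <- mi$iqr_deg[1]; row$iqr_hi <- mi$iqr_deg[2]
    } else {
      row$median_deg <- NA; row$iqr_lo <- NA; row$iqr_hi <- NA
    }
    if (length(ph) >= 5) {
      ut <- uniformity_test(ph)
      row$uniformity_test <- ut$test_name
      row$uniformity_p <- ut$p_value
    } else {
      row$uniformity_test <- NA; row$uniformity_p <- NA
    }
    row
  }))
  cmp <- comparisons_of_interest()
  pair_rows <- list()
  for (i in seq_len(nrow(cmp))) {
    a <- behaviour[behaviour$condition == cmp$condition_a[i], ]
    b <- behaviour[behaviour$condition == cmp$condition_b[i], ]
    common <- intersect(a$participant, b$participant)
    if (length(common) < 5) next
    mt <- moore_paired_test(a$mean_phase_deg[match(common, a$participant)],
                            b$mean_phase_deg[match(common, b$participant)])
    pair_rows[[length(pair_rows) + 1]] <- data.frame(
      condition_a = cmp$condition_a[i], condition_b = cmp$condition_b[i],
      statistic = mt$statistic, p = mt$p_value, n = mt$n)
  }
  pairs <- if (length(pair_rows)) {
    out <- do.call(rbind, pair_rows)
    out$significant <- bonferroni(out$p)$significant
    out
  }
  list(per_condition = per_cond, paired = pairs)
}

#' Human-readable summary of a pipeline bundle
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return A list of class `pipeline_report`: per-condition behavioural
#'   summary (mean ITI-D/ITI-CV, circular median phase), behavioural
#'   contrast table, and the significant electrodes per power comparison.
#' @export
make_report <- function(bundle) {
  if (!inherits(bundle, "pipeline_bundle") || is.null(bundle$behaviour)) {
    stop("incomplete bundle")
  }
  beh <- bundle$behaviour
  conds <- unique(beh$condition)
  beh_summary <- do.call(rbind, lapply(conds, function(lab) {
    sub <- beh[beh$condition == lab, ]
    circ <- bundle$circular$per_condition
    ci <- circ[circ$condition == lab, ]
    data.frame(condition = lab, n = nrow(sub),
               iti_d = mean(sub$iti_d), iti_cv = mean(sub$iti_cv),
               median_phase_deg = ci$median_deg,
               iqr_lo = ci$iqr_lo, iqr_hi = ci$iqr_hi)
  }))
  sig_electrodes <- lapply(bundle$contrasts_power, function(tab) {
    if (is.null(tab)) return(NULL)
    sig <- tab[tab$significant, c("condition_a", "condition_b", "electrode",
                                  "diff_mean")]
    rownames(sig) <- NULL
    sig
  })
  structure(
    list(behaviour_summary = beh_summary,
         behaviour_contrasts = bundle$contrasts_behaviour,
         significant_electrodes = sig_electrodes,
         excluded = bundle$excluded),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Behavioural summary (per condition):\n")
  print(x$behaviour_summary, digits = 3)
  for (m in names(x$behaviour_contrasts)) {
    cat("\nBehavioural contrasts -", m, ":\n")
    print(x$behaviour_contrasts[[m]], digits = 3)
  }
  for (w in names(x$significant_electrodes)) {
    tab <- x$significant_electrodes[[w]]
    cat("\nSignificant electrodes (", w, " tap window): ",
        if (is.null(tab) || nrow(tab) == 0) "none" else "", "\n", sep = "")
    if (!is.null(tab) && nrow(tab) > 0) print(tab, digits = 3)
  }
  if (length(x$excluded)) {
    cat("\nExcluded participant-conditions:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
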