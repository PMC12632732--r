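#' Pipeline run configuration
#'
#' Collects every tunable stage parameter with defaults equal to the study
#' protocol values: 0.25-40 Hz zero-phase band-pass, -100..800 ms epochs
#' with -100..0 ms baseline, pointwise alpha 0.05 with a 10-sample run
#' criterion, and a 100-1000 ms response window capped at the next stimulus
#' onset.
#'
#' @param ... overrides for any default field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    response_window = c(100, 1000),
    filter_low = 0.25,
    filter_high = 40,
    epoch_window = c(-100, 800),
    baseline = c(-100, 0),
    alpha = 0.05,
    min_run = 10L,
    expected_stride_time = 1.3,
    peak_windows = list(P2 = c(200, 280), N2 = c(280, 380),
                        P3 = c(350, 500)),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("run_config: unknown field(s): ",
                            paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration (provenance)
#'
#' @param config a [run_config()].
#' @return md5 string of the serialized configuration.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

.conditions5 <- c("S-NF-T", "W-NF-T", "W-F-T", "W-NF-NT", "W-F-NT")

#' Validate a session manifest
#'
#' A manifest has one row per block with columns `participant`, `group`
#' (`TD` / `ASD`), `condition` (one of the five protocol labels: S-NF-T,
#' W-NF-T, W-F-T, W-NF-NT, W-F-NT), `block`, and file-path columns
#' (`events_path`, `motion_path`, optionally `eeg_path`,
#' `locations_path`); `NA` paths mark streams not recorded for that block.
#'
#' @param manifest data.frame to validate.
#' @param check_paths verify that non-NA paths exist.
#' @return the manifest, invisibly, or an error.
#' @export
validate_manifest <- function(manifest, check_paths = TRUE) {
  need <- c("participant", "group", "condition", "block")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(manifest$condition), .conditions5)
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.conditions5, collapse = ", "), ")")
  }
  if (!all(manifest$group %in% c("TD", "ASD"))) {
    stop("group must be 'TD' or 'ASD'")
  }
  if (check_paths) {
    for (col in intersect(c("events_path", "motion_path", "eeg_path",
                            "locations_path"), names(manifest))) {
      p <- manifest[[col]]
      p <- p[!is.na(p)]
      missing <- p[!file.exists(p)]
      if (length(missing) > 0) {
        stop("missing file(s) in ", col, ": ",
             paste(utils::head(missing, 3), collapse = ", "))
      }
    }
  }
  invisible(manifest)
}

#' Simulate a session on disk and build its manifest
#'
#' Writes events TSVs for the task blocks and motion TSVs for the walking
#' blocks of one participant under `dir`, one block per condition, and
#' returns the manifest rows. Ground-truth behavior and gait parameters are
#' taken from the supplied simulator configs; condition effects enter
#' through per-condition overrides.
#'
#' @param participant participant id string.
#' @param group `"TD"` or `"ASD"`.
#' @param dir output directory (created if needed).
#' @param behavior_config base [behavior_sim_config()].
#' @param gait_config base [gait_sim_config()].
#' @param seed integer; per-block seeds are derived from it.
#' @return manifest data.frame (one row per condition).
#' @export
simulate_session <- function(participant, group, dir,
                             behavior_config = behavior_sim_config(),
                             gait_config = gait_sim_config(),
                             seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(.conditions5)) {
    cond <- .conditions5[i]
    has_task <- grepl("-T$", cond)
    walking <- grepl("^W", cond)
    events_path <- NA_character_
    motion_path <- NA_character_
    if (has_task) {
      bc <- behavior_config
      bc$seed <- seed + 13L * i
      ev <- simulate_behavior(bc)
      events_path <- file.path(dir, paste0(participant, "_", cond,
                                           "_events.tsv"))
      write_events(ev, events_path)
    }
    if (walking) {
      gc <- gait_config
      gc$seed <- seed + 131L * i
      trajs <- simulate_gait(gc)
      motion_path <- file.path(dir, paste0(participant, "_", cond,
                                           "_motion.tsv"))
      write_motion(trajs, motion_path)
    }
    rows[[i]] <- data.frame(participant = participant, group = group,
                            condition = cond, block = 1L,
                            events_path = events_path,
                            motion_path = motion_path)
  }
  do.call(rbind, rows)
}

#' Run the behavioral and gait pipeline over a session manifest
#'
#' For each block: task-inclusive conditions (`*-T`) are scored for d' and
#' mean RT; walking conditions (`W-*`) get gait event detection and
#' stride/step metrics. No-task blocks are excluded from behavioral scoring
#' but kept for gait, per the protocol. Stage failures are caught, logged
#' with block provenance, and do not stop remaining blocks. When enough
#' participants and conditions are present, the inferential layer adds the
#' split-plot ANOVAs (behavior: condition x group; gait: flow x task with
#' group between).
#'
#' @param manifest validated manifest (see [validate_manifest()]).
#' @param config a [run_config()].
#' @return list of class `pipeline_bundle`: `behavior` and `gait` per-block
#'   tables, `anova` (list of `rm_anova` tables, possibly empty), `errors`
#'   (per-block failure log), and `provenance` (config and hash).
#' @export
run_pipeline <- function(manifest, config = run_config()) {
  validate_manifest(manifest)
  beh <- list()
  gait <- list()
  errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    prov <- sprintf("%s/%s/block%s", row$participant, row$condition,
                    row$block)
    if (grepl("-T$", row$condition) && !is.na(row$events_path)) {
      res <- tryCatch({
        ev <- read_events(row$events_path)
        trials <- classify_trials(ev, config$response_window)
        cbind(row[c("participant", "group", "condition", "block")],
              summarize_behavior(trials))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          block = prov, stage = "behavior", message = conditionMessage(res))
      } else {
        beh[[length(beh) + 1L]] <- res
      }
    }
    if (grepl("^W", row$condition) && !is.na(row$motion_path)) {
      res <- tryCatch({
        trajs <- read_motion(row$motion_path)
        sides <- vapply(trajs, function(t) attr(t, "side"), character(1))
        ga <- analyze_gait(trajs[[which(sides == "left")[1]]],
                           trajs[[which(sides == "right")[1]]],
                           config$expected_stride_time)
        cbind(row[c("participant", "group", "condition", "block")],
              ga$metrics)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          block = prov, stage = "gait", message = conditionMessage(res))
      } else {
        gait[[length(gait) + 1L]] <- res
      }
    }
  }
  beh <- if (length(beh)) do.call(rbind, beh) else NULL
  gait <- if (length(gait)) do.call(rbind, gait) else NULL
  anovas <- list()
  if (!is.null(beh) && length(unique(beh$participant)) >= 4 &&
      length(unique(beh$condition)) >= 2 &&
      length(unique(beh$group)) == 2) {
    for (m in c("d_prime", "mean_rt_ms")) {
      anovas[[paste0("behavior_", m)]] <- tryCatch(
        rm_anova(beh, dv = m, within = "condition", between = "group"),
        error = function(e) NULL)
    }
  }
  if (!is.null(gait) && length(unique(gait$participant)) >= 4) {
    g <- gait
    g$flow <- ifelse(grepl("-F-", g$condition), "F", "NF")
    g$task <- ifelse(grepl("-T$", g$condition), "T", "NT")
    between <- if (length(unique(g$group)) == 2) "group" else NULL
    if (length(unique(g$flow)) == 2 && length(unique(g$task)) == 2) {
      for (m in c("mean_stride_time", "mean_stride_length",
                  "mean_step_width", "cv_stride_time", "cv_stride_length",
                  "cv_step_width")) {
        anovas[[paste0("gait_", m)]] <- tryCatch(
          rm_anova(g, dv = m, within = c("flow", "task"), between = between),
          error = function(e) NULL)
      }
    }
  }
  structure(list(
    behavior = beh, gait = gait, anova = anovas,
    errors = if (length(errors)) do.call(rbind, errors) else NULL,
    provenance = list(config = config, hash = config_hash(config))
  ), class = "pipeline_bundle")
}

#' Write a pipeline bundle to CSV files
#'
#' Every file carries the configuration hash in a header comment line.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(tab, name) {
    if (is.null(tab)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    con <- file(p, "w")
    writeLines(paste0("# config_hash: ", bundle$provenance$hash), con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  emit(bundle$behavior, "behavior")
  emit(bundle$gait, "gait")
  for (nm in names(bundle$anova)) emit(bundle$anova[[nm]], paste0("anova_", nm))
  emit(bundle$errors, "errors")
  invisible(paths)
}

#' Simulate a two-group ERP study at the participant-average level
#'
#' Generates per-participant average ERP waveforms for both response types
#' (Hit, CR) in each task-inclusive condition, for a TD and an ASD group.
#' All participants share P2/N2/P3 templates; correct rejections receive a
#' condition- and group-specific P3 amplitude boost (`cr_p3_boost`, uV at
#' the CPz peak), emulating the stronger inhibition-related P3 for withheld
#' responses. Per-participant gain variability and trial noise propagate
#' into the averages.
#'
#' @param n_per_group participants per group.
#' @param cr_p3_boost named list `group -> named numeric by condition` of
#'   CR-specific P3 amplitude increments, uV.
#' @param conditions condition labels to simulate.
#' @param n_trials_per_cell trials averaged per participant cell.
#' @param noise_sd trial noise SD, uV.
#' @param noise_ar1 lag-1 noise autocorrelation.
#' @param participant_gain_sd SD of the per-participant multiplicative gain.
#' @param channels electrode subset (default full 64-channel montage).
#' @param seed integer seed.
#' @return list with `groups` (group -> condition -> list(Hit, CR) arrays of
#'   participants x channels x time), `times`, `sample_rate`, `channels`,
#'   and the generating parameters.
#' @export
simulate_erp_study <- function(
    n_per_group = 12L,
    cr_p3_boost = list(
      TD = c("S-NF-T" = 4.0, "W-NF-T" = 2.2, "W-F-T" = 2.4),
      ASD = c("S-NF-T" = 1.5, "W-NF-T" = 1.8, "W-F-T" = 1.8)),
    conditions = c("S-NF-T", "W-NF-T", "W-F-T"),
    n_trials_per_cell = 24L,
    noise_sd = 6,
    noise_ar1 = 0.9,
    participant_gain_sd = 0.1,
    channels = electrode_positions()$label,
    seed = 1L) {
  base_p3 <- 5
  comps <- list(
    erp_component("P2", peak_latency = 240, peak_amplitude = 4,
                  temporal_width = 30),
    erp_component("N2", peak_latency = 320, peak_amplitude = -3,
                  temporal_width = 30),
    erp_component("P3", peak_latency = 420, peak_amplitude = base_p3,
                  temporal_width = 60)
  )
  cfg <- erp_sim_config(channels = channels, components = comps,
                        latency_jitter_sd = 10, noise_sd = noise_sd,
                        noise_ar1 = noise_ar1,
                        n_trials_per_cell = n_trials_per_cell, seed = seed)
  set.seed(seed)
  gains <- list(
    TD = stats::rnorm(n_per_group, 1, participant_gain_sd),
    ASD = stats::rnorm(n_per_group, 1, participant_gain_sd)
  )
  cell_seed <- 0L
  times <- NULL
  groups <- list()
  for (grp in c("TD", "ASD")) {
    groups[[grp]] <- list()
    for (cond in conditions) {
      arrs <- list()
      for (resp in c("Hit", "CR")) {
        pa <- NULL
        for (p in seq_len(n_per_group)) {
          cell_seed <- cell_seed + 1L
          gain <- max(0.2, gains[[grp]][p])
          scale <- c(P2 = gain, N2 = gain, P3 = gain)
          if (resp == "CR") {
            scale[["P3"]] <- gain *
              (base_p3 + cr_p3_boost[[grp]][[cond]]) / base_p3
          }
          ep <- simulate_erp_epochs(cfg, condition = cond,
                                    response_type = resp, group = grp,
                                    participant = sprintf("%s%02d", grp, p),
                                    amp_scale = scale,
                                    seed = seed + 7919L * cell_seed)
          avg <- apply(ep$data, c(1, 2), mean)
          if (is.null(times)) times <- ep$times
          if (is.null(pa)) {
            pa <- array(NA_real_,
                        dim = c(n_per_group, nrow(avg), ncol(avg)),
                        dimnames = list(sprintf("%s%02d", grp,
                                                seq_len(n_per_group)),
                                        channels, NULL))
          }
          pa[p, , ] <- avg
        }
        arrs[[resp]] <- pa
      }
      groups[[grp]][[cond]] <- arrs
    }
  }
  list(groups = groups, times = times, sample_rate = 512,
       channels = channels,
       params = list(n_per_group = n_per_group, cr_p3_boost = cr_p3_boost,
                     n_trials_per_cell = n_trials_per_cell,
                     noise_sd = noise_sd, noise_ar1 = noise_ar1,
                     seed = seed))
}

#' Hit-vs-CR cluster analysis for one group and condition
#'
#' Pointwise paired t-tests (CR vs Hit) across channels and time with the
#' consecutive-sample cluster criterion.
#'
#' @param study output of [simulate_erp_study()] (or an equivalently shaped
#'   list of participant-average arrays).
#' @param group,condition cell selectors.
#' @param alpha,min_run cluster parameters (see [find_clusters()]).
#' @return list with the `t_map` and the `clusters` table.
#' @export
hit_cr_clusters <- function(study, group, condition, alpha = 0.05,
                            min_run = 10L) {
  cell <- study$groups[[group]][[condition]]
  tm <- pointwise_paired_t(cell$CR, cell$Hit, times = study$times,
                           sample_rate = study$sample_rate)
  list(t_map = tm, clusters = find_clusters(tm, alpha, min_run))
}

#' Group-difference cluster analysis of CR-minus-Hit difference waves
#'
#' Forms each participant's CR - Hit difference wave and compares the two
#' groups with pointwise independent t-tests and the run-length cluster
#' criterion.
#'
#' @inheritParams hit_cr_clusters
#' @param condition condition label.
#' @return list with the `t_map` and the `clusters` table.
#' @export
group_difference_clusters <- function(study, condition, alpha = 0.05,
                                      min_run = 10L) {
  d_td <- study$groups$TD[[condition]]$CR - study$groups$TD[[condition]]$Hit
  d_asd <- study$groups$ASD[[condition]]$CR -
    study$groups$ASD[[condition]]$Hit
  tm <- pointwise_independent_t(d_td, d_asd, times = study$times,
                                sample_rate = study$sample_rate)
  list(t_map = tm, clusters = find_clusters(tm, alpha, min_run))
}
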