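# Pipeline orchestration and CLI ---------------------------------------------
#
# One config (R list, YAML or JSON) drives all stages; all randomness flows
# from config$seed via named sub-seeds. Every stage writes its numeric
# outputs as delimited text plus a JSON provenance sidecar (config echo,
# seeds, package version). Stages never mutate another stage's outputs, so a
# run directory can be regenerated stage by stage.

capnet_default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    write_arrays = FALSE,
    stages = list(simulate = TRUE, envelope = TRUE, cluster = TRUE,
                  rsn = FALSE, metrics = TRUE, compare = TRUE,
                  sweep = FALSE),
    simulate = list(mode = "envelope", n_roi = 100L, k_true = 6L,
                    n_participants = 4L, duration_s = 120, fs = 250,
                    snr = 0.5, occ_rates = NULL, mean_dwell_ms = 80,
                    hierarchy_depth = 0L, n_sensors = 32L,
                    participant_sigma_by_group =
                      c(SM = 0.05, HO = 0.15, Other = 0.3)),
    envelope = list(band = c(8, 12), zscore_axis = "time",
                    edge_trim_s = 0),
    cluster = list(k = 6L, n_init = 10L, max_iter = 300L),
    rsn = list(n_components = 48L, method = "complex"),
    metrics = list(min_run = 1L),
    compare = list(n_perm = 1000L, threshold_frac = 0.2),
    sweep = list(k_list = c(3L, 6L), n_runs = 2L)
  )
}

merge_config <- function(user, default = capnet_default_config(),
                         path = "config") {
  if (is.null(user)) return(default)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop_capnet("unknown config key%s under `%s`: %s",
                if (length(unknown) > 1L) "s" else "", path,
                paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    default[[nm]] <- if (is.list(user[[nm]]) && is.list(default[[nm]]) &&
                         !is.null(names(default[[nm]])))
      merge_config(user[[nm]], default[[nm]], paste0(path, "$", nm))
    else user[[nm]]
  }
  default
}

#' Load a pipeline configuration
#'
#' Reads YAML or JSON (by extension), validates keys against the schema and
#' fills defaults. Unknown keys are an error naming the key.
#'
#' @param path file path, or NULL for the default config.
#' @return validated config list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL
  else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_config(user)
}

write_sidecar <- function(dir, name, info) {
  jsonlite::write_json(info, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the pipeline end-to-end
#'
#' Executes simulate -> [inverse/envelope] -> (cluster + rsn) -> metrics ->
#' compare -> sweep as toggled in the config. Returns the in-memory results
#' and, when `config$out_dir` is set, writes labels, metrics, similarity
#' tables and sidecars there.
#'
#' @param config config list (see [load_config()]), or a path to one.
#' @return named list of stage results.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) config <- load_config(config)
  cfg <- merge_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list(config = cfg)
  stage <- "simulate"
  tryCatch({
    ## simulate ---------------------------------------------------------
    sc <- cfg$simulate
    if (isTRUE(cfg$stages$simulate)) {
      if (is.null(sc$occ_rates))
        sc$occ_rates <- rep(0.7, sc$k_true)
      tpl <- make_templates(sc$n_roi, sc$k_true,
                            hierarchy_depth = sc$hierarchy_depth,
                            seed = derive_seed(cfg$seed, "templates"))
      st0 <- simulate_state_sequence(sc$duration_s, sc$fs, sc$occ_rates,
                                     sc$mean_dwell_ms,
                                     seed = derive_seed(cfg$seed, "states"))
      res$cohort <- simulate_roi_envelopes(
        tpl, st0, snr = sc$snr,
        participant_sigma_by_group = unlist(sc$participant_sigma_by_group),
        n_participants = sc$n_participants,
        seed = derive_seed(cfg$seed, "cohort"))
      if (identical(sc$mode, "oscillation")) {
        lf <- make_lead_field(sc$n_sensors, sc$n_roi,
                              seed = derive_seed(cfg$seed, "leadfield"))
        res$sensor <- lapply(res$cohort$states, function(stp)
          simulate_sensor_eeg(lf, tpl, stp, snr = sc$snr * 20,
                              seed = derive_seed(cfg$seed, "eeg")))
        res$lead_field <- lf
      }
      if (!is.null(out_dir)) {
        write_sidecar(out_dir, "simulate",
                      list(seed = cfg$seed, simulate = sc))
        if (isTRUE(cfg$write_arrays)) write_cohort(res$cohort, out_dir)
      }
    }
    ## envelope ---------------------------------------------------------
    stage <- "envelope"
    if (isTRUE(cfg$stages$envelope)) {
      ec <- cfg$envelope
      if (!is.null(res$sensor)) {
        # oscillation mode: inverse -> bandpass -> Hilbert -> ROI -> z
        res$frames <- lapply(res$sensor, function(ss) {
          lam <- gcv_select_lambda(res$lead_field, ss$phi)
          lam <- regularize_lambda_series(lam)$lambda
          src <- mne_inverse(res$lead_field, ss$phi, lam)
          alpha <- bandpass_alpha(src, ss$fs, band = unlist(ec$band))
          env <- hilbert_envelope(alpha)
          zscore_rois(env, fs = ss$fs, axis = ec$zscore_axis)
        })
      } else {
        res$frames <- lapply(seq_along(res$cohort$env), function(p)
          zscore_rois(res$cohort$env[[p]], fs = res$cohort$states[[p]]$fs,
                      participant = p, axis = ec$zscore_axis))
      }
      trim <- round(cfg$envelope$edge_trim_s *
                      res$frames[[1L]]$fs)
      if (trim > 0)
        res$frames <- lapply(res$frames, function(fr) {
          keep <- (trim + 1L):(ncol(fr$Z) - trim)
          fr$Z <- fr$Z[, keep, drop = FALSE]
          fr
        })
    }
    ## cluster ----------------------------------------------------------
    stage <- "cluster"
    if (isTRUE(cfg$stages$cluster)) {
      X <- t(do.call(cbind, lapply(res$frames, `[[`, "Z")))  # N x R
      pid <- rep(seq_along(res$frames),
                 vapply(res$frames, function(f) ncol(f$Z), integer(1L)))
      km <- kmeans_correlation(X, cfg$cluster$k, n_init = cfg$cluster$n_init,
                               max_iter = cfg$cluster$max_iter,
                               seed = derive_seed(cfg$seed, "cluster"))
      res$kmeans <- km
      res$caps <- build_cap_maps(km$labels, X, pid, k = cfg$cluster$k)
      res$labels_by_participant <-
        split(km$labels, pid)
      if (!is.null(out_dir)) {
        for (p in seq_along(res$labels_by_participant))
          data.table::fwrite(
            data.table::data.table(
              frame_index = seq_along(res$labels_by_participant[[p]]),
              cap_id = res$labels_by_participant[[p]]),
            file.path(out_dir, sprintf("labels_p%02d.tsv", p)), sep = "\t")
        write_sidecar(out_dir, "cluster",
                      list(seed = cfg$seed, cluster = cfg$cluster,
                           objective = km$objective))
      }
    }
    ## rsn --------------------------------------------------------------
    stage <- "rsn"
    if (isTRUE(cfg$stages$rsn)) {
      if (is.null(res$sensor))
        stop_capnet("rsn stage needs oscillation-mode simulation")
      spectra <- lapply(res$sensor, function(ss)
        stft_spectral_series(ss$phi, ss$fs,
                             max_hz = min(100, floor(ss$fs / 2) - 1)))
      alpha_series <- lapply(spectra, alpha_band_average,
                             band = unlist(cfg$envelope$band))
      n_comp <- min(cfg$rsn$n_components, nrow(res$sensor[[1L]]$phi))
      ica <- group_temporal_ica(alpha_series, n_components = n_comp,
                                seed = derive_seed(cfg$seed, "ica"),
                                method = cfg$rsn$method)
      beta <- vector("list", length(res$sensor))
      for (p in seq_along(res$sensor)) {
        ss <- res$sensor[[p]]
        alpha_sens <- bandpass_alpha(ss$phi, ss$fs,
                                     band = unlist(cfg$envelope$band))
        icz <- ic_envelopes_z(alpha_sens, ica)
        beta[[p]] <- regress_rsn_maps(res$frames[[p]]$Z, icz)
      }
      res$ica <- ica
      res$beta_maps <- beta
      res$rsn_group_maps <- group_average(beta)
    }
    ## metrics ----------------------------------------------------------
    stage <- "metrics"
    if (isTRUE(cfg$stages$metrics)) {
      fs <- res$frames[[1L]]$fs
      res$metrics <- cohort_run_metrics(res$labels_by_participant, fs,
                                        min_run = cfg$metrics$min_run)
      res$tests <- list(
        occurrence = temporal_group_tests(res$metrics,
                                          "occurrence_rate_hz"),
        lifetime = temporal_group_tests(res$metrics, "mean_lifetime_ms"))
      if (!is.null(out_dir))
        data.table::fwrite(res$metrics,
                           file.path(out_dir, "cap_metrics.tsv"), sep = "\t")
    }
    ## compare ----------------------------------------------------------
    stage <- "compare"
    if (isTRUE(cfg$stages$compare)) {
      ref <- if (!is.null(res$rsn_group_maps)) res$rsn_group_maps
             else res$cohort$templates$templates
      sim <- similarity_confusion(res$caps$group_maps, ref,
                                  threshold_frac = cfg$compare$threshold_frac)
      res$similarity <- sim
      res$match_test <- permutation_match_test(
        sim, n_perm = cfg$compare$n_perm,
        seed = derive_seed(cfg$seed, "permutation"))
      mp <- res$cohort$templates$mirror_pairs
      res$symmetry <- vapply(seq_len(res$caps$k), function(j)
        symmetry_index(res$caps$group_maps[j, ], mp), numeric(1L))
      res$loo <- loo_consistency(res$caps$participant_maps)
      if (!is.null(out_dir)) {
        data.table::fwrite(as.data.frame(sim$match),
                           file.path(out_dir, "match_table.tsv"), sep = "\t")
        data.table::fwrite(data.frame(cap_id = seq_along(res$symmetry),
                                      symmetry = res$symmetry),
                           file.path(out_dir, "symmetry.tsv"), sep = "\t")
      }
    }
    ## sweep ------------------------------------------------------------
    stage <- "sweep"
    if (isTRUE(cfg$stages$sweep)) {
      X <- t(do.call(cbind, lapply(res$frames, `[[`, "Z")))
      fits <- sweep_k(X, k_values = unlist(cfg$sweep$k_list),
                      seed = derive_seed(cfg$seed, "sweep"))
      res$sweep <- fits
      res$overlap <- overlap_graph(lapply(fits, `[[`, "labels"))
      if (!is.null(out_dir))
        write_overlap_edges(res$overlap,
                            file.path(out_dir, "overlap_edges.tsv"),
                            display_threshold = 0)
    }
  }, error = function(e) {
    stop_capnet("pipeline stage `%s` failed: %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir))
    write_sidecar(out_dir, "run", list(config = cfg,
                                       package_version =
                                         as.character(utils::packageVersion("capnet"))))
  res
}

#' Write a synthetic cohort as delimited text plus JSON sidecar
#'
#' One `participant_XX.tsv` (ROI x time) per participant, ground-truth
#' labels, and a JSON sidecar with seeds and configuration.
#'
#' @param cohort a [simulate_roi_envelopes()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in seq_along(cohort$env)) {
    data.table::fwrite(data.table::as.data.table(cohort$env[[p]]),
                       file.path(dir, sprintf("participant_%02d.tsv", p)),
                       sep = "\t")
    data.table::fwrite(
      data.table::data.table(frame_index =
                               seq_along(cohort$states[[p]]$labels),
                             state = cohort$states[[p]]$labels),
      file.path(dir, sprintf("truth_labels_p%02d.tsv", p)), sep = "\t")
  }
  write_sidecar(dir, "cohort",
                list(config = cohort$config,
                     state_config = cohort$states[[1L]]$config,
                     group_label = cohort$templates$group_label,
                     mirror_spec = cohort$templates$mirror_spec))
  invisible(dir)
}

#' Command-line entry point
#'
#' `capnet run --config <yaml|json> [--out <dir>] [--seed <int>]`, plus
#' per-stage shortcuts (`simulate`, `envelope`, `cluster`, `rsn`, `metrics`,
#' `compare`, `sweep`) that enable only that stage and the ones it depends
#' on.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return the [run_pipeline()] result, invisibly.
#' @export
capnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("simulate", "envelope", "cluster", "rsn", "metrics",
              "compare", "sweep")
  if (length(args) < 1L || !(args[1L] %in% c("run", stages)))
    stop_capnet("usage: capnet <run|%s> --config <file> [--out <dir>]",
                paste(stages, collapse = "|"))
  cmd <- args[1L]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NA_integer_))),
    args = args[-1L])
  cfg <- load_config(opts$config)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (!is.na(opts$seed)) cfg$seed <- opts$seed
  if (cmd != "run") {
    deps <- list(simulate = "simulate",
                 envelope = c("simulate", "envelope"),
                 cluster = c("simulate", "envelope", "cluster"),
                 rsn = c("simulate", "envelope", "rsn"),
                 metrics = c("simulate", "envelope", "cluster", "metrics"),
                 compare = c("simulate", "envelope", "cluster", "compare"),
                 sweep = c("simulate", "envelope", "sweep"))
    for (s in stages) cfg$stages[[s]] <- s %in% deps[[cmd]]
    if (cmd == "rsn") cfg$simulate$mode <- "oscillation"
  }
  invisible(run_pipeline(cfg))
}
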