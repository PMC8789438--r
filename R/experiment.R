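#' Preprocess a raw recording into a screened trial set
#'
#' Convenience chain: band-pass + downsample, epoch, amplitude screen.
#'
#' @param rec A `raw_recording`.
#' @param low,high,fs_out Filter band (Hz) and output rate.
#' @param threshold Validity threshold in microvolts.
#' @return A `trial_set`.
#' @export
preprocess_recording <- function(rec, low = 0.1, high = 10, fs_out = 100,
                                 threshold = 120) {
  rec <- bandpass_downsample(rec, low, high, fs_out)
  screen_validity(epoch_trials(rec), threshold)
}

#' Build source domain and aligned group targets from simulated data
#'
#' Runs the full data-side pipeline: preprocess every recording; fit a CSP
#' filter and ERP template on the pooled single-mind trials; align the pool
#' and extract P3 maps; cluster maps into strong/weak groups; refit the
#' template on the strong subjects only (the template that travels to the
#' target domain); build the labeled source domain from the strong subjects'
#' valid trials; align each group subject with the source template.
#'
#' @param pool Output of [simulate_subject_pool()].
#' @param group Output of [simulate_group()].
#' @param threshold Validity threshold in microvolts.
#' @param cluster_seed Seed for the K-means restarts.
#' @return List: `source` (`source_domain`), `targets` (list of
#'   `aligned_trial_set`), `maps`, `clustering`, `template`,
#'   `pool_aligned`, `group_truth`.
#' @export
prepare_study <- function(pool, group, threshold = 120, cluster_seed = 1L) {
  pool_ts <- lapply(pool$recordings, preprocess_recording,
                    threshold = threshold)
  group_ts <- lapply(group$recordings, preprocess_recording,
                     threshold = threshold)

  # stage 1: pooled template for P3-map extraction over the whole pool
  pooled_t <- pool_target_trials(pool_ts, valid_only = TRUE)
  pooled_n <- pool_nontarget_trials(pool_ts, valid_only = TRUE)
  csp0 <- fit_csp(pooled_t, pooled_n)
  tpl0 <- build_template(csp0, pooled_t)
  pool_al <- lapply(pool_ts, align_trials, template = tpl0)
  maps <- lapply(pool_al, extract_p3_map, template = tpl0)
  cl <- cluster_p3_maps(maps, seed = cluster_seed)

  # stage 2: source template from the strong group only
  strong_ts <- pool_ts[vapply(pool_ts, function(ts)
    ts$subject_id %in% cl$strong_ids, logical(1))]
  st_t <- pool_target_trials(strong_ts, valid_only = TRUE)
  st_n <- pool_nontarget_trials(strong_ts, valid_only = TRUE)
  csp <- fit_csp(st_t, st_n)
  tpl <- build_template(csp, st_t)
  strong_al <- lapply(strong_ts, align_trials, template = tpl)
  source <- build_source_domain(strong_al,
                                vapply(strong_al, function(a) a$subject_id,
                                       character(1)),
                                template = tpl)
  targets <- lapply(group_ts, align_trials, template = tpl)
  list(source = source, targets = targets, maps = maps, clustering = cl,
       template = tpl, pool_aligned = pool_al, group_truth = group$truth)
}

pool_target_trials <- function(ts_list, valid_only = TRUE) {
  pool_class_trials(ts_list, 1L, valid_only)
}

pool_nontarget_trials <- function(ts_list, valid_only = TRUE) {
  pool_class_trials(ts_list, 0L, valid_only)
}

pool_class_trials <- function(ts_list, label, valid_only) {
  parts <- lapply(ts_list, function(ts) {
    keep <- ts$labels == label
    if (valid_only) keep <- keep & ts$validity
    ts$trials[keep, , , drop = FALSE]
  })
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[(at + 1):(at + k), , ] <- p
    at <- at + k
  }
  out
}

#' Study conditions for the synthetic three-observer benchmark
#'
#' One fixed set of simulation and training conditions used throughout the
#' package's own evaluations: a source pool of four strong (9 microvolt) and
#' two weak (3 microvolt) single-mind subjects, and one synchronized
#' three-observer group with heterogeneous P3 amplitudes (8/5/3 microvolts),
#' all at the full session size (100 target + 100 nontarget videos, 600 Hz,
#' 4 percent artifact rate, 4 microvolt pink noise).  Training runs 30
#' epochs at batch 40 — long enough for the loss to flatten on this data
#' while keeping a full multi-seed comparison tractable on one CPU.
#'
#' @param seed Base seed; simulation and training seeds derive from it.
#' @param epochs Training epochs.
#' @return List with `pool_cfg`, `group_cfg`, pool composition, and a
#'   [train_config()] template.
#' @export
benchmark_config <- function(seed = 1L, epochs = 30L) {
  seed <- as.integer(seed)
  list(pool_cfg = sim_config(n_subjects = 1, noise_sd = 4,
                             artifact_rate = 0.04, seed = seed),
       n_strong = 4L, n_weak = 2L,
       strong_amplitude = 9, weak_amplitude = 3,
       group_cfg = sim_config(n_subjects = 3, p3_amplitude = c(8, 5, 3),
                              noise_sd = 4, artifact_rate = 0.04,
                              seed = seed + 101L),
       train = train_config(epochs = epochs, seed = seed + 577L))
}

#' Simulate and prepare the benchmark study data
#'
#' @param bench A [benchmark_config()].
#' @return A [prepare_study()] result.
#' @export
benchmark_data <- function(bench = benchmark_config()) {
  pool <- simulate_subject_pool(bench$pool_cfg, bench$n_strong, bench$n_weak,
                                bench$strong_amplitude,
                                bench$weak_amplitude)
  group <- simulate_group(bench$group_cfg)
  prepare_study(pool, group)
}

#' Run a complete simulated detection experiment
#'
#' Simulates a single-mind source pool and a synchronized observer group,
#' runs the data pipeline ([prepare_study()]), trains the requested
#' frameworks on identical inputs, and reports collaborative and
#' per-network detection metrics.  Fully seeded: identical configurations
#' give identical reports.
#'
#' @param config A list (or path to a YAML file with the same structure):
#'   `seed`; `sim` (arguments to [sim_config()] shared by pool and group,
#'   plus `n_strong`, `n_weak`, `strong_amplitude`, `weak_amplitude`,
#'   `group_amplitude`); `train` (arguments to [train_config()]);
#'   `frameworks` (subset of sbci / sc-cbci / mc-cbci / ml-cbci).
#' @param out_dir Optional directory; if given, the report is written as
#'   `report.tsv` and a text log as `experiment.log`.
#' @return Invisibly, a list with `report` (one data frame row per
#'   framework: accuracy, hit_rate, false_alarm_rate, f1, per-network F1
#'   columns), `study`, `results`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  simc <- config$sim %||% list()
  frameworks <- config$frameworks %||%
    c("sbci", "sc-cbci", "mc-cbci", "ml-cbci")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message("[cobci] ", msg)
  }

  pool_args <- simc
  pool_args$n_subjects <- 1
  pool_args$seed <- seed
  extra <- c("n_strong", "n_weak", "strong_amplitude", "weak_amplitude",
             "group_amplitude")
  pool_cfg <- do.call(sim_config, pool_args[setdiff(names(pool_args), extra)])
  group_args <- simc
  group_args$n_subjects <- simc$n_subjects %||% 3
  group_args$p3_amplitude <- simc$group_amplitude %||% c(8, 5, 3)
  group_args$seed <- seed + 101L
  group_cfg <- do.call(sim_config,
                       group_args[setdiff(names(group_args), extra)])

  say("simulating source pool and observer group (seed ", seed, ")")
  pool <- simulate_subject_pool(pool_cfg,
                                simc$n_strong %||% 4L, simc$n_weak %||% 2L,
                                simc$strong_amplitude %||% 9,
                                simc$weak_amplitude %||% 3)
  group <- simulate_group(group_cfg)
  say("preprocessing, aligning and selecting the source domain")
  study <- prepare_study(pool, group, cluster_seed = seed)
  say("source domain: ", length(study$source$member_ids), " subjects, ",
      dim(study$source$trials)[1], " trials")

  train_args <- config$train %||% list()
  train_args$seed <- train_args$seed %||% (seed + 577L)
  base_cfg <- do.call(train_config, train_args)

  results <- list()
  rows <- list()
  n_grp <- length(study$targets)
  for (fw in frameworks) {
    say("training framework ", fw)
    res <- switch(fw,
      "sbci" = {
        runs <- lapply(study$targets, function(tg)
          run_sbci(study$source, tg, base_cfg))
        list(runs = runs)
      },
      "sc-cbci" = run_sc_cbci(study$source, study$targets, base_cfg),
      "mc-cbci" = run_mc_cbci(study$source, study$targets, base_cfg),
      "ml-cbci" = run_ml_cbci(study$source, study$targets, base_cfg),
      stop("unknown framework: ", fw))
    results[[fw]] <- res
    if (fw == "sbci") {
      ms <- lapply(res$runs, function(r) r$metrics)
      avg <- function(field) mean(vapply(ms, `[[`, numeric(1), field))
      net_f1 <- vapply(ms, `[[`, numeric(1), "f1")
      row <- data.frame(framework = fw, accuracy = avg("accuracy"),
                        hit_rate = avg("hit_rate"),
                        false_alarm_rate = avg("false_alarm_rate"),
                        f1 = avg("f1"))
    } else {
      m <- res$metrics
      pn <- res$per_network_metrics
      net_f1 <- if (is.null(pn)) rep(NA_real_, n_grp) else
        vapply(pn, `[[`, numeric(1), "f1")
      row <- data.frame(framework = fw, accuracy = m$accuracy,
                        hit_rate = m$hit_rate,
                        false_alarm_rate = m$false_alarm_rate, f1 = m$f1)
    }
    for (k in seq_len(n_grp))
      row[[paste0("net_f1_", k)]] <-
        if (k <= length(net_f1)) net_f1[k] else NA_real_
    rows[[fw]] <- row
    say(sprintf("  %s: F1 %.3f accuracy %.3f", fw, row$f1, row$accuracy))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "experiment.log"))
    write_p3_maps(study$maps, file.path(out_dir, "p3_maps.tsv"))
    sel <- data.frame(
      subject_id = vapply(study$maps, function(m) m$subject_id,
                          character(1)),
      p3_strength = vapply(study$maps, p3_strength, numeric(1)))
    sel$group <- ifelse(sel$subject_id %in% study$clustering$strong_ids,
                        "strong", "weak")
    sel$in_source_domain <- sel$subject_id %in% study$source$member_ids
    write.table(sel[order(-sel$p3_strength), ],
                file.path(out_dir, "source_selection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(report = report, study = study, results = results))
}
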