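#' Default pipeline configuration
#'
#' Nested list of every tunable parameter, with defaults matching the study
#' conditions the package models: a 6-block x 48-trial schedule at 25% target
#' prevalence, a ten-observer cohort with mean sensitivity 0.569 (SD 0.109)
#' and specificity 0.774 (SD 0.158), shared-difficulty coupling 0.5, 16
#' EEG channels at 32 Hz with snr 0.18, distance distributions calibrated so
#' the accuracy-optimal threshold sits near 0.526 with a high-specificity /
#' low-sensitivity machine, an 8-fold decoder with unit inverse L2 strength,
#' and all five fusion methods over human group sizes 1 to 10.
#'
#' @return a config list (sections `cohort`, `eeg`, `distances`, `decoder`,
#'   `machine`, `fusion`, plus `seed`).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort = list(
      n_blocks = 6L, trials_per_block = 48L, prevalence = 0.25,
      n_agents = 10L, mean_sens = 0.569, sd_sens = 0.109,
      mean_spec = 0.774, sd_spec = 0.158, coupling = 0.5
    ),
    eeg = list(n_channels = 16L, fs = 32, duration = 1.5, snr = 0.18),
    distances = list(
      mu_target = 0.572, mu_nontarget = 0.658,
      sigma_target = 0.22, sigma_nontarget = 0.06, p_no_face = 0.01
    ),
    decoder = list(band = c(0.15, 40), k = 8L, C = 1),
    machine = list(metric = "accuracy", k = 8L),
    fusion = list(methods = c("a", "b", "c", "d", "e"), sizes = 1:10)
  )
}

#' Write / read a pipeline configuration
#'
#' Round-trip serialisation of the config as YAML.
#'
#' @param config config list.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ## yaml collapses length-1 vectors to scalars; nothing to fix beyond types
  cfg$fusion$sizes <- as.integer(cfg$fusion$sizes)
  cfg$decoder$band <- as.numeric(cfg$decoder$band)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every parameter range and cross-constraint and returns *all*
#' problems found, as data, rather than stopping at the first. Problems at
#' level `"error"` make the config unusable; level `"warning"` flags
#' legitimate-but-unusual settings (e.g. a fold count that does not divide
#' the trial count, giving near-equal folds).
#'
#' @param config config list as from [default_config()].
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  probs <- list()
  add <- function(level, msg) probs[[length(probs) + 1L]] <<- data.frame(
    level = level, message = msg, stringsAsFactors = FALSE)

  ch <- config$cohort
  n_trials <- ch$n_blocks * ch$trials_per_block
  if (is.null(ch$prevalence) || ch$prevalence < 0 || ch$prevalence > 1) {
    add("error", "cohort$prevalence must lie in [0, 1]")
  } else {
    tgt <- ch$prevalence * ch$trials_per_block
    if (abs(tgt - round(tgt)) > 1e-8) {
      add("error", sprintf(
        "prevalence %g x %d trials/block = %g targets is not integral",
        ch$prevalence, ch$trials_per_block, tgt))
    }
  }
  if (ch$n_agents < 1) add("error", "cohort$n_agents must be >= 1")
  for (f in c("mean_sens", "sd_sens", "mean_spec", "sd_spec", "coupling")) {
    v <- ch[[f]]
    if (is.null(v) || v < 0 || (f %in% c("mean_sens", "mean_spec", "coupling") && v > 1)) {
      add("error", sprintf("cohort$%s out of range", f))
    }
  }

  eg <- config$eeg
  if (eg$n_channels < 2) add("error", "eeg$n_channels must be >= 2")
  if (eg$snr < 0) add("error", "eeg$snr must be >= 0")
  if (eg$fs <= 0 || eg$duration <= 0) add("error", "eeg$fs and eeg$duration must be positive")

  ds <- config$distances
  if (!(ds$mu_target < ds$mu_nontarget)) {
    add("error", "distances$mu_target must be below mu_nontarget")
  }
  if (ds$sigma_target <= 0 || ds$sigma_nontarget <= 0) {
    add("error", "distance sigmas must be positive")
  }
  if (ds$p_no_face < 0 || ds$p_no_face > 1) {
    add("error", "distances$p_no_face must lie in [0, 1]")
  }

  dc <- config$decoder
  if (length(dc$band) != 2 || !(dc$band[1] > 0 && dc$band[1] < dc$band[2])) {
    add("error", "decoder$band must be increasing and positive")
  }
  if (dc$k < 2) add("error", "decoder$k must be >= 2")
  if (dc$k > n_trials) add("error", "decoder$k exceeds the trial count")
  if (dc$k >= 2 && dc$k <= n_trials && n_trials %% dc$k != 0) {
    add("warning", sprintf(
      "%d trials are not divisible into %d folds; folds will be near-equal",
      n_trials, dc$k))
  }
  if (dc$C <= 0) add("error", "decoder$C must be positive")

  if (!config$machine$metric %in% c("accuracy", "f1", "kappa")) {
    add("error", sprintf("unknown machine metric '%s'", config$machine$metric))
  }
  fu <- config$fusion
  if (!all(fu$methods %in% c("a", "b", "c", "d", "e"))) {
    add("error", "fusion$methods must be a subset of a-e")
  }
  if (any(fu$sizes < 1 | fu$sizes > ch$n_agents)) {
    add("error", sprintf("fusion$sizes must lie in 1..%d", ch$n_agents))
  }
  if (length(probs) == 0) {
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, probs)
}

## md5 of an in-memory object via a temp file (config hash for the manifest)
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full simulate - decode - calibrate - fuse - evaluate pipeline
#'
#' Executes every stage needed by the requested fusion methods from one
#' config and master seed: cohort simulation, per-agent EEG confidence
#' decoding (only when methods b/d/e are requested), machine threshold
#' calibration and decisions (only for methods c/d/e), the group-fusion
#' campaign, and the evaluation statistics. Stages draw from named seed
#' substreams, so two runs with the same config are identical. When `outdir`
#' is given, tidy CSV artefacts and a JSON run manifest (config hash, file
#' digests, timestamps) are written.
#'
#' @param config config list (validated first; errors abort with the stage
#'   and message).
#' @param outdir optional output directory for CSV artefacts + manifest.
#' @param seed optional master seed overriding `config$seed`.
#' @param quiet suppress per-stage progress messages (default TRUE).
#' @return list with `cohort`, `bci_confidences`, `machine_decisions`,
#'   `threshold_fit`, `records`, `summary`, `hamming`, `wilcoxon`,
#'   `confidence_tests`, `human_metrics`, `machine_metrics`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         seed = NULL, quiet = TRUE) {
  probs <- validate_config(config)
  if (any(probs$level == "error")) {
    stop("invalid config:\n  ",
         paste(probs$message[probs$level == "error"], collapse = "\n  "))
  }
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  methods <- config$fusion$methods
  need_bci <- any(methods %in% c("b", "d", "e"))
  need_machine <- any(methods %in% c("c", "d", "e"))

  say("[simulate] cohort: %d agents x %d trials",
      config$cohort$n_agents,
      config$cohort$n_blocks * config$cohort$trials_per_block)
  cohort <- simulate_cohort(config, with_eeg = need_bci)
  truths <- cohort$schedule$truth

  bci <- NULL
  if (need_bci) {
    say("[decode] CSP + logistic confidence, %d-fold CV", config$decoder$k)
    bci <- do.call(rbind, lapply(
      sort(unique(cohort$decisions$agent_id)),
      function(a) {
        ep <- subset_epochs(cohort$epochs, cohort$epochs$agent_id == a)
        crossval_confidence(ep, k = config$decoder$k, C = config$decoder$C,
                            seed = substream_seed(seed, "cv", a))
      }))
  }

  machine <- NULL
  tfit <- NULL
  if (need_machine) {
    say("[machine] threshold calibration (%s, %d folds)",
        config$machine$metric, config$machine$k)
    machine <- machine_decisions_cv(cohort$distances, truths,
                                    metric = config$machine$metric,
                                    k = config$machine$k,
                                    seed = substream_seed(seed, "machine"))
    tfit <- attr(machine, "threshold_fit")
  }

  say("[fuse] methods %s, sizes %s", paste(methods, collapse = ","),
      paste(range(config$fusion$sizes), collapse = ".."))
  records <- run_campaign(cohort$decisions, bci, machine,
                          methods = methods, sizes = config$fusion$sizes,
                          seed = seed)

  say("[evaluate] %d fused records", nrow(records))
  summary <- summarize_by_size(records, cohort$schedule)
  hamming <- build_hamming_matrix(cohort$decisions, machine, truths)
  wilcox <- wilcoxon_table(summary,
                           pairs = Filter(function(p) all(p %in% methods),
                                          list(c("a", "b"), c("a", "c"),
                                               c("b", "c"), c("c", "d"),
                                               c("b", "d"), c("d", "e"))))
  conf_tests <- NULL
  if (need_bci) {
    conf_tests <- confidence_distribution_tests(bci$w_p, bci$correct)
  }
  human_metrics <- do.call(rbind, lapply(
    split(cohort$decisions, cohort$decisions$agent_id), function(df) {
      mm <- classification_metrics(df$vote, truths[match(df$trial_id,
                                                         cohort$schedule$trial_id)])
      data.frame(agent_id = df$agent_id[1], accuracy = mm$accuracy,
                 specificity = mm$specificity, sensitivity = mm$sensitivity)
    }))
  rownames(human_metrics) <- NULL
  machine_metrics <- if (need_machine) {
    classification_metrics(machine$vote, truths)
  }

  manifest <- list(
    config_md5 = object_md5(config),
    master_seed = seed,
    substreams = list(schedule = substream_seed(seed, "schedule"),
                      agents = substream_seed(seed, "agents"),
                      decisions = substream_seed(seed, "decisions"),
                      eeg = substream_seed(seed, "eeg"),
                      distances = substream_seed(seed, "distances"),
                      machine = substream_seed(seed, "machine")),
    stages_run = c("simulate", if (need_bci) "decode",
                   if (need_machine) "machine", "fuse", "evaluate"),
    n_trials = nrow(cohort$schedule),
    n_agents = config$cohort$n_agents,
    n_records = nrow(records),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = list()
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(outdir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    files <- c(
      wr(cohort$schedule, "schedule.csv"),
      wr(cohort$profiles, "agent_profiles.csv"),
      wr(cohort$decisions, "decisions.csv"),
      wr(cohort$distances, "distances.csv"),
      if (need_bci) wr(bci, "bci_confidences.csv"),
      if (need_machine) wr(machine, "machine_decisions.csv"),
      wr(records, "fused_decisions.csv"),
      wr(summary$per_group, "performance_per_group.csv"),
      wr(summary$by_size, "performance_by_size.csv"),
      wr(as.data.frame(hamming), "hamming_matrix.csv"),
      wr(wilcox, "wilcoxon_pvalues.csv")
    )
    manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(cohort = cohort, bci_confidences = bci, machine_decisions = machine,
       threshold_fit = tfit, records = records, summary = summary,
       hamming = hamming, wilcoxon = wilcox, confidence_tests = conf_tests,
       human_metrics = human_metrics, machine_metrics = machine_metrics,
       manifest = manifest)
}
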