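# End-to-end pipeline on synthetic data, and the thin command-line wrapper.

#' Run the full self-supervised delineation pipeline on synthetic data
#'
#' Simulates a beat train with known fiducials, preprocesses it twice (the
#' pretext path keeps raw amplitudes so the scaling transformation stays
#' learnable; the downstream path normalizes per beat), trains the pretext
#' classifier with cross-validation, transfers and freezes the backbone,
#' fine-tunes the landmark head, and evaluates held-out beats with the
#' deviation, Bland-Altman and regression statistics. Optionally also runs
#' the self-supervised vs from-scratch comparison.
#'
#' @param n_beats Beats in the synthetic record.
#' @param seed Master seed; every stage derives from it.
#' @param config Network configuration (a [net_config()]; `l_net`/`head_dim`
#'   are adjusted per stage). Defaults to [net_config_small()] so the run
#'   finishes on one CPU core in minutes.
#' @param pretext_epochs,pretext_folds Pretext budget.
#' @param downstream_epochs,downstream_folds,downstream_patience Fine-tuning
#'   budget. Head-only epochs on cached backbone features are cheap, so the
#'   default budget is long with early stopping.
#' @param compare_seeds Seeds for the SSL-vs-scratch comparison; `NULL`
#'   skips it.
#' @param compare_epochs Epoch budget of each comparison arm.
#' @param verbose Print stage progress.
#'
#' @return List with elements `record`, `pretext` (`pretext_fit`),
#'   `downstream` (`delineation_fit`), `report` (`deviation_report`),
#'   `bland_altman`, `regression` (both pooled over points) and `comparison`
#'   (tibble or `NULL`).
#' @export
run_delineation_pipeline <- function(n_beats = 300, seed = 1L,
                                     config = net_config_small(),
                                     pretext_epochs = 8, pretext_folds = 5,
                                     downstream_epochs = 400,
                                     downstream_folds = 5,
                                     downstream_patience = 60,
                                     compare_seeds = c(1, 2, 3),
                                     compare_epochs = 30,
                                     verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d beats", n_beats)
  record <- generate_record(n_beats = n_beats, seed = derive_seed(seed, 1))

  say("preprocessing")
  pretext_beats <- prepare_beats(record$signal, record$truth, fs = record$fs,
                                 target_len = 300, denoise = TRUE,
                                 normalize = FALSE)
  down <- prepare_beats(record$signal, record$truth, fs = record$fs,
                        target_len = 324, denoise = TRUE, normalize = TRUE)

  say("pretext task: %d beats -> %d samples", nrow(pretext_beats$x),
      4 * nrow(pretext_beats$x))
  pcfg <- config
  pcfg$l_net <- 300
  pcfg$head_dim <- 4
  pdata <- build_pretext_dataset(pretext_beats$x, seed = derive_seed(seed, 2))
  pretext <- train_pretext(pdata, pcfg, epochs = pretext_epochs,
                           folds = pretext_folds,
                           seed = derive_seed(seed, 3), verbose = verbose)
  say("pretext mean CV accuracy %.3f", pretext$mean_accuracy)

  say("downstream fine-tuning on %d beats", nrow(down$x))
  model <- transfer_and_freeze(pretext, l_net = 324, head_dim = 8,
                               seed = derive_seed(seed, 4))
  downstream <- train_downstream(model, down$x, down$y,
                                 epochs = downstream_epochs,
                                 folds = downstream_folds,
                                 patience = downstream_patience,
                                 seed = derive_seed(seed, 5),
                                 verbose = verbose)
  say("held-out MAE %.2f resampled samples", mean(downstream$test_mae))

  dev <- deviations_ms(downstream$test_pred, downstream$test_truth,
                       l_net = 324, fs = record$fs)
  report <- deviation_report(dev)
  ba <- bland_altman(as.vector(downstream$test_pred[, -5]),
                     as.vector(downstream$test_truth[, -5]))
  reg <- regression_fit(as.vector(downstream$test_pred[, -5]),
                        as.vector(downstream$test_truth[, -5]))

  comparison <- NULL
  if (!is.null(compare_seeds)) {
    say("SSL vs scratch over %d seeds", length(compare_seeds))
    comparison <- compare_ssl_vs_scratch(pretext, down$x, down$y,
                                         seeds = compare_seeds,
                                         epochs = compare_epochs)
  }

  list(record = record, pretext = pretext, downstream = downstream,
       report = report, bland_altman = ba, regression = reg,
       comparison = comparison)
}

#' Command-line interface
#'
#' Thin wrapper with subcommands `simulate`, `pretrain`, `finetune`,
#' `evaluate` and `delineate`; see `inst/cli/ecgdelin.R` for the shell entry
#' point. Artifacts (WFDB files, checkpoints as `.rds`, CSV reports) are
#' written under `--out-dir`, and each stage is deterministic given
#' `--seed`.
#'
#' @param args Character vector of command-line arguments (first element the
#'   subcommand).
#'
#' @return Invisibly, 0 on success; called for its side effects.
#' @export
ecg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: ecgdelin <simulate|pretrain|finetune|evaluate|delineate> [options]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop_ecg("the command-line interface needs the 'optparse' package.", "cli")
  }
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--out-dir", type = "character", default = "ecgdelin-out",
                          dest = "out_dir"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-beats", type = "integer", default = 300L,
                          dest = "n_beats"),
    optparse::make_option("--epochs", type = "integer", default = 20L),
    optparse::make_option("--record", type = "character", default = "synth01"),
    optparse::make_option("--checkpoint", type = "character", default = NULL),
    optparse::make_option("--model", type = "character", default = NULL)
  )), args = rest)
  dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)

  switch(
    sub,
    simulate = {
      rec <- generate_record(n_beats = opts$n_beats, seed = opts$seed)
      write_wfdb(rec, opts$out_dir, record_id = opts$record)
      message("wrote ", file.path(opts$out_dir, opts$record), ".{hea,dat,atr} + truth CSV")
    },
    pretrain = {
      rec <- read_wfdb_record(opts$out_dir, opts$record)
      truth <- utils::read.csv(file.path(opts$out_dir,
                                         paste0(opts$record, "_truth.csv")))
      beats <- prepare_beats(rec$signals[, 1], truth, fs = rec$fs,
                             target_len = 300, normalize = FALSE)
      cfg <- net_config_small(l_net = 300, head_dim = 4)
      pdata <- build_pretext_dataset(beats$x, seed = opts$seed)
      fit <- train_pretext(pdata, cfg, epochs = opts$epochs, seed = opts$seed)
      saveRDS(fit, file.path(opts$out_dir, "pretext.rds"))
      message(sprintf("pretext mean CV accuracy %.3f", fit$mean_accuracy))
    },
    finetune = {
      fit <- readRDS(opts$checkpoint %||% file.path(opts$out_dir, "pretext.rds"))
      rec <- read_wfdb_record(opts$out_dir, opts$record)
      truth <- utils::read.csv(file.path(opts$out_dir,
                                         paste0(opts$record, "_truth.csv")))
      down <- prepare_beats(rec$signals[, 1], truth, fs = rec$fs,
                            target_len = 324, normalize = TRUE)
      model <- transfer_and_freeze(fit, l_net = 324, seed = opts$seed)
      dfit <- train_downstream(model, down$x, down$y, epochs = opts$epochs,
                               folds = 1, seed = opts$seed)
      saveRDS(dfit, file.path(opts$out_dir, "model.rds"))
      message(sprintf("held-out MAE %.2f resampled samples",
                      mean(dfit$test_mae)))
    },
    evaluate = {
      dfit <- readRDS(opts$model %||% file.path(opts$out_dir, "model.rds"))
      dev <- deviations_ms(dfit$test_pred, dfit$test_truth)
      rep <- deviation_report(dev)
      utils::write.csv(rep$per_point,
                       file.path(opts$out_dir, "deviation_report.csv"),
                       row.names = FALSE)
      print(rep)
    },
    delineate = {
      dfit <- readRDS(opts$model %||% file.path(opts$out_dir, "model.rds"))
      rec <- read_wfdb_record(opts$out_dir, opts$record)
      truth <- utils::read.csv(file.path(opts$out_dir,
                                         paste0(opts$record, "_truth.csv")))
      down <- prepare_beats(rec$signals[, 1], truth, fs = rec$fs,
                            target_len = 324, normalize = TRUE)
      pred <- predict_positions(dfit$net, down$x)
      utils::write.csv(as.data.frame(pred),
                       file.path(opts$out_dir, "predicted_fiducials.csv"),
                       row.names = FALSE)
      message("wrote ", file.path(opts$out_dir, "predicted_fiducials.csv"))
    },
    stop_ecg(paste0("unknown subcommand: ", sub), "cli")
  )
  invisible(0L)
}
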