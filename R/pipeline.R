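#' Default end-to-end run configuration
#'
#' A nested list with one section per stage (synth, windows, pretrain,
#' discretize, classifier, sax, lm), a global seed fanned out to per-stage
#' seeds via [derive_seed()], and an output directory. Round-trips through
#' YAML.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed.
#' @param stages Character vector of downstream stages to run after
#'   discretization (subset of `"classifier"`, `"sax"`, `"lm"`).
#' @return A `vqcpc_run_config` list.
#' @export
run_config <- function(out_dir = tempfile("vqcpc_run_"), seed = 1L,
                       stages = "classifier") {
  list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
       synth = list(n_subjects = 6L, bout_s = 40, subject_gain_sd = 0.2),
       windows = list(window_s = 2, overlap_frac = 0.5, rate_hz = 50),
       model = list(channels = c(8L, 16L, 16L, 32L), G = 2L, V = 16L,
                    n_agg_blocks = 2L, K = 10L, n_negatives = 10L,
                    gamma = 0.25),
       pretrain = list(lr = 3e-3, l2 = 1e-4, batch = 8L, max_epochs = 5L,
                       patience = 5L, patience_start = 4L),
       classifier = list(embedding_dim = 16L, rnn_type = "gru",
                         rnn_units = 32L, rnn_layers = 1L,
                         mlp_hidden = c(32L, 16L), lr = 1e-3, l2 = 0,
                         batch = 64L, epochs = 15L),
       sax = list(alphabet_size = 64L, k = 64L),
       lm = list(size = "small", epochs = 5L))
}

#' Load/save run configurations as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config A [run_config()] list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  s <- utils::capture.output(utils::str(config))
  sprintf("%08x", sum(utf8ToInt(paste(s, collapse = "\n")) *
                        (seq_along(utf8ToInt(paste(s, collapse = "\n")))
                         %% 997)) %% 4294967296)
}

log_json <- function(path, record) {
  cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
}

#' Run the full pipeline on the synthetic benchmark
#'
#' Stages in dependency order: synthesize recordings, window + normalize,
#' VQ-CPC pre-training, discretization, then the requested downstream
#' stages (token classifier, SAX baseline, masked LM). Every artifact is
#' written under `config$out_dir` and stamped with a hash of the
#' configuration; logs are line-delimited JSON. Deterministic given
#' `config$seed`.
#'
#' @param config A [run_config()] list.
#' @return Invisibly, a list of in-memory results (model, corpora, reports).
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log.jsonl")
  hash <- config_hash(config)
  stamp <- function(stage) log_json(log_path, list(stage = stage,
                                                   config_hash = hash,
                                                   time = format(Sys.time())))
  # synth
  stamp("synth")
  synth_seed <- derive_seed(config$seed, "synth")
  cfg_s <- default_benchmark(seed = synth_seed)
  cfg_s$n_subjects <- config$synth$n_subjects
  cfg_s$bout_s <- config$synth$bout_s
  cfg_s$subject_gain_sd <- config$synth$subject_gain_sd
  recs <- generate_dataset(cfg_s)
  write_recordings(recs, file.path(config$out_dir, "recordings.csv"))
  # windows + folds + normalization
  stamp("windows")
  windows <- unlist(lapply(recs, make_windows,
                           window_s = config$windows$window_s,
                           overlap_frac = config$windows$overlap_frac),
                    recursive = FALSE)
  folds <- make_participant_folds(vapply(recs, `[[`, "", "subject_id"),
                                  seed = derive_seed(config$seed, "folds"))
  fold1 <- folds[[1L]]
  subj <- window_subjects(windows)
  tr_idx <- subj %in% fold1$train
  stats <- fit_normalization(windows[tr_idx])
  windows <- apply_normalization(windows, stats)
  win_df <- data.frame(subject = subj, label = window_labels(windows),
                       start = vapply(windows, `[[`, 0, "start_index"))
  utils::write.csv(win_df, file.path(config$out_dir, "windows.csv"),
                   row.names = FALSE)
  # pretrain
  stamp("pretrain")
  m <- config$model
  model <- vqcpc_model(
    enc_cfg = encoder_config(channels = m$channels),
    n_agg_blocks = m$n_agg_blocks, G = m$G, V = m$V, gamma = m$gamma,
    K = m$K, n_negatives = m$n_negatives,
    seed = derive_seed(config$seed, "model"))
  pt_cfg <- pretrain_config(lr = config$pretrain$lr, l2 = config$pretrain$l2,
                            batch = config$pretrain$batch,
                            max_epochs = config$pretrain$max_epochs,
                            patience = config$pretrain$patience,
                            patience_start = config$pretrain$patience_start,
                            seed = derive_seed(config$seed, "pretrain"))
  pt <- pretrain(model, windows[tr_idx], windows[subj %in% fold1$val], pt_cfg)
  utils::write.csv(pt$history, file.path(config$out_dir, "pretrain_loss.csv"),
                   row.names = FALSE)
  # discretize
  stamp("discretize")
  seqs <- discretize(pt$model, windows)
  write_token_corpus(seqs, file.path(config$out_dir, "corpus.txt"))
  results <- list(model = pt$model, sequences = seqs, folds = folds,
                  norm_stats = stats)
  # downstream stages
  if ("classifier" %in% config$stages) {
    stamp("classifier")
    results$eval <- classifier_stage(config)
  }
  if ("sax" %in% config$stages) {
    stamp("sax")
    scfg <- sax_config(alphabet_size = config$sax$alphabet_size)
    sx <- sax_repeat_transform(windows[tr_idx], windows[!tr_idx],
                               cfg = scfg, k = config$sax$k,
                               seed = derive_seed(config$seed, "sax"))
    write_token_corpus(sx$train, file.path(config$out_dir, "sax_corpus.txt"))
    results$sax <- sx
  }
  if ("lm" %in% config$stages) {
    stamp("lm")
    vocab <- build_vocabulary(seqs[tr_idx])
    lm_cf <- lm_config(size = config$lm$size, epochs = config$lm$epochs,
                       seed = derive_seed(config$seed, "lm"))
    results$lm <- pretrain_lm(seqs[tr_idx], vocab, lm_cf)
  }
  stamp("done")
  invisible(results)
}

#' Classifier stage over on-disk pipeline artifacts
#'
#' Reads the token corpus and window metadata written by earlier stages of
#' [run_pipeline()] and runs fold-1 cross-validation; a missing upstream
#' artifact is a dependency error.
#'
#' @param config A [run_config()] whose `out_dir` holds `corpus.txt` and
#'   `windows.csv`.
#' @return The evaluation report (also written as `eval_report.json`).
#' @export
classifier_stage <- function(config) {
  corpus_path <- file.path(config$out_dir, "corpus.txt")
  win_path <- file.path(config$out_dir, "windows.csv")
  if (!file.exists(corpus_path) || !file.exists(win_path)) {
    stop_vqcpc("classifier stage requires the token corpus and window table",
               "vqcpc_dependency_error")
  }
  seqs <- read_token_corpus(corpus_path)
  win_df <- utils::read.csv(win_path, stringsAsFactors = FALSE)
  attr(seqs, "label") <- win_df$label
  attr(seqs, "subject") <- win_df$subject
  folds <- make_participant_folds(unique(win_df$subject),
                                  seed = derive_seed(config$seed, "folds"))
  cc <- config$classifier
  clf_cfg <- classifier_config(embedding_dim = cc$embedding_dim,
                               rnn_type = cc$rnn_type,
                               rnn_units = cc$rnn_units,
                               rnn_layers = cc$rnn_layers,
                               mlp_hidden = cc$mlp_hidden, lr = cc$lr,
                               l2 = cc$l2, batch = cc$batch,
                               epochs = cc$epochs,
                               seed = derive_seed(config$seed, "clf"))
  cv <- cross_validate(seqs, folds[1L], cfg = clf_cfg,
                       lr_grid = cc$lr, l2_grid = cc$l2, n_runs = 1L)
  report <- list(mean_f1 = cv$mean_f1, sd_f1 = cv$sd_f1, best = cv$best,
                 config_hash = config_hash(config))
  jsonlite::write_json(report, file.path(config$out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}
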