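#' Assemble a full experiment configuration
#'
#' One object drives the whole pipeline: generate (or load) a cohort, label
#' it under each look-back window, split by patient, preprocess text, tune or
#' load the architecture, train with restarts, calibrate thresholds, and
#' evaluate. Any part can be overridden; everything else keeps the package
#' defaults. Accepts a YAML file with the same nesting.
#'
#' @param config YAML path or a (possibly partial) nested list.
#' @param ... named overrides applied on top (e.g. `seed = 7`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    windows = c(Inf, 24, 12, 6),
    generator = list(),
    policy = list(),
    split = list(fractions = c(train = 0.8, validation = 0.1, test = 0.1)),
    textprep = list(prune_fraction = 0.01, max_len = NULL, min_tokens = 3L),
    model = list(preset = FALSE, grid = NULL),
    train = list(),
    uncertainty_targets = c(0.05, 0.10, 0.15, 0.20),
    out_dir = NULL,
    resume = FALSE
  )
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, list(...))
  cfg$windows <- vapply(cfg$windows, function(w) {
    if (is.character(w)) w <- if (tolower(w) %in% c("inf", "infinite")) Inf else as.numeric(w)
    if (is.na(w) || w <= 0) {
      abort("Windows must be positive month counts or Inf.",
            class = "cvdnotes_config_error")
    }
    as.numeric(w)
  }, numeric(1))
  structure(cfg, class = "experiment_config")
}

.window_tag <- function(w) if (is.finite(w)) paste0("win_", w) else "win_inf"

.stage_paths <- function(dir) {
  list(labelled = file.path(dir, "labelled.csv"),
       vocab = file.path(dir, "vocabulary.tsv"),
       model = file.path(dir, "model.rds"),
       thresholds = file.path(dir, "thresholds.json"),
       evaluation_csv = file.path(dir, "evaluation.csv"),
       evaluation_json = file.path(dir, "evaluation.json"),
       search_log = file.path(dir, "search_log.jsonl"),
       restart_log = file.path(dir, "restart_log.jsonl"),
       run_log = file.path(dir, "run_log.json"),
       hash = file.path(dir, "stage.hash"))
}

.write_jsonl <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
}

#' Run the full experiment for one or more look-back windows
#'
#' Executes generate -> harmonise/label/split -> preprocess -> tune/train ->
#' threshold -> evaluate for each configured window, writing per-window
#' artefacts (labelled dataset CSV, vocabulary TSV, model checkpoint,
#' threshold JSON, evaluation CSV/JSON, search and restart logs, and a run
#' log with every seed) under `out_dir`. Each window directory is
#' content-addressed by a hash of the configuration; with `resume = TRUE` a
#' window whose hash matches on disk is skipped and its evaluation re-read.
#'
#' @param config an [experiment_config()], nested list, or YAML path.
#' @param ... overrides forwarded to [experiment_config()].
#' @return List of class `cvd_experiment`: `evaluation` (combined
#'   `cvd_evaluation` tibble across windows), `windows` (per-window detail:
#'   search, restarts, thresholds, prevalence, paths), `config`.
#' @export
run_experiment <- function(config = list(), ...) {
  cfg <- experiment_config(config, ...)
  out_dir <- cfg$out_dir %||% tempfile("cvdnotes_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  gen_cfg <- do.call(generator_config,
                     utils::modifyList(list(seed = cfg$seed), cfg$generator))
  policy <- do.call(code_policy, cfg$policy)
  tcfg <- do.call(train_config,
                  utils::modifyList(list(seed = cfg$seed + 1000L), cfg$train))
  cohort <- generate_cohort(gen_cfg)

  results <- list()
  evals <- list()
  for (w in cfg$windows) {
    wdir <- file.path(out_dir, .window_tag(w))
    if (!dir.exists(wdir)) dir.create(wdir)
    paths <- .stage_paths(wdir)
    stage_hash <- rlang::hash(list(unclass(gen_cfg), unclass(policy),
                                   unclass(tcfg), cfg$split, cfg$textprep,
                                   cfg$model, cfg$uncertainty_targets, w,
                                   cfg$seed))
    if (isTRUE(cfg$resume) && file.exists(paths$hash) &&
        file.exists(paths$evaluation_csv) &&
        readLines(paths$hash)[1] == stage_hash) {
      ev <- tryCatch(
        readr::read_csv(paths$evaluation_csv, show_col_types = FALSE),
        error = function(e) {
          abort(sprintf("Stage 'evaluate' output is corrupted for %s (%s); delete %s to recompute.",
                        .window_tag(w), conditionMessage(e), paths$evaluation_csv),
                class = "cvdnotes_stage_error")
        })
      if (!all(c("setting", "uncertainty_level", "f1") %in% names(ev))) {
        abort(sprintf("Stage 'evaluate' output is corrupted for %s; delete %s to recompute.",
                      .window_tag(w), paths$evaluation_csv),
              class = "cvdnotes_stage_error")
      }
      class(ev) <- c("cvd_evaluation", class(ev))
      evals[[.window_tag(w)]] <- ev
      results[[.window_tag(w)]] <- list(paths = paths, resumed = TRUE)
      next
    }

    ds <- build_labelled_dataset(cohort$visits, cohort$hospitalisations,
                                 cohort$eligibility, policy, w,
                                 gen_cfg$observation_start,
                                 gen_cfg$observation_end,
                                 fractions = cfg$split$fractions,
                                 seed = cfg$seed + 17L)
    readr::write_csv(ds, paths$labelled)

    tokens <- clean_and_stem(ds$text)
    is_tr <- ds$split == "train"
    vocab <- build_vocabulary(tokens[is_tr],
                              prune_fraction = cfg$textprep$prune_fraction)
    write_vocabulary(vocab, paths$vocab)
    max_len <- cfg$textprep$max_len %||% default_max_len(tokens[is_tr])
    enc <- encode_visits(tokens, vocab, max_len,
                         min_tokens = cfg$textprep$min_tokens)
    keep <- enc$retained
    ds <- ds[keep, ]
    enc <- encoded_subset(enc, keep)
    is_split <- function(s) ds$split == s

    search <- NULL
    if (isTRUE(cfg$model$preset)) {
      mcfg <- preset_config(w, vocab_rows = enc$vocab_rows, max_len = max_len)
    } else if (is.list(cfg$model$preset)) {
      mcfg <- do.call(model_config,
                      c(cfg$model$preset, list(vocab_rows = enc$vocab_rows,
                                               max_len = max_len)))
    } else {
      grid <- cfg$model$grid %||% model_grid()
      search <- random_search(encoded_subset(enc, is_split("train")),
                              ds$label[is_split("train")],
                              ds$patient_id[is_split("train")], tcfg, grid)
      .write_jsonl(search$log, paths$search_log)
      mcfg <- search$best_config
    }

    restarts <- multi_restart(mcfg, encoded_subset(enc, is_split("train")),
                              ds$label[is_split("train")],
                              encoded_subset(enc, is_split("validation")),
                              ds$label[is_split("validation")], tcfg)
    .write_jsonl(restarts$log, paths$restart_log)
    saveRDS(restarts$model, paths$model)

    val_probs <- predict(restarts$model,
                         encoded_subset(enc, is_split("validation")))
    val_y <- ds$label[is_split("validation")]
    rules <- c(list(single = optimise_single(val_probs, val_y)),
               setNames(purrr::map(cfg$uncertainty_targets, function(u) {
                 optimise_double(val_probs, val_y, u, seed = cfg$seed + 29L)
               }), sprintf("double_u%02d", round(100 * cfg$uncertainty_targets))))
    write_threshold_rules(rules, paths$thresholds)

    ev <- evaluate_pipeline(restarts$model, rules,
                            encoded_subset(enc, is_split("test")),
                            ds$label[is_split("test")],
                            ds$patient_id[is_split("test")], window = w)
    readr::write_csv(ev, paths$evaluation_csv)
    jsonlite::write_json(ev, paths$evaluation_json, auto_unbox = TRUE, digits = NA)

    jsonlite::write_json(
      list(window = if (is.finite(w)) w else "inf", seed = cfg$seed,
           generator_seed = gen_cfg$seed, split_seed = cfg$seed + 17L,
           train_seed = tcfg$seed, threshold_seed = cfg$seed + 29L,
           n_visits = nrow(ds), n_patients = dplyr::n_distinct(ds$patient_id),
           prevalence = mean(ds$label), max_len = max_len,
           vocab_size = nrow(vocab)),
      paths$run_log, auto_unbox = TRUE, digits = NA)
    writeLines(stage_hash, paths$hash)

    evals[[.window_tag(w)]] <- ev
    results[[.window_tag(w)]] <- list(
      search = search, restarts = restarts, rules = rules,
      prevalence = mean(ds$label), n_visits = nrow(ds),
      dataset = ds, encoded = enc, paths = paths, resumed = FALSE)
  }
  structure(list(evaluation = {
    ev <- dplyr::bind_rows(evals)
    class(ev) <- c("cvd_evaluation", class(ev))
    ev
  }, windows = results, config = cfg, out_dir = out_dir),
  class = "cvd_experiment")
}

#' @export
print.cvd_experiment <- function(x, ...) {
  cat("<cvd_experiment>", length(x$windows), "window(s), outputs in",
      x$out_dir, "\n")
  print(dplyr::select(x$evaluation, dplyr::all_of(c(
    "setting", "window", "uncertainty_level", "auprc", "precision", "recall",
    "f1"))))
  invisible(x)
}
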