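# End-to-end orchestration: fixture corpus -> patient split -> conditioning ->
# generator training -> generation -> intrinsic metrics -> memorisation audit
# -> extrinsic classification, with per-stage seeds derived from one master
# seed, file digests, and a JSON run manifest.

PIPELINE_VERSION <- "synthnotes-pipeline-v1"

#' Pipeline configuration
#'
#' @param corpus a [synth_config()] (fixture corpus generated in-run) or a
#'   path to an existing corpus exchange file.
#' @param setups conditioning setups to run; `"key"` is the no-model copy
#'   baseline.
#' @param split_fractions train/validation/test patient fractions.
#' @param generator a [generator_config()] template (its seed is replaced by a
#'   stage seed derived from `seed`).
#' @param audit memorisation-audit settings: `list(setup =, ns =, k =)`, or
#'   `NULL` to skip the stage. The audited setup must be a trained one.
#' @param extrinsic extrinsic-evaluation settings: `list(setups =,
#'   classifiers =, n_runs =, cv_folds =, n_topics =, train_fraction =)`, or
#'   `NULL` to skip.
#' @param keep_fraction `top_meta` selection quantile ([select_phrases()]).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage seed is derived from it.
#' @return config list, classed `pipeline_config`.
#' @export
pipeline_config <- function(corpus = synth_config(),
                            setups = c("all", "top_meta", "one_meta", "key"),
                            split_fractions = c(0.8, 0.1, 0.1),
                            generator = generator_config(),
                            audit = list(setup = "top_meta", ns = c(2L, 3L),
                                         k = 200L),
                            extrinsic = NULL,
                            keep_fraction = 0.6,
                            out_dir = tempfile("synthnotes_run_"),
                            seed = 1L) {
  setups <- match.arg(setups, c("all", "top_meta", "one_meta", "key"),
                      several.ok = TRUE)
  if (!is.null(audit) && !audit$setup %in% setdiff(setups, "key")) {
    stop("audit setup '", audit$setup, "' is not among the trained setups")
  }
  cfg <- list(corpus = corpus, setups = setups,
              split_fractions = split_fractions, generator = generator,
              audit = audit, extrinsic = extrinsic,
              keep_fraction = keep_fraction, out_dir = out_dir,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# per-stage seed derivation: documented fixed rule keyed on the stage name
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 1009) %% 2147483647)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_classes)
  }
  x
}

config_json <- function(cfg) {
  jsonlite::toJSON(strip_classes(unclass(cfg)), auto_unbox = TRUE,
                   digits = NA, null = "null")
}

#' Run the full pipeline
#'
#' Stages run in dependency order; every artifact is a plain file under
#' `out_dir` and is recorded in the manifest with its MD5 digest. Re-invoking
#' a completed run with an unchanged config returns the recorded manifest
#' without recomputation.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress lines.
#' @return the run manifest (config snapshot, per-stage seeds, file digests,
#'   stage timings, metric summaries), classed `run_manifest`; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_json <- config_json(cfg)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::fromJSON(readLines(manifest_path), simplifyVector = FALSE)
    if (identical(as.character(old$config_snapshot), as.character(cfg_json)) &&
        all(file.exists(file.path(cfg$out_dir, names(old$files)))) &&
        identical(unname(vapply(old$files, as.character, character(1))),
                  unname(as.character(tools::md5sum(
                    file.path(cfg$out_dir, names(old$files))))))) {
      say("run already complete; returning recorded manifest")
      class(old) <- "run_manifest"
      return(old)
    }
  }
  files <- character(0)
  timings <- list()
  seeds <- list()
  metrics <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("stage %-14s %6.1fs", name, timings[[name]])
    res
  }
  rel <- function(p) sub(paste0("^", cfg$out_dir, "/?"), "", p)
  track <- function(path) files <<- union(files, rel(path))

  # -- corpus ---------------------------------------------------------------
  answer_key <- NULL
  corpus <- t_stage("corpus", {
    if (inherits(cfg$corpus, "synth_config")) {
      sc <- cfg$corpus
      sc$seed <- stage_seed(cfg$seed, "corpus")
      seeds$corpus <- sc$seed
      syn <- generate_corpus(sc)
      answer_key <- syn$answer_key
      write_corpus(syn$corpus, file.path(cfg$out_dir, "corpus.tsv"))
      key_json <- jsonlite::toJSON(
        list(markers = syn$answer_key$markers,
             planted = syn$answer_key$planted),
        auto_unbox = TRUE, digits = NA)
      writeLines(key_json, file.path(cfg$out_dir, "answer_key.json"))
      track("answer_key.json")
      syn$corpus
    } else {
      file.copy(cfg$corpus, file.path(cfg$out_dir, "corpus.tsv"),
                overwrite = TRUE)
      read_corpus(cfg$corpus)
    }
  })
  track("corpus.tsv")

  # -- split ----------------------------------------------------------------
  seeds$split <- stage_seed(cfg$seed, "split")
  split <- t_stage("split", {
    sp <- split_by_patient(corpus, cfg$split_fractions, seeds$split)
    for (part in names(sp)) {
      write_corpus(sp[[part]], file.path(cfg$out_dir, paste0(part, ".tsv")))
      track(paste0(part, ".tsv"))
    }
    sp
  })
  stopwords <- load_stopwords()
  metrics$genuine <- list(
    mean_sentence_length =
      corpus_statistics(split$test)$mean_sentence_length)

  # -- per-setup: condition, train, generate, evaluate ----------------------
  models <- list()
  for (setup in cfg$setups) {
    pairs_train <- t_stage(paste0("condition_", setup), {
      p <- conditioned_pairs(split$train, setup, stopwords, cfg$keep_fraction)
      write_pairs(p, file.path(cfg$out_dir, paste0("pairs_train_", setup)))
      track(paste0("pairs_train_", setup, ".input.txt"))
      track(paste0("pairs_train_", setup, ".target.txt"))
      p
    })
    pairs_val <- conditioned_pairs(split$validation, setup, stopwords,
                                   cfg$keep_fraction)
    pairs_test <- conditioned_pairs(split$test, setup, stopwords,
                                    cfg$keep_fraction)
    write_pairs(pairs_test, file.path(cfg$out_dir, paste0("pairs_test_", setup)))
    track(paste0("pairs_test_", setup, ".input.txt"))
    track(paste0("pairs_test_", setup, ".target.txt"))

    if (setup == "key") {
      gen <- run_copy_baseline(pairs_test)
      ppl <- NULL
    } else {
      gcfg <- cfg$generator
      gcfg$seed <- stage_seed(cfg$seed, paste0("train_", setup))
      seeds[[paste0("train_", setup)]] <- gcfg$seed
      model <- t_stage(paste0("train_", setup), {
        m <- train_generator(pairs_train, pairs_val, gcfg)
        save_generator(m, file.path(cfg$out_dir, paste0("model_", setup, ".rds")))
        track(paste0("model_", setup, ".rds"))
        m
      })
      models[[setup]] <- model
      gen <- t_stage(paste0("generate_", setup),
                     generate_text(model, pairs_test))
      ppl <- perplexity(model, pairs_test)
    }
    gen_corpus <- generated_corpus(split$test, gen)
    write_corpus(gen_corpus, file.path(cfg$out_dir, paste0("generated_", setup, ".tsv")))
    track(paste0("generated_", setup, ".tsv"))
    report <- evaluate_corpus(gen_corpus, split$test, model_ppl = ppl)
    write_metric_report(report, file.path(cfg$out_dir, paste0("metrics_", setup)))
    track(paste0("metrics_", setup, ".metrics.txt"))
    track(paste0("metrics_", setup, ".ter.txt"))
    metrics[[setup]] <- report[c("rouge_l", "bleu", "ter",
                                 "mean_sentence_length", "ppl")]
    say("eval %-10s ROUGE-L %.3f BLEU %.2f TER %.3f len %.2f", setup,
        report$rouge_l, report$bleu, report$ter, report$mean_sentence_length)
  }

  # -- memorisation audit ---------------------------------------------------
  if (!is.null(cfg$audit)) {
    seeds$audit <- stage_seed(cfg$seed, "audit")
    audit_tab <- t_stage("audit", {
      idx <- build_ngram_index(split$train, cfg$audit$ns)
      memorisation_report(models[[cfg$audit$setup]], split$train, idx,
                          ns = cfg$audit$ns, k = cfg$audit$k,
                          seed = seeds$audit, stopwords = stopwords,
                          keep_fraction = cfg$keep_fraction)
    })
    utils::write.table(audit_tab, file.path(cfg$out_dir, "audit.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    track("audit.tsv")
    metrics$audit <- audit_tab
  }

  # -- extrinsic classification --------------------------------------------
  if (!is.null(cfg$extrinsic)) {
    ex <- cfg$extrinsic
    seeds$extrinsic <- stage_seed(cfg$seed, "extrinsic")
    ex_res <- t_stage("extrinsic", {
      run_extrinsic_stage(cfg, ex, split, stopwords, models, seeds$extrinsic)
    })
    utils::write.table(ex_res$samples, file.path(cfg$out_dir, "extrinsic_f1.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    track("extrinsic_f1.tsv")
    utils::write.table(ex_res$ks, file.path(cfg$out_dir, "extrinsic_ks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    track("extrinsic_ks.tsv")
    metrics$extrinsic <- ex_res$ks
  }

  manifest <- list(
    version = PIPELINE_VERSION,
    config_snapshot = as.character(cfg_json),
    seeds = seeds,
    timings = timings,
    metrics = metrics,
    extrinsic_skipped = is.null(cfg$extrinsic),
    audit_skipped = is.null(cfg$audit),
    out_dir = cfg$out_dir,
    files = as.list(stats::setNames(
      as.character(tools::md5sum(file.path(cfg$out_dir, files))), files))
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             manifest_path)
  class(manifest) <- "run_manifest"
  manifest
}

# extrinsic stage: patient-disjoint classification split inside the test set,
# regimes = genuine plus the generated corpora of the requested setups
run_extrinsic_stage <- function(cfg, ex, split, stopwords, models, seed) {
  train_fraction <- if (!is.null(ex$train_fraction)) ex$train_fraction else 0.7
  class_split <- split_by_patient(split$test,
                                  c(train_fraction, 0, 1 - train_fraction),
                                  seed)
  gen_train <- class_split$train
  gen_test <- class_split$test
  regimes <- list(genuine = labelled_documents(gen_train))
  for (setup in ex$setups) {
    pairs <- conditioned_pairs(gen_train, setup, stopwords, cfg$keep_fraction)
    out <- if (setup == "key") run_copy_baseline(pairs) else
      generate_text(models[[setup]], pairs)
    regimes[[setup]] <- labelled_documents(generated_corpus(gen_train, out))
  }
  res <- run_protocol(
    regimes, labelled_documents(gen_test),
    classifiers = ex$classifiers,
    n_runs = if (!is.null(ex$n_runs)) ex$n_runs else 5L,
    cv_folds = ex$cv_folds, seed = seed,
    lda_reference = split$train,
    n_topics = if (!is.null(ex$n_topics)) ex$n_topics else 10L,
    config = if (!is.null(ex$config)) ex$config else list()
  )
  ks_rows <- list()
  for (clf in unique(res$samples$classifier)) {
    base <- res$samples$f1[res$samples$classifier == clf &
                             res$samples$regime == "genuine"]
    for (regime in setdiff(names(regimes), "genuine")) {
      s <- res$samples$f1[res$samples$classifier == clf &
                            res$samples$regime == regime]
      ks <- ks_two_sample(base[!is.na(base)], s[!is.na(s)])
      ks_rows[[length(ks_rows) + 1L]] <- data.frame(
        classifier = clf, regime = regime, D = ks$statistic,
        p_value = ks$p_value, n1 = ks$n1, n2 = ks$n2,
        mean_f1_genuine = mean(base, na.rm = TRUE),
        mean_f1_regime = mean(s, na.rm = TRUE), stringsAsFactors = FALSE
      )
    }
  }
  list(samples = res$samples, ks = do.call(rbind, ks_rows))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s\n  out_dir: %s\n  files: %d tracked\n",
              x$version, x$out_dir, length(x$files)))
  invisible(x)
}

#' Cross-setup comparison table
#'
#' One row per setup with the intrinsic metrics, plus a `genuine` row carrying
#' only the mean sentence length (there is nothing to compare it against).
#' The manifests must come from the same corpus.
#'
#' @param manifests list of `run_manifest` objects (or a single one).
#' @return data frame with columns `setup`, `ppl`, `rouge_l`, `bleu`, `ter`,
#'   `mean_sentence_length`.
#' @export
compare_setups <- function(manifests) {
  if (inherits(manifests, "run_manifest")) manifests <- list(manifests)
  digests <- vapply(manifests, function(m) {
    as.character(m$files[["corpus.tsv"]])
  }, character(1))
  if (length(unique(digests)) != 1L) {
    stop("manifests come from different corpora")
  }
  rows <- list(data.frame(
    setup = "genuine", ppl = NA_real_, rouge_l = NA_real_, bleu = NA_real_,
    ter = NA_real_,
    mean_sentence_length = manifests[[1]]$metrics$genuine$mean_sentence_length,
    stringsAsFactors = FALSE
  ))
  for (m in manifests) {
    for (setup in setdiff(names(m$metrics),
                          c("genuine", "audit", "extrinsic"))) {
      mt <- m$metrics[[setup]]
      ppl <- if (is.null(mt$ppl) || identical(setup, "key")) NA_real_ else
        as.numeric(mt$ppl)
      rows[[length(rows) + 1L]] <- data.frame(
        setup = setup, ppl = ppl, rouge_l = as.numeric(mt$rouge_l),
        bleu = as.numeric(mt$bleu), ter = as.numeric(mt$ter),
        mean_sentence_length = as.numeric(mt$mean_sentence_length),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
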