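#' Configure an end-to-end modelling study
#'
#' Bundles every stage's settings: the input (a CSV path or a
#' [synthetic_spec()]), split counts and seed, feature selection, the
#' model roster, applicability-domain variance target, sensitivity mode
#' and PBT thresholds.
#'
#' @param input A file path to a descriptor CSV or a `synthetic_spec`.
#' @param out_dir Output directory for stage artifacts.
#' @param split_sizes `c(train, verify, test)` counts, or `NULL` to use
#'   [default_split_sizes()] (15%/15% floored, remainder to train).
#' @param seed Integer seed recorded into every artifact.
#' @param selection `NULL` to skip feature selection, or a list with
#'   `method` (`"ga"`, `"forward"`, `"backward"`), optional `config`
#'   ([ga_config()]), `patience` (stepwise) and `forced_in` (curated
#'   descriptors appended to the selection).
#' @param models Named list of model declarations, each a list with
#'   `kind` (`"mlp"`, `"rbf"`, `"grnn"`, `"linear"`, `"ridge"`, `"knn"`)
#'   and kind-specific fields (`spec` for mlp, `centers` for rbf, `hyper`
#'   for baselines).
#' @param variance_target Applicability-domain variance target.
#' @param sensitivity_mode `"mean_substitution"` or `"retrain"`; the
#'   sensitivity stage runs on the first model in `models`.
#' @param thresholds A [pbt_thresholds()].
#' @param id_col,target_col Column names used when `input` is a CSV path.
#' @return A `study_config`.
#' @export
study_config <- function(input, out_dir,
                         split_sizes = NULL, seed = 1L,
                         selection = list(method = "ga",
                                          config = ga_config(preset = "ci"),
                                          forced_in = character(0)),
                         models = list(
                           mlp4 = list(kind = "mlp", spec = mlp_spec()),
                           linear = list(kind = "linear")),
                         variance_target = 0.95,
                         sensitivity_mode = "mean_substitution",
                         thresholds = pbt_thresholds(),
                         id_col = "compound_id", target_col = "logBCF") {
  if (is.character(input) && !file.exists(input)) {
    stop("config error: input file not found: ", input, call. = FALSE)
  }
  if (!is.character(input) && !inherits(input, "synthetic_spec")) {
    stop("config error: input must be a CSV path or a synthetic_spec",
         call. = FALSE)
  }
  structure(
    list(input = input, out_dir = out_dir, split_sizes = split_sizes,
         seed = as.integer(seed), selection = selection, models = models,
         variance_target = variance_target,
         sensitivity_mode = sensitivity_mode, thresholds = thresholds,
         id_col = id_col, target_col = target_col),
    class = "study_config"
  )
}

study_log <- function(con, stage, ...) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, ...)
  message(sprintf("[%s] %s", stage,
                  paste(names(entry)[-(1:2)], unlist(entry[-(1:2)]),
                        sep = "=", collapse = " ")))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  invisible(entry)
}

#' Run a complete modelling study
#'
#' Executes the study stages in order — load/simulate, clean, split,
#' feature selection, model training, assessment, applicability domain,
#' sensitivity, PBT classification — writing per-stage artifacts (CSV and
#' JSON) plus a `manifest.json` of seeds and artifact names to
#' `config$out_dir`, along with a machine-readable `log.jsonl`. Any stage
#' failure halts the run with a stage-named error; artifacts of completed
#' stages are preserved and the manifest records the failure point.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with the table, split, selection result,
#'   trained models, metrics, AD flags, sensitivity report and
#'   classification report.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (is.character(config$input) && !file.exists(config$input)) {
    stop("config error: input file not found: ", config$input, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "log.jsonl"), "w")
  on.exit(close(log_con))
  manifest <- list(seed = config$seed, artifacts = character(0),
                   failed_stage = NULL)
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  results <- list()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    study_log(log_con, name,
              elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 2))
    out
  }
  emit <- function(file) {
    manifest$artifacts <<- c(manifest$artifacts, file)
    file.path(config$out_dir, file)
  }

  # -- load or simulate ------------------------------------------------
  table <- stage("load", function() {
    if (inherits(config$input, "synthetic_spec")) {
      ds <- generate_dataset(config$input)
      write_descriptor_table(ds$table, emit("data.csv"))
      jsonlite::write_json(
        list(seed = config$input$seed, outlier_ids = ds$outlier_ids,
             intercept = config$input$intercept,
             noise_sd = config$input$noise_sd),
        emit("ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
      ds$table
    } else {
      read_descriptor_table(config$input, id_col = config$id_col,
                            target_col = config$target_col)
    }
  })
  if (is.null(table$logbcf)) {
    stop("stage 'load' failed: input has no logBCF target", call. = FALSE)
  }

  table <- stage("clean", function() {
    out <- clean_descriptors(table)
    removed <- attr(out, "removed")
    jsonlite::write_json(removed, emit("removed_descriptors.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    out
  })

  split <- stage("split", function() {
    sizes <- config$split_sizes
    if (is.null(sizes)) sizes <- default_split_sizes(n_compounds(table))
    sp <- split_dataset(table, sizes, seed = config$seed)
    jsonlite::write_json(unclass(sp), emit("split.json"), auto_unbox = FALSE,
                         pretty = TRUE)
    sp
  })

  selection <- stage("select", function() {
    if (is.null(config$selection)) {
      return(NULL)
    }
    method <- config$selection$method
    res <- switch(method,
      ga = {
        cfg <- config$selection$config
        if (is.null(cfg)) cfg <- ga_config(preset = "ci")
        cfg$seed <- config$seed
        ga_select(table, split, cfg)
      },
      forward = stepwise_select(table, "forward", split,
                                patience = config$selection$patience %||% 2),
      backward = stepwise_select(table, "backward", split,
                                 patience = config$selection$patience %||% 2),
      stop("unknown selection method: ", method, call. = FALSE))
    selected <- curate_subset(res, config$selection$forced_in %||% character(0),
                              table)
    jsonlite::write_json(list(method = res$method, selected = selected,
                              fitness = res$fitness),
                         emit("selection.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    utils::write.csv(res$history, emit("selection_trace.csv"),
                     row.names = FALSE)
    list(result = res, selected = selected)
  })
  model_table <- if (is.null(selection)) {
    table
  } else {
    subset_descriptors(table, selection$selected)
  }

  models <- stage("train", function() {
    fits <- lapply(names(config$models), function(nm) {
      decl <- config$models[[nm]]
      switch(decl$kind,
        mlp = {
          spec <- decl$spec %||% mlp_spec()
          train_mlp(model_table, split, spec)
        },
        rbf = train_rbf(model_table, split,
                        centers = decl$centers %||%
                          max(2L, length(split$train_ids) %/% 10L),
                        seed = config$seed),
        grnn = train_grnn(model_table, split),
        linear = ,
        ridge = ,
        knn = train_baseline(model_table, split, decl$kind,
                             decl$hyper %||% list())
      )
    })
    names(fits) <- names(config$models)
    for (nm in names(fits)) {
      write_model(fits[[nm]], emit(paste0("model_", nm, ".json")))
    }
    fits
  })

  metrics <- stage("assess", function() {
    rows <- lapply(names(models), function(nm) {
      cbind(model = nm, metrics_by_subset(models[[nm]], model_table, split))
    })
    out <- do.call(rbind, rows)
    utils::write.csv(out, emit("metrics.csv"), row.names = FALSE)
    out
  })

  ad <- stage("ad", function() {
    model <- fit_ad(subset_rows(model_table, split$train_ids),
                    variance_target = config$variance_target)
    flags <- ad_flag(model, model_table)
    utils::write.csv(flags, emit("ad_flags.csv"), row.names = FALSE)
    list(model = model, flags = flags)
  })

  sens <- stage("sensitivity", function() {
    report <- suppressWarnings(
      rank_descriptors(models[[1]], model_table, split,
                       mode = config$sensitivity_mode))
    utils::write.csv(report$ranking, emit("sensitivity.csv"),
                     row.names = FALSE)
    report
  })

  classification <- stage("classify", function() {
    eval_ids <- c(split$verify_ids, split$test_ids)
    sub <- subset_rows(model_table, eval_ids)
    rep <- classification_report(sub$logbcf, predict(models[[1]], sub),
                                 config$thresholds)
    utils::write.csv(as.data.frame(rep$confusion), emit("confusion.csv"),
                     row.names = FALSE)
    rep
  })

  write_manifest()
  invisible(list(table = table, split = split, selection = selection,
                 models = models, metrics = metrics, ad = ad,
                 sensitivity = sens, classification = classification,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
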