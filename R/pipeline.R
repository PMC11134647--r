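# Tiny FNV-1a hash over a serialized object; used to fingerprint the run
# configuration in the MANIFEST (no external digest dependency).
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, exclusion cascade, derived variables,
#' severity scoring, normality screening, sex-stratified structural model
#' fitting, effect decomposition with optional bootstrap inference, and
#' artifact writing. Artifacts: `attrition.json`, `table1.csv`,
#' `normality.json`, `fit_<sex>.json`, `effects_<sex>.csv`, `table2.csv`
#' (when both sexes are fitted), `MANIFEST.json` and `run.log`.
#'
#' @param config A configuration list, or a path to a YAML file with the same
#'   structure (paths inside the file resolve relative to the file). Fields:
#'   `input` (either `simulate = TRUE` with optional `n_male`/`n_female`, or
#'   `path = "cohort.csv"` with optional `schema`), `model` (model-spec path;
#'   default the packaged model), `strata` (default `c("male", "female")`),
#'   `exclusions` (logical, default `TRUE`), `bootstrap`
#'   (`list(enabled =, B =)`; default enabled with `B = 2000`), `seed`
#'   (mandatory when simulating or bootstrapping), `out_dir` (mandatory).
#' @param quiet Suppress console logging?
#' @return Invisibly, a list with the per-sex fits, effects tables and the
#'   manifest. Artifacts are written to `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    cfg_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    for (f in c("model")) if (!is.null(config[[f]]) &&
                              !file.exists(config[[f]]))
      config[[f]] <- file.path(cfg_dir, config[[f]])
    if (!is.null(config$input$path) && !file.exists(config$input$path))
      config$input$path <- file.path(cfg_dir, config$input$path)
    if (!is.null(config$out_dir) && !grepl("^/", config$out_dir))
      config$out_dir <- file.path(cfg_dir, config$out_dir)
  }
  if (is.null(config$out_dir)) stop("config is missing 'out_dir'")
  if (is.null(config$input)) stop("config is missing 'input'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strata <- config$strata %||% c("male", "female")
  boot <- config$bootstrap %||% list(enabled = TRUE, B = 2000L)
  if (is.null(boot$enabled)) boot$enabled <- TRUE
  boot$B <- as.integer(boot$B %||% 2000L)
  needs_seed <- isTRUE(config$input$simulate) || isTRUE(boot$enabled)
  if (needs_seed && is.null(config$seed))
    stop("config is missing 'seed' (required for stochastic stages)")
  seed <- as.integer(config$seed %||% 0L)
  log_lines <- character(0)
  warnings_seen <- character(0)
  manifest <- list(package = "metsem",
                   version = as.character(utils::packageVersion("metsem")),
                   seed = seed, config_hash = .config_hash(config),
                   complete = FALSE, stages = list(), artifacts = character(0))
  t_all <- proc.time()[3]
  log_stage <- function(stage, msg) {
    line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen,
                          paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[stage]] <<- list(elapsed_s = round(proc.time()[3] - t0, 3))
    log_stage(stage, sprintf("done in %.2fs", proc.time()[3] - t0))
    res
  }
  emit <- function(name) manifest$artifacts <<- c(manifest$artifacts, name)
  finish <- function() {
    manifest$warnings <- as.list(warnings_seen)
    manifest$elapsed_s <- round(proc.time()[3] - t_all, 2)
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  on.exit(finish())

  # --- input ---------------------------------------------------------------
  data <- run_stage("input", {
    if (isTRUE(config$input$simulate)) {
      parts <- lapply(seq_along(strata), function(i) {
        s <- strata[i]
        nn <- config$input[[paste0("n_", s)]]
        generate_cohort(default_config(s, n = nn), seed = seed + i)
      })
      do.call(rbind, parts)
    } else if (!is.null(config$input$path)) {
      read_cohort(config$input$path, schema = config$input$schema)
    } else stop("config$input needs either 'simulate: true' or a 'path'")
  })

  # --- exclusions ----------------------------------------------------------
  if (!identical(config$exclusions, FALSE)) {
    excl <- run_stage("exclude", {
      rules <- default_exclusion_rules()
      rules <- Filter(function(r)
        all(all.vars(r$predicate) %in% names(data)), rules)
      apply_exclusions(data, rules)
    })
    data <- excl$table
    jsonlite::write_json(as.list(excl$report),
                         file.path(out_dir, "attrition.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(utils::capture.output(print(excl$report)),
               file.path(out_dir, "attrition.txt"))
    emit("attrition.json")
  }

  # --- derived variables ---------------------------------------------------
  data <- run_stage("derive", {
    pa_col <- if ("physical_activity" %in% names(data)) "physical_activity"
              else "met_hours"
    if (pa_col %in% names(data))
      data$activity_category <- pa_category(pmax(data[[pa_col]], 24))
    item_cols <- grep("^ses_item", names(data), value = TRUE)
    if (length(item_cols) >= 2) {
      ses <- ses_index(data[, item_cols])
      data$ses <- ses$score
      data$ses_tertile <- ses$tertile
    } else if ("ses" %in% names(data) && is.numeric(data$ses) &&
               length(unique(data$ses)) >= 3) {
      cuts <- stats::quantile(data$ses, c(1 / 3, 2 / 3), na.rm = TRUE,
                              names = FALSE)
      data$ses_tertile <- factor(
        c("low", "moderate", "high")[findInterval(data$ses, cuts) + 1L],
        levels = c("low", "moderate", "high"), ordered = TRUE)
    }
    data
  })

  # --- severity score ------------------------------------------------------
  data <- run_stage("score", {
    if (!"mets_severity" %in% names(data) &&
        all(c("wc", "hdl", "sbp", "tg", "fbs") %in% names(data)))
      data <- score_table(data)
    data
  })
  if (!"mets_severity" %in% names(data))
    stop("no MetS severity column and no component columns to compute it")

  # --- model ---------------------------------------------------------------
  model <- run_stage("model", {
    if (is.null(config$model)) default_model()
    else {
      if (!file.exists(config$model))
        stop("config field 'model' names a missing file: ", config$model)
      parse_model(config$model, file = TRUE)
    }
  })

  # --- normality screen ----------------------------------------------------
  screen <- run_stage("screen", {
    normality_screen(data, intersect(model$observed, names(data)))
  })
  jsonlite::write_json(as.list(as.data.frame(screen)),
                       file.path(out_dir, "normality.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  emit("normality.json")

  # --- descriptive table ---------------------------------------------------
  tab1 <- run_stage("describe", {
    vars <- intersect(c("age", "residence", "ses_tertile",
                        "activity_category", "mets", "mets_severity", "bmi",
                        "wc", "bfm", "sleep_duration", "sleep_latency",
                        "nap_duration", "night_shift"), names(data))
    describe_by_sex(data, vars)
  })
  utils::write.csv(tab1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  emit("table1.csv")

  # --- per-sex fits --------------------------------------------------------
  fits <- list(); effects <- list()
  all_converged <- TRUE
  for (s in intersect(strata, levels(factor(data$sex)))) {
    sub <- data[data$sex == s, , drop = FALSE]
    fit <- run_stage(paste0("fit_", s), fit_ml(model, sub))
    all_converged <- all_converged && fit$converged
    fits[[s]] <- fit
    idx <- fit$indices
    jsonlite::write_json(list(
      sex = s, n = fit$n, fml = fit$fml, chi2 = fit$chi2, df = fit$df,
      converged = fit$converged, grad_norm = fit$grad_norm,
      indices = as.list(stats::setNames(as.numeric(idx), names(idx))),
      acceptable = isTRUE(attr(idx, "acceptable")),
      r_squared = as.list(fit$r2),
      parameters = fit$params),
      file.path(out_dir, paste0("fit_", s, ".json")),
      auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", digits = NA)
    emit(paste0("fit_", s, ".json"))
    eff <- run_stage(paste0("effects_", s), {
      if (isTRUE(boot$enabled))
        bootstrap_effects(model, sub, B = boot$B,
                          seed = seed + 1000L + match(s, strata))
      else decompose_effects(fit)
    })
    attr(eff, "sex") <- s
    effects[[s]] <- eff
    utils::write.csv(cbind(sex = s, as.data.frame(eff)),
                     file.path(out_dir, paste0("effects_", s, ".csv")),
                     row.names = FALSE)
    emit(paste0("effects_", s, ".csv"))
  }

  # --- combined report -----------------------------------------------------
  if (all(c("male", "female") %in% names(effects))) {
    t2 <- report_table2(effects$male, effects$female)
    utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    emit("table2.csv")
  }
  manifest$complete <- TRUE
  if (!all_converged)
    stop("one or more structural model fits did not converge; ",
         "artifacts retained in ", out_dir)
  invisible(list(fits = fits, effects = effects, manifest = manifest,
                 data = data, out_dir = out_dir))
}

#' Side-by-side effects report for the two sexes
#'
#' Combines the male and female effects tables into one layout: per predictor
#' the standardized direct, indirect and total effects per sex, starred at
#' bootstrap p < 0.05, followed by the numeric inference columns when
#' available.
#'
#' @param effects_m,effects_f `effects_table`s sharing the same predictor
#'   rows (from [decompose_effects()] or [bootstrap_effects()]).
#' @return A data frame, one row per predictor.
#' @export
report_table2 <- function(effects_m, effects_f) {
  pm <- effects_m$predictor; pf <- effects_f$predictor
  if (!setequal(pm, pf) || length(pm) != length(pf))
    stop("predictor sets differ: ",
         paste(union(setdiff(pm, pf), setdiff(pf, pm)), collapse = ", "))
  effects_f <- effects_f[match(pm, pf), , drop = FALSE]
  star <- function(est, p) {
    ifelse(is.na(est), NA_character_,
           paste0(formatC(est, digits = 3, format = "f"),
                  ifelse(!is.na(p) & p < 0.05, "*", "")))
  }
  col <- function(tab, ty) {
    p <- tab[[paste0(ty, "_p")]] %||% rep(NA_real_, nrow(tab))
    star(tab[[ty]], p)
  }
  out <- data.frame(predictor = pm, stringsAsFactors = FALSE)
  for (ty in c("direct", "indirect", "total"))
    out[[paste0("men_", ty)]] <- col(effects_m, ty)
  for (ty in c("direct", "indirect", "total"))
    out[[paste0("women_", ty)]] <- col(effects_f, ty)
  for (pre in c("men", "women")) {
    tab <- if (pre == "men") effects_m else effects_f
    for (ty in c("direct", "indirect", "total")) {
      for (sfx in c("ci_low", "ci_high", "p")) {
        nm <- paste0(ty, "_", sfx)
        if (!is.null(tab[[nm]])) out[[paste0(pre, "_", nm)]] <- tab[[nm]]
      }
    }
  }
  out
}
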