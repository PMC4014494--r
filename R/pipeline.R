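## Orchestration: simulate -> drop transient -> estimate exponents per
## age class -> summarise -> pairwise tests -> threshold, plus CSV/JSON
## artifact output and analysis of user-supplied series.

#' Experiment configuration
#'
#' Bundles the treatment panel and the analysis defaults: 50-sample
#' transient cut, embedding `m = 2`, `d = 1` for scalar analyses (`m = 3`
#' for Poincare sections), recurrence neighbourhood `eps = 1` abundance
#' unit, Kantz neighbour gate `nf_min = 10`, significance level 0.05.
#'
#' @param concentrations Concentration panel, ug/l; must include the
#'   control 0. Default `c(0, 2.5, 5, 10, 20, 40)`.
#' @param n_runs Runs per concentration (shared seeds across the panel).
#' @param n_days Simulated days per run.
#' @param base_seed Global seed; run `i` uses `base_seed + i` at every
#'   concentration.
#' @param dose_response,life_history Model parameter objects.
#' @param n_cut Transient samples dropped before analysis.
#' @param m,d Embedding dimension/delay for scalar analyses.
#' @param m_poincare Embedding dimension for Poincare sections.
#' @param eps_recurrence Recurrence neighbourhood radius.
#' @param nf_min Kantz minimum-neighbour gate.
#' @param t_max Kantz look-ahead horizon (steps).
#' @param alpha Significance level for threshold detection.
#' @param age_classes Series analysed per run.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(concentrations = c(0, 2.5, 5, 10, 20, 40),
                              n_runs = 100L, n_days = 365L, base_seed = 1L,
                              dose_response = popchaos::dose_response(),
                              life_history = life_history_params(),
                              n_cut = 50L, m = 2L, d = 1L, m_poincare = 3L,
                              eps_recurrence = 1, nf_min = 10L, t_max = 12L,
                              alpha = 0.05,
                              age_classes = c("neonates", "juveniles",
                                              "adults", "total")) {
  stopifnot(0 %in% concentrations, !anyDuplicated(concentrations),
            all(concentrations >= 0), n_runs >= 2,
            n_days > n_cut + 100L, alpha > 0, alpha < 1)
  structure(list(concentrations = sort(concentrations),
                 n_runs = as.integer(n_runs), n_days = as.integer(n_days),
                 base_seed = as.integer(base_seed),
                 dose_response = dose_response, life_history = life_history,
                 n_cut = as.integer(n_cut), m = as.integer(m),
                 d = as.integer(d), m_poincare = as.integer(m_poincare),
                 eps_recurrence = eps_recurrence, nf_min = as.integer(nf_min),
                 t_max = as.integer(t_max), alpha = alpha,
                 age_classes = age_classes),
            class = "experiment_config")
}

## Internal: per-run, per-class exponents for a list of abundance series
## at one concentration.  Failures are recorded as flagged NA records.
lambda_records <- function(series_list, concentration, config) {
  rows <- list()
  for (s in series_list) {
    run <- attr(s, "run")
    for (cls in config$age_classes) {
      x <- tryCatch(drop_transient(s[[cls]], config$n_cut),
                    error = function(e) NULL)
      est <- if (is.null(x)) NULL else tryCatch(
        estimate_max_lyapunov(x, m = config$m, d = config$d,
                              nf_min = config$nf_min, t_max = config$t_max),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        concentration = concentration, age_class = cls, run = run,
        lambda = if (is.null(est)) NA_real_ else est$lambda,
        flagged = is.null(est) || length(est$flags) > 0)
    }
  }
  do.call(rbind, rows)
}

#' Run the full simulated experiment
#'
#' For every concentration in the panel a Monte-Carlo ensemble is
#' simulated (seeds shared across concentrations for run pairing); each
#' run's post-transient series (per age class and total) is characterised
#' by its maximal Lyapunov exponent; the per-treatment distributions are
#' summarised and compared pairwise with paired signed-rank tests; the
#' lowest-effect concentration is extracted per age class.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, all artifacts are
#'   written there (see [write_result_bundle()]).
#' @param progress Print per-concentration progress?
#' @return A `result_bundle` list: `table` ([lyapunov_table()]),
#'   `summary`, `tests` (per age class), `thresholds` (per age class),
#'   `config`, `log` (seeds, counts, timing), and `paths` when written.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  tabs <- list()
  ensembles <- list()
  for (conc in config$concentrations) {
    cfg <- treatment_config(concentration = conc, n_days = config$n_days,
                            n_runs = config$n_runs,
                            base_seed = config$base_seed,
                            dose_response = config$dose_response,
                            life_history = config$life_history)
    ens <- run_ensemble(cfg)
    ensembles[[as.character(conc)]] <- ens
    tabs[[as.character(conc)]] <- lambda_records(ens, conc, config)
    if (progress) {
      message("concentration ", conc, " ug/l: ", length(ens), " runs done")
    }
  }
  table <- lyapunov_table(do.call(rbind, tabs))
  rownames(table) <- NULL
  tests <- lapply(stats::setNames(config$age_classes, config$age_classes),
                  function(cls) pairwise_tests(table, cls))
  thresholds <- lapply(tests, detect_threshold, alpha = config$alpha)
  bundle <- structure(list(
    table = table,
    summary = summarize_lyapunov(table, strict = FALSE),
    tests = tests,
    thresholds = thresholds,
    config = config,
    ensembles = ensembles,
    log = list(base_seed = config$base_seed,
               run_seeds = config$base_seed + seq_len(config$n_runs),
               n_flagged = sum(table$flagged),
               elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))),
    class = "result_bundle")
  if (!is.null(out_dir)) bundle <- write_result_bundle(bundle, out_dir)
  bundle
}

#' Write a result bundle to disk
#'
#' Layout: `conc_<value>/run_<i>.csv` abundance series with JSON sidecars,
#' `lambda_table.csv`, `summary.csv` (long layout:
#' `concentration,age_class,mean,sd,n`), `pairwise.csv`
#' (`conc_a,conc_b,age_class,p,n`), `threshold.json` and `log.json`.
#'
#' @param bundle A [run_experiment()] result (with ensembles).
#' @param out_dir Output directory (created if absent).
#' @return The bundle with `paths` filled in.
#' @export
write_result_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (conc in names(bundle$ensembles)) {
    cdir <- file.path(out_dir, paste0("conc_", conc))
    dir.create(cdir, showWarnings = FALSE)
    for (s in bundle$ensembles[[conc]]) {
      write_abundance_csv(s, file.path(cdir,
                                       paste0("run_", attr(s, "run"), ".csv")))
    }
  }
  utils::write.csv(bundle$table, file.path(out_dir, "lambda_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  pw <- do.call(rbind, lapply(names(bundle$tests), function(cls) {
    cbind(bundle$tests[[cls]]$pairs[c("conc_a", "conc_b")],
          age_class = cls, bundle$tests[[cls]]$pairs[c("p", "n")])
  }))
  utils::write.csv(pw, file.path(out_dir, "pairwise.csv"), row.names = FALSE)
  thr <- lapply(bundle$thresholds, function(t) {
    list(threshold = if (is.na(t$threshold)) "none" else t$threshold,
         alpha = t$alpha)
  })
  jsonlite::write_json(thr, file.path(out_dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$paths <- list(
    root = out_dir,
    lambda_table = file.path(out_dir, "lambda_table.csv"),
    summary = file.path(out_dir, "summary.csv"),
    pairwise = file.path(out_dir, "pairwise.csv"),
    threshold = file.path(out_dir, "threshold.json"),
    log = file.path(out_dir, "log.json"))
  bundle
}

#' Write / read one abundance series as CSV with JSON sidecar
#'
#' CSV header `day,neonates,juveniles,adults,total`; metadata
#' (`concentration`, `run`, `seed`) in `<file>.json`.
#'
#' @param s An [abundance_series()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(s, path) {
  stopifnot(inherits(s, "abundance_series"))
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  jsonlite::write_json(list(concentration = attr(s, "concentration"),
                            run = attr(s, "run"), seed = attr(s, "seed")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_abundance_csv
#' @param path CSV path to read; a `<file>.json` sidecar is used for
#'   metadata when present.
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- list(concentration = NA_real_, run = NA_integer_,
               seed = NA_integer_)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    got <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  abundance_series(df, concentration = as.numeric(meta$concentration),
                   run = as.integer(meta$run), seed = as.integer(meta$seed))
}

#' Analyse user-supplied abundance series
#'
#' Applies the identical analysis stages as [run_experiment()] (transient
#' cut, per-class exponents, summaries, paired tests, threshold) to
#' already-existing series, either a directory with the
#' `conc_<value>/run_<i>.csv` layout or an explicit list of
#' [abundance_series()] objects.
#'
#' @param source Directory path, or a list of `abundance_series` with
#'   `concentration` and `run` attributes set.
#' @param config An [experiment_config()]; simulation fields are ignored.
#' @return A `result_bundle` (without regenerated ensembles written).
#' @export
analyze_external <- function(source, config = experiment_config()) {
  if (is.character(source)) {
    dirs <- list.dirs(source, recursive = FALSE)
    dirs <- dirs[grepl("^conc_", basename(dirs))]
    if (length(dirs) == 0L) {
      stop("no conc_<value> subdirectories under ", source, call. = FALSE)
    }
    series <- list()
    for (dd in dirs) {
      conc <- as.numeric(sub("^conc_", "", basename(dd)))
      for (f in list.files(dd, pattern = "^run_.*\\.csv$",
                           full.names = TRUE)) {
        s <- tryCatch(read_abundance_csv(f), error = function(e) {
          stop("validation failed for ", f, ": ", conditionMessage(e),
               call. = FALSE)
        })
        if (is.na(attr(s, "concentration"))) attr(s, "concentration") <- conc
        if (is.na(attr(s, "run"))) {
          attr(s, "run") <- as.integer(sub("^run_([0-9]+)\\.csv$", "\\1",
                                           basename(f)))
        }
        series[[length(series) + 1L]] <- s
      }
    }
  } else {
    series <- source
  }
  min_len <- config$n_cut + 100L
  for (s in series) {
    if (nrow(s) < min_len) {
      stop("series (concentration ", attr(s, "concentration"), ", run ",
           attr(s, "run"), ") has ", nrow(s), " samples; at least ",
           min_len, " required (n_cut + 100)", call. = FALSE)
    }
  }
  concs <- vapply(series, function(s) as.numeric(attr(s, "concentration")),
                  numeric(1))
  tabs <- lapply(sort(unique(concs)), function(conc) {
    lambda_records(series[concs == conc], conc, config)
  })
  table <- lyapunov_table(do.call(rbind, tabs))
  rownames(table) <- NULL
  classes <- intersect(config$age_classes, unique(table$age_class))
  tests <- lapply(stats::setNames(classes, classes),
                  function(cls) pairwise_tests(table, cls))
  structure(list(table = table, summary = summarize_lyapunov(table, strict = FALSE),
                 tests = tests,
                 thresholds = lapply(tests, detect_threshold,
                                     alpha = config$alpha),
                 config = config, ensembles = NULL,
                 log = list(n_series = length(series),
                            n_flagged = sum(table$flagged))),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("popchaos result bundle:", length(unique(x$table$concentration)),
      "concentrations x", length(unique(x$table$run)), "runs\n")
  cat("Flagged estimates:", x$log$n_flagged, "of", nrow(x$table), "\n")
  for (cls in names(x$thresholds)) {
    t <- x$thresholds[[cls]]
    cat(sprintf("  %-10s lowest-effect concentration: %s\n", cls,
                if (is.na(t$threshold)) "none" else paste(t$threshold,
                                                          "ug/l")))
  }
  invisible(x)
}
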