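# Orchestration: simulate (or ingest) -> aggregate -> fit -> screen ->
# group statistics -> report bundle. Everything is deterministic per seed;
# screening decisions always appear in the audit output.

#' Pipeline run configuration
#'
#' Either simulation parameters (the default) or a trial table/path are
#' supplied, never both: the configuration describes exactly one data
#' source.
#'
#' @param experiment 1 or 2 (selects the design; see
#'   [experiment_design()]).
#' @param n_participants Number of simulated observers (defaults: 20 for
#'   design 1, 32 for design 2).
#' @param base Baseline [criterion_params()] of the simulated population.
#' @param pss_shift,shift_split,shifted_congruency,pss_sd,shift_sd
#'   Population parameters; see [sim_observer_population()].
#' @param trials A trial-record data frame, or `NULL`.
#' @param trials_path Path to a delimited trial table, or `NULL`.
#' @param fit A [fit_config()].
#' @param alpha Significance level used for screening and group tests.
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = 1,
                       n_participants = if (experiment == 1) 20L else 32L,
                       base = criterion_params(-213, 237, 90, 90),
                       pss_shift = 13.5, shift_split = 0.5,
                       shifted_congruency = "congruent",
                       pss_sd = 30, shift_sd = 18,
                       trials = NULL, trials_path = NULL,
                       fit = fit_config(), alpha = 0.05, seed = 1L) {
  if (!is.null(trials) && !is.null(trials_path))
    stop("supply at most one of trials and trials_path", call. = FALSE)
  structure(
    list(experiment = as.integer(experiment),
         n_participants = as.integer(n_participants), base = base,
         pss_shift = pss_shift, shift_split = shift_split,
         shifted_congruency = shifted_congruency,
         pss_sd = pss_sd, shift_sd = shift_sd,
         trials = trials, trials_path = trials_path,
         fit = fit, alpha = alpha, seed = as.integer(seed)),
    class = "run_config")
}

.pipeline_records <- function(config, design) {
  if (!is.null(config$trials_path))
    return(ingest_trials(config$trials_path, design))
  if (!is.null(config$trials))
    return(ingest_trials(config$trials, design))
  observers <- sim_observer_population(
    n = config$n_participants, base = config$base,
    pss_shift = config$pss_shift, pss_sd = config$pss_sd,
    shift_sd = config$shift_sd, shift_split = config$shift_split,
    shifted_congruency = config$shifted_congruency, seed = config$seed)
  # two independent per-participant seed streams: trial order and responses
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             2L * length(observers)), ncol = 2L)
  recs <- lapply(seq_along(observers), function(i) {
    tr <- enumerate_trials(design, participant = i, seed = seeds[i, 1L])
    simulate_responses(observers[[i]], tr, seed = seeds[i, 2L])
  })
  do.call(rbind, recs)
}

.fit_all_cells <- function(agg, config, by_congruency) {
  keys <- unique(agg[, c("participant", "condition",
                         if (by_congruency) "congruency")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    pid <- keys$participant[i]
    cond <- keys$condition[i]
    cg <- if (by_congruency) keys$congruency[i] else NULL
    cells <- cells_for(agg, pid, cond, cg)
    fit4 <- fit_criterion_model(cells, config$fit)
    fit2 <- fit_single_cdf(cells, config$fit)
    cmp <- model_comparison(fit4, fit2, config$alpha)
    rows[[i]] <- data.frame(
      participant = pid, condition = cond,
      congruency = if (by_congruency) cg else "congruent",
      c_low = fit4$params$c_low, c_high = fit4$params$c_high,
      sigma_low = fit4$params$sigma_low, sigma_high = fit4$params$sigma_high,
      pss = pss(fit4), window = sj_window(fit4),
      loglik = fit4$log_likelihood, deviance = fit4$deviance,
      loglik2 = fit2$log_likelihood, deviance2 = fit2$deviance,
      delta_deviance = cmp$delta_deviance,
      converged = fit4$converged && fit2$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.report_bundle <- function(config, design, records, fits, screening,
                           estimates, tests, means) {
  structure(
    list(version = as.character(packageVersion("sjrecal")),
         config = config, design = design,
         n_trials = nrow(records),
         n_participants_in = length(unique(records$participant)),
         n_participants_retained = length(unique(
           estimates$participant[estimates$retained])),
         n_nonconverged = sum(!fits$converged),
         fits = fits, screening = screening, estimates = estimates,
         tests = tests, condition_means = means),
    class = "sj_report")
}

#' @export
print.sj_report <- function(x, ...) {
  cat(sprintf("SJ analysis report (design %d, sjrecal %s, seed %d)\n",
              x$design$experiment, x$version, x$config$seed))
  cat(sprintf("  %d trials from %d participants; %d retained after screening; %d non-converged fits\n",
              x$n_trials, x$n_participants_in, x$n_participants_retained,
              x$n_nonconverged))
  cat("\nCondition means:\n")
  print(x$condition_means, row.names = FALSE)
  cat("\nGroup tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Run the single-factor adaptation analysis
#'
#' End-to-end analysis of design 1: simulate (or ingest) trials, pool the
#' congruent test pairings, fit the four- and two-parameter models per
#' participant and adaptation condition, screen on the nested-model
#' deviance criterion, and compare PSS and window between the
#' visual-leading and auditory-leading conditions with paired t tests on
#' the retained participants (difference taken visual minus auditory).
#'
#' @param config A [run_config()] with `experiment = 1`.
#' @return An `sj_report` bundle: fit table, screening audit, estimates,
#'   paired-t reports for PSS and window, condition means, configuration
#'   echo and package version.
#' @export
run_experiment_1 <- function(config = run_config(1)) {
  if (!inherits(config, "run_config") || config$experiment != 1L)
    stop("config must be a run_config with experiment = 1", call. = FALSE)
  design <- experiment_design(1)
  records <- .pipeline_records(config, design)
  agg <- aggregate_trials(records)
  fits <- .fit_all_cells(agg, config, by_congruency = FALSE)
  screening <- screen_participants(
    fits[, c("participant", "condition", "delta_deviance")], config$alpha)
  estimates <- merge(
    fits[, c("participant", "condition", "pss", "window", "converged")],
    unique(screening[, c("participant", "retained")]), by = "participant")
  kept <- estimates[estimates$retained, ]
  wide <- function(col) {
    v <- tapply(kept[[col]], list(kept$participant, kept$condition), mean)
    v[, c("visual_leading", "auditory_leading"), drop = FALSE]
  }
  pss_w <- wide("pss")
  win_w <- wide("window")
  tests <- rbind(
    cbind(measure = "pss",
          paired_t(pss_w[, 1L], pss_w[, 2L],
                   "visual_leading - auditory_leading")),
    cbind(measure = "window",
          paired_t(win_w[, 1L], win_w[, 2L],
                   "visual_leading - auditory_leading")))
  means <- data.frame(
    condition = c("visual_leading", "auditory_leading"),
    mean_pss = c(mean(pss_w[, 1L]), mean(pss_w[, 2L])),
    mean_window = c(mean(win_w[, 1L]), mean(win_w[, 2L])))
  .report_bundle(config, design, records, fits, screening, estimates,
                 tests, means)
}

#' Run the congruency x adaptation analysis
#'
#' End-to-end analysis of design 2: per-participant fits in each of the
#' four (adaptation condition x test congruency) cells, screening that
#' requires the four-parameter model to win in every cell, a 2x2
#' repeated-measures ANOVA on PSS (and on window) with congruency and
#' adaptation condition as within-subject factors, and simple main
#' effects of each factor within the levels of the other.
#'
#' @param config A [run_config()] with `experiment = 2`.
#' @return An `sj_report` bundle; `tests` holds the ANOVA and
#'   simple-effect rows for PSS and the ANOVA rows for window.
#' @export
run_experiment_2 <- function(config = run_config(2)) {
  if (!inherits(config, "run_config") || config$experiment != 2L)
    stop("config must be a run_config with experiment = 2", call. = FALSE)
  design <- experiment_design(2)
  records <- .pipeline_records(config, design)
  agg <- aggregate_trials(records)
  fits <- .fit_all_cells(agg, config, by_congruency = TRUE)
  screening <- screen_participants(
    fits[, c("participant", "condition", "congruency", "delta_deviance")],
    config$alpha)
  estimates <- merge(
    fits[, c("participant", "condition", "congruency", "pss", "window",
             "converged")],
    unique(screening[, c("participant", "retained")]), by = "participant")
  kept <- estimates[estimates$retained, ]
  tests <- rbind(
    cbind(measure = "pss", rm_anova_2x2(kept, "pss")),
    cbind(measure = "pss",
          simple_main_effects(kept, "pss", test_factor = "condition",
                              within_factor = "congruency")),
    cbind(measure = "pss",
          simple_main_effects(kept, "pss", test_factor = "congruency",
                              within_factor = "condition")),
    cbind(measure = "window", rm_anova_2x2(kept, "window")))
  means <- aggregate(list(mean_pss = kept$pss, mean_window = kept$window),
                     by = list(congruency = kept$congruency,
                               condition = kept$condition), FUN = mean)
  .report_bundle(config, design, records, fits, screening, estimates,
                 tests, means)
}

#' Validate and type a trial table
#'
#' Reads (or accepts) a trial table and checks it against a design:
#' required columns present, condition and pairing labels known, SOA
#' values on the declared grid, binary responses, congruency consistent
#' with the pairing. Errors name the offending column and row. An
#' external table with different column names can be mapped via
#' `column_map`.
#'
#' @param x A path to a delimited text file (header
#'   `participant,block,condition,pair_type,congruency,soa_ms,response,occasion`)
#'   or a data frame (column `soa` or `soa_ms`).
#' @param design An [experiment_design()] the trials must conform to.
#' @param column_map Optional named character vector mapping required
#'   names to the file's names, e.g. `c(soa_ms = "SOA")`.
#' @param sep Field separator when reading from a path.
#' @return A validated data frame with columns `participant`, `block`,
#'   `condition`, `pair_type`, `congruency`, `soa`, `response`,
#'   `occasion`.
#' @export
ingest_trials <- function(x, design, column_map = NULL, sep = ",") {
  if (!inherits(design, "experiment_design"))
    stop("design must be an experiment_design", call. = FALSE)
  df <- if (is.data.frame(x)) x
        else read.csv(x, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (want in names(column_map)) {
      have <- column_map[[want]]
      if (!have %in% names(df))
        stop(sprintf("mapped column '%s' not found", have), call. = FALSE)
      names(df)[names(df) == have] <- want
    }
  if ("soa_ms" %in% names(df) && !"soa" %in% names(df))
    names(df)[names(df) == "soa_ms"] <- "soa"
  req <- c("participant", "block", "condition", "pair_type", "congruency",
           "soa", "response", "occasion")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  fail <- function(column, row, msg)
    stop(sprintf("invalid trial table: column '%s', row %d: %s",
                 column, row, msg), call. = FALSE)
  bad <- which(!df$condition %in% design$conditions)
  if (length(bad))
    fail("condition", bad[1L],
         sprintf("unknown label '%s'", df$condition[bad[1L]]))
  bad <- which(!df$pair_type %in% design$pair_types)
  if (length(bad))
    fail("pair_type", bad[1L],
         sprintf("unknown pairing '%s'", df$pair_type[bad[1L]]))
  bad <- which(!df$soa %in% design$soa_grid)
  if (length(bad))
    fail("soa", bad[1L],
         sprintf("value %s is not on the declared SOA grid",
                 format(df$soa[bad[1L]])))
  bad <- which(!df$response %in% c(0L, 1L))
  if (length(bad))
    fail("response", bad[1L],
         sprintf("non-binary value '%s'", format(df$response[bad[1L]])))
  bad <- which(df$congruency != pair_congruency(df$pair_type))
  if (length(bad))
    fail("congruency", bad[1L],
         "label inconsistent with the pairing's pitch-elevation congruency")
  df <- df[, req]
  df$participant <- as.integer(df$participant)
  df$response <- as.integer(df$response)
  df
}

#' Write a trial table
#'
#' Delimited text with the canonical header (`soa` written as `soa_ms`);
#' the exact inverse of [ingest_trials()].
#'
#' @param records Trial records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  out <- records[, c("participant", "block", "condition", "pair_type",
                     "congruency", "soa", "response", "occasion")]
  names(out)[names(out) == "soa"] <- "soa_ms"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a report bundle to disk
#'
#' Machine-readable tables (`fits.csv`, `screening.csv`, `estimates.csv`,
#' `tests.csv`) plus a human-readable `summary.txt`.
#'
#' @param report An `sj_report` from [run_experiment_1()] or
#'   [run_experiment_2()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "sj_report"))
    stop("report must be an sj_report", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fits_out <- merge(report$fits,
                    unique(report$screening[, c("participant", "retained")]),
                    by = "participant")
  write.csv(fits_out, file.path(dir, "fits.csv"), row.names = FALSE)
  write.csv(report$screening, file.path(dir, "screening.csv"),
            row.names = FALSE)
  write.csv(report$estimates, file.path(dir, "estimates.csv"),
            row.names = FALSE)
  write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "summary.txt"))
  invisible(dir)
}
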