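#' Write / read a table as delimited text, round-trip exact
#'
#' Numeric columns are serialized with 17 significant digits, which is
#' sufficient for an IEEE double to survive a write-then-read round trip
#' bit-exactly.
#'
#' @param x A data frame.
#' @param path CSV file path.
#' @return \code{write_table} returns \code{path} invisibly;
#'   \code{read_table} returns a data frame.
#' @export
write_table <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
  }
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full simulate - estimate - validate pipeline
#'
#' Orchestrates the end-to-end analysis on synthetic data: generate the
#' area frame and the paired national/regional surveys; compute direct
#' estimates for both; fit the small-area model to the national survey's
#' area counts and bootstrap its MSEs; validate the model estimates against
#' the regional direct estimates; and write every intermediate table, the
#' validation report and a run log under \code{out_dir}. Identical
#' configuration and seed reproduce byte-identical tables.
#'
#' @param cfg A [sim_config()] (or path to a YAML config file).
#' @param out_dir Output directory, created if needed.
#' @param bootstrap_B Bootstrap replicates for the model MSEs.
#' @param stages Character vector of stages to run, a subset of
#'   \code{c("simulate", "direct", "sae", "validate", "report")} in that
#'   order; later stages require the earlier ones in the same call.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the \code{report}
#'   (\code{validation_report}), the \code{fit}, and \code{paths} of the
#'   written files.
#' @export
run_pipeline <- function(cfg, out_dir, bootstrap_B = 200,
                         stages = c("simulate", "direct", "sae", "validate", "report"),
                         quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_sim_config(cfg)
  validate_sim_config(cfg)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()
  log_lines <- c(
    sprintf("saeprev %s | R %s", as.character(utils::packageVersion("saeprev")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d | areas: %d | bootstrap B: %d", cfg$seed, n_areas(cfg), bootstrap_B),
    sprintf("stages: %s", paste(stages, collapse = ", "))
  )

  frame <- national <- regional <- NULL
  fit <- precision <- report <- NULL
  dir_nat <- dir_reg <- sae_tab <- NULL

  if ("simulate" %in% stages) {
    say("simulate: area frame and paired surveys")
    frame <- generate_area_frame(cfg)
    national <- generate_survey(frame, cfg, "national")
    regional <- generate_survey(frame, cfg, "regional")
    paths$frame <- write_table(frame, file.path(out_dir, "area_frame.csv"))
    paths$national <- write_table(national, file.path(out_dir, "microdata_national.csv"))
    paths$regional <- write_table(regional, file.path(out_dir, "microdata_regional.csv"))
    paths$config <- write_sim_config(cfg, file.path(out_dir, "config.yml"))
  }
  if ("direct" %in% stages) {
    if (is.null(frame)) stop("stage 'direct' requires 'simulate' in the same run")
    say("direct: weighted ratio estimates for both surveys")
    dir_nat <- direct_estimates(national, frame)
    dir_reg <- direct_estimates(regional, frame)
    paths$direct_national <- write_table(dir_nat, file.path(out_dir, "direct_national.csv"))
    paths$direct_regional <- write_table(dir_reg, file.path(out_dir, "direct_regional.csv"))
  }
  if ("sae" %in% stages) {
    if (is.null(frame)) stop("stage 'sae' requires 'simulate' in the same run")
    say("sae: fitting the mixed multinomial model to the national survey")
    counts <- aggregate_to_areas(national, frame)
    fit <- fit_sae(counts)
    say(sprintf("sae: bootstrap MSE, B = %d", bootstrap_B))
    precision <- mse_bootstrap(fit, B = bootstrap_B, seed = cfg$seed + 1000L)
    sae_tab <- sae_estimates(fit, precision)
    paths$sae <- write_table(sae_tab, file.path(out_dir, "sae_estimates.csv"))
    fit_summary <- data.frame(
      parameter = c(paste0("beta1_", seq_along(fit$beta1)),
                    paste0("beta2_", seq_along(fit$beta2)), "phi1", "phi2"),
      estimate = c(fit$beta1, fit$beta2, fit$phi))
    paths$fit <- write_table(fit_summary, file.path(out_dir, "sae_fit_summary.csv"))
    log_lines <- c(log_lines,
                   sprintf("sae: converged in %d iterations; phi = %.5f, %.5f; %d bootstrap refit failures",
                           fit$convergence$iterations, fit$phi[1], fit$phi[2],
                           attr(precision, "n_failed")))
  }
  if ("validate" %in% stages) {
    if (is.null(sae_tab) || is.null(dir_reg)) {
      stop("stage 'validate' requires 'direct' and 'sae' in the same run")
    }
    say("validate: concordance of model vs regional direct estimates")
    report <- concordance_report(dir_reg, sae_tab)
    paths$differences <- write_table(report$differences,
                                     file.path(out_dir, "differences.csv"))
    icc_tab <- do.call(rbind, lapply(names(report$icc), function(k) {
      r <- report$icc[[k]]
      data.frame(category = k, D = r$D, icc = r$icc,
                 ci_lower = r$ci_lower, ci_upper = r$ci_upper,
                 acceptable = r$acceptable)
    }))
    paths$icc <- write_table(icc_tab, file.path(out_dir, "icc.csv"))
    paths$cv_summary <- write_table(report$cv$summary,
                                    file.path(out_dir, "cv_summary.csv"))
    log_lines <- c(log_lines,
                   sprintf("validate: %d of %d difference CIs include zero (%.1f%%)",
                           report$zero_inclusion$n_zero, report$zero_inclusion$n_total,
                           report$zero_inclusion$overall_pct))
  }
  if ("report" %in% stages && !is.null(report)) {
    paths$report <- file.path(out_dir, "report.txt")
    con <- file(paths$report, open = "wt")
    sink(con); print(report); sink()
    close(con)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  say("done")
  invisible(list(report = report, fit = fit, precision = precision,
                 frame = frame, paths = paths))
}
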