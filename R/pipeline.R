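#' Run the full Differential Distribution pipeline
#'
#' Orchestrates: parse -> preprocess -> stratify -> per stratum: per-code
#' diagnosis table, Differential Distribution (DD), optional code clustering
#' with cluster-level table and "DD with Clustering", reference intervals for
#' GD / DD / DD_clustered, and DD-vs-GD comparison verdicts. Strata below the
#' RI sample floor are reported and skipped with a warning rather than
#' failing the run. All artifacts are returned, and written as CSV/JSON when
#' `output_dir` is given; outputs are byte-identical for identical
#' configuration and seed.
#'
#' @param input Path to a delimited result table, a raw data frame in the
#'   dialect, or a `ddm_simulation`.
#' @param output_dir Optional directory for the run artifacts
#'   (`diagnosis_tables.csv`, `cluster_tables.csv`,
#'   `cluster_assignments.csv`, `ri_report.csv`, `removed_results.csv`,
#'   `audit.csv`, `run_log.json`).
#' @param dialect A [lab_dialect()].
#' @param value_min,value_max,age_min,age_max,strict_code_filter Passed to
#'   [preprocess_results()].
#' @param band_width Age band width in years.
#' @param alpha Significance level on the q-values.
#' @param normality_alpha Level of the Shapiro-Wilk screen.
#' @param min_n Minimum group size for testing (default 6).
#' @param compare_to_complement,use_p Testing variants; see
#'   [build_diagnosis_table()].
#' @param clustering Run the code-clustering branch as well.
#' @param k,cluster_method,linkage,distance_mode Clustering parameters; see
#'   [cluster_codes()].
#' @param embedding_dim,embedding_window,embedding_epochs,embedding_min_count
#'   Embedding parameters; see [train_code_embeddings()].
#' @param ri_mode `"parametric"` or `"nonparametric"`; see
#'   [ri_for_distribution()].
#' @param trim_z,tol,max_iter Iterative estimator constants.
#' @param ri_min_n Hard sample floor per distribution for RI estimation.
#' @param conf Confidence level of the limit CIs.
#' @param seed Integer master seed (per-stratum embedding seeds are derived
#'   from it).
#' @return Invisibly, an object of class `ddm_run` with elements `strata`,
#'   `tables`, `dds`, `cluster_tables`, `cluster_dds`, `ri_report`,
#'   `removed`, `audit`, `skipped`, `config`.
#' @export
run_ddm <- function(input, output_dir = NULL, dialect = lab_dialect(),
                    value_min = 0.5, value_max = 12,
                    age_min = 20, age_max = 89, strict_code_filter = FALSE,
                    band_width = 10, alpha = 0.05, normality_alpha = 0.05,
                    min_n = 6, compare_to_complement = FALSE, use_p = FALSE,
                    clustering = FALSE, k = 800,
                    cluster_method = "hierarchical", linkage = "average",
                    distance_mode = "one_minus", embedding_dim = 100,
                    embedding_window = 5, embedding_epochs = 20,
                    embedding_min_count = 6,
                    ri_mode = "parametric", trim_z = 1.96, tol = 1e-4,
                    max_iter = 50L, ri_min_n = 120L, conf = 0.90,
                    seed = 1L) {
  config <- as.list(environment())
  config$input <- if (is.character(input)) input else class(input)[1]
  config$dialect <- NULL
  config$output_dir <- NULL

  parsed <- if (is.character(input)) {
    read_results(input, dialect)
  } else if (inherits(input, "ddm_simulation")) {
    parse_result_frame(input$results, dialect)
  } else {
    parse_result_frame(input, dialect)
  }
  pp <- preprocess_results(parsed$results, value_min = value_min,
                           value_max = value_max, age_min = age_min,
                           age_max = age_max,
                           strict_code_filter = strict_code_filter)
  strata <- stratify_results(pp$results, band_width = band_width,
                             age_min = age_min, age_max = age_max)

  tables <- list(); dds <- list()
  cluster_tables <- list(); cluster_dds <- list()
  ri_rows <- list(); removed_rows <- list(); skipped <- character(0)

  for (si in seq_along(strata)) {
    st <- strata[[si]]
    lab <- stratum_label(st)
    if (length(st$gd_values) < ri_min_n) {
      warning("stratum ", lab, " below the RI sample floor (",
              length(st$gd_values), " < ", ri_min_n, "); skipped")
      skipped <- c(skipped, lab)
      next
    }
    tab <- build_diagnosis_table(st, min_n = min_n, alpha = alpha,
                                 normality_alpha = normality_alpha,
                                 compare_to_complement = compare_to_complement,
                                 use_p = use_p)
    dd <- differential_distribution(st, tab)
    tables[[lab]] <- tab
    dds[[lab]] <- dd
    man <- removed_manifest(st, dd)
    if (nrow(man)) {
      removed_rows[[lab]] <- cbind(
        data.frame(stratum_sex = st$sex, stratum_age_lo = st$age_lo,
                   stratum_age_hi = st$age_hi, stringsAsFactors = FALSE),
        man)
    }

    ris <- list()
    ris$GD <- suppressWarnings(
      ri_for_distribution(st$gd_values, mode = ri_mode, conf = conf,
                          trim_z = trim_z, tol = tol, max_iter = max_iter,
                          min_n = ri_min_n))
    if (length(dd$dd_values) >= ri_min_n) {
      ris$DD <- suppressWarnings(
        ri_for_distribution(dd$dd_values, mode = ri_mode, conf = conf,
                            trim_z = trim_z, tol = tol, max_iter = max_iter,
                            min_n = ri_min_n))
    }
    if (clustering) {
      cl_res <- tryCatch({
        corpus <- build_code_corpus(st)
        emb <- train_code_embeddings(
          corpus, dim = embedding_dim, window = embedding_window,
          epochs = embedding_epochs, min_count = embedding_min_count,
          seed = (as.integer(seed) * 1000L + si) %% .Machine$integer.max)
        cl <- cluster_codes(emb, k = k, method = cluster_method,
                            linkage = linkage, distance_mode = distance_mode,
                            seed = seed)
        cluster_table_and_dd(st, cl, min_n = min_n, alpha = alpha,
                             normality_alpha = normality_alpha,
                             compare_to_complement = compare_to_complement,
                             use_p = use_p)
      }, error = function(e) {
        message("clustering skipped for ", lab, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(cl_res)) {
        cluster_tables[[lab]] <- cl_res$table
        cluster_dds[[lab]] <- cl_res$dd
        if (length(cl_res$dd$dd_values) >= ri_min_n) {
          ris$DD_clustered <- suppressWarnings(
            ri_for_distribution(cl_res$dd$dd_values, mode = ri_mode,
                                conf = conf, trim_z = trim_z, tol = tol,
                                max_iter = max_iter, min_n = ri_min_n))
        }
      }
    }
    for (dist_name in names(ris)) {
      ri <- ris[[dist_name]]
      verd <- if (dist_name == "GD") {
        data.frame(bound = c("lower", "upper"), delta = c(0, 0),
                   verdict = c("not_different", "not_different"),
                   stringsAsFactors = FALSE)
      } else {
        compare_ris(ris$GD, ri)
      }
      ri_rows[[length(ri_rows) + 1L]] <- data.frame(
        sex = st$sex, age_lo = st$age_lo, age_hi = st$age_hi,
        distribution = dist_name,
        lower = ri$lower, ci_lower_lo = ri$ci_lower[1],
        ci_lower_hi = ri$ci_lower[2],
        upper = ri$upper, ci_upper_lo = ri$ci_upper[1],
        ci_upper_hi = ri$ci_upper[2],
        n_used = ri$n_used, n_input = ri$n_input,
        verdict_lower = verd$verdict[verd$bound == "lower"],
        verdict_upper = verd$verdict[verd$bound == "upper"],
        delta_lower = verd$delta[verd$bound == "lower"],
        delta_upper = verd$delta[verd$bound == "upper"],
        stringsAsFactors = FALSE)
    }
  }

  run <- structure(list(
    strata = strata,
    tables = tables, dds = dds,
    cluster_tables = cluster_tables, cluster_dds = cluster_dds,
    ri_report = do.call(rbind, ri_rows),
    removed = do.call(rbind, c(removed_rows, list(make.row.names = FALSE))),
    audit = pp$audit, rejects = parsed$rejects, skipped = skipped,
    config = config
  ), class = "ddm_run")

  if (!is.null(output_dir)) write_run(run, output_dir)
  invisible(run)
}

# Flatten a list of per-stratum diagnosis tables into one data frame.
.bind_tables <- function(tables) {
  if (!length(tables)) return(NULL)
  do.call(rbind, c(lapply(tables, function(tab) {
    st <- attr(tab, "stratum")
    if (!nrow(tab)) return(NULL)
    cbind(data.frame(stratum_sex = st[["sex"]],
                     stratum_age_lo = as.integer(st[["age_lo"]]),
                     stratum_age_hi = as.integer(st[["age_hi"]]),
                     stringsAsFactors = FALSE),
          as.data.frame(tab))
  }), list(make.row.names = FALSE)))
}

#' Write the artifacts of a run to a directory
#'
#' @param run A `ddm_run`.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      write.csv(df, file.path(output_dir, name), row.names = FALSE)
    }
  }
  wr(.bind_tables(run$tables), "diagnosis_tables.csv")
  wr(.bind_tables(run$cluster_tables), "cluster_tables.csv")
  if (length(run$cluster_tables)) {
    asn <- do.call(rbind, c(lapply(names(run$cluster_tables), function(lab) {
      members <- attr(run$cluster_tables[[lab]], "cluster_members")
      data.frame(stratum = lab,
                 code = unlist(members, use.names = FALSE),
                 cluster_id = rep(names(members), lengths(members)),
                 stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    wr(asn, "cluster_assignments.csv")
  }
  wr(run$ri_report, "ri_report.csv")
  wr(run$removed, "removed_results.csv")
  wr(run$audit, "audit.csv")
  cfg <- run$config
  cfg$package_version <- as.character(utils::packageVersion("ddmr"))
  cfg$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  cfg$skipped_strata <- run$skipped
  jsonlite::write_json(cfg, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(output_dir)
}

#' @export
print.ddm_run <- function(x, ...) {
  cat(sprintf("<ddm_run> %d strata (%d skipped), %d RI report rows\n",
              length(x$strata), length(x$skipped),
              if (is.null(x$ri_report)) 0L else nrow(x$ri_report)))
  invisible(x)
}

#' Summarise a run per stratum
#'
#' One row per stratum and filtered distribution: removal fraction, reference
#' limit deltas against the GD, and the comparison verdicts.
#'
#' @param run A `ddm_run`, or a directory written by [write_run()].
#' @return Data frame of class `ddm_summary`.
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    path <- file.path(run, "ri_report.csv")
    if (!file.exists(path)) stop("expected artifact not found: ", path)
    report <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    report <- run$ri_report
  }
  if (is.null(report) || !nrow(report)) stop("run has no RI report rows")
  dd_rows <- report[report$distribution != "GD", , drop = FALSE]
  gd_rows <- report[report$distribution == "GD", , drop = FALSE]
  m <- match(paste(dd_rows$sex, dd_rows$age_lo),
             paste(gd_rows$sex, gd_rows$age_lo))
  out <- data.frame(
    stratum = sprintf("%s %d-%d", dd_rows$sex, dd_rows$age_lo,
                      dd_rows$age_hi),
    distribution = dd_rows$distribution,
    removal_fraction = 1 - dd_rows$n_input / gd_rows$n_input[m],
    lower = dd_rows$lower, upper = dd_rows$upper,
    delta_lower = dd_rows$delta_lower, delta_upper = dd_rows$delta_upper,
    verdict_lower = dd_rows$verdict_lower,
    verdict_upper = dd_rows$verdict_upper,
    stringsAsFactors = FALSE)
  class(out) <- c("ddm_summary", "data.frame")
  out
}

#' @export
print.ddm_summary <- function(x, ...) {
  cat("| stratum | distribution | removed | lower (delta) | upper (delta) | verdicts |\n")
  cat("|---|---|---|---|---|---|\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("| %s | %s | %.1f%% | %.3f (%+.3f) | %.3f (%+.3f) | %s/%s |\n",
                x$stratum[i], x$distribution[i], 100 * x$removal_fraction[i],
                x$lower[i], x$delta_lower[i], x$upper[i], x$delta_upper[i],
                x$verdict_lower[i], x$verdict_upper[i]))
  }
  invisible(x)
}

#' Histogram of GD vs DD with reference limits
#'
#' @param run A `ddm_run`.
#' @param sex,age_lo Stratum selector.
#' @param file Optional PNG path; when `NULL`, plots to the active device.
#' @return Invisibly `NULL`.
#' @export
plot_gd_dd <- function(run, sex = "female", age_lo = 50, file = NULL) {
  lab <- NULL
  for (st in run$strata) {
    if (st$sex == sex && st$age_lo == age_lo) lab <- stratum_label(st)
  }
  if (is.null(lab) || is.null(run$dds[[lab]])) {
    stop("no DD available for stratum ", sex, " ", age_lo)
  }
  st <- NULL
  for (s in run$strata) if (stratum_label(s) == lab) st <- s
  dd <- run$dds[[lab]]
  rep_rows <- run$ri_report[run$ri_report$sex == sex &
                              run$ri_report$age_lo == age_lo, ]
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  brk <- pretty(st$gd_values, n = 60)
  h_gd <- graphics::hist(st$gd_values, breaks = brk, plot = FALSE)
  h_dd <- graphics::hist(dd$dd_values, breaks = brk, plot = FALSE)
  graphics::plot(h_gd, col = grDevices::adjustcolor("grey60", 0.6),
                 border = NA, main = paste("GD vs DD:", lab),
                 xlab = "analyte value")
  graphics::plot(h_dd, col = grDevices::adjustcolor("steelblue", 0.6),
                 border = NA, add = TRUE)
  for (i in seq_len(nrow(rep_rows))) {
    col <- if (rep_rows$distribution[i] == "GD") "grey20" else "steelblue4"
    graphics::abline(v = c(rep_rows$lower[i], rep_rows$upper[i]),
                     col = col, lty = if (rep_rows$distribution[i] == "GD") 2
                                      else 1, lwd = 2)
  }
  graphics::legend("topright", fill = c("grey60", "steelblue"),
                   legend = c("GD", "DD"), bty = "n")
  invisible(NULL)
}

#' Read a YAML run configuration
#'
#' Flat YAML keys matching the arguments of [run_ddm()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return Named list suitable for `do.call(run_ddm, ...)`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_ddm)), "dialect")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  cfg
}
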