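#' Two-group comparison (Student's t test, mean +/- SEM)
#'
#' Classical two-sample t test, pooled-variance by default (Welch via
#' `var_equal = FALSE`), reported with group means and standard errors.
#' Zero pooled within-group variance is a reported degenerate-variance
#' error, not an infinite statistic.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2, finite.
#' @param var_equal pooled-variance (classical Student) when `TRUE`.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `sem_a`,
#'   `mean_b`, `sem_b`, `method`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    abort("group values must be finite")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    abort("degenerate within-group variance: t statistic undefined")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         mean_a = mean(values_a), sem_a = sd(values_a) / sqrt(length(values_a)),
         mean_b = mean(values_b), sem_b = sd(values_b) / sqrt(length(values_b)),
         method = if (var_equal) "student" else "welch")
}

#' Run a reproducible simulate / measure / report pipeline
#'
#' Executes the requested stages on each cohort of simulated islets:
#' `simulate` draws `n_islets` sorted islets per cohort (per-islet seeds
#' derived from the global seed) and writes the cell tables; `architecture`
#' measures core/mantle composition per islet; `report` writes per-cohort
#' mean +/- SEM summaries and, for exactly two cohorts, two-sided t-test
#' comparisons per metric. A manifest records the config hash, seed,
#' package version, and every file written.
#'
#' @param config a named list (or path to a YAML file) with elements
#'   `seed` (integer), `stages` (subset of `c("simulate",
#'   "architecture", "report")`, in order), `mantle_depth` (optional,
#'   micrometres), and `cohorts`: a named list where each element has
#'   `n_islets` and `config` (a [sorting_config()], a list of its
#'   arguments, or a path to a YAML config).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `manifest`, per-cohort `metrics`
#'   tibbles, the `summary` tibble and (two cohorts) `comparisons`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$cohorts))
  stages <- config$stages %||% c("simulate", "architecture", "report")
  bad <- setdiff(stages, c("simulate", "architecture", "report"))
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- character(0)
  patterns <- list()
  metrics <- list()
  cohort_names <- names(config$cohorts)

  if ("simulate" %in% stages) {
    for (ci in seq_along(config$cohorts)) {
      nm <- cohort_names[ci]
      spec <- config$cohorts[[ci]]
      base_cfg <- as_sorting_config(spec$config)
      n_islets <- spec$n_islets %||% 1L
      pats <- lapply(seq_len(n_islets), function(k) {
        cfg <- base_cfg
        cfg$seed <- (seed + 7919L * ci + k) %% .Machine$integer.max
        simulate_islet(cfg)
      })
      patterns[[nm]] <- pats
      cells <- dplyr::bind_rows(
        lapply(seq_along(pats), function(k) {
          dplyr::mutate(pats[[k]]$cells, islet = k, .before = 1)
        }))
      f <- file.path(out_dir, paste0(nm, "_cells.csv"))
      readr::write_csv(cells, f)
      files <- c(files, f)
    }
  }

  if ("architecture" %in% stages) {
    if (length(patterns) == 0) {
      abort("architecture stage requires the simulate stage to have produced islets")
    }
    for (nm in names(patterns)) {
      met <- dplyr::bind_rows(lapply(patterns[[nm]], function(p) {
        measure_architecture(p, mantle_depth = config$mantle_depth,
                             boundary = "reconstruct")
      }))
      met <- dplyr::mutate(met, cohort = nm, islet = dplyr::row_number(),
                           .before = 1)
      metrics[[nm]] <- met
      f <- file.path(out_dir, paste0(nm, "_architecture.csv"))
      readr::write_csv(met, f)
      files <- c(files, f)
    }
  }

  summary_tbl <- NULL
  comparisons <- NULL
  if ("report" %in% stages && length(metrics) > 0) {
    all_met <- dplyr::bind_rows(metrics)
    metric_cols <- setdiff(names(all_met)[vapply(all_met, is.numeric, logical(1))],
                           c("islet", "mantle_depth"))
    long <- tidyr::pivot_longer(all_met, dplyr::all_of(metric_cols),
                                names_to = "metric", values_to = "value")
    summary_tbl <- dplyr::summarise(
      dplyr::group_by(long, .data$cohort, .data$metric),
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .groups = "drop")
    f <- file.path(out_dir, "summary.csv")
    readr::write_csv(summary_tbl, f)
    files <- c(files, f)

    if (length(metrics) == 2) {
      comparisons <- dplyr::bind_rows(lapply(metric_cols, function(mc) {
        a <- metrics[[1]][[mc]]; b <- metrics[[2]][[mc]]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        if (sd(a) == 0 && sd(b) == 0) return(NULL)
        dplyr::mutate(compare_groups(a, b), metric = mc,
                      cohort_a = cohort_names[1], cohort_b = cohort_names[2],
                      .before = 1)
      }))
      f <- file.path(out_dir, "comparisons.csv")
      readr::write_csv(comparisons, f)
      files <- c(files, f)
    }
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    stages = stages,
    package_version = as.character(utils::packageVersion("isletmorph")),
    files = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(manifest = manifest, patterns = patterns,
                 metrics = metrics, summary = summary_tbl,
                 comparisons = comparisons, files = c(files, mf)))
}

as_sorting_config <- function(x) {
  if (inherits(x, "sorting_config")) return(x)
  if (is.character(x) && length(x) == 1) return(read_sorting_config(x))
  if (is.list(x)) {
    known <- names(formals(sorting_config))
    return(do.call(sorting_config, x[intersect(names(x), known)]))
  }
  abort("cohort config must be a sorting_config, an argument list, or a YAML path")
}
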