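#' Pipeline configuration
#'
#' Collects paths, label sets, significance levels and every module
#' switch for [run_pipeline()], validating ranges up front.
#'
#' @param responses_path,participants_path Input tables (CSV or XLSX);
#'   `NULL` to simulate instead.
#' @param out_dir Output directory.
#' @param simulate A [simulation_config()] used when no input paths are
#'   given.
#' @param volumes,metrics Label canons.
#' @param alpha Significance level in (0, 1).
#' @param cooks,cooks_cutoff_factor,cooks_cap,cooks_convention Cook's
#'   filter switches (see [cooks_filter()]).
#' @param bh_family BH family convention (see [run_grid()]).
#' @param include_zeros,value_form Keypress-metric switches (see
#'   [assemble_profile()]).
#' @param exact_proportion Heatmap proportion-test variant.
#' @param knn_k,knn_refit_transform kNN switches.
#' @param seed Integer seed for any simulation.
#' @param stages Subset of
#'   `c("simulate", "rpt", "regress", "overlap", "heatmap", "classify")`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(responses_path = NULL, participants_path = NULL,
                            out_dir = tempfile("rptfusion_"),
                            simulate = simulation_config(),
                            volumes = brain_volume_labels(),
                            metrics = keypress_metric_labels(),
                            alpha = 0.05, cooks = TRUE,
                            cooks_cutoff_factor = 4, cooks_cap = 0.2,
                            cooks_convention = "iterative",
                            bh_family = "per_volume",
                            include_zeros = FALSE, value_form = "log",
                            exact_proportion = FALSE,
                            knn_k = 5L, knn_refit_transform = TRUE,
                            seed = 1L,
                            stages = c("simulate", "rpt", "regress",
                                       "overlap", "heatmap", "classify")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("invalid config: 'alpha' must be in (0, 1)", call. = FALSE)
  if (anyDuplicated(volumes) || length(volumes) == 0L)
    stop("invalid config: 'volumes' must be non-empty and unique",
         call. = FALSE)
  if (anyDuplicated(metrics) || length(metrics) == 0L)
    stop("invalid config: 'metrics' must be non-empty and unique",
         call. = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Read a cohort from response and participant tables
#'
#' Reads and schema-validates the raw keypress response table and the
#' participant table (CSV or XLSX), normalizes categorical levels, and
#' computes keypress-metric profiles. Participants whose profiles fail
#' the RPT fit-validity rule are retained with flags (downstream stages
#' filter on the flag).
#'
#' @param responses_path Table with columns `participant_id`,
#'   `category`, `picture`, `valence` (`inc`/`dec`), `keypresses`.
#' @param participants_path Table with `participant_id`, `group`,
#'   `gender`, `age`, `ethnicity`, `education` and the volume columns.
#' @param volumes Volume label canon the participant table must cover.
#' @param include_zeros,value_form Passed to [rpt_profiles()].
#' @return A `cohort_dataset` (with `truth = NULL`).
#' @export
read_cohort <- function(responses_path, participants_path,
                        volumes = brain_volume_labels(),
                        include_zeros = FALSE, value_form = "log") {
  responses <- read_table_any(responses_path)
  need_r <- c("participant_id", "category", "picture", "valence",
              "keypresses")
  miss <- setdiff(need_r, names(responses))
  if (length(miss))
    stop("missing required column(s) ", paste(miss, collapse = ", "),
         " in ", responses_path, call. = FALSE)
  participants <- read_table_any(participants_path)
  need_p <- c("participant_id", "group", "gender", "age", "ethnicity",
              "education", volume_col(volumes))
  miss <- setdiff(need_p, names(participants))
  if (length(miss))
    stop("missing required column(s) ", paste(miss, collapse = ", "),
         " in ", participants_path, call. = FALSE)
  responses$valence <- tolower(trimws(responses$valence))
  if (!all(responses$valence %in% c("inc", "dec")))
    stop("valence must be 'inc' or 'dec' in ", responses_path,
         call. = FALSE)
  participants$group <- toupper(trimws(participants$group))
  if (!all(participants$group %in% group_labels()))
    stop("group must be one of ", paste(group_labels(), collapse = "/"),
         " in ", participants_path, call. = FALSE)
  rid <- unique(responses$participant_id)
  if (!setequal(rid, participants$participant_id))
    stop("participant ids differ between ", responses_path, " and ",
         participants_path, call. = FALSE)
  profiles <- rpt_profiles(responses, include_zeros = include_zeros,
                           value_form = value_form)
  profiles <- profiles[match(participants$participant_id,
                             profiles$participant_id), , drop = FALSE]
  structure(list(responses = tibble::as_tibble(responses),
                 participants = tibble::as_tibble(participants),
                 profiles = profiles, truth = NULL, config = NULL),
            class = "cohort_dataset")
}

#' Write a cohort to CSV (and its planted truth to JSON)
#'
#' Writes `responses.csv` and `participants.csv` (UTF-8, header row,
#' '.' decimal) plus `truth.json` when a coupling spec is present.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(responses = file.path(dir, "responses.csv"),
             participants = file.path(dir, "participants.csv"))
  utils::write.csv(cohort$responses, paths["responses"], row.names = FALSE)
  utils::write.csv(cohort$participants, paths["participants"],
                   row.names = FALSE)
  if (!is.null(cohort$truth) && length(cohort$truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$truth, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (or read), keypress-metric
#' extraction, per-group regression grids with and without covariates,
#' cross-group overlap accounting, beta-matrix heatmap comparisons, and
#' Kruskal-Wallis/Dunn feature selection followed by pairwise
#' leave-one-out kNN over the six feature combinations -- writing tidy
#' CSV/JSON outputs, heatmap PNGs and a run manifest into
#' `config$out_dir`. Identical config + seed yields identical numeric
#' outputs. No stage mutates its inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list (the report bundle): `cohort`, `grids`,
#'   `grids_nocov`, `overlap`, `beta_matrices`, `comparisons`,
#'   `selection`, `classification`, `files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be created by pipeline_config()", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(config$responses_path)) {
      read_cohort(config$responses_path, config$participants_path,
                  volumes = config$volumes,
                  include_zeros = config$include_zeros,
                  value_form = config$value_form)
    } else {
      sim <- config$simulate
      sim$seed <- config$seed
      generate_cohort(sim)
    }
  })
  stage("rpt", {
    f <- file.path(config$out_dir, "profiles.csv")
    utils::write.csv(cohort$profiles, f, row.names = FALSE)
    files <- c(files, f)
  })

  groups_present <- intersect(group_labels(),
                              unique(cohort$participants$group))
  grid_args <- list(volumes = config$volumes, metrics = config$metrics,
                    alpha = config$alpha, cooks = config$cooks,
                    cutoff_factor = config$cooks_cutoff_factor,
                    cap = config$cooks_cap,
                    convention = config$cooks_convention,
                    bh_family = config$bh_family)
  grids <- grids_nocov <- list()
  stage("regress", {
    for (g in groups_present) {
      grids[[g]] <- do.call(run_grid, c(list(cohort, g,
                                              with_covariates = TRUE),
                                         grid_args))
      grids_nocov[[g]] <- do.call(run_grid, c(list(cohort, g,
                                                    with_covariates = FALSE),
                                               grid_args))
      f <- file.path(config$out_dir, paste0("grid_", g, ".csv"))
      utils::write.csv(grids[[g]], f, row.names = FALSE)
      files <- c(files, f)
    }
  })

  overlap <- NULL
  if (length(grids) >= 2L) overlap <- stage("overlap", {
    ov <- overlap_analysis(grids, alpha = config$alpha)
    f <- file.path(config$out_dir, "overlap.json")
    jsonlite::write_json(list(
      n_significant = as.list(ov$n_significant),
      total_significant = ov$total_significant,
      n_common_pairs = ov$n_common_pairs,
      n_consistent_pairs = ov$n_consistent_pairs,
      consistency_fraction = ov$consistency_fraction), f,
      auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    ov
  })

  bms <- list(); comparisons <- list()
  stage("heatmap", {
    for (g in groups_present) {
      bms[[g]] <- structure(list(
        group = g,
        beta = matrix_from_grid(grids_nocov[[g]], "std_beta",
                                config$volumes, config$metrics),
        p = matrix_from_grid(grids_nocov[[g]], "p", config$volumes,
                             config$metrics),
        grid = grids_nocov[[g]]), class = "beta_matrix")
      files <- c(files, render_heatmaps(bms[[g]], config$out_dir))
    }
    if (length(bms) >= 2L) {
      gn <- names(bms)
      for (i in seq_len(length(bms) - 1L))
        for (j in seq(i + 1L, length(bms))) {
          cmp <- compare_beta_matrices(bms[[i]], bms[[j]],
                                       exact_proportion =
                                         config$exact_proportion)
          comparisons[[paste(gn[i], gn[j], sep = "_vs_")]] <- cmp
          files <- c(files, render_heatmaps(cmp, config$out_dir))
        }
      f <- file.path(config$out_dir, "comparisons.json")
      jsonlite::write_json(lapply(comparisons, function(cmp) list(
        pair = cmp$pair, n_cells = cmp$n_cells, t_p = cmp$t_p,
        wilcoxon_p = cmp$wilcoxon_p,
        wilcoxon_median = cmp$wilcoxon_median,
        proportion_p = cmp$proportion_p,
        agree_fraction = cmp$agree_fraction)), f,
        auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
  })

  selection <- NULL; classification <- NULL
  if ("classify" %in% config$stages && length(groups_present) == 3L) {
    stage("classify", {
      selection <- select_features(cohort, volumes = config$volumes,
                                    metrics = config$metrics,
                                    alpha = config$alpha)
      sel_m <- selection$feature[selection$selected &
                                   selection$type == "metric"]
      sel_v <- selection$feature[selection$selected &
                                   selection$type == "volume"]
      if (length(sel_m) + length(sel_v) > 0L) {
        classification <- run_combinations(
          cohort, sel_m, sel_v, k = config$knn_k,
          refit_transform = config$knn_refit_transform)
        f <- file.path(config$out_dir, "classification.csv")
        utils::write.csv(classification, f, row.names = FALSE)
        files <- c(files, f)
      }
      f <- file.path(config$out_dir, "selection.csv")
      utils::write.csv(selection, f, row.names = FALSE)
      files <- c(files, f)
    })
  }

  manifest <- file.path(config$out_dir, "manifest.json")
  cfg_plain <- config
  cfg_plain$simulate <- unclass(cfg_plain$simulate)
  jsonlite::write_json(list(
    package = "rptfusion",
    version = as.character(utils::packageVersion("rptfusion")),
    r_version = R.version.string,
    seed = config$seed,
    config = lapply(unclass(cfg_plain), function(x)
      if (is.function(x)) NULL else x)), manifest,
    auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, manifest)

  invisible(list(cohort = cohort, grids = grids, grids_nocov = grids_nocov,
                 overlap = overlap, beta_matrices = bms,
                 comparisons = comparisons, selection = selection,
                 classification = classification, files = files))
}

# reshape one grid column to a volumes x metrics matrix
matrix_from_grid <- function(grid, col, volumes, metrics) {
  m <- matrix(NA_real_, nrow = length(volumes), ncol = length(metrics),
              dimnames = list(volumes, metrics))
  m[cbind(match(grid$volume, volumes), match(grid$metric, metrics))] <-
    grid[[col]]
  m
}
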