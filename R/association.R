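#' Screen demographic covariates per brain volume
#'
#' Determines, within one group, which demographic variables to include
#' in each volume's regression model: ethnicity is tested with a
#' two-sample Wilcoxon rank-sum between the two largest ethnicity
#' strata (participants identifying as Asian are dropped for this test
#' given typically small samples), and age and years of education with
#' Spearman correlation against the volume. A variable is selected when
#' its screening p-value is below `alpha`.
#'
#' @param participants Participant table with `group`, `age`,
#'   `education`, `ethnicity` and volume columns.
#' @param group Group label to screen within.
#' @param volumes Character vector of volume labels (default the
#'   29-label canon).
#' @param alpha Screening level (default .05).
#' @return Tibble with columns `group`, `volume`, `covariate`, `p`,
#'   `selected`. Ethnicity rows are absent when fewer than two usable
#'   strata exist (the test is skipped, not an error).
#' @export
screen_covariates <- function(participants, group,
                              volumes = brain_volume_labels(),
                              alpha = 0.05) {
  dat <- participants[participants$group == group, , drop = FALSE]
  if (nrow(dat) < 3L) stop("group must have at least 3 members", call. = FALSE)
  rows <- list()
  eth <- dat$ethnicity[dat$ethnicity != "Asian"]
  strata <- names(sort(table(eth), decreasing = TRUE))
  use_eth <- length(strata) >= 2L &&
    sum(table(eth)[strata[1:2]] >= 2L) == 2L
  for (v in volumes) {
    colname <- volume_col(v)
    x <- dat[[colname]]
    if (is.null(x)) stop("participants table lacks volume column '",
                         colname, "'", call. = FALSE)
    for (cov in c("age", "education")) {
      p <- if (stats::sd(x, na.rm = TRUE) == 0) 1 else
        suppressWarnings(stats::cor.test(x, dat[[cov]],
                                         method = "spearman",
                                         exact = FALSE)$p.value)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = group, volume = v, covariate = cov, p = p,
        selected = is.finite(p) && p < alpha)
    }
    if (use_eth) {
      keep <- dat$ethnicity %in% strata[1:2]
      p <- if (stats::sd(x[keep], na.rm = TRUE) == 0) 1 else
        suppressWarnings(stats::wilcox.test(
          x[keep] ~ factor(dat$ethnicity[keep]))$p.value)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = group, volume = v, covariate = "ethnicity", p = p,
        selected = is.finite(p) && p < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Cook's-distance outlier filter
#'
#' Influence-based outlier removal for a single regression. Under the
#' `"iterative"` convention the model is refit repeatedly, removing the
#' single most influential observation while the maximum Cook's
#' distance exceeds `cutoff_factor / n` (n = current sample size),
#' capped at `cap` of the initial sample; `"single_pass"` removes every
#' observation exceeding the cutoff of the initial fit at once. Note
#' that both conventions are anti-conservative: re-testing after
#' influence-based deletion inflates the nominal type-I level (see the
#' package vignette), which is why the filter can be disabled wherever
#' it is applied.
#'
#' @param y,x Numeric response and predictor.
#' @param covariates Optional data frame of additional model terms.
#' @param cutoff_factor Cutoff is `cutoff_factor / n` (default 4).
#' @param cap Maximum fraction of observations removable (default 0.2).
#' @param convention `"iterative"` (default) or `"single_pass"`.
#' @return List with `ok`; when `ok`, `keep` (indices into the
#'   complete-case rows), `n_removed`, `n_used`; when not, `reason`
#'   (`"insufficient_n"` for fewer than 10 complete cases).
#' @export
cooks_filter <- function(y, x, covariates = NULL, cutoff_factor = 4,
                         cap = 0.2,
                         convention = c("iterative", "single_pass")) {
  convention <- match.arg(convention)
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n0 <- nrow(df)
  if (n0 < 10L) return(list(ok = FALSE, reason = "insufficient_n",
                            n_available = n0))
  keep <- seq_len(n0)
  fit_cooks <- function(idx) {
    f <- stats::lm(.y ~ ., data = df[idx, , drop = FALSE])
    # an (all but) exact fit has no meaningful influence structure
    if (suppressWarnings(summary(f)$sigma) < 1e-10 * max(abs(df$.y), 1))
      return(rep(0, length(idx)))
    d <- stats::cooks.distance(f)
    d[!is.finite(d)] <- 0
    d
  }
  if (convention == "single_pass") {
    d <- fit_cooks(keep)
    bad <- which(d > cutoff_factor / n0)
    if (length(bad) > floor(cap * n0))
      bad <- bad[order(d[bad], decreasing = TRUE)][seq_len(floor(cap * n0))]
    if (length(bad)) keep <- keep[-bad]
  } else {
    removed <- 0L
    max_rm <- floor(cap * n0)
    while (removed < max_rm) {
      d <- fit_cooks(keep)
      if (max(d) <= cutoff_factor / length(keep)) break
      keep <- keep[-which.max(d)]
      removed <- removed + 1L
    }
  }
  list(ok = TRUE, keep = keep, n_removed = n0 - length(keep),
       n_used = length(keep), complete = which(cc))
}

#' Fit one standardized structure-behavior regression
#'
#' Ordinary least squares of one keypress metric (response) on one
#' brain volume (predictor), with optional screened covariates.
#' Observations flagged by [cooks_filter()] are removed first; the
#' retained response, predictor and continuous covariates are then
#' z-scored (categorical covariates enter as unscaled indicator
#' contrasts), so the volume coefficient is a standardized beta with
#' |beta| <= 1 in the simple (no-covariate) case, where it equals the
#' Pearson correlation of the retained points. The 95% CI uses the t
#' distribution with residual degrees of freedom.
#'
#' @param y,x Numeric metric and volume vectors.
#' @param covariates Optional data frame (numeric columns are z-scored;
#'   character/factor columns become indicators).
#' @param cooks Apply the Cook's filter? (default TRUE)
#' @param conf_level Confidence level (default .95).
#' @inheritParams cooks_filter
#' @return One-row tibble: `std_beta`, `ci_low`, `ci_high`, `p`,
#'   `n_outliers_removed`, `n_used`, `skipped`, `skip_reason`.
#' @export
fit_bivariate <- function(y, x, covariates = NULL, cooks = TRUE,
                          conf_level = 0.95, cutoff_factor = 4, cap = 0.2,
                          convention = c("iterative", "single_pass")) {
  convention <- match.arg(convention)
  skipped <- function(reason) tibble::tibble(
    std_beta = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, n_outliers_removed = NA_integer_, n_used = NA_integer_,
    skipped = TRUE, skip_reason = reason)

  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) return(skipped("insufficient_n"))
  if (stats::sd(df$.x) == 0 || stats::sd(df$.y) == 0)
    return(skipped("zero_variance"))

  n_removed <- 0L
  if (cooks) {
    cf <- cooks_filter(df$.y, df$.x,
                       covariates = df[, setdiff(names(df), c(".y", ".x")),
                                       drop = FALSE],
                       cutoff_factor = cutoff_factor, cap = cap,
                       convention = convention)
    if (!cf$ok) return(skipped(cf$reason))
    df <- df[cf$keep, , drop = FALSE]
    n_removed <- cf$n_removed
  }
  if (stats::sd(df$.x) == 0 || stats::sd(df$.y) == 0)
    return(skipped("zero_variance"))

  zd <- df
  for (nm in names(zd)) {
    if (is.numeric(zd[[nm]]) && nm %in% c(".y", ".x")) {
      zd[[nm]] <- as.vector(scale(zd[[nm]]))
    } else if (is.numeric(zd[[nm]])) {
      s <- stats::sd(zd[[nm]])
      zd[[nm]] <- if (s > 0) as.vector(scale(zd[[nm]])) else NULL
    } else {
      zd[[nm]] <- factor(zd[[nm]])
      if (nlevels(zd[[nm]]) < 2L) zd[[nm]] <- NULL
    }
  }
  fit <- stats::lm(.y ~ ., data = zd)
  sm <- suppressWarnings(summary(fit))$coefficients
  if (!".x" %in% rownames(sm)) return(skipped("collinear"))
  ci <- suppressWarnings(stats::confint(fit, ".x", level = conf_level))
  tibble::tibble(
    std_beta = unname(sm[".x", "Estimate"]),
    ci_low = ci[1], ci_high = ci[2],
    p = unname(sm[".x", "Pr(>|t|)"]),
    n_outliers_removed = as.integer(n_removed),
    n_used = nrow(zd), skipped = FALSE, skip_reason = "")
}

#' Benjamini-Hochberg q-values for one test family
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement over a declared family of p-values (here, typically the
#' 15 keypress-metric tests sharing one group x volume).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs passed through).
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value family", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Run the full structure-behavior regression grid for one group
#'
#' Fits every volume x metric cell (by default 29 x 15 = 435) for one
#' group with [fit_bivariate()], using covariates selected by
#' [screen_covariates()] when `with_covariates = TRUE` (when ethnicity
#' is selected for a volume, participants identifying as Asian are
#' excluded from those regressions and ethnicity enters as indicator
#' contrasts). Participants with invalid keypress profiles are
#' excluded. q-values are computed per BH family; cells that fail
#' preconditions are retained as skipped rows, never aborting the grid.
#'
#' @param cohort A `cohort_dataset` (or list with `participants` and
#'   `profiles`).
#' @param group Group label.
#' @param with_covariates Include screened demographic covariates?
#' @param volumes,metrics Label sets defining the grid.
#' @param alpha Significance level for the summary counts.
#' @param bh_family `"per_volume"` (default: family = the 15 metrics of
#'   one volume) or `"global"` (all cells of the grid).
#' @inheritParams fit_bivariate
#' @return Tibble of class `regression_grid`: one row per cell with
#'   `group`, `metric`, `volume`, `covariates`, `std_beta`, `ci_low`,
#'   `ci_high`, `p`, `q`, `n_outliers_removed`, `n_used`, `skipped`,
#'   `skip_reason`; attributes `n_sig_p` and `n_sig_q` hold the summary
#'   counts.
#' @export
run_grid <- function(cohort, group, with_covariates = TRUE,
                     volumes = brain_volume_labels(),
                     metrics = keypress_metric_labels(),
                     alpha = 0.05, cooks = TRUE, cutoff_factor = 4,
                     cap = 0.2,
                     convention = c("iterative", "single_pass"),
                     bh_family = c("per_volume", "global")) {
  convention <- match.arg(convention)
  bh_family <- match.arg(bh_family)
  part <- cohort$participants
  prof <- cohort$profiles
  idx <- part$group == group & prof$valid[match(part$participant_id,
                                                prof$participant_id)]
  part <- part[idx, , drop = FALSE]
  prof <- prof[match(part$participant_id, prof$participant_id), ,
               drop = FALSE]

  covmap <- NULL
  if (with_covariates) {
    scr <- screen_covariates(cohort$participants, group,
                             volumes = volumes, alpha = alpha)
    covmap <- scr[scr$selected, , drop = FALSE]
  }

  rows <- list()
  for (v in volumes) {
    xcol <- part[[volume_col(v)]]
    covs <- if (!is.null(covmap))
      covmap$covariate[covmap$volume == v] else character(0)
    cov_df <- NULL
    sub_keep <- rep(TRUE, nrow(part))
    if (length(covs)) {
      cov_df <- data.frame(row.names = seq_len(nrow(part)))
      if ("age" %in% covs) cov_df$age <- part$age
      if ("education" %in% covs) cov_df$education <- part$education
      if ("ethnicity" %in% covs) {
        sub_keep <- part$ethnicity != "Asian"
        cov_df$ethnicity <- part$ethnicity
      }
    }
    for (m in metrics) {
      ycol <- prof[[m]]
      res <- fit_bivariate(
        ycol[sub_keep], xcol[sub_keep],
        covariates = if (!is.null(cov_df))
          cov_df[sub_keep, , drop = FALSE] else NULL,
        cooks = cooks, cutoff_factor = cutoff_factor, cap = cap,
        convention = convention)
      rows[[length(rows) + 1L]] <- cbind(
        tibble::tibble(group = group, metric = m, volume = v,
                       covariates = paste(covs, collapse = ",")),
        res)
    }
  }
  grid <- tibble::as_tibble(do.call(rbind, rows))
  grid$q <- NA_real_
  if (bh_family == "per_volume") {
    for (v in volumes) {
      i <- which(grid$volume == v & !grid$skipped)
      if (length(i)) grid$q[i] <- bh_adjust(grid$p[i])
    }
  } else {
    i <- which(!grid$skipped)
    if (length(i)) grid$q[i] <- bh_adjust(grid$p[i])
  }
  grid <- grid[, c("group", "metric", "volume", "covariates", "std_beta",
                   "ci_low", "ci_high", "p", "q", "n_outliers_removed",
                   "n_used", "skipped", "skip_reason")]
  attr(grid, "n_sig_p") <- sum(grid$p < alpha, na.rm = TRUE)
  attr(grid, "n_sig_q") <- sum(grid$q < alpha, na.rm = TRUE)
  attr(grid, "alpha") <- alpha
  class(grid) <- c("regression_grid", class(grid))
  grid
}

#' Cross-group overlap and consistency of significant regressions
#'
#' For every pair of groups, identifies the (metric, volume) cells
#' significant in both, flags whether the two standardized betas share
#' a sign ("beta agreeance"), and reports the consistency fraction in
#' the a-of-b style `2 * consistent_pairs / total significant
#' regressions`. Volumes shared between two groups' significant cells
#' outside the common cells are also listed.
#'
#' @param grids Named list of `regression_grid` objects over the same
#'   cell universe.
#' @param alpha Significance level.
#' @param use `"p"` (default) or `"q"` as the significance rule.
#' @return Object of class `overlap_summary`: list with `pairs`
#'   (per-pair tibble of common cells and agreement flags),
#'   `n_significant` (per group), `total_significant`,
#'   `n_common_pairs`, `n_consistent_pairs`, `consistency_fraction`
#'   (in percent), and `shared_volumes` (per pair).
#' @export
overlap_analysis <- function(grids, alpha = 0.05, use = c("p", "q")) {
  use <- match.arg(use)
  if (length(grids) < 2L) stop("need at least two grids", call. = FALSE)
  key <- function(g) paste(g$metric, g$volume, sep = " || ")
  universe <- sort(key(grids[[1]]))
  for (g in grids[-1]) {
    if (!identical(sort(key(g)), universe))
      stop("grids do not share the same cell universe", call. = FALSE)
  }
  sig_cells <- lapply(grids, function(g) {
    s <- !g$skipped & is.finite(g[[use]]) & g[[use]] < alpha
    data.frame(cell = key(g)[s], metric = g$metric[s], volume = g$volume[s],
               beta = g$std_beta[s], stringsAsFactors = FALSE)
  })
  n_sig <- vapply(sig_cells, nrow, integer(1))
  gn <- names(grids)
  pair_rows <- list(); shared_volumes <- list()
  for (i in seq_len(length(grids) - 1L)) for (j in seq(i + 1L, length(grids))) {
    a <- sig_cells[[i]]; b <- sig_cells[[j]]
    common <- intersect(a$cell, b$cell)
    ba <- a$beta[match(common, a$cell)]
    bb <- b$beta[match(common, b$cell)]
    agree <- sign(ba) == sign(bb)
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      group_a = gn[i], group_b = gn[j],
      metric = a$metric[match(common, a$cell)],
      volume = a$volume[match(common, a$cell)],
      beta_a = ba, beta_b = bb, beta_agreeance = agree)
    common_vols <- unique(a$volume[match(common, a$cell)])
    sv <- setdiff(intersect(unique(a$volume), unique(b$volume)), common_vols)
    shared_volumes[[paste(gn[i], gn[j], sep = " vs ")]] <- sv
  }
  pairs <- do.call(rbind, pair_rows)
  n_common <- nrow(pairs)
  n_consistent <- sum(pairs$beta_agreeance)
  total <- sum(n_sig)
  structure(list(
    pairs = pairs, n_significant = n_sig, total_significant = total,
    n_common_pairs = n_common, n_consistent_pairs = n_consistent,
    consistency_fraction = if (total > 0) 100 * 2 * n_consistent / total
      else NA_real_,
    shared_volumes = shared_volumes, alpha = alpha, use = use
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> significant cells:",
      paste(sprintf("%s=%d", names(x$n_significant), x$n_significant),
            collapse = ", "), "\n")
  cat("  common pairs:", x$n_common_pairs, "; consistent (same sign):",
      x$n_consistent_pairs,
      sprintf("(%d of %d = %.1f%%)\n", 2L * x$n_consistent_pairs,
              x$total_significant, x$consistency_fraction))
  invisible(x)
}
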