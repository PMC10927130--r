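#' Covariate-free beta matrix for one group
#'
#' Builds the volumes x metrics matrix of standardized betas (and the
#' companion p matrix) from covariate-free structure-behavior
#' regressions, cell-by-cell equal to
#' `run_grid(..., with_covariates = FALSE)`. Skipped cells carry `NA`
#' and are excluded pairwise from downstream tests.
#'
#' @inheritParams run_grid
#' @return Object of class `beta_matrix`: list with `group`, `beta`
#'   (volumes x metrics matrix), `p`, and `grid` (the underlying
#'   [run_grid()] result).
#' @export
beta_matrix <- function(cohort, group,
                        volumes = brain_volume_labels(),
                        metrics = keypress_metric_labels(),
                        cooks = TRUE, cutoff_factor = 4, cap = 0.2,
                        convention = c("iterative", "single_pass")) {
  convention <- match.arg(convention)
  grid <- run_grid(cohort, group, with_covariates = FALSE,
                   volumes = volumes, metrics = metrics, cooks = cooks,
                   cutoff_factor = cutoff_factor, cap = cap,
                   convention = convention)
  shape <- function(val) {
    m <- matrix(NA_real_, nrow = length(volumes), ncol = length(metrics),
                dimnames = list(volumes, metrics))
    m[cbind(match(grid$volume, volumes), match(grid$metric, metrics))] <- val
    m
  }
  structure(list(group = group, beta = shape(grid$std_beta),
                 p = shape(grid$p), grid = grid),
            class = "beta_matrix")
}

#' Compare two groups' beta matrices
#'
#' Elementwise comparison of two groups' standardized-beta matrices on
#' three axes: valence `|beta_A| - |beta_B|` (range -1..1), intensity
#' `|beta_A - beta_B|` (range 0..2), and sign agreement (+1 same
#' direction, -1 opposite). Cells undefined in either matrix are
#' dropped pairwise. Summary tests: a one-sample t-test of the valence
#' values against mean 0, a one-sample Wilcoxon signed-rank test of the
#' intensity values against median 0 (reported with the sample median),
#' and a proportion test of the sign-agreement success fraction against
#' 0.5.
#'
#' @param a,b `beta_matrix` objects with identical labels.
#' @param exact_proportion Use the exact binomial test instead of the
#'   normal-approximation proportion test.
#' @return Object of class `beta_comparison`: matrices `valence`,
#'   `intensity`, `agreement`, plus `t_p`, `t_stat`, `wilcoxon_p`,
#'   `wilcoxon_median`, `proportion_p`, `agree_fraction`, `n_cells`.
#' @export
compare_beta_matrices <- function(a, b, exact_proportion = FALSE) {
  stopifnot(inherits(a, "beta_matrix"), inherits(b, "beta_matrix"))
  if (!identical(dimnames(a$beta), dimnames(b$beta)))
    stop("beta matrices have mismatched labels", call. = FALSE)
  ok <- is.finite(a$beta) & is.finite(b$beta)
  valence <- intensity <- agreement <- a$beta * NA_real_
  valence[ok] <- abs(a$beta[ok]) - abs(b$beta[ok])
  intensity[ok] <- abs(a$beta[ok] - b$beta[ok])
  agreement[ok] <- ifelse(sign(a$beta[ok]) * sign(b$beta[ok]) >= 0, 1, -1)

  if (sum(ok) >= 2L) {
    tt <- valence_ttest(valence[ok])
    wt <- intensity_test(intensity[ok])
    pt <- sign_proportion_test(agreement[ok], exact = exact_proportion)
  } else {
    # too few defined cells to summarize; matrices still returned
    tt <- list(t = NA_real_, p = NA_real_)
    wt <- list(p = NA_real_, median = NA_real_)
    pt <- list(p = NA_real_, agree_fraction = NA_real_)
  }
  structure(list(
    pair = c(a$group, b$group), valence = valence, intensity = intensity,
    agreement = agreement, n_cells = sum(ok),
    t_stat = tt$t, t_p = tt$p,
    wilcoxon_p = wt$p, wilcoxon_median = wt$median,
    proportion_p = pt$p, agree_fraction = pt$agree_fraction
  ), class = "beta_comparison")
}

#' One-sample t-test on beta-valence values
#'
#' Two-sided one-sample t-test of the valence cells
#' (`|beta_A| - |beta_B|`) against mean zero. A degenerate all-zero
#' input is reported as no difference (p = 1) by convention.
#'
#' @param values Numeric vector of defined valence cells.
#' @return List with `t` and `p`.
#' @export
valence_ttest <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(t = 0, p = if (mean(values) == 0) 1 else 0))
  }
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Signed-rank test on beta-intensity values
#'
#' Reports the sample median of the intensity cells
#' (`|beta_A - beta_B|`, range 0..2) and a two-sided one-sample
#' Wilcoxon signed-rank test of the values against median zero (zeros
#' dropped per the standard convention; identical matrices give
#' median 0 and p = 1).
#'
#' @param values Numeric vector of defined intensity cells.
#' @return List with `p` and `median`.
#' @export
intensity_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty intensity values", call. = FALSE)
  med <- stats::median(values)
  if (all(values == 0)) return(list(p = 1, median = med))
  wt <- suppressWarnings(stats::wilcox.test(values, mu = 0))
  list(p = wt$p.value, median = med)
}

#' Proportion test on beta sign agreement
#'
#' Success = the two betas share a direction (+1 cell). Two-sided
#' one-sample proportion z-test of the success fraction against 0.5
#' (normal approximation without continuity correction by default; set
#' `exact = TRUE` for the exact binomial test).
#'
#' @param agreement Numeric vector of +1 / -1 cells.
#' @param exact Use `binom.test` instead of the z approximation.
#' @return List with `agree_fraction`, `p`, and (z variant) `z`.
#' @export
sign_proportion_test <- function(agreement, exact = FALSE) {
  agreement <- agreement[is.finite(agreement)]
  n <- length(agreement)
  if (n == 0L) stop("empty agreement values", call. = FALSE)
  succ <- sum(agreement == 1)
  phat <- succ / n
  if (exact) {
    bt <- stats::binom.test(succ, n, p = 0.5)
    return(list(agree_fraction = phat, p = bt$p.value, z = NA_real_))
  }
  z <- (phat - 0.5) / sqrt(0.25 / n)
  list(agree_fraction = phat, p = 2 * stats::pnorm(-abs(z)), z = z)
}

#' @export
print.beta_comparison <- function(x, ...) {
  cat("<beta_comparison> ", x$pair[1], " vs ", x$pair[2], " (",
      x$n_cells, " cells)\n", sep = "")
  cat(sprintf("  valence t-test p = %.4g; intensity median = %.3f (p = %.4g); sign agreement = %.1f%% (p = %.4g)\n",
              x$t_p, x$wilcoxon_median, x$wilcoxon_p,
              100 * x$agree_fraction, x$proportion_p))
  invisible(x)
}

# long-format data frame from a labeled matrix
melt_matrix <- function(m, value_name = "value") {
  df <- expand.grid(volume = rownames(m), metric = colnames(m),
                    stringsAsFactors = FALSE)
  df[[value_name]] <- as.vector(m)
  df
}

#' Render heatmaps of beta matrices and their comparisons
#'
#' Writes one PNG per heatmap type with a deterministic layout:
#' volumes on the y axis, metrics on the x axis, diverging color scale
#' anchored at the documented range of each type (beta: -1 red to +1
#' blue; valence: -1..1; intensity: 0..2; agreement: opposite/same).
#'
#' @param x A `beta_matrix` or `beta_comparison` object.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @param width,height,dpi Device settings.
#' @return Character vector of written file paths (invisibly).
#' @export
render_heatmaps <- function(x, dir, prefix = NULL, width = 9, height = 9,
                            dpi = 150) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  tile <- function(df, fill_scale, title) {
    ggplot2::ggplot(df, ggplot2::aes(x = metric, y = volume,
                                     fill = value)) +
      ggplot2::geom_tile(color = "grey30") +
      fill_scale +
      ggplot2::labs(title = title, x = "keypress metric",
                    y = "brain volume", fill = NULL) +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
  save_plot <- function(p, file) {
    path <- file.path(dir, file)
    grDevices::png(path, width = width, height = height, units = "in",
                   res = dpi)
    print(p)
    grDevices::dev.off()
    path
  }
  files <- character(0)
  if (inherits(x, "beta_matrix")) {
    pre <- if (is.null(prefix)) paste0("beta_", x$group) else prefix
    sc <- ggplot2::scale_fill_gradient2(low = "red", mid = "white",
                                        high = "blue", limits = c(-1, 1))
    files <- save_plot(tile(melt_matrix(x$beta), sc,
                            paste("Standardized beta:", x$group)),
                       paste0(pre, ".png"))
  } else if (inherits(x, "beta_comparison")) {
    pre <- if (is.null(prefix)) paste0(x$pair[1], "_vs_", x$pair[2]) else
      prefix
    specs <- list(
      valence = list(m = x$valence, sc = ggplot2::scale_fill_gradient2(
        low = "orange", mid = "white", high = "purple", limits = c(-1, 1)),
        title = "Valence |bA| - |bB|"),
      intensity = list(m = x$intensity, sc = ggplot2::scale_fill_gradient(
        low = "orange", high = "purple", limits = c(0, 2)),
        title = "Intensity |bA - bB|"),
      agreement = list(m = x$agreement, sc = ggplot2::scale_fill_gradient2(
        low = "orange", mid = "white", high = "purple", limits = c(-1, 1)),
        title = "Sign agreement"))
    files <- vapply(names(specs), function(nm) {
      s <- specs[[nm]]
      save_plot(tile(melt_matrix(s$m), s$sc,
                     paste0(s$title, ": ", x$pair[1], " vs ", x$pair[2])),
                paste0(pre, "_", nm, ".png"))
    }, character(1))
  } else stop("x must be a beta_matrix or beta_comparison", call. = FALSE)
  invisible(files)
}
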