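#' Shannon entropy of a keypress count distribution
#'
#' Entropy, in bits, of the distribution of a participant's keypresses
#' over the pictures of one category: `H = -sum(p_i * log2(p_i))` with
#' `p_i = k_i / sum(k)` taken over the pictures with nonzero counts
#' (`0 * log(0)` is defined as 0, so zero-count pictures do not
#' contribute). With `n` equally keypressed pictures H attains its
#' ceiling `log2(n)`; a single keypressed picture gives 0 bits.
#'
#' @param counts Nonnegative integer (or numeric) vector of per-picture
#'   keypress counts.
#' @return Entropy in bits, or `NA_real_` when all counts are zero
#'   (the distribution is undefined, not certain).
#' @export
#' @examples
#' shannon_entropy(rep(5, 20))   # log2(20) = 4.3219
#' shannon_entropy(c(1, 0, 0))   # 0
#' shannon_entropy(c(4, 4, 2))   # 1.5219
shannon_entropy <- function(counts) {
  if (length(counts) == 0L) return(NA_real_)
  if (anyNA(counts) || any(counts < 0)) {
    stop("'counts' must be nonnegative and non-missing", call. = FALSE)
  }
  k <- counts[counts > 0]
  if (length(k) == 0L) return(NA_real_)
  p <- k / sum(k)
  -sum(p * log2(p))
}

#' Per-category keypress statistics
#'
#' Summarizes one participant's raw responses into, for every
#' category x valence cell, the mean keypress count K, the standard
#' deviation sigma, the Shannon entropy H (bits) and the number of
#' actively keypressed pictures. By default K and sigma are computed
#' over pictures with a nonzero count of the given valence -- the work
#' actually traded -- with `include_zeros = TRUE` switching to the
#' zero-inclusive variant (H always ignores zero counts).
#'
#' @param responses Data frame with columns `category`, `picture`,
#'   `valence` (`"inc"` for approach, `"dec"` for avoidance) and
#'   `keypresses`, for a single participant.
#' @param include_zeros Include zero-count pictures in K and sigma?
#' @return A tibble with one row per category x valence:
#'   `category`, `valence`, `n_active`, `k`, `sigma`, `h`. Cells with
#'   no active picture carry `NA` for `k`, `sigma`, `h`; a single
#'   active picture gives `sigma = 0` and `h = 0`.
#' @export
category_stats <- function(responses, include_zeros = FALSE) {
  stopifnot(is.data.frame(responses))
  need <- c("category", "picture", "valence", "keypresses")
  miss <- setdiff(need, names(responses))
  if (length(miss)) {
    stop("responses is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(responses) == 0L) {
    stop("responses must contain at least one category", call. = FALSE)
  }
  cats <- sort(unique(responses$category))
  rows <- list()
  for (cat_id in cats) {
    for (val in c("inc", "dec")) {
      sub <- responses[responses$category == cat_id &
                         responses$valence == val, , drop = FALSE]
      counts <- sub$keypresses
      active <- counts[counts > 0]
      n_active <- length(active)
      if (n_active == 0L) {
        k <- s <- h <- NA_real_
      } else {
        base <- if (include_zeros) counts else active
        k <- mean(base)
        s <- if (length(base) > 1L) stats::sd(base) else 0
        h <- shannon_entropy(counts)
        if (n_active == 1L) h <- 0
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        category = cat_id, valence = val,
        n_active = n_active, k = k, sigma = s, h = h
      )
    }
  }
  do.call(rbind, rows)
}

#' Fit the RPT value function
#'
#' Least-squares fit of the value function `H = b * ln(K - x0)` to a
#' participant's per-category (K, H) points for one valence, with both
#' the slope `b` and the x-axis offset `x0` free. The offset makes the
#' logarithmic form fit individual data easily; when the log fit fails
#' numerically, a power-law `H = a * K^b` fallback is attempted (the
#' form can also be forced). On the avoidance side the curvature `b` is
#' the loss-resilience metric and `x0` the negative offset.
#'
#' @param k,h Numeric vectors of per-category mean keypress counts and
#'   entropies (same length).
#' @param form `"log"` (default, with power-law fallback) or `"power"`.
#' @return List with `offset`, `curvature`, `fit_ok`, `form`, `reason`
#'   (empty when `fit_ok`), and `sse` (residual sum of squares).
#' @export
#' @examples
#' k <- c(2, 3, 5, 9)
#' fit_value_function(k, 2 * log(k - 1))  # recovers x0 = 1, b = 2
fit_value_function <- function(k, h, form = c("log", "power")) {
  form <- match.arg(form)
  ok <- is.finite(k) & is.finite(h)
  k <- k[ok]; h <- h[ok]
  fail <- function(reason) list(offset = NA_real_, curvature = NA_real_,
                                fit_ok = FALSE, form = form, reason = reason,
                                sse = NA_real_)
  if (length(unique(k)) < 3L) return(fail("too_few_points"))

  if (form == "log") {
    # profile out b: for fixed x0, b-hat = sum(h*L)/sum(L^2), L = ln(k - x0)
    sse_at <- function(x0) {
      L <- log(k - x0)
      sL2 <- sum(L^2)
      if (!is.finite(sL2) || sL2 < 1e-12) return(Inf)
      b <- sum(h * L) / sL2
      sum((h - b * L)^2)
    }
    span <- max(diff(range(k)), 1)
    upper <- min(k) - 1e-9 * span
    lower <- min(k) - 10 * span
    grid <- seq(lower, upper, length.out = 200L)
    sse_grid <- vapply(grid, sse_at, numeric(1))
    if (all(!is.finite(sse_grid))) {
      log_fit <- NULL
    } else {
      i <- which.min(sse_grid)
      lo <- grid[max(1L, i - 1L)]
      hi <- grid[min(length(grid), i + 1L)]
      opt <- try(stats::optimize(sse_at, c(lo, hi), tol = 1e-12),
                 silent = TRUE)
      if (inherits(opt, "try-error") || !is.finite(opt$objective)) {
        log_fit <- NULL
      } else {
        x0 <- opt$minimum
        L <- log(k - x0)
        b <- sum(h * L) / sum(L^2)
        log_fit <- list(offset = x0, curvature = b, fit_ok = TRUE,
                        form = "log", reason = "", sse = opt$objective)
      }
    }
    if (!is.null(log_fit)) return(log_fit)
  }

  # power-law form (primary when form == "power", fallback otherwise)
  usable <- k > 0 & h > 0
  if (sum(usable) < 3L) return(fail("power_fallback_failed"))
  pf <- stats::lm(log(h[usable]) ~ log(k[usable]))
  b <- unname(stats::coef(pf)[2])
  if (!is.finite(b)) return(fail("power_fallback_failed"))
  list(offset = NA_real_, curvature = b, fit_ok = TRUE, form = "power",
       reason = "", sse = sum(stats::residuals(pf)^2))
}

#' Fit the RPT limit function
#'
#' Least-squares quadratic fit `sigma = a*K^2 + b*K + c` of keypress
#' variability against mean keypress count -- the variance-mean
#' "limit" curve, which rises to a peak then falls. Features are the
#' closed-form vertex and area of the fitted parabola: the turning
#' point `-b/(2a)` (K at which sigma peaks), the apex `c - b^2/(4a)`
#' (peak sigma), and the quadratic area bounded by the K-axis,
#' `(b^2 - 4ac)^(3/2) / (6 a^2)`, defined only when the parabola has
#' real roots.
#'
#' @param k,sigma Numeric vectors of per-category means and standard
#'   deviations (same length).
#' @return List with `apex`, `turning_point`, `quad_area`,
#'   `coefficients` (c(a, b, c)), `fit_ok`, `reason`. `fit_ok` is
#'   `FALSE` when the points are under-determined, the quadratic term
#'   vanishes, or the discriminant is not positive (the area feature is
#'   required downstream).
#' @export
#' @examples
#' k <- c(0, 1, 2, 3, 4)
#' fit_limit_function(k, -(k - 2)^2 + 4)  # apex 4, turning point 2, area 32/3
fit_limit_function <- function(k, sigma) {
  ok <- is.finite(k) & is.finite(sigma)
  k <- k[ok]; sigma <- sigma[ok]
  out <- list(apex = NA_real_, turning_point = NA_real_,
              quad_area = NA_real_, coefficients = c(a = NA_real_,
              b = NA_real_, c = NA_real_), fit_ok = FALSE, reason = "")
  if (length(unique(k)) < 3L) { out$reason <- "too_few_points"; return(out) }
  fit <- stats::lm(sigma ~ k + I(k^2))
  cf <- stats::coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  out$coefficients <- c(a = a, b = b, c = cc)
  if (!is.finite(a) || abs(a) < 1e-10) {
    out$reason <- "degenerate_quadratic"; return(out)
  }
  out$turning_point <- -b / (2 * a)
  out$apex <- cc - b^2 / (4 * a)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) { out$reason <- "no_real_roots"; return(out) }
  out$quad_area <- disc^1.5 / (6 * a^2)
  out$fit_ok <- TRUE
  out
}

#' Trade-off function features
#'
#' Polar-coordinate features of the per-category (H+, H-) trade-off
#' points, which quantify how bundles of approach judgments are
#' balanced against bundles of avoidance judgments. Per category,
#' `r = sqrt(H+^2 + H-^2)` (bits) and the polar angle
#' `theta = atan(H-/H+)` measured in degrees from the H+ axis (90 when
#' H+ = 0; a category with both entropies zero is undefined and
#' dropped). Outputs are the arithmetic mean and sample standard
#' deviation across categories (SD is 0 with a single category).
#'
#' @param h_inc,h_dec Numeric vectors of per-category approach and
#'   avoidance entropies (bits).
#' @return List with `polar_angle`, `polar_dispersion`,
#'   `radial_distance`, `radial_dispersion`, `n_categories` (usable
#'   categories), all `NA` when no category is usable.
#' @export
#' @examples
#' tradeoff_features(3, 4)  # r = 5, theta = 53.130
tradeoff_features <- function(h_inc, h_dec) {
  stopifnot(length(h_inc) == length(h_dec))
  ok <- is.finite(h_inc) & is.finite(h_dec) & !(h_inc == 0 & h_dec == 0)
  hp <- h_inc[ok]; hm <- h_dec[ok]
  if (length(hp) == 0L) {
    return(list(polar_angle = NA_real_, polar_dispersion = NA_real_,
                radial_distance = NA_real_, radial_dispersion = NA_real_,
                n_categories = 0L))
  }
  r <- sqrt(hp^2 + hm^2)
  theta <- atan2(hm, hp) * 180 / pi
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(polar_angle = mean(theta), polar_dispersion = sd0(theta),
       radial_distance = mean(r), radial_dispersion = sd0(r),
       n_categories = length(hp))
}

#' Assemble a participant's keypress-metric profile
#'
#' Computes the 15 keypress metrics for one participant: the six base
#' variables (K, H, sigma averaged across categories for each valence)
#' and the nine RPT features (avoidance value-function curvature and
#' offset, avoidance limit-function apex/turning point/area, and the
#' four trade-off features). The profile is flagged invalid -- with a
#' reason code -- when the avoidance value fit, avoidance limit fit or
#' trade-off construction fails, mirroring the fit-failure exclusion
#' rule applied to real cohorts.
#'
#' @param responses Data frame of raw responses for one participant
#'   (see [category_stats()]).
#' @param include_zeros Passed to [category_stats()].
#' @param value_form Passed to [fit_value_function()].
#' @return One-row tibble with the 15 metric columns named as in
#'   [keypress_metric_labels()] plus `valid` and `exclusion_reason`.
#' @export
assemble_profile <- function(responses, include_zeros = FALSE,
                             value_form = c("log", "power")) {
  value_form <- match.arg(value_form)
  st <- category_stats(responses, include_zeros = include_zeros)
  inc <- st[st$valence == "inc", , drop = FALSE]
  dec <- st[st$valence == "dec", , drop = FALSE]

  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

  vf <- fit_value_function(dec$k, dec$h, form = value_form)
  lf <- fit_limit_function(dec$k, dec$sigma)

  # trade-off points pair H+ and H- within category
  hp <- inc$h[match(sort(unique(st$category)), inc$category)]
  hm <- dec$h[match(sort(unique(st$category)), dec$category)]
  tf <- tradeoff_features(ifelse(is.na(hp), NA_real_, hp),
                          ifelse(is.na(hm), NA_real_, hm))

  valid <- TRUE; reason <- ""
  if (!vf$fit_ok) { valid <- FALSE; reason <- "kh_fit_failure" }
  else if (!lf$fit_ok) { valid <- FALSE; reason <- "ksigma_fit_failure" }
  else if (tf$n_categories == 0L) { valid <- FALSE; reason <- "tradeoff_failure" }

  tibble::tibble(
    loss_resilience = vf$curvature,
    negative_offset = vf$offset,
    negative_apex = lf$apex,
    negative_turning_point = lf$turning_point,
    negative_area = lf$quad_area,
    polar_angle = tf$polar_angle,
    polar_dispersion = tf$polar_dispersion,
    radial_distance = tf$radial_distance,
    radial_dispersion = tf$radial_dispersion,
    mean_k_inc = mean_na(inc$k),
    mean_k_dec = mean_na(dec$k),
    mean_h_inc = mean_na(inc$h),
    mean_h_dec = mean_na(dec$h),
    mean_std_inc = mean_na(inc$sigma),
    mean_std_dec = mean_na(dec$sigma),
    valid = valid,
    exclusion_reason = reason
  )
}

#' Keypress-metric profiles for a whole response table
#'
#' Applies [assemble_profile()] to every participant in a raw keypress
#' response table.
#'
#' @param responses Data frame with columns `participant_id`,
#'   `category`, `picture`, `valence`, `keypresses`.
#' @inheritParams assemble_profile
#' @return Tibble with one row per participant: `participant_id`, the
#'   15 metric columns, `valid`, `exclusion_reason`.
#' @export
rpt_profiles <- function(responses, include_zeros = FALSE,
                         value_form = c("log", "power")) {
  value_form <- match.arg(value_form)
  if (!"participant_id" %in% names(responses)) {
    stop("responses is missing column(s): participant_id", call. = FALSE)
  }
  ids <- unique(responses$participant_id)
  out <- lapply(ids, function(id) {
    p <- assemble_profile(
      responses[responses$participant_id == id, , drop = FALSE],
      include_zeros = include_zeros, value_form = value_form
    )
    cbind(tibble::tibble(participant_id = id), p)
  })
  tibble::as_tibble(do.call(rbind, out))
}
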