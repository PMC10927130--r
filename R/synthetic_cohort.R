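#' Baseline regional volume fractions
#'
#' Plausible mean fractions of total brain volume for the 29 regions in
#' [brain_volume_labels()], used as the group-free baselines around
#' which the generator draws volumes. They sum to about 0.95, leaving
#' the remainder to unmodeled tissue.
#'
#' @return Named numeric vector over the 29 volume labels.
#' @export
volume_baselines <- function() {
  per_side <- c(
    "Cerebral White Matter" = 0.160, "Cerebral Cortex" = 0.220,
    "Cerebellum White Matter" = 0.012, "Cerebellum Cortex" = 0.045,
    "Cerebellum (Exterior)" = 0.004, "Thalamus" = 0.006,
    "Caudate" = 0.003, "Putamen" = 0.004, "Pallidum" = 0.0012,
    "Hippocampus" = 0.003, "Amygdala" = 0.0012,
    "Amygdala (Anterior)" = 0.0006, "Ventral Diencephalon" = 0.003,
    "Nucleus Accumbens" = 0.0005
  )
  labs <- brain_volume_labels()
  out <- numeric(length(labs))
  names(out) <- labs
  for (nm in names(per_side)) {
    out[paste("R", nm)] <- per_side[[nm]]
    out[paste("L", nm)] <- per_side[[nm]]
  }
  out["Brain Stem"] <- 0.018
  out
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects and validates every knob of the synthetic cohort generator.
#' Defaults emulate the three-group study design the analysis assumes:
#' 40 CTRL, 25 MDD and 46 CD participants, four picture categories of
#' 20 pictures each, and per-picture keypress counts whose category
#' means spread enough for the RPT value and limit functions to be
#' identifiable from four per-category points.
#'
#' @param n_per_group Named integer vector of participants per group
#'   (names from [group_labels()]).
#' @param n_categories,n_pictures_per_category Task dimensions.
#' @param approach_mean,avoid_mean Nonnegative expected keypresses per
#'   picture for each category (length `n_categories`), for the
#'   approach and avoidance sides.
#' @param approach_prob Probability that a picture is latently
#'   approach-valenced for a participant (per category, recycled).
#' @param dispersion Negative-binomial size parameter for count noise;
#'   `Inf` (default) gives Poisson counts, small values heavy
#'   overdispersion.
#' @param coupling_spec List of couplings to plant, each a list/row with
#'   `volume` (label from [brain_volume_labels()]), `metric` (label from
#'   [keypress_metric_labels()]), `group`, and `rho` in \[-1, 1\]: the
#'   within-group standardized slope of volume on metric.
#' @param volume_noise_sd Standard deviation of the independent noise
#'   component of volume z-scores (default 1, so a planted `rho` is the
#'   population standardized slope).
#' @param volume_cv Coefficient of variation mapping volume z-scores to
#'   fractions of total brain volume.
#' @param demographic_model List with `age_mean`, `age_sd`, `age_range`,
#'   `education_mean`, `education_sd`, `education_range`,
#'   `gender_prob` (named), `ethnicity_prob` (named).
#' @param age_volume_slope Optional slope adding an age effect to all
#'   volume z-scores (exercises covariate screening); default 0.
#' @param seed Integer seed; identical config + seed gives identical
#'   datasets.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_per_group = c(CTRL = 40L, MDD = 25L, CD = 46L),
    n_categories = 4L,
    n_pictures_per_category = 20L,
    approach_mean = c(3, 5, 8, 12),
    avoid_mean = c(2, 4, 7, 11),
    approach_prob = 0.5,
    dispersion = Inf,
    coupling_spec = list(),
    volume_noise_sd = 1,
    volume_cv = 0.06,
    demographic_model = list(
      age_mean = 37.9, age_sd = 10.6, age_range = c(18, 65),
      education_mean = 14.5, education_sd = 2.5, education_range = c(8, 20),
      gender_prob = c(M = 0.7, F = 0.3),
      ethnicity_prob = c(White = 0.80, Black = 0.12, Hispanic = 0.05,
                         Asian = 0.03)
    ),
    age_volume_slope = 0,
    seed = 1L) {
  bad <- function(field, msg) {
    stop(sprintf("invalid simulation config: '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% group_labels()))
    bad("n_per_group", "must be named with group labels CTRL/MDD/CD")
  if (any(n_per_group < 0) || anyNA(n_per_group))
    bad("n_per_group", "must be nonnegative")
  if (n_categories < 1) bad("n_categories", "must be >= 1")
  if (n_pictures_per_category < 1)
    bad("n_pictures_per_category", "must be >= 1")
  approach_mean <- rep_len(approach_mean, n_categories)
  avoid_mean <- rep_len(avoid_mean, n_categories)
  if (any(approach_mean < 0) || anyNA(approach_mean))
    bad("approach_mean", "rates must be nonnegative")
  if (any(avoid_mean < 0) || anyNA(avoid_mean))
    bad("avoid_mean", "rates must be nonnegative")
  approach_prob <- rep_len(approach_prob, n_categories)
  if (any(approach_prob < 0 | approach_prob > 1))
    bad("approach_prob", "must be in [0, 1]")
  if (dispersion <= 0) bad("dispersion", "must be positive (Inf = Poisson)")
  if (volume_noise_sd < 0) bad("volume_noise_sd", "must be nonnegative")
  if (volume_cv <= 0) bad("volume_cv", "must be positive")
  for (cs in coupling_spec) {
    if (!all(c("volume", "metric", "group", "rho") %in% names(cs)))
      bad("coupling_spec", "entries need volume, metric, group, rho")
    if (abs(cs$rho) > 1) bad("coupling_spec", "|rho| must be <= 1")
    if (!cs$volume %in% brain_volume_labels())
      stop("unknown volume label '", cs$volume, "'; valid labels: ",
           paste(brain_volume_labels(), collapse = ", "), call. = FALSE)
    if (!cs$metric %in% keypress_metric_labels())
      stop("unknown metric label '", cs$metric, "'; valid labels: ",
           paste(keypress_metric_labels(), collapse = ", "), call. = FALSE)
    if (!cs$group %in% group_labels())
      bad("coupling_spec", "group must be one of CTRL/MDD/CD")
  }
  structure(list(
    n_per_group = n_per_group, n_categories = as.integer(n_categories),
    n_pictures_per_category = as.integer(n_pictures_per_category),
    approach_mean = approach_mean, avoid_mean = avoid_mean,
    approach_prob = approach_prob, dispersion = dispersion,
    coupling_spec = coupling_spec, volume_noise_sd = volume_noise_sd,
    volume_cv = volume_cv, demographic_model = demographic_model,
    age_volume_slope = age_volume_slope, seed = as.integer(seed)
  ), class = "simulation_config")
}

# count draw: negative binomial with Poisson limit
rcount <- function(n, mu, size) {
  if (n == 0L) return(integer(0))
  if (mu == 0) return(rep(0L, n))
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Generate raw keypress responses for one participant
#'
#' Each picture receives a latent valence (approach with probability
#' `approach_prob`); the count for that side is drawn from the
#' configured count law and the opposite side is 0, so every
#' (category, picture, valence) cell has exactly one nonnegative count.
#'
#' @param participant_id Identifier copied into each row.
#' @param approach_mean,avoid_mean Per-category rates (keypresses per
#'   picture).
#' @param approach_prob Per-category latent approach probability.
#' @param n_pictures Pictures per category.
#' @param dispersion Negative-binomial size (`Inf` = Poisson).
#' @return Tibble with columns `participant_id`, `category`, `picture`,
#'   `valence`, `keypresses` (two rows per picture).
#' @export
generate_keypress_responses <- function(participant_id, approach_mean,
                                        avoid_mean, approach_prob = 0.5,
                                        n_pictures = 20L, dispersion = Inf) {
  if (any(approach_mean < 0) || any(avoid_mean < 0))
    stop("keypress rates must be nonnegative", call. = FALSE)
  if (n_pictures < 1) stop("n_pictures must be >= 1", call. = FALSE)
  n_cat <- length(approach_mean)
  approach_prob <- rep_len(approach_prob, n_cat)
  rows <- vector("list", n_cat)
  for (cc in seq_len(n_cat)) {
    is_inc <- stats::runif(n_pictures) < approach_prob[cc]
    inc <- integer(n_pictures); dec <- integer(n_pictures)
    inc[is_inc] <- rcount(sum(is_inc), approach_mean[cc], dispersion)
    dec[!is_inc] <- rcount(sum(!is_inc), avoid_mean[cc], dispersion)
    rows[[cc]] <- tibble::tibble(
      participant_id = participant_id,
      category = rep(cc, 2L * n_pictures),
      picture = rep(seq_len(n_pictures), 2L),
      valence = rep(c("inc", "dec"), each = n_pictures),
      keypresses = c(inc, dec)
    )
  }
  do.call(rbind, rows)
}

#' Plant structure-behavior couplings into volume columns
#'
#' Builds the 29 regional volume columns. For each planted coupling
#' (volume, metric, group, rho), that group's volume z-score is
#' `rho * z(metric) + sqrt(1 - rho^2) * volume_noise_sd * noise`, so the
#' within-group population standardized slope of volume on metric is
#' `rho` when `volume_noise_sd = 1`. Uncoupled cells are independent
#' noise around a group-free baseline. Z-scores are mapped to strictly
#' positive fractions of total brain volume via
#' `baseline * (1 + volume_cv * z)` (floored at 5% of baseline).
#'
#' @param profiles Tibble from [rpt_profiles()] (one row per
#'   participant, metric columns).
#' @param groups Character vector of group labels aligned with
#'   `profiles` rows.
#' @param coupling_spec As in [simulation_config()].
#' @param volume_noise_sd,volume_cv As in [simulation_config()].
#' @param baselines Named baseline fractions (default
#'   [volume_baselines()]).
#' @param age,age_volume_slope Optional shared age effect on all volume
#'   z-scores.
#' @return Tibble of 29 volume columns (column-name-safe labels),
#'   strictly positive fractions.
#' @export
plant_coupling <- function(profiles, groups, coupling_spec,
                           volume_noise_sd = 1, volume_cv = 0.06,
                           baselines = volume_baselines(),
                           age = NULL, age_volume_slope = 0) {
  n <- nrow(profiles)
  labs <- names(baselines)
  z <- matrix(stats::rnorm(n * length(labs), sd = volume_noise_sd),
              nrow = n, dimnames = list(NULL, labs))
  for (cs in coupling_spec) {
    if (!cs$volume %in% labs)
      stop("unknown volume label '", cs$volume, "'; valid labels: ",
           paste(labs, collapse = ", "), call. = FALSE)
    if (!cs$metric %in% names(profiles))
      stop("unknown metric label '", cs$metric, "'; valid labels: ",
           paste(keypress_metric_labels(), collapse = ", "), call. = FALSE)
    m <- profiles[[cs$metric]]
    idx <- which(groups == cs$group & is.finite(m))
    if (length(idx) < 2L) next
    zm <- as.vector(scale(m[idx]))
    if (anyNA(zm)) next  # zero-variance metric within group
    z[idx, cs$volume] <- cs$rho * zm +
      sqrt(1 - cs$rho^2) * volume_noise_sd * stats::rnorm(length(idx))
  }
  if (!is.null(age) && age_volume_slope != 0) {
    za <- as.vector(scale(age))
    z <- z + age_volume_slope * za
  }
  vol <- sweep(1 + volume_cv * z, 2, baselines, `*`)
  vol <- pmax(vol, matrix(rep(0.05 * baselines, each = n), nrow = n))
  out <- tibble::as_tibble(as.data.frame(vol))
  names(out) <- volume_col(labs)
  out
}

#' Generate a synthetic three-group cohort
#'
#' Draws a full cohort: per-picture keypress responses, derived
#' keypress-metric profiles, demographics, and 29 normalized brain
#' volumes carrying any planted structure-behavior couplings. The
#' coupling specification is returned as `truth` so recovery can be
#' tested against ground truth. Identical config (including seed)
#' yields identical output.
#'
#' @param config A [simulation_config()].
#' @return Object of class `cohort_dataset`: list with `responses`
#'   (raw keypress table), `participants` (group, demographics, volume
#'   columns), `profiles` (from [rpt_profiles()]), `truth` (the
#'   coupling spec) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be created by simulation_config()", call. = FALSE)
  set.seed(config$seed)
  dm <- config$demographic_model

  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  if (n == 0L) {
    empty_resp <- tibble::tibble(
      participant_id = character(0), category = integer(0),
      picture = integer(0), valence = character(0), keypresses = integer(0))
    empty_prof <- rpt_profile_schema()
    empty_part <- cbind(
      tibble::tibble(participant_id = character(0), group = character(0),
                     gender = character(0), age = numeric(0),
                     ethnicity = character(0), education = numeric(0)),
      stats::setNames(as.data.frame(matrix(numeric(0), ncol = 29)),
                      volume_col(brain_volume_labels())))
    return(structure(list(responses = empty_resp,
                          participants = tibble::as_tibble(empty_part),
                          profiles = empty_prof,
                          truth = config$coupling_spec, config = config),
                     class = "cohort_dataset"))
  }
  ids <- sprintf("%s_%03d", groups, stats::ave(seq_len(n), groups,
                                               FUN = seq_along))

  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  gender <- sample(names(dm$gender_prob), n, replace = TRUE,
                   prob = dm$gender_prob)
  ethnicity <- sample(names(dm$ethnicity_prob), n, replace = TRUE,
                      prob = dm$ethnicity_prob)
  age <- clamp(round(stats::rnorm(n, dm$age_mean, dm$age_sd)), dm$age_range)
  education <- clamp(round(stats::rnorm(n, dm$education_mean,
                                        dm$education_sd)),
                     dm$education_range)

  responses <- do.call(rbind, lapply(seq_len(n), function(i) {
    generate_keypress_responses(
      ids[i], config$approach_mean, config$avoid_mean,
      config$approach_prob, config$n_pictures_per_category,
      config$dispersion)
  }))

  profiles <- rpt_profiles(responses)
  profiles <- profiles[match(ids, profiles$participant_id), , drop = FALSE]

  volumes <- plant_coupling(profiles, groups, config$coupling_spec,
                            volume_noise_sd = config$volume_noise_sd,
                            volume_cv = config$volume_cv,
                            age = age,
                            age_volume_slope = config$age_volume_slope)

  participants <- tibble::as_tibble(cbind(
    tibble::tibble(participant_id = ids, group = groups, gender = gender,
                   age = as.numeric(age), ethnicity = ethnicity,
                   education = as.numeric(education)),
    volumes))

  structure(list(responses = tibble::as_tibble(responses),
                 participants = participants, profiles = profiles,
                 truth = config$coupling_spec, config = config),
            class = "cohort_dataset")
}

# empty profile tibble with full schema
rpt_profile_schema <- function() {
  cols <- c("participant_id", keypress_metric_labels(),
            "valid", "exclusion_reason")
  out <- lapply(cols, function(nm) {
    if (nm %in% c("participant_id", "exclusion_reason")) character(0)
    else if (nm == "valid") logical(0) else numeric(0)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n <- nrow(x$participants)
  cat("<cohort_dataset> ", n, " participants",
      if (n) paste0(" (", paste(sprintf("%s=%d",
        names(table(x$participants$group)),
        as.integer(table(x$participants$group))), collapse = ", "), ")"),
      "\n", sep = "")
  cat("  responses: ", nrow(x$responses), " rows; profiles valid: ",
      sum(x$profiles$valid), "/", n, "; planted couplings: ",
      length(x$truth), "\n", sep = "")
  invisible(x)
}
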