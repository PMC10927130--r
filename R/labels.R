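#' Canonical brain-volume labels
#'
#' The 29 total-brain-normalized regional volumes used throughout the
#' package: 14 bilateral structures (right/left) plus the brain stem.
#' Each volume is expressed as a fraction of total brain volume, so the
#' labels double as column names in participant tables.
#'
#' @param extra Optional character vector of additional volume labels to
#'   append to the canon (user-extensible registry).
#' @return Character vector of 29 (or more) unique volume labels.
#' @export
#' @examples
#' length(brain_volume_labels())  # 29
brain_volume_labels <- function(extra = NULL) {
  bilateral <- c(
    "Cerebral White Matter", "Cerebral Cortex",
    "Cerebellum White Matter", "Cerebellum Cortex", "Cerebellum (Exterior)",
    "Thalamus", "Caudate", "Putamen", "Pallidum",
    "Hippocampus", "Amygdala", "Amygdala (Anterior)",
    "Ventral Diencephalon", "Nucleus Accumbens"
  )
  labs <- c(
    as.vector(t(outer(c("R", "L"), bilateral, paste))),
    "Brain Stem"
  )
  labs <- unique(c(labs, extra))
  labs
}

#' Canonical keypress-metric labels
#'
#' The 15 keypress metrics: nine RPT graph features plus the six base
#' variables (mean keypress intensity K, Shannon entropy H and standard
#' deviation sigma, separately for approach "inc" and avoidance "dec").
#' These are the column names emitted by [rpt_profiles()].
#'
#' @return Character vector of 15 metric labels.
#' @export
keypress_metric_labels <- function() {
  c(
    "loss_resilience", "negative_offset", "negative_apex",
    "negative_turning_point", "negative_area",
    "polar_angle", "polar_dispersion", "radial_distance", "radial_dispersion",
    "mean_k_inc", "mean_k_dec", "mean_h_inc", "mean_h_dec",
    "mean_std_inc", "mean_std_dec"
  )
}

#' Canonical group labels
#' @return Character vector `c("CTRL", "MDD", "CD")`.
#' @export
group_labels <- function() c("CTRL", "MDD", "CD")

# Internal: column-name-safe version of a volume label ("R Thalamus" -> "R_Thalamus")
volume_col <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}
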