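#' Kruskal-Wallis and Dunn post-hoc assessment of one feature
#'
#' Tests a feature for distributional differences across the three
#' groups: the overall Kruskal-Wallis H (tie-corrected), then Dunn's
#' pairwise z statistics from mean ranks of the pooled sample,
#'
#'   z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
#'
#' where `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties. The three
#' pairwise p-values are BH-adjusted within the feature; the feature is
#' selected when any pairwise q falls below `alpha`.
#'
#' @param values Numeric feature vector.
#' @param groups Group labels (three levels expected).
#' @param alpha Selection level (default .05).
#' @return List with `kw_p`, `pairs` (tibble: `group_a`, `group_b`,
#'   `z`, `p`, `q`), and `selected`. A constant feature returns `NA`
#'   statistics and `selected = FALSE`.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  lev <- unique(groups)
  n_g <- table(groups)
  if (any(n_g < 2L)) stop("each group needs n >= 2", call. = FALSE)
  empty <- list(kw_p = NA_real_, pairs = tibble::tibble(
    group_a = character(0), group_b = character(0), z = numeric(0),
    p = numeric(0), q = numeric(0)), selected = FALSE)
  if (stats::sd(values) == 0) return(empty)

  kw <- stats::kruskal.test(values, factor(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  rbar <- tapply(r, groups, mean)

  combs <- utils::combn(sort(lev), 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt(s2 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  q <- bh_adjust(p)
  list(kw_p = kw$p.value,
       pairs = tibble::tibble(group_a = combs[1, ], group_b = combs[2, ],
                              z = z, p = p, q = q),
       selected = any(q < alpha))
}

#' Groupwise feature selection for classification
#'
#' Applies [kruskal_dunn()] to every keypress metric and every brain
#' volume across the three groups, returning the features whose
#' pairwise BH-adjusted q-values reach significance.
#'
#' @param cohort A `cohort_dataset`.
#' @param volumes,metrics Label sets to assess.
#' @param alpha Selection level.
#' @return Tibble with `feature`, `type` (`"metric"`/`"volume"`),
#'   `kw_p`, `min_q`, `selected`.
#' @export
select_features <- function(cohort, volumes = brain_volume_labels(),
                            metrics = keypress_metric_labels(),
                            alpha = 0.05) {
  part <- cohort$participants
  prof <- cohort$profiles[match(part$participant_id,
                                cohort$profiles$participant_id), ,
                          drop = FALSE]
  one <- function(vals, nm, type) {
    kd <- kruskal_dunn(vals, part$group, alpha = alpha)
    tibble::tibble(feature = nm, type = type, kw_p = kd$kw_p,
                   min_q = if (nrow(kd$pairs)) min(kd$pairs$q) else NA_real_,
                   selected = kd$selected)
  }
  rows <- c(
    lapply(metrics, function(m) one(prof[[m]], m, "metric")),
    lapply(volumes, function(v) one(part[[volume_col(v)]], v, "volume")))
  do.call(rbind, rows)
}

#' Mahalanobis whitening transform
#'
#' Computes the inverse principal square root of the pooled
#' within-group covariance so that Euclidean distances in the
#' transformed space are covariance-adjusted; the transformed pooled
#' covariance is the identity.
#'
#' @param x Numeric matrix of continuous features (rows =
#'   observations).
#' @param groups Group labels for pooling the within-group covariance.
#' @param ridge Nonnegative ridge added to the covariance diagonal when
#'   it is singular (0 = error on singularity).
#' @return List of class `mahalanobis_transform` with `w` (the
#'   whitening matrix) and `pooled_cov`; apply with
#'   [apply_transform()].
#' @export
mahalanobis_transform <- function(x, groups, ridge = 0) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  lev <- unique(groups)
  p <- ncol(x)
  s <- matrix(0, p, p)
  df <- 0
  for (g in lev) {
    xg <- x[groups == g, , drop = FALSE]
    if (nrow(xg) > 1L) {
      s <- s + (nrow(xg) - 1L) * stats::cov(xg)
      df <- df + nrow(xg) - 1L
    }
  }
  if (df == 0) stop("no within-group degrees of freedom", call. = FALSE)
  s <- s / df
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(abs(e$values), 1)) {
    if (ridge <= 0)
      stop("pooled within-group covariance is singular; supply ridge > 0",
           call. = FALSE)
    s <- s + ridge * diag(p)
    e <- eigen(s, symmetric = TRUE)
  }
  w <- e$vectors %*% diag(1 / sqrt(e$values), p) %*% t(e$vectors)
  structure(list(w = w, pooled_cov = s), class = "mahalanobis_transform")
}

#' Apply a Mahalanobis whitening transform
#' @param transform A [mahalanobis_transform()].
#' @param x Numeric matrix with matching columns.
#' @return Transformed matrix `x %*% w`.
#' @export
apply_transform <- function(transform, x) {
  as.matrix(x) %*% transform$w
}

# deterministic prior-weighted kNN vote
knn_vote <- function(d, train_labels, k, priors) {
  ord <- order(d, seq_along(d))  # stable tie-break by index
  nn <- train_labels[ord[seq_len(k)]]
  classes <- names(priors)
  votes <- vapply(classes, function(cl) sum(nn == cl), numeric(1))
  score <- priors * votes / k
  best <- which(score == max(score))
  if (length(best) > 1L) {
    best <- best[order(-priors[best], classes[best])][1L]
  }
  classes[best]
}

#' Leave-one-out kNN classification of two groups
#'
#' For each held-out participant the Mahalanobis whitening transform is
#' refit on the remaining observations (avoiding leakage; set
#' `refit_transform = FALSE` for a whole-sample fit), the k nearest
#' neighbors by Euclidean distance in the transformed space vote, and
#' the class score is `prior * (votes / k)`. Score ties break toward
#' the larger prior, then lexicographically. Binary indicator columns
#' bypass the whitening and are appended unscaled.
#'
#' @param x Numeric matrix of continuous features.
#' @param labels Class labels (two classes).
#' @param k Neighbor count (default 5).
#' @param priors Named per-class prior probabilities; `NULL` (default)
#'   uses training-fold class proportions.
#' @param transform `"mahalanobis"` (default) or `"none"`.
#' @param binary Optional matrix of unscaled binary columns appended
#'   after the transform.
#' @param refit_transform Refit the whitening within each fold?
#' @param ridge Ridge passed to [mahalanobis_transform()].
#' @return List with `predicted`, `actual`, and `report` (per-class
#'   tibble: `class`, `n`, `n_correct`, `pct_correct`,
#'   `n_misclassified`, `pct_misclassified`, `N`).
#' @export
knn_loo <- function(x, labels, k = 5L, priors = NULL,
                    transform = c("mahalanobis", "none"), binary = NULL,
                    refit_transform = TRUE, ridge = 1e-8) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  classes <- sort(unique(labels))
  if (any(table(labels) < k + 1L))
    stop("each class needs n >= k + 1", call. = FALSE)
  if (!is.null(binary)) binary <- as.matrix(binary)

  whole_tr <- if (transform == "mahalanobis" && !refit_transform)
    mahalanobis_transform(x, labels, ridge = ridge) else NULL

  predicted <- character(n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    if (transform == "mahalanobis") {
      tr <- if (refit_transform)
        mahalanobis_transform(x[tr_idx, , drop = FALSE], labels[tr_idx],
                              ridge = ridge) else whole_tr
      coords_train <- apply_transform(tr, x[tr_idx, , drop = FALSE])
      coords_test <- apply_transform(tr, x[i, , drop = FALSE])
    } else {
      coords_train <- x[tr_idx, , drop = FALSE]
      coords_test <- x[i, , drop = FALSE]
    }
    if (!is.null(binary)) {
      coords_train <- cbind(coords_train, binary[tr_idx, , drop = FALSE])
      coords_test <- cbind(coords_test, binary[i, , drop = FALSE])
    }
    d <- sqrt(rowSums(sweep(coords_train, 2, as.vector(coords_test))^2))
    pr <- if (is.null(priors)) {
      tab <- table(labels[tr_idx])
      stats::setNames(as.vector(tab) / sum(tab), names(tab))
    } else priors / sum(priors)
    pr <- pr[sort(names(pr))]
    predicted[i] <- knn_vote(d, labels[tr_idx], k, pr)
  }
  report <- do.call(rbind, lapply(classes, function(cl) {
    idx <- labels == cl
    nc <- sum(predicted[idx] == cl)
    tibble::tibble(class = cl, n = sum(idx), n_correct = nc,
                   pct_correct = 100 * nc / sum(idx),
                   n_misclassified = sum(idx) - nc,
                   pct_misclassified = 100 * (sum(idx) - nc) / sum(idx),
                   N = n)
  }))
  list(predicted = predicted, actual = labels, report = report)
}

#' Pairwise kNN classification over the six feature combinations
#'
#' Runs leave-one-out kNN for each group pair (CTRL/MDD, CTRL/CD,
#' MDD/CD) over the six variable combinations: (1) selected keypress
#' metrics only, (2) metrics + demographics, (3) selected brain volumes
#' only, (4) volumes + metrics, (5) volumes + demographics,
#' (6) metrics + volumes + demographics. Demographic age and education
#' are continuous (whitened with the rest); gender and ethnicity enter
#' as one-hot indicators excluded from the Mahalanobis covariance and
#' appended unscaled. Priors default to the pair's class proportions.
#'
#' @param cohort A `cohort_dataset`.
#' @param selected_metrics,selected_volumes Feature labels (e.g. the
#'   `selected` rows of [select_features()]).
#' @param k Neighbor count.
#' @param refit_transform,ridge Passed to [knn_loo()].
#' @return Tibble of class `classification_report`: one row per
#'   (pair, combination, class) with the confusion counts and
#'   percentages; combinations with an empty feature set are marked
#'   `not_run`.
#' @export
run_combinations <- function(cohort, selected_metrics, selected_volumes,
                             k = 5L, refit_transform = TRUE, ridge = 1e-8) {
  part <- cohort$participants
  prof <- cohort$profiles[match(part$participant_id,
                                cohort$profiles$participant_id), ,
                          drop = FALSE]
  vol_cols <- volume_col(selected_volumes)
  combos <- list(
    rpt_only = list(metrics = TRUE, volumes = FALSE, demo = FALSE),
    rpt_demo = list(metrics = TRUE, volumes = FALSE, demo = TRUE),
    volumes_only = list(metrics = FALSE, volumes = TRUE, demo = FALSE),
    volumes_rpt = list(metrics = TRUE, volumes = TRUE, demo = FALSE),
    volumes_demo = list(metrics = FALSE, volumes = TRUE, demo = TRUE),
    volumes_rpt_demo = list(metrics = TRUE, volumes = TRUE, demo = TRUE))
  pairs <- list(c("CTRL", "MDD"), c("CTRL", "CD"), c("MDD", "CD"))

  one_hot <- function(values, name) {
    f <- factor(values)
    if (nlevels(f) < 2L) return(NULL)
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste0(name, "_", levels(f))
    m[, -1L, drop = FALSE]  # reference level dropped
  }

  rows <- list()
  for (pr in pairs) for (cname in names(combos)) {
    cfg <- combos[[cname]]
    cont <- list(); bin <- NULL
    if (cfg$metrics && length(selected_metrics))
      cont$metrics <- as.matrix(prof[, selected_metrics, drop = FALSE])
    if (cfg$volumes && length(vol_cols))
      cont$volumes <- as.matrix(part[, vol_cols, drop = FALSE])
    if (cfg$demo) {
      cont$demo <- cbind(age = part$age, education = part$education)
      bin <- cbind(one_hot(part$gender, "gender"),
                   one_hot(part$ethnicity, "ethnicity"))
    }
    if (length(cont) == 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair = paste(pr, collapse = " vs "), combination = cname,
        class = pr, n = NA_integer_, n_correct = NA_integer_,
        pct_correct = NA_real_, n_misclassified = NA_integer_,
        pct_misclassified = NA_real_, N = NA_integer_, status = "not_run")
      next
    }
    xm <- do.call(cbind, cont)
    in_pair <- part$group %in% pr
    complete <- stats::complete.cases(xm) & in_pair
    if (!is.null(bin)) complete <- complete & stats::complete.cases(bin)
    x <- xm[complete, , drop = FALSE]
    labs <- part$group[complete]
    b <- if (!is.null(bin)) bin[complete, , drop = FALSE] else NULL
    tab <- table(labs)
    priors <- stats::setNames(as.vector(tab) / sum(tab), names(tab))
    res <- knn_loo(x, labs, k = k, priors = priors, binary = b,
                   refit_transform = refit_transform, ridge = ridge)
    rep <- res$report
    rep$pair <- paste(pr, collapse = " vs ")
    rep$combination <- cname
    rep$status <- "ok"
    rows[[length(rows) + 1L]] <- rep[, c("pair", "combination", "class",
                                         "n", "n_correct", "pct_correct",
                                         "n_misclassified",
                                         "pct_misclassified", "N",
                                         "status")]
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("classification_report", class(out))
  out
}
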