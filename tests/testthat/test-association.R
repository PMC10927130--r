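test_that("covariate screening finds planted age effects and skips degenerate strata", {
  set.seed(21)
  n <- 40L
  vols <- volume_col(brain_volume_labels())
  part <- data.frame(participant_id = sprintf("p%02d", 1:n),
                     group = "CTRL", gender = "M",
                     age = round(runif(n, 20, 60)),
                     ethnicity = rep(c("White", "Black"), each = n / 2),
                     education = round(runif(n, 10, 20)))
  for (v in vols) part[[v]] <- rnorm(n)
  # planted: R_Thalamus tracks age almost perfectly
  part$R_Thalamus <- part$age + rnorm(n, sd = 0.01 * sd(part$age))
  # constant volume: nothing selected
  part$L_Caudate <- 1

  scr <- screen_covariates(part, "CTRL")
  sel <- scr[scr$selected, ]
  expect_true(any(sel$volume == "R Thalamus" & sel$covariate == "age"))
  expect_false(any(sel$volume == "L Caudate"))

  # single ethnicity stratum: ethnicity test skipped without error
  part$ethnicity <- "White"
  scr <- screen_covariates(part, "CTRL")
  expect_false(any(scr$covariate == "ethnicity"))
})

test_that("Cook's filter matches a direct influence oracle", {
  # exactly collinear data: no finite distances, nothing removed
  x <- 1:20
  cf <- cooks_filter(2 * x, x)
  expect_equal(cf$n_removed, 0L)

  # one gross outlier on an otherwise linear relation
  set.seed(4)
  n <- 40L
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.3)
  y[n] <- y[n] + 10 * sd(y)
  d <- cooks.distance(lm(y ~ x))             # direct oracle
  expect_identical(unname(which.max(d)), n)
  cf <- cooks_filter(y, x)
  expect_false(n %in% cf$keep)

  expect_false(cooks_filter(rnorm(8), rnorm(8))$ok)
})

test_that("standardized beta equals Pearson correlation without covariates", {
  x <- rnorm(30)
  r <- fit_bivariate(x, x, cooks = FALSE)
  expect_equal(r$std_beta, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    n <- 35L
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    res <- fit_bivariate(y, x)
    cf <- cooks_filter(y, x)
    expect_equal(res$std_beta, cor(y[cf$keep], x[cf$keep]),
                 tolerance = 1e-12)
    expect_lte(res$ci_low, res$std_beta)
    expect_gte(res$ci_high, res$std_beta)
  }

  expect_true(fit_bivariate(rep(1, 20), rnorm(20))$skipped)
})

test_that("BH adjustment matches hand step-up computations", {
  p15 <- c(0.001, runif(14, 0.2, 1))
  q <- bh_adjust(p15)
  expect_equal(q[1], 0.015)

  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))

  # permutation invariance and q >= p
  set.seed(8)
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("regression grid fills every cell with per-volume BH families", {
  ch <- small_cohort()
  vols <- brain_volume_labels()[c(11, 12, 17)]
  mets <- keypress_metric_labels()[c(1, 10, 15)]
  g <- run_grid(ch, "CTRL", volumes = vols, metrics = mets)
  expect_s3_class(g, "regression_grid")
  expect_identical(nrow(g), length(vols) * length(mets))
  expect_true(all(g$q >= g$p, na.rm = TRUE))
  done <- !g$skipped
  expect_true(all(g$ci_low[done] <= g$std_beta[done]))
  expect_true(all(g$std_beta[done] <= g$ci_high[done]))
  # per-volume family: q = BH over that volume's metric p-values
  for (v in vols) {
    i <- which(g$volume == v & !g$skipped)
    expect_equal(g$q[i], bh_adjust(g$p[i]))
  }
  # covariate-free variant matches fit_bivariate cell-by-cell
  g0 <- run_grid(ch, "CTRL", with_covariates = FALSE, volumes = vols,
                 metrics = mets)
  part <- ch$participants[ch$participants$group == "CTRL", ]
  prof <- ch$profiles[match(part$participant_id,
                            ch$profiles$participant_id), ]
  keep <- prof$valid
  cell <- fit_bivariate(prof$mean_k_inc[keep],
                        part[[volume_col(vols[1])]][keep])
  expect_equal(g0$std_beta[g0$volume == vols[1] &
                             g0$metric == "mean_k_inc"], cell$std_beta)
})

test_that("overlap analysis counts common and consistent pairs as hand-tallied", {
  mk_grid <- function(group, sig) {
    cells <- expand.grid(metric = c("m1", "m2", "m3"),
                         volume = c("v1", "v2"),
                         stringsAsFactors = FALSE)
    g <- tibble::tibble(group = group, metric = cells$metric,
                        volume = cells$volume, covariates = "",
                        std_beta = 0.1, ci_low = 0, ci_high = 0.2,
                        p = 0.5, q = 0.6, n_outliers_removed = 0L,
                        n_used = 30L, skipped = FALSE, skip_reason = "")
    for (s in sig) {
      i <- which(g$metric == s$metric & g$volume == s$volume)
      g$p[i] <- 0.01
      g$std_beta[i] <- s$beta
    }
    g
  }
  # A significant {c1 +, c2 -}, B {c2 +, c3 -}: common {c2}, consistent {}
  ga <- mk_grid("A", list(list(metric = "m1", volume = "v1", beta = 0.5),
                          list(metric = "m2", volume = "v1", beta = -0.5)))
  gb <- mk_grid("B", list(list(metric = "m2", volume = "v1", beta = 0.5),
                          list(metric = "m3", volume = "v2", beta = -0.5)))
  ov <- overlap_analysis(list(A = ga, B = gb))
  expect_identical(ov$n_common_pairs, 1L)
  expect_identical(ov$n_consistent_pairs, 0L)
  expect_identical(ov$total_significant, 4L)
  expect_equal(ov$consistency_fraction, 0)

  # identical grids, same signs: full consistency
  ov2 <- overlap_analysis(list(A = ga, B = ga))
  expect_equal(ov2$consistency_fraction, 100)

  # mismatched universes error
  gc <- mk_grid("C", list())
  gc$volume[1] <- "v99"
  expect_error(overlap_analysis(list(A = ga, C = gc)), "universe")
})
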