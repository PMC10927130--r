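test_that("config validation names the offending field", {
  expect_error(simulation_config(n_per_group = c(CTRL = -1, MDD = 1, CD = 1)),
               "n_per_group")
  expect_error(simulation_config(approach_mean = c(-1, 2, 3, 4)),
               "approach_mean")
  expect_error(simulation_config(coupling_spec = list(
    list(volume = "R Thalamus", metric = "mean_k_inc", group = "CTRL",
         rho = 1.2))), "rho")
  expect_error(simulation_config(coupling_spec = list(
    list(volume = "Nonexistent Region", metric = "mean_k_inc",
         group = "CTRL", rho = 0.5))), "valid labels")
})

test_that("empty cohort keeps a valid schema", {
  cfg <- simulation_config(n_per_group = c(CTRL = 0L, MDD = 0L, CD = 0L))
  ch <- generate_cohort(cfg)
  expect_s3_class(ch, "cohort_dataset")
  expect_identical(nrow(ch$responses), 0L)
  expect_identical(nrow(ch$participants), 0L)
  expect_true(all(volume_col(brain_volume_labels()) %in%
                    names(ch$participants)))
  expect_true(all(keypress_metric_labels() %in% names(ch$profiles)))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- simulation_config(n_per_group = c(CTRL = 10L, MDD = 10L, CD = 10L),
                           seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$participants, b$participants)
  cfg2 <- simulation_config(n_per_group = c(CTRL = 10L, MDD = 10L,
                                            CD = 10L), seed = 8L)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a$responses, c2$responses))
})

test_that("cohort invariants: membership, positivity, group labels", {
  ch <- small_cohort()
  expect_setequal(unique(ch$responses$participant_id),
                  ch$participants$participant_id)
  vols <- as.matrix(ch$participants[, volume_col(brain_volume_labels())])
  expect_true(all(vols > 0))
  expect_true(all(ch$participants$group %in% group_labels()))
  expect_true(all(ch$responses$keypresses >= 0))
})

test_that("keypress counts follow the configured law", {
  set.seed(5)
  # zero approach rate: positive-valence side never keypressed
  r0 <- generate_keypress_responses("p", approach_mean = rep(0, 4),
                                    avoid_mean = rep(5, 4),
                                    approach_prob = 0.5)
  expect_true(all(r0$keypresses[r0$valence == "inc"] == 0))
  st <- category_stats(r0)
  expect_true(all(is.na(st$k[st$valence == "inc"])))

  # Poisson mean 5 over 20 pictures: sample mean near 5
  set.seed(123)
  r <- generate_keypress_responses("p", approach_mean = rep(5, 1),
                                   avoid_mean = 0, approach_prob = 1,
                                   n_pictures = 20L)
  m <- mean(r$keypresses[r$valence == "inc"])
  expect_lt(abs(m - 5), 3 * sqrt(5 / 20))

  # heavy overdispersion: variance exceeds mean
  set.seed(7)
  r <- generate_keypress_responses("p", approach_mean = 5,
                                   avoid_mean = 0, approach_prob = 1,
                                   n_pictures = 1000L, dispersion = 0.5)
  k <- r$keypresses[r$valence == "inc"]
  expect_gt(var(k), mean(k))

  expect_error(generate_keypress_responses("p", approach_mean = -1,
                                           avoid_mean = 1), "nonnegative")
})

test_that("planted couplings control the within-group standardized slope", {
  fake_profiles <- function(n) {
    p <- rpt_profiles(structured_responses())[rep(1, n), ]
    p$participant_id <- sprintf("p%03d", seq_len(n))
    p
  }
  std_beta_of <- function(vol, met) {
    unname(coef(lm(scale(vol) ~ scale(met)))[2])
  }

  n <- 60L
  prof <- fake_profiles(n)
  set.seed(1); prof$mean_k_inc <- rnorm(n)
  groups <- rep("CTRL", n)

  # rho = 0, noise 0: constant at baseline
  set.seed(2)
  v <- plant_coupling(prof, groups, list(), volume_noise_sd = 0)
  expect_equal(unique(v$R_Thalamus),
               unname(volume_baselines()["R Thalamus"]))

  # rho = 1, noise 0: standardized slope exactly 1
  set.seed(3)
  v <- plant_coupling(prof, groups,
                      list(list(volume = "R Thalamus",
                                metric = "mean_k_inc", group = "CTRL",
                                rho = 1)), volume_noise_sd = 0)
  expect_equal(std_beta_of(v$R_Thalamus, prof$mean_k_inc), 1,
               tolerance = 1e-9)

  # rho = 0.5, n = 200: fitted standardized beta in [0.4, 0.6] in >= 90%
  n <- 200L
  prof <- fake_profiles(n)
  groups <- rep("CTRL", n)
  set.seed(10)
  hits <- 0L
  for (i in 1:100) {
    prof$mean_k_inc <- rnorm(n)
    v <- plant_coupling(prof, groups,
                        list(list(volume = "R Thalamus",
                                  metric = "mean_k_inc", group = "CTRL",
                                  rho = 0.5)))
    b <- std_beta_of(v$R_Thalamus, prof$mean_k_inc)
    if (b >= 0.4 && b <= 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  expect_error(plant_coupling(prof, groups,
                              list(list(volume = "Bogus",
                                        metric = "mean_k_inc",
                                        group = "CTRL", rho = 0.5))),
               "valid labels")
})
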