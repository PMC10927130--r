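test_that("shannon entropy matches closed forms and handles degenerate input", {
  expect_equal(shannon_entropy(rep(5, 20)), log2(20))
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(4, 4, 2)),
               -(0.4 * log2(0.4) * 2 + 0.2 * log2(0.2)))
  expect_true(is.na(shannon_entropy(c(0, 0, 0))))
  expect_error(shannon_entropy(c(1, -1)), "nonnegative")
})

test_that("category stats recover uniform, point-mass and small hand cases", {
  st <- category_stats(uniform_responses(count = 5L))
  inc <- st[st$valence == "inc", ]
  expect_equal(inc$k, rep(5, 4))
  expect_equal(inc$sigma, rep(0, 4))
  expect_equal(inc$h, rep(log2(20), 4))
  # avoidance side untouched -> undefined
  expect_true(all(is.na(st$k[st$valence == "dec"])))

  one <- data.frame(participant_id = "p", category = 1,
                    picture = 1:20, valence = "inc",
                    keypresses = c(7L, rep(0L, 19L)))
  st1 <- category_stats(one)
  r <- st1[st1$valence == "inc", ]
  expect_equal(r$h, 0)
  expect_equal(r$sigma, 0)
  expect_equal(r$n_active, 1L)

  tri <- data.frame(participant_id = "p", category = 1,
                    picture = 1:3, valence = "inc",
                    keypresses = c(4L, 4L, 2L))
  r <- category_stats(tri)[1, ]
  expect_equal(r$k, 10 / 3)
  expect_equal(r$h, 1.521928, tolerance = 1e-6)
})

test_that("count scaling leaves entropy fixed and scales K and sigma", {
  for (seed in 1:5) {
    set.seed(seed)
    resp <- structured_responses()
    m <- sample(2:6, 1)
    scaled <- resp
    scaled$keypresses <- scaled$keypresses * m
    a <- category_stats(resp)
    b <- category_stats(scaled)
    expect_equal(b$h, a$h)
    expect_equal(b$k, a$k * m)
    expect_equal(b$sigma, a$sigma * m)
  }
})

test_that("value function fit recovers exact and noisy log curves", {
  k <- c(2, 3, 5, 9)
  vf <- fit_value_function(k, 2 * log(k - 1))
  expect_true(vf$fit_ok)
  expect_equal(vf$offset, 1, tolerance = 1e-6)
  expect_equal(vf$curvature, 2, tolerance = 1e-6)
  expect_lt(vf$sse, 1e-10)

  expect_false(fit_value_function(c(2, 5), c(1, 2))$fit_ok)
  expect_false(fit_value_function(c(3, 3, 3, 3), c(1, 2, 3, 4))$fit_ok)

  # Monte-Carlo recovery: known (x0 = 0.5, b = 1.5), 4 noisy points
  set.seed(99)
  err_x0 <- err_b <- numeric(100)
  for (i in 1:100) {
    k <- c(1.5, 3, 6, 10)
    h <- 1.5 * log(k - 0.5) + rnorm(4, sd = 0.05)
    f <- fit_value_function(k, h)
    err_x0[i] <- abs(f$offset - 0.5)
    err_b[i] <- abs(f$curvature - 1.5)
  }
  expect_lt(median(err_x0), 0.5)
  expect_lt(median(err_b), 0.5)
})

test_that("limit function features equal closed-form vertex and area formulas", {
  k <- c(0, 1, 2, 3, 4)
  lf <- fit_limit_function(k, -(k - 2)^2 + 4)
  expect_true(lf$fit_ok)
  expect_equal(lf$turning_point, 2, tolerance = 1e-9)
  expect_equal(lf$apex, 4, tolerance = 1e-9)
  expect_equal(lf$quad_area, 32 / 3, tolerance = 1e-9)

  up <- fit_limit_function(k, (k - 2)^2 + 1)  # disc < 0
  expect_false(up$fit_ok)
  expect_identical(up$reason, "no_real_roots")
  expect_true(is.na(up$quad_area))

  # arbitrary points: coefficients match the normal-equation solution
  set.seed(3)
  k <- c(1, 2.5, 4, 7)
  s <- c(0.8, 2.2, 2.9, 1.1)
  lf <- fit_limit_function(k, s)
  X <- cbind(1, k, k^2)
  beta <- solve(t(X) %*% X, t(X) %*% s)
  expect_equal(unname(lf$coefficients["a"]), beta[3], tolerance = 1e-9)
  expect_equal(unname(lf$coefficients["b"]), beta[2], tolerance = 1e-9)
  expect_equal(unname(lf$coefficients["c"]), beta[1], tolerance = 1e-9)
  # vertex features are the closed forms on those coefficients
  expect_equal(lf$turning_point, -beta[2] / (2 * beta[3]), tolerance = 1e-9)
  expect_equal(lf$apex, beta[1] - beta[2]^2 / (4 * beta[3]),
               tolerance = 1e-9)
})

test_that("trade-off features match hand trigonometry", {
  tf <- tradeoff_features(3, 4)
  expect_equal(tf$radial_distance, 5)
  expect_equal(tf$polar_angle, atan(4 / 3) * 180 / pi, tolerance = 1e-9)
  expect_equal(tf$polar_dispersion, 0)
  expect_equal(tf$radial_dispersion, 0)

  tf <- tradeoff_features(c(1, 0), c(0, 1))
  expect_equal(tf$polar_angle, 45)
  expect_equal(tf$radial_distance, 1)
  expect_equal(tf$radial_dispersion, 0)

  set.seed(11)
  hp <- runif(4, 0.5, 4); hm <- runif(4, 0.5, 4)
  tf <- tradeoff_features(hp, hm)
  r <- sqrt(hp^2 + hm^2)
  th <- atan2(hm, hp) * 180 / pi
  expect_equal(tf$radial_distance, mean(r))
  expect_equal(tf$radial_dispersion, sd(r))
  expect_equal(tf$polar_angle, mean(th))
  expect_equal(tf$polar_dispersion, sd(th))

  # r/theta identity per category and angle bounds
  expect_true(all(th >= 0 & th <= 90))
  expect_equal(r^2, hp^2 + hm^2)
})

test_that("assembled profiles expose 15 metrics and encode fit failures", {
  prof <- assemble_profile(structured_responses())
  expect_true(all(keypress_metric_labels() %in% names(prof)))
  expect_length(setdiff(names(prof), c("valid", "exclusion_reason")), 15L)

  # per-category approach means (2+1/9ths adjust): uniform variant
  resp <- do.call(rbind, lapply(1:4, function(cc) {
    data.frame(participant_id = "p", category = cc, picture = 1:20,
               valence = "inc", keypresses = c(2L, 4L, 6L, 8L)[cc])
  }))
  p <- assemble_profile(resp)
  expect_equal(p$mean_k_inc, 5)

  # all-zero avoidance counts force exclusion with a reason code
  p0 <- assemble_profile(uniform_responses(count = 5L, valence = "inc"))
  expect_false(p0$valid)
  expect_true(p0$exclusion_reason %in%
                c("kh_fit_failure", "ksigma_fit_failure"))
})

test_that("profile table covers every participant with validity flags", {
  ch <- small_cohort()
  prof <- ch$profiles
  expect_setequal(prof$participant_id, ch$participants$participant_id)
  expect_true(all(prof$exclusion_reason[!prof$valid] != ""))
  expect_true(all(prof$exclusion_reason[prof$valid] == ""))
  # entropy ceiling: mean H bounded by log2(20)
  expect_true(all(prof$mean_h_inc <= log2(20) + 1e-9, na.rm = TRUE))
  expect_true(all(prof$mean_h_dec <= log2(20) + 1e-9, na.rm = TRUE))
})
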