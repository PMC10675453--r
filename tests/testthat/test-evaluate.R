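test_that("perfect agreement yields zero error terms", {
  y <- c(3.2, 4.8, 5.5, 7.1)
  rep <- compute_agreement(y, y)
  expect_equal(rep$bias, 0)
  expect_equal(rep$std, 0)
  expect_equal(rep$mse, 0)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$pe, 0)
  expect_equal(rep$rmsne, 0)
  expect_true(rep$clinically_acceptable)
})

test_that("agreement report satisfies its internal invariants", {
  set.seed(31)
  for (i in 1:25) {
    y_ref <- runif(40, 2, 10)
    y_pred <- y_ref + rnorm(40, sd = 0.5)
    rep <- compute_agreement(y_ref, y_pred)
    expect_equal(rep$rmse^2, rep$mse, tolerance = 1e-12)
    expect_equal(rep$loa_half_width, 1.96 * rep$std, tolerance = 1e-12)
    expect_equal(rep$loa_lower, rep$bias - rep$loa_half_width)
    expect_equal(rep$loa_upper, rep$bias + rep$loa_half_width)
    expect_equal(rep$rmsne, 100 * rep$rmse / rep$mean_ref_co)
    expect_equal(rep$pe, 100 * rep$loa_half_width / rep$mean_ref_co)
    expect_true(rep$pearson_r >= -1 && rep$pearson_r <= 1)
  }
})

test_that("swapping and scaling the sequences transform the report as expected", {
  set.seed(32)
  y_ref <- runif(60, 2, 10)
  y_pred <- y_ref + rnorm(60, sd = 0.4)
  a <- compute_agreement(y_ref, y_pred)
  b <- compute_agreement(y_pred, y_ref)    # swapped
  expect_equal(b$bias, -a$bias)
  expect_equal(b$std, a$std)
  expect_equal(b$mse, a$mse)
  expect_equal(b$mae, a$mae)
  expect_equal(b$pearson_r, a$pearson_r)
  cc <- compute_agreement(3 * y_ref, 3 * y_pred)  # common scale
  expect_equal(cc$bias, 3 * a$bias)
  expect_equal(cc$rmse, 3 * a$rmse)
  expect_equal(cc$rmsne, a$rmsne, tolerance = 1e-12)
  expect_equal(cc$pe, a$pe, tolerance = 1e-12)
  expect_equal(cc$pearson_r, a$pearson_r, tolerance = 1e-12)
})

test_that("degenerate paired inputs are rejected", {
  expect_error(compute_agreement(c(4, 5, 6), c(5, 5, 5)), "constant")
  expect_error(compute_agreement(5, 5), "2 pairs")
  expect_error(compute_agreement(c(1, 2), c(1, NA)), "finite")
  # hand-checked arithmetic for the same pairs, correlation aside:
  d <- c(5, 5, 5) - c(4, 5, 6)
  expect_equal(mean(d), 0)
  expect_equal(mean(abs(d)), 2 / 3)
  expect_equal(mean(d^2), 2 / 3)
})

test_that("Bland-Altman data agree with the report's lines", {
  y_ref <- c(4, 6)
  y_pred <- c(5, 5)
  ba <- bland_altman(y_ref, y_pred)
  expect_equal(ba$points$difference, c(1, -1))
  expect_equal(ba$points$mean, c(4.5, 5.5))
  expect_equal(ba$bias, 0)
  set.seed(33)
  y_ref <- runif(50, 2, 10)
  y_pred <- y_ref + rnorm(50, 0.1, 0.4)
  ba <- bland_altman(y_ref, y_pred)
  agg <- compute_agreement(y_ref, y_pred)
  expect_equal(ba$bias, agg$bias)
  expect_equal(ba$loa_lower, agg$loa_lower)
  expect_equal(ba$loa_upper, agg$loa_upper)
  expect_equal(ba$points$difference, y_pred - y_ref)
})

test_that("identity fit recovers exact linear relations and the OLS oracle", {
  y_ref <- c(2, 4, 6, 8)
  f <- identity_fit(y_ref, y_ref)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  f2 <- identity_fit(y_ref, 2 * y_ref + 1)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)
  expect_error(identity_fit(rep(5, 4), 1:4), "constant")
  set.seed(34)
  x <- runif(50, 2, 10)
  y <- 0.9 * x + 0.4 + rnorm(50, sd = 0.3)
  f3 <- identity_fit(x, y)
  # closed-form normal equations as the independent oracle
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  expect_equal(f3$slope, slope, tolerance = 1e-9)
  expect_equal(f3$intercept, mean(y) - slope * mean(x), tolerance = 1e-9)
})
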