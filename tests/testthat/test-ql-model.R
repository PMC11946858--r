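test_that("temperature response peaks exactly at T_opt with value m_opt", {
  p <- ql_temp_params(1, 5e4, 2e5, 300)
  expect_equal(m_of_temperature(p, 300), 1)
  # frozen values verified against independent high-precision evaluation
  expect_equal(m_of_temperature(p, 310), 0.4689322, tolerance = 1e-6)
  expect_equal(m_of_temperature(p, 290), 0.6541943, tolerance = 1e-6)
  expect_true(all(m_of_temperature(p, c(290, 310)) < 1))
})

test_that("m(T) <= m_opt over random valid parameter sets", {
  set.seed(202)
  grid <- seq(278, 323, by = 1)
  for (i in 1:100) {
    h_a <- runif(1, 2e4, 2e5)
    p <- ql_temp_params(runif(1, 0.1, 8), h_a, h_a * runif(1, 1.2, 6),
                        runif(1, 280, 320))
    m <- m_of_temperature(p, grid)
    expect_true(all(m <= p$m_opt + 1e-12))
    expect_equal(m_of_temperature(p, p$T_opt), p$m_opt, tolerance = 1e-12)
  }
})

test_that("qL model matches worked arithmetic and is monotone", {
  expect_equal(ql_mod(0, 2), 1)             # darkness: all centers open
  expect_equal(ql_mod(4, 2), 0.5)           # 2 / (4^0.5 + 2)
  chlf <- seq(0, 200, by = 0.5)
  q <- ql_mod(chlf, 1.7)
  expect_true(all(diff(q) < 0))             # strictly decreasing in ChlF
  expect_lt(ql_mod(1e8, 1.7), 1e-3)         # -> 0 under saturating light
  # increasing in m for ChlF > 1
  ms <- seq(0.5, 6, by = 0.1)
  expect_true(all(diff(ql_mod(10, ms)) > 0))
  expect_error(ql_mod(4, 0), "m must be")
})

test_that("ChlF inversion is the exact inverse of the qL model", {
  expect_equal(invert_qlmod_to_chlf(0.5, 2), 4)
  expect_equal(invert_qlmod_to_chlf(1, 2), 0)
  set.seed(9)
  q <- runif(2000, 0.01, 1)
  m <- runif(2000, 0.2, 8)
  expect_equal(ql_mod(invert_qlmod_to_chlf(q, m), m), q, tolerance = 1e-10)
  expect_error(invert_qlmod_to_chlf(0, 2), "qL")
})

test_that("fit_m recovers m exactly from noise-free pairs", {
  chlf <- c(0.5, 2, 5, 12, 20, 31)
  q <- ql_mod(chlf, 1.7)
  fit <- fit_m(q, chlf)
  expect_equal(fit$m_hat, 1.7, tolerance = 1e-6)
  expect_lt(fit$fit_residual, 1e-7)
  # single exactly-interpolable pair
  expect_equal(fit_m(0.5, 4)$m_hat, 2, tolerance = 1e-6)
  expect_error(fit_m(c(0.5, 0.6), c(0, 0)), "degenerate")
})

test_that("fit_m matches a brute-force grid search", {
  set.seed(77)
  grid <- seq(0.01, 10, by = 1e-4)
  for (i in 1:5) {
    m_true <- runif(1, 0.3, 6)
    chlf <- sort(runif(8, 0.5, 40))
    q <- ql_mod(chlf, m_true)
    sse <- vapply(grid, function(m) sum((q - ql_mod(chlf, m))^2), numeric(1))
    expect_equal(fit_m(q, chlf)$m_hat, grid[which.min(sse)],
                 tolerance = 2e-4)
  }
})

test_that("fit_m is nearly unbiased under 5% multiplicative noise", {
  set.seed(42)
  par_levels <- c(30, 50, 100, 200, 400, 600, 900, 1200, 1500, 1800, 2100)
  chlf <- 40 * par_levels / (par_levels + 600)
  q <- ql_mod(chlf, 1.7)
  bias <- replicate(200, {
    qn <- pmin(q * (1 + rnorm(11, 0, 0.05)), 1)
    fit_m(qn, chlf)$m_hat / 1.7 - 1
  })
  expect_lte(median(abs(bias)), 0.03)
})

test_that("temperature-parameter fit recovers truth and enforces preconditions", {
  tk <- c(288, 293, 298, 303, 308, 313, 318)
  p0 <- ql_temp_params(2, 5e4, 2e5, 303.15)
  fit <- fit_temperature_params(tk, m_of_temperature(p0, tk))
  expect_equal(fit$params$m_opt, p0$m_opt, tolerance = 1e-3)
  expect_equal(fit$params$H_a, p0$H_a, tolerance = 1e-3)
  expect_equal(fit$params$H_d, p0$H_d, tolerance = 1e-3)
  expect_equal(fit$params$T_opt, p0$T_opt, tolerance = 1e-3)
  expect_error(fit_temperature_params(tk[1:3], rep(1, 3)), ">= 4")
  expect_error(fit_temperature_params(c(290, 292, 294, 296), rep(1, 4)),
               "span")
})

test_that("T_opt is recovered within 2 K under 3% noise on m", {
  set.seed(303)
  tk <- celsius_to_kelvin(c(15, 20, 25, 30, 35, 40, 45))
  p0 <- ql_temp_params(2, 5e4, 2e5, 303.15)
  m_true <- m_of_temperature(p0, tk)
  errs <- replicate(100, {
    fit <- fit_temperature_params(tk, m_true * (1 + rnorm(7, 0, 0.03)))
    c(abs(fit$params$T_opt - 303.15), abs(fit$params$m_opt / 2 - 1))
  })
  expect_lte(median(errs[1, ]), 2)
  expect_lte(median(errs[2, ]), 0.05)
})

test_that("predict_ql composes the temperature and qL models", {
  p <- ql_temp_params(2, 5e4, 2e5, 303.15)
  expect_equal(predict_ql(p, 0, 310), 1)
  expect_equal(predict_ql(p, 4, 303.15), 0.5)  # m = m_opt = 2 at T_opt
})

test_that("parameter validation names the offending field", {
  expect_error(ql_temp_params(-1, 5e4, 2e5, 300), "m_opt")
  expect_error(ql_temp_params(1, 5e4, 4e4, 300), "H_d")
  expect_error(ql_temp_params(1, 5e4, 2e5, 400), "T_opt")
})
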