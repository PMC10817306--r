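test_that("linear predictor combines threshold, slope, and lag terms", {
  m <- arirt_model(item_bank(c(1, 1), c(0, 0)))
  expect_equal(linear_predictor(m, 1, theta = 0), 0)
  m2 <- arirt_model(item_bank(c(1, 2), c(0, 1)))
  expect_equal(linear_predictor(m2, 2, theta = 1, history = 0), 1)
  mlag <- arirt_model(item_bank(c(1, 1), c(0, 0)),
                      lag_structure(2, 1, "fixed"), 0.572)
  expect_equal(linear_predictor(mlag, 2, theta = 0, history = 1), 0.572)
  expect_equal(linear_predictor(mlag, 2, theta = 0, history = 0), 0)
  # missing lagged predictor drops the term
  expect_equal(linear_predictor(mlag, 2, theta = 0, history = NA), 0)
  expect_error(linear_predictor(mlag, 3, 0, c(1, 1)), "index")
  expect_error(linear_predictor(mlag, 2, 0, history = c(1, 1)), "length")
})

test_that("response probabilities match direct logistic evaluation", {
  m <- arirt_model(item_bank(1, 0))
  expect_equal(response_probability(m, 1, theta = 0), 0.5)
  # published AR1-2PL item 1 at theta = 0: logistic(1.322)
  ar1 <- spm_parameters("ar1_2pl")
  expect_equal(response_probability(ar1, 1, theta = 0),
               1 / (1 + exp(-1.322)), tolerance = 1e-12)
  mlag <- arirt_model(item_bank(c(1, 1), c(0, 0)),
                      lag_structure(2, 1, "fixed"), 0.572)
  expect_equal(response_probability(mlag, 2, 0, history = 1),
               1 / (1 + exp(-0.572)), tolerance = 1e-12)
})

test_that("probabilities are monotone in theta and in lagged responses", {
  th <- seq(-4, 4, by = 0.25)
  mlag <- arirt_model(item_bank(c(0.9, 1.7), c(-0.4, 0.8)),
                      lag_structure(2, 1, "fixed"), 0.6)
  for (j in 1:2) {
    pr <- response_probability(mlag, j, th, history = rep(0, j - 1))
    expect_true(all(pr > 0 & pr < 1))
    expect_true(all(diff(pr) > 0))
  }
  p0 <- response_probability(mlag, 2, th, history = 0)
  p1 <- response_probability(mlag, 2, th, history = 1)
  expect_true(all(p1 > p0))
})

test_that("an AR model with zero lag coefficients equals the plain 2PL", {
  bank <- toy_bank()
  plain <- arirt_model(bank)
  lg <- lag_structure(3, 2, "variable")
  zero <- arirt_model(bank, lg, rep(0, lg$n_coef))
  th <- seq(-4, 4, by = 0.5)
  for (j in 1:3) {
    for (h in list(rep(0, j - 1), rep(1, j - 1))) {
      expect_equal(response_probability(zero, j, th, h),
                   response_probability(plain, j, th, h),
                   tolerance = 1e-12)
    }
  }
})

test_that("parameterization conversion is exact and round-trips", {
  expect_equal(convert_parameters(item_bank(2, 1))$difficulty, 0.5)
  # published 2PL item 2: threshold/slope
  d <- convert_parameters(item_bank(1.997, -3.554))
  expect_equal(d$difficulty, -3.554 / 1.997, tolerance = 1e-12)
  expect_equal(d$difficulty, -1.77967, tolerance = 1e-5)
  back <- convert_parameters(tibble::tibble(discrimination = 1, difficulty = 0),
                             to = "intercept")
  expect_equal(back$slope, 1)
  expect_equal(back$threshold, 0)
  set.seed(1)
  bank <- item_bank(runif(10, 0.2, 3), rnorm(10, 0, 2))
  rt <- convert_parameters(convert_parameters(bank), to = "intercept")
  expect_equal(rt$slope, bank$slope, tolerance = 1e-10)
  expect_equal(rt$threshold, bank$threshold, tolerance = 1e-10)
  expect_error(convert_parameters(item_bank(c(1, 0), c(0, 0))), "slope is zero")
})

test_that("item information peaks at slope^2 / 4 and vanishes with zero slope", {
  m <- arirt_model(item_bank(c(2, 0), c(1, 0)))
  # P = 0.5 where theta = threshold / slope
  expect_equal(item_information(m, 1, theta = 0.5), 1.0)
  th <- seq(-4, 4, by = 0.1)
  expect_true(all(item_information(m, 1, th) <= 1.0 + 1e-12))
  expect_equal(item_information(m, 2, th), rep(0, length(th)))
})

test_that("conditional information curves are shifted by beta/alpha in theta", {
  alpha <- 1.6; beta <- 0.7
  m <- arirt_model(item_bank(c(1, alpha), c(0, 0.4)),
                   lag_structure(2, 1, "fixed"), beta)
  th <- seq(-3, 3, by = 0.1)
  # success on the previous item shifts the curve left by beta/alpha:
  # I(theta | prev = 1) = I(theta + beta/alpha | prev = 0)
  i1 <- item_information(m, 2, th, history = 1)
  i0_shifted <- item_information(m, 2, th + beta / alpha, history = 0)
  expect_equal(i1, i0_shifted, tolerance = 1e-12)
})

test_that("irf_table enumerates one row per item x theta x condition", {
  m <- arirt_model(item_bank(c(1, 1), c(0, 0)),
                   lag_structure(2, 1, "fixed"), 0.5)
  th <- c(-1, 0, 1)
  tab <- irf_table(m, th)
  expect_equal(nrow(tab), 3 + 6)  # item 1 unconditioned, item 2 has 2 conditions
  expect_equal(sort(unique(tab$condition[tab$item == 1])), "(none)")
  expect_setequal(unique(tab$condition[tab$item == 2]),
                  c("x[j-1]=0", "x[j-1]=1"))
  # values agree with pointwise evaluation
  row <- tab[tab$item == 2 & tab$condition == "x[j-1]=1" & tab$theta == 0, ]
  expect_equal(row$probability, response_probability(m, 2, 0, history = 1))
  expect_equal(row$information, item_information(m, 2, 0, history = 1))
  # no-lag model: one condition per item
  tab0 <- irf_table(arirt_model(toy_bank()), th)
  expect_equal(nrow(tab0), 9)
  expect_equal(unique(tab0$condition), "(none)")
  # AR2 item with two active terms has four conditions
  m2 <- arirt_model(toy_bank(), lag_structure(3, 2, "fixed"), c(0.4, 0.2))
  tab2 <- irf_table(m2, 0)
  expect_equal(sum(tab2$item == 3), 4)
})

test_that("lag structures respect the counting rules and validity limits", {
  expect_equal(lag_structure(12, 1, "fixed")$n_coef, 1L)
  expect_equal(lag_structure(12, 1, "variable")$n_coef, 11L)
  expect_equal(lag_structure(12, 2, "variable")$n_coef, 21L)
  expect_equal(lag_structure(5, 0, "none")$n_coef, 0L)
  sp <- lag_structure(6, 2, "sparse",
                      terms = data.frame(item = c(3, 5), lag = c(2, 1)))
  expect_equal(sp$n_coef, 2L)
  expect_error(lag_structure(6, 1, "sparse",
                             terms = data.frame(item = 1, lag = 1)),
               "non-existent")
  expect_error(lag_structure(3, 3, "fixed"), "exceeds")
  expect_error(arirt_model(toy_bank(), lag_structure(3, 1, "fixed"),
                           c(0.1, 0.2)), "lag coefficient")
})
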