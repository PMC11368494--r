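test_that("correlation screening flags pairs and honors priority order", {
  set.seed(1)
  x <- rnorm(200)
  df <- tibble(x = x, xcopy = x, y = rnorm(200), z = rep(1, 200))
  scr <- pearson_screen(df, threshold = 0.6, priority = c("x", "y", "xcopy"))
  r_xx <- scr$correlations$r[scr$correlations$var1 == "x" &
                               scr$correlations$var2 == "xcopy"]
  expect_equal(r_xx, 1)
  expect_equal(scr$exclude, "xcopy")  # the later-priority member drops
  expect_equal(scr$zero_variance, "z")

  df2 <- tibble(a = x, b = -x)
  scr2 <- pearson_screen(df2)
  expect_equal(scr2$correlations$r, -1)
  expect_equal(scr2$exclude, "b")
})

test_that("a planted correlation structure is detected at strength", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    arrival <- rnorm(500)
    duration <- 0.8 * arrival + sqrt(1 - 0.8^2) * rnorm(500)
    r <- pearson_screen(tibble(arrival, duration))$correlations$r
    if (r >= 0.75 && r <= 0.85) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of seeds land in the band
})

test_that("logistic fits match closed forms and an independent optimizer", {
  # null model: intercept = log odds of the observed split (31 of 56)
  df <- tibble(y = c(rep(1, 31), rep(0, 25)))
  f <- logistic_fit(df, "y")
  expect_equal(unname(coef(f$fit)), log(31 / 25), tolerance = 1e-8)

  # Newton-Raphson oracle on random small problems
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5)))
    if (length(unique(y)) < 2) next
    d <- tibble(y = y, x1 = X[, 1], x2 = X[, 2])
    f2 <- logistic_fit(d, "y", c("x1", "x2"))
    expect_equal(unname(coef(f2$fit)), unname(newton_logit(y, X)),
                 tolerance = 1e-6)
  }

  # perfectly separated toy data is flagged
  ds <- tibble(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12))
  expect_true(logistic_fit(ds, "y", "x")$separated)
})

test_that("slope confidence intervals cover zero under the null", {
  cover <- 0
  for (s in 1:100) {
    set.seed(s)
    d <- tibble(y = rbinom(100, 1, 0.5), x = rnorm(100))
    f <- logistic_fit(d, "y", "x")
    ci <- coef(f$fit)["x"] + c(-1.96, 1.96) * sqrt(vcov(f$fit)["x", "x"])
    if (ci[1] < 0 && ci[2] > 0) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("AICc approaches AIC for large n", {
  set.seed(2)
  d <- tibble(y = rbinom(1e5, 1, 0.4), x1 = rnorm(1e5), x2 = rnorm(1e5))
  f <- logistic_fit(d, "y", c("x1", "x2"))
  expect_lt(abs(f$aicc - stats::AIC(f$fit)), 0.01)
})

test_that("model averaging reproduces hand-computed Akaike weights", {
  set.seed(5)
  d <- tibble(y = rbinom(120, 1, plogis(0.4 + 0.6 * rnorm(120))))
  d$x <- rnorm(120)
  avg <- all_subsets_average(d, "y", "x")
  # independent weight computation from separate glm fits
  aicc_hand <- vapply(list(y ~ 1, y ~ x), function(fm) {
    g <- glm(fm, binomial(), data = d)
    k <- length(coef(g))
    -2 * as.numeric(logLik(g)) + 2 * k + 2 * k * (k + 1) / (120 - k - 1)
  }, double(1))
  delta <- aicc_hand - min(aicc_hand)
  w_hand <- exp(-delta / 2) / sum(exp(-delta / 2))
  got <- avg$models$weight[order(avg$models$terms)]       # (null), x
  expect_equal(got, w_hand[order(c("(null)", "x"))], tolerance = 1e-10)
  expect_equal(sum(avg$models$weight, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("averaging a single retained model returns that model exactly", {
  set.seed(8)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * x))  # overwhelming support for {x}
  d <- tibble(y = y, x = x)
  avg <- all_subsets_average(d, "y", "x", delta_max = 1)
  expect_equal(sum(avg$models$retained), 1)
  f <- logistic_fit(d, "y", "x")
  expect_equal(avg$coefficients$estimate[avg$coefficients$term == "x"],
               unname(coef(f$fit)["x"]), tolerance = 1e-10)
  expect_equal(avg$coefficients$std.error[avg$coefficients$term == "x"],
               sqrt(vcov(f$fit)["x", "x"]), tolerance = 1e-10)
})

test_that("duplicated predictors average symmetrically", {
  set.seed(9)
  x <- rnorm(150)
  d <- tibble(y = rbinom(150, 1, plogis(x)), x1 = x, x2 = x)
  avg <- suppressMessages(all_subsets_average(d, "y", c("x1", "x2")))
  b <- avg$coefficients
  expect_equal(b$estimate[b$term == "x1"], b$estimate[b$term == "x2"],
               tolerance = 1e-10)
})

test_that("a strong planted effect is recovered with a CI excluding zero", {
  hit <- 0
  for (s in 1:40) {
    set.seed(s)
    n <- 300
    x <- rnorm(n); z <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * x))
    d <- tibble(y = y, x = x, z = z)
    avg <- suppressMessages(all_subsets_average(d, "y", c("x", "z")))
    b <- avg$coefficients[avg$coefficients$term == "x", ]
    if (nrow(b) == 1 && b$estimate > 0 && b$conf.low > 0) hit <- hit + 1
  }
  expect_gte(hit, 38)  # >= 95% of seeds
})

test_that("Mann-Whitney U handles exact, tied and extreme cases", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$U), 0)
  expect_true(mw$exact)
  expect_equal(mw$p_value, 0.1)  # 2/20 arrangements, two-sided

  set.seed(3)
  big <- mann_whitney_u(rnorm(60), rnorm(60) + 2)
  expect_lt(big$p_value, 0.001)

  # invariance under strictly monotone transforms
  set.seed(4)
  a <- runif(15); b <- runif(20) + 0.2
  expect_equal(mann_whitney_u(a, b)$p_value,
               mann_whitney_u(exp(3 * a), exp(3 * b))$p_value)
  expect_equal(mann_whitney_u(a, b)$U, mann_whitney_u(log(a), log(b))$U)
})

test_that("one-way ANOVA matches the squared-t identity and edge cases", {
  set.seed(7)
  g1 <- rnorm(12); g2 <- rnorm(15)
  av <- anova_f(c(g1, g2), rep(c("a", "b"), c(12, 15)))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$p_value, tt$p.value, tolerance = 1e-10)

  eq <- anova_f(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(eq$F, 1e-20)

  expect_error(anova_f(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero within-group")
})

test_that("the characteristics table reports n, mean and SE by region", {
  s <- tibble(winter_region = c("MAV", "MAV", "Other"),
              total_distance_km = c(4, 6, 5),
              duration_days = c(90, 96, 93),
              n_stopovers = c(15, 17, 16),
              n_reverse = c(0, 2, 1))
  tab <- characteristics_table(s)
  mav_d <- tab[tab$winter_region == "MAV" &
                 tab$characteristic == "total_distance_km", ]
  expect_equal(mav_d$mean, 5)
  expect_equal(mav_d$se, 1)
  oth <- tab[tab$winter_region == "Other" &
               tab$characteristic == "duration_days", ]
  expect_true(is.na(oth$se))  # single individual: SE absent

  # planted region means are recovered within 2 SE
  set.seed(11)
  sim <- tibble(winter_region = rep(c("A", "B"), each = 40),
                total_distance_km = rnorm(80, rep(c(5000, 5600), each = 40), 300),
                duration_days = rnorm(80, 93, 5),
                n_stopovers = rpois(80, 16),
                n_reverse = rpois(80, 1))
  tab2 <- characteristics_table(sim)
  a <- tab2[tab2$winter_region == "A" &
              tab2$characteristic == "total_distance_km", ]
  expect_lt(abs(a$mean - 5000), 3 * a$se)
  b <- tab2[tab2$winter_region == "B" &
              tab2$characteristic == "total_distance_km", ]
  expect_lt(abs(b$mean - 5600), 3 * b$se)
})

test_that("predictor standardization centers, scales and relevels", {
  df <- tibble(distance = c(4000, 5000, 6000),
               winter_region = c("Other", "MAV", "Chenier"))
  out <- standardize_predictors(df)
  expect_lt(abs(mean(out$distance)), 1e-10)
  expect_equal(sd(out$distance), 1)
  expect_equal(levels(out$winter_region)[1], "MAV")
})
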