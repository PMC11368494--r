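test_that("step construction follows haversine lengths and turn conventions", {
  # three collinear equidistant fixes along a meridian
  fx <- make_fixes(lon = rep(-95, 3), lat = c(45, 45.5, 46))
  st <- build_steps(fx)
  expect_equal(st$step_km, rep(55.6, 2), tolerance = 1e-3)
  expect_true(is.na(st$angle_rad[1]))
  expect_equal(st$angle_rad[2], 0, tolerance = 1e-6)

  # east then north: a 90-degree left turn is +pi/2
  fx2 <- make_fixes(lon = c(0, 0.5, 0.5), lat = c(0, 0, 0.5))
  st2 <- build_steps(fx2)
  expect_equal(st2$angle_rad[2], pi / 2, tolerance = 1e-3)

  # device speed enters the covariate with the +0.1 offset
  fx3 <- make_fixes(lon = c(0, 0.1, 0.2), lat = c(0, 0, 0), speed = 40)
  expect_equal(build_steps(fx3)$speed_cov, rep(40.1, 2))

  expect_error(build_steps(make_fixes(lon = c(0, 1), lat = c(0, 0))),
               "at least 3")
})

test_that("a two-state model is recovered from its own simulations", {
  truth <- two_state_truth()
  steps <- simulate_hmm_steps(truth, 2000, seed = 31)
  fit <- suppressWarnings(fit_hmm(steps, n_states = 2, use_covariate = FALSE,
                                  seed = 1, n_restarts = 2))
  means <- sort(fit$gamma$mean)
  expect_lt(abs(means[1] - 0.2) / 0.2, 0.10)
  expect_lt(abs(means[2] - 30) / 30, 0.10)
  # decoding accuracy on well-separated states
  mapped <- if (fit$gamma$mean[1] < fit$gamma$mean[2])
    steps$true_state else 3 - steps$true_state
  acc <- mean(viterbi(fit, steps) == mapped)
  expect_gte(acc, 0.98)
})

test_that("refits are deterministic given the seed", {
  steps <- simulate_hmm_steps(two_state_truth(), 400, seed = 5)
  f1 <- suppressWarnings(fit_hmm(steps, 2, FALSE, seed = 7, n_restarts = 2))
  f2 <- suppressWarnings(fit_hmm(steps, 2, FALSE, seed = 7, n_restarts = 2))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("a one-state fit reduces to the direct gamma/von Mises MLE", {
  steps <- simulate_hmm_steps(
    as_mig_hmm(gamma = tibble(state = 1, mean = 5, sd = 3),
               vonmises = tibble(state = 1, mean = 0.3, kappa = 2)),
    600, seed = 3)
  fit <- suppressWarnings(fit_hmm(steps, n_states = 1, seed = 1,
                                  n_restarts = 1))
  # independent oracle: direct joint MLE by optim on the iid likelihood
  nll <- function(p) {
    shape <- (exp(p[1]) / exp(p[2]))^2; rate <- exp(p[1]) / exp(p[2])^2
    ang <- steps$angle_rad[-1]
    -(sum(dgamma(steps$step_km, shape, rate, log = TRUE)) +
        sum(exp(p[4]) * cos(ang - p[3]) -
              log(2 * pi * besselI(exp(p[4]), 0))))
  }
  ora <- optim(c(log(5), log(3), 0, log(2)), nll, method = "BFGS",
               control = list(reltol = 1e-12))
  expect_equal(fit$gamma$mean, exp(ora$par[1]), tolerance = 1e-3)
  expect_equal(fit$gamma$sd, exp(ora$par[2]), tolerance = 1e-3)
  expect_equal(fit$vonmises$kappa, exp(ora$par[4]), tolerance = 1e-3)
})

test_that("covariate-dependent transitions are recovered in sign", {
  truth <- two_state_truth()
  truth$trans_b <- matrix(c(0, 2, -2, 0), 2, 2, byrow = TRUE)
  truth$use_covariate <- TRUE
  set.seed(77)
  cov <- rnorm(1200)
  steps <- simulate_hmm_steps(truth, 1200, seed = 9, covariate = cov)
  steps$speed_cov <- cov
  fit <- suppressWarnings(fit_hmm(steps, 2, use_covariate = TRUE, seed = 2,
                                  n_restarts = 2))
  ord <- order(fit$gamma$mean)  # align state labels to truth
  b12 <- fit$trans_b[ord[1], ord[2]]
  expect_gt(b12, 0)  # higher speed pushes toward the fast state
  # transition rows are stochastic at any covariate value
  for (cv in c(-2, 0, 3)) {
    expect_equal(rowSums(transition_matrix(fit, cv)), c(1, 1),
                 tolerance = 1e-12)
  }
})

test_that("forward likelihood is invariant to state relabeling", {
  model <- two_state_truth()
  steps <- simulate_hmm_steps(model, 300, seed = 13)
  perm <- as_mig_hmm(
    gamma = model$gamma[2:1, ] |> mutate(state = 1:2),
    vonmises = model$vonmises[2:1, ] |> mutate(state = 1:2),
    trans_a = model$trans_a[2:1, 2:1],
    delta = model$delta[2:1])
  expect_equal(hmm_loglik(model, steps), hmm_loglik(perm, steps),
               tolerance = 1e-10)
  # role labels are permutation-equivariant
  expect_equal(label_states(model)$role[1], label_states(perm)$role[2])
})

test_that("pseudo-residuals are uniform under the true model and not otherwise", {
  model <- two_state_truth()
  reject <- 0
  for (r in 1:100) {
    steps <- simulate_hmm_steps(model, 400, seed = 500 + r)
    pr <- pseudo_residuals(model, steps)
    if (attr(pr, "ks_p") < 0.01) reject <- reject + 1
  }
  expect_lte(reject, 5)  # uniformity holds in at least 95% of replicates

  # identical inputs give identical residuals
  s1 <- simulate_hmm_steps(model, 300, seed = 1)
  expect_identical(pseudo_residuals(model, s1)$residual_u,
                   pseudo_residuals(model, s1)$residual_u)

  # a one-state model on strongly two-state data is rejected
  big <- simulate_hmm_steps(model, 1500, seed = 2)
  one <- as_mig_hmm(gamma = tibble(state = 1, mean = mean(big$step_km),
                                   sd = sd(big$step_km)),
                    vonmises = tibble(state = 1, mean = 0, kappa = 0.5))
  expect_lt(attr(pseudo_residuals(one, big), "ks_p"), 0.01)
})

test_that("the migratory state has the longest, straightest steps", {
  m <- as_mig_hmm(
    gamma = tibble(state = 1:4, mean = c(0.1, 1, 5, 32), sd = 1),
    vonmises = tibble(state = 1:4, mean = 0, kappa = 1))
  expect_equal(label_states(m)$role, c(rep("stopover", 3), "flight"))

  # near-tied means: higher angular concentration wins
  m2 <- as_mig_hmm(
    gamma = tibble(state = 1:2, mean = c(30, 28.5), sd = c(8, 8)),
    vonmises = tibble(state = 1:2, mean = 0, kappa = c(0.5, 8)))
  expect_equal(label_states(m2)$role, c("stopover", "flight"))

  m3 <- two_state_truth()
  expect_equal(sum(label_states(m3)$role == "flight"), 1)
})
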