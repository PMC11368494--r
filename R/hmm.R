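# Hidden Markov models for trajectory segmentation: gamma step lengths,
# von Mises turning angles, optional speed covariate on the transition
# probabilities (multinomial logit), fitted by direct numerical
# maximization of the forward-algorithm likelihood.

# ---- parameter packing ----------------------------------------------------

hmm_par_layout <- function(k, use_covariate, zero_mass) {
  idx <- list()
  at <- 0
  take <- function(n) { out <- at + seq_len(n); at <<- at + n; out }
  idx$log_mu <- take(k)
  idx$log_sigma <- take(k)
  idx$angle_mean <- take(k)
  idx$log_kappa <- take(k)
  if (zero_mass) idx$logit_zmass <- take(k)
  if (k > 1) {
    idx$trans_a <- take(k * (k - 1))
    if (use_covariate) idx$trans_b <- take(k * (k - 1))
    idx$delta <- take(k - 1)
  }
  idx$n <- at
  idx
}

hmm_unpack <- function(par, k, layout) {
  p <- list(
    mu = exp(par[layout$log_mu]),
    sigma = exp(par[layout$log_sigma]),
    angle_mean = wrap_angle(par[layout$angle_mean]),
    kappa = exp(pmin(par[layout$log_kappa], 6.5)),
    zmass = if (!is.null(layout$logit_zmass))
      stats::plogis(par[layout$logit_zmass]) else rep(0, k)
  )
  if (k > 1) {
    p$a <- matrix(0, k, k)
    p$a[row(p$a) != col(p$a)] <- par[layout$trans_a]
    p$b <- matrix(0, k, k)
    if (!is.null(layout$trans_b))
      p$b[row(p$b) != col(p$b)] <- par[layout$trans_b]
    d <- c(0, par[layout$delta])
    p$delta <- exp(d - max(d)) / sum(exp(d - max(d)))
  } else {
    p$a <- matrix(0, 1, 1); p$b <- matrix(0, 1, 1); p$delta <- 1
  }
  p
}

# per-step k-column log observation density matrix
hmm_logobs <- function(p, step_km, angle_rad) {
  k <- length(p$mu)
  n <- length(step_km)
  shape <- (p$mu / p$sigma)^2
  rate <- p$mu / p$sigma^2
  lo <- matrix(0, n, k)
  zero <- step_km <= 0
  for (j in seq_len(k)) {
    lj <- numeric(n)
    lj[!zero] <- log1p(-p$zmass[j]) +
      dgamma(step_km[!zero], shape = shape[j], rate = rate[j], log = TRUE)
    lj[zero] <- if (p$zmass[j] > 0) log(p$zmass[j]) else -1e10
    ok <- !is.na(angle_rad)
    lj[ok] <- lj[ok] + ldvonmises(angle_rad[ok], p$angle_mean[j], p$kappa[j])
    lo[, j] <- lj
  }
  lo
}

# k x k x n cube of per-step log transition matrices; homogeneous
# transitions collapse to a single slice (the C++ core reuses it)
hmm_logtrans <- function(p, covariate) {
  k <- nrow(p$a)
  n <- length(covariate)
  homo <- all(p$b == 0)
  if (k == 1) return(array(0, dim = c(1, 1, if (homo) 1 else n)))
  if (homo) {
    eta <- p$a
    m <- eta - apply(eta, 1, function(r) {
      mx <- max(r); mx + log(sum(exp(r - mx)))
    })
    cube <- array(m, dim = c(k, k, 1))
  } else {
    cube <- array(0, dim = c(k, k, n))
    for (i in seq_len(k)) {
      eta <- outer(covariate, p$a[i, ], function(cv, a) a) +
        outer(covariate, p$b[i, ]) # n x k
      mx <- apply(eta, 1, max)
      lse <- mx + log(rowSums(exp(eta - mx)))
      cube[i, , ] <- t(eta - lse)
    }
  }
  cube
}

# observation matrix from precomputed sufficient pieces (hot path of the
# optimizer: gamma log-density expanded so log(x) and the angle cos/sin
# are reused across likelihood evaluations)
hmm_logobs_fast <- function(p, ch) {
  k <- length(p$mu)
  n <- length(ch$x)
  shape <- (p$mu / p$sigma)^2
  rate <- p$mu / p$sigma^2
  lo <- matrix(0, n, k)
  for (j in seq_len(k)) {
    kap <- p$kappa[j]
    lj <- log1p(-p$zmass[j]) + (shape[j] - 1) * ch$lx - rate[j] * ch$x +
      shape[j] * log(rate[j]) - lgamma(shape[j])
    if (any(ch$zero)) {
      lj[ch$zero] <- if (p$zmass[j] > 0) log(p$zmass[j]) else -1e10
    }
    angc <- kap * (ch$cosa * cos(p$angle_mean[j]) +
                     ch$sina * sin(p$angle_mean[j])) -
      log(2 * pi) - log(besselI(kap, 0, expon.scaled = TRUE)) - kap
    lj[ch$okang] <- lj[ch$okang] + angc[ch$okang]
    lo[, j] <- lj
  }
  lo
}

hmm_nll <- function(par, k, layout, chunks) {
  p <- hmm_unpack(par, k, layout)
  ll <- 0
  for (ch in chunks) {
    lo <- hmm_logobs_fast(p, ch)
    if (k == 1) {
      ll <- ll + sum(lo)
    } else {
      cube <- hmm_logtrans(p, ch$speed_cov)
      ll <- ll + hmm_forward_cpp(lo, cube, log(p$delta))$loglik
    }
  }
  if (!is.finite(ll)) return(1e12)
  -ll
}

hmm_init_par <- function(steps, k, layout, jitter_sd, rng_jitter) {
  pos <- steps$step_km[steps$step_km > 0]
  # spread the state means across the step distribution, anchoring the
  # top state in the far tail: long flights are rare but extreme
  probs <- seq(0.2, 0.8, length.out = k)
  probs[k] <- 0.995
  qs <- quantile(pos, probs = probs, names = FALSE)
  mu0 <- qs * exp(rnorm(k, 0, jitter_sd))
  par <- numeric(layout$n)
  par[layout$log_mu] <- log(pmax(mu0, 1e-4))
  par[layout$log_sigma] <- log(pmax(mu0, 1e-4)) + rnorm(k, 0, jitter_sd / 2)
  par[layout$angle_mean] <- rnorm(k, 0, 0.1 * jitter_sd / 0.3)
  par[layout$log_kappa] <- log(seq(0.5, 2, length.out = k)) +
    rnorm(k, 0, jitter_sd)
  if (!is.null(layout$logit_zmass)) par[layout$logit_zmass] <- -3
  if (k > 1) {
    par[layout$trans_a] <- -2 + rnorm(k * (k - 1), 0, jitter_sd)
    if (!is.null(layout$trans_b)) par[layout$trans_b] <- 0
    par[layout$delta] <- 0
  }
  par
}

# ---- fitting --------------------------------------------------------------

#' Fit a step-length/turning-angle hidden Markov model
#'
#' States emit gamma-distributed step lengths (mean/sd parameterization,
#' with a per-state zero-mass point probability when zero-length steps
#' occur) and von Mises turning angles. Transition probabilities are
#' either homogeneous or depend on the speed covariate through a
#' multinomial logit. The likelihood is maximized directly (BFGS on
#' unconstrained transformed parameters; forward algorithm with
#' log-sum-exp scaling in C++), with multiple restarts from
#' quantile-spread step-mean initializations; the best restart is kept.
#' Refitting with the same seed reproduces the fit bit for bit.
#'
#' @param steps Step tibble from [build_steps()]; several individuals are
#'   pooled as independent chains sharing parameters.
#' @param n_states Number of states (1-4 supported; 1 reduces to a
#'   direct gamma/von Mises fit).
#' @param use_covariate Put the speed covariate on the transitions.
#' @param seed Integer seed controlling restart initializations.
#' @param n_restarts Restart count (default 10).
#' @param start Optional parameter list (a fitted `mig_hmm`) used as the
#'   single warm start, e.g. per-individual refits from a pooled fit.
#' @param maxit BFGS iteration cap per restart.
#' @return A `mig_hmm` object; see [tidy.mig_hmm()] and
#'   [glance.mig_hmm()].
#' @export
fit_hmm <- function(steps, n_states = 4, use_covariate = TRUE, seed = 1,
                    n_restarts = 10, start = NULL, maxit = 200) {
  stopifnot(n_states >= 1, n_states <= 4)
  if (nrow(steps) < 200) {
    warn("fit_hmm: fewer than 200 steps; parameter estimates may be unstable")
  }
  zero_mass <- any(steps$step_km <= 0)
  layout <- hmm_par_layout(n_states, use_covariate && n_states > 1, zero_mass)
  chunks <- steps |>
    group_by(.data$individual_id) |>
    group_split() |>
    lapply(function(df) {
      x <- df$step_km
      list(x = x, lx = suppressWarnings(log(x)), zero = x <= 0,
           cosa = cos(df$angle_rad), sina = sin(df$angle_rad),
           okang = !is.na(df$angle_rad), speed_cov = df$speed_cov)
    })
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed %% 2147483647)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  n_try <- if (is.null(start)) n_restarts else 1
  for (r in seq_len(n_try)) {
    par0 <- if (!is.null(start)) {
      hmm_repack(start, layout, zero_mass)
    } else {
      hmm_init_par(steps, n_states, layout,
                   jitter_sd = if (r == 1) 0 else 0.3, rng_jitter = r)
    }
    fit <- tryCatch(
      optim(par0, hmm_nll, k = n_states, layout = layout, chunks = chunks,
            method = "BFGS", control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("fit_hmm: no restart converged to a finite likelihood")
  }
  p <- hmm_unpack(best$par, n_states, layout)
  structure(list(
    n_states = n_states,
    gamma = tibble(state = seq_len(n_states), mean = p$mu, sd = p$sigma,
                   zero_mass = p$zmass),
    vonmises = tibble(state = seq_len(n_states), mean = p$angle_mean,
                      kappa = p$kappa),
    trans_a = p$a, trans_b = p$b, delta = p$delta,
    use_covariate = use_covariate && n_states > 1,
    zero_mass_fitted = zero_mass,
    loglik = -best$value, n_par = layout$n, n_steps = nrow(steps),
    convergence = best$convergence, seed = seed,
    par = best$par, layout = layout
  ), class = "mig_hmm")
}

# warm-start parameter vector from an existing fit (layouts must agree on
# k/covariate; zero-mass may differ between datasets)
hmm_repack <- function(model, layout, zero_mass) {
  par <- numeric(layout$n)
  par[layout$log_mu] <- log(model$gamma$mean)
  par[layout$log_sigma] <- log(model$gamma$sd)
  par[layout$angle_mean] <- model$vonmises$mean
  par[layout$log_kappa] <- log(pmax(model$vonmises$kappa, 1e-3))
  if (!is.null(layout$logit_zmass)) {
    par[layout$logit_zmass] <- stats::qlogis(pmin(pmax(model$gamma$zero_mass,
                                                       1e-4), 0.9))
  }
  k <- model$n_states
  if (k > 1) {
    par[layout$trans_a] <- model$trans_a[row(model$trans_a) != col(model$trans_a)]
    if (!is.null(layout$trans_b))
      par[layout$trans_b] <- model$trans_b[row(model$trans_b) != col(model$trans_b)]
    d <- log(pmax(model$delta, 1e-12))
    par[layout$delta] <- (d - d[1])[-1]
  }
  par
}

#' Transition probability matrix at a covariate value
#' @param model A `mig_hmm`.
#' @param covariate Speed covariate value (ignored for homogeneous fits).
#' @return k x k row-stochastic matrix.
#' @export
transition_matrix <- function(model, covariate = 0) {
  k <- model$n_states
  if (k == 1) return(matrix(1, 1, 1))
  eta <- model$trans_a + model$trans_b * covariate
  exp_eta <- exp(eta - apply(eta, 1, max))
  exp_eta / rowSums(exp_eta)
}

#' AIC of a fitted HMM
#' @param object A `mig_hmm`.
#' @param ... Unused.
#' @param k Penalty per parameter (2 = classical AIC).
#' @export
AIC.mig_hmm <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$n_par
}

#' @export
print.mig_hmm <- function(x, ...) {
  cat("Hidden Markov movement model:", x$n_states, "state(s),",
      x$n_steps, "steps\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      " parameters:", x$n_par, "\n")
  cat("step-length means (km):",
      paste(format(x$gamma$mean, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# ---- decoding and diagnostics --------------------------------------------

steps_to_chunks <- function(steps) {
  steps |>
    group_by(.data$individual_id) |>
    group_split()
}

#' Viterbi decoding
#'
#' Most probable joint state path under the fitted model; ties broken
#' toward the lower state index.
#'
#' @param model A `mig_hmm`.
#' @param steps Step tibble (one or more individuals).
#' @return Integer state vector aligned with `steps` rows.
#' @export
viterbi <- function(model, steps) {
  p <- hmm_unpack(model$par, model$n_states, model$layout)
  out <- integer(0)
  for (df in steps_to_chunks(steps)) {
    lo <- hmm_logobs(p, df$step_km, df$angle_rad)
    if (model$n_states == 1) {
      st <- rep(1L, nrow(df))
    } else {
      cube <- hmm_logtrans(p, df$speed_cov)
      st <- hmm_viterbi_cpp(lo, cube, log(p$delta))
    }
    out <- c(out, st)
  }
  out
}

#' Decode states onto the step table
#' @param model A `mig_hmm`.
#' @param steps Step tibble.
#' @return `steps` with an integer `state` column.
#' @export
decode_states <- function(model, steps) {
  ord <- steps |> group_by(.data$individual_id) |> group_rows() |> unlist()
  st <- viterbi(model, steps)
  steps$state <- NA_integer_
  steps$state[ord] <- st
  steps
}

#' One-step-ahead pseudo-residuals for step lengths
#'
#' Probability-integral-transform residuals of the forecast distribution
#' of each step length given the history. Under a correctly specified
#' model they are approximately standard uniform; a Kolmogorov-Smirnov
#' uniformity p-value is attached.
#'
#' @param model A `mig_hmm`.
#' @param steps Step tibble.
#' @return Tibble with `individual_id`, `residual_u` (uniform scale), and
#'   attribute `ks_p`.
#' @export
pseudo_residuals <- function(model, steps) {
  p <- hmm_unpack(model$par, model$n_states, model$layout)
  shape <- (p$mu / p$sigma)^2
  rate <- p$mu / p$sigma^2
  k <- model$n_states
  res <- list()
  for (df in steps_to_chunks(steps)) {
    n <- nrow(df)
    lo <- hmm_logobs(p, df$step_km, df$angle_rad)
    cdf <- sapply(seq_len(k), function(j) {
      p$zmass[j] + (1 - p$zmass[j]) *
        pgamma(df$step_km, shape = shape[j], rate = rate[j])
    })
    if (k == 1) {
      u <- cdf[, 1]
    } else {
      cube <- hmm_logtrans(p, df$speed_cov)
      la <- hmm_forward_cpp(lo, cube, log(p$delta))$logalpha
      homo <- dim(cube)[3] == 1
      G1 <- exp(cube[, , 1])
      w <- matrix(0, n, k)
      w[1, ] <- p$delta
      for (t in 2:n) {
        a <- exp(la[t - 1, ] - max(la[t - 1, ]))
        a <- a / sum(a)
        w[t, ] <- a %*% (if (homo) G1 else exp(cube[, , t]))
      }
      u <- rowSums(w * cdf)
    }
    res[[length(res) + 1]] <- tibble(individual_id = df$individual_id,
                                     residual_u = u)
  }
  out <- list_rbind(res)
  ks <- suppressWarnings(ks.test(out$residual_u, "punif"))
  attr(out, "ks_p") <- unname(ks$p.value)
  out
}

#' Map model states to movement roles
#'
#' The migratory state is the one with the largest mean step length; if
#' the two largest gamma means are within 10% of each other the state
#' with the higher angular concentration (straighter movement) wins. All
#' other states are stopover-role.
#'
#' @param model A `mig_hmm`.
#' @return Tibble `state`, `role` (`"flight"` or `"stopover"`).
#' @export
label_states <- function(model) {
  mu <- model$gamma$mean
  kappa <- model$vonmises$kappa
  ord <- order(mu, decreasing = TRUE)
  mig <- ord[1]
  if (length(mu) > 1) {
    top2 <- ord[1:2]
    if (diff(range(mu[top2])) / max(mu[top2]) < 0.10 &&
        kappa[top2[2]] > kappa[top2[1]]) {
      mig <- top2[2]
    }
  }
  tibble(state = seq_along(mu),
         role = ifelse(seq_along(mu) == mig, "flight", "stopover"))
}

#' Simulate a step series from a fitted or constructed HMM
#'
#' Useful for parameter-recovery tests and pseudo-residual calibration.
#'
#' @param model A `mig_hmm` (or compatible list with `gamma`, `vonmises`,
#'   `trans_a`, `trans_b`, `delta`, `n_states`).
#' @param n Number of steps.
#' @param seed Integer seed.
#' @param covariate Optional covariate vector (length `n`); defaults to
#'   zeros.
#' @param individual_id Id stamped on the output.
#' @return Step tibble with a `true_state` column.
#' @export
simulate_hmm_steps <- function(model, n, seed = 1, covariate = NULL,
                               individual_id = "sim") {
  set.seed(seed %% 2147483647)
  k <- model$n_states
  covariate <- covariate %||% rep(0, n)
  st <- integer(n)
  st[1] <- sample.int(k, 1, prob = model$delta)
  for (t in 2:n) {
    tm <- transition_matrix_raw(model, covariate[t])
    st[t] <- sample.int(k, 1, prob = tm[st[t - 1], ])
  }
  mu <- model$gamma$mean[st]
  sig <- model$gamma$sd[st]
  len <- rgamma(n, shape = (mu / sig)^2, rate = mu / sig^2)
  zm <- model$gamma$zero_mass[st]
  len[runif(n) < zm] <- 0
  ang <- rvonmises(n, model$vonmises$mean[st], model$vonmises$kappa[st])
  ang[1] <- NA_real_
  tibble(individual_id = individual_id,
         t_start = lubridate::as_datetime("2019-03-01", tz = "UTC") +
           (seq_len(n) - 1) * 1800,
         t_end = lubridate::as_datetime("2019-03-01", tz = "UTC") +
           seq_len(n) * 1800,
         step_km = len, angle_rad = ang, interval_min = 30,
         speed_cov = covariate + 0.1,
         lon_from = NA_real_, lat_from = NA_real_,
         lon_to = NA_real_, lat_to = NA_real_,
         true_state = st)
}

transition_matrix_raw <- function(model, covariate) {
  k <- model$n_states
  if (k == 1) return(matrix(1, 1, 1))
  b <- model$trans_b
  if (is.null(b)) b <- matrix(0, k, k)
  eta <- model$trans_a + b * covariate
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

# von Mises sampler (Best & Fisher 1979 rejection method)
rvonmises <- function(n, mu, kappa) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- kappa[i]
    if (k < 1e-6) { out[i] <- runif(1, -pi, pi); next }
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c <- k * (r - f)
      if (c * (2 - c) - u2 > 0 || log(c / u2) + 1 - c >= 0) {
        out[i] <- wrap_angle(sign(u3 - 0.5) * acos(f) + mu[i])
        break
      }
    }
  }
  out
}

#' Construct an HMM object from explicit parameters
#'
#' Builds a `mig_hmm` from parameter tables without fitting, e.g. to
#' decode or simulate under a known model.
#'
#' @param gamma Tibble `state`, `mean`, `sd` (and optional `zero_mass`).
#' @param vonmises Tibble `state`, `mean`, `kappa`.
#' @param trans_a Off-diagonal multinomial-logit intercepts (k x k,
#'   diagonal ignored).
#' @param trans_b Covariate slopes (k x k) or `NULL` for homogeneous
#'   transitions.
#' @param delta Initial state distribution.
#' @return A `mig_hmm` (with `loglik = NA`).
#' @export
as_mig_hmm <- function(gamma, vonmises, trans_a = NULL, trans_b = NULL,
                       delta = NULL) {
  k <- nrow(gamma)
  if (!"zero_mass" %in% names(gamma)) gamma$zero_mass <- 0
  if (is.null(trans_a)) trans_a <- matrix(-2, k, k) * (1 - diag(k))
  use_cov <- !is.null(trans_b)
  if (is.null(trans_b)) trans_b <- matrix(0, k, k)
  if (is.null(delta)) delta <- rep(1 / k, k)
  zero_mass <- any(gamma$zero_mass > 0)
  layout <- hmm_par_layout(k, use_cov && k > 1, zero_mass)
  model <- list(n_states = k, gamma = gamma, vonmises = vonmises,
                trans_a = trans_a, trans_b = trans_b, delta = delta,
                use_covariate = use_cov && k > 1,
                zero_mass_fitted = zero_mass,
                loglik = NA_real_, n_par = layout$n, n_steps = 0L,
                convergence = NA_integer_, seed = NA_integer_,
                layout = layout)
  model$par <- hmm_repack(model, layout, zero_mass)
  class(model) <- "mig_hmm"
  model
}

#' Forward log-likelihood of a step series under a model
#' @param model A `mig_hmm`.
#' @param steps Step tibble.
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(model, steps) {
  p <- hmm_unpack(model$par, model$n_states, model$layout)
  ll <- 0
  for (df in steps_to_chunks(steps)) {
    lo <- hmm_logobs(p, df$step_km, df$angle_rad)
    if (model$n_states == 1) {
      ll <- ll + sum(lo)
    } else {
      cube <- hmm_logtrans(p, df$speed_cov)
      ll <- ll + hmm_forward_cpp(lo, cube, log(p$delta))$loglik
    }
  }
  ll
}
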