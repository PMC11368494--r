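# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted movement HMM
#'
#' One row per state and distribution parameter.
#'
#' @param x A `mig_hmm`.
#' @param ... Unused.
#' @return Tibble: `state`, `role`, `step_mean_km`, `step_sd_km`,
#'   `step_zero_mass`, `angle_mean_rad`, `angle_concentration`.
#' @export
tidy.mig_hmm <- function(x, ...) {
  roles <- label_states(x)
  tibble(state = x$gamma$state,
         role = roles$role,
         step_mean_km = x$gamma$mean,
         step_sd_km = x$gamma$sd,
         step_zero_mass = x$gamma$zero_mass,
         angle_mean_rad = x$vonmises$mean,
         angle_concentration = x$vonmises$kappa)
}

#' One-row fit summary of a movement HMM
#' @param x A `mig_hmm`.
#' @param ... Unused.
#' @return Tibble: `n_states`, `n_steps`, `n_par`, `logLik`, `AIC`,
#'   `converged`.
#' @export
glance.mig_hmm <- function(x, ...) {
  tibble(n_states = x$n_states, n_steps = x$n_steps, n_par = x$n_par,
         logLik = x$loglik, AIC = AIC(x), converged = x$convergence == 0)
}

#' Tidy a model-averaged logistic regression
#' @param x A `mig_modavg`.
#' @param ... Unused.
#' @return The conditional model-averaged coefficient tibble.
#' @export
tidy.mig_modavg <- function(x, ...) x$coefficients

#' Model-set summary of an AICc averaging run
#' @param x A `mig_modavg`.
#' @param ... Unused.
#' @return One-row tibble: `n_models`, `n_retained`, `best_aicc`,
#'   `delta_max`.
#' @export
glance.mig_modavg <- function(x, ...) {
  tibble(n_models = nrow(x$models), n_retained = sum(x$models$retained),
         best_aicc = min(x$models$aicc), delta_max = x$delta_max)
}

#' Tidy a single logistic fit
#' @param x A `mig_logit`.
#' @param ... Unused.
#' @return Coefficient tibble with Wald standard errors.
#' @export
tidy.mig_logit <- function(x, ...) {
  cf <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  tibble(term = names(cf), estimate = unname(cf), std.error = unname(se))
}

#' One-row summary of a logistic fit
#' @param x A `mig_logit`.
#' @param ... Unused.
#' @return Tibble: `n`, `k`, `logLik`, `aicc`, `separated`.
#' @export
glance.mig_logit <- function(x, ...) {
  tibble(n = x$n, k = x$k, logLik = x$loglik, aicc = x$aicc,
         separated = x$separated)
}

#' Tidy a segmentation
#' @param x A `mig_segments`.
#' @param ... Unused.
#' @return The per-segment tibble.
#' @export
tidy.mig_segments <- function(x, ...) x$segments

#' One-row summary of a segmentation
#' @param x A `mig_segments`.
#' @param ... Unused.
#' @export
glance.mig_segments <- function(x, ...) {
  counts <- count_movements(x)
  tibble(n_steps = nrow(x$steps),
         n_flights = sum(x$segments$role == "flight"),
         n_stopovers = counts$n_stopovers,
         n_reverse = counts$n_reverse,
         flight_min_km = x$flight_min_km)
}
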