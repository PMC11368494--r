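# Comparative statistics: correlation screening, logistic regression
# with AICc, all-subsets conditional model averaging, rank and F tests,
# and the regional characteristics table.

#' Center and scale continuous predictors
#'
#' Standardizes every numeric column to mean 0 and unit SD; factors and
#' character columns pass through, with `winter_region` releveled to the
#' `"MAV"` reference when present.
#'
#' @param df Predictor tibble.
#' @param exclude Columns left untouched (e.g. the response).
#' @return Standardized tibble.
#' @export
standardize_predictors <- function(df, exclude = character()) {
  for (nm in names(df)) {
    if (nm %in% exclude) next
    if (is.numeric(df[[nm]])) {
      s <- sd(df[[nm]])
      df[[nm]] <- if (is.na(s) || s == 0) df[[nm]] - mean(df[[nm]])
                  else (df[[nm]] - mean(df[[nm]])) / s
    }
  }
  if ("winter_region" %in% names(df)) {
    lv <- unique(as.character(df$winter_region))
    if ("MAV" %in% lv) lv <- c("MAV", setdiff(lv, "MAV"))
    df$winter_region <- factor(df$winter_region, levels = lv)
  }
  df
}

#' Pearson correlation screening
#'
#' All pairwise correlations among numeric columns; pairs with |r| at or
#' above the threshold are flagged, and of each flagged pair the member
#' appearing later in `priority` is marked for exclusion (iterating
#' until no retained pair is flagged). Zero-variance columns are
#' excluded from correlations and listed separately.
#'
#' @param df Tibble of candidate predictors (numeric columns used).
#' @param threshold Flagging threshold on |r| (default 0.6).
#' @param priority Character vector, most important first (default:
#'   column order).
#' @return List: `correlations` (tibble `var1`, `var2`, `r`, `flagged`),
#'   `exclude` (columns to drop), `zero_variance`.
#' @export
pearson_screen <- function(df, threshold = 0.6, priority = NULL) {
  num <- df[vapply(df, is.numeric, logical(1))]
  if (nrow(num) < 3) abort("pearson_screen: need at least 3 rows")
  zv <- names(num)[vapply(num, function(x) sd(x) == 0 || is.na(sd(x)), logical(1))]
  num <- num[setdiff(names(num), zv)]
  priority <- priority %||% names(num)
  cm <- cor(num)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tab <- tibble(var1 = rownames(cm)[pairs[, 1]],
                var2 = colnames(cm)[pairs[, 2]],
                r = cm[pairs],
                flagged = abs(cm[pairs]) >= threshold)
  retained <- names(num)
  repeat {
    live <- tab$flagged & tab$var1 %in% retained & tab$var2 %in% retained
    if (!any(live)) break
    i <- which(live)[1]
    pair <- c(tab$var1[i], tab$var2[i])
    pr <- match(pair, priority)
    pr[is.na(pr)] <- Inf
    drop <- pair[which.max(pr)]
    retained <- setdiff(retained, drop)
  }
  list(correlations = tab,
       exclude = setdiff(names(num), retained),
       zero_variance = zv)
}

#' Logistic regression with small-sample AIC
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares,
#' deviance tolerance 1e-8) with
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. Complete separation is
#' flagged (the fit is kept but marked so model averaging can skip it).
#'
#' @param data Tibble holding response and predictors.
#' @param response Name of the binary (0/1 or logical) response column.
#' @param predictors Character vector of predictor columns (empty =
#'   intercept-only model).
#' @return A `mig_logit` object: list with the `glm` fit, `aicc`,
#'   `separated`, `predictors`.
#' @export
logistic_fit <- function(data, response, predictors = character()) {
  y <- data[[response]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2) abort("logistic_fit: response has one class")
  k <- length(predictors) + 1  # including intercept (and factor expansion below)
  rhs <- if (length(predictors) == 0) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(paste(sprintf("`%s`", response), "~", rhs))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = data,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  aliased <- any(is.na(coef(fit)))
  cf <- coef(fit)[!is.na(coef(fit))]
  if (any(abs(cf) > 15)) sep <- TRUE
  n <- nrow(data)
  k <- length(cf)
  if (n <= k + 1) abort("logistic_fit: AICc undefined, n <= k + 1")
  aicc <- -2 * as.numeric(logLik(fit)) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(list(fit = fit, aicc = aicc, separated = sep,
                 aliased = aliased, predictors = predictors, n = n, k = k,
                 loglik = as.numeric(logLik(fit))),
            class = "mig_logit")
}

#' @export
print.mig_logit <- function(x, ...) {
  cat("Logistic fit:", if (length(x$predictors) == 0) "(intercept only)"
      else paste(x$predictors, collapse = " + "), "\n")
  cat("logLik", format(x$loglik, digits = 6), " AICc",
      format(x$aicc, digits = 6),
      if (x$separated) " [separation flagged]" else "", "\n")
  invisible(x)
}

#' All-subsets logistic regression with conditional model averaging
#'
#' Fits every subset of the predictors (including the intercept-only
#' model), ranks by AICc, retains the competitive set (delta AICc at
#' most `delta_max`), renormalizes Akaike weights over it, and reports
#' conditional model-averaged coefficients: each term averaged with
#' weights renormalized over the models containing it, with 95%
#' confidence intervals from the weighted unconditional-variance
#' estimator.
#'
#' @param data Tibble with response and predictors.
#' @param response Binary response column name.
#' @param predictors Predictor column names (at most 12).
#' @param delta_max Retention threshold on delta AICc (default 6).
#' @return A `mig_modavg`: list with `models` (per-model tibble) and
#'   `coefficients`; see [tidy.mig_modavg()].
#' @export
all_subsets_average <- function(data, response, predictors, delta_max = 6) {
  stopifnot(length(predictors) <= 12)
  subsets <- purrr::map(0:length(predictors), ~ utils::combn(predictors, .x,
                                                             simplify = FALSE)) |>
    purrr::flatten()
  fits <- purrr::map(subsets, function(ps) {
    tryCatch(logistic_fit(data, response, ps), error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]; subsets <- subsets[keep]
  sepd <- vapply(fits, function(f) f$separated || f$aliased, logical(1))
  if (all(sepd)) abort("all_subsets_average: every candidate model is separated")
  if (any(sepd)) {
    inform(paste0("all_subsets_average: ", sum(sepd),
                  " separated or aliased model(s) excluded from averaging"))
  }
  fits <- fits[!sepd]; subsets <- subsets[!sepd]
  aicc <- vapply(fits, function(f) f$aicc, double(1))
  delta <- aicc - min(aicc)
  models <- tibble(
    model_id = seq_along(fits),
    terms = vapply(subsets, function(s)
      if (length(s) == 0) "(null)" else paste(s, collapse = " + "),
      character(1)),
    k = vapply(fits, function(f) f$k, double(1)),
    loglik = vapply(fits, function(f) f$loglik, double(1)),
    aicc = aicc, delta_aicc = delta
  )
  retained <- which(delta <= delta_max)
  w <- exp(-delta[retained] / 2)
  w <- w / sum(w)
  models$weight <- NA_real_
  models$weight[retained] <- w
  models$retained <- models$delta_aicc <= delta_max
  # conditional averaging over retained models containing each term
  all_terms <- unique(unlist(lapply(fits[retained], function(f)
    names(coef(f$fit)))))
  coefs <- purrr::map(all_terms, function(tm) {
    has <- vapply(seq_along(retained), function(i)
      tm %in% names(coef(fits[[retained[i]]]$fit)), logical(1))
    wi <- w[has] / sum(w[has])
    b <- vapply(retained[has], function(m) coef(fits[[m]]$fit)[[tm]], double(1))
    v <- vapply(retained[has], function(m) vcov(fits[[m]]$fit)[tm, tm], double(1))
    bbar <- sum(wi * b)
    se <- sum(wi * sqrt(v + (b - bbar)^2))  # unconditional variance estimator
    tibble(term = tm, estimate = bbar, std.error = se,
           conf.low = bbar - qnorm(0.975) * se,
           conf.high = bbar + qnorm(0.975) * se,
           n_models = sum(has), weight_sum = sum(w[has]))
  }) |> list_rbind()
  structure(list(models = models, coefficients = coefs,
                 delta_max = delta_max, response = response),
            class = "mig_modavg")
}

#' @export
print.mig_modavg <- function(x, ...) {
  cat("AICc all-subsets averaging of", x$response, ":",
      nrow(x$models), "models,", sum(x$models$retained),
      "retained (delta <=", x$delta_max, ")\n")
  print(x$coefficients)
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value when `length(a) * length(b) <= 400` and the pooled data
#' are tie-free; otherwise the normal approximation with tie and
#' continuity corrections. U counts pairs where `a` precedes `b`
#' (midranks for ties).
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `U`, `p_value`, `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  tibble(U = unname(wt$statistic), p_value = unname(wt$p.value),
         exact = exact)
}

#' One-way ANOVA F test
#'
#' Classical equal-variance one-way analysis of variance.
#'
#' @param values Numeric response.
#' @param group Grouping vector (at least 2 groups of at least 2).
#' @return One-row tibble: `F`, `df1`, `df2`, `p_value`.
#' @export
anova_f <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) abort("anova_f: need at least 2 groups")
  if (any(table(group) < 2)) abort("anova_f: every group needs >= 2 values")
  if (all(tapply(values, group, sd) == 0)) {
    abort("anova_f: zero within-group variance everywhere")
  }
  ow <- oneway.test(values ~ group, var.equal = TRUE)
  tibble(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
         df2 = unname(ow$parameter[2]), p_value = unname(ow$p.value))
}

#' Migration characteristics by wintering region
#'
#' Per-region sample size, mean and standard error (sd/sqrt(n)) of the
#' four migration characteristics; the SE of a single individual is
#' reported absent, not zero.
#'
#' @param summaries Migration-summary tibble (needs `winter_region`,
#'   `total_distance_km`, `duration_days`, `n_stopovers`, `n_reverse`).
#' @return Long tibble: `winter_region`, `characteristic`, `n`, `mean`,
#'   `se`.
#' @export
characteristics_table <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  summaries |>
    select("winter_region", "total_distance_km", "duration_days",
           "n_stopovers", "n_reverse") |>
    tidyr::pivot_longer(-"winter_region", names_to = "characteristic") |>
    group_by(.data$winter_region, .data$characteristic) |>
    summarise(n = sum(!is.na(.data$value)),
              mean = mean(.data$value, na.rm = TRUE),
              se = if (sum(!is.na(.data$value)) > 1)
                sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
              else NA_real_,
              .groups = "drop")
}
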