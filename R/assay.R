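check_curve <- function(data, min_points, what) {
  if (!all(c("concentration", "response") %in% names(data))) {
    stop_input("curve data must have columns 'concentration' and 'response'")
  }
  if (any(!is.finite(data$concentration)) || any(data$concentration <= 0)) {
    stop_input("concentrations must be positive and finite (molar)")
  }
  if (any(!is.finite(data$response))) stop_input("responses must be finite")
  if (length(unique(data$concentration)) < min_points) {
    stop_input(what, " needs at least ", min_points, " distinct concentrations")
  }
  invisible(data)
}

curve_replicates <- function(data) {
  if ("replicate" %in% names(data)) split(data, data$replicate) else list(data)
}

#' Area under a dose-response curve by the trapezoidal rule
#'
#' Composite trapezoid over (log10 molar concentration, response), the
#' summary used for reporter-cell titration comparisons. With a `replicate`
#' column, the AUC is computed per replicate and averaged.
#'
#' @param data Data frame with columns `concentration` (molar, > 0) and
#'   `response`; optional `replicate`.
#' @return AUC in response x log10-concentration units.
#' @examples
#' trapezoid_auc(data.frame(concentration = c(1e-6, 1e-5), response = c(0, 2)))
#' @export
trapezoid_auc <- function(data) {
  check_curve(data, 2, "trapezoid AUC")
  mean(vapply(curve_replicates(data), function(d) {
    d <- d[order(d$concentration), ]
    if (anyDuplicated(d$concentration)) {
      stop_input("duplicate concentrations within a replicate")
    }
    x <- log10(d$concentration); y <- d$response
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }, numeric(1)))
}

#' Area under a dose-response curve by cubic-spline interpolation
#'
#' Integrates the cubic spline through (log10 concentration, response) over
#' the observed log-concentration range. The default boundary condition is
#' the natural spline (zero second derivative at the ends); `"fmm"` is the
#' Forsythe-Malcolm-Moler alternative. With a `replicate` column, per
#' replicate then averaged (set `collapse = "mean"` to spline the replicate
#' means instead).
#'
#' @param data As in [trapezoid_auc()]; needs >= 3 distinct concentrations.
#' @param boundary `"natural"` (default) or `"fmm"`.
#' @param collapse `"replicates"` (default: AUC per replicate, then mean) or
#'   `"mean"` (spline through per-concentration means).
#' @return AUC in response x log10-concentration units.
#' @export
spline_auc <- function(data, boundary = c("natural", "fmm"),
                       collapse = c("replicates", "mean")) {
  boundary <- match.arg(boundary)
  collapse <- match.arg(collapse)
  check_curve(data, 3, "spline AUC")
  sets <- if (collapse == "mean") {
    list(dplyr::summarise(dplyr::group_by(as_tibble(data), .data$concentration),
                          response = mean(.data$response), .groups = "drop"))
  } else {
    curve_replicates(data)
  }
  mean(vapply(sets, function(d) {
    d <- d[order(d$concentration), ]
    if (anyDuplicated(d$concentration)) {
      stop_input("duplicate concentrations within a replicate")
    }
    x <- log10(d$concentration); y <- d$response
    f <- splinefun(x, y, method = boundary)
    integrate(f, min(x), max(x), subdivisions = 500L,
              rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1)))
}

fourpl <- function(x, floor, span, log_ec50, hill) {
  floor + span / (1 + 10^((log_ec50 - x) * hill))
}

#' Fit a four-parameter logistic curve and report the pEC50
#'
#' Least-squares fit of
#' `response = floor + (ceiling - floor) / (1 + 10^((log10(EC50) - x) * hill))`
#' with `x = log10(molar concentration)`, by Levenberg-Marquardt. The span
#' (`ceiling - floor`) is bounded below by zero. pEC50 is the negative log10
#' of the molar EC50, so 1 uM gives 6 and 1 nM gives 9.
#'
#' @param data Data frame with `concentration` (molar) and `response`;
#'   >= 4 distinct concentrations.
#' @return Object of class `pec50_fit`: `pec50`, `parameters` (tibble),
#'   `converged`, `bracketed` (EC50 inside the tested range), `rmse`,
#'   `model` (the underlying `nls` fit), `data`.
#' @export
fit_pec50 <- function(data) {
  check_curve(data, 4, "4PL fit")
  x <- log10(data$concentration)
  y <- data$response
  mid <- (min(y) + max(y)) / 2
  start <- list(floor = min(y), span = max(y) - min(y),
                log_ec50 = x[which.min(abs(y - mid))][1], hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fourpl(x, floor, span, log_ec50, hill),
      start = start,
      lower = c(floor = -Inf, span = 0, log_ec50 = min(x) - 6, hill = 0.05),
      upper = c(floor = Inf, span = Inf, log_ec50 = max(x) + 6, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(pec50 = NA_real_, parameters = NULL, converged = FALSE,
                bracketed = NA, rmse = NA_real_, model = NULL, data = data,
                message = conditionMessage(fit))
    class(out) <- "pec50_fit"
    return(out)
  }
  cf <- coef(fit)
  params <- tibble(
    term = c("floor", "ceiling", "log_ec50", "hill"),
    estimate = c(cf["floor"], cf["floor"] + cf["span"], cf["log_ec50"],
                 cf["hill"]))
  out <- list(
    pec50 = unname(-cf["log_ec50"]),
    parameters = params,
    converged = fit$convInfo$isConv %||% TRUE,
    bracketed = cf["log_ec50"] >= min(x) && cf["log_ec50"] <= max(x),
    rmse = sqrt(mean(resid(fit)^2)),
    model = fit,
    data = as_tibble(data))
  class(out) <- "pec50_fit"
  out
}

#' @export
print.pec50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit did not converge", if (!is.null(x$message)) paste0(": ", x$message), "\n")
    return(invisible(x))
  }
  cat(sprintf("pEC50 = %.3f (EC50 = %.3g M), hill = %.2f, rmse = %.4g%s\n",
              x$pec50, 10^(-x$pec50),
              x$parameters$estimate[x$parameters$term == "hill"], x$rmse,
              if (isTRUE(x$bracketed)) "" else " [EC50 outside tested range]"))
  invisible(x)
}

#' Percent difference from a reference group with a confidence interval
#'
#' Estimates `100 * (mean(comparison) - mean(reference)) / mean(reference)`
#' with a two-sided CI (default level 0.90) by Fieller's theorem on the
#' ratio of means (pooled variance, exact under normality) or by a seeded
#' percentile bootstrap. The comparison is flagged significantly higher than
#' the reference when the CI lower bound exceeds 0%.
#'
#' @param data Data frame with columns `group` and `value`.
#' @param reference Name of the reference level of `group` (default
#'   `"reference"`).
#' @param level Two-sided confidence level (default 0.90).
#' @param method `"fieller"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble of class `percent_diff`: `estimate`, `lower`,
#'   `upper`, `level`, `significant`, `method`, `unbounded` (TRUE when the
#'   Fieller denominator CI spans zero and the interval is not finite).
#' @export
percent_diff_ci <- function(data, reference = "reference", level = 0.90,
                            method = c("fieller", "bootstrap"),
                            n_boot = 10000, seed = 1) {
  method <- match.arg(method)
  if (!all(c("group", "value") %in% names(data))) {
    stop_input("data must have columns 'group' and 'value'")
  }
  ref <- data$value[data$group == reference]
  cmp <- data$value[data$group != reference]
  if (length(ref) < 2 || length(cmp) < 2) {
    stop_input("each group needs at least 2 replicates")
  }
  if (mean(ref) <= 0) stop_input("reference mean must be positive")
  est <- 100 * (mean(cmp) - mean(ref)) / mean(ref)
  unbounded <- FALSE
  if (method == "fieller") {
    n1 <- length(cmp); n2 <- length(ref)
    s2 <- (sum((cmp - mean(cmp))^2) + sum((ref - mean(ref))^2)) / (n1 + n2 - 2)
    vc <- s2 / n1; vr <- s2 / n2
    tq <- qt(1 - (1 - level) / 2, df = n1 + n2 - 2)
    mc <- mean(cmp); mr <- mean(ref)
    if (s2 == 0) {
      lo <- hi <- mc / mr
    } else {
      g <- tq^2 * vr / mr^2
      disc <- vc * mr^2 + vr * mc^2 - tq^2 * vr * vc
      if (g >= 1 || disc < 0) {
        unbounded <- TRUE
        lo <- -Inf; hi <- Inf
      } else {
        rad <- tq * sqrt(disc)
        lo <- (mc * mr - rad) / (mr^2 - tq^2 * vr)
        hi <- (mc * mr + rad) / (mr^2 - tq^2 * vr)
      }
    }
    lower <- 100 * (lo - 1); upper <- 100 * (hi - 1)
  } else {
    stats_boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        rs <- sample(ref, replace = TRUE)
        cs <- sample(cmp, replace = TRUE)
        100 * (mean(cs) - mean(rs)) / mean(rs)
      }, numeric(1))
    })
    lower <- unname(quantile(stats_boot, (1 - level) / 2))
    upper <- unname(quantile(stats_boot, 1 - (1 - level) / 2))
  }
  out <- tibble(estimate = est, lower = lower, upper = upper, level = level,
                significant = is.finite(lower) && lower > 0,
                method = method, unbounded = unbounded)
  class(out) <- c("percent_diff", class(out))
  out
}
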