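#' Dose-response immobilization data
#'
#' Container for acute immobilization counts: one row per replicate
#' exposure group with the concentration, the number of animals exposed and
#' the number scored immobile. Rows at concentration 0 are the negative
#' controls; their pooled immobilization fraction is the control mortality,
#' flagged when it exceeds the 5% QC limit of the standard acute test.
#'
#' @param concentration exposure concentrations (>= 0; 0 = control).
#' @param n_exposed animals exposed per row (> 0).
#' @param n_immobile animals immobile per row (0 <= n_immobile <=
#'   n_exposed; non-integer values are allowed after Abbott correction).
#' @param replicate optional replicate labels.
#' @param units unit label (e.g. "mg/L", "% v/v").
#' @return data frame of class `dr_data` with attributes
#'   `control_mortality` and `qc_flag`.
#' @export
dose_response_data <- function(concentration, n_exposed, n_immobile,
                               replicate = NULL, units = "mg/L") {
  k <- length(concentration)
  check_number(concentration, "concentration", min = 0, len = k)
  check_number(n_exposed, "n_exposed", min = 0, strict_min = TRUE, len = k)
  check_number(n_immobile, "n_immobile", min = 0, len = k)
  if (any(n_immobile > n_exposed)) {
    stop("'n_immobile' cannot exceed 'n_exposed'", call. = FALSE)
  }
  out <- data.frame(
    concentration = concentration,
    n_exposed = n_exposed,
    n_immobile = n_immobile,
    replicate = replicate %||% seq_len(k)
  )
  ctrl <- out$concentration == 0
  p0 <- if (any(ctrl)) sum(out$n_immobile[ctrl]) / sum(out$n_exposed[ctrl]) else 0
  attr(out, "units") <- units
  attr(out, "control_mortality") <- p0
  attr(out, "qc_flag") <- p0 > 0.05
  if (p0 > 0.05) {
    warning(sprintf("control mortality %.1f%% exceeds the 5%% QC limit",
                    100 * p0), call. = FALSE)
  }
  class(out) <- c("dr_data", "data.frame")
  out
}

hill_nll <- function(theta, lc, y, n) {
  ## theta = (log ec50, log h); p = logistic in log concentration
  p <- plogis(exp(theta[2]) * (lc - theta[1]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (n - y) * log(1 - p))
}

#' Fit the two-parameter Hill model by binomial maximum likelihood
#'
#' Fits `F(c) = c^h / (ec50^h + c^h)` to immobilization counts. The
#' likelihood is binomial (respecting the per-group animal counts rather
#' than treating percentages as homoscedastic), optimized on
#' `(log ec50, log h)` from three deterministic starts; the best finishing
#' point wins. A least-squares mode on the response fractions is available
#' for comparison with conventional curve-fitting software.
#'
#' @param data a [dose_response_data()] object (or data frame with the same
#'   columns). At least 4 distinct positive concentrations are required and
#'   the pooled response must be partial (not all 0, not all 1).
#' @param method `"binomial"` (default) or `"ls"`.
#' @return object of class `hill_fit`: list with `ec50`, `hill_slope`,
#'   `log_likelihood`, `converged`, `n_total`, `units`, `method`.
#' @examples
#' cc <- 10^seq(-2, 0, length.out = 7)
#' d <- dose_response_data(cc, rep(1000, 7),
#'                         round(1000 * hill_probability(cc, 0.15, 2)))
#' fit_hill(d)
#' @export
fit_hill <- function(data, method = c("binomial", "ls")) {
  method <- match.arg(method)
  pos <- data[data$concentration > 0, , drop = FALSE]
  if (length(unique(pos$concentration)) < 4) {
    stop("at least 4 distinct positive concentrations are required",
         call. = FALSE)
  }
  y <- pos$n_immobile
  n <- pos$n_exposed
  if (sum(y) == 0 || sum(y) == sum(n)) {
    stop("degenerate data: no partial response; widen the concentration range",
         call. = FALSE)
  }
  lc <- log(pos$concentration)

  ## deterministic initializations: EC50 from where the pooled response
  ## crosses 0.5, slopes spanning shallow to steep
  agg_p <- tapply(y, lc, sum) / tapply(n, lc, sum)
  lc_u <- as.numeric(names(agg_p))
  le0 <- lc_u[which.min(abs(as.numeric(agg_p) - 0.5))]
  starts <- list(c(le0, log(1)), c(le0, log(2)), c(median(lc), log(0.5)))

  obj <- if (method == "binomial") {
    function(theta) hill_nll(theta, lc, y, n)
  } else {
    function(theta) {
      p <- plogis(exp(theta[2]) * (lc - theta[1]))
      sum((y / n - p)^2)
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("Hill fit failed from all initializations", call. = FALSE)
  }
  ll <- if (method == "binomial") {
    -best$value + sum(lchoose(round(n), round(pmin(y, n))))
  } else NA_real_
  structure(list(
    ec50 = exp(best$par[1]),
    hill_slope = exp(best$par[2]),
    log_likelihood = ll,
    converged = best$convergence == 0 && all(is.finite(best$par)),
    n_total = sum(n),
    units = attr(data, "units") %||% "",
    method = method
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): EC50 = %.4g %s, slope = %.3g%s\n",
              x$method, x$ec50, x$units, x$hill_slope,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$ci_ec50)) {
    cat(sprintf("  95%% CI (bootstrap): [%.4g, %.4g]%s\n",
                x$ci_ec50[1], x$ci_ec50[2],
                if (isTRUE(x$ci_unreliable)) "  [unreliable]" else ""))
  }
  invisible(x)
}

#' Effect concentration at an arbitrary response level
#'
#' For the two-parameter Hill curve, `ECx = ec50 * (x / (100 - x))^(1/h)`.
#' `ecx(fit, 50)` returns the EC50 exactly.
#'
#' @param fit a `hill_fit` (or any list with `ec50` and `hill_slope`).
#' @param x_percent response level in percent, strictly between 0 and 100.
#' @return concentration producing `x_percent` of the maximal response.
#' @export
ecx <- function(fit, x_percent) {
  check_number(x_percent, "x_percent", len = length(x_percent))
  if (any(x_percent <= 0 | x_percent >= 100)) {
    stop("'x_percent' must lie strictly between 0 and 100", call. = FALSE)
  }
  fit$ec50 * (x_percent / (100 - x_percent))^(1 / fit$hill_slope)
}

#' Abbott's correction for control mortality
#'
#' Rescales treatment responses by the control response,
#' `p' = (p - p0) / (1 - p0)`, clipped at 0. Off by default in the fitting
#' workflow; apply explicitly when control mortality is non-negligible. The
#' corrected immobile counts (`p' * n_exposed`) are generally non-integer;
#' the binomial likelihood accepts them as expected counts.
#'
#' @param data a [dose_response_data()] object with control rows
#'   (concentration 0).
#' @return corrected `dr_data` (controls set to 0 response).
#' @export
abbott_correct <- function(data) {
  ctrl <- data$concentration == 0
  if (!any(ctrl)) stop("control group (concentration 0) required", call. = FALSE)
  p0 <- sum(data$n_immobile[ctrl]) / sum(data$n_exposed[ctrl])
  if (p0 >= 1) stop("control mortality is 100%; correction undefined",
                    call. = FALSE)
  p <- data$n_immobile / data$n_exposed
  pc <- pmax((p - p0) / (1 - p0), 0)
  out <- dose_response_data(data$concentration, data$n_exposed,
                            pc * data$n_exposed,
                            replicate = data$replicate,
                            units = attr(data, "units") %||% "mg/L")
  attr(out, "control_mortality_precorrection") <- p0
  if (p0 > 0.05) {
    warning(sprintf("control mortality %.1f%% exceeds the 5%% QC limit",
                    100 * p0), call. = FALSE)
  }
  out
}

#' Bootstrap percentile confidence interval for the EC50
#'
#' Nonparametric bootstrap over replicate rows, stratified by
#' concentration: within each concentration the replicate rows are resampled
#' with replacement, the Hill model refitted, and the percentile interval of
#' the EC50 taken. Reproducible from the seed. If more than 20% of
#' resamples fail to fit, the interval is flagged unreliable.
#'
#' @param data a [dose_response_data()] object.
#' @param B number of bootstrap resamples.
#' @param seed explicit integer seed.
#' @param level confidence level (default 0.95).
#' @param method passed to [fit_hill()].
#' @return the `hill_fit` for `data` with `ci_ec50`, `ci_level`,
#'   `ci_unreliable` and `boot_ec50` added.
#' @export
bootstrap_ci <- function(data, B = 1000, seed = 1, level = 0.95,
                         method = "binomial") {
  fit <- fit_hill(data, method = method)
  groups <- split(seq_len(nrow(data)), data$concentration)
  boots <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      d <- data[idx, , drop = FALSE]
      f <- tryCatch(fit_hill(d, method = method), error = function(e) NULL)
      if (is.null(f) || !f$converged) NA_real_ else f$ec50
    }, 1)
  })
  fail <- mean(is.na(boots))
  ok <- boots[!is.na(boots)]
  alpha <- (1 - level) / 2
  fit$ci_ec50 <- if (length(ok) >= 2) {
    unname(quantile(ok, c(alpha, 1 - alpha)))
  } else c(NA_real_, NA_real_)
  fit$ci_level <- level
  fit$ci_unreliable <- fail > 0.2
  if (fit$ci_unreliable) {
    warning(sprintf("%.0f%% of bootstrap resamples failed to fit; interval unreliable",
                    100 * fail), call. = FALSE)
  }
  fit$boot_ec50 <- boots
  fit
}

#' Correlate paired assay formats
#'
#' Pearson linear correlation of paired response values (e.g. chip-based vs
#' static plate immobilization fractions at matched concentrations), with
#' the least-squares line.
#'
#' @param points_a,points_b paired numeric vectors (>= 3 complete pairs).
#' @return list with `r`, `r_squared`, `slope`, `intercept`, `p_value`,
#'   `n`.
#' @export
compare_methods <- function(points_a, points_b) {
  if (length(points_a) != length(points_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(points_a) & is.finite(points_b)
  a <- points_a[ok]; b <- points_b[ok]
  if (length(a) < 3) stop("at least 3 complete pairs are required", call. = FALSE)
  ct <- cor.test(a, b, method = "pearson")
  fit <- lm(b ~ a)
  list(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = ct$p.value,
    n = length(a)
  )
}

#' ANOVA and per-concentration t-tests for behavioral endpoints
#'
#' For each timepoint: a one-way ANOVA of the metric across concentration
#' groups, and independent two-sample Student t-tests of every concentration
#' against the concurrent control (concentration 0). Raw p-values are
#' reported; Holm adjustment of the t-tests is available but off by default
#' (per-comparison testing is the convention this assay follows).
#'
#' @param endpoints data frame with columns `concentration`, `time_h`, and
#'   the metric; >= 2 replicate chambers per group are required.
#' @param metric metric column name.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return list with `anova` (data frame: `time_h`, `p_value`) and
#'   `t_tests` (data frame: `time_h`, `concentration`, `estimate_diff`,
#'   `p_value`, `p_adjusted`).
#' @export
behavioural_stats <- function(endpoints, metric = "total_distance_mm",
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("concentration", "time_h", metric) %in% names(endpoints)))
  if ("valid" %in% names(endpoints)) endpoints <- endpoints[endpoints$valid, ]
  counts <- table(endpoints$concentration, endpoints$time_h)
  if (any(counts[counts > 0] < 2)) {
    stop("at least 2 replicate chambers per group and timepoint are required",
         call. = FALSE)
  }
  anova_rows <- list()
  t_rows <- list()
  for (tt in sort(unique(endpoints$time_h))) {
    sub <- endpoints[endpoints$time_h == tt, , drop = FALSE]
    y <- sub[[metric]]
    g <- factor(sub$concentration)
    p_aov <- if (nlevels(g) > 1) {
      anova(aov(y ~ g))[["Pr(>F)"]][1]
    } else NA_real_
    anova_rows[[length(anova_rows) + 1L]] <-
      data.frame(time_h = tt, p_value = p_aov)
    ctrl <- y[sub$concentration == 0]
    for (cc in setdiff(sort(unique(sub$concentration)), 0)) {
      tv <- y[sub$concentration == cc]
      tst <- t.test(tv, ctrl, var.equal = TRUE)
      t_rows[[length(t_rows) + 1L]] <- data.frame(
        time_h = tt, concentration = cc,
        estimate_diff = mean(tv) - mean(ctrl), p_value = tst$p.value)
    }
  }
  tt_df <- do.call(rbind, t_rows)
  if (!is.null(tt_df)) {
    tt_df$p_adjusted <- if (adjust == "holm") {
      stats::p.adjust(tt_df$p_value, method = "holm")
    } else tt_df$p_value
  }
  list(anova = do.call(rbind, anova_rows), t_tests = tt_df)
}

#' Dose-response plot
#'
#' Observed immobilization fractions with the fitted Hill curve on a log
#' concentration axis.
#'
#' @param x a `hill_fit`.
#' @param data the [dose_response_data()] the fit came from.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hill_fit <- function(x, data = NULL, ...) {
  if (!is.null(data)) {
    pos <- data[data$concentration > 0, , drop = FALSE]
    graphics::plot(pos$concentration, pos$n_immobile / pos$n_exposed,
                   log = "x", xlab = sprintf("concentration (%s)", x$units),
                   ylab = "fraction immobile", ylim = c(0, 1), ...)
    cc <- exp(seq(log(min(pos$concentration)), log(max(pos$concentration)),
                  length.out = 200))
  } else {
    cc <- x$ec50 * 10^seq(-2, 2, length.out = 200)
    graphics::plot(NA, xlim = range(cc), ylim = c(0, 1), log = "x",
                   xlab = sprintf("concentration (%s)", x$units),
                   ylab = "fraction immobile", ...)
  }
  graphics::lines(cc, hill_probability(cc, x$ec50, x$hill_slope), col = 2)
  graphics::abline(v = x$ec50, lty = 2, col = "grey50")
  invisible(x)
}
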