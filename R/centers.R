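# Hotspot-center estimation from cumulative recombination-frequency curves.

#' Cumulative frequency curve of recombination events
#'
#' Builds the cumulative frequency of event positions along the hotspot:
#' crossovers are represented by their breakpoint-interval midpoints
#' (intervals, not points, are observed), non-crossovers by the midpoint of
#' their converted-marker span. Each reciprocal contributes its own empirical
#' distribution and the two are averaged with equal weight, so unequal
#' collection depths do not tilt the curve.
#'
#' @param events Event tibble from [call_events()], or a bare numeric vector
#'   of event positions.
#' @param assay Which assay to curve when `events` is a tibble.
#' @param normalize_reciprocals Average reciprocal-specific curves with equal
#'   weight (default) instead of pooling raw counts.
#' @return A tibble `position`, `cum_freq` (non-decreasing, reaching 1),
#'   with attributes `n_events` and `assay`.
#' @examples
#' cumulative_curve(rnorm(100, 500, 50))
#' @export
cumulative_curve <- function(events, assay = c("CO", "NCO"),
                             normalize_reciprocals = TRUE) {
  if (is.numeric(events)) {
    pos <- sort(events)
    grp <- rep("all", length(pos))
    n_events <- length(pos)
  } else {
    assay <- match.arg(assay)
    ev <- filter(events, .data$scorable, .data$assay == !!assay)
    if (assay == "CO") {
      ev <- filter(ev, .data$event_class %in% c("CO", "CCO"))
      pos <- (ev$bp_lo + ev$bp_hi) / 2
    } else {
      pos <- map_dbl(ev$converted, function(p) (min(p) + max(p)) / 2)
    }
    grp <- if (normalize_reciprocals) ev$reciprocal else rep("all", nrow(ev))
    n_events <- length(pos)
  }
  grid <- sort(unique(pos))
  if (length(grid) < 3) {
    abort("need at least 3 distinct event positions to build a curve")
  }
  by_grp <- split(pos, grp)
  cum <- rowMeans(vapply(by_grp, function(p) {
    vapply(grid, function(x) mean(p <= x), numeric(1))
  }, numeric(length(grid))))
  out <- tibble(position = grid, cum_freq = cum)
  attr(out, "n_events") <- n_events
  attr(out, "assay") <- if (is.numeric(events)) NA_character_ else assay
  out
}

center_fit_obj <- function(model, center, se, width, width_se, coefficients,
                           vcov, rss, n, data, converged = TRUE) {
  structure(
    list(model = model, center = center, se = se, width = width,
         width_se = width_se, coefficients = coefficients, vcov = vcov,
         rss = rss, n = n, data = data, converged = converged),
    class = "center_fit"
  )
}

# starting values from the curve quantiles: centre at the median crossing,
# width from the interquartile span of a Normal
curve_starts <- function(x, y) {
  q <- function(p) x[which.min(abs(y - p))]
  mu0 <- q(0.5)
  sigma0 <- (q(0.75) - q(0.25)) / 1.349
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(x)) / 4
  c(mu0 = mu0, sigma0 = sigma0)
}

fit_center_normal <- function(curve) {
  x <- curve$position
  y <- curve$cum_freq
  n <- attr(curve, "n_events") %||% length(x)
  counts <- n * diff(c(0, y, 1))
  st <- curve_starts(x, y)
  # centre and scale positions so BFGS sees O(1) parameters
  shift <- st[["mu0"]]
  scale <- max(st[["sigma0"]], 1)
  xc <- (x - shift) / scale

  nll <- function(par) {
    p <- diff(c(0, pnorm(xc, par[1], exp(par[2])), 1))
    -sum(counts * log(pmax(p, 1e-300)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14, maxit = 1000))
  if (opt$convergence != 0) {
    stopf("normal-CDF centre fit did not converge (code %d, start mu=%.1f sigma=%.1f, span %.0f-%.0f)",
          opt$convergence, st[["mu0"]], st[["sigma0"]], min(x), max(x))
  }
  mu <- shift + scale * opt$par[1]
  sigma <- scale * exp(opt$par[2])
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  se_mu <- sqrt(vc[1, 1]) * scale
  se_sigma <- sqrt(vc[2, 2]) * sigma # delta method from log scale
  rss <- sum((y - pnorm(x, mu, sigma))^2)
  center_fit_obj("normal_cdf", mu, se_mu, sigma, se_sigma,
                 c(mu = mu, sigma = sigma), vc, rss, n, curve)
}

fit_center_logistic <- function(curve) {
  x <- curve$position
  y <- curve$cum_freq
  n <- attr(curve, "n_events") %||% length(x)
  df <- data.frame(position = x, cum_freq = y)
  fit <- tryCatch(
    nls(cum_freq ~ SSlogis(position, Asym, xmid, scal), data = df),
    error = function(e) {
      stopf("logistic centre fit did not converge over span %.0f-%.0f: %s",
            min(x), max(x), conditionMessage(e))
    }
  )
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  center_fit_obj("logistic3", cf[["xmid"]], se[["xmid"]], cf[["scal"]],
                 se[["scal"]], cf, vcov(fit), sum(residuals(fit)^2), n, curve)
}

#' Fit a hotspot centre to a cumulative curve
#'
#' Estimates the hotspot centre as the inflection point of the cumulative
#' event-frequency curve. Crossover curves are fitted with a Normal CDF;
#' non-crossover curves with the 3-parameter logistic
#' \eqn{a / (1 + e^{-(x - x_0)/s})}. The Normal fit maximises the grouped
#' multinomial likelihood of the curve increments, so the reported standard
#' error reflects the true sampling variability of the centre; least squares
#' on the cumulative curve itself would understate it because cumulative
#' residuals are serially correlated.
#'
#' @param curve Output of [cumulative_curve()].
#' @param model `"normal_cdf"` or `"logistic3"`.
#' @return An object of class `center_fit` with elements `center`, `se`,
#'   `width` (Normal sd or logistic scale), `coefficients`, `vcov`, `rss`
#'   and the input curve; supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' set.seed(1)
#' fit <- fit_center(cumulative_curve(rnorm(500, 6360770, 400)))
#' glance(fit)
#' @export
fit_center <- function(curve, model = c("normal_cdf", "logistic3")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(curve),
            all(c("position", "cum_freq") %in% names(curve)))
  if (is.unsorted(curve$cum_freq)) {
    abort("cum_freq must be non-decreasing")
  }
  fit <- switch(model,
                normal_cdf = fit_center_normal(curve),
                logistic3 = fit_center_logistic(curve))
  span <- range(curve$position)
  if (fit$center < span[1] || fit$center > span[2]) {
    warn(sprintf("fitted centre %.0f lies outside the data span %.0f-%.0f",
                 fit$center, span[1], span[2]))
  }
  fit
}

#' @export
print.center_fit <- function(x, ...) {
  cat("<center_fit> ", x$model, ": centre ", round(x$center, 1), " +/- ",
      signif(x$se, 3), " bp (width ", round(x$width, 1), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.center_fit <- function(x, ...) {
  se <- if (x$model == "normal_cdf") {
    c(mu = x$se, sigma = x$width_se)
  } else {
    sqrt(diag(x$vcov))
  }
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se[names(x$coefficients)] %||% se)
  )
}

#' @export
glance.center_fit <- function(x, ...) {
  tibble(model = x$model, center = x$center, se = x$se, width = x$width,
         rss = x$rss, n_events = x$n, converged = x$converged)
}

#' @export
autoplot.center_fit <- function(object, ...) {
  curve <- object$data
  pred <- if (object$model == "normal_cdf") {
    pnorm(curve$position, object$center, object$width)
  } else {
    object$coefficients[["Asym"]] /
      (1 + exp((object$center - curve$position) / object$width))
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_freq), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = pred), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$center, linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = "cumulative frequency",
                  title = sprintf("%s centre: %.0f +/- %.1f bp",
                                  object$model, object$center, object$se)) +
    ggplot2::theme_minimal()
}
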