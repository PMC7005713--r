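# First-order phospho-decay kinetics: semilog ordinary least squares on
# ln(signal) vs time, half-life = ln 2 / k. This is the estimator used for
# phospho-His stability time courses quantified from gels.

#' Normalize a time course so the t = 0 signal is 100
#'
#' @param tc Tibble with `time` (minutes) and `signal` (> 0 at t = 0)
#'   columns; other columns pass through.
#' @return The tibble with `signal` rescaled to signal(0) = 100.
#' @export
normalize_t0 <- function(tc) {
  stopifnot(all(c("time", "signal") %in% names(tc)))
  i0 <- which(tc$time == 0)
  if (length(i0) != 1) stop("time course must contain exactly one t = 0 point")
  if (!is.finite(tc$signal[i0]) || tc$signal[i0] <= 0) {
    stop("signal at t = 0 must be positive")
  }
  tc$signal <- tc$signal * 100 / tc$signal[i0]
  tc
}

#' Fit first-order decay by semilog least squares
#'
#' Ordinary least squares of ln(signal) on time; the decay rate is k =
#' -slope (per minute) and the half-life is ln 2 / k. A slope that is
#' nonnegative or within tolerance of zero gives an infinite half-life,
#' reported as exceeding the observation window (no decay measurable).
#' Points with nonpositive signal (a gel can read zero) are dropped with a
#' warning; at least `min_points` must survive.
#'
#' A nonlinear least-squares mode (`method = "nls"`, direct fit of
#' A * exp(-k t) via [stats::nls()]) exists for comparison; the semilog fit
#' is the canonical path.
#'
#' @param tc Tibble with `time` and `signal` columns (optionally
#'   `condition`).
#' @param method `"semilog"` (default) or `"nls"`.
#' @param min_points Minimum usable points (default 3).
#' @param k_tol Rates below this are treated as zero (default 1e-10 /min).
#' @return Object of class `decay_fit`: list with `k` (/min), `half_life`
#'   (min; `Inf` when no decay is measurable), `intercept` (log-units),
#'   `r_squared`, `n_points`, `window` (largest observed time, min),
#'   `condition`, `method`.
#' @export
fit_decay <- function(tc, method = c("semilog", "nls"), min_points = 3,
                      k_tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(all(c("time", "signal") %in% names(tc)))
  bad <- !is.finite(tc$signal) | tc$signal <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " point(s) with nonpositive signal")
    tc <- tc[!bad, , drop = FALSE]
  }
  if (nrow(tc) < min_points) {
    stop("need at least ", min_points, " usable points, have ", nrow(tc))
  }
  condition <- if ("condition" %in% names(tc)) tc$condition[1] else NA_character_
  if (method == "semilog") {
    fit <- stats::lm(log(signal) ~ time, data = tc)
    slope <- stats::coef(fit)[["time"]]
    intercept <- stats::coef(fit)[["(Intercept)"]]
    # summary() warns on zero-residual fits; that is a legitimate input here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (!is.finite(r2)) r2 <- NA_real_ # constant signal: zero total variance
    k <- max(-slope, 0)
  } else {
    # start from the semilog estimate; scaleOffset keeps convergence sane
    # on (near-)zero-residual courses
    pre <- stats::coef(stats::lm(log(signal) ~ time, data = tc))
    start <- list(A = exp(pre[[1]]), k = max(-pre[[2]], 1e-6))
    fit <- stats::nls(signal ~ A * exp(-k * time), data = tc, start = start,
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    k <- max(stats::coef(fit)[["k"]], 0)
    intercept <- log(stats::coef(fit)[["A"]])
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((tc$signal - mean(tc$signal))^2)
  }
  structure(
    list(
      k = k,
      half_life = if (k <= k_tol) Inf else log(2) / k,
      intercept = intercept,
      r_squared = r2,
      n_points = nrow(tc),
      window = max(tc$time),
      condition = condition,
      method = method
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  hl <- if (is.finite(x$half_life)) sprintf("%.3g min", x$half_life)
        else sprintf("exceeds observation window (%g min)", x$window)
  cat(sprintf("First-order decay fit (%s, n = %d): k = %.4g /min, t1/2 = %s\n",
              x$method, x$n_points, x$k, hl))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "half_life", "intercept"),
    estimate = c(x$k, x$half_life, x$intercept)
  )
}

#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    condition = x$condition, k = x$k, half_life = x$half_life,
    r_squared = x$r_squared, n_points = x$n_points, window = x$window,
    method = x$method
  )
}

#' Fit decay curves for every group of a long time-course table
#'
#' @param data Tibble with `time`, `signal` and grouping columns.
#' @param ... Unquoted grouping columns (e.g. `condition, replicate`).
#' @param method Passed to [fit_decay()].
#' @return Tibble with one row per group: grouping columns plus `k`,
#'   `half_life`, `r_squared`, `n_points`.
#' @export
fit_decay_by <- function(data, ..., method = "semilog") {
  data |>
    dplyr::group_by(...) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_decay(d, method = method)
      tibble::tibble(k = f$k, half_life = f$half_life,
                     r_squared = f$r_squared, n_points = f$n_points)
    }) |>
    dplyr::ungroup()
}

#' Compare fitted half-lives across conditions
#'
#' @param fits A list of `decay_fit` objects, or a tibble with `half_life`
#'   (and optionally `condition`) columns.
#' @param reference Index or condition label of the reference fit
#'   (default: first).
#' @return Tibble: `condition`, `half_life`, `ratio_vs_reference` and a
#'   `note` column (`"no measurable decay"` for infinite half-lives;
#'   `"reference stable"` for ratios against an infinite reference).
#' @export
compare_conditions <- function(fits, reference = 1) {
  tab <- if (is.data.frame(fits)) {
    if (!"condition" %in% names(fits)) {
      fits$condition <- sprintf("condition %d", seq_len(nrow(fits)))
    }
    fits[, c("condition", "half_life")]
  } else {
    purrr::map_dfr(fits, ~ tibble::tibble(condition = .x$condition,
                                          half_life = .x$half_life))
  }
  if (nrow(tab) < 2) stop("need at least 2 fits to compare")
  ref_i <- if (is.character(reference)) match(reference, tab$condition)
           else as.integer(reference)
  if (is.na(ref_i) || ref_i < 1 || ref_i > nrow(tab)) {
    stop("reference not found")
  }
  ref_hl <- tab$half_life[ref_i]
  tab |>
    dplyr::mutate(
      ratio_vs_reference = .data$half_life / ref_hl,
      note = dplyr::case_when(
        !is.finite(.data$half_life) ~ "no measurable decay",
        !is.finite(ref_hl) ~ "reference stable",
        TRUE ~ ""
      )
    )
}

#' Semilog plot of a time course with its fitted decay line
#'
#' @param object A `decay_fit`.
#' @param tc The time course that was fitted (tibble with `time`, `signal`).
#' @param ... Unused.
#' @return A ggplot (log10 signal axis).
#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, tc, ...) {
  stopifnot(all(c("time", "signal") %in% names(tc)))
  grid <- tibble::tibble(time = seq(0, max(tc$time), length.out = 100))
  grid$signal <- exp(object$intercept - object$k * grid$time)
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "signal (% of t = 0)",
                  title = object$condition) +
    ggplot2::theme_minimal()
}
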