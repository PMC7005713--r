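# Exact 2x2 association testing between crystallization-pH bin and rotamer
# class. The two-sided exact test is implemented here from log-factorials
# (summing hypergeometric probabilities of all tables with the observed
# margins that are no more probable than the observed table).

#' Two-sided exact test for a 2x2 contingency table
#'
#' Computed from first principles: with the margins fixed, the probability
#' of each admissible table is hypergeometric,
#' P(a) = C(r1, a) C(r2, c1 - a) / C(n, c1), evaluated via log-factorials;
#' the two-sided p-value is the sum of P over all tables with
#' P <= P(observed) (with a small relative tolerance for ties). A zero row
#' or column margin yields p = 1 with the `degenerate` flag set.
#'
#' @param table 2x2 matrix (or something coercible) of nonnegative integer
#'   counts; rows are groups, columns outcomes.
#' @return Object of class `exact_2x2`: list with `p_value`, `odds_ratio`
#'   (sample odds ratio; `Inf`/0 sentinels on zero cells), `table`,
#'   `degenerate`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value # ~0.00794
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m))) {
    stop("cells must be nonnegative integers")
  }
  m <- round(m)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  n <- sum(m)
  or <- odds_ratio_2x2(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(structure(list(p_value = 1, odds_ratio = or, table = m,
                          degenerate = TRUE), class = "exact_2x2"))
  }
  lp <- function(a) {
    # log P(a) from log-factorials
    lfact <- function(k) lgamma(k + 1)
    (lfact(r1) - lfact(a) - lfact(r1 - a)) +
      (lfact(r2) - lfact(c1 - a) - lfact(r2 - (c1 - a))) -
      (lfact(n) - lfact(c1) - lfact(n - c1))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lp(support)
  obs <- lp(m[1, 1])
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  structure(list(p_value = min(p, 1), odds_ratio = or, table = m,
                 degenerate = FALSE), class = "exact_2x2")
}

odds_ratio_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
}

#' @export
print.exact_2x2 <- function(x, ...) {
  cat(sprintf("Exact 2x2 test: p = %.4g, odds ratio = %.3g%s\n",
              x$p_value, x$odds_ratio,
              if (x$degenerate) " [degenerate margin]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.exact_2x2 <- function(x, ...) {
  tibble::tibble(estimate = x$odds_ratio, p.value = x$p_value,
                 method = "two-sided exact 2x2 (hypergeometric)",
                 degenerate = x$degenerate)
}

#' Test association between crystallization pH and His rotamer
#'
#' Bins the survey's subunit calls at `threshold` (pH <= threshold vs
#' above; the default 6.5 is the upper edge of the proposed gating window),
#' crosses the bin with the rotamer class (gauche- vs trans), and applies
#' [fisher_exact_2x2()]. gauche+ calls and calls with missing pH are
#' excluded from the table but reported, never silently dropped.
#'
#' @param survey A `rotamer_survey` (or a call tibble with `rotamer`, `ph`
#'   and, for `unit = "structure"`, `pdb_id`).
#' @param threshold Threshold pH (default 6.5).
#' @param unit `"subunit"` (default; one table entry per call) or
#'   `"structure"` (majority label per structure; ties excluded).
#' @return Object of class `ph_association`: the exact-test result plus
#'   `threshold`, `unit`, the 2x2 `table` (rows: pH bins; columns: gauche-,
#'   trans) and an `excluded` tally.
#' @export
test_ph_association <- function(survey, threshold = 6.5,
                                unit = c("subunit", "structure")) {
  unit <- match.arg(unit)
  calls <- if (inherits(survey, "rotamer_survey")) survey$calls else survey
  if (nrow(calls) == 0) stop("no calls to test")
  excluded <- c(
    gauche_plus = sum(calls$rotamer == "gauche+"),
    missing_ph = sum(is.na(calls$ph) & calls$rotamer != "gauche+")
  )
  use <- calls[calls$rotamer %in% c("gauche-", "trans") & !is.na(calls$ph), ,
               drop = FALSE]
  if (unit == "structure") {
    use <- use |>
      dplyr::group_by(.data$pdb_id, .data$ph) |>
      dplyr::summarise(
        n_g = sum(.data$rotamer == "gauche-"),
        n_t = sum(.data$rotamer == "trans"), .groups = "drop"
      ) |>
      dplyr::filter(.data$n_g != .data$n_t) |>
      dplyr::mutate(rotamer = ifelse(.data$n_g > .data$n_t,
                                     "gauche-", "trans"))
    excluded <- c(excluded, tied_structures = NA_integer_)
  }
  if (nrow(use) == 0) stop("no usable calls (known pH, gauche-/trans)")
  bin <- factor(ifelse(use$ph <= threshold,
                       sprintf("pH<=%g", threshold),
                       sprintf("pH>%g", threshold)),
                levels = c(sprintf("pH<=%g", threshold),
                           sprintf("pH>%g", threshold)))
  rot <- factor(use$rotamer, levels = c("gauche-", "trans"))
  tab <- table(bin, rot)
  res <- fisher_exact_2x2(tab)
  structure(
    list(p_value = res$p_value, odds_ratio = res$odds_ratio,
         table = unclass(tab), degenerate = res$degenerate,
         threshold = threshold, unit = unit, excluded = excluded,
         n_used = nrow(use)),
    class = "ph_association"
  )
}

#' @export
print.ph_association <- function(x, ...) {
  cat(sprintf(
    "pH-rotamer association (%s level, threshold pH %g): p = %.4g%s\n",
    x$unit, x$threshold, x$p_value,
    if (x$degenerate) " [degenerate: all calls on one side]" else ""
  ))
  print(x$table)
  if (any(x$excluded > 0, na.rm = TRUE)) {
    cat("excluded calls:",
        paste(names(x$excluded), x$excluded, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ph_association <- function(x, ...) {
  tibble::tibble(
    threshold_ph = x$threshold, unit = x$unit,
    estimate = x$odds_ratio, p.value = x$p_value,
    n = x$n_used, degenerate = x$degenerate
  )
}

#' @exportS3Method generics::glance
glance.ph_association <- function(x, ...) tidy(x)

#' Sweep the pH threshold and report unadjusted exact p-values
#'
#' Exploratory only: p-values are not adjusted for the multiplicity of
#' thresholds, and neighbouring thresholds give strongly dependent tests.
#' The single pre-registered threshold of [test_ph_association()] is the
#' inferential result.
#'
#' @param survey As in [test_ph_association()].
#' @param thresholds Numeric vector of candidate thresholds.
#' @return Tibble: `threshold_ph`, `p.value` (unadjusted), `degenerate`.
#' @export
sweep_ph_thresholds <- function(survey, thresholds = seq(5, 8, by = 0.5)) {
  purrr::map_dfr(thresholds, function(th) {
    r <- test_ph_association(survey, threshold = th)
    tibble::tibble(threshold_ph = th, p.value = r$p_value,
                   degenerate = r$degenerate)
  })
}
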