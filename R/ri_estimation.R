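# SD of a standard normal truncated at +/- z.
.trunc_sd <- function(z) {
  mass <- 2 * stats::pnorm(z) - 1
  sqrt(1 - 2 * z * stats::dnorm(z) / mass)
}

# Self-consistent truncation correction factor for the iterative trimmer.
# At its fixed point the retained set is a Gaussian truncated at +/- trim_z
# times the *observed* (truncated) SD, i.e. at +/- trim_z * c in true-SD
# units where c solves c = .trunc_sd(trim_z * c). Dividing the converged
# sample SD by c recovers the untruncated SD. (For trim_z = 1.96,
# c ~= 0.684.)
.trim_consistency_factor <- function(trim_z) {
  c0 <- 1
  for (i in 1:200) {
    c1 <- .trunc_sd(trim_z * c0)
    if (abs(c1 - c0) < 1e-12) break
    c0 <- c1
  }
  c1
}

.new_ri <- function(lower, upper, ci_lower, ci_upper, n_used, n_input,
                    iterations, converged, mode_mean, mode_sd, mode,
                    trimmed_values = NULL) {
  structure(list(lower = lower, upper = upper, ci_lower = ci_lower,
                 ci_upper = ci_upper, n_used = n_used, n_input = n_input,
                 iterations = iterations, converged = converged,
                 mode_mean = mode_mean, mode_sd = mode_sd, mode = mode,
                 trimmed_values = trimmed_values),
            class = "ddm_ri")
}

#' Iterative Gaussian-mode reference interval estimator
#'
#' Approximates the central Gaussian mode of a value distribution by
#' iteratively trimming: starting from all values, each pass computes the
#' mean m and SD s of the current set and retains the values inside
#' `[m - trim_z * s, m + trim_z * s]`; passes repeat until the window
#' endpoints move less than `tol` (or nothing is removed, or `max_iter` is
#' reached). Because each pass trims an already-truncated set, the converged
#' sample SD underestimates the mode's true SD by the known factor c solving
#' `c = sd(TN(trim_z * c))`, where `sd(TN(a))` is the SD of a standard normal
#' truncated at `+/- a`; the converged SD is divided by this factor. The 95%
#' reference limits are `m +/- qnorm(0.975) * sd_corrected`. Extreme values
#' from contaminating subpopulations are excluded progressively, making the
#' estimator robust to moderate one-sided contamination.
#'
#' @param values Numeric vector, at least `min_n` values.
#' @param trim_z Trimming half-width in (current-pass) SD units.
#' @param tol Convergence tolerance on both window endpoints, in analyte
#'   units.
#' @param max_iter Maximum trimming passes.
#' @param min_n Hard floor on the input size (default 120, the classical
#'   direct-method minimum).
#' @param warn_n Emit a reliability warning below this size (default 5000,
#'   the recommended minimum per mixed patient stratum).
#' @return A `ddm_ri` object (no confidence intervals; see
#'   [ri_for_distribution()]). `mode_mean`/`mode_sd` are the converged,
#'   truncation-corrected Gaussian parameters.
#' @export
iterative_gaussian_ri <- function(values, trim_z = 1.96, tol = 1e-4,
                                  max_iter = 50L, min_n = 120L,
                                  warn_n = 5000L) {
  stopifnot(tol > 0, trim_z > 0, max_iter >= 1)
  values <- values[!is.na(values)]
  n_input <- length(values)
  if (n_input < min_n) {
    stop("insufficient sample: ", n_input, " values (minimum ", min_n, ")")
  }
  if (stats::sd(values) == 0) stop("degenerate distribution: zero variance")
  if (n_input < warn_n) {
    warning("fewer than ", warn_n, " values; reference limits may be ",
            "unreliable for a mixed patient stratum")
  }
  cur <- values
  lo_prev <- -Inf
  hi_prev <- Inf
  iterations <- 0L
  converged <- FALSE
  repeat {
    m <- mean(cur)
    s <- stats::sd(cur)
    if (is.na(s) || s == 0) stop("degenerate distribution: trimming ",
                                 "collapsed to zero variance")
    lo <- m - trim_z * s
    hi <- m + trim_z * s
    keep <- cur >= lo & cur <= hi
    iterations <- iterations + 1L
    if (all(keep)) {            # fixed point: nothing removed
      converged <- TRUE
      break
    }
    if (abs(lo - lo_prev) < tol && abs(hi - hi_prev) < tol) {
      cur <- cur[keep]
      converged <- TRUE
      break
    }
    cur <- cur[keep]
    if (iterations >= max_iter) break
    lo_prev <- lo
    hi_prev <- hi
  }
  m <- mean(cur)
  s_corr <- stats::sd(cur) / .trim_consistency_factor(trim_z)
  z95 <- stats::qnorm(0.975)
  .new_ri(lower = m - z95 * s_corr, upper = m + z95 * s_corr,
          ci_lower = NULL, ci_upper = NULL, n_used = length(cur),
          n_input = n_input, iterations = iterations, converged = converged,
          mode_mean = m, mode_sd = s_corr, mode = "parametric",
          trimmed_values = cur)
}

#' Distribution-free percentile estimate with order-statistic CI
#'
#' The point estimate is the empirical p-quantile with linear interpolation
#' between closest ranks (R's default, type 7). The confidence interval is
#' the binomial order-statistic method: ranks
#' `n*p -/+ z_(1+conf)/2 * sqrt(n*p*(1-p))`, rounded outward, mapped to order
#' statistics of the sample.
#'
#' @param values Numeric vector.
#' @param p Probability in (0, 1).
#' @param conf Confidence level (default 0.90).
#' @return List with `point`, `ci` (length-2 numeric), `rank_lo`, `rank_hi`.
#' @export
percentile_ci <- function(values, p, conf = 0.90) {
  stopifnot(p > 0, p < 1, conf >= 0, conf < 1)
  values <- values[!is.na(values)]
  n <- length(values)
  z <- stats::qnorm((1 + conf) / 2)
  half <- z * sqrt(n * p * (1 - p))
  rank_lo <- floor(n * p - half)
  rank_hi <- ceiling(n * p + half)
  if (rank_lo < 1 || rank_hi > n) {
    stop("sample too small for requested confidence")
  }
  s <- sort(values)
  list(point = unname(stats::quantile(values, probs = p, type = 7,
                                      names = FALSE)),
       ci = c(s[rank_lo], s[rank_hi]),
       rank_lo = rank_lo, rank_hi = rank_hi)
}

#' Reference interval with confidence limits for a value distribution
#'
#' `mode = "parametric"` runs [iterative_gaussian_ri()] and attaches 90%
#' confidence intervals to both reference limits from the normal-theory
#' standard error of an estimated quantile,
#' `se = sd_corrected * sqrt(1/n + z95^2 / (2 n))` with `n` the converged
#' sample size. `mode = "nonparametric"` estimates the 2.5th and 97.5th
#' percentiles of the supplied distribution directly via [percentile_ci()];
#' the iterative trimmer is still run so the Gaussian-mode metadata
#' (`mode_mean`, `mode_sd`, `iterations`, `converged`) is reported alongside.
#'
#' @param values Numeric vector of analyte values (a GD or a DD).
#' @param mode `"parametric"` (default) or `"nonparametric"`.
#' @param conf Confidence level of the limit CIs.
#' @inheritParams iterative_gaussian_ri
#' @return A `ddm_ri` with `lower`, `upper`, `ci_lower`, `ci_upper`,
#'   `n_used`, `n_input`, `iterations`, `converged`, `mode_mean`, `mode_sd`.
#' @export
ri_for_distribution <- function(values, mode = c("parametric",
                                                 "nonparametric"),
                                conf = 0.90, trim_z = 1.96, tol = 1e-4,
                                max_iter = 50L, min_n = 120L,
                                warn_n = 5000L) {
  mode <- match.arg(mode)
  base <- iterative_gaussian_ri(values, trim_z = trim_z, tol = tol,
                                max_iter = max_iter, min_n = min_n,
                                warn_n = warn_n)
  if (mode == "parametric") {
    z <- stats::qnorm((1 + conf) / 2)
    z95 <- stats::qnorm(0.975)
    se <- base$mode_sd * sqrt(1 / base$n_used + z95^2 / (2 * base$n_used))
    hw <- z * se
    base$ci_lower <- c(base$lower - hw, base$lower + hw)
    base$ci_upper <- c(base$upper - hw, base$upper + hw)
    base$trimmed_values <- NULL
    base
  } else {
    values <- values[!is.na(values)]
    lo <- percentile_ci(values, 0.025, conf)
    hi <- percentile_ci(values, 0.975, conf)
    .new_ri(lower = lo$point, upper = hi$point,
            ci_lower = lo$ci, ci_upper = hi$ci,
            n_used = length(values), n_input = length(values),
            iterations = base$iterations, converged = base$converged,
            mode_mean = base$mode_mean, mode_sd = base$mode_sd,
            mode = "nonparametric")
  }
}

#' @export
print.ddm_ri <- function(x, ...) {
  fmt <- function(v) format(v, digits = 4)
  cat(sprintf("<ddm_ri> [%s, %s] (%s)\n", fmt(x$lower), fmt(x$upper), x$mode))
  if (!is.null(x$ci_lower)) {
    cat(sprintf("  lower 90%% CI [%s, %s], upper 90%% CI [%s, %s]\n",
                fmt(x$ci_lower[1]), fmt(x$ci_lower[2]),
                fmt(x$ci_upper[1]), fmt(x$ci_upper[2])))
  }
  cat(sprintf("  mode N(%s, %s^2); n_used = %d / %d; %d iteration(s)%s\n",
              fmt(x$mode_mean), fmt(x$mode_sd), x$n_used, x$n_input,
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Compare DD reference limits against GD reference limits
#'
#' Per bound (lower, upper): verdict `adjusted` when the two 90% CIs are
#' disjoint (the DD offers a genuinely shifted estimate), `not_different`
#' when the DD point estimate falls inside the GD bound's CI, and `overlap`
#' otherwise (CIs overlap but the DD bound sits outside the GD CI — to be
#' further evaluated). `delta` is DD minus GD in analyte units.
#'
#' @param gd_ri,dd_ri `ddm_ri` objects with confidence intervals.
#' @return Data frame with columns `bound`, `delta`, `verdict`.
#' @export
compare_ris <- function(gd_ri, dd_ri) {
  if (is.null(gd_ri$ci_lower) || is.null(dd_ri$ci_lower)) {
    stop("both reference intervals need confidence intervals; ",
         "use ri_for_distribution()")
  }
  one <- function(gd_point, gd_ci, dd_point, dd_ci, bound) {
    disjoint <- dd_ci[2] < gd_ci[1] || dd_ci[1] > gd_ci[2]
    verdict <- if (disjoint) {
      "adjusted"
    } else if (dd_point >= gd_ci[1] && dd_point <= gd_ci[2]) {
      "not_different"
    } else {
      "overlap"
    }
    data.frame(bound = bound, delta = dd_point - gd_point, verdict = verdict,
               stringsAsFactors = FALSE)
  }
  rbind(one(gd_ri$lower, gd_ri$ci_lower, dd_ri$lower, dd_ri$ci_lower,
            "lower"),
        one(gd_ri$upper, gd_ri$ci_upper, dd_ri$upper, dd_ri$ci_upper,
            "upper"))
}
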