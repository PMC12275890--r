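#' Group a stratum's values by ICD-10 category code
#'
#' A result carrying k codes contributes its value to k groups; results with
#' no codes appear in no group but remain part of the Global Distribution.
#'
#' @param stratum A `ddm_stratum` from [stratify_results()].
#' @return Named list mapping code to numeric vector of values.
#' @export
group_by_code <- function(stratum) {
  idx <- .group_indices_by_code(stratum)
  lapply(idx, function(i) stratum$gd_values[i])
}

# Named list mapping code -> integer indices of results in the stratum.
.group_indices_by_code <- function(stratum) {
  m <- .code_matrix(stratum$results)
  if (!length(m) || !nrow(m)) return(stats::setNames(list(), character(0)))
  nz <- m != ""
  if (!any(nz)) return(stats::setNames(list(), character(0)))
  split(row(m)[nz], m[nz])
}

# Shapiro-Wilk normality screen. Samples above `max_n` values are screened on
# a fixed-seed subsample (the test is undefined for n > 5000); degenerate or
# tiny samples are reported as non-normal (normality untestable).
.normality_ok <- function(x, alpha = 0.05, max_n = 5000, seed = 1L) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(FALSE)
  if (n > max_n) x <- with_seed(seed, sample(x, max_n))
  if (stats::var(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Choose between Welch's t-test and the Mann-Whitney U test
#'
#' The parametric test is used only when both the code group and the
#' reference distribution pass a Shapiro-Wilk normality screen at
#' `normality_alpha`; otherwise (including degenerate zero-variance groups,
#' for which normality is untestable) the Mann-Whitney U test is selected.
#' Reference samples larger than 5000 values are screened on a fixed-seed
#' subsample, so the choice is deterministic for fixed inputs.
#'
#' @param group_values,gd_values Numeric vectors.
#' @param normality_alpha Significance level of the normality screen.
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
choose_test <- function(group_values, gd_values, normality_alpha = 0.05) {
  if (.normality_ok(group_values, normality_alpha) &&
      .normality_ok(gd_values, normality_alpha)) "t_test" else "mann_whitney"
}

# Two-sided Mann-Whitney U p-value. Exact by enumeration of all C(n, n1)
# group assignments (midranks, so ties are handled) when the combined sample
# has at most `exact_total` values; tie-corrected normal approximation
# otherwise.
.mann_whitney_p <- function(x, y, exact_total = 16) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_total) {
    cmb <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
  } else {
    nn <- n1 + n2
    ties <- rle(sort(r))$lengths
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(1, p)
}

# Welch two-sample p-value; degenerate inputs fall through per the rules in
# test_group().
.welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
    return(.mann_whitney_p(x, y))
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Two-sided significance test of a code group against a reference
#'
#' `t_test` is the unequal-variance (Welch) form. `mann_whitney` uses exact
#' enumeration over all rank assignments (midranks, so ties are handled
#' exactly) when the combined sample has at most 16 values, and the
#' tie-corrected normal approximation otherwise. If all values
#' in both samples are identical the p-value is 1; two constant samples with
#' different values (Welch undefined) fall back to the Mann-Whitney path.
#'
#' @param group_values,gd_values Numeric vectors.
#' @param test `"t_test"` or `"mann_whitney"`.
#' @return Two-sided p-value in \[0, 1\].
#' @export
test_group <- function(group_values, gd_values,
                       test = c("t_test", "mann_whitney")) {
  test <- match.arg(test)
  if (test == "t_test") .welch_p(group_values, gd_values)
  else .mann_whitney_p(group_values, gd_values)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the proportion of true nulls pi0 by the smoother method: the
#' natural cubic spline (df = 3) of `pi0(lambda) = mean(p > lambda) /
#' (1 - lambda)` over the lambda grid, evaluated at the largest lambda and
#' clamped to (0, 1]. The q-value of the i-th smallest p-value is
#' `min_{j >= i} pi0 * m * p_(j) / j`. With `pi0 = 1` the result equals
#' Benjamini-Hochberg adjusted p-values. With fewer than 20 p-values pi0
#' estimation is unstable and falls back to 1 with a warning.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Strictly increasing grid in \[0, 0.95).
#' @param pi0 Optional: force a pi0 value instead of estimating it.
#' @return List with `q_values` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.90, by = 0.05),
                           pi0 = NULL) {
  if (!length(p)) stop("at least one p-value is required")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.unsorted(lambda, strictly = TRUE) ||
      any(lambda < 0) || any(lambda >= 0.95)) {
    stop("lambda must be strictly increasing within [0, 0.95)")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20) {
      warning("fewer than 20 p-values: pi0 estimation unstable, using pi0 = 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      pi0 <- if (length(lambda) >= 4) {
        fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
        stats::predict(fit, x = max(lambda))$y
      } else {
        pi0_l[length(pi0_l)]
      }
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[ord] <- q
  list(q_values = out, pi0 = pi0)
}

# Shared table builder over arbitrary value-group index lists; used by both
# the per-code and the per-cluster paths so the k = N clustering case reduces
# to per-code behaviour by construction.
.diagnosis_table_core <- function(stratum, groups_idx, min_n, alpha,
                                  normality_alpha, compare_to_complement,
                                  use_p = FALSE, label_col = "code") {
  gd <- stratum$gd_values
  empty <- data.frame(label = character(0), n = integer(0), mean = numeric(0),
                      sd = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), test_used = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  names(empty)[1] <- label_col
  sizes <- lengths(groups_idx)
  groups_idx <- groups_idx[sizes >= min_n]
  mk <- function(tab, pi0) {
    attr(tab, "stratum") <- c(sex = stratum$sex, age_lo = stratum$age_lo,
                              age_hi = stratum$age_hi)
    attr(tab, "pi0") <- pi0
    attr(tab, "alpha") <- alpha
    attr(tab, "min_n") <- min_n
    attr(tab, "label_col") <- label_col
    class(tab) <- c("ddm_diag_table", "data.frame")
    tab
  }
  if (!length(groups_idx)) return(mk(empty, NA_real_))

  gd_normal <- if (!compare_to_complement) .normality_ok(gd, normality_alpha)
               else NA
  labs <- names(groups_idx)
  n <- integer(length(labs)); mu <- numeric(length(labs))
  s <- numeric(length(labs)); pv <- numeric(length(labs))
  tu <- character(length(labs))
  for (i in seq_along(labs)) {
    idx <- groups_idx[[i]]
    g <- gd[idx]
    ref <- if (compare_to_complement) gd[-idx] else gd
    ref_normal <- if (compare_to_complement) {
      .normality_ok(ref, normality_alpha)
    } else gd_normal
    tst <- if (.normality_ok(g, normality_alpha) && isTRUE(ref_normal)) {
      "t_test"
    } else "mann_whitney"
    n[i] <- length(g); mu[i] <- mean(g); s[i] <- stats::sd(g)
    pv[i] <- test_group(g, ref, tst); tu[i] <- tst
  }
  st <- storey_qvalues(pv)
  tab <- data.frame(label = labs, n = n, mean = mu, sd = s, p_value = pv,
                    q_value = st$q_values, test_used = tu,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- label_col
  tab$significant <- if (use_p) tab$p_value < alpha else tab$q_value < alpha
  tab <- tab[order(tab$q_value, tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  mk(tab, st$pi0)
}

#' Build the per-code diagnosis table of a stratum
#'
#' For every ICD-10 category code whose value group has at least `min_n`
#' results (default 6, i.e. strictly more than 5), tests the group against the
#' stratum's Global Distribution and records sample size, mean, standard
#' deviation, p-value, Storey-Tibshirani q-value, the test used, and a
#' significance flag at `alpha`. Groups below `min_n` do not appear in the
#' table; their results remain in the dataset. Rows are sorted by q-value,
#' then p-value.
#'
#' @param stratum A `ddm_stratum`.
#' @param min_n Minimum group size for testing.
#' @param alpha Significance level applied to the q-values (or to raw
#'   p-values when `use_p = TRUE`).
#' @param normality_alpha Level of the Shapiro-Wilk screen in [choose_test()].
#' @param compare_to_complement Test each group against GD minus the group
#'   instead of the full GD (sensitivity-analysis variant; the default keeps
#'   the group inside its reference, which is conservative).
#' @param use_p Flag rows on raw p-values instead of q-values.
#' @return A `ddm_diag_table` data frame with attributes `stratum`, `pi0`,
#'   `alpha`, `min_n`.
#' @export
build_diagnosis_table <- function(stratum, min_n = 6, alpha = 0.05,
                                  normality_alpha = 0.05,
                                  compare_to_complement = FALSE,
                                  use_p = FALSE) {
  .diagnosis_table_core(stratum, .group_indices_by_code(stratum), min_n,
                        alpha, normality_alpha, compare_to_complement,
                        use_p, label_col = "code")
}

#' @export
print.ddm_diag_table <- function(x, ...) {
  st <- attr(x, "stratum")
  cat(sprintf("<ddm_diag_table> %s %s-%s: %d tested groups, %d significant (alpha = %g, pi0 = %s)\n",
              st["sex"], st["age_lo"], st["age_hi"], nrow(x),
              sum(x$significant), attr(x, "alpha"),
              format(attr(x, "pi0"), digits = 3)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Construct the Differential Distribution of a stratum
#'
#' Removes from the Global Distribution every result associated with at least
#' one significant code (or cluster) of the diagnosis table — the any-code
#' rule. Uncoded results always survive.
#'
#' @param stratum A `ddm_stratum`.
#' @param table Diagnosis table from [build_diagnosis_table()] or
#'   [cluster_table_and_dd()].
#' @param alpha Optional: re-threshold the table's q-values at this level
#'   instead of using its `significant` column.
#' @return An object of class `ddm_dd` with fields `sex`, `age_lo`, `age_hi`,
#'   `removed_codes`, `dd_values`, `removed_count`, `removal_fraction`,
#'   `removed_index` (row indices into the stratum's results).
#' @export
differential_distribution <- function(stratum, table, alpha = NULL) {
  label_col <- attr(table, "label_col") %||% "code"
  sig <- if (is.null(alpha)) table$significant else table$q_value < alpha
  sig_labels <- table[[label_col]][sig]
  member_codes <- attr(table, "cluster_members")
  sig_codes <- if (is.null(member_codes)) {
    sig_labels
  } else {
    unique(unlist(member_codes[sig_labels], use.names = FALSE))
  }
  m <- .code_matrix(stratum$results)
  removed <- if (length(sig_codes) && length(m)) {
    rowSums(matrix(m %in% sig_codes, nrow = nrow(m))) > 0
  } else {
    rep(FALSE, length(stratum$gd_values))
  }
  n_gd <- length(stratum$gd_values)
  structure(list(
    sex = stratum$sex, age_lo = stratum$age_lo, age_hi = stratum$age_hi,
    removed_codes = sig_labels,
    dd_values = stratum$gd_values[!removed],
    removed_count = sum(removed),
    removal_fraction = if (n_gd) sum(removed) / n_gd else 0,
    removed_index = which(removed)
  ), class = "ddm_dd")
}

#' @export
print.ddm_dd <- function(x, ...) {
  cat(sprintf("<ddm_dd> %s %d-%d: removed %d / %d (%.1f%%) via %d group(s)\n",
              x$sex, x$age_lo, x$age_hi, x$removed_count,
              x$removed_count + length(x$dd_values),
              100 * x$removal_fraction, length(x$removed_codes)))
  invisible(x)
}

#' Manifest of removed results for auditability
#'
#' @param stratum A `ddm_stratum`.
#' @param dd A `ddm_dd` for that stratum.
#' @return Data frame with `case_id`, `value`, `codes` (semicolon-joined) and
#'   `triggering_codes` for every removed result.
#' @export
removed_manifest <- function(stratum, dd) {
  idx <- dd$removed_index
  m <- .code_matrix(stratum$results)[idx, , drop = FALSE]
  trig_set <- dd$removed_codes
  member_codes <- attr(dd, "cluster_members")
  if (!is.null(member_codes)) {
    trig_set <- unique(unlist(member_codes[trig_set], use.names = FALSE))
  }
  join_rows <- function(mat) {
    out <- do.call(paste, c(asplit(mat, 2), list(sep = ";")))
    out <- gsub(";{2,}", ";", out)
    gsub("^;|;$", "", out)
  }
  tm <- m
  tm[!tm %in% trig_set] <- ""
  data.frame(case_id = stratum$results$case_id[idx],
             value = stratum$results$value[idx],
             codes = if (length(idx)) join_rows(m) else character(0),
             triggering_codes = if (length(idx)) join_rows(tm)
                                else character(0),
             stringsAsFactors = FALSE)
}
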