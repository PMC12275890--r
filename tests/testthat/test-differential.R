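test_that("group_by_code applies the any-code membership rule", {
  st <- make_stratum(c(1, 2, 3),
                     codes = list(c("N18", "I10"), "N18", character(0)))
  g <- group_by_code(st)
  expect_setequal(names(g), c("N18", "I10"))
  expect_setequal(g$N18, c(1, 2))   # multi-coded result feeds both groups
  expect_equal(g$I10, 1)
  # uncoded result appears in no group but stays in the GD
  expect_equal(length(st$gd_values), 3)

  expect_length(group_by_code(make_stratum(rnorm(5))), 0)
  g1 <- group_by_code(make_stratum(1:10, codes = rep(list("E11"), 10)))
  expect_equal(lengths(g1), c(E11 = 10L))
})

test_that("choose_test prefers t-test for Gaussian pairs, Mann-Whitney otherwise", {
  set.seed(21)
  picks <- replicate(60, {
    choose_test(rnorm(5000), rnorm(5000))
  })
  # each Shapiro screen falsely rejects ~5% of the time; the pair passes
  # ~>= 90% of runs
  expect_gt(mean(picks == "t_test"), 0.8)

  expect_equal(choose_test(rep(4, 6), rnorm(100)), "mann_whitney")
  set.seed(22)
  bimodal <- c(rnorm(150, -3, 0.3), rnorm(150, 3, 0.3))
  expect_equal(choose_test(bimodal, rnorm(2000)), "mann_whitney")
})

test_that("test_group returns 1 for identical distributions and handles degenerate input", {
  x <- c(3.9, 4.0, 4.1, 4.2, 4.05, 3.95)
  expect_gte(test_group(x, x, "mann_whitney"), 0.999)
  expect_gte(test_group(x, x, "t_test"), 0.999)
  expect_equal(test_group(rep(4, 6), rep(4, 20), "t_test"), 1)
  # constant-but-different samples: Welch undefined, falls back to ranks
  p <- test_group(c(0, 0), c(1, 1), "t_test")
  expect_true(p >= 0 && p <= 1)
})

test_that("exact Mann-Whitney matches the closed-form separated case", {
  # all 20 assignments of {1..6} into groups of 3; only the two extreme
  # assignments are as extreme as the observed one: p = 2 * 1/20
  expect_equal(test_group(c(1, 2, 3), c(4, 5, 6), "mann_whitney"), 0.1)
})

test_that("exact Mann-Whitney equals the brute-force pair-counting oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- sample(1:5, n1, replace = TRUE)  # integers force ties
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(test_group(x, y, "mann_whitney"), mw_exact_oracle(x, y),
                 info = sprintf("rep %d (n1=%d n2=%d)", rep, n1, n2))
  }
})

test_that("storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  out <- storey_qvalues(c(0.01, 0.02, 0.03, 0.9), pi0 = 1)
  expect_equal(out$q_values, c(0.04, 0.04, 0.04, 0.9))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(5:60, 1))
    expect_equal(storey_qvalues(p, pi0 = 1)$q_values,
                 p.adjust(p, method = "BH"))
  }
})

test_that("storey pi0 is sensible on uniform nulls and clamped to (0, 1]", {
  set.seed(42)
  out <- storey_qvalues(runif(1000))
  expect_gte(out$pi0, 0.85)
  expect_lte(out$pi0, 1)
  # q-values are monotone in p
  ord <- order(runif(1000))
  set.seed(43)
  p <- runif(1000)
  q <- storey_qvalues(p)$q_values
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("storey falls back to pi0 = 1 with a warning for tiny inputs", {
  expect_warning(out <- storey_qvalues(c(1.0)), "pi0")
  expect_equal(out$q_values, 1)
  expect_equal(out$pi0, 1)
  expect_error(storey_qvalues(numeric(0)))
  expect_error(storey_qvalues(c(0.5), lambda = c(0.9, 0.1)))
})

test_that("diagnosis table excludes groups of five or fewer results", {
  set.seed(51)
  codes <- c(rep(list("A01"), 5), rep(list("B02"), 8),
             rep(list(character(0)), 200))
  st <- make_stratum(rnorm(213, 4, 0.35), codes = codes)
  tab <- suppressWarnings(build_diagnosis_table(st))
  expect_false("A01" %in% tab$code)  # n = 5: not tested
  expect_true("B02" %in% tab$code)   # n = 8 > 5: tested
  expect_equal(tab$n[tab$code == "B02"], 8L)
})

test_that("a strongly shifted code group is detected as significant", {
  set.seed(52)
  healthy <- rnorm(4500, 4.0, 0.35)
  renal <- rnorm(500, 4.4, 0.7)  # chronic-kidney-disease-like shift
  st <- make_stratum(c(healthy, renal),
                     codes = c(rep(list(character(0)), 4500),
                               rep(list("N18"), 500)))
  tab <- suppressWarnings(build_diagnosis_table(st))
  row <- tab[tab$code == "N18", ]
  expect_true(row$significant)
  expect_lt(row$q_value, 1e-10)
  expect_equal(row$mean, mean(renal))
  expect_equal(row$sd, sd(renal))
  # q-values are monotone when the table is ordered by p
  expect_true(all(diff(tab$q_value[order(tab$p_value)]) >= -1e-12))
})

test_that("an empty or uncoded stratum yields an empty table and DD = GD", {
  st <- make_stratum(rnorm(50, 4, 0.3))
  tab <- build_diagnosis_table(st)
  expect_equal(nrow(tab), 0)
  dd <- differential_distribution(st, tab)
  expect_equal(dd$dd_values, st$gd_values)
  expect_equal(dd$removal_fraction, 0)
})

test_that("the differential distribution removes by the any-code rule", {
  values <- 1:20
  codes <- c(list(c("A01", "B02")), rep(list("B02"), 3),
             rep(list(character(0)), 16))
  st <- make_stratum(values, codes = codes)
  tab <- suppressWarnings(build_diagnosis_table(st, min_n = 1))
  # force exactly A01 significant
  tab$significant <- tab$code == "A01"
  dd <- differential_distribution(st, tab)
  # the result coded [A01, B02] is removed because A01 is significant
  expect_equal(dd$removed_count, 1L)
  expect_equal(dd$removed_index, 1L)
  expect_equal(length(dd$dd_values), 19)
  expect_equal(dd$removal_fraction, 1 / 20)

  # counting fixture: 4 carriers of a significant code
  st2 <- make_stratum(values, codes = c(rep(list("C03"), 4),
                                        rep(list(character(0)), 16)))
  tab2 <- suppressWarnings(build_diagnosis_table(st2, min_n = 1))
  tab2$significant <- TRUE
  dd2 <- differential_distribution(st2, tab2)
  expect_equal(dd2$removed_count, 4L)
  expect_equal(length(dd2$dd_values), 16)
})

test_that("removal is monotone in alpha and consistent with the table", {
  set.seed(61)
  st <- make_null_stratum(n = 800, n_codes = 12, group_n = 30)
  tab <- suppressWarnings(build_diagnosis_table(st))
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  removed_sets <- lapply(alphas, function(a) {
    differential_distribution(st, tab, alpha = a)$removed_index
  })
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(removed_sets[[i]] %in% removed_sets[[i + 1]]))
  }
  # every removed result carries >= 1 significant code; survivors carry none
  dd <- differential_distribution(st, tab, alpha = 0.5)
  sig <- tab$code[tab$q_value < 0.5]
  carries <- vapply(result_codes(st$results),
                    function(cs) any(cs %in% sig), logical(1))
  expect_equal(which(carries), dd$removed_index)
})

test_that("removed-results manifest lists codes and triggers", {
  st <- make_stratum(1:10, codes = c(list(c("A01", "B02")),
                                     rep(list("B02"), 6),
                                     rep(list(character(0)), 3)))
  tab <- suppressWarnings(build_diagnosis_table(st, min_n = 6))
  tab$significant <- tab$code == "B02"
  dd <- differential_distribution(st, tab)
  man <- removed_manifest(st, dd)
  expect_equal(nrow(man), 7)
  expect_equal(man$codes[1], "A01;B02")
  expect_equal(man$triggering_codes[1], "B02")
})
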