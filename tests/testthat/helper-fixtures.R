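# Shared fixtures and independent oracles for the test suite.

# Build a ddm_stratum directly from values and a list of code vectors.
make_stratum <- function(values, codes = NULL, sex = "female",
                         age_lo = 20, age_hi = 29) {
  n <- length(values)
  if (is.null(codes)) codes <- rep(list(character(0)), n)
  stopifnot(length(codes) == n)
  df <- data.frame(value = values,
                   age = rep(age_lo, n),
                   sex = rep(sex, n),
                   case_id = sprintf("C%06d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (j in 1:5) {
    df[[paste0("code", j)]] <- vapply(codes, function(cs) {
      if (length(cs) >= j) cs[j] else ""
    }, character(1))
  }
  attr(df, "code_cols") <- paste0("code", 1:5)
  structure(list(sex = sex, age_lo = age_lo, age_hi = age_hi,
                 results = df, gd_values = df$value),
            class = "ddm_stratum")
}

# A full-null stratum: Gaussian values, each of n_codes codes attached to a
# random subset of group_n results (subsamples of one Gaussian).
make_null_stratum <- function(n = 2000, n_codes = 30, group_n = 40,
                              seed = 1, mean = 4, sd = 0.35) {
  set.seed(seed)
  values <- rnorm(n, mean, sd)
  codes <- rep(list(character(0)), n)
  labels <- sprintf("%s%02d", LETTERS[(seq_len(n_codes) - 1) %% 26 + 1],
                    seq_len(n_codes) %% 100)
  for (cd in labels) {
    idx <- sample.int(n, group_n)
    for (i in idx) {
      if (length(codes[[i]]) < 5) codes[[i]] <- c(codes[[i]], cd)
    }
  }
  make_stratum(values, codes)
}

# Independent exact Mann-Whitney oracle: enumerates every assignment of the
# combined sample into the two groups and counts exceeding/tied pairs
# directly (no rank sums), two-sided p = min(1, 2 * min(tails)).
mw_exact_oracle <- function(x, y) {
  comb <- c(x, y)
  n1 <- length(x)
  n <- length(comb)
  u_of <- function(idx1) {
    a <- comb[idx1]
    b <- comb[-idx1]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Adjusted Rand index between two labelings (via mclust when available).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(m) sum(choose(m, 2))
  idx <- comb2(tab)
  e <- comb2(rowSums(tab)) * comb2(colSums(tab)) / choose(sum(tab), 2)
  mx <- (comb2(rowSums(tab)) + comb2(colSums(tab))) / 2
  (idx - e) / (mx - e)
}

# Two-block co-occurrence corpus: codes within a block are co-coded on the
# same sentences, blocks never mix.
make_block_corpus <- function(n_per_block = 500, codes_per_block = 8,
                              seed = 1) {
  set.seed(seed)
  blocks <- list(sprintf("A%02d", seq_len(codes_per_block)),
                 sprintf("B%02d", seq_len(codes_per_block)))
  sentences <- lapply(seq_len(2 * n_per_block), function(i) {
    blk <- blocks[[(i - 1) %% 2 + 1]]
    sample(blk, sample(2:min(5, length(blk)), 1))
  })
  vocab <- table(unlist(sentences))
  structure(list(sentences = sentences,
                 vocabulary = setNames(as.integer(vocab), names(vocab))),
            class = "ddm_corpus")
}

# Small random mixed scenario for equivalence checks.
random_small_scenario <- function(seed) {
  set.seed(seed)
  n_comp <- sample(3:5, 1)
  comp <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
    disease_component(sprintf("%s%02d", LETTERS[k], k),
                      prevalence = runif(1, 0.03, 0.08),
                      shift = runif(1, 0.3, 1.0),
                      sd_scale = runif(1, 1.2, 2),
                      block = if (k <= 2) "b1" else NA)
  }))
  ddm_scenario(n_per_stratum = 1500, components = comp,
               background_codes = c("Z03", "M54"), background_rate = 0.08)
}

# Minimal reference-interval stub for verdict tests.
fake_ri <- function(lower, upper, ci_lower, ci_upper) {
  structure(list(lower = lower, upper = upper, ci_lower = ci_lower,
                 ci_upper = ci_upper, n_used = 1000L, n_input = 1000L,
                 iterations = 1L, converged = TRUE, mode_mean = NA,
                 mode_sd = NA, mode = "parametric"),
            class = "ddm_ri")
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
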