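#' Describe a diseased subpopulation for the synthetic generator
#'
#' @param code ICD-10 category code labelling the component.
#' @param prevalence Proportion of each stratum's results drawn from this
#'   component.
#' @param shift Mean offset from the stratum's healthy mean (analyte units).
#' @param sd_scale Multiplicative factor on the healthy SD.
#' @param block Optional comorbidity block label; codes sharing a block are
#'   co-assigned on the same result with the scenario's co-occurrence
#'   probability.
#' @return One-row data frame.
#' @export
disease_component <- function(code, prevalence, shift, sd_scale = 1,
                              block = NA_character_) {
  stopifnot(prevalence > 0, prevalence < 1, sd_scale > 0)
  data.frame(code = code, prevalence = prevalence, shift = shift,
             sd_scale = sd_scale, block = block, stringsAsFactors = FALSE)
}

#' Default disease components of the potassium-like scenario
#'
#' Eight components totalling 25% prevalence, with mean shifts of +0.40 to
#' +1.20 mmol/L and doubled SDs, patterned on the magnitudes seen in renal,
#' cardiovascular-metabolic and acute subpopulations of inpatient potassium
#' data (e.g. chronic kidney disease values centred ~0.4 mmol/L above the
#' healthy mean with roughly double the spread). Two comorbidity blocks
#' ("renal", "cardio") provide planted co-occurrence structure.
#'
#' @return Data frame of components.
#' @export
default_components <- function() {
  rbind(
    disease_component("N18", 0.06, 0.45, 2, "renal"),
    disease_component("N17", 0.03, 0.40, 2, "renal"),
    disease_component("E87", 0.04, 0.60, 2, "renal"),
    disease_component("I10", 0.05, 0.40, 2, "cardio"),
    disease_component("I50", 0.02, 0.50, 2, "cardio"),
    disease_component("E11", 0.02, 0.45, 2, "cardio"),
    disease_component("A41", 0.02, 1.20, 2, NA),
    disease_component("K35", 0.01, 0.80, 2, NA)
  )
}

#' Specify a synthetic mixed-population scenario
#'
#' Per stratum (sex x age band), a healthy Gaussian core plus the configured
#' disease components. Diseased results draw their value from
#' `N(healthy_mean + shift, (healthy_sd * sd_scale)^2)` and carry their
#' component's code; codes within a comorbidity block are co-assigned with
#' probability `cooccur_prob`. Healthy results carry each background (null)
#' code independently with probability `background_rate`. The remainder
#' `1 - sum(prevalence)` of results is healthy. Ground-truth healthy
#' reference limits are available in closed form as
#' `healthy_mean +/- qnorm(0.975) * healthy_sd`.
#'
#' @param n_per_stratum Results per stratum.
#' @param healthy_mean,healthy_sd Healthy Gaussian parameters; `healthy_sd`
#'   may be a vector with one entry per age band (recycled across sexes) to
#'   emulate variance rising with age.
#' @param components Data frame of [disease_component()] rows.
#' @param band_width,age_min,age_max Stratification grid (14 strata by
#'   default).
#' @param cooccur_prob Probability that each other code of the component's
#'   block is co-coded on the result.
#' @param background_codes Null codes attached to healthy results.
#' @param background_rate Per-code attachment probability.
#' @param max_codes Code slots per result (5, as in routine coding).
#' @param disease_dist `"gaussian"` (default) or `"lognormal"`: lognormal
#'   components are moment-matched to the same mean and SD, producing skewed
#'   disease groups that exercise the Mann-Whitney path.
#' @return Object of class `ddm_scenario`.
#' @export
ddm_scenario <- function(n_per_stratum = 20000,
                         healthy_mean = 4.0, healthy_sd = 0.35,
                         components = default_components(),
                         band_width = 10, age_min = 20, age_max = 89,
                         cooccur_prob = 0.5,
                         background_codes = c("Z03", "M54", "J06", "K21",
                                              "R51"),
                         background_rate = 0.05,
                         max_codes = 5,
                         disease_dist = c("gaussian", "lognormal")) {
  disease_dist <- match.arg(disease_dist)
  n_bands <- (age_max - age_min + 1) / band_width
  stopifnot(n_bands == round(n_bands))
  if (!is.null(components) && nrow(components)) {
    stopifnot(!anyDuplicated(components$code))
    if (sum(components$prevalence) > 1) {
      stop("configuration error: component prevalences exceed 1")
    }
    if (any(components$code %in% background_codes)) {
      stop("background codes must be disjoint from component codes")
    }
  }
  healthy_sd <- rep(healthy_sd, length.out = n_bands)
  structure(list(n_per_stratum = n_per_stratum, healthy_mean = healthy_mean,
                 healthy_sd = healthy_sd, components = components,
                 band_width = band_width, age_min = age_min,
                 age_max = age_max, cooccur_prob = cooccur_prob,
                 background_codes = background_codes,
                 background_rate = background_rate, max_codes = max_codes,
                 disease_dist = disease_dist),
            class = "ddm_scenario")
}

#' Zero-shift (null) variant of a scenario
#'
#' Same codes and prevalences, but every component has `shift = 0` and
#' `sd_scale = 1`: all code groups are random subsamples of the healthy
#' Gaussian, so nothing should be removed beyond the false discovery rate.
#'
#' @param ... Passed to [ddm_scenario()].
#' @return A `ddm_scenario`.
#' @export
null_scenario <- function(...) {
  sc <- ddm_scenario(...)
  if (!is.null(sc$components) && nrow(sc$components)) {
    sc$components$shift <- 0
    sc$components$sd_scale <- 1
  }
  sc
}

#' Generate synthetic laboratory results with ground truth
#'
#' Deterministic for a fixed seed. Values, ages (uniform within band), case
#' identifiers and code assignments are drawn per stratum as specified by the
#' scenario.
#'
#' @param scenario A [ddm_scenario()].
#' @param seed Integer seed.
#' @return Object of class `ddm_simulation`: list with `results` (flat data
#'   frame in the default [lab_dialect()]: `value`, `age`, `sex`, `case_id`,
#'   `code1`..`code5`) and `truth` (per-stratum healthy parameters and
#'   closed-form reference limits, per-code component parameters, seed).
#' @export
simulate_lab_data <- function(scenario = ddm_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "ddm_scenario"))
  with_seed(seed, {
    comp <- scenario$components
    n_comp <- if (is.null(comp)) 0L else nrow(comp)
    prev <- if (n_comp) comp$prevalence else numeric(0)
    p_healthy <- 1 - sum(prev)
    los <- seq(scenario$age_min, scenario$age_max, by = scenario$band_width)
    frames <- list()
    truth_strata <- list()
    z95 <- stats::qnorm(0.975)
    case_counter <- 0L
    for (sx in c("female", "male")) {
      for (b in seq_along(los)) {
        lo <- los[b]
        hi <- lo + scenario$band_width - 1
        n <- scenario$n_per_stratum
        mu <- scenario$healthy_mean
        sg <- scenario$healthy_sd[b]
        # component assignment: 0 = healthy, k = k-th component
        assign <- sample.int(n_comp + 1L, n, replace = TRUE,
                             prob = c(p_healthy, prev)) - 1L
        value <- numeric(n)
        healthy_idx <- which(assign == 0L)
        value[healthy_idx] <- stats::rnorm(length(healthy_idx), mu, sg)
        pair_rows <- integer(0)
        pair_codes <- character(0)
        for (k in seq_len(n_comp)) {
          idx <- which(assign == k)
          if (!length(idx)) next
          mk <- mu + comp$shift[k]
          sk <- sg * comp$sd_scale[k]
          value[idx] <- if (scenario$disease_dist == "gaussian") {
            stats::rnorm(length(idx), mk, sk)
          } else {
            # moment-matched lognormal
            s2 <- log(1 + (sk / mk)^2)
            stats::rlnorm(length(idx), log(mk) - s2 / 2, sqrt(s2))
          }
          pair_rows <- c(pair_rows, idx)
          pair_codes <- c(pair_codes, rep(comp$code[k], length(idx)))
          if (!is.na(comp$block[k])) {
            others <- comp$code[!is.na(comp$block) &
                                  comp$block == comp$block[k] &
                                  comp$code != comp$code[k]]
            for (oc in others) {
              add <- idx[stats::runif(length(idx)) < scenario$cooccur_prob]
              pair_rows <- c(pair_rows, add)
              pair_codes <- c(pair_codes, rep(oc, length(add)))
            }
          }
        }
        for (bc in scenario$background_codes) {
          add <- healthy_idx[stats::runif(length(healthy_idx)) <
                               scenario$background_rate]
          pair_rows <- c(pair_rows, add)
          pair_codes <- c(pair_codes, rep(bc, length(add)))
        }
        # flatten (row, code) pairs into code1..codeK columns
        cm <- matrix("", nrow = n, ncol = scenario$max_codes)
        if (length(pair_rows)) {
          o <- order(pair_rows)
          rs <- pair_rows[o]
          cs <- pair_codes[o]
          pos <- sequence(rle(rs)$lengths)
          keep <- pos <= scenario$max_codes
          cm[cbind(rs[keep], pos[keep])] <- cs[keep]
        }
        df <- data.frame(value = round(value, 3),
                         age = sample(lo:hi, n, replace = TRUE),
                         sex = sx,
                         case_id = sprintf("C%08d", case_counter + seq_len(n)),
                         stringsAsFactors = FALSE)
        case_counter <- case_counter + n
        for (j in seq_len(scenario$max_codes)) df[[paste0("code", j)]] <- cm[, j]
        frames[[length(frames) + 1L]] <- df
        truth_strata[[length(truth_strata) + 1L]] <-
          list(sex = sx, age_lo = lo, age_hi = hi, healthy_mean = mu,
               healthy_sd = sg, lower = mu - z95 * sg, upper = mu + z95 * sg)
      }
    }
    results <- do.call(rbind, frames)
    rownames(results) <- NULL
    structure(list(
      results = results,
      truth = list(strata = truth_strata,
                   components = comp,
                   background_codes = scenario$background_codes,
                   seed = as.integer(seed),
                   n_total = nrow(results))
    ), class = "ddm_simulation")
  })
}

#' @export
print.ddm_simulation <- function(x, ...) {
  cat(sprintf("<ddm_simulation> %d results, %d strata (seed %d)\n",
              nrow(x$results), length(x$truth$strata), x$truth$seed))
  invisible(x)
}

#' Write a simulation to disk as CSV + JSON truth manifest
#'
#' The results CSV is readable by [read_results()] with the default dialect;
#' the truth manifest carries the per-stratum closed-form quantiles, the
#' component parameters and the seed. Output is byte-identical across runs
#' with the same seed.
#'
#' @param sim A `ddm_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`results`, `truth`).
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "ddm_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  results_path <- file.path(dir, "results.csv")
  truth_path <- file.path(dir, "truth.json")
  write.csv(sim$results, results_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = results_path, truth = truth_path))
}
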