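#' Column mapping for delimited laboratory result tables
#'
#' Describes how the columns of a delimited text file map onto the fields the
#' pipeline needs: analyte value, patient age, sex, administrative case
#' identifier and up to five ICD-10 category code columns. Sex labels are
#' normalised through `sex_map` (matched case-insensitively after trimming);
#' labels that map to neither `"female"` nor `"male"` are later removed during
#' preprocessing with audit reason `unknown_sex`.
#'
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @param value_col,age_col,sex_col,case_col Column names.
#' @param code_cols Character vector of diagnosis-code column names.
#' @param time_col Optional timestamp column used to order results within an
#'   administrative case; when `NULL`, file order is used.
#' @param sex_map Named character vector mapping raw labels to
#'   `"female"`/`"male"`.
#' @return A list of class `ddm_dialect`.
#' @export
lab_dialect <- function(sep = ",",
                        value_col = "value",
                        age_col = "age",
                        sex_col = "sex",
                        case_col = "case_id",
                        code_cols = paste0("code", 1:5),
                        time_col = NULL,
                        sex_map = c(female = "female", male = "male",
                                    f = "female", m = "male", w = "female")) {
  structure(list(sep = sep, value_col = value_col, age_col = age_col,
                 sex_col = sex_col, case_col = case_col,
                 code_cols = code_cols, time_col = time_col,
                 sex_map = sex_map),
            class = "ddm_dialect")
}

#' Read a laboratory result table from delimited text
#'
#' Reads one row per test result. Rows whose value or age cell is non-empty
#' but not parseable as a number are not turned into results; they are
#' collected in a rejects report instead. No filtering beyond that happens at
#' read time — see [preprocess_results()].
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param dialect A [lab_dialect()] describing separators and column names.
#' @return A list with `results` (data frame with columns `value`, `age`,
#'   `sex`, `case_id`, `code1`..`codek`, optionally `time`) and `rejects`
#'   (data frame with `row` and `reason`).
#' @export
read_results <- function(path, dialect = lab_dialect()) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- read.csv(path, sep = dialect$sep, colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE)
  parse_result_frame(raw, dialect)
}

#' Parse an in-memory raw table using a dialect
#'
#' Workhorse behind [read_results()], exposed so that tables already in memory
#' (e.g. from [simulate_lab_data()]) can enter the pipeline without a round
#' trip through disk.
#'
#' @param raw Data frame of character (or mixed) columns.
#' @param dialect A [lab_dialect()].
#' @return Same structure as [read_results()].
#' @export
parse_result_frame <- function(raw, dialect = lab_dialect()) {
  needed <- c(dialect$value_col, dialect$age_col, dialect$sex_col,
              dialect$case_col, dialect$code_cols, dialect$time_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("configured column(s) not present in input: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  val_raw <- trimws(as.character(raw[[dialect$value_col]]))
  age_raw <- trimws(as.character(raw[[dialect$age_col]]))
  value <- suppressWarnings(as.numeric(val_raw))
  age <- suppressWarnings(as.numeric(age_raw))

  bad_value <- !is.na(val_raw) & val_raw != "" & is.na(value)
  bad_age <- !is.na(age_raw) & age_raw != "" & is.na(age)
  reject_idx <- which(bad_value | bad_age)
  rejects <- data.frame(
    row = reject_idx,
    reason = ifelse(bad_value[reject_idx], "unparseable_value",
                    "unparseable_age"),
    stringsAsFactors = FALSE
  )

  sex_raw <- tolower(trimws(as.character(raw[[dialect$sex_col]])))
  sex <- unname(dialect$sex_map[sex_raw])

  results <- data.frame(
    value = value,
    age = age,
    sex = sex,
    case_id = as.character(raw[[dialect$case_col]]),
    stringsAsFactors = FALSE
  )
  code_cols <- paste0("code", seq_along(dialect$code_cols))
  for (i in seq_along(dialect$code_cols)) {
    cc <- trimws(as.character(raw[[dialect$code_cols[i]]]))
    cc[is.na(cc)] <- ""
    results[[code_cols[i]]] <- cc
  }
  if (!is.null(dialect$time_col)) {
    results$time <- as.character(raw[[dialect$time_col]])
  }
  if (length(reject_idx)) results <- results[-reject_idx, , drop = FALSE]
  rownames(results) <- NULL
  cm <- .compact_codes(as.matrix(results[code_cols]))
  results[code_cols] <- cm
  attr(results, "code_cols") <- code_cols
  list(results = results, rejects = rejects)
}

#' Preprocess laboratory results before stratification
#'
#' Applies, in order: (1) de-duplication to the first result per
#' administrative case (file order, or `time` order when present, with a
#' stable tie-break on row order); (2) removal of results with unknown sex,
#' age outside `[age_min, age_max]`, missing value, or value outside the
#' analyte plausibility bounds (non-positive values are always implausible);
#' (3) cleaning of the diagnosis codes — codes not matching the ICD-10
#' category pattern (one uppercase letter + two digits) are dropped from the
#' record, duplicates within a record are collapsed. With
#' `strict_code_filter = TRUE` a record carrying any malformed code is removed
#' entirely instead (audit reason `invalid_codes`).
#'
#' Every removal is counted in an audit table whose counts sum exactly to
#' `nrow(input) - nrow(output)`. The operation is idempotent.
#'
#' @param results Result data frame from [read_results()]`$results`.
#' @param value_min,value_max Analyte plausibility bounds; defaults are for
#'   plasma potassium in mmol/L and only catch unit/entry errors.
#' @param age_min,age_max Inclusive adult age range in whole years.
#' @param strict_code_filter Remove whole records with malformed codes.
#' @return List with `results` (kept rows), `audit` (data frame `reason`,
#'   `count`) and `n_codes_dropped` (malformed code cells blanked).
#' @export
preprocess_results <- function(results, value_min = 0.5, value_max = 12,
                               age_min = 20, age_max = 89,
                               strict_code_filter = FALSE) {
  stopifnot(value_min < value_max)
  n_in <- nrow(results)
  reasons <- c("duplicate_case", "unknown_sex", "invalid_age",
               "missing_value", "implausible_value", "invalid_codes")
  audit <- stats::setNames(integer(length(reasons)), reasons)

  # 1. first result per administrative case
  ord <- if (!is.null(results$time)) order(results$time, seq_len(n_in))
         else seq_len(n_in)
  dup_in_ord <- duplicated(results$case_id[ord])
  drop_dup <- sort(ord[dup_in_ord])
  audit["duplicate_case"] <- length(drop_dup)
  if (length(drop_dup)) results <- results[-drop_dup, , drop = FALSE]

  # 2. validity filters, applied sequentially so each removal has one reason
  keep <- rep(TRUE, nrow(results))
  tally <- function(bad, reason) {
    bad <- bad & keep
    audit[reason] <<- sum(bad)
    keep <<- keep & !bad
  }
  tally(is.na(results$sex) | !results$sex %in% c("female", "male"),
        "unknown_sex")
  tally(is.na(results$age) | results$age < age_min | results$age > age_max,
        "invalid_age")
  tally(is.na(results$value), "missing_value")
  tally(!is.na(results$value) &
          (results$value <= 0 | results$value < value_min |
             results$value > value_max),
        "implausible_value")

  # 3. diagnosis code hygiene
  cm <- .code_matrix(results)
  cm_up <- toupper(cm)
  valid <- cm_up == "" | is_icd10_category(cm_up)
  if (strict_code_filter) {
    tally(rowSums(!valid) > 0, "invalid_codes")
  }
  results <- results[keep, , drop = FALSE]
  cm_up <- cm_up[keep, , drop = FALSE]
  valid <- valid[keep, , drop = FALSE]
  n_codes_dropped <- sum(!valid)
  cm_up[!valid] <- ""
  # collapse duplicate codes within a record (only rows that can have them)
  k <- rowSums(cm_up != "")
  dup_rows <- which(k > 1)
  if (length(dup_rows)) {
    has_dup <- vapply(dup_rows, function(i) {
      r <- cm_up[i, ]
      anyDuplicated(r[r != ""]) > 0
    }, logical(1))
    for (i in dup_rows[has_dup]) {
      r <- unique(cm_up[i, ][cm_up[i, ] != ""])
      length(r) <- ncol(cm_up)
      r[is.na(r)] <- ""
      cm_up[i, ] <- r
    }
  }
  cm_up <- .compact_codes(cm_up)
  code_cols <- attr(results, "code_cols") %||%
    grep("^code[0-9]+$", names(results), value = TRUE)
  results[code_cols] <- cm_up
  rownames(results) <- NULL
  attr(results, "code_cols") <- code_cols
  attr(results, "preprocessed") <- TRUE

  audit_df <- data.frame(reason = names(audit), count = unname(audit),
                         stringsAsFactors = FALSE)
  stopifnot(sum(audit_df$count) == n_in - nrow(results))
  list(results = results, audit = audit_df, n_codes_dropped = n_codes_dropped)
}

#' Stratify preprocessed results into sex and age-band slices
#'
#' Splits the data into one stratum per combination of sex (`female`, `male`)
#' and inclusive age band of `band_width` whole years spanning
#' `[age_min, age_max]` (defaults: 20-29, 30-39, ..., 80-89, i.e. 14 strata).
#' Each stratum holds its results and its Global Distribution (GD): the
#' multiset of all analyte values in the slice before any health-status
#' filtering.
#'
#' @param results Preprocessed result data frame.
#' @param band_width Age band width in years; must divide the age span.
#' @param age_min,age_max Inclusive overall age range.
#' @return An object of class `ddm_strata`: a list of `ddm_stratum` objects,
#'   each with fields `sex`, `age_lo`, `age_hi`, `results`, `gd_values`.
#' @export
stratify_results <- function(results, band_width = 10,
                             age_min = 20, age_max = 89) {
  span <- age_max - age_min + 1
  if (span %% band_width != 0) {
    stop("band_width must divide the age span ", age_min, "-", age_max)
  }
  if (nrow(results) &&
      (any(results$age < age_min) || any(results$age > age_max))) {
    stop("internal consistency error: ages outside [", age_min, ", ",
         age_max, "] after preprocessing")
  }
  los <- seq(age_min, age_max, by = band_width)
  strata <- list()
  for (sx in c("female", "male")) {
    for (lo in los) {
      hi <- lo + band_width - 1
      sel <- results$sex == sx & results$age >= lo & results$age <= hi
      sub <- results[sel, , drop = FALSE]
      rownames(sub) <- NULL
      attr(sub, "code_cols") <- attr(results, "code_cols")
      strata[[length(strata) + 1L]] <- structure(
        list(sex = sx, age_lo = lo, age_hi = hi,
             results = sub, gd_values = sub$value),
        class = "ddm_stratum")
    }
  }
  n_strata_results <- sum(vapply(strata, function(s) nrow(s$results), 0L))
  if (n_strata_results != nrow(results)) {
    stop("internal consistency error: stratification is not a partition")
  }
  structure(strata, class = "ddm_strata")
}

#' @export
print.ddm_stratum <- function(x, ...) {
  cat(sprintf("<ddm_stratum> %s %d-%d: n = %d\n",
              x$sex, x$age_lo, x$age_hi, length(x$gd_values)))
  invisible(x)
}

#' @export
print.ddm_strata <- function(x, ...) {
  cat(sprintf("<ddm_strata> %d strata, %d results\n", length(x),
              sum(vapply(x, function(s) length(s$gd_values), 0L))))
  for (s in x) {
    cat(sprintf("  %-6s %d-%d  n = %d\n", s$sex, s$age_lo, s$age_hi,
                length(s$gd_values)))
  }
  invisible(x)
}

#' Label of a stratum, e.g. "female 20-29"
#' @param stratum A `ddm_stratum`.
#' @return Character scalar.
#' @export
stratum_label <- function(stratum) {
  sprintf("%s %d-%d", stratum$sex, stratum$age_lo, stratum$age_hi)
}
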