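# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Pattern for a valid ICD-10 category ("three-character") code: one uppercase
# letter followed by exactly two digits, e.g. "N18".
.code_pattern <- "^[A-Z][0-9]{2}$"

is_icd10_category <- function(x) grepl(.code_pattern, x)

# Character matrix view of the code columns of a results data frame.
.code_matrix <- function(results) {
  cols <- attr(results, "code_cols")
  if (is.null(cols)) cols <- grep("^code[0-9]+$", names(results), value = TRUE)
  m <- as.matrix(results[, cols, drop = FALSE])
  m[is.na(m)] <- ""
  m
}

#' Diagnosis codes of each result as a list of character vectors
#'
#' @param results A result data frame (from [read_results()],
#'   [preprocess_results()] or a stratum's `results`).
#' @return List with one character vector of ICD-10 category codes per row.
#' @export
result_codes <- function(results) {
  m <- .code_matrix(results)
  nz <- m != ""
  rows <- row(m)[nz]
  codes <- m[nz]
  out <- rep(list(character(0)), nrow(m))
  if (length(rows)) {
    spl <- split(codes, rows)
    out[as.integer(names(spl))] <- spl
  }
  out
}

# Left-compact a character matrix of codes row-wise (empties pushed right),
# touching only rows that need it. A row needs compacting iff the position of
# its last non-empty cell exceeds its count of non-empty cells.
.compact_codes <- function(m) {
  nz <- m != ""
  k <- rowSums(nz)
  last <- max.col(nz + 0, ties.method = "last") * (k > 0)
  need <- which(k > 0 & last > k)
  if (length(need)) {
    m[need, ] <- t(vapply(need, function(i) {
      r <- m[i, ][nz[i, ]]
      length(r) <- ncol(m)
      r[is.na(r)] <- ""
      r
    }, character(ncol(m))))
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
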