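#' Build the code co-occurrence corpus of a stratum
#'
#' Each result with at least one ICD-10 code contributes one "sentence": the
#' ordered list of its co-coded diagnoses. Uncoded results contribute nothing.
#'
#' @param stratum A `ddm_stratum`.
#' @return Object of class `ddm_corpus` with `sentences` (list of character
#'   vectors) and `vocabulary` (named integer vector of code frequencies).
#' @export
build_code_corpus <- function(stratum) {
  codes <- result_codes(stratum$results)
  sentences <- codes[lengths(codes) > 0]
  vocab <- table(unlist(sentences, use.names = FALSE))
  structure(list(sentences = unname(sentences),
                 vocabulary = stats::setNames(as.integer(vocab),
                                              names(vocab))),
            class = "ddm_corpus")
}

#' Train code embeddings by skip-gram with negative sampling
#'
#' Learns one dense vector per sufficiently frequent code from the
#' co-occurrence of codes on the same test result, word2vec style: a shallow
#' network trained to discriminate observed (code, co-code) pairs from
#' negative pairs sampled from the unigram distribution raised to 3/4.
#' Training is single-threaded with its own deterministic generator, so a
#' fixed seed reproduces the vectors exactly.
#'
#' @param corpus A `ddm_corpus` from [build_code_corpus()].
#' @param dim Embedding dimension.
#' @param window Context window; with window >= 4 all pairs within a 5-code
#'   sentence co-occur.
#' @param epochs Training passes over the corpus.
#' @param min_count Minimum code frequency to receive a vector (default 6,
#'   aligned with the n > 5 testing filter).
#' @param negative Negative samples per positive pair.
#' @param learning_rate,min_learning_rate Linear learning-rate decay bounds.
#' @param seed Integer seed.
#' @return Object of class `ddm_embedding` with `vectors` (codes x dim
#'   matrix, rownames = codes) and `params`.
#' @export
train_code_embeddings <- function(corpus, dim = 100, window = 5, epochs = 20,
                                  min_count = 6, negative = 5,
                                  learning_rate = 0.025,
                                  min_learning_rate = 1e-4, seed = 1L) {
  stopifnot(inherits(corpus, "ddm_corpus"))
  vocab <- corpus$vocabulary[corpus$vocabulary >= min_count]
  codes <- names(vocab)
  sentences <- lapply(corpus$sentences, function(s) s[s %in% codes])
  sentences <- sentences[lengths(sentences) >= 2]
  if (length(codes) < 2 || length(sentences) < 2) {
    stop("no co-occurrence signal in corpus (all sentences have fewer than ",
         "two frequent codes); skip clustering for this stratum")
  }
  ids <- lapply(sentences, function(s) match(s, codes) - 1L)
  vec <- sgns_train(ids, length(codes), as.numeric(vocab),
                    as.integer(dim), as.integer(window),
                    as.integer(epochs), as.integer(negative),
                    as.numeric(learning_rate), as.numeric(min_learning_rate),
                    as.integer(seed))
  rownames(vec) <- codes
  structure(list(vectors = vec,
                 params = list(dim = dim, window = window, epochs = epochs,
                               min_count = min_count, negative = negative,
                               learning_rate = learning_rate,
                               algorithm = "skip-gram", seed = seed)),
            class = "ddm_embedding")
}

#' @export
print.ddm_embedding <- function(x, ...) {
  cat(sprintf("<ddm_embedding> %d codes x %d dims (skip-gram, seed %d)\n",
              nrow(x$vectors), ncol(x$vectors), x$params$seed))
  invisible(x)
}

#' Pairwise cosine similarity matrix of an embedding
#'
#' @param embedding A `ddm_embedding`, or a numeric matrix with one row per
#'   code (rownames = codes).
#' @return Symmetric N x N matrix with unit diagonal; entries in \[-1, 1\].
#'   Codes with zero-norm vectors are dropped with a warning.
#' @export
similarity_matrix <- function(embedding) {
  v <- if (inherits(embedding, "ddm_embedding")) embedding$vectors
       else embedding
  norms <- sqrt(rowSums(v^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " code(s) with zero-norm vectors: ",
            paste(rownames(v)[zero], collapse = ", "))
    v <- v[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  s <- tcrossprod(v / norms)
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  s
}

#' Partition codes into clusters from their similarity matrix
#'
#' The similarity is converted to a distance (default: `1 - similarity`,
#' clamped at zero; `"angular"` uses `acos(similarity)`) and the codes are
#' partitioned either by bottom-up (agglomerative) hierarchical clustering cut
#' at `min(k, N)` clusters, or by k-means on the embedding vectors.
#'
#' @param similarity An N x N cosine similarity matrix, or a `ddm_embedding`
#'   (from which both the similarity and the vectors are derived).
#' @param k Requested number of clusters (default 800, capped at N).
#' @param method `"hierarchical"` (default) or `"kmeans"`.
#' @param linkage Agglomeration rule for hierarchical clustering.
#' @param seed Seed for the k-means initialisation.
#' @param distance_mode `"one_minus"` or `"angular"`.
#' @param vectors Embedding matrix, required for `method = "kmeans"` when
#'   `similarity` is a plain matrix.
#' @return Object of class `ddm_clustering` with `similarity`, `distance`,
#'   `assignments` (named integer vector code -> cluster id), `k`, `method`,
#'   `linkage`.
#' @export
cluster_codes <- function(similarity, k = 800,
                          method = c("hierarchical", "kmeans"),
                          linkage = "average", seed = 1L,
                          distance_mode = c("one_minus", "angular"),
                          vectors = NULL) {
  method <- match.arg(method)
  distance_mode <- match.arg(distance_mode)
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("configuration error: k must be an integer >= 1")
  }
  if (inherits(similarity, "ddm_embedding")) {
    vectors <- similarity$vectors
    similarity <- similarity_matrix(similarity)
  }
  if (!isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-8)) ||
      any(abs(diag(similarity) - 1) > 1e-8) ||
      any(similarity < -1 - 1e-8) || any(similarity > 1 + 1e-8)) {
    stop("similarity must be symmetric with unit diagonal and entries in ",
         "[-1, 1]")
  }
  n <- nrow(similarity)
  d <- switch(distance_mode,
              one_minus = pmax(1 - similarity, 0),
              angular = acos(pmin(pmax(similarity, -1), 1)))
  diag(d) <- 0
  k_eff <- min(as.integer(k), n)
  assignments <- if (method == "hierarchical") {
    if (k_eff == n) {
      stats::setNames(seq_len(n), rownames(similarity))
    } else {
      hc <- stats::hclust(stats::as.dist(d), method = linkage)
      stats::cutree(hc, k = k_eff)
    }
  } else {
    if (is.null(vectors)) {
      stop("method = \"kmeans\" needs the embedding vectors")
    }
    if (k_eff == n) {
      stats::setNames(seq_len(n), rownames(vectors))
    } else {
      km <- with_seed(seed, stats::kmeans(vectors, centers = k_eff,
                                          nstart = 10, iter.max = 50))
      stats::setNames(km$cluster, rownames(vectors))
    }
  }
  structure(list(similarity = similarity, distance = d,
                 assignments = assignments, k = k_eff, method = method,
                 linkage = if (method == "hierarchical") linkage else NA),
            class = "ddm_clustering")
}

#' @export
print.ddm_clustering <- function(x, ...) {
  cat(sprintf("<ddm_clustering> %d codes into %d clusters (%s%s)\n",
              length(x$assignments), length(unique(x$assignments)), x$method,
              if (!is.na(x$linkage)) paste0(", ", x$linkage) else ""))
  invisible(x)
}

#' Cluster-level diagnosis table and Differential Distribution
#'
#' Groups a stratum's results by ICD-10 code cluster (a result belongs to a
#' cluster group if any of its codes is a member — mirroring the any-code
#' rule, so a result can feed several cluster groups), tests each cluster
#' group against the Global Distribution exactly as in
#' [build_diagnosis_table()], and removes all results associated with
#' significant clusters ("DD with Clustering"). Codes present in the stratum
#' but absent from the clustering (e.g. below the embedding's `min_count`)
#' form singleton pseudo-clusters so rare codes are still tested per-code.
#'
#' @param stratum A `ddm_stratum`.
#' @param clustering A `ddm_clustering` from [cluster_codes()].
#' @inheritParams build_diagnosis_table
#' @return List with `table` (a `ddm_diag_table` whose label column is
#'   `cluster` and which carries a `member_codes` column) and `dd`
#'   (a `ddm_dd`).
#' @export
cluster_table_and_dd <- function(stratum, clustering, min_n = 6, alpha = 0.05,
                                 normality_alpha = 0.05,
                                 compare_to_complement = FALSE,
                                 use_p = FALSE) {
  assignments <- clustering$assignments
  cluster_of <- stats::setNames(paste0("c", assignments), names(assignments))
  vocab <- unique(unlist(result_codes(stratum$results), use.names = FALSE))
  orphan <- setdiff(vocab, names(cluster_of))
  if (length(orphan)) {
    cluster_of <- c(cluster_of,
                    stats::setNames(paste0("s:", orphan), orphan))
  }
  members <- split(names(cluster_of), unname(cluster_of))

  m <- .code_matrix(stratum$results)
  groups_idx <- list()
  if (length(m) && nrow(m)) {
    nz <- m != ""
    rows <- row(m)[nz]
    cl <- unname(cluster_of[m[nz]])
    keep <- !is.na(cl)
    rows <- rows[keep]; cl <- cl[keep]
    first <- !duplicated(paste(rows, cl, sep = "\r"))  # one membership per result
    groups_idx <- split(rows[first], cl[first])
  }
  tab <- .diagnosis_table_core(stratum, groups_idx, min_n, alpha,
                               normality_alpha, compare_to_complement,
                               use_p, label_col = "cluster")
  tab$member_codes <- vapply(tab$cluster, function(cl) {
    paste(sort(members[[cl]]), collapse = ";")
  }, character(1))
  attr(tab, "cluster_members") <- members
  dd <- differential_distribution(stratum, tab)
  attr(dd, "cluster_members") <- members
  list(table = tab, dd = dd)
}

#' Cluster assignments as a data frame
#'
#' @param clustering A `ddm_clustering`.
#' @return Data frame with `code`, `cluster_id`, `cluster_size`.
#' @export
cluster_assignments <- function(clustering) {
  a <- clustering$assignments
  sizes <- table(a)
  data.frame(code = names(a), cluster_id = unname(a),
             cluster_size = as.integer(sizes[as.character(a)]),
             stringsAsFactors = FALSE)
}
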