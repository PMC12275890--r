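test_that("the code corpus mirrors coded results", {
  st <- make_stratum(1:5, codes = list(c("N18", "I10", "E11"), "N18",
                                       character(0), character(0),
                                       c("I10", "N18")))
  corpus <- build_code_corpus(st)
  expect_length(corpus$sentences, 3)  # uncoded results contribute nothing
  expect_equal(corpus$sentences[[1]], c("N18", "I10", "E11"))
  expect_setequal(names(corpus$vocabulary), c("N18", "I10", "E11"))
  expect_equal(unname(corpus$vocabulary["N18"]), 3L)
})

test_that("embedding training is deterministic and respects min_count", {
  corpus <- make_block_corpus(n_per_block = 100, seed = 3)
  e1 <- train_code_embeddings(corpus, dim = 16, epochs = 5, seed = 7)
  e2 <- train_code_embeddings(corpus, dim = 16, epochs = 5, seed = 7)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_code_embeddings(corpus, dim = 16, epochs = 5, seed = 8)
  expect_false(identical(e1$vectors, e3$vectors))

  # a code seen only 3 times is excluded at min_count = 10
  corpus$sentences <- c(corpus$sentences,
                        rep(list(c("Z99", "A01")), 3))
  corpus$vocabulary <- table(unlist(corpus$sentences))
  corpus$vocabulary <- setNames(as.integer(corpus$vocabulary),
                                names(corpus$vocabulary))
  e4 <- train_code_embeddings(corpus, dim = 16, epochs = 5, min_count = 10,
                              seed = 7)
  expect_false("Z99" %in% rownames(e4$vectors))
})

test_that("training fails informatively without co-occurrence signal", {
  corpus <- structure(list(sentences = rep(list("N18"), 30),
                           vocabulary = c(N18 = 30L)),
                      class = "ddm_corpus")
  expect_error(train_code_embeddings(corpus), "co-occurrence")
})

test_that("planted co-occurrence blocks separate in cosine similarity", {
  corpus <- make_block_corpus(n_per_block = 250, codes_per_block = 4,
                              seed = 5)
  emb <- train_code_embeddings(corpus, dim = 25, epochs = 10, seed = 5)
  s <- similarity_matrix(emb)
  expect_gt(s["A01", "A02"], s["A01", "B01"])  # within-block > between-block
})

test_that("similarity matrix has unit diagonal, symmetry and correct extremes", {
  v <- rbind(c(1, 0), c(2, 0), c(0, 3), c(-1, 0))
  rownames(v) <- c("A01", "A02", "B01", "C01")
  s <- similarity_matrix(v)
  expect_equal(diag(s), setNames(rep(1, 4), rownames(v)))
  expect_equal(s, t(s))
  expect_equal(s["A01", "A02"], 1)    # identical direction
  expect_equal(s["A01", "B01"], 0)    # orthogonal
  expect_equal(s["A01", "C01"], -1)   # antipodal
  expect_true(all(s >= -1 & s <= 1))

  v2 <- rbind(v, D01 = c(0, 0))
  expect_warning(s2 <- similarity_matrix(v2), "zero-norm")
  expect_false("D01" %in% rownames(s2))
})

test_that("cluster_codes handles the extreme values of k", {
  corpus <- make_block_corpus(n_per_block = 150, codes_per_block = 4,
                              seed = 9)
  emb <- train_code_embeddings(corpus, dim = 16, epochs = 8, seed = 9)
  n <- nrow(emb$vectors)
  cl_n <- cluster_codes(emb, k = n)
  expect_equal(length(unique(cl_n$assignments)), n)  # every code its own
  cl_big <- cluster_codes(emb, k = 800)
  expect_equal(cl_big$k, n)                          # capped at vocabulary
  cl_1 <- cluster_codes(emb, k = 1)
  expect_equal(length(unique(cl_1$assignments)), 1L)
  expect_error(cluster_codes(emb, k = 0), "k must be")
  # distance matrix: symmetric, non-negative, zero diagonal
  expect_true(all(cl_1$distance >= 0))
  expect_equal(diag(cl_1$distance), setNames(rep(0, n),
                                             rownames(emb$vectors)))
})

test_that("agglomerative clustering at k = 2 recovers planted blocks", {
  corpus <- make_block_corpus(n_per_block = 500, codes_per_block = 8,
                              seed = 13)
  emb <- train_code_embeddings(corpus, seed = 13)
  cl <- cluster_codes(emb, k = 2)
  truth <- substr(names(cl$assignments), 1, 1)
  expect_equal(ari(cl$assignments, truth), 1)
  # k-means route agrees on this well-separated fixture
  km <- cluster_codes(emb, k = 2, method = "kmeans", seed = 13)
  expect_equal(ari(km$assignments, truth), 1)
})

test_that("cluster-level DDM with singleton clusters equals per-code DDM", {
  sim <- simulate_lab_data(random_small_scenario(17), seed = 17)
  pp <- preprocess_results(parse_result_frame(sim$results)$results)
  st <- stratify_results(pp$results)[[3]]
  corpus <- build_code_corpus(st)
  emb <- train_code_embeddings(corpus, dim = 25, epochs = 10, seed = 17)
  cl <- cluster_codes(emb, k = nrow(emb$vectors))
  out <- suppressWarnings(cluster_table_and_dd(st, cl))
  tab <- suppressWarnings(build_diagnosis_table(st))
  dd <- differential_distribution(st, tab)
  expect_setequal(out$dd$removed_index, dd$removed_index)
  # same rows up to labels: compare by member code
  key_cl <- setNames(out$table$q_value, out$table$member_codes)
  key_pc <- setNames(tab$q_value, tab$code)
  expect_equal(key_cl[sort(names(key_cl))], key_pc[sort(names(key_pc))])
})

test_that("pooling rare codes into one cluster recovers power per-code testing lacks", {
  set.seed(19)
  healthy <- rnorm(192, 4, 0.35)
  shifted <- rnorm(8, 5.5, 0.35)  # strong shift, split over two rare codes
  st <- make_stratum(c(healthy, shifted),
                     codes = c(rep(list(character(0)), 192),
                               rep(list("X01"), 4), rep(list("X02"), 4)))
  # per-code: both groups have n = 4 <= 5, nothing can be tested or removed
  tab <- build_diagnosis_table(st)
  expect_equal(nrow(tab), 0)
  expect_equal(differential_distribution(st, tab)$removed_count, 0L)
  # clustered: X01 and X02 pooled -> n = 8 > 5, tested and removed
  clustering <- structure(list(
    similarity = NULL, distance = NULL,
    assignments = c(X01 = 1L, X02 = 1L), k = 1L,
    method = "hierarchical", linkage = "average"), class = "ddm_clustering")
  out <- suppressWarnings(cluster_table_and_dd(st, clustering))
  expect_equal(nrow(out$table), 1)
  expect_true(out$table$significant)
  expect_equal(out$dd$removed_count, 8L)
  expect_equal(sort(out$dd$dd_values), sort(healthy))
})

test_that("codes without vectors become singleton pseudo-clusters", {
  set.seed(23)
  st <- make_stratum(rnorm(100, 4, 0.35),
                     codes = c(rep(list(c("A01", "B02")), 40),
                               rep(list("R99"), 10),
                               rep(list(character(0)), 50)))
  clustering <- structure(list(
    similarity = NULL, distance = NULL,
    assignments = c(A01 = 1L, B02 = 1L), k = 1L,
    method = "hierarchical", linkage = "average"), class = "ddm_clustering")
  out <- suppressWarnings(cluster_table_and_dd(st, clustering))
  # R99 was not embedded but is still tested as its own pseudo-cluster
  expect_true("s:R99" %in% out$table$cluster)
  expect_equal(out$table$n[out$table$cluster == "s:R99"], 10L)
})

test_that("a stratum with no coded results yields an empty cluster table", {
  st <- make_stratum(rnorm(30, 4, 0.35))
  clustering <- structure(list(similarity = NULL, distance = NULL,
                               assignments = setNames(integer(0),
                                                      character(0)),
                               k = 0L, method = "hierarchical",
                               linkage = "average"),
                          class = "ddm_clustering")
  out <- cluster_table_and_dd(st, clustering)
  expect_equal(nrow(out$table), 0)
  expect_equal(out$dd$dd_values, st$gd_values)
})
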