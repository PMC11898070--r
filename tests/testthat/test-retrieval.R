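test_that("stores build deterministically and persist losslessly", {
  man <- generate_synthetic_dataset(6, 4, length_range = c(8, 14), motif = "WWWWW",
                                    seed = 2)
  cfg <- small_embedder()
  st <- build_store(man, cfg)
  expect_equal(length(st$ids), 10)
  expect_identical(st$pooled, build_store(man, cfg)$pooled)

  dir <- withr::local_tempdir()
  save_store(st, dir)
  back <- load_store(dir)
  expect_identical(back$pooled, st$pooled)
  expect_equal(back$ids, st$ids)
  expect_equal(back$labels, st$labels)
  expect_true(all(vapply(seq_along(st$matrices),
                         function(i) identical(back$matrices[[i]], st$matrices[[i]]),
                         logical(1))))
})

test_that("store entry counts scale to the retrieval-database size", {
  # synthetic stand-in at the published database class sizes: 513 + 9379
  man <- generate_synthetic_dataset(513, 9379, length_range = c(8, 35),
                                    motif = "WWWWW", seed = 6)
  cfg <- embedder_config(dim = 4, padded_length = 36, seed = 0)
  st <- build_store(man, cfg)
  expect_equal(length(st$ids), 9892)
})

test_that("retrieval matches the brute-force distance sort on random stores", {
  for (trial in 1:8) {
    set.seed(100 + trial)
    n <- sample(5:100, 1)
    metric <- if (trial %% 2 == 0) "cosine" else "euclidean"
    man <- generate_synthetic_dataset(ceiling(n / 2), floor(n / 2),
                                      length_range = c(6, 15), motif = "ACD",
                                      seed = 200 + trial)
    st <- build_store(man, small_embedder(dim = 6, seed = trial))
    q <- rnorm(6)
    k <- sample(1:5, 1)
    got <- retrieve_top_k(st, q, fusion_config(k = k, metric = metric,
                                               exclude_self = FALSE))
    expect_equal(got$index, brute_force_neighbors(st, q, k, metric))
    expect_true(all(diff(got$distance) >= -1e-12))
  }
})

test_that("an exact stored query is its own nearest neighbor unless excluded", {
  man <- generate_synthetic_dataset(5, 5, length_range = c(8, 12), motif = "ACD",
                                    seed = 31)
  cfg <- small_embedder(dim = 10)
  st <- build_store(man, cfg)
  emb <- embed_dataset(man, cfg)
  q <- mean_pool(emb[[3]])
  hit <- retrieve_top_k(st, q, fusion_config(k = 1, exclude_self = FALSE))
  expect_equal(hit$index, 3)
  expect_equal(hit$distance, 0, tolerance = 1e-12)

  excl <- retrieve_top_k(st, q, fusion_config(k = 9, exclude_self = TRUE),
                         query_sequence = man$peptides$sequence[3])
  expect_false(3 %in% excl$index)

  small <- man$peptides[1:3, ]
  st3 <- build_store(peptide_manifest(small, "tiny"), cfg)
  expect_warning(got <- retrieve_top_k(st3, q, fusion_config(k = 5, exclude_self = FALSE)),
                 "only 3 eligible")
  expect_equal(nrow(got), 3)
})

test_that("neighbor averaging equals explicit elementwise arithmetic", {
  man <- generate_synthetic_dataset(6, 0, length_range = c(6, 12), motif = "ACD",
                                    seed = 8)
  cfg <- small_embedder(dim = 7)
  st <- build_store(man, cfg)

  one <- data.frame(peptide_id = st$ids[2], index = 2, distance = 0)
  avg1 <- average_neighbors(st, one)
  expect_equal(avg1$values, st$matrices[[2]])

  five <- data.frame(peptide_id = st$ids[1:5], index = 1:5, distance = 0)
  avg5 <- average_neighbors(st, five)
  manual <- (st$matrices[[1]] + st$matrices[[2]] + st$matrices[[3]] +
               st$matrices[[4]] + st$matrices[[5]]) / 5
  expect_equal(avg5$values, manual)
  expect_equal(avg5$true_length, max(st$true_lengths[1:5]))

  # symmetric matrices cancel
  st2 <- st
  st2$matrices[[2]] <- -st2$matrices[[1]]
  two <- data.frame(peptide_id = st$ids[1:2], index = 1:2, distance = 0)
  expect_true(all(average_neighbors(st2, two)$values == 0))
})

test_that("fusion is the documented weighted convex combination", {
  mk <- function(x) ragmcnn:::new_embedding_matrix(matrix(x, 6, 4), 5, "m")
  q <- mk(1); r <- mk(3)

  expect_equal(fuse_embeddings(q, r, fusion_config(ratio_query = 1,
                                                   ratio_retrieved = 1))$values,
               mk(2)$values)
  expect_equal(fuse_embeddings(q, r, fusion_config(ratio_query = 1,
                                                   ratio_retrieved = 0))$values,
               q$values)
  expect_equal(fuse_embeddings(q, q, fusion_config(ratio_query = 2,
                                                   ratio_retrieved = 7))$values,
               q$values)

  # published sweep ratios give retrieved-side weights b/(a+b)
  sweep <- list(c(1, 2), c(1, 5), c(2, 1), c(5, 1))
  wts <- c(2 / 3, 5 / 6, 1 / 3, 1 / 6)
  for (i in seq_along(sweep)) {
    f <- fuse_embeddings(q, r, fusion_config(ratio_query = sweep[[i]][1],
                                             ratio_retrieved = sweep[[i]][2]))
    expect_equal(f$values[1, 1], 1 * (1 - wts[i]) + 3 * wts[i])
  }

  set.seed(5)
  qa <- ragmcnn:::new_embedding_matrix(matrix(rnorm(24), 6, 4), 5, "a")
  rb <- ragmcnn:::new_embedding_matrix(matrix(rnorm(24), 6, 4), 6, "b")
  f12 <- fuse_embeddings(qa, rb, fusion_config(ratio_query = 1, ratio_retrieved = 2))
  # convexity: each fused component lies between its two sources
  expect_true(all(f12$values >= pmin(qa$values, rb$values) - 1e-12 &
                    f12$values <= pmax(qa$values, rb$values) + 1e-12))
  # scale invariance of the weight pair
  f36 <- fuse_embeddings(qa, rb, fusion_config(ratio_query = 3, ratio_retrieved = 6))
  expect_equal(f12$values, f36$values)
  # fused result keeps the query's true length
  expect_equal(f12$true_length, 5)

  bad <- ragmcnn:::new_embedding_matrix(matrix(0, 5, 4), 4, "bad")
  expect_error(fuse_embeddings(qa, bad, fusion_config()), "shape mismatch")
  expect_error(fusion_config(ratio_query = 0, ratio_retrieved = 0), "zero")
})

test_that("augmentation with self-exclusion never retrieves the query itself", {
  man <- generate_synthetic_dataset(10, 10, length_range = c(8, 12),
                                    motif = "WWWWW", seed = 17)
  cfg <- small_embedder(dim = 8)
  st <- build_store(man, cfg)
  emb <- embed_dataset(man, cfg)
  for (i in c(1, 7, 15)) {
    nb <- retrieve_top_k(st, mean_pool(emb[[i]]), fusion_config(k = 5),
                         query_sequence = man$peptides$sequence[i])
    expect_false(i %in% nb$index)
  }
})
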