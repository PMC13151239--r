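test_that("graph construction doubles associations into directed edge pairs", {
  at <- association_table(data.frame(d = c("d1", "d1", "d2"),
                                     m = c("m1", "m2", "m1")))
  g <- build_graph(at)
  expect_equal(nrow(g$edges), 6L)
  nd <- g$n_diseases
  # every edge crosses the bipartition and has its reverse
  from_d <- g$edges[, 1] <= nd
  to_d <- g$edges[, 2] <= nd
  expect_true(all(xor(from_d, to_d)))
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev_key <- paste(g$edges[, 2], g$edges[, 1])
  expect_setequal(key, rev_key)
})

test_that("symmetric degree normalisation reproduces closed forms", {
  # single association: 1/sqrt(1*1)
  at1 <- association_table(data.frame(d = "d1", m = "m1"))
  a1 <- as.matrix(normalize_adjacency(build_graph(at1)))
  expect_equal(a1[1, 2], 1)
  expect_equal(a1[2, 1], 1)

  # star: one disease linked to 4 miRNAs -> 1/2 each
  at2 <- association_table(data.frame(d = rep("d1", 4), m = paste0("m", 1:4)))
  a2 <- as.matrix(normalize_adjacency(build_graph(at2)))
  expect_equal(unname(a2[1, 2:5]), rep(1 / 2, 4))

  # path d1-m1, m1-d2, d2-m2: middle edges 1/sqrt(2*2), ends 1/sqrt(2)
  at3 <- association_table(data.frame(d = c("d1", "d2", "d2"),
                                      m = c("m1", "m1", "m2")))
  a3 <- as.matrix(normalize_adjacency(build_graph(at3)))
  # node order: d1 d2 m1 m2; degrees 1 2 2 1
  expect_equal(a3[1, 3], 1 / sqrt(2))
  expect_equal(a3[2, 3], 1 / 2)
  expect_equal(a3[2, 4], 1 / sqrt(2))

  # dropping all edges leaves a zero matrix
  a0 <- normalize_adjacency(build_graph(at1), drop_pairs = cbind(1L, 1L))
  expect_true(all(as.matrix(a0) == 0))

  # row sums bounded by sqrt(max degree)
  at4 <- random_assoc(6, 9, seed = 4)
  g4 <- build_graph(at4)
  a4 <- normalize_adjacency(g4)
  deg <- Matrix::rowSums(Matrix::sparseMatrix(
    i = g4$edges[, 1], j = g4$edges[, 2], x = 1,
    dims = rep(g4$n_diseases + g4$n_mirnas, 2)))
  expect_true(all(Matrix::rowSums(a4) <= sqrt(max(deg)) + 1e-12))
})

test_that("negative sampling avoids positives, is seeded and bounded", {
  at <- association_table(data.frame(d = c("d1", "d1", "d2"),
                                     m = c("m1", "m2", "m1")))
  # 2x2 universe with 3 positives: the only free pair is (d2, m2)
  neg <- sample_negatives(at, 1, seed = 1)
  expect_equal(unname(neg), cbind(2L, 2L), ignore_attr = TRUE)
  expect_error(sample_negatives(at, 2, seed = 1), "only 1")

  big <- random_assoc(10, 10, p = 0.3, seed = 2)
  expect_identical(sample_negatives(big, 20, seed = 7),
                   sample_negatives(big, 20, seed = 7))
  pos_key <- paste(big$pairs[, 1], big$pairs[, 2])
  for (s in 1:200) {
    neg <- sample_negatives(big, 30, seed = s)
    expect_equal(anyDuplicated(paste(neg[, 1], neg[, 2])), 0L)
    expect_false(any(paste(neg[, 1], neg[, 2]) %in% pos_key))
  }
})

test_that("fold assignment is balanced, disjoint and covers every sample", {
  pos <- cbind(rep(1:10, each = 10), rep(1:10, 10))
  neg <- pos[1:97, ]
  pt <- make_folds(pos, neg, k = 5, seed = 11)
  expect_equal(unname(table(pt$fold_pos)), rep(20L, 5), ignore_attr = TRUE)
  # 97 = 5*19 + 2: earlier folds absorb the remainder
  expect_equal(as.integer(table(pt$fold_neg)), c(20L, 20L, 19L, 19L, 19L))
  expect_equal(sort(unique(pt$fold_pos)), 1:5)
  expect_equal(length(pt$fold_pos), nrow(pos))

  # 7 samples in 5 folds -> sizes {2, 2, 1, 1, 1}
  p7 <- make_folds(pos[1:7, ], neg[1:7, ], k = 5, seed = 2)
  expect_equal(as.integer(table(factor(p7$fold_pos, levels = 1:5))),
               c(2L, 2L, 1L, 1L, 1L))

  expect_error(make_folds(pos[1:3, ], neg[1:3, ], k = 5), "fewer samples")

  # export is readable and labelled
  at <- random_assoc(10, 10, seed = 2)
  pt2 <- make_folds(at$pairs, sample_negatives(at, nrow(at$pairs), 3),
                    k = 5, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(pt2, at, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2L * nrow(at$pairs))
  expect_setequal(unique(tab$label), c(0L, 1L))
})

test_that("held-out fold samples never enter that fold's training set", {
  at <- random_assoc(12, 12, seed = 5)
  neg <- sample_negatives(at, nrow(at$pairs), seed = 6)
  pt <- make_folds(at$pairs, neg, k = 5, seed = 7)
  for (fold in 1:5) {
    tr_pos <- pt$positives[pt$fold_pos != fold, , drop = FALSE]
    te_pos <- pt$positives[pt$fold_pos == fold, , drop = FALSE]
    # test-fold positives are disjoint from that fold's training positives
    expect_length(intersect(paste(tr_pos[, 1], tr_pos[, 2]),
                            paste(te_pos[, 1], te_pos[, 2])), 0)
    expect_equal(nrow(tr_pos) + nrow(te_pos), nrow(pt$positives))
  }
  # every positive sample index appears in exactly one fold
  expect_equal(sort(unlist(lapply(1:5, function(f) which(pt$fold_pos == f)))),
               seq_len(nrow(pt$positives)))
})
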