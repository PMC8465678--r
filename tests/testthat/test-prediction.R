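fake_embeddings <- function(n_m = 3, n_d = 2, BE = 4, seed = 1,
                            types = association_types()) {
  set.seed(seed)
  nodes <- c(sprintf("m%02d", seq_len(n_m)), sprintf("d%02d", seq_len(n_d)))
  out <- lapply(types, function(tp)
    matrix(rnorm((n_m + n_d) * BE), n_m + n_d, BE, dimnames = list(nodes, NULL)))
  names(out) <- types
  out
}

test_that("triple features concatenate layer-specific endpoint embeddings", {
  emb <- fake_embeddings(BE = 4)
  tri <- tiny_triples(c("m01", "d01", "target"), c("m01", "d01", "genetics"))
  X <- make_triple_features(emb, tri)
  expect_equal(dim(X), c(2, 8))
  expect_equal(X[1, ], c(emb$target["m01", ], emb$target["d01", ]))
  expect_false(isTRUE(all.equal(X[1, ], X[2, ])))  # same pair, different layer
  z <- emb; for (tp in names(z)) z[[tp]][] <- 0
  expect_equal(unname(make_triple_features(z, tri)), matrix(0, 2, 8))
  expect_error(make_triple_features(emb, tiny_triples(c("mX", "d01", "target"))),
               "mX")
})

test_that("negative pool keeps exactly the candidates beyond the mean distance", {
  pos <- rbind(c(0, 0), c(0, 0))
  unconf <- rbind(c(1, 0), c(3, 0))  # distances 1 and 3, mean 2
  pool <- build_negative_pool(pos, unconf)
  expect_equal(pool$dis_r, 2)
  expect_equal(pool$eligible, 2L)
  # all equidistant -> none strictly beyond the mean
  eq <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  expect_length(build_negative_pool(pos, eq)$eligible, 0)
  expect_warning(p0 <- build_negative_pool(pos, matrix(0, 0, 2)), "empty")
  expect_length(p0$eligible, 0)
})

test_that("negative sampling is seeded, capped and pool-restricted", {
  pool <- structure(list(eligible = 1:10, dis_r = 1, distances = rep(2, 10)),
                    class = "negative_pool")
  s1 <- sample_negatives(pool, 5, seed = 3)
  expect_identical(s1, sample_negatives(pool, 5, seed = 3))
  expect_length(s1, 5)
  expect_true(all(s1 %in% pool$eligible))
  small <- structure(list(eligible = 1:3), class = "negative_pool")
  expect_warning(s2 <- sample_negatives(small, 5, seed = 1), "smaller")
  expect_identical(s2, 1:3)
  expect_error(sample_negatives(structure(list(eligible = integer(0)),
                                          class = "negative_pool"), 1), "empty")
})

test_that("the forest separates separable classes and is reproducible", {
  set.seed(44)
  n <- 200
  X <- rbind(matrix(rnorm(n / 2 * 4, mean = 2), n / 2),
             matrix(rnorm(n / 2 * 4, mean = -2), n / 2))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  idx <- sample(n, 150)
  m <- train_classifier(X[idx, ], y[idx], num_trees = 200, seed = 7)
  sc <- mdlinker:::classifier_scores(m, X[-idx, ])
  acc <- mean((sc >= 0.5) == y[-idx])
  expect_gt(acc, 0.95)
  m2 <- train_classifier(X[idx, ], y[idx], num_trees = 200, seed = 7)
  expect_equal(sc, mdlinker:::classifier_scores(m2, X[-idx, ]))
  expect_error(train_classifier(X, rep(TRUE, n)), "both classes")
})

test_that("scoring covers every queried triple with probabilities", {
  emb <- fake_embeddings(BE = 4, seed = 2)
  tri <- tiny_triples(c("m01", "d01", "target"), c("m02", "d02", "genetics"),
                      c("m03", "d01", "tissue"), c("m01", "d02", "circulating"))
  X <- make_triple_features(emb, tri)
  m <- train_classifier(X, c(TRUE, TRUE, FALSE, FALSE), num_trees = 50, seed = 1)
  pairs <- expand.grid(mirna = c("m01", "m02"), disease = c("d01", "d02"),
                       stringsAsFactors = FALSE)
  query <- data.frame(mirna = rep(pairs$mirna, each = 5),
                      disease = rep(pairs$disease, each = 5),
                      type = rep(association_types(), 4),
                      stringsAsFactors = FALSE)
  sc <- score_triples(m, emb, query)
  expect_equal(nrow(sc), nrow(pairs) * 5)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_identical(sc$score, score_triples(m, emb, query)$score)
})

test_that("candidate universe excludes exactly the known triples", {
  known <- tiny_triples(c("m01", "d01", "target"))
  uni <- candidate_universe(c("m01", "m02"), c("d01"), known)
  expect_equal(nrow(uni), 2 * 1 * 5 - 1)
  expect_false(any(uni$mirna == "m01" & uni$disease == "d01" & uni$type == "target"))
})

test_that("fitted cores never sample negatives overlapping the positives", {
  ds <- gen_planted_amhn(planted_config(n_mirna = 10, n_disease = 8, n_blocks = 2,
                                        p_within = 0.5, p_cross = 0.05, seed = 6))
  feats <- tiny_features(10, 8, NE = 4, seed = 2)
  rownames(feats$mirna) <- sprintf("mirna%03d", 1:10)
  rownames(feats$disease) <- sprintf("disease%03d", 1:8)
  ctl <- mdlinker_control("desk", g_epochs = 1, num_trees = 50)
  core <- suppressWarnings(mdlinker:::fit_core(ds$associations, feats, ctl, seed = 5))
  key <- function(d) paste(d$mirna, d$disease, d$type)
  expect_length(intersect(key(core$negatives), key(ds$associations)), 0)
  # sampled negatives strictly exceed the per-type distance threshold
  for (tp in names(core$pools)) {
    pool <- core$pools[[tp]]
    expect_true(all(pool$distances[pool$eligible] > pool$dis_r))
  }
  # 1:1 ratio per type when the pool suffices
  tab_pos <- table(ds$associations$type)
  tab_neg <- table(core$negatives$type)
  for (tp in names(tab_neg)) expect_lte(tab_neg[[tp]], tab_pos[[tp]])
})
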