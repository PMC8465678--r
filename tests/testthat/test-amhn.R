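amhn_fixture <- function(n_m = 3, n_d = 3, NE = 4, seed = 1,
                         triples = NULL, types = association_types()) {
  feats <- tiny_features(n_m, n_d, NE, seed)
  if (is.null(triples)) {
    triples <- tiny_triples(
      c("m01", "d01", "target"), c("m01", "d02", "target"),
      c("m02", "d01", "genetics"), c("m03", "d03", "tissue"))
  }
  build_amhn(triples, feats, types)
}

test_that("network construction puts each association type in its own layer", {
  g <- amhn_fixture()
  expect_equal(nrow(g$layers$target), 2)
  expect_equal(nrow(g$layers$genetics), 1)
  expect_equal(nrow(g$layers$epigenetics), 0)
  expect_equal(length(g$nodes), 6)
  # bipartite: every edge joins one miRNA (type 1) and one disease (type 2)
  for (L in g$layers) {
    if (nrow(L)) {
      expect_true(all(g$type[L[, 1]] == 1))
      expect_true(all(g$type[L[, 2]] == 2))
    }
  }
  expect_warning(build_amhn(tiny_triples()[0, ], tiny_features(2, 2)), "empty")
  expect_error(build_amhn(tiny_triples(c("mX", "d01", "target")),
                          tiny_features(2, 2)), "without feature")
})

test_that("edge embeddings aggregate neighbors and pass isolated nodes through", {
  g <- amhn_fixture()
  p <- gatne_init(g, BE = 3, DE = 3, att_dim = 2, K = 2, seed = 4)
  lv <- aggregate_edge_embedding(g, p, "target", all_levels = TRUE)
  # level 0 is exactly the affine transform of the attributes
  i <- 2  # m02, isolated in layer "target"
  z <- g$type[i]
  expect_equal(lv[[1]][i, ],
               as.numeric(g$X[i, ] %*% p$Wg[[z]][[match("target", g$types)]]) +
                 p$bg[[z]][[match("target", g$types)]])
  # isolated node keeps its level-0 value at every depth
  expect_equal(lv[[3]][i, ], lv[[1]][i, ])
  # connected node: one step of mean + tanh
  r <- match("target", g$types)
  nb <- g$nbrs[[r]][[1]]
  expect_equal(lv[[2]][1, ], tanh(colMeans(lv[[1]][nb, , drop = FALSE])))
})

test_that("star-graph aggregation equals the hand-computed mean of leaves", {
  feats <- tiny_features(1, 4, NE = 3, seed = 2)
  tri <- tiny_triples(c("m01", "d01", "target"), c("m01", "d02", "target"),
                      c("m01", "d03", "target"), c("m01", "d04", "target"))
  g <- build_amhn(tri, feats)
  p <- gatne_init(g, BE = 2, DE = 3, att_dim = 2, K = 1, seed = 6)
  lv <- aggregate_edge_embedding(g, p, "target", all_levels = TRUE)
  expect_equal(lv[[2]][1, ], tanh(colMeans(lv[[1]][2:5, ])))
})

test_that("attention weights are a proper distribution with expected limits", {
  g <- amhn_fixture()
  p <- gatne_init(g, BE = 3, DE = 3, att_dim = 2, seed = 8)
  Di <- matrix(rnorm(3 * 5), 3, 5)
  at <- attention_combine(p, Di, r = 1)
  expect_true(all(at$a >= 0))
  expect_equal(sum(at$a), 1)
  expect_length(at$u, 3)
  # zero attention matrix -> uniform weights over the m layers
  p0 <- p; p0$Watt[[1]][] <- 0
  expect_equal(attention_combine(p0, Di, 1)$a, rep(1 / 5, 5))
  # single layer -> degenerate softmax and u = alpha * M' d
  g1 <- amhn_fixture(types = "target",
                     triples = tiny_triples(c("m01", "d01", "target")))
  p1 <- gatne_init(g1, BE = 3, DE = 3, att_dim = 2, seed = 9)
  d1 <- matrix(rnorm(3), 3, 1)
  at1 <- attention_combine(p1, d1, 1)
  expect_equal(at1$a, 1)
  expect_equal(at1$u, p1$alpha[1] * as.numeric(t(p1$M[[1]]) %*% d1))
})

test_that("final embeddings collapse to the base term when alpha = beta = 0", {
  g <- amhn_fixture()
  p <- gatne_init(g, BE = 3, DE = 3, att_dim = 2, seed = 5)
  p$alpha[] <- 0; p$beta[] <- 0
  V <- final_embedding(g, p)
  base <- t(vapply(seq_along(g$nodes), function(i) {
    z <- g$type[i]
    as.numeric(g$X[i, ] %*% p$Wh[[z]]) + p$bh[[z]]
  }, numeric(3)))
  for (r in seq_along(V)) expect_equal(unname(V[[r]]), base)
})

test_that("layers with identical edges and parameters embed identically", {
  feats <- tiny_features(2, 2, NE = 3, seed = 3)
  tri <- tiny_triples(c("m01", "d01", "genetics"), c("m02", "d02", "genetics"),
                      c("m01", "d01", "epigenetics"), c("m02", "d02", "epigenetics"))
  g <- build_amhn(tri, feats)
  p <- gatne_init(g, BE = 2, DE = 2, att_dim = 2, seed = 7)
  for (z in 1:2) p$Wg[[z]][[2]] <- p$Wg[[z]][[1]]
  p$Watt[[2]] <- p$Watt[[1]]; p$watt[[2]] <- p$watt[[1]]; p$M[[2]] <- p$M[[1]]
  V <- final_embedding(g, p)
  expect_equal(V$genetics, V$epigenetics)
})

test_that("forward pass agrees with straight-line recomputation", {
  for (seed in 1:3) {
    g <- amhn_fixture(3, 3, NE = 4, seed = seed)
    p <- gatne_init(g, BE = 3, DE = 4, att_dim = 3, K = 2, seed = seed + 10)
    V <- final_embedding(g, p)
    for (i in c(1, 4, 6)) {
      for (r in c(1, 4)) {
        expect_equal(unname(V[[r]][i, ]), oracle_final_embedding(g, p, i, r),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("training is reproducible and keeps attention normalized per epoch", {
  ds <- gen_planted_amhn(planted_config(n_mirna = 8, n_disease = 6, n_blocks = 2,
                                        p_within = 0.6, p_cross = 0.1, seed = 3))
  feats <- tiny_features(8, 6, NE = 4, seed = 2)
  rownames(feats$mirna) <- sprintf("mirna%03d", 1:8)
  rownames(feats$disease) <- sprintf("disease%03d", 1:6)
  g <- build_amhn(ds$associations, feats)
  fit1 <- train_gatne(g, BE = 4, DE = 4, att_dim = 3, epochs = 2, seed = 21)
  fit2 <- train_gatne(g, BE = 4, DE = 4, att_dim = 3, epochs = 2, seed = 21)
  expect_identical(fit1$embeddings, fit2$embeddings)
  # epoch-by-epoch warm start: attention stays a distribution after each epoch
  params <- NULL
  for (ep in 1:3) {
    fit <- train_gatne(g, epochs = 1, init = params %||%
                         gatne_init(g, BE = 4, DE = 4, att_dim = 3, seed = 21),
                       seed = 21 + ep)
    params <- fit$params
    A <- attention_weights(g, params)
    for (r in seq_along(A)) {
      expect_true(all(A[[r]] >= 0))
      expect_equal(unname(rowSums(A[[r]])), rep(1, nrow(A[[r]])), tolerance = 1e-12)
    }
  }
  g0 <- suppressWarnings(build_amhn(tiny_triples()[0, ], tiny_features(2, 2)))
  expect_error(train_gatne(g0, epochs = 1), "empty")
})

test_that("information flows across layers into an empty layer", {
  # layer 1 (genetics) empty; layer 2 (epigenetics) carries two tight blocks.
  # In the empty layer, nodes connected in layer 2 should sit closer together
  # than random node pairs, because cross-layer attention mixes edge
  # embeddings from all layers into each layer's representation.
  wins <- 0
  for (s in 1:10) {
    ds <- gen_planted_amhn(planted_config(n_mirna = 10, n_disease = 8,
                                          n_blocks = 2, p_within = 0.7,
                                          p_cross = 0.05, n_types = 1,
                                          type_correlation = 0, seed = s))
    tri <- ds$associations
    tri$type <- "epigenetics"
    feats <- tiny_features(10, 8, NE = 4, seed = s)
    rownames(feats$mirna) <- sprintf("mirna%03d", 1:10)
    rownames(feats$disease) <- sprintf("disease%03d", 1:8)
    g <- build_amhn(tri, feats, types = c("genetics", "epigenetics"))
    fit <- train_gatne(g, BE = 4, DE = 4, att_dim = 3, epochs = 3, seed = 100 + s)
    V1 <- fit$embeddings$genetics
    conn <- unique(tri[c("mirna", "disease")])
    d_conn <- mean(sqrt(rowSums((V1[conn$mirna, , drop = FALSE] -
                                 V1[conn$disease, , drop = FALSE])^2)))
    set.seed(s)
    rnd <- data.frame(m = sample(rownames(feats$mirna), 200, replace = TRUE),
                      d = sample(rownames(feats$disease), 200, replace = TRUE))
    d_rnd <- mean(sqrt(rowSums((V1[rnd$m, , drop = FALSE] -
                                V1[rnd$d, , drop = FALSE])^2)))
    if (d_conn < d_rnd) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
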