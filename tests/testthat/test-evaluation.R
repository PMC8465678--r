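test_that("rank-based metrics reproduce hand-worked values", {
  # perfect separation
  expect_equal(auc_score(c(.9, .8, .4, .1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(aupr_score(c(.9, .8, .4, .1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(f1_at(c(.9, .8, .4, .1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # all tied -> chance-level ranking
  expect_equal(auc_score(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  # inverted ranking
  expect_equal(auc_score(c(.1, .9), c(TRUE, FALSE)), 0)
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("metrics agree with brute-force threshold sweeps on small tables", {
  set.seed(12)
  for (trial in 1:200) {
    n <- sample(2:8, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    scores <- round(runif(n), sample(c(1, 2), 1))  # coarse grid forces ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
    expect_equal(aupr_score(scores, labels), oracle_aupr(scores, labels))
    expect_equal(f1_at(scores, labels), oracle_f1(scores, labels))
  }
})

test_that("fold assignment partitions with near-equal sizes", {
  f <- assign_folds(23, 10, seed = 4)
  expect_length(f, 23)
  expect_true(all(diff(range(table(f))) <= 1))
  expect_identical(f, assign_folds(23, 10, seed = 4))
  expect_error(assign_folds(5, 10), "fewer")
})

small_planted_data <- function(seed = 5, ctl = NULL) {
  ctl <- ctl %||% mdlinker_control("desk", NE = 8, BE = 8, DE = 8, att_dim = 4,
                                   g_epochs = 1, n2v_epochs = 1,
                                   n2v_walk_length = 15, n2v_walks_per_node = 3,
                                   num_trees = 50, folds = 3)
  ds <- gen_planted_dataset(planted_config(n_mirna = 14, n_disease = 10,
                                           n_blocks = 2, p_within = 0.5,
                                           p_cross = 0.05, seed = seed))
  list(data = mdlinker_prepare(ds$associations, ds$mesh, ds$sequences, ctl,
                               seed = seed),
       ctl = ctl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pair-level cross-validation reports coherent top-1 metrics", {
  sp <- small_planted_data(5)
  rep <- suppressWarnings(cv_type(sp$data, sp$ctl, seed = 2, folds = 3))
  expect_s3_class(rep, "md_metrics")
  expect_equal(nrow(rep$per_fold), 3)
  with(rep$per_fold, {
    expect_true(all(top1_precision >= 0 & top1_precision <= 1))
    expect_true(all(top1_recall >= 0 & top1_recall <= 1))
    expect_equal(top1_precision, hits / n_pairs)
    expect_equal(top1_recall, hits / n_triples)
  })
  # fold units are pairs: every pair's triples all land in one fold
  expect_true(sum(rep$per_fold$n_triples) == nrow(sp$data$triples))
})

test_that("triple-level cross-validation reports AUPR/AUC/F1 within range", {
  sp <- small_planted_data(6)
  rep <- suppressWarnings(cv_triple(sp$data, sp$ctl, seed = 2, folds = 3))
  expect_equal(nrow(rep$per_fold), 3)
  expect_true(all(unlist(rep$per_fold[c("aupr", "auc", "f1")]) >= 0))
  expect_true(all(unlist(rep$per_fold[c("aupr", "auc", "f1")]) <= 1))
  expect_true(all(rep$per_fold$n_neg <= rep$per_fold$n_pos))
  expect_equal(sum(rep$per_fold$n_pos), nrow(sp$data$triples))
})

test_that("cross-validation is a pure function of its seed", {
  sp <- small_planted_data(7)
  r1 <- suppressWarnings(cv_triple(sp$data, sp$ctl, seed = 9, folds = 3))
  r2 <- suppressWarnings(cv_triple(sp$data, sp$ctl, seed = 9, folds = 3))
  expect_identical(r1, r2)
  t1 <- suppressWarnings(cv_type(sp$data, sp$ctl, seed = 9, folds = 3))
  t2 <- suppressWarnings(cv_type(sp$data, sp$ctl, seed = 9, folds = 3))
  expect_identical(t1, t2)
})

test_that("consensus ranking aggregates runs by frequency", {
  sp <- small_planted_data(8)
  top <- consensus_rank(sp$data, sp$ctl, n_runs = 2, k = 5, seed = 3)
  expect_lte(nrow(top), 5)
  expect_true(all(top$frequency >= 1 & top$frequency <= 2))
  expect_true(!is.unsorted(rev(top$frequency)))  # frequency-sorted
  expect_identical(top, consensus_rank(sp$data, sp$ctl, n_runs = 2, k = 5, seed = 3))
  # a single run reduces to that run's top-k by score
  one <- consensus_rank(sp$data, sp$ctl, n_runs = 1, k = 5, seed = 3)
  core <- mdlinker:::fit_core(sp$data$triples, sp$data$features, sp$ctl,
                              mdlinker:::derive_seed(3, "consensus1"))
  sc <- score_triples(core$classifier, core$embeddings, core$unconf)
  best <- sc[order(-sc$score, sc$mirna, sc$disease, sc$type), ][1:5, ]
  expect_setequal(paste(one$mirna, one$disease, one$type),
                  paste(best$mirna, best$disease, best$type))
})
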