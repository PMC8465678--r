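#' Feature vectors for miRNA-disease-type triples
#'
#' The feature of triple (miRNA, disease, type r) is the concatenation of the
#' layer-`r` embedding of the miRNA followed by the layer-`r` embedding of
#' the disease, length `2 * BE`. The same pair under two types gets two
#' distinct vectors because both halves are layer-specific.
#'
#' @param embeddings per-layer embedding matrices (rownames = node names),
#'   e.g. from [train_gatne()].
#' @param triples data frame with columns `mirna`, `disease`, `type`.
#' @return Numeric matrix with one row per triple.
#' @export
make_triple_features <- function(embeddings, triples) {
  BE <- ncol(embeddings[[1]])
  out <- matrix(0, nrow(triples), 2 * BE)
  for (tp in unique(triples$type)) {
    E <- embeddings[[tp]]
    if (is.null(E)) stop("no embeddings for layer: ", tp)
    sel <- which(triples$type == tp)
    mi <- match(triples$mirna[sel], rownames(E))
    di <- match(triples$disease[sel], rownames(E))
    if (anyNA(mi) || anyNA(di)) {
      missing <- unique(c(triples$mirna[sel][is.na(mi)], triples$disease[sel][is.na(di)]))
      stop("no embedding in layer ", tp, " for: ", paste(missing, collapse = ", "))
    }
    out[sel, ] <- cbind(E[mi, , drop = FALSE], E[di, , drop = FALSE])
  }
  out
}

#' Candidate triples not among the known positives
#'
#' Enumerates the full cross-product miRNAs x diseases x types and removes
#' the known triples: the remaining "unconfirmed or non-existent" triples are
#' the universe from which negatives are drawn and for which predictions are
#' made.
#'
#' @param mirnas,diseases entity name vectors.
#' @param known data frame of known positive triples (`mirna`, `disease`,
#'   `type`).
#' @param types type vocabulary; default [association_types()].
#' @return Data frame of candidate triples.
#' @export
candidate_universe <- function(mirnas, diseases, known, types = association_types()) {
  uni <- expand.grid(mirna = mirnas, disease = diseases, type = types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(uni$mirna, uni$disease, uni$type, sep = "\r")
  bad <- key %in% paste(known$mirna, known$disease, known$type, sep = "\r")
  out <- uni[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance-filtered negative candidate pool for one type
#'
#' Computes the mean feature vector `f_avg` of the training positives of one
#' type, measures the Euclidean distance from `f_avg` to every unconfirmed
#' triple of that type, and keeps as eligible negatives exactly those lying
#' strictly farther than the mean distance `dis_r` — triples far from the
#' positive centroid are more reliable negatives.
#'
#' @param pos_features feature matrix of the training positives of the type
#'   (at least one row).
#' @param unconf_features feature matrix of the unconfirmed triples of the
#'   type.
#' @return List of class `"negative_pool"`: `f_avg`, `dis_r` (mean distance),
#'   `distances`, `eligible` (row indices into `unconf_features`). An empty
#'   `unconf_features` yields an empty pool with a warning.
#' @export
build_negative_pool <- function(pos_features, unconf_features) {
  if (nrow(pos_features) < 1) stop("need at least one training positive")
  f_avg <- colMeans(pos_features)
  if (is.null(unconf_features) || nrow(unconf_features) == 0) {
    warning("no unconfirmed triples; empty negative pool")
    return(structure(list(f_avg = f_avg, dis_r = NA_real_,
                          distances = numeric(0), eligible = integer(0)),
                     class = "negative_pool"))
  }
  d <- sqrt(rowSums(sweep(unconf_features, 2, f_avg)^2))
  dis_r <- mean(d)
  structure(list(f_avg = f_avg, dis_r = dis_r, distances = d,
                 eligible = which(d > dis_r)),
            class = "negative_pool")
}

#' Sample negatives from a pool
#'
#' Uniform, without replacement, seeded. When the pool holds fewer than
#' `n_pos` eligible triples, all of them are returned with a warning (the 1:1
#' negative:positive ratio then cannot be met).
#'
#' @param pool a [build_negative_pool()] result.
#' @param n_pos number of negatives requested (the positive count of the
#'   type).
#' @param seed integer seed.
#' @return Integer vector of row indices into the pool's unconfirmed set.
#' @export
sample_negatives <- function(pool, n_pos, seed = 1) {
  if (length(pool$eligible) == 0) stop("empty negative pool")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  if (length(pool$eligible) < n_pos) {
    warning("pool smaller than requested: ", length(pool$eligible), " < ", n_pos)
    return(pool$eligible)
  }
  sort(sample(pool$eligible, n_pos))
}

#' Train the link-type classifier
#'
#' A random forest (500 bagged trees, sqrt-features per split) on the
#' concatenated-embedding features, producing class-probability scores. One
#' shared forest serves all five types — the type is already encoded in the
#' layer-specific embedding halves.
#'
#' @param features numeric feature matrix.
#' @param labels logical or 0/1 vector (TRUE/1 = positive); both classes must
#'   be present.
#' @param num_trees number of trees; default 500.
#' @param seed integer seed.
#' @return A fitted `ranger` probability forest.
#' @export
train_classifier <- function(features, labels, num_trees = 500, seed = 1) {
  y <- factor(ifelse(as.logical(labels), "pos", "neg"), levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2) stop("both classes required to train")
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  ranger::ranger(x = as.data.frame(features), y = y, probability = TRUE,
                 num.trees = num_trees, mtry = max(1, floor(sqrt(ncol(features)))),
                 seed = seed, num.threads = 1)
}

classifier_scores <- function(model, features) {
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  as.numeric(predict(model, data = as.data.frame(features),
                     num.threads = 1)$predictions[, "pos"])
}

#' Score candidate triples
#'
#' @param model classifier from [train_classifier()] (or the per-type list
#'   from [fit_core()] with `per_type = TRUE`).
#' @param embeddings per-layer embedding matrices.
#' @param triples data frame of triples to score (`mirna`, `disease`,
#'   `type`); to score whole pairs use [candidate_universe()] or
#'   `expand.grid` over the five types.
#' @return `triples` with a `score` column of association probabilities in
#'   `[0, 1]`.
#' @export
score_triples <- function(model, embeddings, triples) {
  feats <- make_triple_features(embeddings, triples)
  triples$score <- if (inherits(model, "ranger")) {
    classifier_scores(model, feats)
  } else {
    s <- numeric(nrow(triples))
    for (tp in unique(triples$type)) {
      sel <- triples$type == tp
      s[sel] <- classifier_scores(model[[tp]], feats[sel, , drop = FALSE])
    }
    s
  }
  triples
}

# One full modelling pass on a fixed training triple set: multi-layer graph,
# embedding training, negative selection and classifier fit. `exclude` lists
# triples that must never be sampled as negatives (e.g. held-out positives).
fit_core <- function(train_triples, features, control, seed, exclude = NULL,
                     types = association_types()) {
  graph <- build_amhn(train_triples, features, types)
  emb <- train_gatne(graph,
                     BE = control$BE, DE = control$DE, att_dim = control$att_dim,
                     K = control$K, walk_length = control$g_walk_length,
                     walks_per_node = control$g_walks_per_node,
                     window = control$g_window, negative = control$g_negative,
                     epochs = control$g_epochs, lr = control$g_lr,
                     batch = control$g_batch, aggregator = control$aggregator,
                     train_ab = control$train_ab,
                     seed = derive_seed(seed, "gatne"))
  known <- if (is.null(exclude)) train_triples else
    rbind(train_triples[c("mirna", "disease", "type")],
          exclude[c("mirna", "disease", "type")])
  mirnas <- graph$nodes[graph$type == 1]
  diseases <- graph$nodes[graph$type == 2]
  unconf <- candidate_universe(mirnas, diseases, known, types)
  unconf_feats <- make_triple_features(emb$embeddings, unconf)
  pos_feats <- make_triple_features(emb$embeddings, train_triples)

  pools <- list(); neg_rows <- list()
  for (tp in types) {
    psel <- which(train_triples$type == tp)
    usel <- which(unconf$type == tp)
    if (length(psel) == 0) next
    pool <- build_negative_pool(pos_feats[psel, , drop = FALSE],
                                unconf_feats[usel, , drop = FALSE])
    pool$rows <- usel[pool$eligible]  # row indices into the full candidate set
    pools[[tp]] <- pool
    if (length(pool$eligible))
      neg_rows[[tp]] <- usel[sample_negatives(pool, length(psel),
                                              derive_seed(seed, paste0("neg", tp)))]
  }
  neg_idx <- unlist(neg_rows, use.names = FALSE)
  negatives <- unconf[neg_idx, , drop = FALSE]
  X <- rbind(pos_feats, unconf_feats[neg_idx, , drop = FALSE])
  y <- rep(c(TRUE, FALSE), c(nrow(pos_feats), length(neg_idx)))
  model <- if (isTRUE(control$per_type_classifier)) {
    tri <- rbind(train_triples[c("mirna", "disease", "type")],
                 negatives[c("mirna", "disease", "type")])
    ms <- lapply(types, function(tp) {
      sel <- tri$type == tp
      if (!any(sel & y) || !any(sel & !y)) return(NULL)
      train_classifier(X[sel, , drop = FALSE], y[sel], control$num_trees,
                       derive_seed(seed, paste0("rf", tp)))
    })
    names(ms) <- types
    ms
  } else {
    train_classifier(X, y, control$num_trees, derive_seed(seed, "rf"))
  }
  list(graph = graph, params = emb$params, embeddings = emb$embeddings,
       pools = pools, negatives = negatives, unconf = unconf, classifier = model)
}
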