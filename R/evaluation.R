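#' Area under the ROC curve
#'
#' Tie-aware rank statistic (equivalent to the Wilcoxon-Mann-Whitney
#' estimate): the probability that a random positive scores above a random
#' negative, counting ties as 1/2. All-tied scores give 0.5; perfect
#' separation gives 1.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) true labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("need both classes")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step integration over the distinct score thresholds taken in decreasing
#' order: at each threshold the classifier predicts positive for scores at or
#' above it; the area is the sum of precision times recall increment.
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  if (npos == 0 || npos == length(labels)) stop("need both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); pp <- seq_along(l)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  prec <- tp[last] / pp[last]
  rec <- tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a probability threshold
#'
#' Scores at or above `threshold` are predicted positive. Returns 0 when
#' precision and recall are both undefined or zero.
#'
#' @inheritParams auc_score
#' @param threshold decision threshold; default 0.5.
#' @return F1 in `[0, 1]`.
#' @export
f1_at <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(labels)
  2 * prec * rec / (prec + rec)
}

#' Partition units into cross-validation folds
#'
#' Random partition into `k` folds whose sizes differ by at most one,
#' seeded.
#'
#' @param n number of units.
#' @param k number of folds; default 10.
#' @param seed integer seed.
#' @return Integer vector of fold labels `1..k`, length `n`.
#' @export
assign_folds <- function(n, k = 10, seed = 1) {
  if (n < k) stop("fewer units (", n, ") than folds (", k, ")")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  sample(rep(seq_len(k), length.out = n))
}

#' Pair-level cross-validation (CV-Type)
#'
#' Known miRNA-disease pairs are split into `folds` parts. For each fold, the
#' model is refit on the triples of the training pairs only (embeddings
#' retrained per fold, so no test edge ever influences training); each test
#' pair's five type scores are then ranked and the top-ranked type counts as
#' a hit when it is one of the pair's true types (score ties broken by the
#' canonical type order). Top-1 precision is hits over test pairs, top-1
#' recall is hits over true test triples, and top-1 F1 their harmonic mean.
#'
#' @param data an [mdlinker_prepare()] object.
#' @param control an [mdlinker_control()] list.
#' @param seed integer seed governing folds, embedding training and negative
#'   sampling.
#' @param folds number of folds; default `control$folds`.
#' @return Object of class `"md_metrics"` with per-fold and mean top-1
#'   precision/recall/F1.
#' @export
cv_type <- function(data, control = data$control, seed = 1, folds = control$folds) {
  triples <- data$triples
  pairs <- unique(triples[c("mirna", "disease")])
  rownames(pairs) <- NULL
  fold <- assign_folds(nrow(pairs), folds, derive_seed(seed, "cvtype_folds"))
  pair_key <- paste(pairs$mirna, pairs$disease, sep = "\r")
  tri_pair <- match(paste(triples$mirna, triples$disease, sep = "\r"), pair_key)
  types <- association_types()
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_pairs <- which(fold == f)
    train_tri <- triples[!(tri_pair %in% test_pairs), , drop = FALSE]
    test_tri <- triples[tri_pair %in% test_pairs, , drop = FALSE]
    core <- fit_core(train_tri, data$features, control,
                     derive_seed(seed, paste0("cvtype", f)), exclude = test_tri)
    query <- data.frame(
      mirna = rep(pairs$mirna[test_pairs], each = length(types)),
      disease = rep(pairs$disease[test_pairs], each = length(types)),
      type = rep(types, length(test_pairs)), stringsAsFactors = FALSE)
    sc <- score_triples(core$classifier, core$embeddings, query)
    hits <- 0
    for (ii in seq_along(test_pairs)) {
      block <- sc[((ii - 1) * length(types) + 1):(ii * length(types)), ]
      top <- block$type[which.max(block$score)]  # first max = canonical order
      truth <- triples$type[tri_pair == test_pairs[ii]]
      hits <- hits + (top %in% truth)
    }
    prec <- hits / length(test_pairs)
    rec <- hits / nrow(test_tri)
    rows[[f]] <- data.frame(fold = f, n_pairs = length(test_pairs),
                            n_triples = nrow(test_tri), hits = hits,
                            top1_precision = prec, top1_recall = rec,
                            top1_f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(mode = "cv_type", per_fold = per_fold,
                 mean = colMeans(per_fold[c("top1_precision", "top1_recall", "top1_f1")])),
            class = "md_metrics")
}

#' Triple-level cross-validation (CV-Triple)
#'
#' Known miRNA-disease-type triples are split into `folds` parts. For each
#' fold the model is refit on the remaining triples; the held-out positives
#' are scored together with an equal number of seeded negatives per type,
#' drawn from the distance-filtered pool (never overlapping the training
#' negatives nor any known positive). AUC (tie-aware rank statistic), AUPR
#' (step integration) and F1 at threshold 0.5 are reported per fold with
#' their means.
#'
#' @inheritParams cv_type
#' @return Object of class `"md_metrics"` with per-fold and mean AUPR, AUC
#'   and F1.
#' @export
cv_triple <- function(data, control = data$control, seed = 1, folds = control$folds) {
  triples <- data$triples
  if (nrow(triples) < folds) stop("fewer triples than folds")
  fold <- assign_folds(nrow(triples), folds, derive_seed(seed, "cvtriple_folds"))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    train_tri <- triples[fold != f, , drop = FALSE]
    test_tri <- triples[fold == f, , drop = FALSE]
    core <- fit_core(train_tri, data$features, control,
                     derive_seed(seed, paste0("cvtriple", f)), exclude = test_tri)
    # test negatives: per type, equal to the test positives, from the pool,
    # disjoint from the training negatives
    used <- paste(core$negatives$mirna, core$negatives$disease, core$negatives$type, sep = "\r")
    neg_list <- list()
    for (tp in unique(test_tri$type)) {
      pool <- core$pools[[tp]]
      if (is.null(pool) || length(pool$rows) == 0) next
      cand <- core$unconf[pool$rows, , drop = FALSE]
      avail <- which(!(paste(cand$mirna, cand$disease, cand$type, sep = "\r") %in% used))
      n_want <- sum(test_tri$type == tp)
      old <- local_rng(derive_seed(seed, paste0("testneg", f, tp)))
      pick <- if (length(avail) <= n_want) avail else sample(avail, n_want)
      restore_rng(old)
      neg_list[[tp]] <- cand[pick, , drop = FALSE]
    }
    test_neg <- do.call(rbind, neg_list)
    sc_pos <- score_triples(core$classifier, core$embeddings, test_tri)
    sc_neg <- score_triples(core$classifier, core$embeddings, test_neg)
    scores <- c(sc_pos$score, sc_neg$score)
    labels <- rep(c(TRUE, FALSE), c(nrow(sc_pos), nrow(sc_neg)))
    rows[[f]] <- data.frame(fold = f, n_pos = nrow(sc_pos), n_neg = nrow(sc_neg),
                            aupr = aupr_score(scores, labels),
                            auc = auc_score(scores, labels),
                            f1 = f1_at(scores, labels))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(mode = "cv_triple", per_fold = per_fold,
                 mean = colMeans(per_fold[c("aupr", "auc", "f1")])),
            class = "md_metrics")
}

#' Consensus ranking of novel triples over repeated runs
#'
#' Because walk sampling makes single runs stochastic, the model is refit
#' `n_runs` times under distinct derived seeds; each run contributes its
#' `2 * k` highest-scoring unconfirmed triples, and candidates are ranked by
#' how often they appear across runs (ties broken by mean probability). The
#' top `k` by consensus frequency are returned.
#'
#' @inheritParams cv_type
#' @param n_runs number of refits; default 50.
#' @param k size of the returned list; default 20.
#' @return Data frame of the top-`k` triples with columns `mirna`, `disease`,
#'   `type`, `frequency` (runs containing the triple in their top list) and
#'   `mean_score`.
#' @export
consensus_rank <- function(data, control = data$control, n_runs = 50, k = 20,
                           seed = 1) {
  tally <- list()
  for (run in seq_len(n_runs)) {
    core <- fit_core(data$triples, data$features, control,
                     derive_seed(seed, paste0("consensus", run)))
    sc <- score_triples(core$classifier, core$embeddings, core$unconf)
    ord <- order(-sc$score, sc$mirna, sc$disease, sc$type)
    top <- sc[ord[seq_len(min(2 * k, nrow(sc)))], , drop = FALSE]
    top$key <- paste(top$mirna, top$disease, top$type, sep = "\r")
    tally[[run]] <- top
  }
  all_top <- do.call(rbind, tally)
  freq <- table(all_top$key)
  msc <- tapply(all_top$score, all_top$key, mean)
  keys <- names(freq)
  ord <- order(-as.integer(freq), -as.numeric(msc[keys]), keys)
  keys <- keys[ord][seq_len(min(k, length(keys)))]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(mirna = vapply(parts, `[`, "", 1),
             disease = vapply(parts, `[`, "", 2),
             type = vapply(parts, `[`, "", 3),
             frequency = as.integer(freq[keys]),
             mean_score = as.numeric(msc[keys]),
             stringsAsFactors = FALSE)
}

#' @export
print.md_metrics <- function(x, ...) {
  cat("Cross-validation report (", x$mode, "), ",
      nrow(x$per_fold), " folds\n", sep = "")
  cat("Mean metrics:\n")
  print(round(x$mean, 4))
  invisible(x)
}
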