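#' Pipeline hyperparameters
#'
#' Collects every tunable parameter of the pipeline. The `"paper"` profile
#' uses the settings of the original study (attribute dimension `NE = 128`,
#' edge and base embedding dimensions `DE = BE = 32`, walk bias `p = 1`,
#' `q = 2`, ancestor decay `alpha = 0.5`); the `"desk"` profile shrinks the
#' embedding dimensions and training effort for small synthetic data sets so
#' a full cross-validation runs in seconds on one CPU. Any field can be
#' overridden by name.
#'
#' @param profile `"paper"` (default) or `"desk"`.
#' @param ... named overrides of individual fields.
#' @return Named list of class `"mdlinker_control"`.
#' @export
mdlinker_control <- function(profile = c("paper", "desk"), ...) {
  profile <- match.arg(profile)
  ctl <- list(
    # similarity
    alpha = 0.5, cgr_k = 3,
    # node attribute features (biased walks + skip-gram)
    NE = 128, p = 1, q = 2, n2v_walk_length = 80, n2v_walks_per_node = 10,
    n2v_window = 5, n2v_negative = 5, n2v_epochs = 5, n2v_lr = 0.025,
    sparsify_k = NULL,
    # multi-layer embedding
    BE = 32, DE = 32, att_dim = 16, K = 2, g_walk_length = 10,
    g_walks_per_node = 20, g_window = 5, g_negative = 5, g_epochs = 5,
    g_lr = 0.025, g_batch = 64, aggregator = "mean", train_ab = FALSE,
    # classifier and evaluation
    num_trees = 500, per_type_classifier = FALSE, folds = 10
  )
  if (profile == "desk") {
    ctl[c("NE", "n2v_walk_length", "n2v_walks_per_node", "n2v_epochs",
          "BE", "DE", "att_dim", "g_walks_per_node", "g_batch")] <-
      list(32, 40, 5, 3, 16, 16, 8, 5, 512)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(ctl))
  if (length(bad)) stop("unknown control field(s): ", paste(bad, collapse = ", "))
  ctl[names(over)] <- over
  structure(ctl, class = "mdlinker_control")
}

#' Prepare a data set: filtering, similarities and node attributes
#'
#' Runs the deterministic and fold-independent part of the pipeline once:
#' restricts to entities present in all inputs, builds the disease hierarchy
#' and semantic similarity matrix, the CGR sequence similarity matrix, and
#' the per-class node attribute vectors from biased random walks. The result
#' feeds [mdlinker()], [cv_type()], [cv_triple()] and [consensus_rank()]
#' without recomputation (the similarity networks involve no association
#' edges, so they are safe to share across cross-validation folds).
#'
#' @param associations association records (data frame from
#'   [read_associations()] or [gen_planted_amhn()]).
#' @param mesh disease tree codes ([read_mesh()] / [gen_mesh_tree()]).
#' @param sequences miRNA sequences ([read_fasta()] / [gen_sequences()]).
#' @param control an [mdlinker_control()] list.
#' @param seed integer master seed.
#' @return Object of class `"mdlinker_data"`: `inputs`, `dag`, `sim_mirna`,
#'   `sim_disease`, `features` (list `mirna`, `disease`), `triples`,
#'   `control`, `seed`.
#' @export
mdlinker_prepare <- function(associations, mesh, sequences,
                             control = mdlinker_control(), seed = 1) {
  inputs <- intersect_entities(associations, mesh, sequences)
  if (length(inputs$mirnas) < 2 || length(inputs$diseases) < 2)
    stop("need at least 2 miRNAs and 2 diseases after intersection")
  dag <- build_dag(inputs$mesh, alpha = control$alpha)
  sim_d <- disease_similarity_matrix(dag, inputs$diseases)
  seqs <- inputs$sequences[match(inputs$mirnas, inputs$sequences$mirna), , drop = FALSE]
  sim_m <- mirna_similarity(seqs, k = control$cgr_k)
  nf <- function(S, stream) {
    node_features(S, dim = control$NE, p = control$p, q = control$q,
                  walk_length = control$n2v_walk_length,
                  walks_per_node = control$n2v_walks_per_node,
                  window = control$n2v_window, negative = control$n2v_negative,
                  epochs = control$n2v_epochs, lr = control$n2v_lr,
                  sparsify_k = control$sparsify_k,
                  seed = derive_seed(seed, stream))
  }
  features <- list(mirna = nf(sim_m, "feat_mirna"), disease = nf(sim_d, "feat_disease"))
  structure(list(inputs = inputs, dag = dag, sim_mirna = sim_m,
                 sim_disease = sim_d, features = features,
                 triples = inputs$associations, control = control, seed = seed),
            class = "mdlinker_data")
}

#' Fit the miRNA-disease association-type model
#'
#' Full pipeline fit on all confirmed triples: attribute features from the
#' similarity networks, multi-layer heterogeneous network embedding over the
#' five association-type layers, distance-filtered 1:1 negative sampling, and
#' a random-forest classifier on concatenated endpoint embeddings. The
#' returned object scores any (miRNA, disease, type) candidate via
#' [predict.mdlinker()].
#'
#' @inheritParams mdlinker_prepare
#' @param data optionally a precomputed [mdlinker_prepare()] object; when
#'   given, `associations`/`mesh`/`sequences` are ignored.
#' @return Object of class `"mdlinker"`.
#' @export
mdlinker <- function(associations, mesh, sequences,
                     control = mdlinker_control(), seed = 1, data = NULL) {
  if (is.null(data))
    data <- mdlinker_prepare(associations, mesh, sequences, control, seed)
  core <- fit_core(data$triples, data$features, data$control,
                   derive_seed(seed, "fit"))
  structure(c(list(data = data, control = data$control, seed = seed), core),
            class = "mdlinker")
}

#' Score candidate triples with a fitted model
#'
#' @param object a fitted [mdlinker()] model.
#' @param pairs optional data frame with columns `mirna`, `disease`; default:
#'   every miRNA x disease pair in the model. Each pair is scored under all
#'   five types.
#' @param ... unused.
#' @return Data frame (`mirna`, `disease`, `type`, `score`, `known`) with one
#'   row per pair and type; `score` is the predicted association probability
#'   and `known` flags triples already in the training data.
#' @export
predict.mdlinker <- function(object, pairs = NULL, ...) {
  types <- association_types()
  if (is.null(pairs)) {
    pairs <- expand.grid(mirna = object$graph$nodes[object$graph$type == 1],
                         disease = object$graph$nodes[object$graph$type == 2],
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  query <- data.frame(mirna = rep(pairs$mirna, each = length(types)),
                      disease = rep(pairs$disease, each = length(types)),
                      type = rep(types, nrow(pairs)), stringsAsFactors = FALSE)
  sc <- score_triples(object$classifier, object$embeddings, query)
  known <- paste(object$data$triples$mirna, object$data$triples$disease,
                 object$data$triples$type, sep = "\r")
  sc$known <- paste(sc$mirna, sc$disease, sc$type, sep = "\r") %in% known
  sc
}

#' @export
print.mdlinker <- function(x, ...) {
  g <- x$graph
  cat("Multi-layer miRNA-disease association-type model\n")
  cat(sprintf("  %d miRNAs, %d diseases, %d confirmed triples\n",
              sum(g$type == 1), sum(g$type == 2), nrow(x$data$triples)))
  ec <- vapply(g$layers, nrow, integer(1))
  cat("  edges per layer:", paste(sprintf("%s=%d", names(ec), ec), collapse = ", "), "\n")
  cat(sprintf("  dims: NE=%d BE=%d DE=%d, aggregation depth K=%d\n",
              x$control$NE, x$control$BE, x$control$DE, x$control$K))
  invisible(x)
}

#' @export
summary.mdlinker <- function(object, ...) {
  tt <- table(object$data$triples$type)
  cat("Confirmed triples per type:\n")
  print(tt)
  cat("\nNegative pools (eligible / threshold dis_r):\n")
  for (tp in names(object$pools)) {
    p <- object$pools[[tp]]
    cat(sprintf("  %-12s %6d eligible, dis_r = %.4f\n",
                tp, length(p$eligible), p$dis_r))
  }
  cat("\nTraining negatives:", nrow(object$negatives), "\n")
  invisible(object)
}

#' Attention-weight overview plot
#'
#' Boxplots of the cross-layer attention weights each layer's embeddings put
#' on the five source layers — a view of how much information each
#' association type borrows from the others.
#'
#' @param x a fitted [mdlinker()] model.
#' @param layer layer (type name) whose attention head to show; default the
#'   first type.
#' @param ... passed to [graphics::boxplot()].
#' @return The attention matrix, invisibly.
#' @export
plot.mdlinker <- function(x, layer = association_types()[1], ...) {
  A <- attention_weights(x$graph, x$params)[[layer]]
  graphics::boxplot(as.data.frame(A), ylab = "attention weight",
                    xlab = "source layer",
                    main = paste("attention of layer", layer), ...)
  invisible(A)
}
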