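#' Build the attributed multi-layer heterogeneous network
#'
#' Nodes are the miRNAs and diseases of the feature tables; each association
#' type is one layer holding the bipartite miRNA-disease edges of that type.
#' The node set (and each node's attribute vector) is shared across layers —
#' layers differ only in their edge sets.
#'
#' @param records an `"md_associations"` data frame (miRNA, disease, type).
#'   Every referenced entity must have a feature vector.
#' @param features list with elements `mirna` and `disease`: feature matrices
#'   with entity rownames and a common column count `NE`.
#' @param types layer vocabulary; default [association_types()].
#' @return Object of class `"amhn"`: list with `nodes` (names, miRNAs first),
#'   `type` (1 = miRNA, 2 = disease per node), `X` (node-by-NE attribute
#'   matrix), `types`, `layers` (per type, a 2-column index matrix of edges),
#'   `nbrs` (per type, per node, neighbor indices).
#' @export
build_amhn <- function(records, features, types = association_types()) {
  Xm <- as.matrix(features$mirna)
  Xd <- as.matrix(features$disease)
  if (ncol(Xm) != ncol(Xd)) stop("miRNA and disease features must share NE")
  nodes <- c(rownames(Xm), rownames(Xd))
  if (anyDuplicated(nodes)) stop("duplicate node names across classes")
  ztype <- rep(1:2, c(nrow(Xm), nrow(Xd)))
  X <- rbind(Xm, Xd)
  if (nrow(records) == 0) warning("no association records; all layers empty")
  miss <- setdiff(c(unique(records$mirna), unique(records$disease)), nodes)
  if (length(miss)) stop("node(s) without feature vector: ", paste(miss, collapse = ", "))
  bad <- !(records$type %in% types)
  if (any(bad)) stop("unknown type(s): ", paste(unique(records$type[bad]), collapse = ", "))
  mi <- match(records$mirna, nodes)
  di <- match(records$disease, nodes)
  layers <- lapply(types, function(tp) {
    sel <- which(records$type == tp)
    e <- cbind(mirna = mi[sel], disease = di[sel])
    e[!duplicated(e), , drop = FALSE]
  })
  names(layers) <- types
  nbrs <- lapply(layers, function(e) {
    nl <- rep(list(integer(0)), length(nodes))
    if (nrow(e)) {
      for (k in seq_len(nrow(e))) {
        nl[[e[k, 1]]] <- c(nl[[e[k, 1]]], e[k, 2])
        nl[[e[k, 2]]] <- c(nl[[e[k, 2]]], e[k, 1])
      }
      nl <- lapply(nl, function(v) sort(unique(v)))
    }
    nl
  })
  structure(list(nodes = nodes, type = ztype, X = X, types = types,
                 layers = layers, nbrs = nbrs),
            class = "amhn")
}

#' Initialize embedding parameters
#'
#' Creates the trainable parameter set: per node class, the base transform
#' (`NE x BE`) and attribute transform (`NE x BE`); per (class, layer), the
#' initial edge-embedding transform (`NE x DE`); per layer, the attention
#' head (`att_dim x DE` and `att_dim`) and the edge-to-base map (`DE x BE`);
#' plus per-layer scalars `alpha` (edge-embedding weight) and `beta`
#' (attribute weight), and one context vector per node for the skip-gram
#' objective. Transform weights start at small seeded uniforms, contexts at
#' zero, `alpha = beta = 1`.
#'
#' @param graph an [build_amhn()] object.
#' @param BE base embedding dimension; default 32.
#' @param DE edge embedding dimension; default 32.
#' @param att_dim attention hidden dimension; default 16.
#' @param K neighbor-aggregation depth; default 2.
#' @param aggregator neighbor aggregation: `"mean"` (mean then tanh, default)
#'   or `"max"` (elementwise max then tanh).
#' @param seed integer seed.
#' @return List of class `"gatne_params"`.
#' @export
gatne_init <- function(graph, BE = 32, DE = 32, att_dim = 16, K = 2,
                       aggregator = c("mean", "max"), seed = 1) {
  aggregator <- match.arg(aggregator)
  old <- local_rng(derive_seed(seed, "gatne_init"))
  on.exit(restore_rng(old))
  NE <- ncol(graph$X)
  R <- length(graph$types)
  n <- length(graph$nodes)
  rmat <- function(a, b) matrix(runif(a * b, -0.05, 0.05), a, b)
  p <- list(
    Wh = lapply(1:2, function(z) rmat(NE, BE)),
    bh = lapply(1:2, function(z) numeric(BE)),
    Wg = lapply(1:2, function(z) lapply(seq_len(R), function(r) rmat(NE, DE))),
    bg = lapply(1:2, function(z) lapply(seq_len(R), function(r) numeric(DE))),
    Watt = lapply(seq_len(R), function(r) rmat(att_dim, DE)),
    watt = lapply(seq_len(R), function(r) as.numeric(rmat(att_dim, 1))),
    M = lapply(seq_len(R), function(r) rmat(DE, BE)),
    Dz = lapply(1:2, function(z) rmat(NE, BE)),
    alpha = rep(1, R),
    beta = rep(1, R),
    Ctx = matrix(0, n, BE),
    BE = BE, DE = DE, att_dim = att_dim, K = K, n_layers = R,
    aggregator = aggregator
  )
  class(p) <- "gatne_params"
  p
}

#' Aggregated edge embeddings of one layer
#'
#' Level 0 is the per-node transform of the attribute vector,
#' `g_{z,r}(x_i)`; level `k` replaces each connected node's value by the
#' elementwise `tanh` of the mean of its layer-`r` neighbors' level-`k-1`
#' values. A node with no neighbors in the layer keeps its level-`k-1` value
#' unchanged, so every node carries an edge embedding in every layer.
#'
#' @param graph an [build_amhn()] object.
#' @param params a [gatne_init()] parameter set.
#' @param r layer index or type name.
#' @param K aggregation depth; defaults to `params$K`.
#' @param all_levels if `TRUE`, return the list of all levels `0..K`.
#' @return `n x DE` matrix of level-`K` edge embeddings (or list of levels).
#' @export
aggregate_edge_embedding <- function(graph, params, r, K = params$K,
                                     all_levels = FALSE) {
  if (is.character(r)) r <- match(r, graph$types)
  n <- length(graph$nodes)
  max_pool <- identical(params$aggregator, "max")
  d <- matrix(0, n, params$DE)
  for (z in 1:2) {
    sel <- graph$type == z
    d[sel, ] <- graph$X[sel, , drop = FALSE] %*% params$Wg[[z]][[r]] +
      rep(params$bg[[z]][[r]], each = sum(sel))
  }
  levels <- list(d)
  nb <- graph$nbrs[[r]]
  if (K > 0) for (k in seq_len(K)) {
    prev <- levels[[k]]
    cur <- prev
    for (i in seq_len(n)) {
      if (length(nb[[i]])) {
        agg <- if (max_pool) apply(prev[nb[[i]], , drop = FALSE], 2, max)
               else colMeans(prev[nb[[i]], , drop = FALSE])
        cur[i, ] <- tanh(agg)
      }
    }
    levels[[k + 1]] <- cur
  }
  if (all_levels) levels else levels[[K + 1]]
}

#' Cross-layer self-attention combination
#'
#' Mixes a node's aggregated edge embeddings from all layers into the
#' layer-`r` correction term: attention weights
#' `a = softmax(w_r' tanh(W_r D_i))` over the layers, then
#' `u = alpha_r * M_r' (D_i a)`. Weights are nonnegative and sum to 1; with a
#' zero attention matrix every layer receives weight `1/m`.
#'
#' @param params a [gatne_init()] parameter set.
#' @param Di `DE x m` matrix whose columns are one node's aggregated edge
#'   embeddings across the `m` layers.
#' @param r target layer index.
#' @return List with `a` (attention weights, length `m`) and `u` (the
#'   combined vector in base-embedding space, length `BE`).
#' @export
attention_combine <- function(params, Di, r) {
  if (nrow(Di) != params$DE) stop("Di must be DE x m")
  s <- drop(crossprod(params$watt[[r]], tanh(params$Watt[[r]] %*% Di)))
  a <- exp(s - max(s))
  a <- a / sum(a)
  u <- params$alpha[r] * drop(crossprod(params$M[[r]], Di %*% a))
  list(a = as.numeric(a), u = u)
}

#' Per-layer node embeddings
#'
#' The final representation of node `i` on layer `r` sums three parts: the
#' attribute term `beta_r * Dz' x_i`, the layer-shared base embedding
#' `b_i = h_z(x_i)`, and the attention-combined edge term `u_{i,r}`.
#'
#' @param graph an [build_amhn()] object.
#' @param params a [gatne_init()] (or trained) parameter set.
#' @param r optional layer selection (indices or names); default all layers.
#' @return List (per layer) of `n x BE` matrices with node rownames.
#' @export
final_embedding <- function(graph, params, r = NULL) {
  R <- length(graph$types)
  rs <- if (is.null(r)) seq_len(R) else if (is.character(r)) match(r, graph$types) else r
  n <- length(graph$nodes)
  dK <- lapply(seq_len(R), function(rr) aggregate_edge_embedding(graph, params, rr))
  base <- matrix(0, n, params$BE)
  attr <- matrix(0, n, params$BE)
  for (z in 1:2) {
    sel <- graph$type == z
    base[sel, ] <- graph$X[sel, , drop = FALSE] %*% params$Wh[[z]] +
      rep(params$bh[[z]], each = sum(sel))
    attr[sel, ] <- graph$X[sel, , drop = FALSE] %*% params$Dz[[z]]
  }
  out <- lapply(rs, function(rr) {
    V <- matrix(0, n, params$BE, dimnames = list(graph$nodes, NULL))
    for (i in seq_len(n)) {
      Di <- vapply(dK, function(m) m[i, ], numeric(params$DE))
      att <- attention_combine(params, Di, rr)
      V[i, ] <- params$beta[rr] * attr[i, ] + base[i, ] + att$u
    }
    V
  })
  names(out) <- graph$types[rs]
  out
}

#' Attention weights of every node on every layer
#'
#' @inheritParams final_embedding
#' @return List (per layer) of `n x m` matrices of attention weights; each
#'   row is nonnegative and sums to 1.
#' @export
attention_weights <- function(graph, params) {
  R <- length(graph$types)
  dK <- lapply(seq_len(R), function(rr) aggregate_edge_embedding(graph, params, rr))
  n <- length(graph$nodes)
  out <- lapply(seq_len(R), function(rr) {
    A <- matrix(0, n, R, dimnames = list(graph$nodes, graph$types))
    for (i in seq_len(n)) {
      Di <- vapply(dK, function(m) m[i, ], numeric(params$DE))
      A[i, ] <- attention_combine(params, Di, rr)$a
    }
    A
  })
  names(out) <- graph$types
  out
}

#' Train the multi-layer embedding
#'
#' Generates within-layer meta-path walks (miRNA and disease nodes alternate
#' because every layer is bipartite), then optimizes all parameters by
#' skip-gram with negative sampling: for a center node the layer-`r`
#' representation `v_{i,r}` is scored against context embeddings of nearby
#' walk nodes, with negatives drawn per context from the same node class's
#' unigram^(3/4) distribution. Stochastic-gradient training is seeded and
#' single-threaded, hence reproducible.
#'
#' @param graph an [build_amhn()] object with at least one non-empty layer.
#' @param BE,DE,att_dim,K architecture, see [gatne_init()].
#' @param walk_length,walks_per_node meta-path walk shape; defaults 10 and 20.
#' @param window skip-gram window; default 5.
#' @param negative negatives per positive; default 5.
#' @param epochs training passes; default 5.
#' @param lr initial learning rate; default 0.025.
#' @param batch centers per synchronous parameter flush; default 64.
#' @param aggregator neighbor aggregation, `"mean"` or `"max"`; see
#'   [gatne_init()].
#' @param train_ab if `TRUE`, the per-layer scalars `alpha`, `beta` are
#'   trained; by default they stay fixed at 1.
#' @param init optional warm-start `"gatne_params"` (e.g. to continue
#'   training); overrides the architecture arguments.
#' @param seed integer seed.
#' @return List with `params` (trained `"gatne_params"`) and `embeddings`
#'   (per-layer `n x BE` matrices from [final_embedding()]).
#' @export
train_gatne <- function(graph, BE = 32, DE = 32, att_dim = 16, K = 2,
                        walk_length = 10, walks_per_node = 20, window = 5,
                        negative = 5, epochs = 5, lr = 0.025, batch = 64,
                        aggregator = c("mean", "max"), train_ab = FALSE,
                        init = NULL, seed = 1) {
  if (all(vapply(graph$layers, nrow, integer(1)) == 0))
    stop("all layers are empty; nothing to train on")
  params <- init %||% gatne_init(graph, BE, DE, att_dim, K,
                                 match.arg(aggregator), seed)
  walks <- lapply(seq_along(graph$types), function(r) {
    mp_walks_cpp(graph$nbrs[[r]], walk_length, walks_per_node,
                 derive_seed(seed, paste0("mp", r)))
  })
  upd <- gatne_train_cpp(graph$X, graph$type, graph$nbrs, walks, params,
                         params$K, window, negative, epochs, lr, batch,
                         derive_seed(seed, "gatne_sgd"), train_ab,
                         identical(params$aggregator, "max"))
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  list(params = params, embeddings = final_embedding(graph, params))
}
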