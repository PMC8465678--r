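#' Second-order biased transition distribution
#'
#' Given the previous node `t` and current node `v` of a walk on a weighted
#' graph, the unnormalized probability of stepping to neighbor `x` is
#' `alpha_pq(t, x) * w_vx`, where `alpha_pq` is `1/p` when `x == t` (distance
#' 0), `1` when `x` is also a neighbor of `t` (distance 1) and `1/q`
#' otherwise (distance 2). The first step of a walk (`t = NULL`) samples
#' neighbors proportionally to edge weight alone. Return parameter `p`
#' controls immediate backtracking, in-out parameter `q` the preference for
#' breadth-first (`q > 1`) versus depth-first exploration.
#'
#' @param W symmetric nonnegative weight matrix; the diagonal is ignored
#'   (no self-loops).
#' @param v current node (index or name).
#' @param t previous node, or `NULL` for the first step.
#' @param p return parameter (> 0); default 1.
#' @param q in-out parameter (> 0); default 2.
#' @return Named numeric vector of probabilities over the neighbors of `v`
#'   (empty if `v` is isolated), summing to 1.
#' @export
transition_probs <- function(W, v, t = NULL, p = 1, q = 2) {
  stopifnot(p > 0, q > 0)
  if (is.character(v)) v <- match(v, rownames(W))
  if (!is.null(t) && is.character(t)) t <- match(t, rownames(W))
  w <- W[v, ]
  w[v] <- 0
  nbrs <- which(w > 0)
  if (length(nbrs) == 0) return(setNames(numeric(0), character(0)))
  wt <- w[nbrs]
  if (!is.null(t)) {
    a <- vapply(nbrs, function(x) {
      if (x == t) 1 / p
      else if (x != t && W[t, x] > 0) 1
      else 1 / q
    }, numeric(1))
    wt <- wt * a
  }
  pr <- wt / sum(wt)
  names(pr) <- if (!is.null(rownames(W))) rownames(W)[nbrs] else as.character(nbrs)
  pr
}

#' Generate a biased random-walk corpus
#'
#' Runs `walks_per_node` second-order biased walks of length `walk_length`
#' from every node, following the transition law of [transition_probs()].
#' Walks starting at an isolated node consist of that node alone. The corpus
#' is a pure function of the seed.
#'
#' @inheritParams transition_probs
#' @param walk_length walk length in nodes.
#' @param walks_per_node number of walks started per node.
#' @param seed integer seed.
#' @return List of integer vectors of node indices (1-based).
#' @export
generate_walks <- function(W, walk_length = 80, walks_per_node = 10,
                           p = 1, q = 2, seed = 1) {
  stopifnot(nrow(W) == ncol(W), p > 0, q > 0)
  nv_walks_cpp(unname(as.matrix(W)), walk_length, walks_per_node, p, q,
               as.integer(seed))
}

#' Train node features by skip-gram with negative sampling
#'
#' Learns one `dim`-dimensional vector per node from a random-walk corpus so
#' that nodes co-occurring within `window` positions get nearby vectors
#' (negative examples drawn from the unigram distribution raised to 3/4).
#' Nodes absent from every walk keep a zero vector and trigger a warning.
#'
#' @param walks corpus from [generate_walks()].
#' @param n_nodes number of nodes in the graph.
#' @param dim embedding dimension; default 128.
#' @param window skip-gram context window; default 5.
#' @param negative negative samples per positive pair; default 5.
#' @param epochs passes over the corpus; default 5.
#' @param lr initial learning rate, linearly decayed; default 0.025.
#' @param seed integer seed.
#' @param labels optional node names for the rownames of the result.
#' @return `n_nodes x dim` numeric matrix.
#' @export
train_features <- function(walks, n_nodes, dim = 128, window = 5, negative = 5,
                           epochs = 5, lr = 0.025, seed = 1, labels = NULL) {
  if (length(walks) == 0) stop("empty walk corpus")
  emb <- sgns_cpp(walks, as.integer(n_nodes), as.integer(dim), as.integer(window),
                  as.integer(negative), as.integer(epochs), lr, as.integer(seed))
  seen <- sort(unique(unlist(walks)))
  absent <- setdiff(seq_len(n_nodes), seen)
  if (length(absent)) {
    warning(length(absent), " node(s) absent from all walks; zero feature vector assigned")
    emb[absent, ] <- 0
  }
  if (!is.null(labels)) rownames(emb) <- labels
  emb
}

#' Node attribute vectors from a similarity network
#'
#' End-to-end feature construction for one node class: biased second-order
#' random walks on the weighted similarity graph followed by skip-gram
#' training. Nodes with higher similarity end up with closer feature vectors.
#'
#' @param S similarity matrix (symmetric, unit diagonal) with dimnames.
#' @param dim feature dimension `NE`; default 128.
#' @param p,q walk bias parameters; defaults 1 and 2.
#' @param walk_length,walks_per_node,window,negative,epochs,lr skip-gram and
#'   walk settings, see [generate_walks()] and [train_features()].
#' @param sparsify_k optionally keep only the top-`k` neighbors of each node
#'   (union-symmetrized) before walking; `NULL` (default) walks the full
#'   weighted graph.
#' @param seed integer seed controlling walks and training.
#' @return Matrix of node features with rownames from `S`.
#' @export
node_features <- function(S, dim = 128, p = 1, q = 2, walk_length = 80,
                          walks_per_node = 10, window = 5, negative = 5,
                          epochs = 5, lr = 0.025, sparsify_k = NULL, seed = 1) {
  if (!is.null(sparsify_k)) S <- sparsify_topk(S, sparsify_k)
  walks <- generate_walks(S, walk_length, walks_per_node, p, q,
                          seed = derive_seed(seed, "walks"))
  train_features(walks, n_nodes = nrow(S), dim = dim, window = window,
                 negative = negative, epochs = epochs, lr = lr,
                 seed = derive_seed(seed, "sgns"), labels = rownames(S))
}

#' Keep the strongest k neighbors of each node
#'
#' Zeroes all but the `k` largest off-diagonal weights per row, then
#' symmetrizes by union (an edge survives if either endpoint kept it).
#'
#' @param S symmetric weight matrix.
#' @param k neighbors to keep per node.
#' @return Sparsified symmetric matrix with the original diagonal.
#' @export
sparsify_topk <- function(S, k) {
  n <- nrow(S)
  M <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    w <- S[i, ]
    w[i] <- -Inf
    keep <- order(w, decreasing = TRUE)[seq_len(min(k, n - 1))]
    M[i, keep] <- S[i, keep]
  }
  M <- pmax(M, t(M))
  diag(M) <- diag(S)
  M
}
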