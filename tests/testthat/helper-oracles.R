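# Independent reference implementations used to cross-check the package.
# These deliberately avoid the package's code paths and data structures.

# --- disease semantic similarity ---------------------------------------------
# With a single decay factor, the contribution of ancestor node t to disease P
# collapses to alpha^(minimum number of truncation steps from t down to any of
# P's own positions), the maximum over P's positions. Nodes are identified by
# disease name where a position is named, otherwise by the position itself.

oracle_prefixes <- function(code) {
  segs <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(segs), function(k) paste(segs[1:k], collapse = "."), character(1))
}

oracle_semantic <- function(mesh, disease, alpha = 0.5) {
  own <- mesh$code[mesh$disease == disease]
  pos_depth <- list()  # position -> min steps up from an own position
  for (c0 in own) {
    pre <- oracle_prefixes(c0)
    steps <- rev(seq_along(pre)) - 1  # last prefix (own code) = 0 steps
    for (i in seq_along(pre)) {
      p <- pre[i]
      s <- length(pre) - i
      if (is.null(pos_depth[[p]]) || s < pos_depth[[p]]) pos_depth[[p]] <- s
    }
  }
  lab <- setNames(mesh$disease, mesh$code)
  ids <- vapply(names(pos_depth), function(p)
    if (!is.na(lab[p])) unname(lab[p]) else paste0("code:", p), character(1))
  D <- tapply(alpha^unlist(pos_depth), ids, max)
  list(D = setNames(as.numeric(D), names(D)), DV = sum(D))
}

oracle_disease_sim <- function(mesh, P, Q, alpha = 0.5) {
  sp <- oracle_semantic(mesh, P, alpha)
  sq <- oracle_semantic(mesh, Q, alpha)
  shared <- intersect(names(sp$D), names(sq$D))
  if (!length(shared)) return(0)
  sum(sp$D[shared] + sq$D[shared]) / (sp$DV + sq$DV)
}

# random small hierarchy: chains of random codes over a small segment alphabet
random_mesh <- function(n_dis, max_depth = 4, n_roots = 3) {
  codes <- character(n_dis)
  for (i in seq_len(n_dis)) {
    d <- sample(max_depth, 1)
    segs <- c(sample(LETTERS[seq_len(n_roots)], 1),
              if (d > 1) sample(letters[1:4], d - 1, replace = TRUE))
    codes[i] <- paste(segs, collapse = ".")
  }
  codes <- unique(codes)
  data.frame(disease = paste0("dz", seq_along(codes)), code = codes,
             stringsAsFactors = FALSE)
}

# --- CGR ----------------------------------------------------------------------
oracle_cgr_points <- function(sequence) {
  corners <- list(A = c(0, 0), C = c(0, 1), G = c(1, 1), U = c(1, 0))
  pt <- c(0.5, 0.5)
  out <- matrix(NA_real_, nchar(sequence), 2)
  for (i in seq_len(nchar(sequence))) {
    pt <- (pt + corners[[substr(sequence, i, i)]]) / 2
    out[i, ] <- pt
  }
  out
}

oracle_cgr_freq <- function(sequence, k) {
  pts <- oracle_cgr_points(sequence)
  m <- 2^k
  f <- matrix(0, m, m)
  for (i in seq_len(nrow(pts))) {
    r <- min(floor(pts[i, 2] * m), m - 1) + 1
    c <- min(floor(pts[i, 1] * m), m - 1) + 1
    f[r, c] <- f[r, c] + 1
  }
  f / nrow(pts)
}

# --- second-order walk law ----------------------------------------------------
oracle_transition <- function(W, v, t, p, q) {
  n <- nrow(W)
  pr <- numeric(n)
  for (x in seq_len(n)) {
    if (x == v || W[v, x] <= 0) next
    a <- if (is.null(t)) 1
    else if (x == t) 1 / p
    else if (W[t, x] > 0) 1
    else 1 / q
    pr[x] <- a * W[v, x]
  }
  keep <- which(pr > 0)
  setNames(pr[keep] / sum(pr), as.character(keep))
}

# --- multi-layer embedding forward pass ---------------------------------------
# Straight-line recomputation of the final embedding of one node on one layer
# from the raw parameter matrices, written with explicit loops.
oracle_final_embedding <- function(graph, params, i, r) {
  n <- length(graph$nodes)
  R <- length(graph$types)
  K <- params$K
  max_pool <- identical(params$aggregator, "max")
  dK <- vector("list", R)
  for (rr in seq_len(R)) {
    d <- matrix(NA_real_, n, params$DE)
    for (j in seq_len(n)) {
      z <- graph$type[j]
      d[j, ] <- as.numeric(graph$X[j, ] %*% params$Wg[[z]][[rr]]) + params$bg[[z]][[rr]]
    }
    if (K > 0) for (k in seq_len(K)) {
      d2 <- d
      for (j in seq_len(n)) {
        nb <- graph$nbrs[[rr]][[j]]
        if (length(nb)) {
          agg <- numeric(params$DE)
          for (dd in seq_len(params$DE)) {
            vals <- d[nb, dd]
            agg[dd] <- if (max_pool) max(vals) else mean(vals)
          }
          d2[j, ] <- tanh(agg)
        }
      }
      d <- d2
    }
    dK[[rr]] <- d
  }
  Di <- matrix(NA_real_, params$DE, R)
  for (rr in seq_len(R)) Di[, rr] <- dK[[rr]][i, ]
  s <- numeric(R)
  for (rr in seq_len(R))
    s[rr] <- sum(params$watt[[r]] * tanh(params$Watt[[r]] %*% Di[, rr]))
  a <- exp(s - max(s)); a <- a / sum(a)
  u <- params$alpha[r] * as.numeric(t(params$M[[r]]) %*% (Di %*% a))
  z <- graph$type[i]
  b <- as.numeric(graph$X[i, ] %*% params$Wh[[z]]) + params$bh[[z]]
  attr <- as.numeric(graph$X[i, ] %*% params$Dz[[z]])
  params$beta[r] * attr + b + u
}

# --- classification metrics ---------------------------------------------------
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (th in ths) {
    pred <- scores >= th
    tp <- sum(pred & labels)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels)
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

oracle_f1 <- function(scores, labels, th = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= th
  tp <- sum(pred & labels)
  if (tp == 0) return(0)
  p <- tp / sum(pred); r <- tp / sum(labels)
  2 * p * r / (p + r)
}

# --- tiny fixtures ------------------------------------------------------------
tiny_features <- function(n_mirna, n_disease, NE = 4, seed = 1) {
  set.seed(seed)
  list(
    mirna = matrix(rnorm(n_mirna * NE), n_mirna, NE,
                   dimnames = list(sprintf("m%02d", seq_len(n_mirna)), NULL)),
    disease = matrix(rnorm(n_disease * NE), n_disease, NE,
                     dimnames = list(sprintf("d%02d", seq_len(n_disease)), NULL))
  )
}

tiny_triples <- function(...) {
  tri <- rbind(...)
  data.frame(mirna = tri[, 1], disease = tri[, 2], type = tri[, 3],
             stringsAsFactors = FALSE)
}
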