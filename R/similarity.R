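#' Build a disease DAG from tree codes
#'
#' Every dot-separated tree code is a position in the hierarchy; the parent of
#' a position is obtained by truncating its last segment, so the graph is a
#' forest of positions and acyclicity is guaranteed by construction. Positions
#' named by an input disease are labelled with that name; positions that no
#' disease occupies remain anonymous internal nodes (they still contribute
#' semantic value). A disease occupying several positions owns all of them.
#'
#' @param mesh a data frame with columns `disease`, `code` (see [read_mesh()]).
#' @param alpha ancestor contribution factor in (0, 1]; each generation of
#'   ancestry is decayed by this factor. Default 0.5.
#' @return An object of class `"disease_dag"`: list with `positions` (all tree
#'   codes in the prefix closure), `parent` (named character, NA at roots),
#'   `label` (named character, disease name or NA per position) and
#'   `diseases` (named list mapping each disease to its positions), `alpha`.
#' @export
build_dag <- function(mesh, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  codes <- unique(mesh$code)
  closure <- unique(unlist(lapply(codes, code_prefixes)))
  parent <- vapply(closure, function(p) {
    segs <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (length(segs) == 1) NA_character_ else paste(segs[-length(segs)], collapse = ".")
  }, character(1))
  # map positions to disease names; a code carried by two diseases is ambiguous
  lab <- setNames(rep(NA_character_, length(closure)), closure)
  for (i in seq_len(nrow(mesh))) {
    code <- mesh$code[i]; d <- mesh$disease[i]
    if (!is.na(lab[code]) && lab[code] != d)
      stop("tree code ", code, " assigned to two diseases: ", lab[code], ", ", d)
    lab[code] <- d
  }
  diseases <- split(mesh$code, mesh$disease)
  structure(list(positions = closure, parent = parent, label = lab,
                 diseases = diseases, alpha = alpha),
            class = "disease_dag")
}

code_prefixes <- function(code) {
  segs <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(segs), function(k) paste(segs[1:k], collapse = "."), character(1))
}

# Ancestor-node identifiers for disease P: named positions collapse to the
# disease name, anonymous positions keep a "code:" identifier.
node_id <- function(dag, pos) {
  lab <- dag$label[pos]
  ifelse(is.na(lab), paste0("code:", pos), lab)
}

#' Semantic value decomposition of a disease
#'
#' For disease `P`, the ancestor set `N_P` contains `P` and every ancestor
#' reachable by truncating its tree codes. `P` itself contributes 1; each
#' ancestor node `t` contributes `alpha` times the maximum contribution of its
#' children inside `N_P`, so contributions decay geometrically with distance.
#' The semantic value `DV(P)` is the sum of all contributions. When the same
#' ancestor disease is reachable through chains of different depths (multiple
#' tree codes), the maximum contribution is used.
#'
#' @param dag a `"disease_dag"` from [build_dag()].
#' @param disease a disease name present in the DAG.
#' @return List with `D` (named numeric vector of contributions over the
#'   ancestor nodes of `disease`) and `DV` (their sum, always >= 1).
#' @export
semantic_values <- function(dag, disease) {
  own <- dag$diseases[[disease]]
  if (is.null(own)) stop("disease not in DAG: ", disease)
  positions <- unique(unlist(lapply(own, code_prefixes)))
  # contribution per position: own positions get 1, ancestors alpha * max(child)
  depth <- nchar(gsub("[^.]", "", positions))
  ord <- positions[order(depth, decreasing = TRUE)]  # children before parents
  dpos <- setNames(rep(NA_real_, length(positions)), positions)
  dpos[own] <- 1
  for (p in ord) {
    if (!is.na(dpos[p]) && dpos[p] == 1) next
    children <- positions[!is.na(dag$parent[positions]) & dag$parent[positions] == p]
    dpos[p] <- max(dag$alpha * dpos[children], if (!is.na(dpos[p])) dpos[p] else NULL)
  }
  # collapse positions to nodes (same named disease at several positions: max)
  ids <- node_id(dag, positions)
  D <- tapply(dpos[positions], ids, max)
  D <- setNames(as.numeric(D), names(D))
  list(D = D, DV = sum(D))
}

#' Semantic similarity between two diseases
#'
#' The similarity of `P` and `Q` is the summed contribution of their shared
#' ancestor nodes, relative to the total semantic value of both diseases:
#' `sum over t in N_P intersect N_Q of (D_P(t) + D_Q(t)) / (DV(P) + DV(Q))`.
#' Diseases in disjoint hierarchy components have similarity 0; every disease
#' has similarity 1 with itself.
#'
#' @inheritParams semantic_values
#' @param P,Q disease names present in the DAG.
#' @return Similarity in `[0, 1]`.
#' @export
disease_similarity <- function(dag, P, Q) {
  sp <- semantic_values(dag, P)
  sq <- semantic_values(dag, Q)
  shared <- intersect(names(sp$D), names(sq$D))
  if (length(shared) == 0) return(0)
  sum(sp$D[shared] + sq$D[shared]) / (sp$DV + sq$DV)
}

#' Disease-disease semantic similarity matrix
#'
#' @inheritParams semantic_values
#' @param diseases disease names to include (default: all named diseases in
#'   the DAG), in the order of the output matrix.
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`, dimnames
#'   set to `diseases`.
#' @export
disease_similarity_matrix <- function(dag, diseases = names(dag$diseases)) {
  sv <- lapply(diseases, function(d) semantic_values(dag, d))
  names(sv) <- diseases
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  if (n < 2) return(S)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(sv[[i]]$D), names(sv[[j]]$D))
      s <- if (length(shared)) sum(sv[[i]]$D[shared] + sv[[j]]$D[shared]) /
        (sv[[i]]$DV + sv[[j]]$DV) else 0
      S[i, j] <- S[j, i] <- s
    }
  }
  S
}

#' Chaos-game representation profile of an RNA sequence
#'
#' Maps a sequence into the unit square by the iterative midpoint rule with
#' corners A=(0,0), C=(0,1), G=(1,1), U=(1,0), starting from the centre
#' (0.5, 0.5): each residue moves the current point halfway towards its
#' corner. The square is divided into `2^k x 2^k` subregions and the visit
#' frequency of each subregion (over the L points of a length-L sequence)
#' forms the profile.
#'
#' @param sequence a string over A/C/G/U (see [read_fasta()]).
#' @param k resolution; the square is split into `2^k` rows and columns.
#'   Default 3 (64 regions).
#' @return A `2^k x 2^k` matrix of nonnegative frequencies summing to 1; rows
#'   index the y axis from 0, columns the x axis from 0. Class `"cgr_profile"`.
#' @export
cgr_profile <- function(sequence, k = 3) {
  s <- strsplit(toupper(sequence), "")[[1]]
  if (length(s) < k) stop("sequence shorter than resolution k")
  if (any(!s %in% c("A", "C", "G", "U"))) stop("sequence must be over A/C/G/U")
  cx <- c(A = 0, C = 0, G = 1, U = 1)[s]
  cy <- c(A = 0, C = 1, G = 1, U = 0)[s]
  n <- length(s)
  x <- numeric(n); y <- numeric(n)
  px <- 0.5; py <- 0.5
  for (i in seq_len(n)) {
    px <- (px + cx[i]) / 2
    py <- (py + cy[i]) / 2
    x[i] <- px; y[i] <- py
  }
  m <- 2^k
  row <- pmin(floor(y * m), m - 1) + 1
  col <- pmin(floor(x * m), m - 1) + 1
  freq <- matrix(0, m, m)
  for (i in seq_len(n)) freq[row[i], col[i]] <- freq[row[i], col[i]] + 1
  freq <- freq / n
  class(freq) <- c("cgr_profile", class(freq))
  freq
}

#' miRNA-miRNA similarity from CGR region distance
#'
#' Computes the Euclidean (Frobenius) distance between the subregion
#' visit-frequency matrices of every pair of sequences and inverts it to a
#' similarity by min-max scaling: `sim = 1 - d / max(d)`. Identical profiles
#' get similarity 1; the most dissimilar pair gets 0. The diagonal is forced
#' to 1.
#'
#' @param seqs a data frame with columns `mirna`, `sequence`, or a named list
#'   of precomputed [cgr_profile()] matrices sharing one resolution.
#' @param k CGR resolution used when `seqs` contains raw sequences.
#' @return Symmetric similarity matrix with unit diagonal and dimnames set to
#'   the miRNA names.
#' @export
mirna_similarity <- function(seqs, k = 3) {
  if (is.data.frame(seqs)) {
    profiles <- lapply(seqs$sequence, cgr_profile, k = k)
    names(profiles) <- seqs$mirna
  } else {
    profiles <- seqs
    dims <- vapply(profiles, nrow, integer(1))
    if (length(unique(dims)) > 1) stop("profiles must share one resolution")
  }
  n <- length(profiles)
  if (n < 2) stop("need at least 2 profiles")
  P <- t(vapply(profiles, as.numeric, numeric(length(profiles[[1]]))))
  D <- as.matrix(stats::dist(P))
  mx <- max(D)
  S <- if (mx > 0) 1 - D / mx else matrix(1, n, n)
  diag(S) <- 1
  dimnames(S) <- list(names(profiles), names(profiles))
  S
}
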