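#' Generate a toy disease hierarchy
#'
#' Builds a deterministic rooted tree of positions (one root, `branching`
#' children per node down to `depth` levels) and names a seeded random subset
#' of the positions with disease labels. When `block_assignments` is given,
#' diseases of the same block are placed inside the same depth-1 subtree so
#' that semantic similarity carries the block signal; the tree then needs
#' `branching >= number of blocks`.
#'
#' @param n_diseases number of named diseases.
#' @param depth tree depth below the root.
#' @param branching children per internal node.
#' @param seed integer seed; output is a pure function of it.
#' @param block_assignments optional integer vector of length `n_diseases`
#'   giving a block index per disease.
#' @param prefix disease name prefix.
#' @return A `"mesh_entries"` data frame (columns `disease`, `code`).
#' @export
gen_mesh_tree <- function(n_diseases, depth = 3, branching = 3, seed = 1,
                          block_assignments = NULL, prefix = "disease") {
  positions <- "R01"
  frontier <- positions
  for (d in seq_len(depth)) {
    frontier <- unlist(lapply(frontier, function(p) paste0(p, ".", sprintf("%03d", seq_len(branching)))))
    positions <- c(positions, frontier)
  }
  nms <- sprintf("%s%03d", prefix, seq_len(n_diseases))
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  if (is.null(block_assignments)) {
    if (n_diseases > length(positions)) stop("more diseases than tree positions")
    picked <- sample(positions, n_diseases)
  } else {
    stopifnot(length(block_assignments) == n_diseases)
    blocks <- sort(unique(block_assignments))
    if (length(blocks) > branching) stop("need branching >= number of blocks")
    top <- paste0("R01.", sprintf("%03d", seq_along(blocks)))
    picked <- character(n_diseases)
    for (bi in seq_along(blocks)) {
      members <- which(block_assignments == blocks[bi])
      sub <- positions[startsWith(positions, top[bi])]
      if (length(members) > length(sub)) stop("subtree too small for block; increase depth/branching")
      picked[members] <- sample(sub, length(members))
    }
  }
  out <- data.frame(disease = nms, code = picked, stringsAsFactors = FALSE)
  class(out) <- c("mesh_entries", "data.frame")
  out
}

#' Generate block-structured RNA sequences
#'
#' Draws one random ancestor sequence per block and derives each member by
#' independent point mutations at rate `mutation_rate`, so within-block CGR
#' similarity exceeds between-block similarity in expectation (exactly 1 at
#' rate 0; block structure destroyed at rate 1).
#'
#' @param n number of sequences; ignored when `block_assignments` is given.
#' @param length_range integer range for ancestor sequence lengths.
#' @param block_assignments integer vector of block indices (one per
#'   sequence); default one block for all.
#' @param mutation_rate per-residue substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @param prefix miRNA name prefix.
#' @return A `"mirna_sequences"` data frame (columns `mirna`, `sequence`).
#' @export
gen_sequences <- function(n, length_range = c(60, 100), block_assignments = NULL,
                          mutation_rate = 0.05, seed = 1, prefix = "mirna") {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  if (is.null(block_assignments)) block_assignments <- rep(1L, n)
  n <- length(block_assignments)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  alph <- c("A", "C", "G", "U")
  blocks <- sort(unique(block_assignments))
  anc <- lapply(blocks, function(b) {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    sample(alph, len, replace = TRUE)
  })
  names(anc) <- as.character(blocks)
  seqs <- vapply(block_assignments, function(b) {
    s <- anc[[as.character(b)]]
    mut <- runif(length(s)) < mutation_rate
    if (any(mut)) s[mut] <- sample(alph, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  out <- data.frame(mirna = sprintf("%s%03d", prefix, seq_len(n)),
                    sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("mirna_sequences", "data.frame")
  out
}

#' Configuration for a planted multi-layer association network
#'
#' @param n_mirna,n_disease node counts per class.
#' @param n_types number of association types (layers); default 5.
#' @param n_blocks number of matched miRNA/disease blocks.
#' @param p_within per-type edge probability for same-block pairs.
#' @param p_cross per-type edge probability for cross-block pairs; must be
#'   below `p_within` for a recoverable signal.
#' @param type_correlation probability that a pair with at least one positive
#'   type gains one additional correlated type.
#' @param seed integer seed.
#' @return List of class `"planted_config"`.
#' @export
planted_config <- function(n_mirna = 60, n_disease = 40, n_types = 5,
                           n_blocks = 3, p_within = 0.3, p_cross = 0.02,
                           type_correlation = 0.2, seed = 1) {
  stopifnot(p_within > p_cross)
  structure(list(n_mirna = n_mirna, n_disease = n_disease, n_types = n_types,
                 n_blocks = n_blocks, p_within = p_within, p_cross = p_cross,
                 type_correlation = type_correlation, seed = seed),
            class = "planted_config")
}

#' Generate a planted multi-layer association network
#'
#' miRNA and disease blocks are matched one-to-one; for every type, a
#' same-block (miRNA, disease) pair receives a positive triple with
#' probability `p_within` and a cross-block pair with probability `p_cross`.
#' Each pair that has at least one positive triple then gains, with
#' probability `type_correlation`, one extra type drawn uniformly from its
#' missing types — emulating association pairs carrying multiple evidence
#' types.
#'
#' @param config a [planted_config()].
#' @return List with `associations` (an `"md_associations"` data frame),
#'   `mirna_blocks` and `disease_blocks` (named integer vectors).
#' @export
gen_planted_amhn <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  old <- local_rng(config$seed)
  on.exit(restore_rng(old))
  types <- association_types()[seq_len(config$n_types)]
  mb <- rep(seq_len(config$n_blocks), length.out = config$n_mirna)
  db <- rep(seq_len(config$n_blocks), length.out = config$n_disease)
  mn <- sprintf("mirna%03d", seq_len(config$n_mirna))
  dn <- sprintf("disease%03d", seq_len(config$n_disease))
  names(mb) <- mn; names(db) <- dn
  same <- outer(mb, db, "==")
  rec <- list()
  for (r in seq_along(types)) {
    p <- ifelse(same, config$p_within, config$p_cross)
    hit <- which(matrix(runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
    if (nrow(hit)) {
      rec[[r]] <- data.frame(mirna = mn[hit[, 1]], disease = dn[hit[, 2]],
                             type = types[r], stringsAsFactors = FALSE)
    }
  }
  assoc <- do.call(rbind, rec)
  if (is.null(assoc)) assoc <- data.frame(mirna = character(), disease = character(),
                                          type = character(), stringsAsFactors = FALSE)
  # correlated extra types for positive pairs
  if (config$type_correlation > 0 && nrow(assoc)) {
    pairs <- unique(assoc[c("mirna", "disease")])
    gain <- runif(nrow(pairs)) < config$type_correlation
    extra <- list()
    for (i in which(gain)) {
      have <- assoc$type[assoc$mirna == pairs$mirna[i] & assoc$disease == pairs$disease[i]]
      miss <- setdiff(types, have)
      if (length(miss)) {
        extra[[length(extra) + 1]] <- data.frame(
          mirna = pairs$mirna[i], disease = pairs$disease[i],
          type = if (length(miss) == 1) miss else sample(miss, 1),
          stringsAsFactors = FALSE)
      }
    }
    if (length(extra)) assoc <- rbind(assoc, do.call(rbind, extra))
  }
  assoc <- assoc[!duplicated(assoc), , drop = FALSE]
  assoc$source_id <- NA_character_
  assoc <- assoc[order(assoc$mirna, assoc$disease, assoc$type), , drop = FALSE]
  rownames(assoc) <- NULL
  class(assoc) <- c("md_associations", "data.frame")
  list(associations = assoc, mirna_blocks = mb, disease_blocks = db)
}

#' Generate a complete synthetic study data set
#'
#' Couples [gen_planted_amhn()], [gen_mesh_tree()] and [gen_sequences()] with
#' consistent block structure: miRNA sequences mutate from per-block
#' ancestors, and diseases of one block share a subtree of the hierarchy, so
#' both similarity networks carry the planted signal.
#'
#' @param config a [planted_config()].
#' @param mutation_rate sequence mutation rate.
#' @param depth,branching tree shape passed to [gen_mesh_tree()] (branching
#'   defaults to the number of blocks).
#' @return List with `associations`, `mesh`, `sequences`, `mirna_blocks`,
#'   `disease_blocks`.
#' @export
gen_planted_dataset <- function(config, mutation_rate = 0.05, depth = 4,
                                branching = config$n_blocks) {
  net <- gen_planted_amhn(config)
  mesh <- gen_mesh_tree(config$n_disease, depth = depth, branching = branching,
                        seed = derive_seed(config$seed, "mesh"),
                        block_assignments = unname(net$disease_blocks))
  seqs <- gen_sequences(block_assignments = unname(net$mirna_blocks),
                        mutation_rate = mutation_rate,
                        seed = derive_seed(config$seed, "seq"))
  c(net, list(mesh = mesh, sequences = seqs))
}

#' Write a synthetic data set bundle to disk
#'
#' @param dataset output of [gen_planted_dataset()].
#' @param dir output directory (created if needed); writes
#'   `associations.tsv`, `mesh.tsv`, `sequences.fa`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(dataset$associations, file.path(dir, "associations.tsv"))
  write_mesh(dataset$mesh, file.path(dir, "mesh.tsv"))
  write_fasta(dataset$sequences, file.path(dir, "sequences.fa"))
  invisible(dir)
}

# Seed scoping: save/restore the global RNG state so generators are pure
# functions of their seed argument without disturbing the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
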