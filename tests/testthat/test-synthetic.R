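test_that("generated tree codes form a valid prefix hierarchy", {
  mesh <- gen_mesh_tree(10, depth = 3, branching = 3, seed = 2)
  expect_equal(nrow(mesh), 10)
  expect_true(all(grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", mesh$code)))
  expect_true(all(startsWith(mesh$code, "R01")))  # single shared root
  expect_identical(mesh, gen_mesh_tree(10, depth = 3, branching = 3, seed = 2))
  # shared root: every disease pair has positive similarity
  S <- disease_similarity_matrix(build_dag(mesh))
  expect_true(all(S > 0))
})

test_that("a chain hierarchy makes similarity fall with tree distance", {
  mesh <- gen_mesh_tree(5, depth = 6, branching = 1, seed = 3)
  dag <- build_dag(mesh)
  depth <- nchar(gsub("[^.]", "", mesh$code))
  ord <- order(depth)
  deepest <- mesh$disease[ord[length(ord)]]
  sims <- vapply(mesh$disease[ord[-length(ord)]],
                 function(d) disease_similarity(dag, deepest, d), numeric(1))
  # partners closer in the chain (deeper) are more similar
  expect_true(all(diff(sims) >= -1e-12))
})

test_that("block-structured sequences carry the planted contrast", {
  blk <- rep(1:2, each = 6)
  s0 <- gen_sequences(block_assignments = blk, mutation_rate = 0, seed = 4)
  S0 <- mirna_similarity(s0, k = 2)
  expect_true(all(S0[1:6, 1:6] == 1))  # zero mutation: identical within block
  s5 <- gen_sequences(block_assignments = blk, mutation_rate = 0.05, seed = 4)
  S5 <- mirna_similarity(s5, k = 2)
  same <- outer(blk, blk, "==") & upper.tri(S5)
  expect_gt(mean(S5[same]), mean(S5[!same & upper.tri(S5)]))
  expect_identical(s5, gen_sequences(block_assignments = blk,
                                     mutation_rate = 0.05, seed = 4))
  # full mutation destroys the ancestors entirely
  s1 <- gen_sequences(block_assignments = blk, mutation_rate = 1, seed = 4)
  expect_false(any(duplicated(s1$sequence)))
})

test_that("planted networks respect block structure and edge rates", {
  cfg <- planted_config(n_mirna = 20, n_disease = 20, n_blocks = 2,
                        p_within = 0.4, p_cross = 0, type_correlation = 0,
                        seed = 9)
  ds <- gen_planted_amhn(cfg)
  a <- ds$associations
  expect_true(all(ds$mirna_blocks[a$mirna] == ds$disease_blocks[a$disease]))
  # expected count: n_blocks * within-pairs * p * n_types, within 3 sigma
  n_within <- sum(outer(ds$mirna_blocks, ds$disease_blocks, "=="))
  expected <- n_within * 0.4 * 5
  sigma <- sqrt(n_within * 5 * 0.4 * 0.6)
  expect_lt(abs(nrow(a) - expected), 3 * sigma)
  expect_identical(ds, gen_planted_amhn(cfg))
  expect_error(planted_config(p_within = 0.1, p_cross = 0.2), "p_within > p_cross")
})

test_that("type correlation adds extra types to positive pairs", {
  base <- gen_planted_amhn(planted_config(n_mirna = 30, n_disease = 30,
                                          p_within = 0.2, type_correlation = 0,
                                          seed = 12))
  more <- gen_planted_amhn(planted_config(n_mirna = 30, n_disease = 30,
                                          p_within = 0.2, type_correlation = 0.9,
                                          seed = 12))
  multi_frac <- function(a) {
    k <- table(paste(a$mirna, a$disease))
    mean(k >= 2)
  }
  expect_gt(multi_frac(more$associations), multi_frac(base$associations))
})

test_that("generated bundles round-trip through the readers", {
  ds <- gen_planted_dataset(planted_config(n_mirna = 8, n_disease = 6,
                                           n_blocks = 2, p_within = 0.5,
                                           p_cross = 0.05, seed = 10))
  dir <- file.path(tempdir(), "synth-bundle")
  write_dataset(ds, dir)
  assoc <- read_associations(file.path(dir, "associations.tsv"))
  mesh <- read_mesh(file.path(dir, "mesh.tsv"))
  seqs <- read_fasta(file.path(dir, "sequences.fa"))
  key <- function(d) sort(paste(d$mirna, d$disease, d$type))
  expect_equal(key(assoc), key(ds$associations))
  expect_equal(nrow(mesh), nrow(ds$mesh))
  expect_equal(seqs$sequence[match(ds$sequences$mirna, seqs$mirna)],
               ds$sequences$sequence)
  # and the full pipeline accepts them
  prep <- mdlinker_prepare(assoc, mesh, seqs,
                           mdlinker_control("desk", NE = 8, n2v_epochs = 1,
                                            n2v_walk_length = 10,
                                            n2v_walks_per_node = 2), seed = 1)
  expect_s3_class(prep, "mdlinker_data")
  expect_setequal(rownames(prep$features$mirna), ds$sequences$mirna)
})
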