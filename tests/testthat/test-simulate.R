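test_that("codon-pair simulation is deterministic and honours target_ks = 0", {
  s1 <- simulate_codon_pair(50, 0.2, 0.3, seed = 99)
  s2 <- simulate_codon_pair(50, 0.2, 0.3, seed = 99)
  expect_identical(s1$pair$seq_a, s2$pair$seq_a)
  expect_identical(s1$pair$seq_b, s2$pair$seq_b)
  expect_identical(s1$truth, s2$truth)

  s0 <- simulate_codon_pair(40, 0, 0.5, seed = 1)
  expect_identical(s0$pair$seq_a, s0$pair$seq_b)
  r <- compute_kaks(s0$pair)
  expect_equal(r$Ks, 0)
  expect_equal(s0$truth$syn_a + s0$truth$syn_b, 0L)

  expect_error(simulate_codon_pair(0, 0.1, 0.2, seed = 1), "n_codons")
  expect_error(simulate_codon_pair(10, -1, 0.2, seed = 1), "target_ks")
})

test_that("realized synonymous events hit the per-lineage target by construction", {
  for (seed in 1:5) {
    s <- simulate_codon_pair(100, 0.4, 0.2, seed = seed)
    need <- s$truth$needed_syn_per_lineage
    expect_gte(s$truth$syn_a, need)
    expect_lt(s$truth$syn_a, need + 1)  # stops at the first crossing
    expect_gte(s$truth$syn_b, need)
    expect_lt(s$truth$syn_b, need + 1)
    expect_equal(need, 0.4 / 2 * s$truth$S_anc)
  }
})

test_that("omega = 0 simulations never accept nonsynonymous changes", {
  s <- simulate_codon_pair(60, 0.3, 0, seed = 5)
  expect_equal(s$truth$nonsyn_a + s$truth$nonsyn_b, 0L)
  r <- suppressWarnings(compute_kaks(s$pair))
  expect_gt(r$Ks, 0)
})

test_that("genome simulation plants exactly the requested structure", {
  g0 <- simulate_genome(n_chromosomes = 2, genes_per_chromosome = 10,
                        n_tandem_arrays = 0, n_proximal_pairs = 0,
                        n_collinear_blocks = 0, seed = 1)
  expect_true(all(g0$truth == "singleton"))
  expect_equal(nrow(g0$homolog_pairs), 0L)

  g1 <- simulate_genome(n_chromosomes = 2, genes_per_chromosome = 10,
                        n_tandem_arrays = 1, tandem_array_size = 2,
                        n_proximal_pairs = 0, n_collinear_blocks = 0,
                        seed = 2)
  expect_equal(sum(g1$truth == "tandem"), 2L)

  # ranks unique per chromosome, consecutive from 0
  g <- simulate_genome(seed = 3)
  by_chrom <- split(g$loci$rank, g$loci$chrom)
  for (r in by_chrom) expect_equal(sort(r), seq_along(r) - 1L)

  expect_identical(simulate_genome(seed = 7), simulate_genome(seed = 7))
  expect_error(simulate_genome(n_chromosomes = 1, genes_per_chromosome = 3,
                               n_tandem_arrays = 5, n_proximal_pairs = 0,
                               n_collinear_blocks = 0, seed = 1),
               "capacity")
})

test_that("the classifier recovers planted genome structure exactly", {
  for (seed in 1:10) {
    g <- simulate_genome(n_chromosomes = 3, genes_per_chromosome = 25,
                         n_tandem_arrays = 2, tandem_array_size = 3,
                         n_proximal_pairs = 2, n_collinear_blocks = 2,
                         block_length = 3, n_dispersed_pairs = 1,
                         proximal_window = 8, seed = seed)
    res <- classify_genes(names(g$truth), g$homolog_pairs,
                          g$collinear_pairs, g$loci, proximal_window = 8)
    expect_identical(setNames(as.character(res$class), res$gene_id), g$truth)
  }
})

test_that("gene-tree simulation is deterministic and congruent without events", {
  st <- recon_species_trees[[2]]
  s0 <- simulate_gene_tree(st, NULL, seed = 1)
  expect_equal(s0$truth, list(duplications = 0L, losses = 0L))
  expect_equal(sort(unname(s0$leaf_species_map)), sort(st$tip.label))
  r <- count_duplications_losses(s0$gene_tree, s0$species_tree,
                                 s0$leaf_species_map)
  expect_equal(r$total_duplications + r$total_losses, 0L)

  ev <- data.frame(branch = "R", type = "duplication")
  s1 <- simulate_gene_tree(recon_species_trees[[1]], ev, seed = 2)
  expect_equal(ape::Ntip(s1$gene_tree), 8L)  # 2 copies x 4 species
  expect_equal(s1$truth$duplications, 1L)

  s1b <- simulate_gene_tree(recon_species_trees[[1]], ev, seed = 2)
  expect_equal(ape::write.tree(s1$gene_tree), ape::write.tree(s1b$gene_tree))

  bad <- data.frame(branch = "nowhere", type = "loss")
  expect_error(simulate_gene_tree(st, bad, seed = 1), "nowhere")
})

test_that("losses that erase the whole family are rejected", {
  st <- ape::read.tree(text = "(A,B)R;")
  ev <- data.frame(branch = c("A", "B"), type = "loss")
  expect_error(simulate_gene_tree(st, ev, seed = 1), "emptied|single leaf")
})

test_that("reconciliation recovers planted duplication/loss totals", {
  for (seed in 1:10) {
    set.seed(seed + 1000)
    tree <- recon_species_trees[[(seed %% 2) + 1]]
    ev <- sample_safe_events(tree)
    sim <- simulate_gene_tree(tree, ev, seed = seed)
    rec <- count_duplications_losses(sim$gene_tree, sim$species_tree,
                                     sim$leaf_species_map)
    expect_equal(rec$total_duplications, sim$truth$duplications)
    expect_equal(rec$total_losses, sim$truth$losses)
  }
})
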