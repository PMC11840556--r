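small_sp_tree <- function(n = 6, seed = 17) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

test_that("the stand-in species tree is fixed and calibrated", {
  t1 <- standin_species_tree()
  t2 <- standin_species_tree()
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 34L)
  expect_equal(max(ape::node.depth.edgelength(t1)), 0.5, tolerance = 1e-12)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
})

test_that("coalescent gene trees track the species tree as theta shrinks", {
  sp <- small_sp_tree()
  gts <- simulate_gene_trees(sp, 5, coalescent_scale = 1e-8, seed = 3)
  expect_length(gts, 5L)
  for (gt in gts) {
    expect_setequal(gt$tip.label, sp$tip.label)
    expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(sp)), 0,
                 ignore_attr = TRUE)
  }
  flat <- sp
  flat$edge.length[1] <- 0
  expect_error(simulate_gene_trees(flat, 1, 1), "positive branch lengths")
})

test_that("three-taxon discordance matches the closed form", {
  # species tree ((A,B):T,C) with internal branch T, coalescent scale theta:
  # P(gene tree topology != species tree) = (2/3) exp(-T / theta)
  theta <- 0.1; Tint <- 0.15
  sp <- ape::read.tree(text = sprintf("((A:0.2,B:0.2):%f,C:0.35);", Tint))
  n <- 600
  gts <- simulate_gene_trees(sp, n, coalescent_scale = theta, seed = 21)
  # discordant iff A and B are not sisters in the rooted gene tree
  discord <- vapply(gts, function(gt) {
    !ape::is.monophyletic(gt, c("A", "B"))
  }, logical(1))
  p_expect <- (2 / 3) * exp(-Tint / theta)
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(mean(discord) - p_expect), 4 * se + 0.01)
})

test_that("sequence simulation respects the indel-free limit and homology", {
  sp <- small_sp_tree()
  cfg0 <- sim_config(species_tree = sp, indel_rate = 0, n_regions = 1)
  aln <- simulate_alignment(sp, cfg0, seed = 5)
  expect_false(any(aln$seq == "-"))
  expect_equal(ncol(aln$seq) >= 1, TRUE)

  # with indels, gap structure appears but every row ungaps to a clean
  # nucleotide sequence
  cfg <- sim_config(species_tree = sp, n_regions = 1)
  aln2 <- simulate_alignment(sp, cfg, seed = 6)
  expect_true(any(aln2$seq == "-"))
  ungapped <- gsub("-", "", as.character(aln2))
  expect_true(all(grepl("^[ACGT]+$", ungapped)))
})

test_that("root sequence length is centered on the configured mean", {
  sp <- small_sp_tree(4)
  cfg <- sim_config(species_tree = sp, indel_rate = 0, n_regions = 1,
                    mean_seq_length = 300)
  lens <- vapply(1:40, function(i)
    ncol(simulate_alignment(sp, cfg, seed = i)$seq), numeric(1))
  # Poisson(300) mean over 40 draws: tolerance ~ 4 * sd
  expect_lt(abs(mean(lens) - 300), 4 * sqrt(300 / 40) + 1)
})

test_that("a long branch drives base composition to the stationary F", {
  two <- ape::read.tree(text = "(A:25,B:25);")
  freqs <- c(0.1, 0.2, 0.3, 0.4)
  cfg <- sim_config(species_tree = small_sp_tree(4), base_freqs = freqs,
                    mean_seq_length = 4000, indel_rate = 0, n_regions = 1)
  aln <- simulate_alignment(two, cfg, seed = 11)
  tab <- table(factor(aln$seq[1, ], levels = c("A", "C", "G", "T")))
  emp <- as.numeric(tab / sum(tab))
  expect_lt(max(abs(emp - freqs)), 0.03)
})

test_that("the binary trait follows its Markov model", {
  sp <- small_sp_tree(8)
  # vanishing rates: every tip inherits the root state
  tiny <- simulate_trait(sp, rate01 = 1e-9, seed = 2)
  expect_equal(length(unique(as.character(tiny))), 1L)
  expect_error(simulate_trait(sp, 0, 0), "zero")
  expect_error(simulate_trait(sp, -1), "rates")

  # symmetric rates: marginal tip distribution is one half
  frac <- vapply(1:300, function(i) {
    mean(simulate_trait(sp, rate01 = 2, seed = i) == "yes")
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.5), 0.05)

  # enormous rates wash out phylogenetic signal: sister tips nearly
  # independent, so P(same state) is close to one half
  two <- ape::read.tree(text = "(A:1,B:1);")
  same <- vapply(1:400, function(i) {
    tr <- simulate_trait(two, rate01 = 500, seed = i)
    tr[["A"]] == tr[["B"]]
  }, logical(1))
  expect_lt(abs(mean(same) - 0.5), 0.07)
})

test_that("masking replaces whole rows at the configured probability", {
  sp <- small_sp_tree()
  cfg <- sim_config(species_tree = sp, n_regions = 1)
  aln <- simulate_alignment(sp, cfg, seed = 3)
  m0 <- apply_masking(aln, 0, seed = 1)
  expect_identical(m0$alignment$seq, aln$seq)
  expect_length(m0$masked_tips, 0L)
  m1 <- apply_masking(aln, 1, seed = 1)
  expect_true(all(m1$alignment$seq == "-"))

  hits <- unlist(lapply(1:150, function(i)
    length(apply_masking(aln, 0.1, seed = i)$masked_tips)))
  n_draws <- 150 * length(sp$tip.label)
  phat <- sum(hits) / n_draws
  expect_lt(abs(phat - 0.1), 4 * sqrt(0.1 * 0.9 / n_draws))
})

test_that("regions replay bit-for-bit from the same configuration", {
  cfg <- sim_config(species_tree = small_sp_tree(), n_regions = 2, seed = 9)
  r1 <- simulate_region(cfg, "regionX")
  r2 <- simulate_region(cfg, "regionX")
  expect_identical(r1$alignment$seq, r2$alignment$seq)
  expect_identical(r1$trait, r2$trait)
  expect_identical(ape::write.tree(r1$gene_tree),
                   ape::write.tree(r2$gene_tree))
  # traits always usable for training
  expect_gte(sum(r1$trait == "yes"), 2L)
  expect_gte(sum(r1$trait == "no"), 2L)
  # a different region id gives different data
  r3 <- simulate_region(cfg, "regionY")
  expect_false(identical(r1$alignment$seq, r3$alignment$seq))
})
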