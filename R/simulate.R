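# Benchmark simulator: gene trees within a species tree, sequence evolution
# with indels producing a true-homology gapped alignment, a binary trait on
# the gene tree, and lineage-specific whole-sequence deletion.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Stand-in species tree
#'
#' A seeded pure-birth (Yule) tree rescaled to a fixed root-to-tip depth,
#' shipped as a reproducible stand-in species phylogeny for simulation
#' studies (the default: 34 tips, depth 0.5 substitutions/site). The
#' internal seed is fixed so the same tree is obtained in every session;
#' change `tree_seed` to draw a different stand-in.
#'
#' @param n_tips number of species.
#' @param depth root-to-tip depth in expected substitutions per site.
#' @param tree_seed seed of the tree draw (fixed default on purpose).
#' @return an ultrametric rooted [ape::phylo] with tips `sp01`, `sp02`, ...
#' @export
standin_species_tree <- function(n_tips = 34L, depth = 0.5,
                                 tree_seed = 101L) {
  tr <- with_seed(tree_seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$edge.length <- tr$edge.length * depth / max(node_ages(tr))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

# distance of every node from the root
node_ages <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  age <- numeric(n)
  edges <- reorder(tree, "cladewise")$edge
  lens <- reorder(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges)))
    age[edges[i, 2L]] <- age[edges[i, 1L]] + lens[i]
  age
}

#' Simulation configuration
#'
#' Bundles the benchmark's statistical structure. Defaults are the study
#' conditions: the 34-tip stand-in species tree, sequences of mean length
#' 1,575 nucleotides, an indel rate of 0.23 relative to the substitution
#' rate (split evenly between insertions and deletions, Zipf-distributed
#' lengths), a GTR+F model with equal exchangeabilities and frequencies
#' unless overridden, a symmetric two-state Markov trait whose rate gives
#' about three expected flips across the tree, moderate coalescent
#' discordance, and a 5% per-tip whole-sequence deletion probability.
#'
#' @param species_tree rooted [ape::phylo] with branch lengths (or Newick).
#' @param n_regions number of regions to simulate.
#' @param mean_seq_length mean root sequence length (Poisson draw per
#'   region).
#' @param indel_rate total indel event rate per site relative to the
#'   substitution rate.
#' @param indel_zipf_exponent,indel_max_length indel length distribution:
#'   P(len = z) proportional to z^-exponent on 1..max.
#' @param gtr_rates six GTR exchangeabilities (order AC, AG, AT, CG, CT,
#'   GT).
#' @param base_freqs equilibrium base frequencies (A, C, G, T), sum 1.
#' @param trait_rate per-direction flip rate of the binary trait per unit
#'   branch length; `NULL` sets it so the expected number of flips over
#'   the species tree is 3.
#' @param coalescent_scale coalescent population-size parameter in branch
#'   -length units; smaller means gene trees track the species tree more
#'   closely.
#' @param mask_prob per-tip probability of replacing the sequence with
#'   all gaps (whole-gene deletion).
#' @param seed master seed for region simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(species_tree = standin_species_tree(),
                       n_regions = 1000L, mean_seq_length = 1575,
                       indel_rate = 0.23, indel_zipf_exponent = 1.7,
                       indel_max_length = 100L,
                       gtr_rates = rep(1, 6), base_freqs = rep(0.25, 4),
                       trait_rate = NULL, coalescent_scale = 0.05,
                       mask_prob = 0.05, seed = 1L) {
  species_tree <- as_rooted_tree(species_tree)
  if (is.null(species_tree$edge.length) || any(species_tree$edge.length <= 0))
    stop_input("species tree must have positive branch lengths")
  if (any(gtr_rates < 0) || all(gtr_rates == 0))
    stop_input("invalid GTR exchangeabilities")
  if (any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-8)
    stop_input("base frequencies must be nonnegative and sum to 1")
  if (mask_prob < 0 || mask_prob > 1) stop_input("mask_prob must be in [0, 1]")
  if (indel_rate < 0) stop_input("indel_rate must be >= 0")
  if (is.null(trait_rate))
    trait_rate <- 3 / sum(species_tree$edge.length)
  if (trait_rate < 0) stop_input("trait_rate must be >= 0")
  structure(list(species_tree = species_tree,
                 n_regions = as.integer(n_regions),
                 mean_seq_length = mean_seq_length, indel_rate = indel_rate,
                 indel_zipf_exponent = indel_zipf_exponent,
                 indel_max_length = as.integer(indel_max_length),
                 gtr_rates = gtr_rates, base_freqs = base_freqs,
                 trait_rate = trait_rate,
                 coalescent_scale = coalescent_scale,
                 mask_prob = mask_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene trees under the multispecies coalescent
#'
#' Samples one gene tree per region within the species tree: one lineage
#' enters per tip species, and within each ancestral population lineages
#' coalesce at rate `choose(k, 2) / coalescent_scale` per unit branch
#' length (all remaining lineages coalesce above the root). As
#' `coalescent_scale` approaches 0 the gene-tree topology collapses onto
#' the species tree.
#'
#' @param species_tree rooted [ape::phylo] with positive branch lengths.
#' @param n_regions number of gene trees.
#' @param coalescent_scale coalescent scale parameter, > 0.
#' @param seed integer seed.
#' @return list of [ape::phylo] gene trees with the species-tree tip set.
#' @export
simulate_gene_trees <- function(species_tree, n_regions, coalescent_scale,
                                seed = 1L) {
  species_tree <- as_rooted_tree(species_tree)
  if (is.null(species_tree$edge.length) || any(species_tree$edge.length <= 0))
    stop_input("species tree must have positive branch lengths")
  lapply(seq_len(n_regions), function(i)
    with_seed(derive_seed(seed, "genetree", i),
              msc_one_tree(species_tree, coalescent_scale)))
}

msc_one_tree <- function(sp, theta) {
  ntip <- length(sp$tip.label)
  age <- node_ages(sp)                # distance from root
  root <- ntip + 1L
  children <- split(sp$edge[, 2L], sp$edge[, 1L])
  # gene-tree nodes: grow lists of (id, age); tips are 1..ntip
  g_age <- numeric(ntip); g_children <- vector("list", ntip)
  new_node <- function(kids, a) {
    g_age[length(g_age) + 1L] <<- a
    g_children[[length(g_age)]] <<- kids
    length(g_age)
  }
  coalesce_branch <- function(lineages, from_age, to_age) {
    # ages run from larger (tipward) to smaller (rootward); to_age = -Inf
    # means the root population
    a <- from_age
    while (length(lineages) >= 2L) {
      k <- length(lineages)
      wait <- stats::rexp(1L, rate = choose(k, 2) / theta)
      if (a - wait < to_age) break
      a <- a - wait
      pair <- sample.int(k, 2L)
      merged <- new_node(lineages[pair], a)
      lineages <- c(lineages[-pair], merged)
    }
    lineages
  }
  pop_lineages <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]], function(ch)
      coalesce_branch(pop_lineages(ch), from_age = age[ch],
                      to_age = age[node])))
  }
  lin <- coalesce_branch(pop_lineages(root), from_age = 0, to_age = -Inf)
  stopifnot(length(lin) == 1L)
  # emit newick with branch lengths age(child) - age(parent)
  nwk <- function(node, parent_age) {
    lab <- if (node <= ntip) sp$tip.label[node]
           else paste0("(", paste(vapply(g_children[[node]], nwk, "",
                                         parent_age = g_age[node]),
                                  collapse = ","), ")")
    paste0(lab, ":", format(if (node <= ntip) age[node] - parent_age
                            else g_age[node] - parent_age, digits = 12))
  }
  txt <- paste0("(", paste(vapply(g_children[[lin]], nwk, "",
                                  parent_age = g_age[lin]),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

# GTR rate matrix scaled to one expected substitution per site per unit time
gtr_q <- function(rates, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (i in seq_len(6)) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    Q[a, b] <- rates[i] * freqs[b]
    Q[b, a] <- rates[i] * freqs[a]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * freqs)
}

# transition probabilities exp(Qt) via the reversible symmetrization
gtr_transition <- function(Q, freqs, t) {
  s <- sqrt(freqs)
  B <- diag(s) %*% Q %*% diag(1 / s)
  ei <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / s) %*% ei$vectors %*% diag(exp(ei$values * t)) %*%
    t(ei$vectors) %*% diag(s)
  P[P < 0] <- 0
  P / rowSums(P)
}

zipf_sample <- function(n, exponent, max_len) {
  probs <- (seq_len(max_len))^(-exponent)
  sample.int(max_len, n, replace = TRUE, prob = probs)
}

#' Simulate a gapped alignment along a gene tree
#'
#' Evolves a root sequence (length Poisson around `mean_seq_length`,
#' drawn from the equilibrium frequencies) along the tree under GTR+F
#' substitutions, with insertion/deletion events arising as a Poisson
#' process at rate `indel_rate` per site relative to the substitution
#' rate (events split evenly between insertions and deletions;
#' Zipf-distributed lengths). Homology is tracked exactly: every site
#' ever created occupies one global alignment column, so the output is a
#' true-homology gapped multiple alignment — removing the gaps of any row
#' recovers that tip's evolved sequence.
#'
#' @param gene_tree [ape::phylo] with branch lengths.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param region_id id for the resulting alignment.
#' @return a `gap_alignment`.
#' @export
simulate_alignment <- function(gene_tree, config, seed = 1L,
                               region_id = "sim") {
  with_seed(seed, sim_alignment_(gene_tree, config, region_id))
}

sim_alignment_ <- function(tree, cfg, region_id) {
  ntip <- length(tree$tip.label)
  Q <- gtr_q(cfg$gtr_rates, cfg$base_freqs)
  L0 <- max(1L, stats::rpois(1L, cfg$mean_seq_length))
  glob <- seq_len(L0)                    # global column order (site ids)
  n_sites <- L0
  root_state <- sample.int(4L, L0, replace = TRUE, prob = cfg$base_freqs)
  edges <- reorder(tree, "cladewise")$edge
  lens <- reorder(tree, "cladewise")$edge.length
  seqs <- vector("list", ntip + tree$Nnode)  # list(ids, nuc)
  seqs[[ntip + 1L]] <- list(ids = glob, nuc = root_state)

  evolve_branch <- function(node_seq, t) {
    ids <- node_seq$ids; nuc <- node_seq$nuc
    born <- numeric(length(ids))         # time into branch each site appeared
    u <- 0
    repeat {
      L <- length(ids)
      rate <- cfg$indel_rate * L
      if (rate <= 0) break
      u <- u + stats::rexp(1L, rate)
      if (u >= t) break
      z <- zipf_sample(1L, cfg$indel_zipf_exponent, cfg$indel_max_length)
      if (stats::runif(1L) < 0.5) {      # insertion after position j in 0..L
        j <- sample.int(L + 1L, 1L) - 1L
        new_ids <- n_sites + seq_len(z)
        n_sites <<- n_sites + z
        gpos <- if (L == 0L) length(glob)
                else if (j == 0L) match(ids[1L], glob) - 1L
                else match(ids[j], glob)
        glob <<- append(glob, new_ids, after = gpos)
        ids <- append(ids, new_ids, after = j)
        nuc <- append(nuc, sample.int(4L, z, replace = TRUE,
                                      prob = cfg$base_freqs), after = j)
        born <- append(born, rep(u, z), after = j)
      } else {                           # deletion starting at position j
        if (L == 0L) next
        j <- sample.int(L, 1L)
        del <- j:min(L, j + z - 1L)
        ids <- ids[-del]; nuc <- nuc[-del]; born <- born[-del]
      }
    }
    # substitutions over each site's residence time on the branch
    # (drawn against the pre-branch states, never against updated ones)
    new_nuc <- nuc
    for (b in unique(born)) {
      sel <- which(born == b)
      P <- gtr_transition(Q, cfg$base_freqs, t - b)
      for (s in 1:4) {
        at <- sel[nuc[sel] == s]
        if (length(at))
          new_nuc[at] <- sample.int(4L, length(at), replace = TRUE,
                                    prob = P[s, ])
      }
    }
    list(ids = ids, nuc = new_nuc)
  }

  for (i in seq_len(nrow(edges)))
    seqs[[edges[i, 2L]]] <- evolve_branch(seqs[[edges[i, 1L]]], lens[i])

  width <- length(glob)
  pos_of <- integer(n_sites)
  pos_of[glob] <- seq_len(width)
  letters4 <- c("A", "C", "G", "T")
  rows <- vapply(seq_len(ntip), function(i) {
    r <- rep("-", width)
    r[pos_of[seqs[[i]]$ids]] <- letters4[seqs[[i]]$nuc]
    paste(r, collapse = "")
  }, character(1L))
  new_alignment(tree$tip.label, rows, region_id = region_id)
}

#' Simulate a binary trait along a gene tree
#'
#' A two-state continuous-time Markov chain: the root state is drawn from
#' the stationary distribution and evolves along every branch. State 1
#' maps to phenotype `yes`, state 0 to `no`.
#'
#' @param gene_tree [ape::phylo] with branch lengths.
#' @param rate01 rate no -> yes per unit branch length.
#' @param rate10 rate yes -> no; defaults to `rate01` (symmetric trait).
#' @param seed integer seed.
#' @return named factor of tip phenotypes (levels `no`, `yes`,
#'   `unknown`).
#' @export
simulate_trait <- function(gene_tree, rate01, rate10 = rate01, seed = 1L) {
  if (rate01 < 0 || rate10 < 0) stop_input("trait rates must be >= 0")
  if (rate01 == 0 && rate10 == 0)
    stop_input("both trait rates are zero: the trait cannot evolve")
  with_seed(seed, {
    ntip <- length(gene_tree$tip.label)
    q <- rate01 + rate10
    pi1 <- rate01 / q
    state <- integer(ntip + gene_tree$Nnode)
    state[ntip + 1L] <- stats::rbinom(1L, 1L, pi1)
    edges <- reorder(gene_tree, "cladewise")$edge
    lens <- reorder(gene_tree, "cladewise")$edge.length
    for (i in seq_len(nrow(edges))) {
      s <- state[edges[i, 1L]]
      e <- exp(-q * lens[i])
      p1 <- pi1 + (s - pi1) * e       # P(state 1 | parent s)
      state[edges[i, 2L]] <- stats::rbinom(1L, 1L, p1)
    }
    make_labels(gene_tree$tip.label,
                ifelse(state[seq_len(ntip)] == 1L, "yes", "no"))
  })
}

#' Replace random tip sequences with all gaps
#'
#' Models lineage-specific whole-gene deletion (or an unalignable/absent
#' gene copy): each tip row is independently replaced by an all-gap row
#' with probability `mask_prob`.
#'
#' @param alignment a `gap_alignment`.
#' @param mask_prob per-tip masking probability in \[0, 1\].
#' @param seed integer seed.
#' @return list with `alignment` (masked `gap_alignment`) and
#'   `masked_tips` (character vector).
#' @export
apply_masking <- function(alignment, mask_prob, seed = 1L) {
  stopifnot(inherits(alignment, "gap_alignment"))
  if (mask_prob < 0 || mask_prob > 1) stop_input("mask_prob must be in [0, 1]")
  mask <- with_seed(seed,
                    stats::runif(length(alignment$species)) < mask_prob)
  alignment$seq[mask, ] <- "-"
  list(alignment = alignment, masked_tips = alignment$species[mask])
}

#' Simulate one benchmark region
#'
#' Gene tree, gapped alignment, binary trait and masking, all replayable
#' from `(region_id, config$seed, config)`.
#'
#' @param config a [sim_config()].
#' @param region_id region identifier (also a seed component).
#' @return a `sim_region` list: `region_id`, `gene_tree`, `alignment`,
#'   `trait`, `associated` (TRUE: the trait evolved on this region's gene
#'   tree), `masked_tips`.
#' @export
simulate_region <- function(config, region_id = "region1") {
  stopifnot(inherits(config, "sim_config"))
  base <- derive_seed(config$seed, region_id)
  gt <- with_seed(derive_seed(base, "genetree"),
                  msc_one_tree(config$species_tree, config$coalescent_scale))
  aln <- simulate_alignment(gt, config, seed = derive_seed(base, "aln"),
                            region_id = region_id)
  # redraw a degenerate trait (fewer than 2 tips in a class): such traits
  # cannot be cross-validated and carry no learnable signal
  trait <- NULL
  for (try in 1:100) {
    trait <- simulate_trait(gt, config$trait_rate,
                            seed = derive_seed(base, "trait", try))
    if (sum(trait == "yes") >= 2L && sum(trait == "no") >= 2L) break
  }
  msk <- apply_masking(aln, config$mask_prob, seed = derive_seed(base, "mask"))
  structure(list(region_id = region_id, gene_tree = gt,
                 alignment = msk$alignment, trait = trait,
                 associated = TRUE, masked_tips = msk$masked_tips),
            class = "sim_region")
}

#' Simulate a set of benchmark regions
#'
#' @param config a [sim_config()].
#' @param n_regions how many (defaults to `config$n_regions`).
#' @return list of `sim_region` objects named `region1`, `region2`, ...
#' @export
simulate_regions <- function(config, n_regions = config$n_regions) {
  ids <- paste0("region", seq_len(n_regions))
  stats::setNames(lapply(ids, function(id) simulate_region(config, id)), ids)
}

#' @export
print.sim_region <- function(x, ...) {
  cat("Simulated region '", x$region_id, "': ", length(x$alignment$species),
      " tips, ", ncol(x$alignment$seq), " columns, ",
      sum(x$trait == "yes"), " yes / ", sum(x$trait == "no"), " no, ",
      length(x$masked_tips), " masked\n", sep = "")
  invisible(x)
}

#' Write simulated regions to disk
#'
#' Per region: FASTA alignment, trait TSV, gene-tree Newick; plus a
#' truth table across regions.
#'
#' @param regions list of `sim_region`.
#' @param dir output directory (created).
#' @export
write_regions <- function(regions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in regions) {
    seqs <- as.character(r$alignment)
    writeLines(paste0(">", names(seqs), "\n", seqs),
               file.path(dir, paste0(r$region_id, ".fasta")))
    utils::write.table(
      data.frame(species = names(r$trait), phenotype = as.character(r$trait)),
      file.path(dir, paste0(r$region_id, ".trait.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(r$gene_tree,
                    file.path(dir, paste0(r$region_id, ".genetree.nwk")))
  }
  truth <- data.frame(
    region_id = vapply(regions, `[[`, "", "region_id"),
    associated = vapply(regions, `[[`, TRUE, "associated"))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the simulation benchmark
#'
#' The full evaluation protocol: simulate `n_regions` regions, run the
#' selection pipeline on each with the trait simulated on the region's
#' own gene tree (alignment-only features and, optionally, alignment +
#' species-tree clade features), then repeat with random Bernoulli(0.5)
#' labels unrelated to the alignments. A region counts as called when its
#' minimum cross-validation error is at or below `threshold`; calls under
#' the true traits give the true positive rate, calls under random labels
#' the false positive rate.
#'
#' @param config a [sim_config()].
#' @param grid hyperparameter [gap_grid()] (default [reduced_grid()]).
#' @param n_regions number of regions (defaults to `config$n_regions`).
#' @param threshold calling threshold on the minimum CV error.
#' @param with_tree also run with clade features appended.
#' @param null_labels also run with randomized labels (for the FPR).
#' @param progress print a line every 10 regions.
#' @return a `gapnet_benchmark` list: `per_region` data.frame (columns
#'   `err_aln`, `err_tree`, `err_aln_null`, `err_tree_null`, ...) and
#'   `metrics` (mean CV errors, TPR and FPR per feature set).
#' @export
run_benchmark <- function(config, grid = reduced_grid(),
                          n_regions = config$n_regions, threshold = 0.1,
                          with_tree = TRUE, null_labels = TRUE,
                          progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  sp_tree <- config$species_tree
  rows <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    id <- paste0("region", i)
    reg <- simulate_region(config, id)
    seed_i <- derive_seed(config$seed, "fit", id)
    err <- function(labels, tree) {
      fit <- tryCatch(gapnet(reg$alignment, labels, tree = tree, grid = grid,
                             seed = seed_i),
                      error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$cv_error
    }
    null_lab <- if (null_labels) random_labels(sp_tree$tip.label,
                                               derive_seed(config$seed,
                                                           "null", id))
    rows[[i]] <- data.frame(
      region_id = id,
      n_yes = sum(reg$trait == "yes"),
      n_masked = length(reg$masked_tips),
      err_aln = err(reg$trait, NULL),
      err_tree = if (with_tree) err(reg$trait, sp_tree) else NA_real_,
      err_aln_null = if (null_labels) err(null_lab, NULL) else NA_real_,
      err_tree_null = if (null_labels && with_tree) err(null_lab, sp_tree)
                      else NA_real_)
    if (progress && i %% 10L == 0L)
      message(sprintf("  %d / %d regions", i, n_regions))
  }
  per_region <- do.call(rbind, rows)
  called <- function(e) mean(e[!is.na(e)] <= threshold)
  metrics <- list(
    mean_cv_error_aln = mean(per_region$err_aln, na.rm = TRUE),
    mean_cv_error_tree = mean(per_region$err_tree, na.rm = TRUE),
    tpr_aln = called(per_region$err_aln),
    tpr_tree = called(per_region$err_tree),
    fpr_aln = called(per_region$err_aln_null),
    fpr_tree = called(per_region$err_tree_null))
  structure(list(per_region = per_region, metrics = metrics,
                 threshold = threshold, n_regions = n_regions,
                 config = config),
            class = "gapnet_benchmark")
}

random_labels <- function(species, seed) {
  for (try in 1:100) {
    lab <- with_seed(derive_seed(seed, try),
                     ifelse(stats::runif(length(species)) < 0.5, "yes", "no"))
    if (sum(lab == "yes") >= 2L && sum(lab == "no") >= 2L) break
  }
  make_labels(species, lab)
}

#' @export
print.gapnet_benchmark <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Simulation benchmark: %d regions, threshold %.3g\n",
              x$n_regions, x$threshold))
  cat(sprintf("  alignment only : mean CV error %.4g | TPR %.3f | FPR %s\n",
              m$mean_cv_error_aln, m$tpr_aln,
              if (is.na(m$fpr_aln)) "NA" else sprintf("%.3f", m$fpr_aln)))
  if (!is.na(m$mean_cv_error_tree))
    cat(sprintf("  + species tree : mean CV error %.4g | TPR %.3f | FPR %s\n",
                m$mean_cv_error_tree, m$tpr_tree,
                if (is.na(m$fpr_tree)) "NA" else sprintf("%.3f", m$fpr_tree)))
  invisible(x)
}
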