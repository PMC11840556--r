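# Fixtures are built in code; nothing is read from disk except through
# tempfiles written by the tests themselves.

# tiny hand-made alignment: gap pattern carries a clean yes/no split
toy_alignment <- function() {
  new_alignment(
    species = paste0("sp", 1:6),
    seqs = c("ACGTACGT",
             "ACGTAC--",
             "ACG--C--",
             "A-GTACGT",
             "A-G--CGT",
             "ACGTACGT"),
    region_id = "toy")
}

toy_labels <- function() {
  make_labels(paste0("sp", 1:6), c("yes", "yes", "no", "yes", "no", "unknown"))
}

# a region where one contiguous block of columns is gapped in exactly the
# "no" species, on a background of noise gaps. Background gaps are spread
# proportionally across the two classes so that non-block columns carry no
# class signal even in-sample: any position the method flags outside the
# block is then a genuine false positive, not a chance correlate.
block_region <- function(n_species = 50, p = 500, block = 201:225,
                         n_no = 20, noise = 0.08, seed = 42) {
  set.seed(seed)
  species <- sprintf("s%02d", seq_len(n_species))
  lab <- rep("yes", n_species)
  lab[sample.int(n_species, n_no)] <- "no"
  idx_no <- which(lab == "no"); idx_yes <- which(lab == "yes")
  mat <- matrix(sample(c("A", "C", "G", "T"), n_species * p, replace = TRUE),
                n_species, p)
  for (j in setdiff(seq_len(p), block)) {
    g <- rbinom(1, n_species, noise)
    g_no <- min(length(idx_no), round(g * length(idx_no) / n_species))
    g_yes <- min(length(idx_yes), g - g_no)
    rows <- c(sample(idx_no, g_no), sample(idx_yes, g_yes))
    mat[rows, j] <- "-"
  }
  mat[, block] <- "A"                     # block starts clean
  mat[lab == "no", block] <- "-"          # gapped exactly in the no class
  list(alignment = new_alignment(species, apply(mat, 1, paste, collapse = "")),
       labels = make_labels(species, lab),
       block = block)
}

# small grid for fast unit tests (not the reduced benchmark profile)
tiny_grid <- function(layers = 0L)
  gap_grid(lambdas = c(1e-4, 1e-1), gammas = c(0, 1), layers = layers, k = 2L)

# quick training config for tests that only need a working fit
quick_config <- function(epochs = 150L) training_config(epochs = epochs)

write_fasta_tmp <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
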