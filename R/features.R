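#' Principal-component features of a gap matrix
#'
#' Reduces the centered gap matrix to the smallest number m of principal
#' components whose cumulative explained variance reaches `var_threshold`
#' (default 95%), capped at p - 1 so that m < p always holds. Columns are
#' centered but never rescaled. The decomposition is a plain SVD of the
#' centered matrix; the sign of each loading vector is fixed so that its
#' largest-magnitude entry is positive, making results reproducible.
#'
#' @param gm a centered `gap_matrix` with at least 2 rows.
#' @param var_threshold fraction of variance to capture, in (0, 1].
#' @return an object of class `gap_pca`: `scores` (n x m, the z features),
#'   `loadings` (p x m orthonormal), `explained_fraction`, `m`, `sdev`
#'   (all singular-value sds), and the preprocessing handles
#'   `position_index` / `column_means` copied from `gm`.
#' @export
pca_reduce <- function(gm, var_threshold = 0.95) {
  stopifnot(inherits(gm, "gap_matrix"))
  if (!gm$centered) stop_input("pca_reduce expects a centered gap matrix")
  if (!is.numeric(var_threshold) || length(var_threshold) != 1L ||
      var_threshold <= 0 || var_threshold > 1)
    stop_input("var_threshold must be in (0, 1]")
  X <- gm$values
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop_input("need at least 2 species for PCA")
  sv <- svd(X)
  ev <- sv$d^2 # proportional to explained variance
  pos <- ev > max(ev) * 1e-12
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= var_threshold)[1L]
  m <- min(m, p - 1L, sum(pos), n - 1L)
  m <- max(m, 1L)
  V <- sv$v[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-|entry| element of each loading is positive
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(m))
  rownames(scores) <- gm$species
  structure(list(scores = scores, loadings = V,
                 explained_fraction = cum[m], m = m,
                 sdev = sv$d / sqrt(max(1, n - 1)),
                 position_index = gm$position_index,
                 column_means = gm$column_means,
                 species = gm$species),
            class = "gap_pca")
}

#' @export
print.gap_pca <- function(x, ...) {
  cat("Gap PCA: m =", x$m, "components capturing",
      format(100 * x$explained_fraction, digits = 4), "% of variance\n")
  invisible(x)
}

#' Project gap-matrix rows onto stored principal components
#'
#' Used to score additional species (e.g. unknown-status species) in the
#' same PC space as the fit: the rows must have been encoded with the same
#' retained positions and centered with the stored column means.
#'
#' @param pc a `gap_pca`.
#' @param gm a `gap_matrix` whose columns match `pc$position_index`. If the
#'   matrix is uncentered it is centered here with `pc$column_means`.
#' @return rows x m score matrix.
#' @export
project_rows <- function(pc, gm) {
  stopifnot(inherits(pc, "gap_pca"))
  X <- if (inherits(gm, "gap_matrix")) {
    if (ncol(gm$values) != nrow(pc$loadings))
      stop_input("column mismatch: matrix has ", ncol(gm$values),
                 " positions, loadings expect ", nrow(pc$loadings))
    if (gm$centered) gm$values
    else sweep(gm$values, 2L, pc$column_means)
  } else {
    gm <- as.matrix(gm)
    if (ncol(gm) != nrow(pc$loadings)) stop_input("column mismatch")
    gm
  }
  out <- X %*% pc$loadings
  colnames(out) <- colnames(pc$loadings)
  out
}

#' Clade-membership features from a rooted species tree
#'
#' Every internal node of the rooted tree except the root defines one
#' binary feature column: species i gets a 1 when it descends from that
#' node and 0 otherwise. The root clade contains all species (all 1s) and
#' is therefore uninformative and dropped, so a tree with c internal nodes
#' yields t = c - 1 features. Columns follow the tree's preorder node
#' numbering; polytomies are allowed. Branch lengths are ignored (topology
#' only).
#'
#' @param tree an [ape::phylo] rooted tree, or a path to / string of rooted
#'   Newick.
#' @param species_order character vector giving the row order; every
#'   element must be a tip of the tree.
#' @return an object of class `gap_treefeatures`: `values` (n x t binary
#'   matrix), `clade_ids`, `t`, and `c` (internal nodes before root
#'   removal).
#' @export
encode_tree_features <- function(tree, species_order) {
  tree <- as_rooted_tree(tree)
  species_order <- as.character(species_order)
  missing <- setdiff(species_order, tree$tip.label)
  if (length(missing))
    stop_input("species not in tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + nnode), root)
  # preorder over internal nodes
  ord <- reorder(tree, "cladewise")$edge[, 2L]
  internal <- ord[ord %in% internal]
  tipsets <- descendant_tips(tree)
  vals <- matrix(0L, nrow = length(species_order), ncol = length(internal),
                 dimnames = list(species_order, NULL))
  clade_ids <- character(length(internal))
  for (j in seq_along(internal)) {
    tips <- tree$tip.label[tipsets[[internal[j] - ntip]]]
    vals[species_order %in% tips, j] <- 1L
    clade_ids[j] <- paste0("clade", internal[j] - ntip)
  }
  colnames(vals) <- clade_ids
  structure(list(values = vals, clade_ids = clade_ids,
                 t = length(internal), c = nnode),
            class = "gap_treefeatures")
}

as_rooted_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1L && file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
    if (is.null(tree)) stop_input("could not parse Newick tree")
  }
  if (!inherits(tree, "phylo")) stop_input("tree must be a phylo object or Newick")
  if (!ape::is.rooted(tree)) stop_input("tree must be rooted")
  tree
}

# tip indices under each internal node (list indexed by node - ntip)
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", tree$Nnode)
  edges <- reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    par <- edges[i, 1L] - ntip
    ch <- edges[i, 2L]
    add <- if (ch <= ntip) ch else sets[[ch - ntip]]
    sets[[par]] <- c(sets[[par]], add)
  }
  lapply(sets, sort)
}

#' @export
print.gap_treefeatures <- function(x, ...) {
  cat("Tree features:", nrow(x$values), "species x", x$t,
      "clades (root removed)\n")
  invisible(x)
}

#' Assemble the classifier feature table
#'
#' Horizontally concatenates the PC scores z with the clade features t when
#' a tree is supplied, giving the network input of width m (+ t).
#'
#' @param pc a `gap_pca`.
#' @param tf optional `gap_treefeatures` with matching row order.
#' @return an object of class `gap_features`: `values` (n x (m \[+ t\])),
#'   `feature_names`, `m`, `includes_tree`.
#' @export
assemble_features <- function(pc, tf = NULL) {
  stopifnot(inherits(pc, "gap_pca"))
  vals <- pc$scores
  if (!is.null(tf)) {
    stopifnot(inherits(tf, "gap_treefeatures"))
    if (!identical(rownames(tf$values), rownames(pc$scores)))
      stop_input("row order of tree features does not match PC scores")
    vals <- cbind(pc$scores, tf$values)
  }
  structure(list(values = vals, feature_names = colnames(vals),
                 m = pc$m, includes_tree = !is.null(tf)),
            class = "gap_features")
}
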