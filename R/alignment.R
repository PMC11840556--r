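#' Read a multiple sequence alignment from FASTA
#'
#' Reads one aligned genomic region. All records must have equal length
#' (it is an alignment, not a set of unaligned reads); sequence case is
#' normalized to upper case. The gap character is `-`; every other symbol
#' (including `N` and IUPAC ambiguity codes) counts as a nucleotide being
#' present. A record consisting entirely of `-` is valid and models a
#' whole-region deletion in that species.
#'
#' @param path path to an aligned FASTA file.
#' @param region_id identifier for the region; defaults to the file name
#'   without extension.
#' @return an object of class `gap_alignment`: a list with `species`
#'   (character vector of record ids), `seq` (n x width character matrix)
#'   and `region_id`.
#' @export
read_alignment <- function(path, region_id = NULL) {
  if (!file.exists(path)) stop_input("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop_input("not a FASTA file (no leading '>'): ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids) # first token only
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  if (length(seqs) != length(ids))
    stop_input("FASTA record without sequence in ", path)
  region_id <- region_id %||% sub("\\.[^.]*$", "", basename(path))
  new_alignment(ids, toupper(seqs), region_id)
}

#' Construct an alignment object from sequences in memory
#'
#' @param species character vector of unique species ids.
#' @param seqs character vector of equal-length aligned sequences
#'   (gap = `-`), same length as `species`.
#' @param region_id region identifier string.
#' @return a `gap_alignment` object; see [read_alignment()].
#' @export
new_alignment <- function(species, seqs, region_id = "region") {
  species <- as.character(species)
  seqs <- toupper(as.character(seqs))
  if (length(species) != length(seqs))
    stop_input("species and seqs lengths differ")
  if (anyDuplicated(species))
    stop_input("duplicate species ids: ",
               paste(unique(species[duplicated(species)]), collapse = ", "))
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop_input("sequences are not aligned: lengths ",
               paste(sort(w), collapse = ", "))
  if (w == 0L) stop_input("alignment has zero columns")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(species), byrow = TRUE,
              dimnames = list(species, NULL))
  structure(list(species = species, seq = m, region_id = region_id),
            class = "gap_alignment")
}

#' @export
print.gap_alignment <- function(x, ...) {
  cat("Alignment '", x$region_id, "': ", length(x$species), " species x ",
      ncol(x$seq), " columns (",
      format(100 * mean(x$seq == "-"), digits = 3), "% gaps)\n", sep = "")
  invisible(x)
}

#' @export
as.character.gap_alignment <- function(x, ...) {
  stats::setNames(apply(x$seq, 1L, paste, collapse = ""), x$species)
}

#' Read a species phenotype table
#'
#' Expects a TSV with header `species<TAB>phenotype`; phenotype is one of
#' `yes`, `no`, `unknown` (case-insensitive).
#'
#' @param path path to the TSV file.
#' @return a named factor with levels `no`, `yes`, `unknown`, named by
#'   species.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_input("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_input("label table needs two columns")
  make_labels(tab[[1L]], tab[[2L]])
}

#' Construct a phenotype label vector
#'
#' @param species character vector of species ids (unique).
#' @param phenotype character vector over `yes` / `no` / `unknown`
#'   (case-insensitive), parallel to `species`.
#' @return named factor with levels `no`, `yes`, `unknown`.
#' @export
make_labels <- function(species, phenotype) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop_input("duplicate species in label table")
  ph <- tolower(trimws(as.character(phenotype)))
  bad <- setdiff(unique(ph), c("yes", "no", "unknown"))
  if (length(bad))
    stop_input("invalid phenotype value(s): ", paste(bad, collapse = ", "))
  stats::setNames(factor(ph, levels = c("no", "yes", "unknown")), species)
}

#' One-hot encode alignment gaps
#'
#' Converts an alignment into the binary presence/absence matrix x: entry
#' `x[i, j]` is 0 where species i has a gap at column j and 1 where it has
#' any nucleotide (the encoding depends only on gap vs non-gap, never on
#' nucleotide identity). No columns are dropped at this stage.
#'
#' @param aln a `gap_alignment`.
#' @return an object of class `gap_matrix` with elements `values` (n x p
#'   numeric), `species`, `position_index` (original 1-based alignment
#'   columns), `centered` (flag) and `column_means` (`NULL` until
#'   [center_columns()] is applied).
#' @export
one_hot_gaps <- function(aln) {
  stopifnot(inherits(aln, "gap_alignment"))
  v <- (aln$seq != "-") * 1
  dimnames(v) <- list(aln$species, NULL)
  new_gap_matrix(v, aln$species, seq_len(ncol(v)), centered = FALSE,
                 column_means = NULL, region_id = aln$region_id)
}

new_gap_matrix <- function(values, species, position_index, centered,
                           column_means, region_id = "region") {
  structure(list(values = values, species = species,
                 position_index = as.integer(position_index),
                 centered = centered, column_means = column_means,
                 region_id = region_id),
            class = "gap_matrix")
}

#' @export
print.gap_matrix <- function(x, ...) {
  cat("Gap matrix: ", nrow(x$values), " species x ", ncol(x$values),
      " positions", if (x$centered) " (centered)", "\n", sep = "")
  invisible(x)
}

#' Remove invariant alignment positions
#'
#' Keeps exactly the columns whose gap/nucleotide state differs across the
#' supplied rows; `position_index` keeps track of the original 1-based
#' alignment coordinates of the retained columns.
#'
#' @param gm an uncentered `gap_matrix`.
#' @return a filtered `gap_matrix`.
#' @export
filter_invariant <- function(gm) {
  stopifnot(inherits(gm, "gap_matrix"))
  if (gm$centered) stop_input("filter_invariant expects an uncentered matrix")
  keep <- matrixStats_colVar(gm$values) > 0
  if (!any(keep))
    stop_input("no informative positions: all alignment columns are invariant")
  new_gap_matrix(gm$values[, keep, drop = FALSE], gm$species,
                 gm$position_index[keep], centered = FALSE,
                 column_means = NULL, region_id = gm$region_id)
}

# variance per column without an extra dependency; binary input so
# "any difference from row 1" is enough, but keep it general
matrixStats_colVar <- function(m) {
  mu <- colMeans(m)
  colMeans(m * m) - mu * mu
}

#' Center gap-matrix columns
#'
#' Subtracts each column's mean (computed over all supplied rows, labeled
#' and unknown alike) and records the means so that new rows can later be
#' centered consistently. Centering an already-centered matrix is a no-op.
#'
#' @param gm a `gap_matrix` (usually after [filter_invariant()]).
#' @return a centered `gap_matrix` with `column_means` recorded.
#' @export
center_columns <- function(gm) {
  stopifnot(inherits(gm, "gap_matrix"))
  if (gm$centered) return(gm)
  mu <- colMeans(gm$values)
  new_gap_matrix(sweep(gm$values, 2L, mu), gm$species, gm$position_index,
                 centered = TRUE, column_means = mu, region_id = gm$region_id)
}

#' Encode, filter and center in one step
#'
#' Convenience wrapper: [one_hot_gaps()] then [filter_invariant()] then
#' [center_columns()].
#'
#' @param aln a `gap_alignment`.
#' @return a centered, filtered `gap_matrix`.
#' @export
encode_alignment <- function(aln) {
  center_columns(filter_invariant(one_hot_gaps(aln)))
}

#' Write an encoded gap matrix as TSV
#'
#' Species as rows; original alignment column numbers as headers.
#'
#' @param gm a `gap_matrix`.
#' @param path output file.
#' @export
write_gap_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "gap_matrix"))
  df <- as.data.frame(gm$values)
  names(df) <- gm$position_index
  df <- cbind(species = gm$species, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
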