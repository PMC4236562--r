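# Distance-based phylogenetics: alignment slicing, JC69 / p distances with
# pairwise deletion, neighbour-joining (via ape), bootstrap support and
# outgroup-rooted monophyly testing. The same machinery serves the 16S
# nucleotide tree and the prenyltransferase protein tree (p-distance).

#' Keep the leading columns of an alignment
#'
#' @param msa Named character vector of equal-length gapped strings.
#' @param length Number of columns to keep (e.g. 929 for the 16S fragment).
#' @param start First column of the slice, default 1.
#' @return The sliced alignment.
#' @export
slice_alignment <- function(msa, length, start = 1) {
  w <- unique(nchar(msa))
  stopifnot(length(w) == 1)
  if (length < 1) stop("slice length must be >= 1")
  if (start + length - 1 > w) stop("alignment has ", w,
                                   " columns; cannot slice ", length,
                                   " from ", start)
  vapply(msa, substr, character(1), start, start + length - 1)
}

.valid_chars <- function(alphabet) {
  if (alphabet == "dna") c("A", "C", "G", "T")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' Pairwise distances under JC69 or raw p-distance
#'
#' Columns where either sequence has a gap or ambiguous symbol are dropped
#' for that pair (pairwise deletion). `jc69_distance()` applies the
#' Jukes-Cantor correction `d = -(3/4) ln(1 - 4p/3)` and errors (naming the
#' pair) when `p >= 0.75`, where the correction is undefined (saturation).
#' `p_distance()` returns the uncorrected mismatch proportion and also
#' works on protein alignments.
#'
#' @param msa Named character vector of equal-length strings (>= 2 rows).
#' @param alphabet `"dna"` or `"protein"` (p-distance only).
#' @return Symmetric distance matrix with zero diagonal, taxa as dimnames.
#' @export
jc69_distance <- function(msa) {
  p <- .mismatch_matrix(msa, "dna")
  if (any(p >= 0.75)) {
    bad <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)[1, ]
    stop("saturated pair (p >= 0.75): ", rownames(p)[bad[1]], " vs ",
         colnames(p)[bad[2]])
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  diag(d) <- 0
  d
}

#' @rdname jc69_distance
#' @export
p_distance <- function(msa, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  .mismatch_matrix(msa, alphabet)
}

.mismatch_matrix <- function(msa, alphabet) {
  n <- length(msa)
  if (n < 2) stop("need >= 2 sequences")
  if (length(unique(nchar(msa))) != 1) stop("rows must have equal length")
  if (is.null(names(msa))) names(msa) <- paste0("taxon", seq_len(n))
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  ok <- matrix(chars %in% .valid_chars(alphabet), nrow = n)
  p <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      valid <- ok[i, ] & ok[j, ]
      if (!any(valid)) stop("no comparable columns for pair ",
                            names(msa)[i], " vs ", names(msa)[j])
      p[i, j] <- p[j, i] <- sum(chars[i, valid] != chars[j, valid]) / sum(valid)
    }
  }
  p
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \code{ape::nj}); negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to 0
#' with a warning. The result is unrooted.
#'
#' @param D Symmetric distance matrix with >= 3 taxa.
#' @return An \code{ape} \code{phylo} tree.
#' @export
neighbor_joining <- function(D) {
  if (nrow(D) < 3) stop("neighbour joining needs >= 3 taxa")
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for the neighbour-joining tree
#'
#' Builds the full-data NJ tree, then `n_replicates` trees from alignments
#' resampled column-wise with replacement (seeded). Each internal edge of
#' the full-data tree is annotated (as `node.label`) with the percentage of
#' replicate trees containing the same bipartition. Replicates whose
#' distance matrix has a saturated pair are skipped with a warning and the
#' denominator adjusts.
#'
#' @param msa Named character vector (alignment rows).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer RNG seed.
#' @param distance Distance function taking an msa, default [jc69_distance()].
#' @return The full-data `phylo` tree with `node.label` supports in
#'   \[0, 100\].
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1,
                              distance = jc69_distance) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  full <- neighbor_joining(distance(msa))
  chars <- do.call(rbind, strsplit(msa, ""))
  ncol_aln <- ncol(chars)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rep_trees <- list()
  skipped <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_msa <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                              collapse = ""), names(msa))
    t <- tryCatch(suppressWarnings(neighbor_joining(distance(rep_msa))),
                  error = function(e) NULL)
    if (is.null(t)) skipped <- skipped + 1L else
      rep_trees[[length(rep_trees) + 1L]] <- t
  }
  if (skipped > 0) {
    warning(skipped, " replicate(s) skipped (saturated pair); supports use ",
            length(rep_trees), " trees")
  }
  if (length(rep_trees) == 0) stop("all bootstrap replicates failed")
  class(rep_trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- round(100 * counts / length(rep_trees), 1)
  full
}

#' Root on an outgroup and test monophyly of a taxon set
#'
#' The tree is rooted on the outgroup leaf; the result is `TRUE` iff
#' `taxa_subset` is exactly the leaf set of some clade of the rooted tree.
#'
#' @param tree A `phylo` tree.
#' @param taxa_subset Non-empty character vector of tip labels, excluding
#'   the outgroup.
#' @param outgroup_taxon Tip label used to root the tree.
#' @return Logical scalar.
#' @export
root_and_test_monophyly <- function(tree, taxa_subset, outgroup_taxon) {
  unknown <- setdiff(c(taxa_subset, outgroup_taxon), tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (length(taxa_subset) == 0) stop("taxa_subset is empty")
  if (outgroup_taxon %in% taxa_subset) stop("taxa_subset must exclude the outgroup")
  rooted <- ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa_subset)
}
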