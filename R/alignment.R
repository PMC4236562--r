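# Global pairwise alignment and percent identity -- the quantitative basis
# for every homology statement in the cluster comparison.

#' Scoring schemes for global alignment
#'
#' `protein_scheme()` uses BLOSUM62 with affine gap penalties; a gap of
#' length k costs `gap_open + (k - 1) * gap_extend`. `nucleotide_scheme()`
#' uses a simple match/mismatch matrix. `gap_open <= gap_extend <= 0`.
#'
#' @param gap_open Score for the first residue of a gap (non-positive).
#' @param gap_extend Score for each further gap residue (non-positive).
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @return A `scoring_scheme` object: substitution matrix, gap penalties and
#'   alphabet type.
#' @export
protein_scheme <- function(gap_open = -10, gap_extend = -1) {
  mat <- .blosum62()
  .new_scheme(mat, gap_open, gap_extend, "protein")
}

#' @rdname protein_scheme
#' @export
nucleotide_scheme <- function(match = 2, mismatch = -3,
                              gap_open = -5, gap_extend = -2) {
  alpha <- c("A", "C", "G", "T")
  mat <- matrix(mismatch, 4, 4, dimnames = list(alpha, alpha))
  diag(mat) <- match
  .new_scheme(mat, gap_open, gap_extend, "nucleotide")
}

.new_scheme <- function(mat, gap_open, gap_extend, alphabet) {
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("require gap_open <= gap_extend <= 0")
  }
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend,
                 alphabet = alphabet),
            class = "scoring_scheme")
}

.blosum62_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum62_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    keep <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
    .blosum62_cache$mat <- e$BLOSUM62[keep, keep]
  }
  .blosum62_cache$mat
}

.encode_seq <- function(s, scheme, what) {
  chars <- strsplit(toupper(s), "")[[1]]
  idx <- match(chars, rownames(scheme$matrix))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("symbol(s) outside ", scheme$alphabet, " alphabet in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  idx
}

#' Optimal global alignment of two sequences
#'
#' Needleman-Wunsch with affine gaps (three-state recurrence). The traceback
#' is deterministic: ties are broken diagonal > up > left.
#'
#' @param a,b Non-empty sequences consistent with the scheme's alphabet.
#' @param scheme A [protein_scheme()] or [nucleotide_scheme()].
#' @return A `pairwise_alignment`: `aligned_a`, `aligned_b` (equal-length
#'   gapped strings), `score`, and `identity_pct` (gap-inclusive columns,
#'   see [percent_identity()]).
#' @export
needleman_wunsch <- function(a, b, scheme = protein_scheme()) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  ea <- .encode_seq(a, scheme, "a")
  eb <- .encode_seq(b, scheme, "b")
  res <- nw_align_cpp(ea, eb, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  moves <- strsplit(res$moves, "")[[1]]
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  out_a <- character(length(moves))
  out_b <- character(length(moves))
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    m <- moves[k]
    if (m == "D") {
      i <- i + 1L; j <- j + 1L
      out_a[k] <- ca[i]; out_b[k] <- cb[j]
    } else if (m == "U") {
      i <- i + 1L
      out_a[k] <- ca[i]; out_b[k] <- "-"
    } else {
      j <- j + 1L
      out_a[k] <- "-"; out_b[k] <- cb[j]
    }
  }
  aln <- structure(list(aligned_a = paste(out_a, collapse = ""),
                        aligned_b = paste(out_b, collapse = ""),
                        score = res$score,
                        identity_pct = NA_real_),
                   class = "pairwise_alignment")
  aln$identity_pct <- percent_identity(aln)
  aln
}

#' Percent identity of a pairwise alignment
#'
#' `100 * identical residue pairs / alignment columns`, counting gap columns
#' in the denominator; reported to 1 decimal. This gap-inclusive definition
#' is conservative near classification thresholds.
#'
#' @param aln A `pairwise_alignment`.
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  if (length(ca) == 0) stop("zero-length alignment")
  matches <- sum(ca == cb & ca != "-")
  round(100 * matches / length(ca), 1)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment: score", x$score,
      sprintf("(%.1f%% identity, %d columns)\n",
              x$identity_pct, nchar(x$aligned_a)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Center-star multiple alignment
#'
#' The center is the input maximising summed pairwise identity against all
#' others (ties: first in input order); the remaining sequences are merged
#' against it under the "once a gap, always a gap" rule.
#'
#' @param seqs Character vector of >= 2 sequences (names kept if present).
#' @param scheme Scoring scheme.
#' @return Named character vector of equal-length gapped strings, input order.
#' @export
center_star_msa <- function(seqs, scheme = protein_scheme()) {
  n <- length(seqs)
  if (n < 2) stop("need >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  idm <- matrix(100, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <-
        needleman_wunsch(seqs[[i]], seqs[[j]], scheme)$identity_pct
    }
  }
  center <- which.max(rowSums(idm))
  rows <- list(strsplit(toupper(seqs[[center]]), "")[[1]])
  row_ids <- center
  for (k in seq_len(n)[-center]) {
    aln <- needleman_wunsch(seqs[[center]], seqs[[k]], scheme)
    merged <- .merge_into_star(rows, strsplit(aln$aligned_a, "")[[1]],
                               strsplit(aln$aligned_b, "")[[1]])
    rows <- merged
    row_ids <- c(row_ids, k)
  }
  out <- vapply(rows, paste, character(1), collapse = "")
  out <- out[order(row_ids)]
  names(out) <- names(seqs)
  out
}

# rows: list of char vectors, rows[[1]] is the (gapped) center.
# c_new/s_new: a fresh pairwise alignment of the ungapped center vs a new seq.
.merge_into_star <- function(rows, c_new, s_new) {
  c_master <- rows[[1]]
  i <- 1L; j <- 1L
  mi <- integer(0); nj <- integer(0)
  nm <- length(c_master); nn <- length(c_new)
  while (i <= nm || j <= nn) {
    if (i <= nm && c_master[i] == "-") {
      mi <- c(mi, i); nj <- c(nj, 0L); i <- i + 1L
    } else if (j <= nn && c_new[j] == "-") {
      mi <- c(mi, 0L); nj <- c(nj, j); j <- j + 1L
    } else {
      mi <- c(mi, i); nj <- c(nj, j); i <- i + 1L; j <- j + 1L
    }
  }
  out <- lapply(rows, function(r) ifelse(mi > 0L, r[pmax(mi, 1L)], "-"))
  new_row <- ifelse(nj > 0L, s_new[pmax(nj, 1L)], "-")
  c(out, list(new_row))
}
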