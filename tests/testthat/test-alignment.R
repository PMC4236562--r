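simple_scheme <- function(alphabet, match = 1, mismatch = -1,
                          go = -5, ge = -1) {
  mat <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- match
  hapalocompare:::.new_scheme(mat, go, ge, "protein")
}

test_that("identical sequences align gap-free at 100% identity", {
  aln <- needleman_wunsch("MKTAYIAK", "MKTAYIAK")
  expect_equal(aln$identity_pct, 100)
  expect_false(grepl("-", aln$aligned_a))
  expect_false(grepl("-", aln$aligned_b))
})

test_that("a single substitution scores and measures as expected", {
  sch <- simple_scheme(c("A", "C", "D", "E"))
  aln <- needleman_wunsch("ACDE", "ACDD", sch)
  expect_equal(aln$score, 2)            # 3 matches - 1 mismatch
  expect_equal(aln$identity_pct, 75.0)
  expect_false(grepl("-", aln$aligned_a))
  expect_equal(aln$score, oracle_nw_score("ACDE", "ACDD", sch))
})

test_that("deletions are placed optimally (brute-force check)", {
  sch <- simple_scheme(c("M", "K", "T"))
  aln <- needleman_wunsch("MKT", "MT", sch)
  expect_equal(aln$score, oracle_nw_score("MKT", "MT", sch))
  expect_equal(nchar(aln$aligned_a), 3)
  expect_equal(lengths(regmatches(aln$aligned_b, gregexpr("-", aln$aligned_b))), 1)
})

test_that("alignment rejects empty input and foreign symbols", {
  expect_error(needleman_wunsch("", "ACGT", nucleotide_scheme()), "non-empty")
  expect_error(needleman_wunsch("ACGT", "ACGU", nucleotide_scheme()),
               "outside nucleotide alphabet")
  expect_error(protein_scheme(gap_open = -1, gap_extend = -3),
               "gap_open <= gap_extend")
})

test_that("NW score equals the exhaustive-alignment oracle on short pairs", {
  set.seed(101)
  schemes <- list(nucleotide_scheme(), protein_scheme(),
                  nucleotide_scheme(1, -2, -3, -1))
  for (trial in seq_len(200)) {
    sch <- schemes[[sample(3, 1)]]
    alpha <- rownames(sch$matrix)
    if (length(alpha) > 6) alpha <- sample(alpha, 6)
    a <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(needleman_wunsch(a, b, sch)$score,
                 oracle_nw_score(a, b, sch),
                 info = paste(a, "vs", b))
  }
})

test_that("score is symmetric and reversal-invariant", {
  set.seed(77)
  for (trial in seq_len(40)) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:10, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:10, 1), replace = TRUE),
               collapse = "")
    sch <- nucleotide_scheme()
    f <- needleman_wunsch(a, b, sch)
    r <- needleman_wunsch(b, a, sch)
    expect_equal(f$score, r$score)
    expect_equal(f$identity_pct, r$identity_pct)
    rev1 <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
    rev2 <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
    expect_equal(needleman_wunsch(rev1, rev2, sch)$score, f$score)
  }
})

test_that("gapped strings recover the inputs and percent identity is
          column-based", {
  aln <- needleman_wunsch("MKTAYIAK", "MKAYIAK")
  expect_equal(gsub("-", "", aln$aligned_a), "MKTAYIAK")
  expect_equal(gsub("-", "", aln$aligned_b), "MKAYIAK")
  # 7 matching residues over 8 columns (one gap column)
  expect_equal(aln$identity_pct, 87.5)
  fake <- structure(list(aligned_a = "MKTA", aligned_b = "MKTT"),
                    class = "pairwise_alignment")
  expect_equal(percent_identity(fake), 75.0)
  ident <- structure(list(aligned_a = "MKTAYIAKQW", aligned_b = "MKTAYIAKQW"),
                     class = "pairwise_alignment")
  expect_equal(percent_identity(ident), 100)
})

test_that("scores agree with an independent affine-gap implementation", {
  set.seed(9)
  for (trial in seq_len(20)) {
    a <- paste(sample(AA20, sample(10:40, 1), replace = TRUE), collapse = "")
    b <- paste(sample(AA20, sample(10:40, 1), replace = TRUE), collapse = "")
    mine <- needleman_wunsch(a, b, protein_scheme())$score
    # Biostrings charges gapOpening + k * gapExtension for a length-k gap;
    # our -10/-1 open/extend maps to gapOpening 9, gapExtension 1
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = "BLOSUM62",
                                         gapOpening = 9, gapExtension = 1,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("center-star MSA handles identical, indel and permuted inputs", {
  msa <- center_star_msa(c(a = "MKTAYI", b = "MKTAYI", c = "MKTAYI"))
  expect_true(all(msa == "MKTAYI"))

  seqs <- c(x = "MKTAYIAK", y = "MKTYIAK")  # one-residue deletion in y
  msa2 <- center_star_msa(seqs)
  expect_equal(unique(nchar(msa2)), 8L)
  expect_equal(sum(strsplit(msa2[["y"]], "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", msa2[["y"]]), "MKTYIAK")

  seqs3 <- c(p = "MKTAYIAK", q = "MKTFYIAK", r = "MKTAYIAL")
  m1 <- center_star_msa(seqs3)
  m2 <- center_star_msa(seqs3[c(3, 1, 2)])
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
  expect_error(center_star_msa("MKT"), ">= 2")
})
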