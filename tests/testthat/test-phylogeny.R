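test_that("alignment slicing keeps the leading columns", {
  msa <- setNames(replicate(3, paste(sample(c("A", "C", "G", "T"), 1000,
                                            replace = TRUE), collapse = "")),
                  c("a", "b", "c"))
  sliced <- slice_alignment(msa, 929)
  expect_equal(unique(nchar(sliced)), 929L)
  expect_equal(sliced, vapply(msa, substr, character(1), 1, 929))
  expect_equal(slice_alignment(msa, 1000), msa)
  expect_error(slice_alignment(msa, 0), ">= 1")
  expect_error(slice_alignment(msa, 1001), "cannot slice")
})

test_that("JC69 distances follow the closed form with pairwise deletion", {
  same <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_true(all(jc69_distance(same) == 0))

  # 10 mismatches over 100 sites: d = -(3/4) ln(1 - 4*0.1/3)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  d <- jc69_distance(c(x = s1, y = s2))
  expect_equal(unname(d["x", "y"]), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-12)
  expect_equal(round(unname(d["x", "y"]), 6), 0.107326)

  # gap and N columns are deleted for the affected pair only
  g1 <- c(p = "ACGTACGTAC", q = "ACGTACGTA-", r = "ACGTACGTAN")
  dg <- jc69_distance(g1)
  expect_equal(unname(dg["p", "q"]), 0)
  expect_equal(unname(dg["q", "r"]), 0)

  sat <- c(u = paste(rep("A", 100), collapse = ""),
           v = paste(c(rep("C", 80), rep("A", 20)), collapse = ""))
  expect_error(jc69_distance(sat), "saturated pair.*u.*v")
})

test_that("JC69 agrees with an independent implementation", {
  set.seed(808)
  msa <- simulate_16s_msa(random_unrooted_tree(6), 500, seed = 2)$msa
  mine <- jc69_distance(msa)
  bin <- ape::as.DNAbin(strsplit(msa, ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("three-taxon NJ solves the three-point equations exactly", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["B"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["C"]), (0.4 + 0.5 - 0.3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers additive trees exactly (path-length oracle)", {
  set.seed(909)
  for (trial in seq_len(30)) {
    true_tree <- random_unrooted_tree(sample(4:6, 1))
    D <- ape::cophenetic.phylo(true_tree)
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    Dhat <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(Dhat, D, tolerance = 1e-8)
  }
})

test_that("bootstrap supports are seeded, bounded and strong for a clean
          split", {
  # two well-separated 5-taxon groups
  nwk <- paste0("(((g1:0.01,g2:0.01):0.01,(g3:0.01,g4:0.012):0.01):0.15,",
                "((h1:0.01,h2:0.01):0.01,(h3:0.01,h4:0.012):0.01):0.15,",
                "h5:0.2);")
  msa <- simulate_16s_msa(nwk, 800, seed = 3)$msa
  tr <- bootstrap_support(msa, n_replicates = 50, seed = 21)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  expect_gte(clade_support(tr, paste0("g", 1:4), "h5"), 95)

  tr2 <- bootstrap_support(msa, n_replicates = 50, seed = 21)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrap_support(msa, n_replicates = 0), ">= 1")
})

test_that("outgroup rooting tests monophyly exactly", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,out:3);")
  expect_true(root_and_test_monophyly(tr, c("A", "B"), "out"))
  expect_true(root_and_test_monophyly(tr, c("C", "D"), "out"))
  expect_true(root_and_test_monophyly(tr, c("A", "B", "C", "D"), "out"))
  expect_false(root_and_test_monophyly(tr, c("A", "C"), "out"))
  expect_error(root_and_test_monophyly(tr, c("A", "Z"), "out"), "unknown")
  expect_error(root_and_test_monophyly(tr, c("A", "out"), "out"), "exclude")
})

test_that("newick write/read round-trips topology, lengths and supports", {
  msa <- simulate_16s_msa(random_unrooted_tree(6), 400, seed = 4)$msa
  tr <- bootstrap_support(msa, n_replicates = 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)
  expect_equal(as.numeric(back$node.label), as.numeric(tr$node.label))
})

test_that("p-distance supports protein alignments for the prenyltransferase
          tree path", {
  msa <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MKTAWIAKHR")
  d <- p_distance(msa, "protein")
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 0.2)
})
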