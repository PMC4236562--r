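make_idm <- function(ids, pairs) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  }
  m
}

test_that("identity matrix is symmetric with diagonal 100", {
  expect_equal(identity_matrix(c(p1 = "MKTAYIAK")),
               matrix(100, 1, 1, dimnames = list("p1", "p1")))
  m <- identity_matrix(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  expect_equal(m["a", "b"], 100)
  expect_error(identity_matrix(c(a = "MKT", a = "MKT")), "unique")

  fam <- simulate_protein_family(200, 95, 3, seed = 7)
  m3 <- identity_matrix(fam$proteins)
  expect_true(isSymmetric(m3))
  expect_true(all(diag(m3) == 100))
  offdiag <- m3[upper.tri(m3)]
  expect_true(all(offdiag >= 90 & offdiag <= 100))
  expect_true(all(abs(offdiag - 95) <= 3))
})

test_that("single linkage joins chains and respects the strict 90 boundary", {
  chain <- make_idm(c("A", "B", "C"),
                    list(list("A", "B", 92), list("B", "C", 91),
                         list("A", "C", 85)))
  fams <- assign_families(chain, 90)
  expect_length(fams, 1)
  expect_setequal(fams[[1]]$members$protein_id, c("A", "B", "C"))

  exact <- make_idm(c("A", "B"), list(list("A", "B", 90)))
  expect_length(assign_families(exact, 90), 2)  # 90.0 is not > 90

  all95 <- make_idm(c("A", "B", "C"),
                    list(list("A", "B", 95), list("B", "C", 95),
                         list("A", "C", 95)))
  expect_length(assign_families(all95, 90), 1)
  expect_error(assign_families(all95, 0), "threshold")
  expect_error(assign_families(all95, 101), "threshold")
})

test_that("families partition the proteins and match a reachability oracle", {
  set.seed(202)
  for (trial in seq_len(200)) {
    n <- sample(2:8, 1)
    ids <- paste0("p", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    vals <- sample(c(50, 85, 89, 90, 91, 95, 100),
                   n * (n - 1) / 2, replace = TRUE)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    diag(m) <- 100
    thr <- sample(c(85, 90, 94), 1)
    fams <- assign_families(m, thr)
    got <- lapply(fams, function(f) match(f$members$protein_id, ids))
    adj <- m > thr
    diag(adj) <- FALSE
    expected <- oracle_components(adj)
    norm <- function(x) unname(lapply(x, sort)[order(vapply(x, min, 1))])
    expect_equal(norm(got), norm(expected))
    expect_setequal(unlist(got), seq_len(n))  # disjoint and exhaustive
  }
})

test_that("raising the threshold only refines the partition", {
  set.seed(303)
  for (trial in seq_len(30)) {
    n <- sample(3:8, 1)
    ids <- paste0("p", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 60, 100)
    m <- m + t(m)
    diag(m) <- 100
    lo <- assign_families(m, 80)
    hi <- assign_families(m, 95)
    lo_of <- function(p) which(vapply(lo, function(f)
      p %in% f$members$protein_id, logical(1)))
    for (f in hi) {
      anchors <- vapply(f$members$protein_id, lo_of, integer(1))
      expect_length(unique(anchors), 1)  # each hi family sits inside one lo family
    }
  }
})

test_that("family naming follows the catalog with fresh-label fallback", {
  sim <- simulate_cluster_set(small_mimic_config(seed = 11))
  proteins <- cluster_proteins(sim$clusters)
  sub <- proteins[proteins$cluster_id == "hpiA" | proteins$cluster_id == "ambA", ]
  idm <- identity_matrix(sub)
  fams <- assign_families(idm, 90, sub)
  named <- name_families(fams, sim$truth$catalog, sub)
  truth <- sim$truth$families
  for (f in named) {
    expect_equal(unique(truth$family_label[match(f$members$protein_id,
                                                 truth$protein_id)]),
                 f$family_label)
  }
  # a family absent from the catalog falls back to its category prefix
  novel <- data.frame(protein_id = "x|nov", cluster_id = "x", label = "nov",
                      product = "oxygenase",
                      sequence = paste(rep("MW", 40), collapse = ""),
                      stringsAsFactors = FALSE)
  idm1 <- identity_matrix(novel)
  f1 <- assign_families(idm1, 90, novel)
  named1 <- name_families(f1, sim$truth$catalog, novel)
  expect_equal(named1[[1]]$family_label, "Onew1")
})

test_that("core families honour the required fraction", {
  fam <- function(label, clusters) structure(
    list(family_label = label,
         members = data.frame(protein_id = paste0(clusters, "|x"),
                              cluster_id = clusters),
         min_identity_pct = NA_real_, mean_identity_pct = NA_real_),
    class = "homolog_family")
  fams <- list(fam("A", c("c1", "c2", "c3")), fam("B", c("c1", "c2", "c3")),
               fam("C", "c3"))
  expect_equal(core_families(fams, c("c1", "c2", "c3")), c("A", "B"))
  expect_equal(core_families(fams, c("c1", "c2", "c3"), 0.5), c("A", "B"))
  expect_equal(core_families(fams, c("c1", "c2", "c3"), 1 / 3),
               c("A", "B", "C"))
})

test_that("identity summaries give min and mean over member pairs", {
  m2 <- make_idm(c("A", "B"), list(list("A", "B", 97.7)))
  fam2 <- assign_families(m2, 90)[[1]]
  expect_equal(unname(family_identity_summary(fam2, m2)), c(97.7, 97.7))

  m3 <- make_idm(c("A", "B", "C"),
                 list(list("A", "B", 94), list("A", "C", 96),
                      list("B", "C", 98)))
  fam3 <- assign_families(m3, 90)[[1]]
  expect_equal(unname(family_identity_summary(fam3, m3)), c(94.0, 96.0))

  single <- assign_families(make_idm("A", list()), 90)[[1]]
  expect_true(all(is.na(family_identity_summary(single, make_idm("A", list())))))
})
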