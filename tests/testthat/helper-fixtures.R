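# Fixture builders and a per-session cache of the nine-cluster synthetic
# comparison, shared across test files so the all-vs-all alignment runs
# once.

# A hand-written GenBank fixture: 3 CDS (two forward, one reverse); the
# reverse CDS (101..202, 102 nt) has no /translation and must be translated
# from the sequence.
toy_genbank_sequence <- function() {
  set.seed(42001)
  paste(sample(c("a", "c", "g", "t"), 300, replace = TRUE), collapse = "")
}

write_toy_genbank <- function(path) {
  s <- toy_genbank_sequence()
  lines <- c(
    "LOCUS       toylocus 300 bp    DNA     linear   BCT",
    "DEFINITION  toy cluster.",
    "ACCESSION   TOY00001",
    "SOURCE      .",
    "  ORGANISM  Fischerella sp. toy",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     CDS             1..30",
    '                     /gene="toyA"',
    '                     /product="enzyme"',
    '                     /translation="MAAAAAAAA"',
    "     CDS             complement(101..202)",
    '                     /gene="toyB"',
    '                     /product="oxygenase"',
    "     CDS             250..279",
    '                     /gene="toyC"',
    '                     /translation="MKKKKKKKK"',
    "ORIGIN")
  for (p in seq(1, 300, 60)) {
    chunk <- substr(s, p, p + 59)
    groups <- substring(chunk, seq(1, 60, 10), seq(10, 60, 10))
    lines <- c(lines, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  invisible(s)
}

# small cluster record built directly from gene features
make_cluster <- function(id, strands, labels = NULL, gene_len = 30L,
                         gap = 10L) {
  n <- length(strands)
  if (is.null(labels)) labels <- paste0("g", seq_len(n))
  genes <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    start <- pos + gap + 1L
    end <- start + gene_len - 1L
    genes[[i]] <- gene_feature(paste0(id, "_g", i), labels[i], start, end,
                               strands[i], protein = "MKT")
    pos <- end
  }
  cluster_record(id, sequence = paste(rep("A", pos + gap), collapse = ""),
                 genes = genes)
}

# three-cluster config for fast pipeline runs
small_mimic_config <- function(seed = 1) {
  cfg <- paper_mimic_config(seed)
  keep <- c("hpiA", "ambA", "welA")
  cfg$clusters <- cfg$clusters[cfg$clusters$cluster_id %in% keep, ]
  cfg$layouts <- cfg$layouts[keep]
  cfg$families <- unique(unlist(lapply(cfg$layouts, `[[`, "family")))
  cfg
}

# cached nine-cluster synthetic comparison (simulation, identity matrix,
# named families, per-cluster label sets)
.mimic_cache <- new.env(parent = emptyenv())

mimic_results <- function(seed = 1) {
  key <- paste0("s", seed)
  if (!is.null(.mimic_cache[[key]])) return(.mimic_cache[[key]])
  sim <- simulate_cluster_set(paper_mimic_config(seed))
  proteins <- cluster_proteins(sim$clusters)
  idm <- identity_matrix(proteins)
  fams <- assign_families(idm, 90, proteins)
  fams <- name_families(fams, sim$truth$catalog, proteins)
  cluster_families <- lapply(names(sim$clusters), function(cid)
    vapply(Filter(function(f) cid %in% f$members$cluster_id, fams),
           `[[`, character(1), "family_label"))
  names(cluster_families) <- names(sim$clusters)
  res <- list(sim = sim, proteins = proteins, idm = idm, families = fams,
              cluster_families = cluster_families)
  .mimic_cache[[key]] <- res
  res
}
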