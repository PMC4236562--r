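test_that("a GenBank fixture with 3 CDS parses in start order", {
  gbk <- withr::local_tempfile(fileext = ".gbk")
  write_toy_genbank(gbk)
  cl <- suppressWarnings(read_genbank(gbk))
  expect_s3_class(cl, "cluster_record")
  expect_equal(cl$cluster_id, "toylocus")
  expect_equal(cl$source_accession, "TOY00001")
  expect_equal(cl$organism, "Fischerella sp. toy")
  expect_length(cl$genes, 3)
  expect_equal(vapply(cl$genes, `[[`, character(1), "label"),
               c("toyA", "toyB", "toyC"))
  expect_equal(vapply(cl$genes, `[[`, character(1), "strand"),
               c("+", "-", "+"))
  expect_equal(vapply(cl$genes, `[[`, integer(1), "start"), c(1L, 101L, 250L))
  expect_equal(nchar(cl$sequence), 300L)
})

test_that("a minus-strand CDS without /translation is translated from the
          reverse complement", {
  gbk <- withr::local_tempfile(fileext = ".gbk")
  seq <- write_toy_genbank(gbk)
  cl <- suppressWarnings(read_genbank(gbk))
  # independent oracle: extract 101..202, reverse-complement, translate
  dna <- Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(substr(seq, 101, 202))))
  expected <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  expected <- gsub("\\*", "X", sub("\\*$", "", expected))
  expect_equal(cl$genes[[2]]$protein, expected)
})

test_that("GenBank write -> read round-trips coordinates, strands, labels
          and proteins", {
  sim <- simulate_cluster_set(small_mimic_config(seed = 4))
  cl <- sim$clusters[[1]]
  gbk <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(cl, gbk)
  back <- read_genbank(gbk)
  expect_equal(back$sequence, cl$sequence)
  for (field in c("start", "end", "strand", "label", "protein")) {
    expect_equal(lapply(back$genes, `[[`, field),
                 lapply(cl$genes, `[[`, field))
  }
})

test_that("GFF3 and GenBank parsers agree on the same locus", {
  sim <- simulate_cluster_set(small_mimic_config(seed = 5))
  cl <- sim$clusters[[2]]
  td <- withr::local_tempdir()
  write_genbank(cl, file.path(td, "x.gbk"))
  write_gff3(cl, file.path(td, "x.gff3"), file.path(td, "x.fna"))
  from_gbk <- read_genbank(file.path(td, "x.gbk"))
  from_gff <- read_gff3(file.path(td, "x.gff3"), file.path(td, "x.fna"))
  expect_equal(from_gff$sequence, from_gbk$sequence)
  for (field in c("start", "end", "strand", "label", "protein")) {
    expect_equal(lapply(from_gff$genes, `[[`, field),
                 lapply(from_gbk$genes, `[[`, field))
  }
})

test_that("GFF3 edge cases: no features, seqid mismatch, broken phase", {
  td <- withr::local_tempdir()
  writeLines(c("##gff-version 3", "##sequence-region chr1 1 60"),
             file.path(td, "empty.gff3"))
  dna <- Biostrings::DNAStringSet(paste(rep("ACGT", 15), collapse = ""))
  names(dna) <- "chr1"
  Biostrings::writeXStringSet(dna, file.path(td, "chr1.fna"))
  expect_warning(cl <- read_gff3(file.path(td, "empty.gff3"),
                                 file.path(td, "chr1.fna")),
                 "no CDS")
  expect_length(cl$genes, 0)

  writeLines(c("##gff-version 3",
               paste("chrX", "src", "CDS", 1, 30, ".", "+", "0", "ID=a",
                     sep = "\t")),
             file.path(td, "mismatch.gff3"))
  expect_error(read_gff3(file.path(td, "mismatch.gff3"),
                         file.path(td, "chr1.fna")), "seqid mismatch")

  writeLines(c("##gff-version 3",
               paste("chr1", "src", "CDS", 1, 30, ".", "+", "2", "ID=a",
                     sep = "\t")),
             file.path(td, "phase.gff3"))
  expect_error(read_gff3(file.path(td, "phase.gff3"),
                         file.path(td, "chr1.fna")), "phase")
})

test_that("internal stop codons warn and translate to X", {
  # ATG AAA TAA AAA TGA: internal stop at codon 3, terminal stop
  seq <- "ATGAAATAAAAATGA"
  expect_warning(p <- hapalocompare:::.translate_feature(seq, 1, 15, "+"),
                 "internal stop")
  expect_equal(p, "MKXK")
})

test_that("cluster summaries report kb length and CDS count", {
  genes <- lapply(1:30, function(i)
    gene_feature(paste0("g", i), start = i * 100, end = i * 100 + 29,
                 strand = "+", protein = "MK"))
  cl <- cluster_record("syn40k", organism = "synthetic",
                       sequence = paste(rep("A", 40200), collapse = ""),
                       genes = genes)
  s <- summarize_cluster(cl)
  expect_equal(s$length_kb, 40.2)
  expect_equal(s$n_genes, 30L)
  expect_error(summarize_cluster(cluster_record("empty")), "empty sequence")

  sims <- simulate_cluster_set(small_mimic_config(seed = 2))
  tab <- summarize_clusters(sims$clusters)
  expect_equal(tab$n_genes,
               vapply(sims$clusters, function(cl) length(cl$genes),
                      integer(1), USE.NAMES = FALSE))
})

test_that("feature validation enforces coordinates and alphabet", {
  expect_error(gene_feature("g", start = 5, end = 3, strand = "+"))
  expect_error(gene_feature("g", start = 1, end = 3, strand = "*"))
  expect_error(gene_feature("g", start = 1, end = 3, strand = "+",
                            protein = "MKB*"), "invalid letters")
  g <- gene_feature("g", start = 10, end = 12, strand = "+", protein = "M")
  expect_error(cluster_record("c", sequence = "ACGTACGT", genes = list(g)),
               "exceed")
})
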