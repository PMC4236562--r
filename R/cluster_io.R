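# Reading, writing and summarising annotated gene-cluster records.
# Coordinates are 1-based inclusive (GenBank convention) throughout; GFF3 is
# also 1-based inclusive, so no shift happens at that boundary.

.aa_letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Construct a gene feature
#'
#' @param feature_id Unique id within the cluster.
#' @param label Gene name (e.g. `"welP1"`); may be `""`.
#' @param start,end 1-based inclusive nucleotide coordinates, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param product Free-text product annotation.
#' @param protein Amino-acid translation (20 IUPAC letters plus X).
#' @return A `gene_feature` list.
#' @export
gene_feature <- function(feature_id, label = "", start, end, strand,
                         product = "", protein = "") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 1, end >= start, strand %in% c("+", "-"))
  if (nchar(protein) > 0) {
    bad <- setdiff(unique(strsplit(toupper(protein), "")[[1]]), .aa_letters)
    if (length(bad) > 0) {
      stop("protein of ", feature_id, " contains invalid letters: ",
           paste(bad, collapse = ""))
    }
  }
  structure(list(feature_id = feature_id, label = label, start = start,
                 end = end, strand = strand, product = product,
                 protein = toupper(protein)),
            class = "gene_feature")
}

#' Construct a cluster record
#'
#' Genes are sorted by start coordinate; when a sequence is present every
#' feature must lie within it.
#'
#' @param cluster_id Cluster identifier.
#' @param organism Organism name.
#' @param sequence Nucleotide string (may be `""` when only features are
#'   supplied).
#' @param genes List of [gene_feature()] objects.
#' @param source_accession Originating accession, or `""`.
#' @return A `cluster_record` list.
#' @export
cluster_record <- function(cluster_id, organism = "", sequence = "",
                           genes = list(), source_accession = "") {
  sequence <- toupper(sequence)
  if (length(genes) > 0) {
    genes <- genes[order(vapply(genes, `[[`, integer(1), "start"))]
    if (nchar(sequence) > 0) {
      ends <- vapply(genes, `[[`, integer(1), "end")
      if (any(ends > nchar(sequence))) {
        stop("feature coordinates exceed sequence length in ", cluster_id)
      }
    }
  }
  structure(list(cluster_id = cluster_id, organism = organism,
                 sequence = sequence, genes = genes,
                 source_accession = source_accession),
            class = "cluster_record")
}

#' @export
print.cluster_record <- function(x, ...) {
  cat("Cluster", x$cluster_id,
      if (nzchar(x$organism)) paste0("(", x$organism, ")") else "",
      "-", length(x$genes), "genes,",
      nchar(x$sequence), "nt\n")
  invisible(x)
}

# Translate a CDS span with the standard bacterial genetic code (table 11).
# Ambiguous codons give X; internal stops are replaced by X with a warning
# (draft-genome tolerance); a trailing stop is stripped.
.translate_feature <- function(sequence, start, end, strand, feature_id = "?") {
  if (end > nchar(sequence)) stop("CDS ", feature_id, " outside sequence")
  dna <- Biostrings::DNAString(substr(sequence, start, end))
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  if (length(dna) %% 3 != 0) {
    stop("CDS ", feature_id, " length not a multiple of 3")
  }
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa)) {
    warning("internal stop codon(s) in CDS ", feature_id, "; replaced by X")
    aa <- gsub("\\*", "X", aa)
  }
  aa
}

#' Read a GenBank flat file into a cluster record
#'
#' Parses LOCUS, ACCESSION, ORGANISM, the feature table and ORIGIN. CDS
#' features become gene features; `/translation` is used when present,
#' otherwise the CDS is translated with the bacterial code (table 11). The
#' gene label is taken from `/gene`, else `/locus_tag`.
#'
#' @param path Path to a GenBank flat file with a single record.
#' @return A [cluster_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) stop("malformed GenBank file (no LOCUS line): ", path)
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "[[:space:]]+")[[1]]
  cluster_id <- locus[1]
  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i)) trimws(sub("^ACCESSION", "", lines[acc_i[1]])) else ""
  org_i <- grep("^ {2,}ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^ *ORGANISM", "", lines[org_i[1]])) else ""

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (length(end_i) == 0) end_i <- length(lines) + 1L

  sequence <- ""
  if (length(origin_i)) {
    seq_lines <- lines[(origin_i[1] + 1):(end_i[1] - 1)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  genes <- list()
  if (length(feat_i)) {
    stop_at <- if (length(origin_i)) origin_i[1] else end_i[1]
    fl <- lines[(feat_i[1] + 1):(stop_at - 1)]
    # split into (key, location+qualifier block) entries
    starts <- grep("^ {5}\\S", fl)
    cds_n <- 0L
    for (s in seq_along(starts)) {
      from <- starts[s]
      to <- if (s < length(starts)) starts[s + 1] - 1L else length(fl)
      block <- fl[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (key != "CDS") next
      cds_n <- cds_n + 1L
      body <- sub("^ {5}\\S+\\s*", "", block[1])
      # location may continue until the first qualifier line
      qual_start <- grep("^ +/", block)
      loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
      if (loc_end > 1) {
        body <- paste0(body, paste(trimws(block[2:loc_end]), collapse = ""))
      }
      loc <- gsub("[<>[:space:]]", "", body)
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("join|order", loc)) {
        stop("unsupported compound location in CDS near feature line: ", block[1])
      }
      m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
      if (length(m) != 3) stop("cannot parse CDS location: ", body)
      start <- as.integer(m[2]); end <- as.integer(m[3])
      quals <- .parse_qualifiers(block[seq_along(block) > loc_end])
      label <- quals[["gene"]] %||% quals[["locus_tag"]] %||% ""
      protein <- quals[["translation"]] %||% ""
      if (protein == "") {
        if (sequence == "") {
          stop("CDS ", cds_n, " has no /translation and record has no sequence")
        }
        protein <- .translate_feature(sequence, start, end, strand,
                                      paste0("cds", cds_n))
      }
      genes[[length(genes) + 1L]] <- gene_feature(
        feature_id = paste0(cluster_id, "_cds", cds_n),
        label = label, start = start, end = end, strand = strand,
        product = quals[["product"]] %||% "", protein = protein)
    }
  }
  cluster_record(cluster_id, organism, sequence, genes, accession)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  txt <- trimws(lines)
  starts <- grep("^/", txt)
  out <- list()
  for (s in seq_along(starts)) {
    from <- starts[s]
    to <- if (s < length(starts)) starts[s + 1] - 1L else length(txt)
    joined <- paste(txt[from:to], collapse = "")
    m <- regmatches(joined, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', joined))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Write a cluster record as a GenBank flat file
#'
#' @param cluster A [cluster_record()] with non-empty sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(cluster, path) {
  if (nchar(cluster$sequence) == 0) stop("cannot write GenBank without sequence")
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
            cluster$cluster_id, nchar(cluster$sequence)),
    sprintf("DEFINITION  %s biosynthetic gene cluster.", cluster$cluster_id),
    sprintf("ACCESSION   %s",
            if (nzchar(cluster$source_accession)) cluster$source_accession
            else cluster$cluster_id),
    "SOURCE      .",
    sprintf("  ORGANISM  %s", cluster$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(cluster$sequence))
  )
  for (g in cluster$genes) {
    loc <- sprintf("%d..%d", g$start, g$end)
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc))
    if (nzchar(g$label)) out <- c(out, sprintf('                     /gene="%s"', g$label))
    out <- c(out, sprintf('                     /locus_tag="%s"', g$feature_id))
    if (nzchar(g$product)) out <- c(out, sprintf('                     /product="%s"', g$product))
    tr <- paste0('/translation="', g$protein, '"')
    wrapped <- substring(tr, seq(1, nchar(tr), 58), pmin(seq(1, nchar(tr), 58) + 57, nchar(tr)))
    out <- c(out, paste0("                     ", wrapped))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(cluster$sequence)
  pos <- seq(1, nchar(s), 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a GFF3 + FASTA pair into a cluster record
#'
#' Produces the same record as [read_genbank()] on an equivalent locus.
#' Proteins are obtained by translating each CDS (table 11).
#'
#' @param gff_path GFF3 file with CDS lines (phase 0).
#' @param fasta_path FASTA with a sequence whose id matches the GFF seqid.
#' @param organism Optional organism name (GFF3 carries none).
#' @return A [cluster_record()].
#' @export
read_gff3 <- function(gff_path, fasta_path, organism = "") {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) {
    warning("no CDS features in ", gff_path)
    sid <- names(seqs)[1]
    return(cluster_record(sid, organism, as.character(seqs[[1]]), list()))
  }
  sid <- unique(as.character(GenomicRanges::seqnames(cds)))
  if (length(sid) != 1) stop("multiple seqids in GFF3: ", paste(sid, collapse = ", "))
  if (!sid %in% names(seqs)) {
    stop("seqid mismatch: GFF3 uses '", sid, "' absent from FASTA (",
         paste(names(seqs), collapse = ", "), ")")
  }
  phase <- cds$phase
  if (!is.null(phase) && any(!is.na(phase) & as.integer(phase) != 0L)) {
    stop("phase-broken CDS (non-zero phase) in ", gff_path)
  }
  sequence <- as.character(seqs[[sid]])
  genes <- vector("list", length(cds))
  for (i in seq_along(cds)) {
    start <- GenomicRanges::start(cds)[i]
    end <- GenomicRanges::end(cds)[i]
    strand <- as.character(GenomicRanges::strand(cds))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    label <- cds$gene[i] %||% NA_character_
    if (is.na(label)) label <- cds$locus_tag[i] %||% NA_character_
    if (is.na(label)) label <- ""
    fid <- cds$ID[i] %||% NA_character_
    if (is.na(fid)) fid <- paste0(sid, "_cds", i)
    product <- cds$product[i] %||% NA_character_
    if (is.na(product)) product <- ""
    genes[[i]] <- gene_feature(
      feature_id = fid, label = label, start = start, end = end,
      strand = strand, product = product,
      protein = .translate_feature(sequence, start, end, strand, fid))
  }
  cluster_record(sid, organism, sequence, genes)
}

#' Write a cluster record as a GFF3 + FASTA pair
#'
#' @param cluster A [cluster_record()].
#' @param gff_path,fasta_path Output paths.
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(cluster, gff_path, fasta_path) {
  if (nchar(cluster$sequence) == 0) stop("cannot write FASTA without sequence")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", cluster$cluster_id,
                     nchar(cluster$sequence)))
  for (g in cluster$genes) {
    attrs <- sprintf("ID=%s", g$feature_id)
    if (nzchar(g$label)) attrs <- paste0(attrs, ";gene=", g$label)
    if (nzchar(g$product)) {
      attrs <- paste0(attrs, ";product=", gsub("[;=,]", "%2C", g$product))
    }
    lines <- c(lines, paste(cluster$cluster_id, "hapalocompare", "CDS",
                            g$start, g$end, ".", g$strand, "0", attrs,
                            sep = "\t"))
  }
  writeLines(lines, gff_path)
  dna <- Biostrings::DNAStringSet(cluster$sequence)
  names(dna) <- cluster$cluster_id
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(gff_path)
}

#' Write cluster proteins as a FASTA file
#'
#' Headers are `cluster_id|feature_id|label`.
#'
#' @param cluster A [cluster_record()].
#' @param path Output path.
#' @export
write_protein_fasta <- function(cluster, path) {
  aas <- vapply(cluster$genes, `[[`, character(1), "protein")
  names(aas) <- vapply(cluster$genes, function(g) {
    paste(cluster$cluster_id, g$feature_id, g$label, sep = "|")
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aas), path)
  invisible(path)
}

#' Summarise a cluster (length in kb, protein-coding gene count)
#'
#' Length is `round(nt/1000, 1)` (round-half-even, one printed decimal);
#' the gene count is the number of CDS features.
#'
#' @param cluster A [cluster_record()] with non-empty sequence.
#' @return `data.frame(cluster_id, organism, length_kb, n_genes)`.
#' @export
summarize_cluster <- function(cluster) {
  if (nchar(cluster$sequence) == 0) stop("empty sequence in ", cluster$cluster_id)
  data.frame(cluster_id = cluster$cluster_id,
             organism = cluster$organism,
             length_kb = round(nchar(cluster$sequence) / 1000, 1),
             n_genes = length(cluster$genes),
             stringsAsFactors = FALSE)
}

#' Summarise several clusters into one table
#'
#' @param clusters List of [cluster_record()] objects.
#' @param path Optional TSV output path (header: cluster_id, organism,
#'   length_kb, n_genes).
#' @return The summary data frame.
#' @export
summarize_clusters <- function(clusters, path = NULL) {
  df <- do.call(rbind, lapply(clusters, summarize_cluster))
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
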