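# Orchestration of the full comparative analysis: io -> alignment ->
# families -> operons -> motifs -> classification -> phylogeny, emitting a
# paper-style report bundle (TSV tables, JSON classifications, newick tree,
# run metadata). With a fixed config + seed the bundle is byte-identical
# across runs.

#' Run the full cluster-comparison pipeline
#'
#' @param config A list, or the path to a YAML file, with fields:
#'   \describe{
#'     \item{clusters}{Character vector of cluster files. `.gbk/.gb/.gbff`
#'       are read as GenBank; `.gff3` expects a sibling `.fna`/`.fasta`.}
#'     \item{catalog_file}{Optional protein FASTA whose names are canonical
#'       family labels; required for family naming and classification.}
#'     \item{msa_file}{Optional aligned 16S FASTA for the phylogeny stage.}
#'     \item{outgroup}{Tip label used to root the 16S tree.}
#'     \item{identity_threshold}{Strict identity threshold, default 90.}
#'     \item{bootstrap_replicates}{Default 100.}
#'     \item{msa_slice}{Columns of the alignment used, default 929.}
#'     \item{seed}{Integer seed for the bootstrap.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report bundle: summaries, families, identity
#'   matrix, transcripts, motif hits, classifications, tree, metadata.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(identity_threshold = 90, bootstrap_replicates = 100,
         msa_slice = 929, seed = 1, catalog_file = NULL, msa_file = NULL,
         outgroup = NULL),
    config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "io"
  bundle <- tryCatch({
    clusters <- lapply(cfg$clusters, .read_cluster_file)
    names(clusters) <- vapply(clusters, `[[`, character(1), "cluster_id")
    summaries <- summarize_clusters(clusters,
                                    file.path(out_dir, "cluster_summary.tsv"))

    stage <- "operons"
    tx <- lapply(clusters, predict_transcripts)
    tx_rows <- do.call(rbind, lapply(names(tx), function(cid) {
      data.frame(cluster_id = cid, tx[[cid]][, c("transcript_id", "strand",
                                                 "start", "end", "n_genes")],
                 gene_labels = vapply(tx[[cid]]$gene_labels, paste,
                                      character(1), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write.table(tx_rows, file.path(out_dir, "transcripts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "motifs"
    proteins <- cluster_proteins(clusters)
    motif_hits <- scan_proteins(proteins, builtin_motifs(),
                                file.path(out_dir, "motif_hits.tsv"))

    families <- NULL; idm <- NULL; classifications <- NULL; pa <- NULL
    if (length(clusters) >= 2) {
      stage <- "alignment"
      idm <- identity_matrix(proteins)
      stage <- "families"
      families <- assign_families(idm, cfg$identity_threshold, proteins)
      if (!is.null(cfg$catalog_file)) {
        cat_seqs <- Biostrings::readAAStringSet(cfg$catalog_file)
        catalog <- setNames(as.character(cat_seqs),
                            sub("\\s.*$", "", names(cat_seqs)))
        families <- name_families(families, catalog, proteins,
                                  cfg$identity_threshold)
      } else {
        for (k in seq_along(families)) {
          families[[k]]$family_label <- sprintf("F%03d", k)
        }
      }
      families_table(families, idm, file.path(out_dir, "families.tsv"))

      cluster_families <- lapply(names(clusters), function(cid) {
        labs <- vapply(families, function(f)
          if (cid %in% f$members$cluster_id) f$family_label else NA_character_,
          character(1))
        labs[!is.na(labs)]
      })
      names(cluster_families) <- names(clusters)
      pa <- presence_absence_matrix(cluster_families,
                                    file.path(out_dir, "presence_absence.tsv"))

      stage <- "classify"
      if (!is.null(cfg$catalog_file)) {
        classifications <- lapply(names(cluster_families), function(cid)
          classify(cid, cluster_families[[cid]]))
        names(classifications) <- names(cluster_families)
        json <- lapply(classifications, function(x)
          list(predicted_class = x$predicted_class,
               evidence = x$evidence$family_label,
               flags = x$flags, missing_core = x$missing_core))
        jsonlite::write_json(json,
                             file.path(out_dir, "classifications.json"),
                             auto_unbox = TRUE, pretty = TRUE)
      }
    } else {
      message("single cluster input: families, classification and ",
              "phylogeny skipped")
    }

    tree <- NULL
    if (!is.null(cfg$msa_file) && length(clusters) >= 2) {
      stage <- "phylogeny"
      seqs <- Biostrings::readDNAStringSet(cfg$msa_file)
      msa <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
      msa <- slice_alignment(msa, min(cfg$msa_slice, unique(nchar(msa))[1]))
      tree <- bootstrap_support(msa, cfg$bootstrap_replicates, cfg$seed)
      ape::write.tree(tree, file.path(out_dir, "tree_16s.nwk"))
    }

    meta <- list(
      package = "hapalocompare",
      version = as.character(utils::packageVersion("hapalocompare")),
      seed = cfg$seed,
      identity_threshold = cfg$identity_threshold,
      identity_definition = "matches / alignment columns (gaps included)",
      linkage = "single",
      distance_model = "JC69, pairwise deletion",
      bootstrap_replicates = cfg$bootstrap_replicates,
      msa_slice = cfg$msa_slice,
      clusters = names(clusters))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(summaries = summaries, transcripts = tx_rows,
         motif_hits = motif_hits, identity = idm, families = families,
         presence_absence = pa, classifications = classifications,
         tree = tree, metadata = meta)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(bundle)
}

.read_cluster_file <- function(path) {
  if (grepl("\\.(gbk|gb|gbff)$", path, ignore.case = TRUE)) {
    return(read_genbank(path))
  }
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    stem <- sub("\\.gff3?$", "", path, ignore.case = TRUE)
    fasta <- c(paste0(stem, ".fna"), paste0(stem, ".fasta"),
               paste0(stem, ".fa"))
    fasta <- fasta[file.exists(fasta)]
    if (length(fasta) == 0) stop("no FASTA found next to ", path)
    return(read_gff3(path, fasta[1]))
  }
  stop("unrecognised cluster file type: ", path)
}
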