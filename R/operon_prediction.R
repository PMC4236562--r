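# Transcript (operon) prediction from gene orientation: maximal runs of
# consecutive same-strand genes, optionally broken at large intergenic gaps.

#' Predict co-transcribed gene blocks from strand runs
#'
#' Consecutive genes on the same strand are predicted to form one
#' transcript. The default uses orientation only; `max_intergenic_nt` adds
#' the gap cutoff real operon callers apply.
#'
#' @param cluster A [cluster_record()] with >= 1 gene.
#' @param max_intergenic_nt Optional integer; a run also breaks where the
#'   gap between consecutive genes exceeds this.
#' @return Data frame ordered 5'->3' along the cluster: `transcript_id`,
#'   `strand`, `start`, `end`, `n_genes`, and a list column `gene_labels`.
#' @export
predict_transcripts <- function(cluster, max_intergenic_nt = NULL) {
  genes <- cluster$genes
  if (length(genes) == 0) stop("cluster has no genes")
  strands <- vapply(genes, `[[`, character(1), "strand")
  starts <- vapply(genes, `[[`, integer(1), "start")
  ends <- vapply(genes, `[[`, integer(1), "end")
  labels <- vapply(genes, function(g)
    if (nzchar(g$label)) g$label else g$feature_id, character(1))

  breaks <- logical(length(genes))  # TRUE: gene i starts a new transcript
  breaks[1] <- TRUE
  if (length(genes) > 1) {
    for (i in 2:length(genes)) {
      breaks[i] <- strands[i] != strands[i - 1]
      if (!is.null(max_intergenic_nt) && !breaks[i]) {
        gap <- starts[i] - ends[i - 1] - 1L
        if (gap > max_intergenic_nt) breaks[i] <- TRUE
      }
    }
  }
  run_id <- cumsum(breaks)
  out <- lapply(unique(run_id), function(r) {
    idx <- which(run_id == r)
    data.frame(transcript_id = sprintf("%s_tx%d", cluster$cluster_id, r),
               strand = strands[idx[1]],
               start = min(starts[idx]),
               end = max(ends[idx]),
               n_genes = length(idx),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$gene_labels <- I(lapply(unique(run_id), function(r) labels[run_id == r]))
  df
}

#' Write transcript predictions as a BED-like TSV
#'
#' Coordinates are converted to BED convention (0-based half-open) at this
#' boundary; internal coordinates stay 1-based inclusive.
#'
#' @param transcripts Output of [predict_transcripts()].
#' @param cluster_id Chromosome/cluster name for column 1.
#' @param path Output path.
#' @export
write_transcripts_bed <- function(transcripts, cluster_id, path) {
  bed <- data.frame(chrom = cluster_id,
                    chromStart = transcripts$start - 1L,
                    chromEnd = transcripts$end,
                    name = vapply(transcripts$gene_labels, paste,
                                  character(1), collapse = ","),
                    score = transcripts$n_genes,
                    strand = transcripts$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
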