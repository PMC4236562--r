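# Rule-based prediction of product class (hpi / amb / wel) from a cluster's
# homolog-family complement, with a functionality flag when conserved core
# genes are missing.

#' Default marker and core gene sets
#'
#' `wel_marker_labels()`: families observed only in welwitindolinone
#' clusters (methyltransferases M1-3, regulator R3, exporter E4, oxygenases
#' O11-O19, DUF proteins U7/U8). `required_core_labels()`: conserved core
#' genes whose absence flags a cluster as putatively non-functional.
#'
#' @return Character vector of family labels.
#' @export
wel_marker_labels <- function() {
  c("M1", "M2", "M3", "R3", "E4", paste0("O", 11:19), "U7", "U8")
}

#' @rdname wel_marker_labels
#' @export
required_core_labels <- function() {
  c("I1", "I3", "P1", "P2", paste0("D", 1:4), paste0("T", 1:5),
    paste0("C", 1:3))
}

#' Classify a cluster from its family-label complement
#'
#' Precedence: (1) `P3` present -> `amb` (the ambiguine-specific aromatic
#' prenyltransferase); (2) any wel marker present -> `wel`; (3) otherwise
#' `hpi`. A cluster carrying both P3 and wel markers is called `amb` with a
#' warning (no known cluster carries both sets). The
#' `putatively_nonfunctional` flag is raised when any required core gene is
#' absent.
#'
#' @param cluster_id Cluster identifier.
#' @param family_labels Character vector of canonical family labels present
#'   in the cluster (from [name_families()]).
#' @param core_reference Labels whose absence flags non-functionality;
#'   default [required_core_labels()].
#' @param wel_markers Wel-diagnostic labels; default [wel_marker_labels()].
#' @return A `classification_result`: `cluster_id`, `predicted_class`,
#'   `evidence` (data frame of label/rule pairs), `flags`, `missing_core`.
#' @export
classify <- function(cluster_id, family_labels,
                     core_reference = required_core_labels(),
                     wel_markers = wel_marker_labels()) {
  family_labels <- unique(family_labels)
  if (length(family_labels) == 0) stop("empty family label set for ", cluster_id)
  wel_hits <- sort(intersect(family_labels, wel_markers))
  has_p3 <- "P3" %in% family_labels
  if (has_p3) {
    if (length(wel_hits) > 0) {
      warning(cluster_id, " carries both P3 and wel markers (",
              paste(wel_hits, collapse = ","), "); calling amb by precedence")
    }
    predicted <- "amb"
    evidence <- data.frame(family_label = "P3", rule = "amb_marker_P3",
                           stringsAsFactors = FALSE)
  } else if (length(wel_hits) > 0) {
    predicted <- "wel"
    evidence <- data.frame(family_label = wel_hits,
                           rule = "wel_marker_present",
                           stringsAsFactors = FALSE)
  } else {
    predicted <- "hpi"
    evidence <- data.frame(family_label = character(0), rule = character(0),
                           stringsAsFactors = FALSE)
  }
  missing_core <- sort(setdiff(core_reference, family_labels))
  flags <- character(0)
  if (length(missing_core) > 0) flags <- "putatively_nonfunctional"
  structure(list(cluster_id = cluster_id, predicted_class = predicted,
                 evidence = evidence, flags = flags,
                 missing_core = missing_core),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(x$cluster_id, "->", x$predicted_class)
  if (nrow(x$evidence) > 0) {
    cat(" [", paste(x$evidence$family_label, collapse = ","), "]", sep = "")
  }
  if (length(x$flags) > 0) cat(" flags:", paste(x$flags, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Family presence/absence matrix across clusters
#'
#' Rows are families in canonical order (letter category, then number);
#' columns are clusters. Serialised with "-" marking absence, mirroring the
#' comparison tables.
#'
#' @param cluster_families Named list: cluster_id -> character vector of
#'   family labels present.
#' @param path Optional TSV output path.
#' @return Binary integer matrix (family x cluster).
#' @export
presence_absence_matrix <- function(cluster_families, path = NULL) {
  if (length(cluster_families) == 0) stop("empty cluster list")
  labels <- unique(unlist(cluster_families))
  labels <- labels[order(.label_category(labels), .label_number(labels), labels)]
  m <- sapply(cluster_families, function(labs) as.integer(labels %in% labs))
  m <- matrix(m, nrow = length(labels),
              dimnames = list(labels, names(cluster_families)))
  if (!is.null(path)) {
    chr <- ifelse(m == 1L, "1", "-")
    df <- data.frame(family = rownames(m), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  m
}

.label_category <- function(labels) sub("^([A-Za-z]+).*$", "\\1", labels)

.label_number <- function(labels) {
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+(new)?", "", labels)))
  ifelse(is.na(n), 0L, n)
}
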