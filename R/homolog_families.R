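# Homolog-family assignment across clusters: all-vs-all percent identity,
# single-linkage grouping above a strict threshold (the ">90%" rule), family
# naming against a reference catalog, core-family detection and identity
# summaries.

#' Collect proteins from a set of cluster records
#'
#' @param clusters List of [cluster_record()] objects.
#' @return `data.frame(protein_id, cluster_id, label, product, sequence)`;
#'   `protein_id` is `cluster_id|feature_id` and unique across the set.
#' @export
cluster_proteins <- function(clusters) {
  rows <- lapply(clusters, function(cl) {
    if (length(cl$genes) == 0) return(NULL)
    data.frame(
      protein_id = vapply(cl$genes, function(g)
        paste0(cl$cluster_id, "|", g$feature_id), character(1)),
      cluster_id = cl$cluster_id,
      label = vapply(cl$genes, `[[`, character(1), "label"),
      product = vapply(cl$genes, `[[`, character(1), "product"),
      sequence = vapply(cl$genes, `[[`, character(1), "protein"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All-vs-all percent-identity matrix
#'
#' Each unordered pair is aligned once with [needleman_wunsch()]; the matrix
#' is symmetric with diagonal 100.
#'
#' @param proteins Named character vector of sequences, or a data frame with
#'   `protein_id` and `sequence` columns (as from [cluster_proteins()]).
#' @param scheme Scoring scheme, default [protein_scheme()].
#' @return Symmetric numeric matrix of percent identities with protein ids
#'   as dimnames.
#' @export
identity_matrix <- function(proteins, scheme = protein_scheme()) {
  if (is.data.frame(proteins)) {
    seqs <- setNames(proteins$sequence, proteins$protein_id)
  } else {
    seqs <- proteins
  }
  if (length(seqs) < 1) stop("need >= 1 protein")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("protein ids must be present and unique")
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <-
          needleman_wunsch(seqs[[i]], seqs[[j]], scheme)$identity_pct
      }
    }
  }
  m
}

#' Group proteins into homolog families by single linkage
#'
#' Families are the connected components of the graph with an edge wherever
#' identity is strictly greater than the threshold ("greater than 90%").
#' Single linkage makes the shared-label rule transitive: a chain
#' A-B 92, B-C 91 joins A, B, C even if A-C is below threshold.
#'
#' @param m Identity matrix from [identity_matrix()].
#' @param threshold_pct Strict lower bound on identity, in (0, 100\];
#'   default 90.
#' @param meta Optional data frame with `protein_id` and `cluster_id`
#'   columns; when given, members carry their cluster of origin.
#' @return List of `homolog_family` objects ordered by smallest member
#'   index; singletons allowed. Each has `family_label` (unset, see
#'   [name_families()]), `members` (data frame), `min_identity_pct`,
#'   `mean_identity_pct`.
#' @export
assign_families <- function(m, threshold_pct = 90, meta = NULL) {
  if (!(threshold_pct > 0 && threshold_pct <= 100)) {
    stop("threshold must be in (0, 100]")
  }
  ids <- rownames(m)
  adj <- m > threshold_pct
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # order components by smallest member index for determinism
  first_idx <- tapply(seq_along(comp), comp, min)
  ord <- order(first_idx)
  fams <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    idx <- sort(which(comp == names(first_idx)[ord[k]]))
    members <- data.frame(protein_id = ids[idx], stringsAsFactors = FALSE)
    members$cluster_id <- if (!is.null(meta)) {
      meta$cluster_id[match(members$protein_id, meta$protein_id)]
    } else NA_character_
    summ <- .pair_identity_summary(m, idx)
    fams[[k]] <- structure(
      list(family_label = NA_character_, members = members,
           min_identity_pct = summ[1], mean_identity_pct = summ[2]),
      class = "homolog_family")
  }
  fams
}

.pair_identity_summary <- function(m, idx) {
  if (length(idx) < 2) return(c(NA_real_, NA_real_))
  vals <- m[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  c(round(min(vals), 1), round(mean(vals), 1))
}

#' Min and mean pairwise identity within a family
#'
#' @param family A `homolog_family`.
#' @param m The identity matrix the family was assigned from.
#' @return Named numeric vector `c(min_identity_pct, mean_identity_pct)`
#'   to 1 decimal; both `NA` for a singleton (printed as "n/a" in tables).
#' @export
family_identity_summary <- function(family, m) {
  idx <- match(family$members$protein_id, rownames(m))
  v <- .pair_identity_summary(m, idx)
  c(min_identity_pct = v[1], mean_identity_pct = v[2])
}

# category prefix for fresh labels, from product annotation
.category_prefix <- function(products) {
  p <- tolower(paste(products, collapse = " "))
  if (grepl("oxygenase|monooxygenase", p)) return("O")
  if (grepl("methyltransferase", p)) return("M")
  if (grepl("prenyltransferase|pyrophosphate synthase", p)) return("P")
  if (grepl("regulator", p)) return("R")
  if (grepl("exporter|transporter", p)) return("E")
  if (grepl("transposase", p)) return("orf")
  if (grepl("unknown|duf|hypothetical", p)) return("U")
  "F"
}

#' Name families against a reference catalog of exemplar proteins
#'
#' Each family is labelled by its best-matching catalog exemplar: the
#' exemplar with the highest identity (strictly above the threshold) to any
#' member, ties broken by the lexicographically smallest canonical label.
#' Families without a catalog hit get fresh sequential labels from their
#' product-category prefix (e.g. `"Onew1"` for an unmatched oxygenase).
#'
#' @param families List from [assign_families()].
#' @param catalog Named character vector: canonical label -> exemplar
#'   amino-acid sequence (e.g. labels `T1`-`T5`, `O1`-`O19`, `P3`, ...).
#' @param proteins Data frame from [cluster_proteins()] (supplies member
#'   sequences and products).
#' @param threshold_pct Identity a hit must exceed; default 90.
#' @param scheme Scoring scheme.
#' @return The families, with `family_label` filled in.
#' @export
name_families <- function(families, catalog, proteins,
                          threshold_pct = 90, scheme = protein_scheme()) {
  stopifnot(length(catalog) > 0, !is.null(names(catalog)))
  assigned <- character(0)
  fresh_counter <- new.env(parent = emptyenv())
  for (k in seq_along(families)) {
    fam <- families[[k]]
    midx <- match(fam$members$protein_id, proteins$protein_id)
    seqs <- proteins$sequence[midx]
    best_label <- NA_character_
    best_id <- -Inf
    for (lab in sort(names(catalog))) {
      ids <- vapply(seqs, function(s)
        needleman_wunsch(s, catalog[[lab]], scheme)$identity_pct, numeric(1))
      hit <- max(ids)
      if (hit > threshold_pct && hit > best_id) {
        best_id <- hit
        best_label <- lab
      }
    }
    if (is.na(best_label)) {
      prefix <- .category_prefix(proteins$product[midx])
      n <- (fresh_counter[[prefix]] %||% 0L) + 1L
      fresh_counter[[prefix]] <- n
      best_label <- paste0(prefix, "new", n)
    } else if (best_label %in% assigned) {
      other <- which(vapply(families[seq_len(k - 1)], function(f)
        identical(f$family_label, best_label), logical(1)))
      stop("two families map to canonical label '", best_label,
           "': members {",
           paste(families[[other[1]]]$members$protein_id, collapse = ","),
           "} and {", paste(fam$members$protein_id, collapse = ","), "}")
    }
    assigned <- c(assigned, best_label)
    families[[k]]$family_label <- best_label
  }
  families
}

#' Families present in (a fraction of) all clusters
#'
#' @param families Named families (from [name_families()] or with
#'   `family_label` set) whose members carry `cluster_id`.
#' @param cluster_ids Character vector of all cluster ids under comparison.
#' @param required_fraction Fraction of clusters a family must appear in to
#'   count as core; default 1 (all clusters).
#' @return Character vector of core family labels.
#' @export
core_families <- function(families, cluster_ids, required_fraction = 1.0) {
  need <- required_fraction * length(cluster_ids)
  labs <- vapply(families, function(f) {
    hit <- length(unique(intersect(f$members$cluster_id, cluster_ids)))
    if (hit >= need) f$family_label else NA_character_
  }, character(1))
  sort(labs[!is.na(labs)])
}

#' Tabulate families with identity summaries
#'
#' @param families Named families.
#' @param m Identity matrix.
#' @param path Optional TSV output path; singleton identities print "n/a".
#' @return Data frame: family_label, n_members, clusters, min_identity_pct,
#'   mean_identity_pct.
#' @export
families_table <- function(families, m, path = NULL) {
  df <- do.call(rbind, lapply(families, function(f) {
    data.frame(family_label = f$family_label,
               n_members = nrow(f$members),
               clusters = paste(sort(unique(f$members$cluster_id)),
                                collapse = ","),
               min_identity_pct = f$min_identity_pct,
               mean_identity_pct = f$mean_identity_pct,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    out <- df
    out$min_identity_pct <- ifelse(is.na(out$min_identity_pct), "n/a",
                                   format(out$min_identity_pct, nsmall = 1))
    out$mean_identity_pct <- ifelse(is.na(out$mean_identity_pct), "n/a",
                                    format(out$mean_identity_pct, nsmall = 1))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
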