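# PROSITE-style degenerate motif scanning. The motifs carried as defaults
# are the diagnostic ones used as functional evidence in the cluster
# comparison: FAD binding (GxGxxG), tryptophan binding (WxWxIP), the
# Mg-dependent prenyl diphosphate binding motif ([ND]DxxD, whose absence in
# P1 is itself evidence), and the Rieske [2Fe-2S] ligating pattern.

# x matches any of the 20 standard residues; an unknown residue X in the
# protein never satisfies any pattern element, which avoids false motif
# calls on low-quality translations.
.x_class <- "[ACDEFGHIKLMNPQRSTVWY]"

#' Compile a PROSITE-style pattern
#'
#' Supports `x` (any residue), literal residues, `[...]` alternatives and
#' `x(m,n)` / `[..](m,n)` bounded repetition. Elements may be separated by
#' dashes (`"G-x-G-x-x-G"`) or written compactly (`"GxGxxG"`). Matching is
#' case-insensitive; variable repeats match leftmost-shortest.
#'
#' @param prosite Pattern string.
#' @param name Motif name.
#' @return A `motif_pattern` with the compiled regular expression.
#' @export
compile_pattern <- function(prosite, name = prosite) {
  src <- gsub("\\s", "", prosite)
  tokens <- if (grepl("-", src)) {
    strsplit(src, "-", fixed = TRUE)[[1]]
  } else {
    .tokenize_compact(src)
  }
  regex <- character(0)
  pos <- 1L
  for (tok in tokens) {
    if (tok == "") stop("empty pattern element at token ", pos)
    m <- regmatches(tok, regexec("^([^()]+)(\\(([0-9]+)(,([0-9]+))?\\))?$", tok))[[1]]
    if (length(m) == 0) stop("cannot parse pattern element '", tok, "' at token ", pos)
    core <- m[2]
    if (grepl("^\\[[A-Za-z]+\\]$", core)) {
      elem <- toupper(core)
    } else if (toupper(core) == "X") {
      elem <- .x_class
    } else if (grepl("^[A-Za-z]$", core)) {
      elem <- toupper(core)
    } else {
      stop("invalid pattern element '", core, "' at token ", pos)
    }
    if (m[3] != "") {
      lo <- as.integer(m[4])
      hi <- if (m[6] != "") as.integer(m[6]) else lo
      if (lo > hi) stop("invalid repetition bounds (", lo, ",", hi,
                        ") at token ", pos, ": m > n")
      elem <- sprintf("(?:%s){%d,%d}?", elem, lo, hi)
    }
    regex <- c(regex, elem)
    pos <- pos + 1L
  }
  structure(list(name = name, pattern = prosite,
                 regex = paste(regex, collapse = "")),
            class = "motif_pattern")
}

# compact form: single letters, x, and bracket groups, each optionally
# followed by (m,n)
.tokenize_compact <- function(src) {
  tokens <- character(0)
  i <- 1L
  n <- nchar(src)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(src, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated [ at position ", i)
      tok <- substr(src, i, i + j - 1L)
      i <- i + j
    } else if (grepl("^[A-Za-z]$", ch)) {
      tok <- ch
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i)
    }
    if (i <= n && substr(src, i, i) == "(") {
      j <- regexpr(")", substr(src, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated ( at position ", i)
      tok <- paste0(tok, substr(src, i, i + j - 1L))
      i <- i + j
    }
    tokens <- c(tokens, tok)
  }
  tokens
}

#' Scan a protein for all (overlapping) motif matches
#'
#' Every start position is tried, so overlapping hits are reported; for
#' variable repeats the match at each start is the leftmost-shortest one.
#' An empty result is itself evidence (absence of a motif).
#'
#' @param protein Amino-acid string.
#' @param pattern A [compile_pattern()] result.
#' @param protein_id Optional id recorded in the hits.
#' @return Data frame `protein_id, motif_name, start, match` (0 rows when
#'   the motif is absent).
#' @export
scan_motif <- function(protein, pattern, protein_id = "") {
  stopifnot(inherits(pattern, "motif_pattern"))
  s <- toupper(protein)
  anchored <- paste0("^(?:", pattern$regex, ")")
  starts <- integer(0)
  matches <- character(0)
  for (i in seq_len(nchar(s))) {
    m <- regexpr(anchored, substr(s, i, nchar(s)), perl = TRUE)
    if (m > 0) {
      starts <- c(starts, i)
      matches <- c(matches, substr(s, i, i + attr(m, "match.length") - 1L))
    }
  }
  data.frame(protein_id = rep(protein_id, length(starts)),
             motif_name = rep(pattern$name, length(starts)),
             start = starts, match = matches,
             stringsAsFactors = FALSE)
}

#' Built-in diagnostic motif library
#'
#' FAD binding `G-x-G-x-x-G`, tryptophan binding `W-x-W-x-I-P`, prenyl
#' diphosphate binding `[ND]-D-x-x-D`, and the Rieske [2Fe-2S] pattern
#' `C-x-H-x(15,17)-C-x-x-H` (canonical ligand spacing; adjust via `extra`
#' if needed).
#'
#' @param extra Optional named character vector of additional PROSITE-style
#'   patterns (name -> pattern) to append.
#' @return Named list of `motif_pattern` objects.
#' @export
builtin_motifs <- function(extra = NULL) {
  pats <- c(FAD_binding = "G-x-G-x-x-G",
            Trp_binding = "W-x-W-x-I-P",
            prenyl_PP = "[ND]-D-x-x-D",
            Rieske_2Fe2S = "C-x-H-x(15,17)-C-x-x-H")
  if (!is.null(extra)) pats <- c(pats, extra)
  out <- lapply(names(pats), function(nm) compile_pattern(pats[[nm]], nm))
  setNames(out, names(pats))
}

#' Scan every protein of a set against a motif library
#'
#' @param proteins Data frame from [cluster_proteins()].
#' @param motifs List from [builtin_motifs()].
#' @param path Optional TSV output path.
#' @return Data frame of all hits.
#' @export
scan_proteins <- function(proteins, motifs = builtin_motifs(), path = NULL) {
  hits <- list()
  for (i in seq_len(nrow(proteins))) {
    for (p in motifs) {
      h <- scan_motif(proteins$sequence[i], p, proteins$protein_id[i])
      if (nrow(h) > 0) hits[[length(hits) + 1L]] <- h
    }
  }
  df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(0), motif_name = character(0),
               start = integer(0), match = character(0))
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
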