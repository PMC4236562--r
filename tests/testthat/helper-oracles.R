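# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: alignments are enumerated exhaustively, components grown
# by reachability closure, motifs expanded to concrete strings.

# --- exhaustive global-alignment oracle (affine gaps) -----------------------

# all move strings (D = substitute, U = residue of a vs gap, L = gap vs b)
enumerate_alignments <- function(n, m) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == n && j == m) return("")
    res <- character(0)
    if (i < n && j < m) res <- c(res, paste0("D", rec(i + 1, j + 1)))
    if (i < n) res <- c(res, paste0("U", rec(i + 1, j)))
    if (j < m) res <- c(res, paste0("L", rec(i, j + 1)))
    memo[[key]] <- res
    res
  }
  rec(0, 0)
}

score_alignment_moves <- function(moves, a, b, scheme) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  S <- scheme$matrix
  mv <- strsplit(moves, "")[[1]]
  i <- 0L; j <- 0L; prev <- ""
  s <- 0
  for (m in mv) {
    if (m == "D") {
      i <- i + 1L; j <- j + 1L
      s <- s + S[ca[i], cb[j]]
    } else if (m == "U") {
      i <- i + 1L
      s <- s + if (prev == "U") scheme$gap_extend else scheme$gap_open
    } else {
      j <- j + 1L
      s <- s + if (prev == "L") scheme$gap_extend else scheme$gap_open
    }
    prev <- m
  }
  s
}

oracle_nw_score <- function(a, b, scheme) {
  alns <- enumerate_alignments(nchar(a), nchar(b))
  max(vapply(alns, score_alignment_moves, numeric(1), a, b, scheme))
}

# --- reachability-closure connected components ------------------------------

oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  groups <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  split(seq_len(n), match(groups, unique(groups)))
}

# --- motif oracle by pattern expansion --------------------------------------

# tokens: list of list(options = character vector of residues, lo, hi)
oracle_expand_tokens <- function(tokens) {
  out <- ""
  for (tok in tokens) {
    pieces <- character(0)
    for (cnt in tok$lo:tok$hi) {
      if (cnt == 0) { pieces <- c(pieces, ""); next }
      combos <- do.call(expand.grid,
                        c(rep(list(tok$options), cnt),
                          stringsAsFactors = FALSE))
      pieces <- c(pieces, apply(combos, 1, paste, collapse = ""))
    }
    out <- as.vector(outer(out, unique(pieces), paste0))
  }
  unique(out)
}

oracle_motif_starts <- function(seq, tokens) {
  expansions <- oracle_expand_tokens(tokens)
  starts <- integer(0)
  for (e in expansions) {
    w <- nchar(e)
    if (w == 0 || w > nchar(seq)) next
    for (i in seq_len(nchar(seq) - w + 1)) {
      if (substr(seq, i, i + w - 1) == e) starts <- c(starts, i)
    }
  }
  sort(unique(starts))
}

tokens_to_prosite <- function(tokens) {
  paste(vapply(tokens, function(tok) {
    core <- if (length(tok$options) == 20) "x"
            else if (length(tok$options) == 1) tok$options
            else paste0("[", paste(tok$options, collapse = ""), "]")
    if (tok$lo == 1 && tok$hi == 1) core
    else paste0(core, "(", tok$lo, ",", tok$hi, ")")
  }, character(1)), collapse = "-")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_motif_tokens <- function(n_elem) {
  tokens <- list()
  n_x <- 0L
  for (i in seq_len(n_elem)) {
    kind <- sample(c("lit", "x", "set"), 1,
                   prob = c(0.5, if (n_x < 2) 0.25 else 0, 0.25))
    tok <- switch(kind,
      lit = list(options = sample(AA20, 1), lo = 1L, hi = 1L),
      x = { n_x <- n_x + 1L; list(options = AA20, lo = 1L, hi = 1L) },
      set = list(options = sort(sample(AA20, sample(2:3, 1))), lo = 1L, hi = 1L))
    if (kind != "x" && runif(1) < 0.2) {
      tok$lo <- sample(0:2, 1)
      tok$hi <- tok$lo + sample(0:2, 1)
      if (tok$hi == 0) tok$hi <- 1L
    }
    tokens[[i]] <- tok
  }
  # avoid patterns that can match the empty string
  if (all(vapply(tokens, `[[`, numeric(1), "lo") == 0)) {
    tokens[[1]]$lo <- 1L
    tokens[[1]]$hi <- max(tokens[[1]]$hi, 1L)
  }
  tokens
}

# --- tree helpers -----------------------------------------------------------

# support value attached to the edge separating `taxa` from the rest
clade_support <- function(tree, taxa, outgroup) {
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  nd <- ape::getMRCA(rooted, taxa)
  as.numeric(rooted$node.label[nd - length(rooted$tip.label)])
}

random_unrooted_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 0.5))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}
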