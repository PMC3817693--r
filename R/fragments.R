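#' The BLOSUM62 substitution matrix
#'
#' Returns the canonical BLOSUM62 integer matrix (from Biostrings'
#' packaged copy), validated on first use: symmetric, with every diagonal
#' entry the maximum of its row over the 20 standard residues.
#'
#' @return 20+ x 20+ integer matrix with amino-acid row/column names
#' @export
blosum62 <- function() {
  if (is.null(.denseloop_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    stopifnot(isTRUE(all.equal(m, t(m))))
    sub <- m[AA1, AA1]
    if (!all(diag(sub) == apply(sub, 1, max)))
      stop("BLOSUM62 diagonal-dominance check failed")
    .denseloop_cache$blosum62 <- m
  }
  .denseloop_cache$blosum62
}

.denseloop_cache <- new.env(parent = emptyenv())

new_fragment <- function(torsions, seq, source_id, window) {
  colnames(torsions) <- c("phi", "psi", "omega")
  structure(list(torsions = torsions, seq = seq, source_id = source_id,
                 window = window), class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment: %d-mer '%s' from %s@%d\n", nrow(x$torsions),
              paste(x$seq, collapse = ""), x$source_id, x$window))
  invisible(x)
}

#' Build a fragment library from backbone models
#'
#' One fragment per contiguous window per model; windows crossing a
#' recorded chain break are skipped. Fragments store the window's backbone
#' torsions and source sequence. Torsions undefined at a chain terminus
#' (phi of the first residue, psi/omega of the last) are kept as NA; such
#' entries are ignored at insertion time.
#'
#' @param models list of [backbone_model()] (a single model is accepted)
#' @param length fragment length in residues (3 or 9 by convention)
#' @param ids source identifiers, one per model
#' @return an object of class `fragment_library`
#' @export
build_library <- function(models, length = 9,
                          ids = sprintf("model%02d", seq_along(models))) {
  if (inherits(models, "backbone_model")) models <- list(models)
  frags <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    n <- n_res(m)
    if (n < length) next
    hc <- has_coords(m)
    for (w in seq_len(n - length + 1)) {
      span <- w:(w + length - 1)
      if (!all(hc[span])) next
      if (length(span) > 1 && any(m$break_after[span[-base::length(span)]])) next
      frags[[base::length(frags) + 1]] <-
        new_fragment(m$torsions[span, , drop = FALSE], m$seq[span], ids[mi], w)
    }
  }
  if (base::length(frags) == 0) stop("no valid fragment windows in the input models")
  structure(list(length = length, fragments = frags,
                 metadata = sprintf("%d models", base::length(models))),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("fragment_library: %d fragments of length %d (%s)\n",
              length(x$fragments), x$length, x$metadata))
  invisible(x)
}

#' Score a fragment against a query window
#'
#' The profile-free similarity: the sum over positions of the substitution
#' score between the query residue and the fragment's source residue.
#' Higher is better; `distance = TRUE` returns the negated similarity for
#' callers who want a distance to minimize.
#'
#' @param query_window character string (or vector) of one-letter codes
#' @param frag a `fragment`
#' @param matrix substitution matrix (default [blosum62()])
#' @param distance return the negated score
#' @return numeric score
#' @export
score_fragment <- function(query_window, frag, matrix = blosum62(),
                           distance = FALSE) {
  q <- if (length(query_window) == 1) strsplit(query_window, "")[[1]] else query_window
  if (length(q) != nrow(frag$torsions))
    stop("query window length != fragment length")
  s <- sum(lookup_subst(matrix, q, frag$seq))
  if (distance) -s else s
}

lookup_subst <- function(matrix, a, b) {
  fix <- function(x) {
    bad <- !(x %in% rownames(matrix))
    if (any(bad)) {
      if (!("X" %in% rownames(matrix)))
        stop("non-standard residue letter(s) ", paste(unique(x[bad]), collapse = ","),
             " and matrix has no X row")
      x[bad] <- "X"
    }
    x
  }
  a <- fix(a); b <- fix(b)
  matrix[cbind(a, b)]
}

#' Pick the best-scoring fragments for a query window
#'
#' Deterministic: fragments are ranked by decreasing similarity, ties
#' broken by (source_id, window position) lexicographic order.
#'
#' @param query_window one-letter codes of the target window
#' @param library a `fragment_library` of matching length
#' @param n_picks number of fragments to return (default 25)
#' @param matrix substitution matrix
#' @return list of `fragment`s, best first, with a `scores` attribute
#' @export
pick_fragments <- function(query_window, library, n_picks = 25,
                           matrix = blosum62()) {
  q <- if (length(query_window) == 1) strsplit(query_window, "")[[1]] else query_window
  if (length(q) != library$length)
    stop("query window length ", length(q), " != library length ", library$length)
  if (n_picks == 0) return(list())
  frs <- library$fragments
  sc <- vapply(frs, function(f) sum(lookup_subst(matrix, q, f$seq)), numeric(1))
  src <- vapply(frs, function(f) f$source_id, character(1))
  win <- vapply(frs, function(f) f$window, numeric(1))
  o <- order(-sc, src, win)
  if (n_picks > length(frs)) {
    warning("n_picks ", n_picks, " > library size ", length(frs), "; returning all")
    n_picks <- length(frs)
  }
  out <- frs[o[seq_len(n_picks)]]
  attr(out, "scores") <- sc[o[seq_len(n_picks)]]
  out
}

#' Write a fragment library in the plain-text exchange format
#'
#' Header line `length <L> count <N>`, then per-fragment blocks: a `>`
#' line with source id and window position, the source sequence, and one
#' `phi psi omega` line per position.
#'
#' @param library a `fragment_library`
#' @param path output file
#' @export
write_fraglib <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("length %d count %d", library$length,
                     length(library$fragments)), con)
  for (f in library$fragments) {
    writeLines(sprintf("> %s %d", f$source_id, f$window), con)
    writeLines(paste(f$seq, collapse = ""), con)
    writeLines(apply(f$torsions, 1, function(t)
      sprintf("%.4f %.4f %.4f", t[1], t[2], t[3])), con)
  }
  invisible(path)
}

#' Read a fragment library written by [write_fraglib()]
#' @param path library file
#' @return a `fragment_library`
#' @export
read_fraglib <- function(path) {
  ln <- readLines(path)
  hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  L <- as.integer(hd[2]); cnt <- as.integer(hd[4])
  frags <- vector("list", cnt)
  pos <- 2
  for (k in seq_len(cnt)) {
    meta <- strsplit(sub("^>\\s*", "", ln[pos]), "\\s+")[[1]]
    sq <- strsplit(ln[pos + 1], "")[[1]]
    # "NA" encodes torsions undefined at a chain terminus
    tor <- t(vapply(ln[(pos + 2):(pos + 1 + L)], function(s)
      suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]])),
      numeric(3)))
    rownames(tor) <- NULL
    frags[[k]] <- new_fragment(tor, sq, meta[1], as.integer(meta[2]))
    pos <- pos + 2 + L
  }
  structure(list(length = L, fragments = frags, metadata = path),
            class = "fragment_library")
}
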