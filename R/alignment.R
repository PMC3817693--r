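#' Alignment specification
#'
#' Pairs template residues with target residues; maximal runs of target
#' residues absent from the pairing are the gap segments to be rebuilt.
#'
#' @param template_sequence template one-letter sequence (string)
#' @param target_sequence target one-letter sequence (string)
#' @param aligned_pairs 2-column matrix of (template index, target index),
#'   monotone in both coordinates
#' @return object of class `alignment_spec` with derived `gap_segments`
#'   (data.frame start/end/length in target numbering, closed intervals)
#' @export
alignment_spec <- function(template_sequence, target_sequence, aligned_pairs) {
  ap <- matrix(as.integer(aligned_pairs), ncol = 2)
  if (nrow(ap) > 1 && (any(diff(ap[, 1]) <= 0) || any(diff(ap[, 2]) <= 0)))
    stop("aligned_pairs must be strictly increasing in both coordinates")
  nt <- nchar(template_sequence)
  nq <- nchar(target_sequence)
  if (nrow(ap) > 0 && (max(ap[, 1]) > nt || max(ap[, 2]) > nq || min(ap) < 1))
    stop("aligned_pairs reference residues outside the sequences")
  gap <- setdiff(seq_len(nq), ap[, 2])
  segs <- if (length(gap) == 0) {
    data.frame(start = integer(0), end = integer(0), length = integer(0))
  } else {
    brk <- cumsum(c(1, diff(gap) != 1))
    do.call(rbind, lapply(split(gap, brk), function(g)
      data.frame(start = min(g), end = max(g), length = length(g))))
  }
  rownames(segs) <- NULL
  structure(list(template_sequence = template_sequence,
                 target_sequence = target_sequence,
                 aligned_pairs = ap, gap_segments = segs),
            class = "alignment_spec")
}

#' @export
print.alignment_spec <- function(x, ...) {
  cat(sprintf("alignment_spec: %d/%d template residues aligned to target of %d; %d gap segment(s)\n",
              nrow(x$aligned_pairs), nchar(x$template_sequence),
              nchar(x$target_sequence), nrow(x$gap_segments)))
  if (nrow(x$gap_segments) > 0) print(x$gap_segments)
  invisible(x)
}

#' Read a gapped alignment (two aligned FASTA records, '-' for gaps)
#'
#' The first record is the template, the second the target.
#'
#' @param path alignment file
#' @return an [alignment_spec()]
#' @export
read_alignment <- function(path) {
  ln <- readLines(path)
  hd <- grep("^>", ln)
  if (length(hd) != 2) stop("expected exactly two FASTA records in ", path)
  grab <- function(i) {
    to <- if (i < length(hd)) hd[i + 1] - 1 else length(ln)
    paste(ln[(hd[i] + 1):to], collapse = "")
  }
  s1 <- strsplit(gsub("\\s", "", grab(1)), "")[[1]]
  s2 <- strsplit(gsub("\\s", "", grab(2)), "")[[1]]
  if (length(s1) != length(s2)) stop("aligned records differ in length")
  ti <- cumsum(s1 != "-")
  qi <- cumsum(s2 != "-")
  both <- s1 != "-" & s2 != "-"
  alignment_spec(paste(s1[s1 != "-"], collapse = ""),
                 paste(s2[s2 != "-"], collapse = ""),
                 cbind(ti[both], qi[both]))
}

#' Write a gapped alignment as two aligned FASTA records
#'
#' @param aln an [alignment_spec()]
#' @param path output file
#' @param ids record names
#' @export
write_alignment <- function(aln, path, ids = c("template", "target")) {
  tpl <- strsplit(aln$template_sequence, "")[[1]]
  tgt <- strsplit(aln$target_sequence, "")[[1]]
  ap <- aln$aligned_pairs
  r1 <- character(0); r2 <- character(0)
  ti <- 1L; qi <- 1L
  for (k in seq_len(nrow(ap) + 1)) {
    nt <- if (k <= nrow(ap)) ap[k, 1] else length(tpl) + 1L
    nq <- if (k <= nrow(ap)) ap[k, 2] else length(tgt) + 1L
    while (ti < nt) { r1 <- c(r1, tpl[ti]); r2 <- c(r2, "-"); ti <- ti + 1L }
    while (qi < nq) { r1 <- c(r1, "-"); r2 <- c(r2, tgt[qi]); qi <- qi + 1L }
    if (k <= nrow(ap)) {
      r1 <- c(r1, tpl[ti]); r2 <- c(r2, tgt[qi]); ti <- ti + 1L; qi <- qi + 1L
    }
  }
  writeLines(c(paste0(">", ids[1]), paste(r1, collapse = ""),
               paste0(">", ids[2]), paste(r2, collapse = "")), path)
  invisible(path)
}
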