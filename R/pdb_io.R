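#' Read a backbone model from a PDB file
#'
#' Parses ATOM records (via bio3d), keeps one chain, and builds a
#' [backbone_model()] from the N/CA/C/O/CB atoms. Residues missing any of
#' N, CA or C are dropped with a warning and leave a recorded chain break;
#' missing carbonyl O atoms are rebuilt from ideal geometry, and a
#' side-chain centroid CB is constructed at the ideal tetrahedral position
#' whenever absent (always for glycine). Alternate conformations other than
#' the first and residues with insertion codes are rejected with a warning.
#'
#' @param path PDB file
#' @param chain chain identifier; default: first chain in the file
#' @return a [backbone_model()]
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain | (is.na(at$chain) & is.na(chain)), , drop = FALSE]
  if (!is.null(at$insert)) {
    ins <- !is.na(at$insert) & at$insert != ""
    if (any(ins)) {
      warning("residues with insertion codes rejected (", sum(ins), " atoms)")
      at <- at[!ins, , drop = FALSE]
    }
  }
  if (!is.null(at$alt)) {
    altbad <- !is.na(at$alt) & !(at$alt %in% c("", "A"))
    if (any(altbad)) {
      warning("alternate conformations beyond 'A' rejected (", sum(altbad), " atoms)")
      at <- at[!altbad, , drop = FALSE]
    }
  }
  resnos <- unique(at$resno)
  geom <- ideal_geometry()
  keep <- list()
  for (r in resnos) {
    rows <- at[at$resno == r, , drop = FALSE]
    getxyz <- function(name) {
      i <- which(rows$elety == name)[1]
      if (is.na(i)) return(NULL)
      as.numeric(rows[i, c("x", "y", "z")])
    }
    N <- getxyz("N"); CA <- getxyz("CA"); C <- getxyz("C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      warning(sprintf("residue %d missing a backbone atom; dropped, chain break recorded", r))
      next
    }
    aa <- bio3d::aa321(rows$resid[1])
    if (is.na(aa) || aa == "X") aa <- "X"
    O <- getxyz("O")
    CB <- getxyz("CB")
    keep[[length(keep) + 1]] <- list(resno = r, aa = aa, N = N, CA = CA, C = C,
                                     O = O, CB = CB)
  }
  if (length(keep) == 0) stop("zero parseable residues in ", path)
  n <- length(keep)
  co <- array(NA_real_, c(n, 5, 3))
  seqv <- character(n); resno <- integer(n)
  for (i in seq_len(n)) {
    k <- keep[[i]]
    co[i, 1, ] <- k$N; co[i, 2, ] <- k$CA; co[i, 3, ] <- k$C
    resno[i] <- k$resno; seqv[i] <- k$aa
    nn <- if (i < n && keep[[i + 1]]$resno == k$resno + 1) keep[[i + 1]]$N else NULL
    ocb <- place_o_cb(k$N, k$CA, k$C, n_next = nn, geom = geom)
    co[i, 4, ] <- if (is.null(k$O)) ocb$O else k$O
    co[i, 5, ] <- if (is.null(k$CB) || k$aa == "G") ocb$CB else k$CB
  }
  backbone_model(co, seqv, resno = resno)
}

#' Write a backbone model to a PDB file
#'
#' Writes N/CA/C/O ATOM records (plus CB for non-glycine residues) at the
#' PDB format's 3-decimal coordinate precision. Residues without
#' coordinates are skipped.
#'
#' @param model a [backbone_model()]
#' @param path output file
#' @param chain chain identifier to write
#' @export
write_pdb <- function(model, path, chain = "A") {
  hc <- which(has_coords(model))
  if (length(hc) == 0) stop("model has no residues with coordinates")
  xyz <- c(); resno <- c(); elety <- c(); resid <- c()
  for (i in hc) {
    slots <- if (model$seq[i] == "G") 1:4 else 1:5
    for (a in slots) {
      xyz <- c(xyz, model$coords[i, a, ])
      resno <- c(resno, model$resno[i])
      elety <- c(elety, ATOM_SLOTS[a])
      resid <- c(resid, bio3d::aa123(model$seq[i]))
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(chain, length(resno)))
  invisible(path)
}
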