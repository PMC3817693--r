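#' Backbone model object
#'
#' A `backbone_model` holds an ordered single chain of residues with
#' backbone atoms N, CA, C, O and a side-chain centroid CB (glycine carries
#' a pseudo-CB at the ideal tetrahedral position). Torsions (phi, psi,
#' omega, degrees in (-180, 180]) are kept synchronized with the Cartesian
#' coordinates; chain breaks are recorded explicitly so that gapped or
#' partially built chains are representable.
#'
#' @param coords numeric array `c(n, 5, 3)`; atom slots N, CA, C, O, CB.
#'   `NA` rows mark residues without coordinates (e.g. unbuilt gap
#'   residues).
#' @param seq character vector of one-letter amino-acid codes, length `n`.
#' @param resno integer residue numbers, strictly increasing (default
#'   `1:n`).
#' @param break_after logical length `n`; `TRUE` between `i` and `i + 1`
#'   marks an explicit chain break. Breaks implied by missing coordinates
#'   or non-bonded C-N distances are added automatically.
#' @param movable logical per-residue movability mask.
#' @param tag per-residue alignment tag: one of `"aligned"`, `"rebuilt"`,
#'   `"gap-flank"`.
#' @return An object of class `backbone_model`.
#' @export
backbone_model <- function(coords, seq, resno = seq_len(dim(coords)[1]),
                           break_after = NULL, movable = NULL, tag = NULL) {
  n <- dim(coords)[1]
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 5, dim(coords)[3] == 3,
            length(seq) == n, length(resno) == n)
  dimnames(coords) <- list(NULL, ATOM_SLOTS, c("x", "y", "z"))
  if (is.null(break_after)) break_after <- rep(FALSE, n)
  if (is.null(movable)) movable <- rep(TRUE, n)
  if (is.null(tag)) tag <- rep("aligned", n)
  m <- structure(list(resno = as.integer(resno), seq = as.character(seq),
                      coords = coords, torsions = NULL,
                      break_after = break_after, movable = movable, tag = tag),
                 class = "backbone_model")
  m <- detect_breaks(m)
  m <- sync_torsions(m)
  validate_backbone_model(m)
  m
}

#' Number of residues in a model
#' @param model a [backbone_model()]
#' @return integer
#' @export
n_res <- function(model) length(model$resno)

#' Residues that have complete N/CA/C coordinates
#' @param model a [backbone_model()]
#' @return logical vector over residues
#' @export
has_coords <- function(model) {
  apply(model$coords[, 1:3, , drop = FALSE], 1, function(x) all(is.finite(x)))
}

# record breaks implied by the coordinates (gap residues, unbonded C-N)
detect_breaks <- function(model) {
  n <- n_res(model)
  if (n < 2) return(model)
  hc <- has_coords(model)
  for (i in seq_len(n - 1)) {
    if (model$break_after[i]) next
    if (!hc[i] || !hc[i + 1]) {
      model$break_after[i] <- TRUE
      next
    }
    d <- vnorm(model$coords[i + 1, "N", ] - model$coords[i, "C", ])
    if (d <= 0.5 || d >= 3.0) model$break_after[i] <- TRUE
    if (model$resno[i + 1] != model$resno[i] + 1L) model$break_after[i] <- TRUE
  }
  model$break_after[n] <- FALSE
  model
}

validate_backbone_model <- function(model) {
  n <- n_res(model)
  if (n == 0) stop("backbone_model with zero residues")
  if (any(diff(model$resno) <= 0)) stop("residue numbers must be strictly increasing")
  hc <- has_coords(model)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (model$break_after[i] || !hc[i] || !hc[i + 1]) next
      d <- vnorm(model$coords[i + 1, "N", ] - model$coords[i, "C", ])
      if (d <= 0.5 || d >= 3.0)
        stop(sprintf("C(%d)-N(%d) distance %.2f A outside (0.5, 3.0) without a recorded break",
                     model$resno[i], model$resno[i + 1], d))
    }
  }
  invisible(model)
}

#' Synchronize stored torsions from the coordinates
#' @param model a [backbone_model()]
#' @return the model with `torsions` recomputed (NA across termini, breaks
#'   and missing residues)
#' @export
sync_torsions <- function(model) {
  n <- n_res(model)
  hc <- has_coords(model)
  co <- model$coords
  co[!hc, , ] <- 0  # placeholder; masked below
  br <- model$break_after | c(!hc[-1], TRUE)[seq_len(n)] | !hc
  tor <- cpp_backbone_torsions(co, as.logical(br | !hc))
  colnames(tor) <- c("phi", "psi", "omega")
  tor[!hc, ] <- NA_real_
  model$torsions <- tor
  model
}

# place O(i) and CB(i) from the residue frame; o_ref is N(i+1) when the
# next residue is bonded, otherwise O is placed from psi (default 180)
place_o_cb <- function(N, CA, C, n_next = NULL, psi = NA, geom = ideal_geometry()) {
  if (!is.null(n_next)) {
    O <- place_atom(n_next, CA, C, geom$b_c_o, geom$a_ca_c_o, 180)
  } else {
    if (is.na(psi)) psi <- 180
    O <- place_atom(N, CA, C, geom$b_c_o, geom$a_ca_c_o, psi + 180)
  }
  CB <- place_atom(C, N, CA, geom$b_ca_cb, geom$a_n_ca_cb, geom$t_cb)
  list(O = O, CB = CB)
}

#' Build a fresh ideal-geometry chain from torsions
#'
#' Grows an N-to-C chain with the ideal internal coordinates of
#' [ideal_geometry()], consuming per-residue (phi, psi, omega). phi of the
#' first and psi/omega of the last residue are not needed; NA entries fall
#' back to 180 where a value is required (terminal carbonyl O).
#'
#' @param torsions numeric matrix `n x 3` (phi, psi, omega in degrees)
#' @param seq one-letter codes (default poly-A)
#' @param ... passed to [backbone_model()]
#' @return a [backbone_model()]
#' @export
build_from_torsions <- function(torsions, seq = rep("A", nrow(torsions)), ...) {
  geom <- ideal_geometry()
  n <- nrow(torsions)
  co <- array(NA_real_, c(n, 5, 3))
  co[1, 1, ] <- c(0, 0, 0)
  co[1, 2, ] <- c(geom$b_n_ca, 0, 0)
  a <- geom$a_n_ca_c * pi / 180
  co[1, 3, ] <- co[1, 2, ] + geom$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    N <- co[i, 1, ]; CA <- co[i, 2, ]; C <- co[i, 3, ]
    if (i < n) {
      psi <- torsions[i, 1 + 1]; om <- torsions[i, 3]
      if (is.na(psi)) psi <- 180
      if (is.na(om)) om <- 180
      phi1 <- torsions[i + 1, 1]
      if (is.na(phi1)) phi1 <- -120
      Nn <- place_atom(N, CA, C, geom$b_c_n, geom$a_ca_c_n, psi)
      CAn <- place_atom(CA, C, Nn, geom$b_n_ca, geom$a_c_n_ca, om)
      Cn <- place_atom(C, Nn, CAn, geom$b_ca_c, geom$a_n_ca_c, phi1)
      co[i + 1, 1, ] <- Nn; co[i + 1, 2, ] <- CAn; co[i + 1, 3, ] <- Cn
      ocb <- place_o_cb(N, CA, C, n_next = Nn, geom = geom)
    } else {
      ocb <- place_o_cb(N, CA, C, psi = torsions[i, 2], geom = geom)
    }
    co[i, 4, ] <- ocb$O
    co[i, 5, ] <- ocb$CB
  }
  backbone_model(co, seq, ...)
}

#' Regenerate coordinates from stored torsions, propagating from an anchor
#'
#' Coordinates downstream of `anchor` (in the stated direction) are rebuilt
#' from the stored torsions using ideal internal coordinates; coordinates
#' upstream of the anchor are untouched (the carbonyl O of the anchor
#' itself follows psi(anchor) and is refreshed in the N-to-C direction).
#'
#' @param model a [backbone_model()]
#' @param anchor residue index (position in the model, not resno)
#' @param direction `"N2C"` (rebuild anchor+1..n) or `"C2N"` (rebuild
#'   1..anchor-1)
#' @param upto optional last residue index to rebuild (limits propagation)
#' @param refresh_anchor_o re-place the anchor's carbonyl O from its
#'   (possibly changed) psi; set FALSE to leave the anchor strictly
#'   untouched
#' @return the modified model (torsions re-synchronized)
#' @export
rebuild_from_torsions <- function(model, anchor, direction = c("N2C", "C2N"),
                                  upto = NULL, refresh_anchor_o = TRUE) {
  direction <- match.arg(direction)
  geom <- ideal_geometry()
  n <- n_res(model)
  if (anchor < 1 || anchor > n) stop("anchor out of range")
  tor <- model$torsions
  co <- model$coords
  if (direction == "N2C") {
    last <- if (is.null(upto)) n else upto
    if (anchor < last) {
      for (i in anchor:(last - 1)) {
        N <- co[i, 1, ]; CA <- co[i, 2, ]; C <- co[i, 3, ]
        psi <- tor[i, 2]; om <- tor[i, 3]; phi1 <- tor[i + 1, 1]
        if (is.na(psi)) psi <- 180
        if (is.na(om)) om <- 180
        if (is.na(phi1)) phi1 <- -120
        Nn <- place_atom(N, CA, C, geom$b_c_n, geom$a_ca_c_n, psi)
        CAn <- place_atom(CA, C, Nn, geom$b_n_ca, geom$a_c_n_ca, om)
        Cn <- place_atom(C, Nn, CAn, geom$b_ca_c, geom$a_n_ca_c, phi1)
        co[i + 1, 1, ] <- Nn; co[i + 1, 2, ] <- CAn; co[i + 1, 3, ] <- Cn
        ocb <- place_o_cb(N, CA, C, n_next = Nn, geom = geom)
        if (i > anchor || refresh_anchor_o) co[i, 4, ] <- ocb$O
        if (i > anchor) co[i, 5, ] <- ocb$CB
        if (i + 1 == last) {
          nn2 <- if (last < n && !model$break_after[last]) co[last + 1, 1, ] else NULL
          ocb2 <- place_o_cb(Nn, CAn, Cn, n_next = nn2, psi = tor[last, 2], geom = geom)
          co[last, 4, ] <- ocb2$O; co[last, 5, ] <- ocb2$CB
        }
      }
    }
  } else {
    first <- if (is.null(upto)) 1L else upto
    if (anchor > first) {
      for (i in anchor:(first + 1)) {
        N <- co[i, 1, ]; CA <- co[i, 2, ]; C <- co[i, 3, ]
        phi <- tor[i, 1]; om <- tor[i - 1, 3]; psi0 <- tor[i - 1, 2]
        if (is.na(phi)) phi <- -120
        if (is.na(om)) om <- 180
        if (is.na(psi0)) psi0 <- 180
        Cp <- place_atom(C, CA, N, geom$b_c_n, geom$a_c_n_ca, phi)
        CAp <- place_atom(CA, N, Cp, geom$b_ca_c, geom$a_ca_c_n, om)
        Np <- place_atom(N, Cp, CAp, geom$b_n_ca, geom$a_n_ca_c, psi0)
        co[i - 1, 1, ] <- Np; co[i - 1, 2, ] <- CAp; co[i - 1, 3, ] <- Cp
        ocb <- place_o_cb(Np, CAp, Cp, n_next = N, geom = geom)
        co[i - 1, 4, ] <- ocb$O; co[i - 1, 5, ] <- ocb$CB
      }
    }
  }
  model$coords <- co
  sync_torsions(model)
}

#' Flat atom table of a model
#'
#' @param model a [backbone_model()]
#' @param slots atom slots to include (default all five)
#' @return list with `xyz` (m x 3), `res` (residue position per atom),
#'   `slot` (atom slot name) and `amp` (scattering amplitude)
#' @export
atom_table <- function(model, slots = ATOM_SLOTS) {
  hc <- which(has_coords(model))
  idx <- match(slots, ATOM_SLOTS)
  nh <- length(hc); ns <- length(idx)
  arr <- model$coords[hc, idx, , drop = FALSE]
  # rows ordered residue-major, atom slot minor
  xyz <- matrix(aperm(arr, c(2, 1, 3)), nh * ns, 3)
  slot <- rep(ATOM_SLOTS[idx], times = nh)
  list(xyz = xyz, res = rep(hc, each = ns), slot = slot,
       amp = unname(ATOM_AMPS[slot]))
}

#' @export
print.backbone_model <- function(x, ...) {
  n <- n_res(x)
  nb <- sum(x$break_after)
  nc <- sum(has_coords(x))
  cat(sprintf("backbone_model: %d residues (%d with coordinates), %d chain break(s)\n",
              n, nc, nb))
  cat(sprintf("  resno %d..%d  movable %d  tags: %s\n", x$resno[1], x$resno[n],
              sum(x$movable), paste(names(table(x$tag)), table(x$tag),
                                    sep = ":", collapse = " ")))
  invisible(x)
}
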