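# Smooth low-resolution energy: R-facing wrappers over the C++ terms.
# Every term returns the total energy plus an analytic Cartesian gradient
# with the same n x 5 x 3 layout as the model coordinates.

# Restrict to residues with coordinates and recompute break flags on that
# subset. Only *structural* gaps (missing residues, resno jumps) break the
# energy connectivity; a merely geometric break (bonded neighbours pulled
# apart) keeps its inter-residue terms so that chain breaks are penalized
# rather than forbidden.
energy_inputs <- function(model) {
  hc <- which(has_coords(model))
  if (length(hc) == 0) stop("model has no residues with coordinates")
  n <- length(hc)
  co <- model$coords[hc, , , drop = FALSE]
  br <- rep(FALSE, n)
  if (n > 1) {
    for (j in seq_len(n - 1)) {
      br[j] <- (hc[j + 1] != hc[j] + 1) ||
        (model$resno[hc[j + 1]] != model$resno[hc[j]] + 1L)
    }
  }
  list(co = co, breaks = br, resno = model$resno[hc], idx = hc,
       n_full = n_res(model))
}

# lift a subset gradient back onto the full-size residue array
lift_grad <- function(grad_sub, idx, n_full) {
  g <- array(0, c(n_full, 5, 3))
  g[idx, , ] <- grad_sub
  g
}

#' Ramachandran energy
#'
#' `E = sum_i -log P(phi_i, psi_i)` where `P` is a smooth 360-degree
#' periodic mixture of anisotropic Gaussian basins (alpha, beta,
#' left-alpha) over a uniform floor. Terminal residues and residues at
#' chain breaks are skipped. Gradients flow through the torsion
#' definitions onto the Cartesian coordinates of the atoms involved.
#'
#' @param model a [backbone_model()]
#' @param params from [default_energy_params()]
#' @return list with `energy`, `grad` (n x 5 x 3) and `per_residue`
#' @export
rama_energy <- function(model, params = default_energy_params()) {
  ei <- energy_inputs(model)
  r <- cpp_rama(ei$co, ei$breaks, params$rama)
  pr <- rep(0, ei$n_full); pr[ei$idx] <- r$per_residue
  list(energy = r$energy, grad = lift_grad(r$grad, ei$idx, ei$n_full),
       per_residue = pr)
}

#' Soft-sphere van der Waals energy
#'
#' Purely repulsive: `k * (r0 - d)^2` for `d < r0`, summed over atom pairs
#' separated by at least two residues in sequence numbering. The CB slot is
#' a soft side-chain interaction center (pseudo-CB for glycine).
#'
#' @inheritParams rama_energy
#' @return list with `energy` and `grad`
#' @export
vdw_energy <- function(model, params = default_energy_params()) {
  ei <- energy_inputs(model)
  r <- cpp_vdw(ei$co, ei$resno, unname(params$vdw$radii), params$vdw$k)
  list(energy = r$energy, grad = lift_grad(r$grad, ei$idx, ei$n_full))
}

#' Backbone hydrogen-bond energy
#'
#' Donor N-H (amide H built on the fly from ideal geometry), acceptor
#' carbonyl O. `E = -depth * f(d_HO) * g(theta_NHO)` with `f` a Gaussian
#' well centered at 1.9 A and `g` a cosine-squared switch vanishing for
#' angles below 90 degrees. Pairs closer than two residues in sequence are
#' excluded.
#'
#' @inheritParams rama_energy
#' @return list with `energy`, `grad`, `pair_energies` (donor x acceptor
#'   matrix) and `n_wells` (pairs below `-0.1 * depth`)
#' @export
hbond_bb_energy <- function(model, params = default_energy_params()) {
  ei <- energy_inputs(model)
  p <- params$hbond
  r <- cpp_hbond(ei$co, ei$resno, ei$breaks, p$depth, p$d0, p$sigma_d, p$l_nh)
  pe <- r$pair_energies
  list(energy = r$energy, grad = lift_grad(r$grad, ei$idx, ei$n_full),
       pair_energies = pe, n_wells = sum(pe < -0.1 * p$depth))
}

#' Bond-geometry restraint energy
#'
#' Harmonic penalties on every backbone bond length, bond angle, omega
#' planarity and the carbonyl/CB impropers against [ideal_geometry()].
#' Inter-residue C-N terms are included except across recorded chain
#' breaks, so unintended breaks are penalized rather than forbidden.
#'
#' @inheritParams rama_energy
#' @return list with `energy`, `grad` and `max_bond_dev` (largest absolute
#'   bond-length deviation, Angstrom)
#' @export
cart_bonded_energy <- function(model, params = default_energy_params()) {
  ei <- energy_inputs(model)
  p <- params$cart
  r <- cpp_cart_bonded(ei$co, ei$breaks, params$geom, p$k_len, p$k_ang,
                       p$k_omega)
  list(energy = r$energy, grad = lift_grad(r$grad, ei$idx, ei$n_full),
       max_bond_dev = r$max_bond_dev)
}

#' Combined low-resolution objective
#'
#' Weighted sum of the enabled terms; the gradient is the weighted sum of
#' the term gradients. The density term is the fast spline score
#' ([fast_density_score()]) and requires a precomputed field.
#'
#' @param model a [backbone_model()]
#' @param field a `spline_score_field`, or NULL when the density weight is 0
#' @param weights named weights (see [default_weights()])
#' @param params from [default_energy_params()]
#' @return list with `energy`, `grad` (n x 5 x 3) and per-term `terms`
#' @export
total_energy <- function(model, field = NULL, weights = default_weights(),
                         params = default_energy_params()) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  w <- default_weights()
  w[names(weights)] <- weights
  n <- n_res(model)
  g <- array(0, c(n, 5, 3))
  terms <- c(rama = 0, vdw = 0, hbond_bb = 0, cart_bonded = 0, density = 0)
  if (w["rama"] > 0) {
    r <- rama_energy(model, params)
    terms["rama"] <- r$energy; g <- g + w["rama"] * r$grad
  }
  if (w["vdw"] > 0) {
    r <- vdw_energy(model, params)
    terms["vdw"] <- r$energy; g <- g + w["vdw"] * r$grad
  }
  if (w["hbond_bb"] > 0) {
    r <- hbond_bb_energy(model, params)
    terms["hbond_bb"] <- r$energy; g <- g + w["hbond_bb"] * r$grad
  }
  if (w["cart_bonded"] > 0) {
    r <- cart_bonded_energy(model, params)
    terms["cart_bonded"] <- r$energy; g <- g + w["cart_bonded"] * r$grad
  }
  if (w["density"] > 0) {
    if (is.null(field))
      stop("density weight > 0 but no spline score field supplied")
    r <- fast_density_score(model, field)
    terms["density"] <- r$score
    if (nrow(r$grad) > 0) {
      base <- r$atoms$res + n * (match(r$atoms$slot, ATOM_SLOTS) - 1L)
      for (x in 1:3)
        g[base + 5L * n * (x - 1L)] <- g[base + 5L * n * (x - 1L)] +
          w["density"] * r$grad[, x]
    }
  }
  list(energy = sum(w * terms), grad = g, terms = terms, weights = w)
}
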