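#' Ideal backbone internal coordinates
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used both to build
#' chains from torsions and as the targets of the bond-geometry restraint
#' term. `t_cb` is the improper dihedral C-N-CA-CB placing the side-chain
#' centroid with L-amino-acid chirality.
#'
#' @return Named list of bond lengths, angles (degrees) and the CB improper.
#' @export
ideal_geometry <- function() {
  list(
    b_n_ca  = 1.458,
    b_ca_c  = 1.525,
    b_c_n   = 1.329,
    b_c_o   = 1.231,
    b_ca_cb = 1.521,
    b_n_h   = 1.010,
    a_n_ca_c  = 111.2,
    a_ca_c_n  = 116.2,
    a_c_n_ca  = 121.7,
    a_ca_c_o  = 120.8,
    a_o_c_n   = 123.0,   # coplanar with a_ca_c_o + a_ca_c_n (sums to 360)
    a_n_ca_cb = 110.5,
    t_cb      = 122.6    # dihedral(C, N, CA, CB), degrees
  )
}

# atom slot order used throughout the package
ATOM_SLOTS <- c("N", "CA", "C", "O", "CB")

# relative scattering amplitudes (electron counts; CB is a carbon centroid)
ATOM_AMPS <- c(N = 7, CA = 6, C = 6, O = 8, CB = 6)

#' Default parameters of the smooth low-resolution energy
#'
#' All terms are analytic and C1-continuous. The Ramachandran term is a
#' periodic mixture of anisotropic Gaussian basins (alpha, beta, left-alpha)
#' over a uniform floor; van der Waals is a purely repulsive soft sphere on
#' backbone atoms plus a CB side-chain centroid; the backbone hydrogen bond
#' is a Gaussian distance well times a cosine-squared angular switch; bond
#' geometry is harmonic about [ideal_geometry()].
#'
#' @return Nested list of term parameters (`geom`, `rama`, `vdw`, `hbond`,
#'   `cart`).
#' @export
default_energy_params <- function() {
  list(
    geom = ideal_geometry(),
    rama = list(
      centers = rbind(alpha = c(-63, -43),
                      beta  = c(-120, 130),
                      lalpha = c(57, 47)),
      sigmas  = rbind(alpha = c(12, 14),
                      beta  = c(30, 22),
                      lalpha = c(11, 11)),
      weights = c(alpha = 1.0, beta = 1.0, lalpha = 0.35),
      floor   = 0.002
    ),
    vdw = list(
      # per-slot radii (N, CA, C, O, CB); soft, smaller than full vdW so
      # that native backbone contacts (helix H-bonds) score zero
      radii = c(N = 1.40, CA = 1.60, C = 1.60, O = 1.35, CB = 1.80),
      k = 1.0
    ),
    hbond = list(depth = 2.0, d0 = 1.9, sigma_d = 0.3, l_nh = 1.010),
    cart = list(k_len = 100, k_ang = 20, k_omega = 10)
  )
}

#' Default weights of the combined low-resolution objective
#'
#' @return Named numeric vector over terms `rama`, `vdw`, `hbond_bb`,
#'   `cart_bonded`, `density`.
#' @export
default_weights <- function() {
  c(rama = 0.5, vdw = 1.0, hbond_bb = 1.0, cart_bonded = 1.0, density = 0.05)
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
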