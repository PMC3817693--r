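# R-side evaluation of the packaged Ramachandran mixture (test oracle)
rama_mixture <- function(phi, psi, p = default_energy_params()$rama) {
  wrap <- function(d) ((d + 180) %% 360) - 180
  P <- p$floor
  for (b in seq_len(nrow(p$centers))) {
    dphi <- wrap(phi - p$centers[b, 1]); dpsi <- wrap(psi - p$centers[b, 2])
    P <- P + p$weights[b] * exp(-0.5 * (dphi^2 / p$sigmas[b, 1]^2 +
                                          dpsi^2 / p$sigmas[b, 2]^2))
  }
  -log(P)
}

test_that("rama energy follows the basin mixture and is periodic", {
  n <- 9
  alpha <- build_from_torsions(cbind(rep(-63, n), rep(-43, n), rep(180, n)))
  r <- rama_energy(alpha)
  expect_equal(unname(r$per_residue[5]), unname(rama_mixture(-63, -43)),
               tolerance = 1e-6)
  # the alpha basin floor is far below a disallowed region
  expect_gt(rama_mixture(60, -60) - rama_mixture(-63, -43), 2)
  # periodicity of the mixture
  expect_equal(rama_mixture(-63 + 360, -43), rama_mixture(-63, -43))
  # stationary at the basin center: numeric torsion-gradient ~ 0
  h <- 1e-4
  expect_lt(abs(rama_mixture(-63 + h, -43) - rama_mixture(-63 - h, -43)) /
              (2 * h), 1e-6)
  expect_lt(abs(rama_mixture(-63, -43 + h) - rama_mixture(-63, -43 - h)) /
              (2 * h), 1e-6)
})

test_that("vdw is zero without contacts and matches a brute-force oracle", {
  ext <- extended_chain(10)
  expect_equal(vdw_energy(ext)$energy, 0)

  m <- wobbly_helix(12, sd = 0.4, seed = 7)
  p <- default_energy_params()$vdw
  at <- atom_table(m)
  oracle <- 0
  for (i in seq_len(nrow(at$xyz) - 1)) {
    for (j in (i + 1):nrow(at$xyz)) {
      if (abs(at$res[i] - at$res[j]) < 2) next
      d <- sqrt(sum((at$xyz[i, ] - at$xyz[j, ])^2))
      r0 <- p$radii[at$slot[i]] + p$radii[at$slot[j]]
      if (d < r0) oracle <- oracle + p$k * (r0 - d)^2
    }
  }
  expect_equal(vdw_energy(m)$energy, unname(oracle), tolerance = 1e-10)
  # a pair at half its contact radius contributes k * (r0/2)^2
  r0 <- 2 * p$radii["CA"]
  expect_equal(p$k * (r0 / 2)^2, p$k * r0^2 / 4)
})

test_that("backbone hydrogen bonds appear in helices and vanish when stretched", {
  L <- 15
  hx <- ideal_helix(L)
  hb <- hbond_bb_energy(hx)
  expect_lt(hb$energy, 0)
  # roughly one i,i+4 well per turn position
  expect_gte(hb$n_wells, L - 5)
  expect_lte(hb$n_wells, L + 2)

  ext <- extended_chain(12)
  expect_lt(abs(hbond_bb_energy(ext)$energy), 1e-6)

  big <- hx
  big$coords <- big$coords * 2
  big <- suppressWarnings(denseloop:::detect_breaks(sync_torsions(big)))
  expect_lt(abs(hbond_bb_energy(big)$energy), 1e-6)
})

test_that("bond-geometry restraints are exactly zero on ideal chains and harmonic", {
  set.seed(5)
  m <- build_from_torsions(cbind(runif(10, -180, 180), runif(10, -180, 180),
                                 rep(180, 10)))
  expect_lt(cart_bonded_energy(m)$energy, 1e-8)

  # stretch one C-N bond by translating everything downstream along it
  k <- 5
  u <- m$coords[k + 1, 1, ] - m$coords[k, 3, ]
  u <- u / sqrt(sum(u^2))
  m2 <- m
  for (i in (k + 1):10) for (a in 1:5)
    m2$coords[i, a, ] <- m2$coords[i, a, ] + 0.5 * u
  m2 <- suppressWarnings(sync_torsions(m2))
  p <- default_energy_params()$cart
  expect_equal(cart_bonded_energy(m2)$energy, p$k_len * 0.25,
               tolerance = 1e-9)
})

test_that("minimizing bond geometry restores an ideal chain from noise", {
  set.seed(31)
  m <- ideal_helix(12)
  m$coords <- m$coords + array(rnorm(length(m$coords), 0, 0.3), dim(m$coords))
  m <- suppressWarnings(denseloop:::detect_breaks(sync_torsions(m)))
  w <- c(rama = 0, vdw = 0, hbond_bb = 0, cart_bonded = 1, density = 0)
  r <- cartesian_minimize(m, weights = w, movable = rep(TRUE, 12),
                          max_evals = 3000)
  expect_lt(cart_bonded_energy(r$model)$max_bond_dev, 0.02)
})

test_that("the combined objective is linear and homogeneous in its weights", {
  m <- wobbly_helix(10, seed = 3)
  z <- total_energy(m, weights = c(rama = 0, vdw = 0, hbond_bb = 0,
                                   cart_bonded = 0, density = 0))
  expect_equal(z$energy, 0)
  expect_true(all(z$grad == 0))

  r1 <- total_energy(m, weights = c(rama = 1, vdw = 0, hbond_bb = 0,
                                    cart_bonded = 0, density = 0))
  expect_equal(r1$energy, rama_energy(m)$energy)

  wA <- c(rama = 0.5, vdw = 1, hbond_bb = 1, cart_bonded = 1, density = 0)
  a <- total_energy(m, weights = wA)
  b <- total_energy(m, weights = 2 * wA)
  expect_equal(b$energy, 2 * a$energy, tolerance = 1e-12)
  expect_equal(b$grad, 2 * a$grad, tolerance = 1e-12)

  expect_error(total_energy(m, field = NULL,
                            weights = c(density = 1)), "field")
})

test_that("every term is invariant under rigid motion", {
  m <- wobbly_helix(11, seed = 9)
  th <- 0.7; ax <- c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m2 <- m
  for (i in 1:11) for (a in 1:5)
    m2$coords[i, a, ] <- as.numeric(R %*% m$coords[i, a, ]) + c(3, -2, 7)
  m2 <- sync_torsions(m2)
  for (f in list(rama_energy, vdw_energy, hbond_bb_energy,
                 cart_bonded_energy)) {
    expect_equal(f(m2)$energy, f(m)$energy, tolerance = 1e-8)
  }
})

test_that("analytic gradients match finite differences for every term", {
  m <- wobbly_helix(12, sd = 0.15, seed = 4)
  terms <- list(rama = rama_energy, vdw = vdw_energy,
                hbond = hbond_bb_energy, cart = cart_bonded_energy)
  for (nm in names(terms)) {
    expect_lt(fd_gradient_error(terms[[nm]], m), 1e-4)
  }
  w <- c(rama = 0.5, vdw = 1, hbond_bb = 1, cart_bonded = 1, density = 0)
  expect_lt(fd_gradient_error(function(mm) total_energy(mm, weights = w), m),
            1e-4)
})

test_that("the energy surface is finite along conformational interpolations", {
  a <- random_chain(10, seed = 11)
  b <- random_chain(10, seed = 12)
  w <- c(rama = 0.5, vdw = 1, hbond_bb = 1, cart_bonded = 1, density = 0)
  for (t in seq(0, 1, length.out = 200)) {
    m <- a
    m$coords <- (1 - t) * a$coords + t * b$coords
    m <- suppressWarnings(sync_torsions(m))
    e <- total_energy(m, weights = w)$energy
    expect_true(is.finite(e))
  }
})
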