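# single-residue model with one atom placed exactly (helper)
one_atom_model <- function(pos) {
  m <- ideal_helix(1)
  shift <- pos - m$coords[1, 2, ]
  for (a in 1:5) m$coords[1, a, ] <- m$coords[1, a, ] + shift
  sync_torsions(m)
}

test_that("simulated maps peak at atom positions and shift with the atom", {
  m <- one_atom_model(c(8, 8, 8))
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 6)
  # the five atoms coincide after the shift trick? no -- use a CA-only probe:
  at <- atom_table(m, slots = "CA")
  vals <- cpp_simulate_map(at$xyz, at$amp, map$origin, map$spacing,
                           dim(map$values), atom_kernels(3)$sigma)
  node <- round((c(8, 8, 8) - map$origin) / map$spacing) + 1
  expect_equal(vals[node[1], node[2], node[3]], max(vals))
  # translation by exactly one grid step permutes the array by one voxel
  v2 <- cpp_simulate_map(at$xyz + rep(c(1, 0, 0), each = nrow(at$xyz)),
                         at$amp, map$origin, map$spacing, dim(map$values),
                         atom_kernels(3)$sigma)
  d <- dim(vals)
  expect_lt(max(abs(v2[2:d[1], , ] - vals[1:(d[1] - 1), , ])),
            1e-9 * max(vals))
})

test_that("the map integral matches the summed kernel amplitudes", {
  m <- ideal_helix(20)
  map <- simulate_map(m, spacing = 0.5, resolution = 3, padding = 6)
  integral <- sum(map$values) * prod(map$spacing)
  expect_lt(abs(integral - sum(atom_table(m)$amp)) / sum(atom_table(m)$amp),
            0.02)
})

test_that("masked per-residue correlation is exact for self, negation and misplacement", {
  m <- ideal_helix(12)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 5)
  cc <- masked_residue_cc(m, map)
  expect_true(all(abs(cc$cc - 1) < 1e-6))
  expect_equal(cc$total, -mean(cc$cc))

  neg <- map; neg$values <- -neg$values
  ccn <- masked_residue_cc(m, neg)
  expect_true(all(abs(ccn$cc + 1) < 1e-6))

  # misplacement against a realistic (noisy) observed map: masks land on
  # featureless noise, so the mean correlation collapses
  cs <- load_case("gap")
  m3 <- cs$truth
  m3$coords <- m3$coords + 10 / sqrt(3)
  m3 <- suppressWarnings(sync_torsions(m3))
  cct <- masked_residue_cc(m3, cs$map)
  expect_lt(mean(cct$cc, na.rm = TRUE), 0.2)
})

test_that("the spline field interpolates its nodes exactly", {
  m <- ideal_helix(10)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 6)
  field <- build_spline_field(map, standardize = FALSE)
  d <- dim(field$base)
  set.seed(5)
  lo <- pmax(floor(d / 3), 3); hi <- pmin(ceiling(2 * d / 3), d - 3)
  ijk <- cbind(sample(lo[1]:hi[1], 25, TRUE), sample(lo[2]:hi[2], 25, TRUE),
               sample(lo[3]:hi[3], 25, TRUE))
  pts <- sweep((ijk - 1) * rep(field$spacing, each = 25), 2, field$origin, `+`)
  fi <- field_interp(field, pts, "CA")
  # node values computed independently by the brute-force real-space sum
  dd <- dim(map$values)
  gx <- map$origin[1] + (0:(dd[1] - 1)) * map$spacing[1]
  gy <- map$origin[2] + (0:(dd[2] - 1)) * map$spacing[2]
  gz <- map$origin[3] + (0:(dd[3] - 1)) * map$spacing[3]
  nodes <- vapply(1:25, function(i) {
    r2 <- outer(outer((gx - pts[i, 1])^2, (gy - pts[i, 2])^2, `+`),
                (gz - pts[i, 3])^2, `+`)
    6 * sum(exp(-r2 / (2 * field$sigma^2)) *
              (2 * pi * field$sigma^2)^(-1.5) * map$values)
  }, numeric(1))
  expect_lt(max(abs(fi$value - nodes)) / max(abs(nodes)), 1e-8)
})

test_that("field values match the brute-force real-space convolution off-grid", {
  m <- ideal_helix(10)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 6)
  field <- build_spline_field(map, standardize = FALSE)
  set.seed(6)
  ctr <- colMeans(atom_table(m)$xyz)
  pts <- matrix(rep(ctr, 200), 200, 3, byrow = TRUE) +
    matrix(runif(600, -4, 4), 200, 3)
  fi <- field_interp(field, pts, "C")
  d <- dim(map$values)
  gx <- map$origin[1] + (0:(d[1] - 1)) * map$spacing[1]
  gy <- map$origin[2] + (0:(d[2] - 1)) * map$spacing[2]
  gz <- map$origin[3] + (0:(d[3] - 1)) * map$spacing[3]
  sig <- field$sigma
  oracle <- vapply(1:200, function(i) {
    r2 <- outer(outer((gx - pts[i, 1])^2, (gy - pts[i, 2])^2, `+`),
                (gz - pts[i, 3])^2, `+`)
    6 * sum(exp(-r2 / (2 * sig^2)) * (2 * pi * sig^2)^(-1.5) * map$values)
  }, numeric(1))
  expect_lt(max(abs(fi$value - oracle)) / max(abs(oracle)), 1e-3)
})

test_that("delta and uniform maps convolve to the kernel and to a constant", {
  vals <- array(0, c(24, 24, 24))
  vals[12, 12, 12] <- 1
  dmap <- density_map(vals, 1, c(0, 0, 0), resolution = 3)
  field <- build_spline_field(dmap, standardize = FALSE)
  kern <- atom_kernels(3)
  # field at distance r from the spike equals the kernel value there
  for (r in c(0, 0.5, 1.25)) {
    p <- matrix(c(11 + r, 11, 11), 1)
    fi <- field_interp(field, p, "CA")
    expect_equal(fi$value, 6 * exp(-r^2 / (2 * kern$sigma^2)) *
                   (2 * pi * kern$sigma^2)^(-1.5), tolerance = 1e-3)
  }
  u <- density_map(array(2, c(20, 20, 20)), 1, c(0, 0, 0), resolution = 3)
  uf <- build_spline_field(u, standardize = FALSE)
  p <- matrix(c(10.3, 9.6, 10.1), 1)
  gx <- (0:19)
  k1 <- sum(exp(-outer(outer((gx - 10.3)^2, (gx - 9.6)^2, `+`), (gx - 10.1)^2,
                       `+`) / (2 * kern$sigma^2))) * (2 * pi * kern$sigma^2)^(-1.5)
  expect_equal(field_interp(uf, p, "CA")$value, 6 * 2 * k1, tolerance = 1e-3)
})

test_that("fast density score prefers the generating pose and has exact gradients", {
  m <- ideal_helix(15)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 6)
  field <- build_spline_field(map)
  s0 <- fast_density_score(m, field)
  m2 <- m; m2$coords <- m2$coords + 2 / sqrt(3)
  s2 <- fast_density_score(sync_torsions(m2), field)
  expect_lt(s0$score, s2$score)

  # analytic gradients vs central differences at 50 atoms
  at <- atom_table(m)
  set.seed(8)
  ks <- sample(nrow(at$xyz), 50)
  h <- 0.01
  err <- 0
  for (k in ks) {
    i <- at$res[k]; a <- match(at$slot[k], c("N", "CA", "C", "O", "CB"))
    for (x in 1:3) {
      mp <- m; mp$coords[i, a, x] <- mp$coords[i, a, x] + h
      mm <- m; mm$coords[i, a, x] <- mm$coords[i, a, x] - h
      num <- (fast_density_score(mp, field)$score -
                fast_density_score(mm, field)$score) / (2 * h)
      err <- max(err, abs(num - s0$grad[k, x]))
    }
  }
  expect_lt(err / max(abs(s0$grad)), 1e-4)

  # empty model
  e <- backbone_model(array(NA_real_, c(2, 5, 3)), c("A", "A"))
  fe <- fast_density_score(e, field)
  expect_equal(fe$score, 0)
  expect_equal(nrow(fe$grad), 0)
})

test_that("fast score ordering tracks the global unmasked correlation", {
  set.seed(12)
  m <- ideal_helix(20)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 6)
  field <- build_spline_field(map)
  fasts <- numeric(50); ccs <- numeric(50)
  for (k in 1:50) {
    mp <- m
    mp$coords <- mp$coords + array(rnorm(length(mp$coords), 0, runif(1, 0, 1.2)),
                                   dim(mp$coords))
    mp <- sync_torsions(mp)
    fasts[k] <- fast_density_score(mp, field)$score
    calc <- simulate_map(mp, spacing = 1, resolution = 3,
                         grid = list(origin = map$origin, dims = dim(map$values)))
    ccs[k] <- cor(as.numeric(calc$values), as.numeric(map$values))
  }
  expect_gte(cor(fasts, -ccs, method = "spearman"), 0.9)
})

test_that("per-call fast scoring is much cheaper than the masked correlation", {
  m <- ideal_helix(100)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 5)
  field <- build_spline_field(map)
  fast_density_score(m, field)  # warm up
  t_fast <- system.time(for (i in 1:30) fast_density_score(m, field))[3]
  t_mask <- system.time(for (i in 1:30) masked_residue_cc(m, map))[3]
  expect_gt(t_mask / t_fast, 5)
})

test_that("out-of-field atoms are clamped and counted rather than crashing", {
  m <- ideal_helix(8)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 5)
  field <- build_spline_field(map)
  m2 <- m; m2$coords <- m2$coords + 100
  m2 <- sync_torsions(m2)
  r <- fast_density_score(m2, field)
  expect_gt(r$n_clamped, 0)
  expect_true(is.finite(r$score))
})
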