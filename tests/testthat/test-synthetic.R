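test_that("topology strings build the requested secondary structure deterministically", {
  h <- make_topology("H12", seed = 3)
  expect_equal(n_res(h), 12)
  expect_gte(hbond_bb_energy(h)$n_wells, 7)

  h2 <- make_topology("H12", seed = 3)
  expect_identical(h$coords, h2$coords)
  expect_identical(h$seq, h2$seq)

  l <- make_topology("L3", seed = 4)
  expect_equal(n_res(l), 3)
  expect_equal(vdw_energy(l)$energy, 0)

  mixed <- make_topology("H8-L4-E6", seed = 5)
  expect_equal(n_res(mixed), 18)
  expect_equal(vdw_energy(mixed)$energy, 0)
  expect_error(make_topology("H8-Q4"), "bad topology")
})

test_that("a null perturbation returns the truth with an identity alignment", {
  truth <- make_topology("H10-L4-E6", seed = 6)
  tp <- make_template(truth, list())
  expect_equal(tp$template$coords, truth$coords)
  expect_equal(nrow(tp$alignment$gap_segments), 0)
  expect_equal(tp$alignment$aligned_pairs[, 1],
               tp$alignment$aligned_pairs[, 2])
})

test_that("segment deletion produces exactly one gap of the stated length", {
  truth <- make_topology("H10-L6-H10", seed = 7)
  tp <- make_template(truth, list(delete_segment = c(11, 16)))
  gs <- tp$alignment$gap_segments
  expect_equal(nrow(gs), 1)
  expect_equal(unlist(gs[1, ]), c(start = 11, end = 16, length = 6))
  expect_equal(n_res(tp$template), 20)
})

test_that("a rigid loop shift displaces the loop but not the core", {
  truth <- make_topology("H10-L8-H10", seed = 8)
  tp <- make_template(truth, list(loop_shift = list(segment = c(11, 18),
                                                    dist = 4)))
  thr <- thread_template(tp$template, tp$alignment)
  loop_rmsd <- sqrt(mean(rowSums((thr$coords[11:18, 2, ] -
                                    truth$coords[11:18, 2, ])^2)))
  core <- c(1:10, 19:28)
  core_rmsd <- sqrt(mean(rowSums((thr$coords[core, 2, ] -
                                    truth$coords[core, 2, ])^2)))
  expect_gte(loop_rmsd, 3.5)
  expect_lt(core_rmsd, 0.1)
})

test_that("register shifts slide the alignment and open an in-strand gap", {
  truth <- random_chain(26, seed = 9)
  tp <- make_template(truth, list(register_shift = list(segment = c(19, 26),
                                                        k = 2)))
  gs <- tp$alignment$gap_segments
  expect_equal(unlist(gs[1, ]), c(start = 19, end = 20, length = 2))
  thr <- thread_template(tp$template, tp$alignment)
  # downstream residues carry the coordinates of their k-shifted ancestors
  expect_equal(thr$coords[21, 2, ], truth$coords[19, 2, ])
  expect_error(make_template(truth, list(register_shift =
                                           list(segment = c(25, 26), k = 3))),
               "larger than the chain")
})

test_that("noisy map generation hits a requested truth correlation", {
  truth <- make_topology("H10-L4-E8", seed = 10)
  tp <- make_template(truth, list(delete_segment = c(11, 14)))
  clean <- make_noisy_map(truth, tp$template, bias_fraction = 0,
                          noise_sd = 0)
  expect_equal(model_map_cc(truth, clean), 1, tolerance = 1e-6)

  allbias <- make_noisy_map(truth, thread_template(tp$template, tp$alignment),
                            bias_fraction = 1, noise_sd = 0)
  expect_lt(model_map_cc(truth, allbias), 1)

  set.seed(2)
  m30 <- make_noisy_map(truth, tp$template, bias_fraction = 0.3,
                        target_cc = 0.30)
  got <- model_map_cc(truth, m30)
  expect_gte(got, 0.28); expect_lte(got, 0.32)

  expect_error(make_noisy_map(truth, tp$template, bias_fraction = 0.3,
                              target_cc = 0.999),
               "unreachable")
})

test_that("the packaged benchmark is valid, solvable and byte-reproducible", {
  dir <- benchmark_dir()
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  expect_length(manifest, 3)
  for (nm in c("gap", "register", "loop")) {
    cs <- load_case(nm)
    expect_gt(n_res(cs$truth), 55)
    expect_s3_class(cs$map, "density_map")
    expect_equal(cs$lib3$length, 3)
    expect_equal(cs$lib9$length, 9)
    # every gap window has a near-native fragment in the library
    seg <- CASE_GAPS[[nm]]
    L <- if (seg[2] - seg[1] + 1 <= 4) 3 else 9
    lib <- if (L == 3) cs$lib3 else cs$lib9
    nat <- Filter(function(f) f$source_id == "native" &&
                    f$window <= seg[1] && f$window + L - 1 >= seg[1],
                  lib$fragments)
    expect_gt(length(nat), 0)
    devs <- vapply(nat, function(f) {
      d <- abs(f$torsions - cs$truth$torsions[f$window:(f$window + L - 1), ]) %% 360
      mean(pmin(d, 360 - d), na.rm = TRUE)
    }, numeric(1))
    expect_true(any(devs <= 10))
  }
  # byte-identical regeneration under the same seed
  dir2 <- file.path(tempdir(), "denseloop-bench-regen")
  unlink(dir2, recursive = TRUE)
  make_benchmark(dir2, seed = 0)
  for (f in c("case_gap/truth.pdb", "case_gap/map.mrc",
              "case_register/frags_9.lib", "manifest.json")) {
    expect_identical(readBin(file.path(dir, f), "raw", 4e6),
                     readBin(file.path(dir2, f), "raw", 4e6))
  }
  unlink(dir2, recursive = TRUE)
})

test_that("each benchmark case is solvable with oracle information", {
  # with the native torsions and a noise-free map, the rebuilt model must
  # essentially coincide with the truth density
  cs <- load_case("gap")
  seg <- CASE_GAPS$gap
  clean <- simulate_map(cs$truth, spacing = 1, resolution = 3, padding = 5)
  field <- build_spline_field(clean)
  thr <- thread_template(cs$template, cs$alignment)
  thr$torsions[seg[1]:seg[2], ] <- cs$truth$torsions[seg[1]:seg[2], ]
  m <- rebuild_from_torsions(thr, anchor = seg[1] - 1, "N2C",
                             upto = seg[2] + 1)
  m <- heal_insertion(m, seg, field = field, max_evals = 500)
  expect_gt(model_map_cc(m, clean), 0.95)
})
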