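test_that("identity threading reproduces the template", {
  m <- random_chain(15, seed = 31)
  sq <- paste(m$seq, collapse = "")
  aln <- alignment_spec(sq, sq, cbind(1:15, 1:15))
  thr <- thread_template(m, aln)
  expect_equal(thr$coords, m$coords)
  expect_true(all(thr$tag == "aligned"))
  expect_equal(nrow(attr(thr, "gap_segments")), 0)
})

test_that("threading records deletions as coordinate-free gap segments", {
  m <- random_chain(20, seed = 32)
  sq <- paste(m$seq, collapse = "")
  keep <- setdiff(1:20, 10:14)
  aln <- alignment_spec(paste(m$seq[keep], collapse = ""), sq,
                        cbind(seq_along(keep), keep))
  tpl <- backbone_model(m$coords[keep, , , drop = FALSE], m$seq[keep])
  thr <- thread_template(tpl, aln)
  expect_equal(n_res(thr), 20)
  expect_false(any(has_coords(thr)[10:14]))
  gs <- attr(thr, "gap_segments")
  expect_equal(unlist(gs[1, ]), c(start = 10, end = 14, length = 5))
  expect_true(all(thr$tag[10:14] == "rebuilt"))
  # mutated identities come from the target
  expect_equal(thr$seq, m$seq)
})

test_that("threading rejects alignments that reference nonexistent residues", {
  m <- random_chain(8, seed = 33)
  aln <- alignment_spec(paste(rep("A", 12), collapse = ""),
                        paste(rep("A", 12), collapse = ""),
                        cbind(1:12, 1:12))
  expect_error(thread_template(m, aln), "beyond the model")
})

test_that("the Metropolis criterion accepts downhill always and uphill at the Boltzmann rate", {
  expect_true(metropolis_accept(-5, 2))
  expect_true(metropolis_accept(0, 2))
  set.seed(55)
  dE <- 1.5; Temp <- 2
  acc <- mean(replicate(4000, metropolis_accept(dE, Temp)))
  p <- exp(-dE / Temp)
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(acc - p), 3 * se)
})

test_that("trajectories are deterministic given the seed and differ across seeds", {
  cs <- load_case("gap")
  field <- cached("field_gap", build_spline_field(cs$map))
  thr <- thread_template(cs$template, cs$alignment)
  cfg <- rebuild_config(protocol = "2011", n_cycles = 6, final_evals = 100,
                        rng_seed = 4)
  r1 <- run_rebuild(thr, NULL, list(cs$lib3, cs$lib9), cs$map, cfg,
                    field = field)
  r2 <- run_rebuild(thr, NULL, list(cs$lib3, cs$lib9), cs$map, cfg,
                    field = field)
  expect_identical(r1$final$coords, r2$final$coords)
  expect_identical(r1$records, r2$records)
  cfg$rng_seed <- 5
  r3 <- run_rebuild(thr, NULL, list(cs$lib3, cs$lib9), cs$map, cfg,
                    field = field)
  expect_false(identical(r1$final$coords, r3$final$coords))
  expect_equal(r1$acceptance_rate,
               r1$n_accepted / r1$n_proposals)
})

test_that("protocol 2011 leaves aligned residues outside the flanks bitwise frozen", {
  cs <- load_case("gap")
  field <- cached("field_gap", build_spline_field(cs$map))
  thr <- thread_template(cs$template, cs$alignment)
  cfg <- rebuild_config(protocol = "2011", n_cycles = 10, final_evals = 200,
                        rng_seed = 2)
  r <- run_rebuild(thr, NULL, list(cs$lib3, cs$lib9), cs$map, cfg,
                   field = field)
  frozen <- which(r$final$tag == "aligned")
  expect_gt(length(frozen), 30)
  expect_identical(r$final$coords[frozen, , ], thr$coords[frozen, , ])
})

test_that("protocol 2013 moves aligned template residues", {
  cs <- load_case("loop")
  field <- cached("field_loop", build_spline_field(cs$map))
  thr <- thread_template(cs$template, cs$alignment)
  cfg <- rebuild_config(protocol = "2013", n_cycles = 4, heal_evals = 80,
                        final_evals = 300, rng_seed = 2)
  r <- run_rebuild(thr, NULL, list(cs$lib3, cs$lib9), cs$map, cfg,
                   field = field)
  aligned <- which(thr$tag == "aligned")
  moved <- sqrt(rowSums((r$final$coords[aligned, 2, ] -
                           thr$coords[aligned, 2, ])^2))
  expect_gt(max(moved), 0.5)
})

test_that("segment rebuilds do not interact under protocol 2011", {
  # a chain with two separated gaps: rebuilding the second leaves the
  # first segment's rebuilt coordinates bitwise unchanged
  m <- random_chain(40, seed = 77)
  sq <- paste(m$seq, collapse = "")
  keep <- setdiff(1:40, c(10:13, 26:29))
  aln <- alignment_spec(paste(m$seq[keep], collapse = ""), sq,
                        cbind(seq_along(keep), keep))
  tpl <- backbone_model(m$coords[keep, , , drop = FALSE], m$seq[keep])
  thr <- thread_template(tpl, aln)
  map <- simulate_map(m, spacing = 1, resolution = 3, padding = 5)
  field <- build_spline_field(map)
  lib <- build_library(lapply(1:4, function(s) random_chain(16, seed = s)), 3)
  cfg <- rebuild_config(protocol = "2011", n_cycles = 6, rng_seed = 9)
  set.seed(9)
  rA <- rebuild_segment_2011(thr, c(10, 13), lib, field, cfg)
  rB <- rebuild_segment_2011(rA$model, c(26, 29), lib, field, cfg)
  spanA <- 6:17  # segment A plus its widest flanks
  expect_identical(rB$model$coords[spanA, , ], rA$model$coords[spanA, , ])
})

test_that("a gap-free threading degenerates to a single final minimization", {
  cs <- load_case("gap")
  field <- cached("field_gap", build_spline_field(cs$map))
  sq <- paste(cs$truth$seq, collapse = "")
  aln <- alignment_spec(sq, sq, cbind(1:n_res(cs$truth), 1:n_res(cs$truth)))
  cfg <- rebuild_config(protocol = "2013", n_cycles = 5, final_evals = 150,
                        rng_seed = 1)
  expect_message(r <- run_rebuild(cs$truth, aln, list(cs$lib3, cs$lib9),
                                  cs$map, cfg, field = field),
                 "final minimization only")
  expect_equal(r$n_proposals, 0)
})

test_that("rebuilding improves the fit of the packaged gap fixture", {
  cs <- load_case("gap")
  field <- cached("field_gap", build_spline_field(cs$map))
  thr <- thread_template(cs$template, cs$alignment)
  ref <- cached("refmap_gap",
                simulate_map(cs$truth, spacing = 1, resolution = 3,
                             padding = 5))
  improved <- 0
  for (seed in 1:3) {
    cfg <- rebuild_config(protocol = "2013", n_cycles = 15, heal_evals = 100,
                          final_evals = 400, rng_seed = seed)
    r <- run_rebuild(thr, NULL, list(cs$lib3, cs$lib9), cs$map, cfg,
                     field = field)
    cc_in <- model_map_cc(thr, ref)
    improved <- improved + (model_map_cc(r$final, ref) > cc_in)
  }
  expect_gte(improved, 2)
})
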