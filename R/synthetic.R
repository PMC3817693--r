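# Synthetic fixture generator: ground-truth structures, corrupted
# templates with alignments, and noisy model-biased maps with controllable
# truth correlation. All randomness flows through R's RNG so fixtures are
# fully seed-deterministic.

ELEMENT_TORSIONS <- list(
  H = c(-57, -47),
  E = c(-125, 130)
)

# coil/turn torsion pool (includes the classic beta-turn positions so that
# short strand-connecting loops can form hairpins)
COIL_POOL <- rbind(
  c(-70, 150), c(-105, 120), c(-80, -20), c(-140, 80), c(-60, 140),
  c(60, 30), c(90, 0),      # type I' turn
  c(60, -120), c(-80, 0)    # type II' turn
)

ELEMENT_SEQPOOL <- list(
  H = c("A", "L", "E", "K", "Q", "R", "M"),
  E = c("V", "I", "F", "Y", "T", "W"),
  L = c("G", "S", "N", "D", "T")
)

parse_topology_spec <- function(spec) {
  parts <- strsplit(spec, "-")[[1]]
  ok <- grepl("^[HEL][0-9]+$", parts)
  if (!all(ok)) stop("bad topology spec element(s): ",
                     paste(parts[!ok], collapse = ","))
  data.frame(type = substr(parts, 1, 1),
             len = as.integer(substring(parts, 2)))
}

#' Build a synthetic ground-truth structure from a topology string
#'
#' `spec` is a dash-separated string over H (helix), E (strand) and L
#' (loop) elements with lengths, e.g. `"H12-L6-E8-L4-E8"`. Helix and
#' strand residues get basin-typical torsions plus Gaussian noise
#' (`noise_sd`, degrees); loop residues draw from a coil/turn pool and are
#' resampled until the model is clash-free (soft-sphere vdW energy zero).
#'
#' @param spec topology string
#' @param seed optional seed (uses the current RNG state when NULL)
#' @param noise_sd torsion noise, degrees (default 3)
#' @param max_tries clash-free resampling budget (default 1000)
#' @return a [backbone_model()] with an `elements` attribute
#' @export
make_topology <- function(spec, seed = NULL, noise_sd = 3, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  el <- parse_topology_spec(spec)
  n <- sum(el$len)
  type <- rep(el$type, el$len)
  seqv <- unlist(lapply(seq_len(nrow(el)), function(k) {
    pool <- ELEMENT_SEQPOOL[[el$type[k]]]
    sample(pool, el$len[k], replace = TRUE)
  }))
  base_tor <- function() {
    tor <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      if (type[i] == "L") {
        tor[i, 1:2] <- COIL_POOL[sample.int(nrow(COIL_POOL), 1), ]
      } else {
        tor[i, 1:2] <- ELEMENT_TORSIONS[[type[i]]]
      }
      tor[i, 1:2] <- tor[i, 1:2] + stats::rnorm(2, 0, noise_sd)
      tor[i, 3] <- 180 + stats::rnorm(1, 0, 1)
    }
    tor
  }
  for (try in seq_len(max_tries)) {
    tor <- base_tor()
    m <- build_from_torsions(tor, seqv)
    if (vdw_energy(m)$energy == 0) {
      attr(m, "elements") <- el
      attr(m, "element_of") <- type
      return(m)
    }
  }
  stop("could not build a clash-free '", spec, "' in ", max_tries, " attempts")
}

#' Corrupt a ground truth into a template plus alignment
#'
#' Supported corruptions (applied together when several are given):
#' `delete_segment = c(start, end)` removes target residues from the
#' alignment (a gap segment to rebuild); `loop_shift = list(segment =
#' c(start, end), dist = <A>)` rigidly displaces the loop's atoms while
#' keeping it aligned; `register_shift = list(segment = c(start, end),
#' k = <int>)` slides the alignment by `k` residues from `segment[1]`
#' onward (an insertion inside the segment), the register-shift
#' misalignment scenario.
#'
#' @param truth a [backbone_model()]
#' @param perturbation list with any of `delete_segment`, `loop_shift`,
#'   `register_shift`
#' @return list with `template` ([backbone_model()]) and `alignment`
#'   ([alignment_spec()])
#' @export
make_template <- function(truth, perturbation = list()) {
  n <- n_res(truth)
  map <- seq_len(n)  # target position -> truth residue supplying coords
  rs <- perturbation$register_shift
  if (!is.null(rs)) {
    s <- rs$segment[1]; k <- rs$k
    if (s + k > n) stop("register shift larger than the chain supports")
    map[s:(s + k - 1)] <- NA
    idx <- (s + k):n
    map[idx] <- idx - k
  }
  ds <- perturbation$delete_segment
  if (!is.null(ds)) {
    if (ds[2] > n) stop("delete_segment outside the chain")
    map[ds[1]:ds[2]] <- NA
  }
  co <- truth$coords
  lsft <- perturbation$loop_shift
  if (!is.null(lsft)) {
    span <- lsft$segment[1]:lsft$segment[2]
    if (max(span) > n) stop("loop_shift outside the chain")
    ctr_all <- colMeans(co[, 2, ])
    ctr_loop <- colMeans(co[span, 2, , drop = FALSE])
    dirv <- ctr_loop - ctr_all
    if (vnorm(dirv) < 1e-6) dirv <- c(0, 0, 1)
    shift <- lsft$dist * vunit(dirv)
    for (i in span) for (a in 1:5) co[i, a, ] <- co[i, a, ] + shift
  }
  tres <- sort(unique(map[!is.na(map)]))
  tco <- co[tres, , , drop = FALSE]
  template <- backbone_model(tco, truth$seq[tres], resno = seq_along(tres))
  pairs <- cbind(match(map[!is.na(map)], tres), which(!is.na(map)))
  aln <- alignment_spec(paste(truth$seq[tres], collapse = ""),
                        paste(truth$seq, collapse = ""), pairs)
  list(template = template, alignment = aln)
}

#' Simulate a noisy, model-biased observed map
#'
#' `map = (1 - b) * density(truth) + b * density(template) + noise`, the
#' stand-in for a model-phased 2mFo-DFc map from a weak molecular-
#' replacement solution: `b` controls model bias toward the (wrong)
#' template and the additive Gaussian noise is low-pass filtered at the
#' map resolution (white voxel noise would be removed by the resolution
#' cutoff of the correlation). When `target_cc` is given, the noise level
#' is bisected until `model_map_cc(truth, map)` lands within 0.02 of it.
#'
#' @param truth ground-truth [backbone_model()]
#' @param template corrupted template model (used for the bias component)
#' @param resolution map resolution in Angstrom (default 3)
#' @param bias_fraction b in `[0, 1]` (default 0.3)
#' @param target_cc desired truth-map correlation, or NULL to use
#'   `noise_sd` directly
#' @param noise_sd noise level relative to the sd of the noise-free map
#' @param spacing grid step (default resolution / 3)
#' @param padding map padding in Angstrom
#' @return a [density_map()] with attributes `achieved_cc` and `noise_sd`
#' @export
make_noisy_map <- function(truth, template = NULL, resolution = 3,
                           bias_fraction = 0.3, target_cc = NULL,
                           noise_sd = 0.3, spacing = resolution / 3,
                           padding = 5) {
  b <- bias_fraction
  if (b < 0 || b > 1) stop("bias_fraction must be in [0, 1]")
  at <- atom_table(truth)$xyz
  if (!is.null(template)) at <- rbind(at, atom_table(template)$xyz)
  lo <- apply(at, 2, min) - padding
  hi <- apply(at, 2, max) + padding
  origin <- floor(lo / spacing) * spacing
  dims <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  grid <- list(origin = origin, dims = dims)
  tmap <- simulate_map(truth, spacing, resolution, grid = grid)
  base <- (1 - b) * tmap$values
  if (b > 0) {
    if (is.null(template)) stop("bias_fraction > 0 needs a template")
    base <- base + b * simulate_map(template, spacing, resolution,
                                    grid = grid)$values
  }
  raw <- array(stats::rnorm(prod(dims)), dims)
  sm <- lowpass_filter(raw, rep(spacing, 3), resolution)
  sm <- sm / stats::sd(as.numeric(sm))
  s0 <- stats::sd(as.numeric(base))
  mk <- function(sig) density_map(base + sig * s0 * sm, spacing, origin,
                                  resolution)
  ccof <- function(sig) model_map_cc(truth, mk(sig), resolution)
  if (is.null(target_cc)) {
    out <- mk(noise_sd)
    attr(out, "achieved_cc") <- ccof(noise_sd)
    attr(out, "noise_sd") <- noise_sd
    return(out)
  }
  cc0 <- ccof(0)
  if (target_cc > cc0 || target_cc <= 0)
    stop(sprintf("target_cc %.2f unreachable; achievable range is (0, %.3f]",
                 target_cc, cc0))
  lo_s <- 0; hi_s <- 1
  while (ccof(hi_s) > target_cc) {
    lo_s <- hi_s; hi_s <- hi_s * 2
    if (hi_s > 512) stop("noise bisection failed to bracket target_cc")
  }
  for (it in 1:60) {
    mid <- (lo_s + hi_s) / 2
    cm <- ccof(mid)
    if (abs(cm - target_cc) <= 0.015) { lo_s <- hi_s <- mid; break }
    if (cm > target_cc) lo_s <- mid else hi_s <- mid
  }
  sig <- (lo_s + hi_s) / 2
  out <- mk(sig)
  ach <- ccof(sig)
  if (abs(ach - target_cc) > 0.02)
    stop(sprintf("noise bisection missed target_cc %.2f (achieved %.3f)",
                 target_cc, ach))
  attr(out, "achieved_cc") <- ach
  attr(out, "noise_sd") <- sig
  out
}

# Re-place the chain from strand s2 onward so that s2 pairs antiparallel
# with s1 at sheet separation `sep`, then pull the connecting turn closed
# and relax. Torsion-only construction cannot make paired sheets (lever-arm
# effects); this geometric placement plus minimization can. Retries a few
# rotated sheet offsets until the result is pairing and essentially
# clash-free.
pair_strands <- function(model, s1, s2, sep = 4.8, tries = 8,
                         min_wells = 4, vdw_tol = 0.5) {
  n <- n_res(model)
  ls <- length(s1)
  ca1 <- model$coords[s1, 2, ]
  axis <- vunit(ca1[ls, ] - ca1[1, ])
  off0 <- colMeans(model$coords[s2, 2, , drop = FALSE]) - colMeans(ca1)
  off0 <- off0 - sum(off0 * axis) * axis
  if (vnorm(off0) < 1e-3) off0 <- vcross(axis, c(0, 0, 1))
  off0 <- vunit(off0)
  perp <- vcross(axis, off0)
  best <- NULL; best_score <- -Inf
  angles <- c(0, stats::runif(tries - 1, -180, 180))
  for (ang in angles) {
    th <- ang * pi / 180
    off <- cos(th) * off0 + sin(th) * perp
    tgt <- t(vapply(seq_len(ls), function(i) ca1[ls + 1 - i, ] + sep * off,
                    numeric(3)))
    fit <- kabsch_fit(model$coords[s2, 2, ], tgt)
    prop <- model
    for (i in s2[1]:n)
      for (a in 1:5)
        prop$coords[i, a, ] <- apply_fit(matrix(model$coords[i, a, ], 1, 3), fit)
    prop <- detect_breaks(sync_torsions(prop))
    w <- c(rama = 0.5, vdw = 1, hbond_bb = 2, cart_bonded = 1, density = 0)
    h <- heal_insertion(prop, c(s1[ls] + 1, s2[1] - 1), weights = w,
                        max_evals = 1500)
    h <- cartesian_minimize(h, weights = c(rama = 0.5, vdw = 4, hbond_bb = 2,
                                           cart_bonded = 2, density = 0),
                            movable = rep(TRUE, n), max_evals = 1500)$model
    pe <- hbond_bb_energy(h)$pair_energies
    wells <- sum(pe[s1, s2] < -0.1) + sum(pe[s2, s1] < -0.1)
    vd <- vdw_energy(h)$energy
    sc <- wells - 2 * max(0, vd - vdw_tol)
    if (wells >= min_wells && vd <= vdw_tol) {
      attr(h, "strand_wells") <- wells
      return(h)
    }
    if (sc > best_score) { best_score <- sc; best <- h; attr(best, "strand_wells") <- wells }
  }
  warning("pair_strands: pairing target not fully met (best wells ",
          attr(best, "strand_wells"), ")")
  best
}

circ_absdiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# mean absolute circular torsion deviation between a fragment and the
# native torsions of a window (NA positions skipped)
fragment_torsion_dev <- function(frag, native_tor) {
  d <- circ_absdiff(frag$torsions, native_tor)
  mean(d[is.finite(d)])
}

# near-native + decoy library for the gap windows of one case
case_library <- function(truth, segs, L, flank = 4, n_native = 3,
                         native_sd = 5, decoys) {
  n <- n_res(truth)
  frags <- list()
  for (k in seq_len(nrow(segs))) {
    s <- segs$start[k]; e <- segs$end[k]
    ws <- max(2, s - flank):min(n - L, e + flank - L + 1)
    ws <- ws[ws <= e & ws + L - 1 >= s & ws + L - 1 <= n - 1]
    for (w in ws) {
      span <- w:(w + L - 1)
      for (r in seq_len(n_native)) {
        tor <- truth$torsions[span, , drop = FALSE] +
          matrix(stats::rnorm(3 * L, 0, native_sd), L, 3)
        tor[] <- ((tor + 180) %% 360) - 180
        frags[[length(frags) + 1]] <-
          new_fragment(tor, truth$seq[span], "native", w)
      }
    }
  }
  nat <- length(frags)
  if (nat == 0) stop("no native windows for the case library")
  dl <- decoys$fragments
  nd <- min(length(dl), 10 * nat)
  frags <- c(frags, dl[seq_len(nd)])
  structure(list(length = L, fragments = frags,
                 metadata = sprintf("synthetic: %d native + %d decoys", nat, nd)),
            class = "fragment_library")
}

#' Generate the packaged synthetic benchmark
#'
#' Three cases standing in for the classic model-rebuilding failure modes:
#' (a) `gap` -- a clean 6-residue deletion to rebuild; (b) `register` -- a
#' 2-residue register-shift misalignment inside a beta-hairpin strand; (c)
#' `loop` -- an 8-residue loop rigidly displaced by 4 Angstrom (plus a
#' small 3-residue deletion to exercise rebuilding). Each case gets a
#' ground truth, corrupted template + alignment, a noisy model-biased map,
#' and fragment libraries (3-mers and 9-mers) containing near-native
#' fragments plus a tenfold excess of decoys from unrelated topologies.
#'
#' @param dir output directory (created); files are written per case
#' @param seed RNG seed (fixtures are byte-identical given the seed)
#' @param target_cc truth-vs-map correlation of the observed maps
#' @param resolution map resolution (default 3 A)
#' @param cases subset of `c("gap", "register", "loop")`
#' @return (invisibly) a list of per-case descriptors (paths and achieved
#'   map correlation)
#' @export
make_benchmark <- function(dir, seed = 0, target_cc = 0.6, resolution = 3,
                           cases = c("gap", "register", "loop")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    gap = list(topo = "H16-L6-H14-L4-E9-L4-E9-L2",
               pert = list(delete_segment = c(17, 22))),
    register = list(topo = "H20-L4-H12-L3-E8-L2-E8-L3",
                    strands = list(s1 = 40:47, s2 = 50:57),
                    pert = list(register_shift = list(segment = c(50, 57),
                                                      k = 2))),
    loop = list(topo = "H14-L3-E8-L8-E8-L3-H14-L2",
                strands = list(s1 = 18:25, s2 = 34:41),
                pert = list(loop_shift = list(segment = c(26, 33), dist = 4),
                            delete_segment = c(15, 17)))
  )
  out <- list()
  for (nm in cases) {
    sp <- specs[[nm]]
    truth <- NULL
    if (!is.null(sp$strands)) {
      # these cases need genuinely paired strands in the truth
      best <- NULL; best_wl <- -1
      for (try in 1:6) {
        cand <- suppressWarnings(pair_strands(make_topology(sp$topo),
                                              sp$strands$s1, sp$strands$s2))
        wl <- attr(cand, "strand_wells")
        if (is.null(wl)) wl <- 0
        if (wl > best_wl && vdw_energy(cand)$energy <= 2) {
          best <- cand; best_wl <- wl
        }
        if (is.null(best)) { best <- cand; best_wl <- wl }
        if (wl >= 4 && vdw_energy(cand)$energy <= 0.5) break
      }
      if (best_wl < 4)
        warning("case ", nm, ": hairpin folded with only ", best_wl,
                " inter-strand wells")
      truth <- best
    } else {
      truth <- make_topology(sp$topo)
    }
    tp <- make_template(truth, sp$pert)
    map <- make_noisy_map(truth, tp$template, resolution = resolution,
                          bias_fraction = 0.3, target_cc = target_cc)
    decoy1 <- make_topology("H10-L5-E6-L5-H10-L4-E6-L4-H8")
    decoy2 <- make_topology("E7-L4-H12-L3-E7-L5-H10-L3-E5")
    libs <- list()
    for (L in c(3, 9)) {
      dec <- build_library(list(decoy1, decoy2), L,
                           ids = c("decoy1", "decoy2"))
      libs[[as.character(L)]] <- case_library(truth, tp$alignment$gap_segments,
                                              L, decoys = dec)
      # the library must contain a usable near-native fragment per gap
      for (k in seq_len(nrow(tp$alignment$gap_segments))) {
        s <- tp$alignment$gap_segments$start[k]
        covers <- Filter(function(f) f$source_id == "native" &&
                           f$window <= s && f$window + L - 1 >= s,
                         libs[[as.character(L)]]$fragments)
        devs <- vapply(covers, function(f)
          fragment_torsion_dev(f, truth$torsions[f$window:(f$window + L - 1), ,
                                                 drop = FALSE]),
          numeric(1))
        if (!any(devs <= 10))
          stop("no near-native fragment within 10 degrees for case ", nm)
      }
    }
    cdir <- file.path(dir, paste0("case_", nm))
    dir.create(cdir, showWarnings = FALSE)
    write_pdb(truth, file.path(cdir, "truth.pdb"))
    write_pdb(tp$template, file.path(cdir, "template.pdb"))
    write_alignment(tp$alignment, file.path(cdir, "align.fasta"))
    write_map(map, file.path(cdir, "map.mrc"))
    write_fraglib(libs[["3"]], file.path(cdir, "frags_3.lib"))
    write_fraglib(libs[["9"]], file.path(cdir, "frags_9.lib"))
    out[[nm]] <- list(name = nm, dir = cdir, topo = sp$topo,
                      gap_segments = tp$alignment$gap_segments,
                      strands = sp$strands,
                      achieved_cc = attr(map, "achieved_cc"),
                      resolution = resolution)
  }
  manifest <- lapply(out, function(cs)
    list(name = cs$name, dir = basename(cs$dir), topology = cs$topo,
         input_cc = round(cs$achieved_cc, 4), resolution = cs$resolution,
         gaps = cs$gap_segments))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "manifest.json"))
  invisible(out)
}

# count hydrogen-bond wells between the two strand elements of a hairpin
# topology (elements attribute required)
hairpin_hbonds <- function(model) {
  el <- attr(model, "elements")
  type <- attr(model, "element_of")
  if (is.null(el) || sum(el$type == "E") < 2) return(0L)
  idx <- which(type == "E")
  # split strand residues into the two elements
  brk <- which(diff(idx) > 1)
  if (length(brk) == 0) return(0L)
  s1 <- idx[1:brk[1]]; s2 <- idx[(brk[1] + 1):length(idx)]
  pe <- hbond_bb_energy(model)$pair_energies
  sum(pe[s1, s2] < -0.2) + sum(pe[s2, s1] < -0.2)
}
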