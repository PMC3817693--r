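#' Rebuild configuration
#'
#' @param protocol `"2011"` (torsion insertion with cutpoint propagation
#'   and CCD chain closure; aligned residues frozen) or `"2013"`
#'   (superposition insertion with whole-structure Cartesian minimization;
#'   the template backbone may move).
#' @param n_cycles Monte Carlo cycles per gap segment (default 200)
#' @param temperature Metropolis temperature in energy units (default 2),
#'   geometrically cooled by `cooling` every `cooling_every` cycles
#' @param cooling,cooling_every cooling schedule (defaults 0.95 / 20)
#' @param flank movable residues immediately adjacent to each gap (2-5)
#' @param max_gap_len longest gap segment that is sampled (default 8)
#' @param fast_density score proposals with the fast spline field
#'   (default); otherwise with the masked per-residue correlation
#' @param rng_seed trajectory seed
#' @param n_picks fragments kept per window (default 25)
#' @param heal_evals minimization budget per 2013 insertion (default 400)
#' @param final_evals budget of the final whole-structure relax (2000)
#' @param mask_radius mask radius for the slow density score
#' @param cc_weight weight of the masked-correlation score when
#'   `fast_density = FALSE`
#' @param cutpoint cutpoint placement within segments: `"end"` (default:
#'   one-sided classic CCD onto the fixed downstream anchor, the most
#'   reliable closure), `"mid"` or `"start"`
#' @return a `rebuild_config` list
#' @export
rebuild_config <- function(protocol = c("2013", "2011"), n_cycles = 200,
                           temperature = 2.0, cooling = 0.95,
                           cooling_every = 20, flank = 3, max_gap_len = 8,
                           fast_density = TRUE, rng_seed = 1, n_picks = 25,
                           heal_evals = 400, final_evals = 2000,
                           mask_radius = 3.2, cc_weight = 30,
                           cutpoint = c("end", "mid", "start")) {
  protocol <- match.arg(as.character(protocol), c("2013", "2011"))
  cutpoint <- match.arg(cutpoint)
  if (flank < 2 || flank > 5) stop("flank must be in [2, 5]")
  if (max_gap_len < 1) stop("max_gap_len must be >= 1")
  structure(list(protocol = protocol, n_cycles = n_cycles,
                 temperature = temperature, cooling = cooling,
                 cooling_every = cooling_every, flank = flank,
                 max_gap_len = max_gap_len, fast_density = fast_density,
                 rng_seed = rng_seed, n_picks = n_picks,
                 heal_evals = heal_evals, final_evals = final_evals,
                 mask_radius = mask_radius, cc_weight = cc_weight,
                 cutpoint = cutpoint),
            class = "rebuild_config")
}

#' Metropolis acceptance
#'
#' Accept with probability `min(1, exp(-delta / temperature))`.
#'
#' @param delta energy change of the proposal
#' @param temperature Metropolis temperature (energy units)
#' @return logical
#' @export
metropolis_accept <- function(delta, temperature) {
  if (delta <= 0) return(TRUE)
  if (temperature <= 0) return(FALSE)
  stats::runif(1) < exp(-delta / temperature)
}

#' Thread a template onto a target sequence through an alignment
#'
#' All unaligned template residues are removed and aligned residues are
#' mutated to the target identities; the result is numbered in target
#' numbering with gap residues present but coordinate-free (tag
#' `"rebuilt"`, movable), ready for rebuilding.
#'
#' @param template a [backbone_model()]
#' @param alignment an [alignment_spec()]
#' @param target_seq optional target sequence (default: the alignment's)
#' @return a [backbone_model()] carrying a `gap_segments` attribute
#' @export
thread_template <- function(template, alignment, target_seq = NULL) {
  if (is.null(target_seq)) target_seq <- alignment$target_sequence
  tseq <- strsplit(target_seq, "")[[1]]
  n <- length(tseq)
  ap <- alignment$aligned_pairs
  if (nrow(ap) == 0) stop("empty alignment")
  if (max(ap[, 1]) > n_res(template))
    stop("alignment references template residues beyond the model")
  if (max(ap[, 2]) > n)
    stop("alignment references target residues beyond the sequence")
  co <- array(NA_real_, c(n, 5, 3))
  tag <- rep("rebuilt", n)
  for (k in seq_len(nrow(ap))) {
    co[ap[k, 2], , ] <- template$coords[ap[k, 1], , ]
    tag[ap[k, 2]] <- "aligned"
  }
  m <- backbone_model(co, tseq, resno = seq_len(n),
                      movable = tag != "aligned", tag = tag)
  attr(m, "gap_segments") <- alignment$gap_segments
  m
}

# write fragment torsions into the stored torsion table (NA entries of the
# fragment leave the model's values untouched)
insert_fragment_torsions <- function(model, frag, window) {
  L <- nrow(frag$torsions)
  for (p in seq_len(L)) {
    for (t in 1:3) {
      v <- frag$torsions[p, t]
      if (is.finite(v)) model$torsions[window + p - 1, t] <- v
    }
  }
  model
}

# movable span and anchors around a gap segment
segment_bounds <- function(model, segment, flank) {
  n <- n_res(model)
  s <- segment[1]; e <- segment[2]
  m_lo <- max(2, s - flank)
  m_hi <- min(n - 1, e + flank)
  if (m_lo > s || m_hi < e || m_lo - 1 < 1 || m_hi + 1 > n)
    stop(sprintf("segment %d-%d lacks anchors within the chain", s, e))
  list(s = s, e = e, m_lo = m_lo, m_hi = m_hi,
       cut_mid = (s + e) %/% 2)
}

segment_cutpoint <- function(b, config) {
  switch(config$cutpoint, mid = b$cut_mid, start = b$s, end = b$e)
}

# regenerate the movable span from stored torsions: left part from the
# left anchor toward the cutpoint, right part from the right anchor back
# to cutpoint+1 (leaving the junction open for closure)
propagate_to_cutpoint <- function(model, b, cut) {
  tor <- model$torsions
  model <- rebuild_from_torsions(model, anchor = b$m_lo - 1, "N2C", upto = cut,
                                 refresh_anchor_o = FALSE)
  model$torsions <- tor
  model <- rebuild_from_torsions(model, anchor = b$m_hi + 1, "C2N",
                                 upto = cut + 1, refresh_anchor_o = FALSE)
  model$torsions <- tor
  model
}

# give unbuilt gap residues starting coordinates (generic coil torsions),
# then close the junction geometrically
init_segment <- function(model, b, cut, config) {
  for (i in b$s:b$e) {
    if (!is.finite(model$torsions[i, 1])) model$torsions[i, 1] <- -70
    if (!is.finite(model$torsions[i, 2])) model$torsions[i, 2] <- 140
    if (!is.finite(model$torsions[i, 3])) model$torsions[i, 3] <- 180
  }
  hc <- has_coords(model)
  need <- any(!hc[b$s:b$e])
  tor_keep <- model$torsions
  model <- propagate_to_cutpoint(model, b, cut)
  model$torsions[b$s:b$e, ] <- tor_keep[b$s:b$e, ]
  cc <- ccd_close(model, c(b$m_lo, b$m_hi), cut)
  cc$model
}

# unified proposal scorer: combined low-resolution energy with either the
# fast spline density term or the masked per-residue correlation
score_model <- function(model, field, config, weights, params, map = NULL) {
  if (config$fast_density || is.null(map)) {
    total_energy(model, field, weights, params)$energy
  } else {
    w <- default_weights()
    w[names(weights)] <- weights
    wcc <- config$cc_weight
    w["density"] <- 0
    e <- total_energy(model, NULL, w, params)$energy
    e + wcc * masked_residue_cc(model, map, config$mask_radius)$total
  }
}

eligible_windows <- function(b, L) {
  w <- seq(b$m_lo, b$m_hi - L + 1)
  w[w <= b$e & (w + L - 1) >= b$s]
}

#' Rebuild one gap segment with the torsion-insertion + CCD protocol
#'
#' Monte Carlo over fragment insertions: fragment torsions are written into
#' a window overlapping the segment, the movable span is regenerated with
#' movement propagating toward the segment cutpoint, the chain is closed by
#' [ccd_close()], and the proposal is accepted or rejected by the
#' Metropolis criterion on the combined energy + density score. Aligned
#' residues outside the flanks never move.
#'
#' @param model threaded [backbone_model()]
#' @param segment (start, end) positions of the gap segment
#' @param frags a `fragment_library`
#' @param field spline score field of the observed map
#' @param config a [rebuild_config()]
#' @param weights,params objective weights and parameters
#' @param map observed [density_map()] (only needed when
#'   `fast_density = FALSE`)
#' @return list with `model` (best accepted), `records`, `n_accepted`,
#'   `n_proposals`, `unresolved`
#' @export
rebuild_segment_2011 <- function(model, segment, frags, field, config,
                                 weights = default_weights(),
                                 params = default_energy_params(),
                                 map = NULL) {
  b <- segment_bounds(model, segment, config$flank)
  cut <- segment_cutpoint(b, config)
  L <- frags$length
  wins <- eligible_windows(b, L)
  if (length(wins) == 0)
    stop("no fragment window of length ", L, " fits the movable span")
  model <- init_segment(model, b, cut, config)
  cur_e <- score_model(model, field, config, weights, params, map)
  best <- model; best_e <- cur_e
  picks <- lapply(wins, function(w)
    pick_fragments(model$seq[w:(w + L - 1)], frags, config$n_picks))
  rec <- vector("list", config$n_cycles)
  n_acc <- 0L; n_prop <- 0L; n_closed <- 0L
  for (cyc in seq_len(config$n_cycles)) {
    temp <- config$temperature *
      config$cooling^((cyc - 1) %/% config$cooling_every)
    wi <- if (length(wins) == 1) 1L else sample.int(length(wins), 1)
    pk <- picks[[wi]]
    fr <- pk[[if (length(pk) == 1) 1L else sample.int(length(pk), 1)]]
    prop <- insert_fragment_torsions(model, fr, wins[wi])
    tor_ins <- prop$torsions
    prop <- propagate_to_cutpoint(prop, b, cut)
    prop$torsions[b$m_lo:b$m_hi, ] <- tor_ins[b$m_lo:b$m_hi, ]
    cl <- ccd_close(prop, c(b$m_lo, b$m_hi), cut)
    # CCD can stall in a local minimum; retry from jittered torsions
    retry <- 0L
    while (!cl$closed && retry < 2L) {
      retry <- retry + 1L
      jit <- prop
      jit$torsions[b$m_lo:cut, 1:2] <- jit$torsions[b$m_lo:cut, 1:2] +
        matrix(stats::rnorm(2 * (cut - b$m_lo + 1), 0, 25),
               cut - b$m_lo + 1, 2)
      jit <- propagate_to_cutpoint(jit, b, cut)
      cl2 <- ccd_close(jit, c(b$m_lo, b$m_hi), cut)
      if (cl2$final_dev < cl$final_dev) cl <- cl2
    }
    n_prop <- n_prop + 1L
    accepted <- FALSE
    e <- NA_real_
    if (cl$closed) {
      n_closed <- n_closed + 1L
      e <- score_model(cl$model, field, config, weights, params, map)
      if (metropolis_accept(e - cur_e, temp)) {
        accepted <- TRUE
        model <- cl$model
        cur_e <- e
        if (e < best_e) { best <- model; best_e <- e }
      }
    }
    rec[[cyc]] <- data.frame(cycle = cyc, segment = b$s, window = wins[wi],
                             closed = cl$closed, accepted = accepted,
                             energy = e, temperature = temp)
    n_acc <- n_acc + accepted
  }
  list(model = best, records = do.call(rbind, rec), n_accepted = n_acc,
       n_proposals = n_prop, unresolved = n_closed == 0L)
}

#' Rebuild one gap segment with the superposition + minimization protocol
#'
#' Fragments are built in Cartesian space from their torsions, rigidly
#' superposed onto the current conformation over `flank` overlap residues
#' at each end of the window, spliced in, and the entire structure is
#' relaxed by [heal_insertion()] before the Metropolis test. All residues
#' may move.
#'
#' @inheritParams rebuild_segment_2011
#' @return list with `model`, `records`, `n_accepted`, `n_proposals`
#' @export
rebuild_segment_2013 <- function(model, segment, frags, field, config,
                                 weights = default_weights(),
                                 params = default_energy_params(),
                                 map = NULL) {
  b <- segment_bounds(model, segment, config$flank)
  cut <- segment_cutpoint(b, config)
  L <- frags$length
  wins <- eligible_windows(b, L)
  if (length(wins) == 0)
    stop("no fragment window of length ", L, " fits the movable span")
  ov <- min(config$flank, max(1L, (L - 1L) %/% 2L))
  if (any(!has_coords(model)[b$s:b$e])) {
    model <- init_segment(model, b, cut, config)
    model <- heal_insertion(model, c(b$m_lo, b$m_hi),
                            field = if (config$fast_density) field else NULL,
                            weights = weights, params = params,
                            max_evals = config$heal_evals)
  }
  cur_e <- score_model(model, field, config, weights, params, map)
  best <- model; best_e <- cur_e
  picks <- lapply(wins, function(w)
    pick_fragments(model$seq[w:(w + L - 1)], frags, config$n_picks))
  rec <- vector("list", config$n_cycles)
  n_acc <- 0L; n_prop <- 0L
  ovpos <- c(1:ov, (L - ov + 1):L)
  for (cyc in seq_len(config$n_cycles)) {
    temp <- config$temperature *
      config$cooling^((cyc - 1) %/% config$cooling_every)
    wi <- if (length(wins) == 1) 1L else sample.int(length(wins), 1)
    w <- wins[wi]
    pk <- picks[[wi]]
    fr <- pk[[if (length(pk) == 1) 1L else sample.int(length(pk), 1)]]
    span <- w:(w + L - 1)
    if (any(!has_coords(model)[span])) next
    fchain <- build_from_torsions(fr$torsions, fr$seq)
    moving <- NULL; fixed <- NULL
    for (p in ovpos) {
      moving <- rbind(moving, fchain$coords[p, 1:3, ])
      fixed <- rbind(fixed, model$coords[span[p], 1:3, ])
    }
    fit <- kabsch_fit(moving, fixed)
    prop <- model
    for (p in seq_len(L)) {
      xf <- apply_fit(fchain$coords[p, , ], fit)
      prop$coords[span[p], , ] <- xf
    }
    prop <- detect_breaks(sync_torsions(prop))
    prop <- heal_insertion(prop, c(w, w + L - 1),
                           field = if (config$fast_density) field else NULL,
                           weights = weights, params = params,
                           max_evals = config$heal_evals)
    n_prop <- n_prop + 1L
    e <- score_model(prop, field, config, weights, params, map)
    accepted <- metropolis_accept(e - cur_e, temp)
    if (accepted) {
      model <- prop
      cur_e <- e
      if (e < best_e) { best <- model; best_e <- e }
    }
    rec[[cyc]] <- data.frame(cycle = cyc, segment = b$s, window = w,
                             closed = TRUE, accepted = accepted,
                             energy = e, temperature = temp)
    n_acc <- n_acc + accepted
  }
  list(model = best, records = do.call(rbind, rec), n_accepted = n_acc,
       n_proposals = n_prop, unresolved = FALSE)
}

#' Run a full rebuild trajectory
#'
#' Threads the template (when an alignment is given), rebuilds every gap
#' segment of length `<= max_gap_len` independently in left-to-right
#' order with the configured protocol, and finishes with a whole-structure
#' Cartesian minimization (2013: all residues movable; 2011: only
#' rebuilt/flank residues, keeping the aligned template frozen).
#' Deterministic given `config$rng_seed`.
#'
#' @param model a threaded [backbone_model()], or a template to thread
#' @param alignment an [alignment_spec()] (NULL if `model` is already
#'   threaded)
#' @param library a `fragment_library` or list of libraries of different
#'   lengths (3-mers used for segments of up to 4 residues, else 9-mers)
#' @param map observed [density_map()]
#' @param config a [rebuild_config()]
#' @param weights,params objective weights and parameters
#' @param field optional prebuilt `spline_score_field` of `map` (rebuilt
#'   internally when NULL; pass one to amortize the FFT over many
#'   trajectories)
#' @return a `trajectory_result`: list with `final` model, `records`,
#'   `acceptance_rate`, `seed`, `skipped_segments`
#' @export
run_rebuild <- function(model, alignment = NULL, library, map,
                        config = rebuild_config(),
                        weights = default_weights(),
                        params = default_energy_params(), field = NULL) {
  set.seed(config$rng_seed)
  if (!is.null(alignment)) model <- thread_template(model, alignment)
  segs <- attr(model, "gap_segments")
  if (is.null(segs)) segs <- data.frame(start = integer(0), end = integer(0),
                                        length = integer(0))
  if (is.null(field)) field <- build_spline_field(map)
  libs <- if (inherits(library, "fragment_library")) list(library) else library
  lens <- vapply(libs, function(l) l$length, numeric(1))
  pick_lib <- function(seg_len, span_len) {
    want <- if (seg_len <= 4 && any(lens == 3)) 3 else max(lens[lens <= span_len])
    libs[[which(lens == want)[1]]]
  }
  n <- n_res(model)
  records <- list()
  n_acc <- 0L; n_prop <- 0L
  skipped <- integer(0)
  seg_fun <- if (config$protocol == "2011") rebuild_segment_2011 else rebuild_segment_2013
  if (nrow(segs) == 0) message("no gap segments: running final minimization only")
  for (k in seq_len(nrow(segs))) {
    s <- segs$start[k]; e <- segs$end[k]
    if (segs$length[k] > config$max_gap_len ||
        s - config$flank < 2 || e + config$flank > n - 1) {
      warning(sprintf("segment %d-%d left unbuilt (too long or unanchored)", s, e))
      skipped <- c(skipped, k)
      next
    }
    model$tag[s:e] <- "rebuilt"
    fl <- setdiff(max(2, s - config$flank):min(n - 1, e + config$flank), s:e)
    model$tag[fl][model$tag[fl] == "aligned"] <- "gap-flank"
    model$movable[c(s:e, fl)] <- TRUE
    lib <- pick_lib(segs$length[k], (e + config$flank) - (s - config$flank) + 1)
    r <- seg_fun(model, c(s, e), lib, field, config, weights, params, map)
    model <- r$model
    records[[length(records) + 1]] <- r$records
    n_acc <- n_acc + r$n_accepted
    n_prop <- n_prop + r$n_proposals
  }
  movable_final <- if (config$protocol == "2011") {
    model$tag != "aligned" & has_coords(model)
  } else rep(TRUE, n)
  if (any(movable_final)) {
    fin <- cartesian_minimize(model, field = field, weights = weights,
                              params = params, movable = movable_final,
                              max_evals = config$final_evals)
    model <- fin$model
  }
  structure(list(final = model,
                 records = if (length(records)) do.call(rbind, records) else NULL,
                 acceptance_rate = if (n_prop > 0) n_acc / n_prop else NA_real_,
                 n_accepted = n_acc, n_proposals = n_prop,
                 seed = config$rng_seed, skipped_segments = skipped,
                 protocol = config$protocol),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory_result (protocol %s, seed %d): %d/%d proposals accepted (%.2f)\n",
              x$protocol, x$seed, x$n_accepted, x$n_proposals,
              ifelse(is.na(x$acceptance_rate), NaN, x$acceptance_rate)))
  print(x$final)
  invisible(x)
}
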