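#' Gaussian atom kernels for density calculation
#'
#' Each atom contributes a single isotropic Gaussian with width
#' `sigma = resolution / (pi * sqrt(2))` (the standard low-resolution
#' approximation: the Fourier transform falls to ~exp(-2) at the resolution
#' limit) and an amplitude proportional to its electron count (C 6, N 7,
#' O 8, CB centroid 6).
#'
#' @param resolution map resolution in Angstrom
#' @return list with `sigma` and the named amplitude vector over atom slots
#' @export
atom_kernels <- function(resolution) {
  list(sigma = resolution / (pi * sqrt(2)), amps = ATOM_AMPS,
       resolution = resolution)
}

#' Simulate a density map from a model
#'
#' Sums per-atom Gaussian kernels on an orthogonal grid enclosing the model
#' plus `padding` on every side. Deterministic.
#'
#' @param model a [backbone_model()]
#' @param spacing grid step in Angstrom; must satisfy
#'   `spacing <= resolution / 3`
#' @param resolution nominal resolution (sets the kernel width)
#' @param padding Angstrom of empty border (default 5; keep `>= 4 * sigma`
#'   so that FFT wrap in downstream convolutions stays negligible)
#' @param grid optional list(origin, dims) to force an existing geometry
#' @return a [density_map()]
#' @export
simulate_map <- function(model, spacing = resolution / 3, resolution = 3,
                         padding = 5, grid = NULL) {
  at <- atom_table(model)
  if (nrow(at$xyz) == 0) stop("model has no coordinates")
  if (spacing > resolution / 3 + 1e-9)
    stop(sprintf("spacing %.3f A too coarse: Nyquist-safe bound is resolution/3 = %.3f A",
                 spacing, resolution / 3))
  kern <- atom_kernels(resolution)
  if (is.null(grid)) {
    lo <- apply(at$xyz, 2, min) - padding
    hi <- apply(at$xyz, 2, max) + padding
    origin <- floor(lo / spacing) * spacing
    dims <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  } else {
    origin <- grid$origin
    dims <- grid$dims
  }
  vals <- cpp_simulate_map(at$xyz, at$amp, origin, rep(spacing, 3), dims,
                           kern$sigma)
  density_map(vals, spacing, origin, resolution)
}

#' Masked per-residue real-space correlation
#'
#' For each residue, the Pearson correlation of model-simulated density
#' against the observed map over all voxels within `mask_radius` of any
#' atom of that residue. The mask is recomputed from the current
#' coordinates on every call. The total score is the negative mean over
#' residues with a defined correlation (lower is better, matching the
#' energy convention).
#'
#' @param model a [backbone_model()]
#' @param map a [density_map()] (the observed density)
#' @param mask_radius mask radius in Angstrom (default 3.2)
#' @return list with `cc` (per-residue, NA where the mask is empty),
#'   `nvox`, `missing` (residue positions with no usable mask) and `total`
#' @export
masked_residue_cc <- function(model, map, mask_radius = 3.2) {
  at <- atom_table(model)
  calc <- simulate_map(model, spacing = map$spacing[1],
                       resolution = map$resolution,
                       grid = list(origin = map$origin, dims = dim(map$values)))
  res <- cpp_masked_cc(at$xyz, at$res, n_res(model), map$values, calc$values,
                       map$origin, map$spacing, dim(map$values), mask_radius)
  cc <- res$cc
  miss <- which(is.na(cc) & seq_len(n_res(model)) %in% at$res)
  list(cc = cc, nvox = res$nvox, missing = miss,
       total = -mean(cc, na.rm = TRUE))
}

#' Precompute the FFT-convolved density score field
#'
#' Computes, for every atom type, the cross-correlation of the atom's
#' Gaussian kernel with the observed map via forward/inverse FFT at the
#' map's own grid sampling. Because all atom types share the kernel width
#' and differ only in amplitude, one base convolution is stored and scaled
#' per type at evaluation time. Values and analytic gradients at arbitrary
#' points come from separable tricubic interpolation on prefiltered cubic
#' B-spline coefficients (exact at grid nodes via the prefilter, C2
#' everywhere, so analytic gradients agree with finite differences).
#'
#' @param map a [density_map()]
#' @param kernels from [atom_kernels()]; defaults to the map's resolution
#' @param standardize center/scale the observed map to zero mean and unit
#'   sd before convolution so that the density weight is comparable across
#'   maps (global normalization folded into the weight); default TRUE
#' @param oversample dense-grid sampling factor for the convolution: the
#'   field is computed on a grid `oversample` times finer than the map so
#'   that the cubic interpolation error stays below 1e-3 of the field
#'   maximum (default 3)
#' @return an object of class `spline_score_field`
#' @export
build_spline_field <- function(map, kernels = atom_kernels(map$resolution),
                               standardize = TRUE, oversample = 3) {
  vals <- map$values
  if (standardize) {
    s <- stats::sd(as.numeric(vals))
    if (s < 1e-30) stop("map has zero variance")
    vals <- (vals - mean(vals)) / s
  }
  d <- dim(vals)
  os <- as.integer(oversample)
  sp <- map$spacing
  spf <- sp / os
  fd <- d * os
  sigma <- kernels$sigma
  # map voxels become delta weights on the fine grid, so the FFT product
  # is exactly the discrete cross-correlation sum_v k(x - v) m(v)
  fine <- array(0, fd)
  fine[seq(1, fd[1], os), seq(1, fd[2], os), seq(1, fd[3], os)] <- vals
  ax <- function(n, h) {
    i <- 0:(n - 1)
    pmin(i, n - i) * h
  }
  gx <- ax(fd[1], spf[1]); gy <- ax(fd[2], spf[2]); gz <- ax(fd[3], spf[3])
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  kern <- exp(-r2 / (2 * sigma^2)) * (2 * pi * sigma^2)^(-1.5)
  field <- Re(fft(fft(fine) * fft(kern), inverse = TRUE)) / length(fine)
  field <- cpp_bspline_prefilter(field)
  structure(list(base = field, origin = map$origin, spacing = spf,
                 amps = kernels$amps, sigma = sigma,
                 resolution = kernels$resolution,
                 n_clamped = 0L),
            class = "spline_score_field")
}

#' @export
print.spline_score_field <- function(x, ...) {
  d <- dim(x$base)
  cat(sprintf("spline_score_field: %d x %d x %d nodes, sigma %.3f A, types %s\n",
              d[1], d[2], d[3], x$sigma, paste(names(x$amps), collapse = "/")))
  invisible(x)
}

#' Evaluate the spline field for one atom type at arbitrary points
#'
#' @param field a `spline_score_field`
#' @param pts m x 3 matrix of Cartesian points
#' @param type atom slot name (`"N"`, `"CA"`, `"C"`, `"O"`, `"CB"`)
#' @return list with `value`, `grad` (m x 3, field units per Angstrom) and
#'   `n_clamped`
#' @export
field_interp <- function(field, pts, type = "CA") {
  amp <- unname(field$amps[type])
  r <- cpp_tricubic(field$base, field$origin, field$spacing, pts)
  list(value = amp * r$value, grad = amp * r$grad, n_clamped = r$n_clamped)
}

#' Fast unmasked density score with analytic gradients
#'
#' `score = -sum_atoms amp(type) * interp(field, position)`: the negative
#' sum of per-atom kernel-map cross-correlations, i.e. an unnormalized,
#' unmasked correlation (lower is better). Gradients are analytic tricubic
#' derivatives, negated to point downhill in score. Atoms outside the
#' interpolable interior are clamped to the 2-voxel margin and counted.
#'
#' @param model a [backbone_model()]
#' @param field from [build_spline_field()]
#' @return list with `score`, `grad` (m x 3 over the atoms of
#'   [atom_table()]), `atoms` (the atom table) and `n_clamped`
#' @export
fast_density_score <- function(model, field) {
  at <- atom_table(model)
  if (nrow(at$xyz) == 0)
    return(list(score = 0, grad = matrix(0, 0, 3), atoms = at, n_clamped = 0L))
  r <- cpp_tricubic(field$base, field$origin, field$spacing, at$xyz)
  amp <- at$amp
  list(score = -sum(amp * r$value),
       grad = -amp * r$grad,
       atoms = at, n_clamped = r$n_clamped)
}
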