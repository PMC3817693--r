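#' Model-vs-map density correlation
#'
#' Simulates the model's density on the reference grid, low-pass filters
#' both maps by hard Fourier truncation at `1 / resolution_limit`, and
#' returns the global Pearson correlation.
#'
#' @param model a [backbone_model()]
#' @param reference_map a [density_map()]
#' @param resolution_limit high-resolution cutoff in Angstrom (default 3)
#' @return Pearson correlation in `[-1, 1]`
#' @export
model_map_cc <- function(model, reference_map, resolution_limit = 3) {
  calc <- simulate_map(model, spacing = reference_map$spacing[1],
                       resolution = reference_map$resolution,
                       grid = list(origin = reference_map$origin,
                                   dims = dim(reference_map$values)))
  a <- lowpass_filter(calc$values, reference_map$spacing, resolution_limit)
  b <- lowpass_filter(reference_map$values, reference_map$spacing,
                      resolution_limit)
  va <- stats::var(as.numeric(a)); vb <- stats::var(as.numeric(b))
  if (va < 1e-30 || vb < 1e-30)
    stop("zero-variance map after resolution filtering")
  stats::cor(as.numeric(a), as.numeric(b))
}

# hard Fourier truncation: zero all frequencies with |s| > 1/res (s in 1/A)
lowpass_filter <- function(values, spacing, resolution_limit) {
  d <- dim(values)
  fr <- function(n, h) {
    i <- 0:(n - 1)
    pmin(i, n - i) / (n * h)
  }
  s2 <- outer(outer(fr(d[1], spacing[1])^2, fr(d[2], spacing[2])^2, `+`),
              fr(d[3], spacing[3])^2, `+`)
  keep <- s2 <= (1 / resolution_limit)^2
  Re(fft(fft(values) * keep, inverse = TRUE)) / length(values)
}

#' Ensemble statistics: average, best and selected correlation
#'
#' Mirrors the standard evaluation of a model ensemble against a reference
#' density: the mean CC, the best sampled CC, and the best CC among the
#' `select_k` models ranked best by an independent selector score computed
#' without reference to the evaluation map (lower selector = better, as
#' for [fast_density_score()]).
#'
#' @param models list of [backbone_model()]
#' @param reference_map evaluation [density_map()]
#' @param select_k how many top-ranked models the selector may nominate
#'   (default 5)
#' @param selector_score function(model) -> numeric, lower is better
#' @param resolution_limit CC resolution cutoff (default 3)
#' @return list with `avg_cc`, `best_cc`, `sel_cc`, `cc` (per model) and
#'   `selector` (per model)
#' @export
ensemble_stats <- function(models, reference_map, select_k = 5,
                           selector_score, resolution_limit = 3) {
  if (select_k <= 0) stop("select_k must be positive")
  if (length(models) < select_k)
    stop("fewer models than select_k")
  cc <- vapply(models, model_map_cc, numeric(1),
               reference_map = reference_map,
               resolution_limit = resolution_limit)
  sel <- vapply(models, selector_score, numeric(1))
  top <- order(sel)[seq_len(select_k)]
  list(avg_cc = mean(cc), best_cc = max(cc), sel_cc = max(cc[top]),
       cc = cc, selector = sel)
}

#' Expected selected-model correlation as a function of sample count
#'
#' For each `N = 1..N_max`, the expected CC of the model selected (best
#' selector score) from the first `N` models, averaged over random
#' reorderings of the ensemble.
#'
#' @param models list of models in generation order
#' @param reference_map evaluation map
#' @param selector_score function(model) -> numeric, lower is better
#' @param N_max largest ensemble size to evaluate
#' @param n_perm permutations to average over (default 100)
#' @param resolution_limit CC resolution cutoff
#' @return data.frame with columns `N` and `expected_sel_cc`
#' @export
cc_vs_samples <- function(models, reference_map, selector_score,
                          N_max = length(models), n_perm = 100,
                          resolution_limit = 3) {
  stopifnot(length(models) >= N_max)
  cc <- vapply(models, model_map_cc, numeric(1),
               reference_map = reference_map,
               resolution_limit = resolution_limit)
  sel <- vapply(models, selector_score, numeric(1))
  m <- length(models)
  acc <- numeric(N_max)
  for (p in seq_len(n_perm)) {
    o <- sample.int(m)
    best_i <- o[1]
    for (N in seq_len(N_max)) {
      if (N > 1 && sel[o[N]] < sel[best_i]) best_i <- o[N]
      acc[N] <- acc[N] + cc[best_i]
    }
  }
  out <- acc / n_perm
  out[1] <- mean(cc)  # the N = 1 expectation is exactly the ensemble mean
  data.frame(N = seq_len(N_max), expected_sel_cc = out)
}
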