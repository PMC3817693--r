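# shared fixtures, all generated in code

ideal_helix <- function(n = 15, seq = rep("A", n)) {
  build_from_torsions(cbind(rep(-57, n), rep(-47, n), rep(180, n)), seq)
}

extended_chain <- function(n = 10, seq = rep("A", n)) {
  build_from_torsions(cbind(rep(-120, n), rep(120, n), rep(180, n)), seq)
}

random_chain <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build_from_torsions(cbind(stats::runif(n, -180, 180),
                            stats::runif(n, -180, 180),
                            180 + stats::rnorm(n, 0, 5)))
}

# a compact random-ish but clash-poor chain for energy tests
wobbly_helix <- function(n = 12, sd = 0.15, seed = 1) {
  set.seed(seed)
  m <- ideal_helix(n)
  m$coords <- m$coords + array(stats::rnorm(length(m$coords), 0, sd),
                               dim(m$coords))
  sync_torsions(m)
}

# numeric gradient of a term function(model) -> list(energy, grad)
fd_gradient_error <- function(fun, model, n_coords = 40, h = 1e-5, seed = 2) {
  r <- fun(model)
  set.seed(seed)
  samp <- sample(length(r$grad), n_coords)
  num <- vapply(samp, function(k) {
    mp <- model; mp$coords[k] <- mp$coords[k] + h
    mm <- model; mm$coords[k] <- mm$coords[k] - h
    (fun(mp)$energy - fun(mm)$energy) / (2 * h)
  }, numeric(1))
  ana <- r$grad[samp]
  scale <- max(abs(ana), abs(num), 1e-8)
  max(abs(num - ana)) / scale
}

# benchmark fixture shared across test files (generated once per run)
benchmark_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "denseloop-bench")
      if (!file.exists(file.path(dir, "manifest.json")))
        make_benchmark(dir, seed = 0)
    }
    dir
  }
})

load_case <- function(name) {
  d <- file.path(benchmark_dir(), paste0("case_", name))
  list(dir = d,
       truth = read_pdb(file.path(d, "truth.pdb")),
       template = read_pdb(file.path(d, "template.pdb")),
       alignment = read_alignment(file.path(d, "align.fasta")),
       map = read_map(file.path(d, "map.mrc")),
       lib3 = read_fraglib(file.path(d, "frags_3.lib")),
       lib9 = read_fraglib(file.path(d, "frags_9.lib")))
}

# cache heavyweight shared objects (spline fields, model ensembles)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

strand_wells <- function(model, s1, s2, thresh = -0.2) {
  pe <- hbond_bb_energy(model)$pair_energies
  sum(pe[s1, s2] < thresh) + sum(pe[s2, s1] < thresh)
}

CASE_STRANDS <- list(register = list(s1 = 40:47, s2 = 50:57),
                     loop = list(s1 = 18:25, s2 = 34:41))
CASE_GAPS <- list(gap = c(17, 22), register = c(50, 51), loop = c(15, 17))
CASE_LOOP_SHIFT <- c(26, 33)
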