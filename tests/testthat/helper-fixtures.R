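# Shared fixtures, all generated in code.

tiny_grid <- function() wavenumber_grid(1000, 1200, 10)

# a small clean population rendered without stochastic terms
clean_set <- function(n = 4, group = "control", effect = 0) {
  m <- default_band_model(group, effect)
  set_from_spectra(lapply(seq_len(n), function(i) {
    render_spectrum(m, wavenumber_grid(), no_noise(),
                    cell_id = sprintf("%s_%02d", group, i))
  }))
}

# a quick noisy population on the default grid
quick_population <- function(n = 10, group = "control", effect = 0.5,
                             seed = 1, mie = NULL) {
  synth_population(n, default_band_model(group, effect), wavenumber_grid(),
                   noise_model(), mie = mie, seed = seed)
}

# random spectrum set with iid gaussian traces (for distance oracles)
random_set <- function(n, npts = 50, seed = 1, group = "g") {
  with_seed_test(seed, {
    grid <- wavenumber_grid(1000, 1000 + 4 * (npts - 1), 4)
    ftir_set(grid, matrix(rnorm(n * npts), n, npts),
             cell_id = sprintf("%s_%02d", group, seq_len(n)), group = group)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force elementwise euclidean distance, the independent oracle
loop_distance <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}
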