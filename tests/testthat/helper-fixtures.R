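# Shared fixtures: small fields and maps built in code so tests stay fast
# while exercising the same code paths as the full-scale defaults.

# a reduced trial: 20 DH lines, 2 sites, 3-chromosome map carrying the
# default QTL architecture; renders in well under a second per site
tiny_config <- function(seed = 1L, n_lines = 20L, ...) {
  sim_config(seed = seed, n_lines = n_lines, include_parents = FALSE,
             n_chromosomes = 3L, chrom_names = c("4B", "4D", "6D"),
             ...)
}

# flat, noise-free, spike-everywhere variant: rendered canopy equals
# terrain + true height exactly
degenerate_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, noise_sd = 0, spike_fraction = 1, spike_sd = 0,
              terrain_amplitude = 0, ...)
}

# constant-value raster helper
flat_raster <- function(value, nr = 40, nc = 40, cellsize = 0.025) {
  elev_raster(matrix(value, nr, nc), xmin = 0, ymin = 0, cellsize = cellsize)
}

# tilted plane z = a + bx + cy evaluated at pixel centres
plane_raster <- function(a, b, cc, nr = 80, nc = 60, cellsize = 0.05) {
  r <- elev_raster(matrix(0, nr, nc), xmin = 0, ymin = 0, cellsize = cellsize)
  xs <- uavheight:::raster_x(r)
  ys <- uavheight:::raster_y(r)
  r$values <- outer(ys, xs, function(y, x) a + b * x + cc * y)
  r
}
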