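# shared builders for canonical test parameter sets

# symmetric soil-water kernel, tolerant light curve, mid-range degree-days
ref_kernel <- function(code = "ref") {
  species_params(code, c1 = 1, c2 = 4.64, cp = 0.05,
                 swc_min = 0, swc_max = 1, psi = 0.5,
                 gdd_min = 1000, gdd_max = 3000, shade_tolerance_class = 3)
}

ref_growth <- function(code = "ref", ...) {
  growth_params(code, g_growth = 170, d_max = 50, h_max = 3000,
                age_max = 300, shade_tolerance_class = 3,
                gdd_min = 1000, gdd_max = 3000, ...)
}

# randomized valid kernel parameters under a caller-controlled RNG state
random_kernel <- function(code = "rnd") {
  swc_min <- runif(1, 0, 0.3)
  swc_max <- runif(1, 0.7, 1)
  psi <- runif(1, swc_min + 0.1, swc_max - 0.1)
  gdd_min <- runif(1, 200, 1500)
  species_params(code,
                 c1 = runif(1, 0.8, 2.24), c2 = runif(1, 1, 5),
                 cp = runif(1, 0, 0.15),
                 swc_min = swc_min, swc_max = swc_max, psi = psi,
                 gdd_min = gdd_min, gdd_max = gdd_min + runif(1, 500, 2500),
                 shade_tolerance_class = sample(1:5, 1))
}

# tiny co-registered raster from a matrix
tiny_raster <- function(m, cellsize = 70) raster_surface(m, cellsize = cellsize)

# two-species successional pair: shade-intolerant fast-grower vs
# shade-tolerant slow-grower, both unconstrained by the benign site
succession_pair <- function() {
  list(fast = growth_params("fast", 300, 50, 2500, 80, 1, 500, 3000,
                            recruit_rate = 1),
       slow = growth_params("slow", 100, 60, 3000, 400, 5, 500, 3000,
                            recruit_rate = 1))
}
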