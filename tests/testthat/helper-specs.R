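# Random but physically valid model specs for property-style tests.
# Ranges bracket the reference parameter set by a couple of decades on
# each side; b/a is drawn in [20, 200] around the 100x convention.
# n sampling radii spanning [0, b], always containing 0, a and b
.acc_radii <- function(spec, n) {
  a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
  sort(unique(c(seq(0, a, length.out = ceiling(n / 2)),
                seq(a, b, length.out = floor(n / 2) + 1L))))
}

random_spec <- function() {
  a <- 10^stats::runif(1, -9.3, -7.7)              # 0.5 .. 20 nm
  model_spec(
    cnt = material(10^stats::runif(1, 2, 3.6),
                   density = stats::runif(1, 800, 2200),
                   specific_heat = stats::runif(1, 300, 1200)),
    tissue = material(10^stats::runif(1, -0.7, 0.3),
                      density = stats::runif(1, 900, 1100),
                      specific_heat = stats::runif(1, 3000, 4500)),
    laser = laser_source(intensity = 10^stats::runif(1, 8, 11),
                         absorption_coefficient = 10^stats::runif(1, 6, 8),
                         reflectivity = stats::runif(1, 0, 0.9)),
    geometry = geometry(a, far_radius = stats::runif(1, 20, 200) * a,
                        far_temperature = 310.15)
  )
}
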