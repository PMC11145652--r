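# fixtures shared across the suite; everything is generated in code

bbg1_mixture <- function() example_mixture("BBG1")
bbg2_mixture <- function() example_mixture("BBG2")

# small, fast simulation settings for unit tests (coarser grids than the
# full acquisition layout used in the acceptance suite)
quick_sim <- function(mixture = bbg1_mixture(), noise_sigma = 0.01,
                      seed = 1L, ...) {
  simulation_spec(mixture,
                  t_grid = seq(0, 14, by = 0.25),
                  noise_sigma = noise_sigma, seed = seed, ...)
}

quick_c_grid <- function() seq(0.5, 40, by = 0.5)

# simulate, normalize and reference-divide in one step
quick_divided <- function(spec = quick_sim(), constants = kernel_constants(),
                          c_grid = quick_c_grid()) {
  set <- simulate_traceset(spec, constants, c_grid = c_grid)
  set$main <- lapply(set$main, normalize_trace)
  set$reference <- normalize_trace(set$reference)
  reference_deconvolve(set)
}

# conformer with n_h hydrogens placed uniformly inside a ball of given
# radius (nm) around a central heavy atom (the label site)
ball_conformer <- function(n_h, radius = 2.5, center_element = "N",
                           seed = 1L) {
  xyz <- withr::with_seed(seed, {
    r <- radius * stats::runif(n_h)^(1 / 3)
    phi <- stats::runif(n_h, 0, 2 * pi)
    cth <- stats::runif(n_h, -1, 1)
    sth <- sqrt(1 - cth^2)
    cbind(r * sth * cos(phi), r * sth * sin(phi), r * cth)
  })
  conformer(c(center_element, rep("H", n_h)),
            rbind(c(0, 0, 0), xyz),
            label_sites = 1L)
}
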