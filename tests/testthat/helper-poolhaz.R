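# shared fixtures built in code

# a smooth, strictly positive synthetic population hazard with Q ~ 3e-3,
# loosely pancreatic-shaped, on the default grid
toy_population <- function(grid = age_grid(), stratum = "toy") {
  t <- grid$midpoints
  rate <- 9e-5 * exp(-((t - 78) / 18)^2) + 5e-7
  population_hazard(rate, se = 0.02 * rate, grid = grid,
                    stratum = stratum, per_100k = FALSE)
}

rel_dev <- function(x, ref) abs(x - ref) / abs(ref)
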