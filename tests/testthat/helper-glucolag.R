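# Shared fixtures, all built in code.

default_cfg <- function(...) model_config(...)

# unit-k capillary: P*A/F = 1
unit_k <- function(k = 1) capillary_params(permeability = k, area = 1, flow = 1)

# a random but valid Starling parameter draw
random_starling <- function() {
  P_v <- runif(1, 5, 20)
  P_a <- P_v + runif(1, 5, 40)
  starling_params(K_f = runif(1, 0.1, 5),
                  sigma_pi_c = runif(1, P_v, P_a),
                  P_a = P_a, P_v = P_v)
}

# random piecewise-linear boundary series on [0, span]
random_boundary <- function(span = 40, lo = 80, hi = 320) {
  tb <- sort(unique(c(0, sample(seq(2.5, span - 2.5, 2.5),
                                sample(4:8, 1)), span)))
  glucose_series(tb, runif(length(tb), lo, hi), label = "boundary")
}

random_tissue <- function() {
  tissue_params(D = runif(1, 200, 900), x = runif(1, 10, 35),
                C_isf0 = runif(1, 80, 150))
}

# fast config for randomized sweeps: shorter internal grid
sweep_config <- function(mode = "superposition") {
  model_config(
    capillary = capillary_params(permeability = runif(1, 1e-4, 1e-3),
                                 area = runif(1, 50, 200),
                                 flow = runif(1, 0.01, 0.06)),
    starling = random_starling(),
    tissue = random_tissue(),
    weights = model_weights(R_fick = runif(1)),
    mode = mode,
    dt = 0.2
  )
}

gtt_blood <- function(interval = 10, t_end = 100) {
  generate_blood_gtt(sample_interval = interval, t_end = t_end)
}
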