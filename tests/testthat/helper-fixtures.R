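# Shared fixtures: small configurations keep the default suite fast.

# compact 3-stage lifecycle (60 slots) with the default coupling structure
small_config <- function(seed = 1, ...) {
  sim_config(n_slots = 60L, stage_boundaries = c(20L, 40L), seed = seed, ...)
}

# one linear regime, very low noise
flat_config <- function(seed = 1, n = 60L, noise = 0.05) {
  sim_config(n_slots = n, stage_boundaries = integer(0),
             index_intercept = matrix(5 * 1:5, 1, 5),
             index_slope = matrix(0.05, 1, 5),
             index_curvature = matrix(0, 1, 5),
             index_noise_sd = noise, seed = seed)
}

# noise-free config with per-index curvature, so every index has a distinct
# within-stage shape and grey ranking has deterministic ground truth
curved_noiseless_config <- function(seed = 1) {
  sim_config(index_noise_sd = 0, env_noise_sd = 0,
             index_curvature = matrix(1e-4 * (1:15) / 8, 3, 5),
             seed = seed)
}

# hand-built T-S FNN with given parameter matrices (no input scaling)
manual_tsfnn <- function(centers, widths, consequents, k = 3L) {
  structure(list(centers = centers, widths = widths,
                 consequents = consequents, k = k,
                 trace = numeric(0), epochs_run = 0L,
                 shift = NULL, scale = NULL),
            class = "tsfnn")
}

# closed-form area of the union of two equal disks at centre distance d
two_disk_union <- function(r, d) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

random_membership <- function(k, n) {
  U <- matrix(stats::runif(k * n), k, n)
  sweep(U, 2, colSums(U), "/")
}
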