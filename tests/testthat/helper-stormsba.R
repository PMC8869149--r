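# shared test fixtures, all generated in code

# closed-form CDF of Uniform[-R, R] convolved with N(0, s); oracle for the
# sphere-surface projection (Archimedes hat-box)
unif_conv_cdf <- function(x, R, s) {
  iPhi <- function(u) u * pnorm(u) + dnorm(u)
  (s / (2 * R)) * (iPhi((x + R) / s) - iPhi((x - R) / s))
}

# noiseless profile synthesized from known parameters
make_model_profile <- function(shape = "sphere_surface", R = 100, sigma = 20,
                               A = 5000, b = 2, center = 13,
                               from = -300, to = 320, bw = 5) {
  mp <- model_profile(structural_model(shape, R), gaussian_kernel(sigma),
                      amplitude = A, background = b, center = center)
  stormsba:::profile_from_model(mp, from, to, bw)
}

# one simulated sphere replicate piped to its principal-axis profile
sim_sphere_profile <- function(seed, diameter = 100, n_fluor = 334L,
                               sigma_loc = 20, bin_width = 10) {
  spec <- emitter_spec("sphere_surface", diameter = diameter,
                       n_fluorophores = n_fluor)
  tab <- simulate_localizations(spec, sim_config(sigma_loc = sigma_loc,
                                                 seed = seed))
  cl <- find_clusters(tab)
  cl <- cl[[which.max(vapply(cl, `[[`, 0L, "n_localizations"))]]
  extract_profile(cl, tab, bin_width = bin_width)
}
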