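# Shared fixtures: small phantoms and noise-free stacks built in code.

tiny_phantom <- function(seed = 1, h = 64, w = 64, ...) {
  make_phantom(h, w, seed = seed, ...)
}

# An aligned stack of the clean image plus additive Gaussian noise only
# (speckle disabled): the analytic averaging oracle applies exactly.
additive_noise_stack <- function(truth, n, sigma, seed = 1) {
  truth$speckle_shape <- Inf
  truth$sensor_sigma <- sigma
  acquire_frames(truth, n, motion_scale = c(0, 0), p_fixation_loss = 0,
                 seed = seed)$stack
}
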