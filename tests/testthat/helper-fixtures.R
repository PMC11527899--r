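# Shared fixtures: small protocols and cached sessions so each expensive
# generation runs once per test session.

tiny_protocol <- function(spp = 2, interval = 38, blocks = 1, rest = 0) {
  protocol_spec(n_blocks = blocks,
                swallows_per_position_per_block = spp,
                inter_swallow_interval = interval,
                inter_block_rest = rest)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noise-free session with events spaced beyond the kernel support (and the
# 10 s pre-onset window), so every epoch is exactly amplitude x kernel
noisefree_session <- function() {
  cached("noisefree", simulate_session(
    protocol = tiny_protocol(spp = 2, interval = 80),
    noise = noise_off(), seed = 301
  ))
}

noisy_tiny_session <- function() {
  cached("noisy_tiny", simulate_session(
    protocol = tiny_protocol(spp = 2), seed = 302
  ))
}

null_hrf <- function(level = 0.9) {
  hrf_params(amplitude_by_position = c(down = level, neutral = level,
                                       up = level))
}
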