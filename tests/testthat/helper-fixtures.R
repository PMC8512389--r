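# Shared fixtures, built in code at test time.

# hidden-target toy landscape: fitness = fraction of bits matching `target`;
# exhaustive enumeration over all 2^N masks gives the true optimum
toy_target <- function(n, seed = 42) {
  # fixed irregular pattern, no RNG needed
  as.integer(rep_len(c(1, 0, 1, 1, 0, 0, 1, 0), n))
}

toy_fitness <- function(target) {
  force(target)
  function(mask) sum(mask == target) / length(target)
}

enumerate_optimum <- function(fn, n) {
  best <- -Inf; best_mask <- NULL
  for (code in seq_len(2^n) - 1L) {
    m <- as.integer(intToBits(code)[1:n])
    if (!any(m == 1L)) next
    v <- fn(m)
    if (v > best) { best <- v; best_mask <- m }
  }
  list(value = best, mask = best_mask)
}

small_planted <- function(seed = 1, n = 120, classes = 3, inf = 5, red = 2,
                          noise = 23, effect = 1.5) {
  sim_feature_table(planted_spec(n, classes, inf, red, noise,
                                 effect_size = effect, seed = seed))
}

demo_recording <- function(seed = 1, fs = 50, duration = 8) {
  classes <- data.frame(
    label = c("walk", "still"),
    f_lo = c(1.5, 0), f_hi = c(2.5, 0.01),
    amplitude = c(2, 0),
    ox = c(0, 0), oy = c(0, 0), oz = c(1, 1),
    noise_sd = c(0.3, 0.1))
  sim_recording(recording_spec(fs, duration, classes, seed = seed))
}
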