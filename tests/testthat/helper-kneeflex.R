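# shared fixtures and small oracles used across test files

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

perp_component <- function(o, j) o - j * sum(o * j)

rms <- function(x) sqrt(mean(x^2))

# short noise-free trial with impacts, shared by several files
short_trial <- local({
  cache <- new.env()
  function(seed = 3, duration_s = 10, noise = noise_free(impacts = TRUE)) {
    key <- paste(seed, duration_s, digest_noise(noise), sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_running_trial(duration_s = duration_s,
                                             noise = noise, seed = seed)
    cache[[key]]
  }
})

digest_noise <- function(np) paste(unlist(np), collapse = "|")

# fixed rotation helpers for hand-built mountings
rot_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(deg * pi / 180) * K + (1 - cos(deg * pi / 180)) * (K %*% K)
}

# a calibration object built directly from known axes/centres
truth_calibration <- function(j1, j2, o1, o2) {
  joint_calibration(list(phi1 = 0, theta1 = 0, phi2 = 0, theta2 = 0,
                         j1 = j1, j2 = j2, final_cost = 0),
                    list(o1 = o1, o2 = o2, final_cost = 0))
}
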