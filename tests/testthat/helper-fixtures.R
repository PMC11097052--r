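# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, make) {
  if (is.null(.fx[[key]])) .fx[[key]] <- make()
  .fx[[key]]
}

# 20 s rest, 30 s gait (2 Hz steps, 0.5 g swing), 10 s rest
fx_gait <- function() fx_cache("gait", function()
  generate_recording(sim_config(list(
    sim_segment("rest", 20),
    sim_segment("gait", 30, step_freq_hz = 2, swing_amp_g = 0.5),
    sim_segment("rest", 10)), seed = 1L)))

# rest-only, 30 s, upright, low noise
fx_rest <- function() fx_cache("rest", function()
  generate_recording(sim_config(list(sim_segment("rest", 30)), seed = 2L)))

# random rotation matrix (uniform via QR), deterministic per seed
fx_rotation <- function(seed = 11L) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_recording <- function(recording, rot) {
  new_recording(recording$acc %*% t(rot), recording$fs,
                recording$subject_id, recording$group, recording$meta)
}

# bare interval data.frame for attribute-free comparisons
gs_df <- function(g) data.frame(start_s = as.numeric(g$start_s),
                                end_s = as.numeric(g$end_s))
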