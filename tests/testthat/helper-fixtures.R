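# a reduced fixture spec for fast unit tests
small_spec <- function(...) {
  fixture_spec(n_participants = 6, total_rows = 360, ...)
}

small_gait_table <- function(seed = 42, ...) {
  simulate_gait_table(small_spec(...), seed = seed)
}

# a fully dense landmark frame table: every landmark at a fixed offset
# grid so kinematic identities are easy to reason about
dense_frames <- function(n_frames, fps = 30, ids = 0:32,
                         x0 = 0.5, y0 = 0.1) {
  do.call(rbind, lapply(seq_len(n_frames), function(i) {
    data.frame(frame = i, timestamp = (i - 1) / fps, landmark_id = ids,
               x = x0 + ids * 1e-3, y = y0 + ids * 2e-3, visibility = 1)
  }))
}

toy_profile <- function(id = "T01", height = 1.66, mass = 64, age = 80,
                        fall = 0) {
  participant_profile(id, height, mass, age, fall, warn = FALSE)
}
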