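test_that("segment CoM is the unweighted mean of its landmarks", {
  expect_equal(segment_com(rbind(c(0, 0), c(2, 0))), c(1, 0))
  expect_equal(segment_com(rbind(c(1, 1))), c(1, 1))
  expect_equal(segment_com(rbind(c(0, 0), c(1, 0), c(2, 3))), c(1, 1))
  expect_error(segment_com(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("body CoM is the weight-normalized mean of segment CoMs", {
  model <- anthropometric_model()
  at <- function(p) lapply(model$segments, function(s) p)
  expect_equal(body_com(at(c(0.3, 0.7)), model), c(0.3, 0.7))

  coms <- at(c(0, 0)); coms$head <- c(1, 0)
  expect_equal(body_com(coms, model)[1], 0.081 / 0.953, tolerance = 1e-10)

  two_seg <- list(segments = model$segments[c("head", "torso")],
                  weights = model$weights[c("head", "torso")])
  expect_equal(body_com(list(head = c(1, 0), torso = c(0, 0)), two_seg)[1],
               0.081 / 0.578, tolerance = 1e-10)
  expect_error(body_com(list(head = c(1, 0)), model), "missing segment")
})

test_that("CoM velocity is the fps-scaled backward difference", {
  com <- cbind(c(0, 0.01, 0.02), c(0, 0, 0))
  v <- com_velocity(com, 30)
  expect_equal(v[2, 1], 0.3)
  expect_equal(v[1, ], v[2, ])  # first frame copies the second
  expect_equal(com_velocity(cbind(rep(1, 5), rep(2, 5)), 30),
               matrix(0, 5, 2))
  # reversing the sequence negates each interior velocity
  vr <- com_velocity(com[3:1, ], 30)
  expect_equal(vr[3:2, ], -v[3:2, ])
  expect_error(com_velocity(com, 0), "positive")
})

test_that("XCoM offsets the CoM by v / omega0 and scales linearly in v", {
  com <- c(0.5, 0.9)
  expect_equal(extrapolated_com(com, c(0, 0), 1.0), com)
  # l = 0.981 m, g = 9.81 -> omega0 = sqrt(10); v_x = 0.31623 -> offset 0.1
  x1 <- extrapolated_com(c(0, 0), c(0.31623, 0), 0.981)
  expect_equal(x1[1], 0.31623 / sqrt(10), tolerance = 1e-10)
  x2 <- extrapolated_com(c(0, 0), c(0.63246, 0), 0.981)
  expect_equal(x2, 2 * x1)
  # offset is parallel to v with magnitude |v| / omega0
  v <- c(0.2, -0.1)
  off <- extrapolated_com(c(0, 0), v, 0.9, 9.81)
  expect_equal(off / sqrt(sum(off^2)), v / sqrt(sum(v^2)))
  expect_equal(sqrt(sum(off^2)), sqrt(sum(v^2)) / sqrt(9.81 / 0.9))
  expect_error(extrapolated_com(com, c(0, 0), 0), "positive")
})

test_that("boundary distance is the perpendicular point-line distance", {
  expect_equal(boundary_distance(c(0, 1), c(-1, 0), c(1, 0)), 1)
  expect_equal(boundary_distance(c(0.3, 0), c(-1, 0), c(1, 0)), 0)
  expect_equal(boundary_distance(c(4, -3), c(0, 0), c(3, 4)), 5)
  expect_error(boundary_distance(c(0, 1), c(1, 1), c(1, 1)), "degenerate")
})

test_that("boundary distance is invariant under rigid motions and scales with c", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(2); a <- runif(2); b <- runif(2) + 1
    d0 <- boundary_distance(p, a, b)
    shift <- runif(2, -5, 5)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tf <- function(q) as.vector(R %*% q + shift)
    expect_equal(boundary_distance(tf(p), tf(a), tf(b)), d0,
                 tolerance = 1e-10)
    expect_equal(boundary_distance(3 * p, 3 * a, 3 * b), 3 * d0,
                 tolerance = 1e-10)
  }
})

test_that("margin of stability is the minimum distance and vanishes on the line", {
  a <- c(-1, 0); b <- c(1, 0)
  expect_equal(margin_of_stability(c(0, 0.02), c(0, 0.05), a, b), 0.02)
  expect_equal(margin_of_stability(c(0.5, 0), c(0, 0.4), a, b), 0)
  set.seed(3)
  for (i in 1:20) {
    mos <- margin_of_stability(runif(2, -2, 2), runif(2, -2, 2),
                               runif(2), runif(2) + 1)
    expect_gte(mos, 0)
  }
})

test_that("step width is the symmetric ankle distance", {
  expect_equal(step_width(c(0.2, 0.5), c(0.2, 0.5)), 0)
  expect_equal(step_width(c(0.10, 0.50), c(0.35, 0.50)), 0.25)
  l <- c(0.1, 0.4); r <- c(0.3, 0.45)
  expect_equal(step_width(l, r), step_width(r, l))
  expect_error(step_width(c(NA, 1), c(0, 0)), "ankle")
})

test_that("gait tables have one row per frame with constant static attributes", {
  spec <- small_spec(noise_sd = 0, dropout = 0)
  prof <- toy_profile(age = 86, fall = 1)
  seq <- simulate_landmark_walk(prof, spec, seed = 1, duration = 100 / 30)
  gt <- compute_gait_table(preprocess_landmarks(seq), prof)
  expect_equal(nrow(gt), 100)
  expect_true(all(gt$Age == 1) && all(gt$Fall_History == 1))
  seq_cols <- c("X_Coordinate_CoM", "Y_Coordinate_CoM", "CoM_Velocity",
                "Step_Width", "MoS")
  expect_true(all(is.finite(as.matrix(gt[seq_cols]))))
  expect_true(all(gt$MoS >= 0) && all(gt$Step_Width >= 0))
})

test_that("a static pose yields zero velocity and XCoM equal to CoM", {
  frames <- dense_frames(40)
  prof <- toy_profile()
  seq <- landmark_sequence("S", 30, frames)
  gt <- compute_gait_table(seq, prof, kinematics_config(scale = 1))
  expect_equal(gt$CoM_Velocity, rep(0, 40))
  expect_equal(sd(gt$X_Coordinate_CoM), 0)
  expect_equal(sd(gt$MoS), 0)
})

test_that("step-width series oscillates at the programmed cadence", {
  spec <- small_spec(noise_sd = 0, dropout = 0, cadence = 1.5)
  prof <- toy_profile()
  seq <- simulate_landmark_walk(prof, spec, seed = 2, duration = 8)
  gt <- compute_gait_table(preprocess_landmarks(seq), prof)
  sw <- gt$Step_Width - mean(gt$Step_Width)
  spec_f <- abs(fft(sw))^2
  n <- length(sw)
  freq <- (seq_len(n %/% 2) - 1) * spec$fps / n
  peak <- freq[which.max(spec_f[seq_len(n %/% 2)])]
  expect_equal(peak, spec$cadence, tolerance = spec$fps / n + 1e-9)
})

test_that("scaling all coordinates scales step width and MoS coherently", {
  frames <- dense_frames(30)
  # break collinearity so distances are non-trivial
  set.seed(9)
  frames$x <- frames$x + rnorm(nrow(frames), 0, 0.01)
  frames$y <- frames$y + rnorm(nrow(frames), 0, 0.01)
  prof <- toy_profile()
  seq1 <- landmark_sequence("S", 30, frames)
  gt1 <- compute_gait_table(seq1, prof, kinematics_config(scale = 1))
  # units coherence requires scaling gravity with the lengths, since the
  # eigenfrequency couples the two: omega0 = sqrt(g / l)
  gt2 <- compute_gait_table(seq1, prof,
                            kinematics_config(scale = 3, g = 3 * 9.81))
  expect_equal(gt2$Step_Width, 3 * gt1$Step_Width, tolerance = 1e-9)
  expect_equal(gt2$MoS, 3 * gt1$MoS, tolerance = 1e-9)
  expect_equal(gt2$CoM_Velocity, 3 * gt1$CoM_Velocity, tolerance = 1e-9)
})

test_that("auto-height calibration recovers the simulated camera scale", {
  spec <- small_spec(noise_sd = 0, dropout = 0)
  prof <- toy_profile(height = 1.70)
  seq <- simulate_landmark_walk(prof, spec, seed = 3, duration = 3)
  gt_auto <- compute_gait_table(preprocess_landmarks(seq), prof,
                                kinematics_config(scale = "auto-height"))
  gt_true <- compute_gait_table(preprocess_landmarks(seq), prof,
                                kinematics_config(scale = 1 / spec$image_units_per_m))
  # nose-to-ankle span is slightly under full stature, so calibration
  # is within a few percent of the true camera scale
  ratio <- median(gt_auto$Step_Width / gt_true$Step_Width)
  expect_equal(ratio, 1, tolerance = 0.08)
})

test_that("sequences shorter than two frames are rejected", {
  frames <- dense_frames(1)
  expect_error(compute_gait_table(landmark_sequence("S", 30, frames),
                                  toy_profile(), kinematics_config(scale = 1)),
               "two frames")
})
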