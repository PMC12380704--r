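#' Specification of the synthetic walking fixture
#'
#' Describes the statistical structure of a small older-adult walking
#' cohort: 14 participants totalling 1,878 timesteps at 30 fps, cohort
#' anthropometrics 86.7 +/- 6.2 years, 1.656 +/- 0.099 m,
#' 64.0 +/- 12.5 kg, target Spearman correlations rho(Step_Width, MoS) =
#' 0.768 and rho(CoM_Velocity, MoS) = -0.487, and variable bounds
#' step width 0.002-0.266 m and MoS 0.004-0.054 m. Remaining knobs
#' (cadence, sway, noise, dropout, the fall-history MoS shift) are
#' fixture parameters with defaults chosen to be realistic for self-paced
#' walking in this population.
#'
#' @param n_participants Number of participants (default 14).
#' @param total_rows Total timesteps across participants (default 1878);
#'   the remainder over an even split goes to the first participant.
#' @param fps Frame rate in Hz (default 30).
#' @param age_mean,age_sd Cohort age moments in years (86.7, 6.2).
#' @param height_mean,height_sd Height moments in m (1.656, 0.099).
#' @param mass_mean,mass_sd Mass moments in kg (64.0, 12.5).
#' @param p_fall Fall-history probability (default 0.3).
#' @param rho_sw_mos Target Spearman between step width and MoS (0.768).
#' @param rho_v_mos Target Spearman between CoM velocity and MoS (-0.487).
#' @param rho_sw_v Spearman between step width and CoM velocity (-0.30, a
#'   fixture choice keeping the correlation matrix feasible).
#' @param bounds Named list of `(min, max)` bounds per sequential column.
#' @param ar1 Within-participant lag-1 coupling of the latent series
#'   (default 0.6).
#' @param entity_tau Between-participant share of the latent variance
#'   (default 0.35).
#' @param fall_mos_shift Downward shift (latent SD units) of MoS for
#'   participants with fall history (default 0.3) so utility evaluation
#'   has signal to find.
#' @param cadence Step cadence in Hz (default 1.6, self-paced older
#'   adults).
#' @param sway_amplitude Lateral CoM sway amplitude in m (default 0.03).
#' @param noise_sd Additive landmark noise SD in normalized image units
#'   (default 0.002).
#' @param dropout Per-landmark dropout probability (default 0.02).
#' @param image_units_per_m Metres-to-normalized-image-units factor of the
#'   simulated camera (default 0.5).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_participants = 14,
                         total_rows = 1878,
                         fps = 30,
                         age_mean = 86.7, age_sd = 6.2,
                         height_mean = 1.656, height_sd = 0.099,
                         mass_mean = 64.0, mass_sd = 12.5,
                         p_fall = 0.3,
                         rho_sw_mos = 0.768,
                         rho_v_mos = -0.487,
                         rho_sw_v = -0.30,
                         bounds = list(
                           Step_Width = c(0.002, 0.266),
                           MoS = c(0.004, 0.054),
                           CoM_Velocity = c(0.02, 0.60),
                           X_Coordinate_CoM = c(-0.15, 0.15),
                           Y_Coordinate_CoM = c(0.85, 1.10)),
                         ar1 = 0.6,
                         entity_tau = 0.35,
                         fall_mos_shift = 0.3,
                         cadence = 1.6,
                         sway_amplitude = 0.03,
                         noise_sd = 0.002,
                         dropout = 0.02,
                         image_units_per_m = 0.5) {
  spec <- structure(as.list(environment()), class = "fixture_spec")
  stopifnot(n_participants >= 1, total_rows >= n_participants, fps > 0,
            abs(rho_sw_mos) < 1, abs(rho_v_mos) < 1, abs(rho_sw_v) < 1,
            ar1 >= 0, ar1 < 1, entity_tau >= 0, entity_tau < 1,
            p_fall >= 0, p_fall <= 1)
  for (b in bounds) stopifnot(length(b) == 2, b[1] < b[2])
  spec
}

# per-participant row counts: even split, remainder to the first entity
fixture_entity_lengths <- function(spec) {
  base <- spec$total_rows %/% spec$n_participants
  lens <- rep(base, spec$n_participants)
  lens[1] <- lens[1] + spec$total_rows %% spec$n_participants
  lens
}

# truncated-normal draw by inverse-CDF on the truncated probability mass
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a cohort of older-adult participants
#'
#' Ages, heights and masses are drawn from truncated normal
#' distributions at the spec's moments (truncation keeps the draws
#' physiologically plausible: age 70-104 y, height 1.35-1.95 m, mass
#' 35-110 kg); fall history is Bernoulli.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return A data.frame of [participant_profile()] rows.
#' @export
simulate_cohort <- function(spec = fixture_spec(), seed = 1) {
  set.seed(seed)
  n <- spec$n_participants
  age <- rtrunc_norm(n, spec$age_mean, spec$age_sd, 70, 104)
  height <- rtrunc_norm(n, spec$height_mean, spec$height_sd, 1.35, 1.95)
  mass <- rtrunc_norm(n, spec$mass_mean, spec$mass_sd, 35, 110)
  fall <- stats::rbinom(n, 1, spec$p_fall)
  ids <- sprintf("P%02d", seq_len(n))
  participant_profile(ids, height, mass, age, fall, warn = FALSE)
}

# meters offsets of each of the 33 pose landmarks from the pelvis midline
# at ground level, for a participant of height h; ankles are handled
# dynamically. A coarse template: only the kinematics landmark set
# matters downstream, the rest hang near their parent joints.
landmark_template <- function(h) {
  t <- matrix(NA_real_, 33, 2, dimnames = list(0:32, c("dx", "dy")))
  set_lm <- function(ids, dx, dy) t[as.character(ids), ] <<- cbind(dx, dy)
  set_lm(0, 0, 1.00 * h)                        # nose (head-top proxy)
  set_lm(c(1, 2, 3), c(0.015, 0.03, 0.045), 0.965 * h)   # left eye group
  set_lm(c(4, 5, 6), c(-0.015, -0.03, -0.045), 0.965 * h) # right eye group
  set_lm(c(7, 8), c(0.07, -0.07), 0.94 * h)     # ears
  set_lm(c(9, 10), c(0.02, -0.02), 0.92 * h)    # mouth
  set_lm(c(11, 12), c(0.18, -0.18), 0.82 * h)   # shoulders
  set_lm(c(13, 14), c(0.22, -0.22), 0.63 * h)   # elbows
  set_lm(c(15, 16), c(0.24, -0.24), 0.47 * h)   # wrists
  set_lm(c(17, 19, 21), 0.25, 0.42 * h)         # left hand
  set_lm(c(18, 20, 22), -0.25, 0.42 * h)        # right hand
  set_lm(c(23, 24), c(0.09, -0.09), 0.53 * h)   # hips
  set_lm(c(25, 26), c(0.08, -0.08), 0.28 * h)   # knees
  set_lm(c(27, 28), c(0.08, -0.08), 0.04 * h)   # ankles (dynamic laterally)
  set_lm(c(29, 31), 0.09, 0.02 * h)             # left heel/toe
  set_lm(c(30, 32), -0.09, 0.02 * h)            # right heel/toe
  t
}

#' Simulate a frontal-plane walking landmark sequence
#'
#' A kinematic toy model of treadmill-free walking viewed from the
#' front: the body midline sways laterally as a sinusoid at half the
#' step cadence, the ankles alternate laterally so the instantaneous
#' step width oscillates within the spec bounds, the trunk bounces
#' vertically at step frequency, and all other landmarks ride along at
#' anthropometric offsets. Gaussian coordinate noise and random landmark
#' dropout are added on top. Coordinates are in normalized image units
#' (the kinematics stage converts to metres via height calibration).
#'
#' @param profile A [participant_profile()] row.
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @param duration Sequence duration in seconds (default gives the
#'   spec's per-participant length).
#' @return A [landmark_sequence()].
#' @export
simulate_landmark_walk <- function(profile, spec = fixture_spec(), seed = 1,
                                   duration = NULL) {
  set.seed(seed)
  n <- if (is.null(duration)) fixture_entity_lengths(spec)[1] else
    round(duration * spec$fps)
  t_s <- (seq_len(n) - 1) / spec$fps
  h <- profile$height
  k <- spec$image_units_per_m

  sway <- spec$sway_amplitude * sin(2 * pi * (spec$cadence / 2) * t_s)
  b <- spec$bounds$Step_Width
  w_mid <- mean(b)
  w_amp <- 0.45 * diff(b)
  width <- w_mid + w_amp * sin(2 * pi * spec$cadence * t_s)
  bounce <- 0.01 * h * sin(2 * pi * spec$cadence * t_s + pi / 3)

  template <- landmark_template(h)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x_m <- sway[i] + template[, "dx"]
    y_m <- template[, "dy"] + bounce[i]
    # ankles/feet follow the oscillating step width about the midline
    x_m["27"] <- sway[i] + width[i] / 2
    x_m["28"] <- sway[i] - width[i] / 2
    x_m[c("29", "31")] <- x_m["27"] + 0.01
    x_m[c("30", "32")] <- x_m["28"] - 0.01
    y_m[c("27", "28")] <- template[c("27", "28"), "dy"]
    rows[[i]] <- data.frame(
      frame = i, timestamp = t_s[i], landmark_id = 0:32,
      x = x_m * k, y = y_m * k, visibility = 1, row.names = NULL)
  }
  df <- do.call(rbind, rows)
  if (spec$noise_sd > 0) {
    df$x <- df$x + stats::rnorm(nrow(df), 0, spec$noise_sd)
    df$y <- df$y + stats::rnorm(nrow(df), 0, spec$noise_sd)
  }
  if (spec$dropout > 0) {
    drop <- stats::runif(nrow(df)) < spec$dropout
    df <- df[!drop, , drop = FALSE]
  }
  landmark_sequence(profile$participant_id, spec$fps, df)
}

# target Gaussian-copula (Pearson) correlation matrix over the five
# sequential columns, from the spec's Spearman targets:
# r = 2 sin(pi * rho_s / 6)
fixture_latent_correlation <- function(spec) {
  cols <- GAIT_SEQUENTIAL  # CoM x, CoM y, velocity, step width, MoS
  R <- diag(length(cols))
  dimnames(R) <- list(cols, cols)
  s2p <- function(rho) 2 * sin(pi * rho / 6)
  R["Step_Width", "MoS"] <- R["MoS", "Step_Width"] <- s2p(spec$rho_sw_mos)
  R["CoM_Velocity", "MoS"] <- R["MoS", "CoM_Velocity"] <- s2p(spec$rho_v_mos)
  R["Step_Width", "CoM_Velocity"] <- R["CoM_Velocity", "Step_Width"] <-
    s2p(spec$rho_sw_v)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    stop("infeasible correlation targets: matrix not positive definite",
         call. = FALSE)
  }
  R
}

#' Simulate a gait table directly (table-level fixture)
#'
#' Draws the five sequential variables from a Gaussian copula whose
#' latent correlation hits the spec's Spearman targets (via
#' `r = 2 sin(pi rho_s / 6)`), with within-participant lag-1 smoothing,
#' correlated participant-level offsets, and bounded Beta-shaped
#' marginals mapped through the copula ranks — so every value respects
#' the spec bounds by construction and Spearman correlations survive the
#' monotone marginal transforms. Participants with fall history get a
#' configurable downward latent shift of MoS. Timestamps restart at 0
#' per participant and step by 1/fps; static categoricals come from a
#' simulated cohort.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return A gait-table data.frame with `spec$total_rows` rows.
#' @export
simulate_gait_table <- function(spec = fixture_spec(), seed = 1) {
  cohort <- simulate_cohort(spec, seed)
  set.seed(seed + 1L)
  R <- fixture_latent_correlation(spec)
  cols <- colnames(R)
  lens <- fixture_entity_lengths(spec)
  tau <- spec$entity_tau
  phi <- spec$ar1

  marginals <- list(
    X_Coordinate_CoM = c(3, 3),
    Y_Coordinate_CoM = c(3, 3),
    CoM_Velocity = c(2.5, 2.5),
    Step_Width = c(2, 3.5),   # right-skewed, as step width tends to be
    MoS = c(2, 2.5)
  )

  tabs <- vector("list", spec$n_participants)
  for (e in seq_len(spec$n_participants)) {
    n_e <- lens[e]
    alpha <- rmvn(1, R)                       # participant offset
    eps <- rmvn(n_e, R)                       # innovations
    w <- matrix(0, n_e, length(cols), dimnames = list(NULL, cols))
    w[1, ] <- eps[1, ]
    if (n_e > 1) {
      s <- sqrt(1 - phi^2)
      for (i in 2:n_e) w[i, ] <- phi * w[i - 1, ] + s * eps[i, ]
    }
    z <- sqrt(1 - tau^2) * w + tau * matrix(alpha, n_e, length(cols),
                                            byrow = TRUE)
    z[, "MoS"] <- z[, "MoS"] - spec$fall_mos_shift * cohort$fall_history[e]
    u <- stats::pnorm(z)
    vals <- sapply(cols, function(col) {
      b <- spec$bounds[[col]]
      ab <- marginals[[col]]
      b[1] + diff(b) * stats::qbeta(u[, col], ab[1], ab[2])
    })
    tabs[[e]] <- data.frame(
      ID = cohort$participant_id[e],
      Timestamp = (seq_len(n_e) - 1) / spec$fps,
      X_Coordinate_CoM = vals[, "X_Coordinate_CoM"],
      Y_Coordinate_CoM = vals[, "Y_Coordinate_CoM"],
      CoM_Velocity = vals[, "CoM_Velocity"],
      Step_Width = vals[, "Step_Width"],
      MoS = vals[, "MoS"],
      Age = cohort$age_category[e],
      BMI = cohort$bmi_category[e],
      Fall_History = cohort$fall_history[e],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
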