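#' Anthropometric segment model for a 33-landmark pose
#'
#' Maps body segments to pose-landmark ids and assigns each segment its
#' mass fraction from standard anthropometry: head 8.1%, torso 49.7%,
#' each arm 2.65%, each leg 16.1%. The fractions sum to 0.953; the
#' whole-body centre of mass divides by their sum, so the shortfall is
#' harmless. The partition uses the face landmarks (0-4) for the head,
#' shoulders plus hips (11, 12, 23, 24) for the torso, elbow plus wrist
#' for each arm (13/15, 14/16) and knee plus ankle for each leg
#' (25/27, 26/28).
#'
#' @return A list with `segments` (named list of landmark-id vectors) and
#'   `weights` (named numeric mass fractions).
#' @export
anthropometric_model <- function() {
  list(
    segments = list(
      head      = c(0, 1, 2, 3, 4),
      torso     = c(11, 12, 23, 24),
      arm_left  = c(13, 15),
      arm_right = c(14, 16),
      leg_left  = c(25, 27),
      leg_right = c(26, 28)
    ),
    weights = c(head = 0.081, torso = 0.497,
                arm_left = 0.0265, arm_right = 0.0265,
                leg_left = 0.161, leg_right = 0.161)
  )
}

# landmark ids the kinematics requires in every frame
com_landmark_set <- function(model = anthropometric_model()) {
  sort(unique(unlist(model$segments)))
}

#' Kinematics configuration
#'
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @param fps Sampling rate in Hz (default 30).
#' @param leg_length_fraction Fraction of the CoM-to-ankle-midpoint
#'   distance used as the pendulum length l in the eigenfrequency
#'   `omega0 = sqrt(g / l)` (default 1, must lie in (0, 1.5]).
#' @param scale Either `"auto-height"` (calibrate metres per coordinate
#'   unit from the participant's height and the median full-body landmark
#'   span over the first 30 valid frames) or an explicit numeric
#'   metres-per-unit factor.
#' @return A list of class `kinematics_config`.
#' @export
kinematics_config <- function(g = 9.81, fps = 30, leg_length_fraction = 1.0,
                              scale = "auto-height") {
  stopifnot(g > 0, fps > 0,
            leg_length_fraction > 0, leg_length_fraction <= 1.5)
  if (!(identical(scale, "auto-height") ||
        (is.numeric(scale) && scale > 0))) {
    stop('`scale` must be "auto-height" or a positive number', call. = FALSE)
  }
  structure(list(g = g, fps = fps,
                 leg_length_fraction = leg_length_fraction, scale = scale),
            class = "kinematics_config")
}

#' Centre of mass of one body segment
#'
#' The segment CoM is the unweighted mean of its landmark positions.
#'
#' @param points Numeric matrix (n x 2) of landmark (x, y) positions.
#' @return Numeric (x, y).
#' @export
segment_com <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 1 || !all(is.finite(points))) {
    stop("segment_com needs at least one finite point", call. = FALSE)
  }
  colMeans(points[, 1:2, drop = FALSE])
}

#' Whole-body centre of mass from segment centres
#'
#' Weighted mean of the segment CoMs, normalized by the sum of the
#' segment mass fractions actually present in the model.
#'
#' @param segment_coms Named list (or 2-column matrix with rownames) of
#'   segment CoM (x, y) positions.
#' @param model An [anthropometric_model()]; its `weights` must cover
#'   every named segment.
#' @return Numeric (x, y).
#' @export
body_com <- function(segment_coms, model = anthropometric_model()) {
  w <- model$weights
  if (is.list(segment_coms)) {
    segment_coms <- do.call(rbind, segment_coms)
  }
  missing_seg <- setdiff(names(w), rownames(segment_coms))
  if (length(missing_seg)) {
    stop("missing segment CoM(s): ", paste(missing_seg, collapse = ", "),
         call. = FALSE)
  }
  m <- segment_coms[names(w), , drop = FALSE]
  colSums(m * w) / sum(w)
}

#' Frame-to-frame centre-of-mass velocity
#'
#' Backward difference scaled by the frame rate,
#' `v(t) = fps * (CoM(t) - CoM(t-1))`. The first frame, where the
#' difference is undefined, is assigned the second frame's velocity so
#' the series keeps the input length.
#'
#' @param com Numeric matrix (n x 2) of CoM positions in metres.
#' @param fps Sampling rate in Hz (> 0).
#' @return Numeric matrix (n x 2) of velocity components in m/s.
#' @export
com_velocity <- function(com, fps) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  com <- rbind(com)
  if (nrow(com) < 2) stop("need at least two CoM samples", call. = FALSE)
  v <- fps * diff(com)
  rbind(v[1, , drop = FALSE], v)
}

#' Extrapolated centre of mass (XCoM)
#'
#' `XCoM = CoM + v / omega0` with the inverted-pendulum eigenfrequency
#' `omega0 = sqrt(g / l)` for pendulum length `l`.
#'
#' @param com CoM position (x, y) in m, or an (n x 2) matrix.
#' @param v CoM velocity (vx, vy) in m/s, same shape as `com`.
#' @param leg_length Pendulum length l in m (> 0).
#' @param g Gravitational acceleration in m/s^2.
#' @return XCoM position(s), same shape as `com`.
#' @export
extrapolated_com <- function(com, v, leg_length, g = 9.81) {
  if (!is.numeric(leg_length) || leg_length <= 0) {
    stop("leg_length must be positive", call. = FALSE)
  }
  omega0 <- sqrt(g / leg_length)
  com + v / omega0
}

#' Perpendicular distance from a point to the base-of-support boundary
#'
#' The boundary is the infinite line through the two ankle positions.
#' With `v_point = point - boundary_a` and
#' `v_boundary = boundary_b - boundary_a`, the distance is
#' `|cross_z(v_point, v_boundary)| / ||v_boundary||`.
#'
#' @param point Query position (x, y).
#' @param boundary_a,boundary_b The two ankle positions (x, y); must be
#'   distinct.
#' @return Non-negative distance in the units of the inputs.
#' @export
boundary_distance <- function(point, boundary_a, boundary_b) {
  vb <- boundary_b - boundary_a
  nb <- sqrt(sum(vb^2))
  if (nb == 0) {
    stop("degenerate base of support: coincident ankle positions",
         call. = FALSE)
  }
  vp <- point - boundary_a
  abs(vp[1] * vb[2] - vp[2] * vb[1]) / nb
}

#' Margin of stability
#'
#' The minimum of the perpendicular distances of the XCoM and the CoM
#' from the base-of-support boundary (the line through the ankles):
#' `MoS = min(d_XCoM, d_CoM)`. Always non-negative; zero exactly when
#' either point lies on the boundary line.
#'
#' @param xcom Extrapolated CoM position (x, y).
#' @param com CoM position (x, y).
#' @param boundary_a,boundary_b Ankle positions (x, y).
#' @return Non-negative margin in input units.
#' @export
margin_of_stability <- function(xcom, com, boundary_a, boundary_b) {
  min(boundary_distance(xcom, boundary_a, boundary_b),
      boundary_distance(com, boundary_a, boundary_b))
}

#' Step width
#'
#' Euclidean distance between the left and right ankle landmarks in the
#' frontal plane.
#'
#' @param left_ankle,right_ankle Ankle positions (x, y).
#' @return Non-negative width in input units.
#' @export
step_width <- function(left_ankle, right_ankle) {
  if (anyNA(left_ankle) || anyNA(right_ankle)) {
    stop("both ankle positions are required (impute upstream)", call. = FALSE)
  }
  sqrt(sum((left_ankle - right_ankle)^2))
}

# per-frame wide coordinate arrays for the required landmark set;
# errors if a required landmark is absent anywhere
landmark_arrays <- function(seq, ids) {
  frames <- seq$frames
  frame_ids <- sort(unique(frames$frame))
  get_coord <- function(coord) {
    m <- matrix(NA_real_, length(frame_ids), length(ids),
                dimnames = list(NULL, ids))
    keep <- frames$landmark_id %in% ids
    fi <- match(frames$frame[keep], frame_ids)
    li <- match(frames$landmark_id[keep], ids)
    m[cbind(fi, li)] <- frames[[coord]][keep]
    m
  }
  x <- get_coord("x"); y <- get_coord("y")
  if (anyNA(x) || anyNA(y)) {
    n_missing <- sum(is.na(x))
    stop(sprintf(paste0("sequence has %d missing required landmark value(s); ",
                        "run preprocess_landmarks() first"), n_missing),
         call. = FALSE)
  }
  list(frames = frame_ids,
       timestamp = frames$timestamp[!duplicated(frames$frame)][order(frame_ids)],
       x = x, y = y)
}

# metres-per-coordinate-unit calibration from participant height:
# height / median span between landmark 0 (head-top proxy) and the ankle
# midpoint over the first 30 valid frames
auto_height_scale <- function(arr, height, n_frames = 30) {
  n <- min(n_frames, nrow(arr$x))
  hx <- arr$x[seq_len(n), "0"]; hy <- arr$y[seq_len(n), "0"]
  ax <- (arr$x[seq_len(n), "27"] + arr$x[seq_len(n), "28"]) / 2
  ay <- (arr$y[seq_len(n), "27"] + arr$y[seq_len(n), "28"]) / 2
  span <- sqrt((hx - ax)^2 + (hy - ay)^2)
  med <- stats::median(span)
  if (!is.finite(med) || med <= 0) {
    stop("auto-height calibration failed: degenerate landmark span",
         call. = FALSE)
  }
  height / med
}

#' Compute a gait table from a landmark sequence
#'
#' Runs the full kinematic chain per frame: segment CoMs, whole-body CoM,
#' CoM velocity, extrapolated CoM, perpendicular distances to the
#' ankle-line base of support, margin of stability, and step width.
#' Coordinates are converted to metres using the configured scale
#' (`"auto-height"` calibration or an explicit factor); the pendulum
#' length is `leg_length_fraction` times the mean CoM-to-ankle-midpoint
#' distance of the sequence. Static attributes (two-level Age and BMI
#' categories, fall history) come from the participant profile.
#'
#' @param seq A preprocessed [landmark_sequence()] — filtered and imputed,
#'   with every required landmark present in every frame.
#' @param profile A [participant_profile()] row supplying height and the
#'   categorical attributes.
#' @param cfg A [kinematics_config()].
#' @return A gait-table data.frame with columns `ID, Timestamp,
#'   X_Coordinate_CoM, Y_Coordinate_CoM, CoM_Velocity, Step_Width, MoS,
#'   Age, BMI, Fall_History`, one row per frame.
#' @export
compute_gait_table <- function(seq, profile, cfg = kinematics_config()) {
  stopifnot(inherits(seq, "landmark_sequence"))
  model <- anthropometric_model()
  arr <- landmark_arrays(seq, com_landmark_set(model))
  n <- nrow(arr$x)
  if (n < 2) stop("sequence must have at least two frames", call. = FALSE)

  scale <- if (identical(cfg$scale, "auto-height")) {
    auto_height_scale(arr, profile$height)
  } else {
    cfg$scale
  }
  X <- arr$x * scale
  Y <- arr$y * scale

  seg_ids <- lapply(model$segments, as.character)
  seg_x <- vapply(seg_ids, function(ids)
    rowMeans(X[, ids, drop = FALSE]), numeric(n))
  seg_y <- vapply(seg_ids, function(ids)
    rowMeans(Y[, ids, drop = FALSE]), numeric(n))
  w <- model$weights[colnames(seg_x)]
  com <- cbind(x = as.vector(seg_x %*% w) / sum(w),
               y = as.vector(seg_y %*% w) / sum(w))

  v <- com_velocity(com, cfg$fps)
  speed <- sqrt(rowSums(v^2))

  ankle_mid <- cbind((X[, "27"] + X[, "28"]) / 2,
                     (Y[, "27"] + Y[, "28"]) / 2)
  leg_length <- cfg$leg_length_fraction *
    mean(sqrt(rowSums((com - ankle_mid)^2)))
  xcom <- extrapolated_com(com, v, leg_length, cfg$g)

  mos <- numeric(n)
  sw <- numeric(n)
  for (i in seq_len(n)) {
    a <- c(X[i, "27"], Y[i, "27"])
    b <- c(X[i, "28"], Y[i, "28"])
    mos[i] <- margin_of_stability(xcom[i, ], com[i, ], a, b)
    sw[i] <- step_width(a, b)
  }

  out <- data.frame(
    ID = profile$participant_id,
    Timestamp = arr$timestamp,
    X_Coordinate_CoM = com[, "x"],
    Y_Coordinate_CoM = com[, "y"],
    CoM_Velocity = speed,
    Step_Width = sw,
    MoS = mos,
    Age = profile$age_category,
    BMI = profile$bmi_category,
    Fall_History = profile$fall_history,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
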