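#' Preprocessing configuration
#'
#' @param filter_order Butterworth order of the underlying design
#'   (default 4; even, >= 2). The filter is applied forward and backward,
#'   so the effective roll-off is twice this order.
#' @param cutoff Low-pass cutoff in Hz (default 4; must be below the
#'   Nyquist frequency `fs / 2`).
#' @param fs Sampling rate in Hz (default 30).
#' @param outlier_k Threshold factor k of the mean +/- k sigma outlier
#'   rule (default 2).
#' @param missing_threshold Maximum tolerated missing-frame fraction per
#'   window; windows strictly above it are rejected (default 0.20).
#' @param window Window length in frames used to approximate one gait
#'   cycle for the missing-data gate (default 30, i.e. 1 s at 30 fps).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 4, cutoff = 4, fs = 30,
                              outlier_k = 2, missing_threshold = 0.20,
                              window = 30) {
  stopifnot(filter_order >= 2, filter_order %% 2 == 0,
            cutoff > 0, cutoff < fs / 2,
            outlier_k > 0,
            missing_threshold > 0, missing_threshold < 1,
            window >= 5)
  structure(list(filter_order = filter_order, cutoff = cutoff, fs = fs,
                 outlier_k = outlier_k,
                 missing_threshold = missing_threshold, window = window),
            class = "preprocess_config")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass design forward and backward
#' (`signal::filtfilt`), which cancels the phase response: the output is
#' not delayed relative to the input and the effective attenuation order
#' doubles. Intended for per-coordinate landmark trajectories before the
#' gait metrics are (re)computed.
#'
#' @param x Numeric series.
#' @param cfg A [preprocess_config()].
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, cfg = preprocess_config()) {
  min_len <- 3 * (cfg$filter_order + 1)
  if (length(x) < min_len) {
    stop(sprintf("series too short for stable filtering (need >= %d samples)",
                 min_len), call. = FALSE)
  }
  if (anyNA(x)) stop("series contains NA; impute before filtering",
                     call. = FALSE)
  bf <- signal::butter(cfg$filter_order, 2 * cfg$cutoff / cfg$fs,
                       type = "low")
  # odd-symmetric edge padding before the forward-backward pass, so the
  # startup transient falls on the padding, not on the data
  n <- length(x)
  m <- mean(x)
  xc <- x - m
  pad <- min(n - 1, 6 * (cfg$filter_order * 2 + 1))
  xp <- c(2 * xc[1] - xc[seq(pad + 1, 2)],
          xc,
          2 * xc[n] - xc[seq(n - 1, n - pad)])
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(pad + 1):(pad + n)]) + m
}

#' Neighbour-mean imputation of gaps in a series
#'
#' Interior gaps are filled with the mean of the nearest preceding and
#' following observed values; leading/trailing gaps copy the nearest
#' observed value. Observed values are never altered.
#'
#' @param x Numeric series with `NA` gaps.
#' @return Series with all gaps filled.
#' @export
impute_missing <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) stop("all values missing; cannot impute",
                             call. = FALSE)
  if (length(obs) == length(x)) return(x)
  out <- x
  for (i in which(is.na(x))) {
    prev <- obs[obs < i]
    nxt <- obs[obs > i]
    out[i] <- if (length(prev) && length(nxt)) {
      (x[max(prev)] + x[min(nxt)]) / 2
    } else if (length(prev)) {
      x[max(prev)]
    } else {
      x[min(nxt)]
    }
  }
  out
}

#' Missing-data gate over sliding windows
#'
#' Partitions the frame sequence into consecutive windows (a proxy for
#' gait cycles) and rejects any window whose missing-frame fraction
#' strictly exceeds the configured threshold. A frame counts as missing
#' when any landmark required by the kinematics is absent.
#'
#' @param x Either a [landmark_sequence()] or a logical vector marking
#'   missing frames.
#' @param cfg A [preprocess_config()].
#' @return A data.frame with one row per window: `window`, `start`,
#'   `end`, `n_missing`, `fraction`, `pass`; attribute `"pass"` gives the
#'   overall verdict.
#' @export
missingness_gate <- function(x, cfg = preprocess_config()) {
  missing_mask <- if (inherits(x, "landmark_sequence")) {
    ids <- com_landmark_set()
    frames <- sort(unique(x$frames$frame))
    counts <- table(factor(x$frames$frame[x$frames$landmark_id %in% ids],
                           levels = frames))
    as.vector(counts) < length(ids)
  } else {
    as.logical(x)
  }
  n <- length(missing_mask)
  starts <- seq(1, n, by = cfg$window)
  rows <- lapply(seq_along(starts), function(w) {
    i0 <- starts[w]
    i1 <- min(i0 + cfg$window - 1, n)
    if (i1 - i0 + 1 < 5) return(NULL)  # ignore a tail shorter than 5 frames
    frac <- mean(missing_mask[i0:i1])
    data.frame(window = w, start = i0, end = i1,
               n_missing = sum(missing_mask[i0:i1]), fraction = frac,
               pass = frac <= cfg$missing_threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Remove outliers by the mean +/- k sigma rule
#'
#' The mean and *population* standard deviation are computed from the
#' input series; values outside `[mu - k*sigma, mu + k*sigma]` are
#' flagged and removed. With k = 2 this retains approximately 95% of
#' normally distributed data. A constant series (sigma = 0) removes
#' nothing.
#'
#' @param x Numeric series (length >= 3).
#' @param k Threshold factor (> 0), default 2.
#' @return A list with `values` (kept series), `removed` (logical mask on
#'   the input), `mu`, `sigma`.
#' @export
remove_outliers <- function(x, k = 2) {
  stopifnot(length(x) >= 3, k > 0)
  mu <- mean(x)
  sigma <- pop_sd(x)
  removed <- if (sigma == 0) rep(FALSE, length(x)) else
    x < mu - k * sigma | x > mu + k * sigma
  list(values = x[!removed], removed = removed, mu = mu, sigma = sigma)
}

#' Fit a min-max scaler
#'
#' Learns per-feature minima and maxima from a training table; applied
#' features are mapped by `(x - min) / (max - min)` so the training range
#' becomes `[0, 1]`. Test values outside the training range scale beyond
#' that interval (no clipping). Constant features map to 0 with a warning.
#'
#' @param train Training data.frame (non-empty).
#' @param columns Features to scale; defaults to the numeric model inputs
#'   `X_Coordinate_CoM, Y_Coordinate_CoM, CoM_Velocity, Step_Width`.
#' @return A list of class `minmax_scaler`.
#' @export
fit_minmax <- function(train,
                       columns = c("X_Coordinate_CoM", "Y_Coordinate_CoM",
                                   "CoM_Velocity", "Step_Width")) {
  if (nrow(train) == 0) stop("training table is empty", call. = FALSE)
  rng <- lapply(columns, function(col) {
    r <- range(train[[col]])
    if (r[1] == r[2]) {
      warning(sprintf("feature `%s` is constant; it will scale to 0", col),
              call. = FALSE)
    }
    r
  })
  structure(list(columns = columns,
                 min = vapply(rng, `[`, 0, 1),
                 max = vapply(rng, `[`, 0, 2)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param table Data.frame containing the scaler's columns.
#' @param state A `minmax_scaler` from [fit_minmax()].
#' @return `table` with the scaled columns replaced.
#' @export
apply_minmax <- function(table, state) {
  stopifnot(inherits(state, "minmax_scaler"))
  for (i in seq_along(state$columns)) {
    col <- state$columns[i]
    span <- state$max[i] - state$min[i]
    table[[col]] <- if (span == 0) rep(0, nrow(table)) else
      (table[[col]] - state$min[i]) / span
  }
  table
}

#' Invert a min-max scaling
#'
#' @inheritParams apply_minmax
#' @return `table` with the scaled columns mapped back to original units.
#' @export
invert_minmax <- function(table, state) {
  stopifnot(inherits(state, "minmax_scaler"))
  for (i in seq_along(state$columns)) {
    col <- state$columns[i]
    span <- state$max[i] - state$min[i]
    table[[col]] <- table[[col]] * span + state$min[i]
  }
  table
}

#' Filter and impute a landmark sequence
#'
#' Densifies the required landmark set onto the full frame grid, fills
#' gaps per coordinate with [impute_missing()], then applies the
#' zero-phase low-pass filter per coordinate. Gait metrics should be
#' (re)computed from the returned sequence.
#'
#' @param seq A [landmark_sequence()].
#' @param cfg A [preprocess_config()].
#' @return A dense, filtered [landmark_sequence()].
#' @export
preprocess_landmarks <- function(seq, cfg = preprocess_config()) {
  stopifnot(inherits(seq, "landmark_sequence"))
  ids <- com_landmark_set()
  frames <- seq$frames
  frame_ids <- sort(unique(frames$frame))
  ts <- frames$timestamp[!duplicated(frames$frame)]
  rows <- lapply(ids, function(id) {
    sub <- frames[frames$landmark_id == id, , drop = FALSE]
    x <- y <- rep(NA_real_, length(frame_ids))
    fi <- match(sub$frame, frame_ids)
    x[fi] <- sub$x; y[fi] <- sub$y
    x <- lowpass_filter(impute_missing(x), cfg)
    y <- lowpass_filter(impute_missing(y), cfg)
    data.frame(frame = frame_ids, timestamp = ts, landmark_id = id,
               x = x, y = y, visibility = 1)
  })
  landmark_sequence(seq$participant_id, seq$fps, do.call(rbind, rows))
}

#' Remove outlier rows from a gait table
#'
#' Applies the mean +/- k sigma rule per sequential variable *per
#' participant* (pooling across participants would conflate
#' between-subject differences) and drops a row when any of its
#' sequential variables is flagged.
#'
#' @param table Gait table.
#' @param cfg A [preprocess_config()].
#' @return The filtered gait table; attribute `"n_removed"` records the
#'   number of dropped rows.
#' @export
preprocess_gait_table <- function(table, cfg = preprocess_config()) {
  check_gait_table(table)
  keep <- rep(TRUE, nrow(table))
  for (id in unique(table$ID)) {
    idx <- which(table$ID == id)
    if (length(idx) < 3) next
    for (col in GAIT_SEQUENTIAL) {
      res <- remove_outliers(table[[col]][idx], cfg$outlier_k)
      keep[idx[res$removed]] <- FALSE
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}
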