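#' Construct a pose-landmark sequence
#'
#' A landmark sequence holds the per-frame 2D positions of the 33 standard
#' full-body pose landmarks (ids 0-32) for one participant, in long format.
#' Landmarks that were not tracked in a frame are simply absent from the
#' table — missing points are never recorded as zeros.
#'
#' @param participant_id Identifier string.
#' @param fps Frame rate in Hz (> 0).
#' @param frames Data frame with columns `frame`, `timestamp`,
#'   `landmark_id`, `x`, `y` and optionally `visibility` (in `[0, 1]`).
#' @return An object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(participant_id, fps, frames) {
  stopifnot(is.numeric(fps), fps > 0)
  frames <- as.data.frame(frames)
  required <- c("frame", "timestamp", "landmark_id", "x", "y")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols)) {
    stop("landmark frames lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"visibility" %in% names(frames)) frames$visibility <- 1
  bad <- which(!(frames$landmark_id %in% 0:32))
  if (length(bad)) {
    stop(sprintf("landmark_id outside 0..32 at row %d (value %s)",
                 bad[1], frames$landmark_id[bad[1]]), call. = FALSE)
  }
  frames <- frames[order(frames$frame, frames$landmark_id), , drop = FALSE]
  rownames(frames) <- NULL
  if (anyDuplicated(paste(frames$frame, frames$landmark_id))) {
    stop("duplicated (frame, landmark_id) rows", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         fps = as.numeric(fps),
         frames = frames[, c("frame", "timestamp", "landmark_id",
                             "x", "y", "visibility")]),
    class = "landmark_sequence"
  )
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence> participant %s: %d frames at %g fps, %d points\n",
              x$participant_id, length(unique(x$frames$frame)), x$fps,
              nrow(x$frames)))
  invisible(x)
}

#' Read a pose-landmark sequence from disk
#'
#' Two on-disk dialects are supported: a long CSV with columns
#' `participant_id,frame,timestamp,landmark_id,x,y,visibility`, and a JSON
#' document `{participant_id, fps, frames: [{frame, timestamp, points:
#' {"<id>": {x, y, visibility}}}]}`. Landmarks with visibility below
#' `visibility_min` are treated as missing (dropped), mirroring tracking
#' loss in markerless pose estimation; they are never zero-filled.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"json"`.
#' @param fps Frame rate in Hz. For CSV input it is inferred from the
#'   timestamp grid when omitted; JSON input carries its own `fps`.
#' @param visibility_min Visibility threshold below which a landmark is
#'   treated as missing (default 0.5).
#' @return A [landmark_sequence()].
#' @export
read_landmark_sequence <- function(path, dialect = c("csv", "json"),
                                   fps = NULL, visibility_min = 0.5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    required <- c("participant_id", "frame", "timestamp", "landmark_id", "x", "y")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols)) {
      stop("malformed landmark CSV, missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (col in c("frame", "timestamp", "landmark_id", "x", "y")) {
      if (!is.numeric(df[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
        stop(sprintf("malformed landmark CSV: non-numeric `%s` at data line %d",
                     col, if (is.na(bad)) 1L else bad), call. = FALSE)
      }
    }
    if (!"visibility" %in% names(df)) df$visibility <- 1
    pid <- unique(df$participant_id)
    if (length(pid) != 1) {
      stop("landmark CSV must contain exactly one participant_id", call. = FALSE)
    }
    if (is.null(fps)) {
      ts <- sort(unique(df$timestamp))
      dt <- stats::median(diff(ts))
      if (!is.finite(dt) || dt <= 0) {
        stop("cannot infer fps from timestamps; supply `fps`", call. = FALSE)
      }
      fps <- 1 / dt
    }
    keep <- is.na(df$visibility) | df$visibility >= visibility_min
    df <- df[keep, , drop = FALSE]
    landmark_sequence(pid, fps, df[, c("frame", "timestamp", "landmark_id",
                                       "x", "y", "visibility")])
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$participant_id) || is.null(doc$fps) || is.null(doc$frames)) {
      stop("malformed landmark JSON: need participant_id, fps, frames",
           call. = FALSE)
    }
    rows <- lapply(doc$frames, function(fr) {
      pts <- fr$points
      if (!length(pts)) return(NULL)
      ids <- as.integer(names(pts))
      data.frame(frame = fr$frame, timestamp = fr$timestamp,
                 landmark_id = ids,
                 x = vapply(pts, function(p) as.numeric(p$x), 0),
                 y = vapply(pts, function(p) as.numeric(p$y), 0),
                 visibility = vapply(pts, function(p)
                   as.numeric(p$visibility %||% 1), 0),
                 row.names = NULL)
    })
    df <- do.call(rbind, rows)
    df <- df[df$visibility >= visibility_min, , drop = FALSE]
    landmark_sequence(doc$participant_id, doc$fps, df)
  }
}

#' Write a pose-landmark sequence to disk
#'
#' @param seq A [landmark_sequence()].
#' @param path Output file.
#' @param dialect `"csv"` or `"json"` (see [read_landmark_sequence()]).
#' @return `path`, invisibly.
#' @export
write_landmark_sequence <- function(seq, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(seq, "landmark_sequence"))
  if (dialect == "csv") {
    df <- cbind(participant_id = seq$participant_id, seq$frames)
    write.csv(df, path, row.names = FALSE)
  } else {
    frames <- split(seq$frames, seq$frames$frame)
    doc <- list(
      participant_id = seq$participant_id,
      fps = seq$fps,
      frames = lapply(frames, function(fr) {
        pts <- lapply(seq_len(nrow(fr)), function(i)
          list(x = fr$x[i], y = fr$y[i], visibility = fr$visibility[i]))
        names(pts) <- fr$landmark_id
        list(frame = fr$frame[1], timestamp = fr$timestamp[1], points = pts)
      })
    )
    names(doc$frames) <- NULL
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Age category of an older-adult participant
#'
#' Two bins are used: 0 = middle-old (75-84 years), 1 = oldest-old
#' (>= 85 years). Ages below 75 fall outside the defined bins and are
#' mapped to 0 with a warning.
#'
#' @param age Age in years.
#' @return Integer vector of 0/1 categories.
#' @export
derive_age_category <- function(age) {
  if (any(age < 75)) {
    warning("age below 75 outside the defined bins; mapped to category 0",
            call. = FALSE)
  }
  as.integer(age >= 85)
}

#' BMI category of an older-adult participant
#'
#' Two bins are used: 0 = underweight (BMI < 23), 1 = healthy weight
#' (23 <= BMI <= 30). BMI above 30 falls outside the defined bins and is
#' mapped to 1 with a warning.
#'
#' @param bmi Body-mass index in kg/m^2.
#' @return Integer vector of 0/1 categories.
#' @export
derive_bmi_category <- function(bmi) {
  if (any(bmi > 30)) {
    warning("BMI above 30 outside the defined bins; mapped to category 1",
            call. = FALSE)
  }
  as.integer(bmi >= 23)
}

#' Build a participant profile
#'
#' Derives BMI and the two-level age/BMI categories from raw
#' anthropometrics.
#'
#' @param participant_id Identifier.
#' @param height Height in m (> 0).
#' @param mass Mass in kg (> 0).
#' @param age Age in years.
#' @param fall_history 0/1 (or logical): at least one fall in the last
#'   6 months.
#' @param warn Emit warnings for out-of-bin age/BMI (default `TRUE`).
#' @return A one-row data.frame of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, height, mass, age,
                                fall_history, warn = TRUE) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  bmi <- mass / height^2
  derive <- function(f, x) if (warn) f(x) else suppressWarnings(f(x))
  out <- data.frame(
    participant_id = as.character(participant_id),
    height = height, mass = mass, age = age, bmi = bmi,
    fall_history = as.integer(fall_history),
    age_category = derive(derive_age_category, age),
    bmi_category = derive(derive_bmi_category, bmi),
    stringsAsFactors = FALSE
  )
  class(out) <- c("participant_profile", "data.frame")
  out
}

#' Read a cohort table
#'
#' Expects CSV columns `participant_id,height_m,mass_kg,age_years,
#' fall_history` and derives BMI plus the two-level age/BMI categories.
#'
#' @param path CSV file.
#' @return A data.frame of [participant_profile()] rows.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "height_m", "mass_kg", "age_years",
                "fall_history")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  participant_profile(df$participant_id, df$height_m, df$mass_kg,
                      df$age_years, df$fall_history)
}

#' Write a cohort table
#'
#' @param cohort A data.frame of [participant_profile()] rows.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(participant_id = cohort$participant_id,
                    height_m = cohort$height, mass_kg = cohort$mass,
                    age_years = cohort$age,
                    fall_history = cohort$fall_history)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a gait table to CSV
#'
#' Columns: `ID,Timestamp,X_Coordinate_CoM,Y_Coordinate_CoM,CoM_Velocity,
#' Step_Width,MoS,Age,BMI,Fall_History`.
#'
#' @param table Gait table (non-empty).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_gait_table <- function(table, path) {
  check_gait_table(table)
  if (nrow(table) == 0) stop("refusing to write an empty gait table",
                             call. = FALSE)
  write.csv(table[, GAIT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a gait table from CSV
#'
#' @param path CSV file written by [write_gait_table()].
#' @return A gait-table data.frame.
#' @export
read_gait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_gait_table(df, arg = path)
  df$ID <- as.character(df$ID)
  df[, GAIT_COLUMNS]
}
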