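`%||%` <- function(a, b) if (is.null(a)) b else a

# Spearman rank correlation without the ties warning from cor.test
spearman <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# moment coefficient of skewness, population form
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# draw n rows from MVN(0, R) given a correlation matrix, using base RNG so
# that a single set.seed() call upstream fixes the whole stream
rmvn <- function(n, R) {
  p <- ncol(R)
  L <- tryCatch(chol(R), error = function(e) {
    chol(nearest_psd(R))
  })
  matrix(stats::rnorm(n * p), n, p) %*% L
}

# repair a symmetric matrix to the nearest positive semi-definite
# correlation matrix
nearest_psd <- function(R) {
  out <- Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE)
  as.matrix(out$mat)
}

# canonical gait-table column order
GAIT_COLUMNS <- c("ID", "Timestamp", "X_Coordinate_CoM", "Y_Coordinate_CoM",
                  "CoM_Velocity", "Step_Width", "MoS",
                  "Age", "BMI", "Fall_History")

GAIT_SEQUENTIAL <- c("X_Coordinate_CoM", "Y_Coordinate_CoM",
                     "CoM_Velocity", "Step_Width", "MoS")

GAIT_CATEGORICAL <- c("Age", "BMI", "Fall_History")

check_gait_table <- function(table, arg = "table") {
  if (!is.data.frame(table)) {
    stop(sprintf("`%s` must be a data.frame", arg), call. = FALSE)
  }
  missing_cols <- setdiff(GAIT_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop(sprintf("`%s` lacks gait-table column(s): %s", arg,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(table)
}
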