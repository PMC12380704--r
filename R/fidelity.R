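#' Kolmogorov-Smirnov complement of two numeric samples
#'
#' `1 - sup |ECDF_real - ECDF_syn|`, with the supremum evaluated at every
#' sample point of both samples (right-continuous ECDFs). 1 means the
#' empirical distributions coincide; 0 means disjoint supports.
#'
#' @param real_col,syn_col Non-empty numeric samples.
#' @return Score in `[0, 1]`.
#' @export
ks_complement <- function(real_col, syn_col) {
  if (!length(real_col) || !length(syn_col)) {
    stop("empty sample", call. = FALSE)
  }
  pts <- sort(unique(c(real_col, syn_col)))
  d <- max(abs(stats::ecdf(real_col)(pts) - stats::ecdf(syn_col)(pts)))
  1 - d
}

#' Total-variation complement of two categorical samples
#'
#' `1 - 0.5 * sum_c |p_real(c) - p_syn(c)|` over the union of observed
#' categories.
#'
#' @param real_col,syn_col Non-empty categorical samples.
#' @return Score in `[0, 1]`.
#' @export
tv_complement <- function(real_col, syn_col) {
  if (!length(real_col) || !length(syn_col)) {
    stop("empty sample", call. = FALSE)
  }
  lev <- union(unique(real_col), unique(syn_col))
  p <- prop.table(table(factor(real_col, levels = lev)))
  q <- prop.table(table(factor(syn_col, levels = lev)))
  1 - 0.5 * sum(abs(p - q))
}

# columns scored by fidelity metrics: every numeric (incl. the timestamp)
# plus the categoricals; the entity key is excluded
fidelity_columns <- function(metadata) {
  list(numeric = metadata$numeric_cols, categorical = metadata$categorical)
}

#' Aggregate univariate resemblance (column shapes)
#'
#' Unweighted mean of the per-column KS complement (numeric columns,
#' including the timestamp) and TV complement (categorical columns).
#'
#' @param real,syn Gait tables with the same schema.
#' @param metadata A [derive_metadata()] result (defaults to metadata of
#'   `real`).
#' @return A list with `score` and `columns` (per-column metric/score).
#' @export
column_shapes <- function(real, syn, metadata = derive_metadata(real)) {
  if (!all(names(real) %in% names(syn)) ||
      !all(names(syn) %in% names(real))) {
    stop("real and synthetic tables have different schemas", call. = FALSE)
  }
  cols <- fidelity_columns(metadata)
  rows <- rbind(
    do.call(rbind, lapply(cols$numeric, function(col)
      data.frame(column = col, metric = "KSComplement",
                 score = ks_complement(real[[col]], syn[[col]])))),
    do.call(rbind, lapply(cols$categorical, function(col)
      data.frame(column = col, metric = "TVComplement",
                 score = tv_complement(real[[col]], syn[[col]]))))
  )
  list(score = mean(rows$score), columns = rows)
}

# total-variation similarity between normalized joint contingency tables;
# numeric partners are discretized into quartile bins on the pooled data
pair_contingency_score <- function(rx, sx, ry, sy) {
  discretize <- function(r, s) {
    if (is.numeric(r) && length(unique(c(r, s))) > 8) {
      br <- unique(stats::quantile(c(r, s), probs = seq(0, 1, 0.25)))
      if (length(br) < 2) return(list(r = factor(rep(1, length(r))),
                                      s = factor(rep(1, length(s)))))
      list(r = cut(r, br, include.lowest = TRUE),
           s = cut(s, br, include.lowest = TRUE))
    } else {
      lev <- union(unique(r), unique(s))
      list(r = factor(r, levels = lev), s = factor(s, levels = lev))
    }
  }
  dx <- discretize(rx, sx)
  dy <- discretize(ry, sy)
  p <- prop.table(table(dx$r, dy$r))
  q <- prop.table(table(dx$s, dy$s))
  1 - 0.5 * sum(abs(p - q))
}

#' Aggregate bivariate resemblance (column pair trends)
#'
#' Numeric-numeric pairs score `1 - |pearson_real - pearson_syn| / 2`;
#' pairs involving a categorical (or a constant numeric) column score the
#' total-variation similarity of their normalized joint contingency
#' tables, with numeric partners discretized into pooled quartile bins.
#' The aggregate is the unweighted mean over all column pairs.
#'
#' @inheritParams column_shapes
#' @return A list with `score` and `pairs` (per-pair scores).
#' @export
pair_trends <- function(real, syn, metadata = derive_metadata(real)) {
  cols <- fidelity_columns(metadata)
  all_cols <- c(cols$numeric, cols$categorical)
  if (length(all_cols) < 2) stop("need at least two columns", call. = FALSE)
  pairs <- utils::combn(all_cols, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    numeric_pair <- a %in% cols$numeric && b %in% cols$numeric &&
      stats::sd(real[[a]]) > 0 && stats::sd(real[[b]]) > 0 &&
      stats::sd(syn[[a]]) > 0 && stats::sd(syn[[b]]) > 0
    score <- if (numeric_pair) {
      1 - abs(stats::cor(real[[a]], real[[b]]) -
                stats::cor(syn[[a]], syn[[b]])) / 2
    } else {
      pair_contingency_score(real[[a]], syn[[a]], real[[b]], syn[[b]])
    }
    data.frame(a = a, b = b,
               method = if (numeric_pair) "correlation" else "contingency",
               score = score)
  })
  rows <- do.call(rbind, rows)
  list(score = mean(rows$score), pairs = rows)
}

#' Overall fidelity score
#'
#' Arithmetic mean of the column-shapes and column-pair-trends scores.
#'
#' @param shapes,trends Scores in `[0, 1]`, or the result lists of
#'   [column_shapes()] / [pair_trends()].
#' @return Score in `[0, 1]`.
#' @export
overall_fidelity <- function(shapes, trends) {
  s <- if (is.list(shapes)) shapes$score else shapes
  t <- if (is.list(trends)) trends$score else trends
  stopifnot(s >= 0, s <= 1, t >= 0, t <= 1)
  mean(c(s, t))
}

#' Hellinger distance between two samples
#'
#' Numeric samples are binned into `bins` equal-width bins spanning the
#' pooled range; categorical samples use their category frequencies
#' directly. With binned probability vectors p and q,
#' `H = sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))`, in `[0, 1]`: 0 for
#' identical distributions, 1 for disjoint supports.
#'
#' @param real_col,syn_col Non-empty samples.
#' @param bins Number of bins for numeric data (default 30, >= 2).
#' @param categorical Treat the samples as categorical (default guesses
#'   from type).
#' @return Distance in `[0, 1]`.
#' @export
hellinger <- function(real_col, syn_col, bins = 30,
                      categorical = !is.numeric(real_col)) {
  if (!length(real_col) || !length(syn_col)) {
    stop("empty sample", call. = FALSE)
  }
  if (categorical) {
    lev <- union(unique(real_col), unique(syn_col))
    p <- prop.table(table(factor(real_col, levels = lev)))
    q <- prop.table(table(factor(syn_col, levels = lev)))
  } else {
    stopifnot(bins >= 2)
    rng <- range(c(real_col, syn_col))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    p <- tabulate(findInterval(real_col, br, rightmost.closed = TRUE),
                  nbins = bins) / length(real_col)
    q <- tabulate(findInterval(syn_col, br, rightmost.closed = TRUE),
                  nbins = bins) / length(syn_col)
  }
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}

#' Full resemblance report between a real and a synthetic table
#'
#' Combines per-column KS/TV complements, the aggregate column-shapes
#' and pair-trends scores, the overall fidelity score (their mean), and
#' per-column plus overall (mean) Hellinger distances. The Hellinger bin
#' count is recorded alongside the scores.
#'
#' @inheritParams column_shapes
#' @param bins Hellinger bin count for numeric columns (default 30).
#' @return A list of class `fidelity_report`.
#' @export
fidelity_report <- function(real, syn, metadata = derive_metadata(real),
                            bins = 30) {
  shapes <- column_shapes(real, syn, metadata)
  trends <- pair_trends(real, syn, metadata)
  cols <- fidelity_columns(metadata)
  hd <- c(
    vapply(cols$numeric, function(col)
      hellinger(real[[col]], syn[[col]], bins = bins,
                categorical = FALSE), 0),
    vapply(cols$categorical, function(col)
      hellinger(real[[col]], syn[[col]], categorical = TRUE), 0)
  )
  structure(
    list(column_shapes = shapes$score,
         pair_trends = trends$score,
         overall = overall_fidelity(shapes$score, trends$score),
         columns = shapes$columns,
         pairs = trends$pairs,
         hellinger = hd,
         hellinger_overall = mean(hd),
         hellinger_bins = bins),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> shapes %.4f | pair trends %.4f | overall %.4f\n",
              x$column_shapes, x$pair_trends, x$overall))
  cat(sprintf("  Hellinger overall %.4f (%d bins)\n",
              x$hellinger_overall, x$hellinger_bins))
  print(x$columns, row.names = FALSE)
  invisible(x)
}
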