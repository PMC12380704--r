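#' Derive synthesis metadata from a gait table
#'
#' Summarizes the training table for the synthesizer: per-numeric-column
#' bounds (observed min/max — the domain constraints enforced at sampling
#' time), Pearson correlation matrix and skewness over the sequential
#' columns, categorical frequency tables, and the temporal keys
#' (`Timestamp` as sort key, `ID` as entity key).
#'
#' @param table Gait table, non-empty and sorted by (ID, Timestamp).
#' @param sort_key Temporal sorting column (default `"Timestamp"`).
#' @param entity_key Entity identifier column (default `"ID"`).
#' @param categorical Categorical columns (default Age, BMI,
#'   Fall_History).
#' @return A list of class `synthesis_metadata`.
#' @export
derive_metadata <- function(table, sort_key = "Timestamp",
                            entity_key = "ID",
                            categorical = GAIT_CATEGORICAL) {
  check_gait_table(table)
  if (nrow(table) < 2) {
    stop("need at least two rows to derive metadata", call. = FALSE)
  }
  stopifnot(sort_key != entity_key)
  numeric_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          c(entity_key, categorical))
  sequential <- setdiff(numeric_cols, sort_key)
  bounds <- lapply(table[numeric_cols], range)
  corr <- stats::cor(table[sequential])
  skew <- vapply(table[sequential], skewness, 0)
  freqs <- lapply(table[categorical], function(col)
    prop.table(table(col)))
  entities <- unique(table[[entity_key]])
  structure(
    list(sort_key = sort_key, entity_key = entity_key,
         numeric_cols = numeric_cols, sequential = sequential,
         categorical = categorical, bounds = bounds,
         correlation = corr, skewness = skew, frequencies = freqs,
         n_entities = length(entities), entities = entities,
         n_rows = nrow(table)),
    class = "synthesis_metadata"
  )
}

#' @export
print.synthesis_metadata <- function(x, ...) {
  cat(sprintf("<synthesis_metadata> %d rows, %d entities; sort=%s, entity=%s\n",
              x$n_rows, x$n_entities, x$sort_key, x$entity_key))
  cat("  sequential:", paste(x$sequential, collapse = ", "), "\n")
  cat("  categorical:", paste(x$categorical, collapse = ", "), "\n")
  invisible(x)
}

# normal scores of a numeric vector (average ranks, (r - 0.5)/n)
normal_scores <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Fit the Gaussian-copula time-series synthesizer
#'
#' The model captures, per sequential column: the marginal distribution
#' as the empirical quantile function of the training values; the
#' cross-column rank dependence as a Gaussian copula on normal scores;
#' the temporal structure as a lag-1 autoregressive coupling estimated
#' within entities; and between-entity heterogeneity as correlated
#' entity-level offsets. The innovation correlation is adjusted so that
#' the stationary cross-correlation of the AR(1) latents reproduces the
#' training copula correlation; any indefiniteness introduced by the
#' adjustment is repaired to the nearest positive semi-definite
#' correlation matrix (with a warning).
#'
#' @param table Training gait table.
#' @param metadata A [derive_metadata()] result consistent with `table`.
#' @param seed Integer seed recorded in the model (fitting itself is
#'   deterministic).
#' @return A list of class `synthesis_model`.
#' @export
fit_synthesizer <- function(table, metadata = derive_metadata(table),
                            seed = 1) {
  check_gait_table(table)
  stopifnot(inherits(metadata, "synthesis_metadata"))
  if (!setequal(unique(table[[metadata$entity_key]]), metadata$entities)) {
    stop("metadata entities do not match the table", call. = FALSE)
  }
  table <- table[order(table[[metadata$entity_key]],
                       table[[metadata$sort_key]]), , drop = FALSE]
  cols <- metadata$sequential
  ids <- table[[metadata$entity_key]]
  ent <- metadata$entities

  Z <- vapply(table[cols], normal_scores, numeric(nrow(table)))

  # entity decomposition on the normal-score scale
  ent_means <- do.call(rbind, lapply(ent, function(e)
    colMeans(Z[ids == e, , drop = FALSE])))
  tau <- pmin(apply(ent_means, 2, pop_sd), 0.95)
  B <- if (length(ent) > 2) {
    b <- suppressWarnings(stats::cor(ent_means))
    b[!is.finite(b)] <- 0; diag(b) <- 1
    nearest_psd(b)
  } else diag(length(cols))
  dimnames(B) <- list(cols, cols)

  # within-entity residuals, restandardized
  W <- Z - ent_means[match(ids, ent), , drop = FALSE]
  wsd <- apply(W, 2, pop_sd)
  wsd[wsd == 0] <- 1
  W <- sweep(W, 2, wsd, "/")
  Cw <- stats::cor(W)

  # lag-1 coupling within entities
  phi <- vapply(cols, function(col) {
    num <- 0; den <- 0
    for (e in ent) {
      w <- W[ids == e, col]
      if (length(w) > 2) {
        num <- num + sum(w[-1] * w[-length(w)])
        den <- den + sum(w^2)
      }
    }
    max(min(num / den, 0.98), -0.98)
  }, 0)

  # innovation correlation so the AR(1) stationary cross-correlation
  # matches Cw: C_in[a,b] = Cw[a,b] (1 - phi_a phi_b) / (s_a s_b)
  s <- sqrt(1 - phi^2)
  C_in <- Cw * (1 - outer(phi, phi)) / outer(s, s)
  diag(C_in) <- 1
  C_in[C_in > 0.999] <- 0.999
  C_in[C_in < -0.999] <- -0.999
  ev <- eigen(C_in, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("innovation correlation not positive definite; ",
            "repaired to the nearest PSD matrix", call. = FALSE)
    C_in <- nearest_psd(C_in)
  }

  # per-entity timestamp grids and categorical combos, copied at sampling
  grids <- lapply(ent, function(e) table[[metadata$sort_key]][ids == e])
  combos <- lapply(ent, function(e)
    table[ids == e, metadata$categorical, drop = FALSE][1, , drop = FALSE])

  structure(
    list(metadata = metadata,
         quantiles = lapply(table[cols], sort),
         tau = tau, B = B, Cw = nearest_psd(Cw), C_in = C_in, phi = phi,
         entities = ent, grids = grids, combos = combos,
         fit_seed = seed),
    class = "synthesis_model"
  )
}

#' @export
print.synthesis_model <- function(x, ...) {
  cat(sprintf("<synthesis_model> %d entities, %d rows; lag-1 phi in [%.2f, %.2f]\n",
              length(x$entities), x$metadata$n_rows,
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Sample a synthetic gait table
#'
#' Generates a table with the same entities, per-entity row counts and
#' timestamp grids as the training data (the grids are copied, so the
#' Timestamp column is identical as a multiset). Latent normal series
#' are drawn per entity as correlated-offset plus AR(1) processes, mapped
#' through the empirical quantile transforms, and clamped to the
#' metadata bounds. Static categorical attributes are assigned by
#' stratified proportional allocation: each synthetic entity takes the
#' attribute combination of its training counterpart, so categorical
#' frequencies are preserved exactly.
#'
#' @param model A fitted [fit_synthesizer()] model.
#' @param seed Integer seed.
#' @return A synthetic gait-table data.frame with the training table's
#'   shape.
#' @export
sample_synthetic <- function(model, seed = 1) {
  stopifnot(inherits(model, "synthesis_model"))
  set.seed(seed)
  md <- model$metadata
  cols <- md$sequential
  tau <- model$tau
  phi <- model$phi

  tabs <- vector("list", length(model$entities))
  for (e in seq_along(model$entities)) {
    n_e <- length(model$grids[[e]])
    alpha <- rmvn(1, model$B)
    w <- matrix(0, n_e, length(cols), dimnames = list(NULL, cols))
    w[1, ] <- rmvn(1, model$Cw)
    if (n_e > 1) {
      eps <- rmvn(n_e, model$C_in)
      s <- sqrt(1 - phi^2)
      for (i in 2:n_e) w[i, ] <- phi * w[i - 1, ] + s * eps[i, ]
    }
    z <- sweep(w, 2, sqrt(1 - tau^2), "*") +
      matrix(tau * alpha, n_e, length(cols), byrow = TRUE)
    u <- stats::pnorm(z)
    vals <- sapply(cols, function(col) {
      q <- stats::quantile(model$quantiles[[col]], probs = u[, col],
                           type = 8, names = FALSE)
      b <- md$bounds[[col]]
      pmin(pmax(q, b[1]), b[2])
    })
    if (n_e == 1) vals <- matrix(vals, 1, dimnames = list(NULL, cols))
    df <- data.frame(ID = model$entities[e],
                     Timestamp = model$grids[[e]],
                     stringsAsFactors = FALSE)
    df[cols] <- vals
    df[md$categorical] <- model$combos[[e]][rep(1, n_e), , drop = FALSE]
    tabs[[e]] <- df
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out[, GAIT_COLUMNS]
}

#' Build a rank-correlation constraint set
#'
#' @param ... Constraints, each a list `list(a, b, cmp, rho)` where `cmp`
#'   is `">"` or `"<"` and `rho` the Spearman threshold in (-1, 1).
#' @return A data.frame of class `constraint_set`.
#' @export
constraint_set <- function(...) {
  items <- list(...)
  out <- do.call(rbind, lapply(items, function(it) {
    stopifnot(it$cmp %in% c(">", "<"), abs(it$rho) < 1)
    data.frame(a = it$a, b = it$b, cmp = it$cmp, rho = it$rho,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(a = character(), b = character(), cmp = character(),
                      rho = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- c("constraint_set", "data.frame")
  out
}

#' The study's biomechanical constraint pair
#'
#' Step width must correlate positively with MoS (Spearman rho > 0.7,
#' the wider base of support improving stability) and CoM velocity must
#' correlate negatively with MoS (rho < -0.3, reduced control at higher
#' speeds).
#'
#' @return A [constraint_set()].
#' @export
gait_constraints <- function() {
  constraint_set(
    list(a = "Step_Width", b = "MoS", cmp = ">", rho = 0.7),
    list(a = "CoM_Velocity", b = "MoS", cmp = "<", rho = -0.3)
  )
}

#' Validate rank-correlation constraints on a table
#'
#' Computes the Spearman correlation for each constrained column pair
#' and compares it with the threshold under the strict comparator. A
#' constant column makes the correlation undefined and the constraint
#' fail, with a reason recorded.
#'
#' @param table Gait table with at least 3 rows.
#' @param constraints A [constraint_set()].
#' @return A list of class `constraint_report` with `results` (one row
#'   per constraint: observed, threshold, satisfied) and `pass`.
#' @export
check_constraints <- function(table, constraints = gait_constraints()) {
  stopifnot(nrow(table) >= 3)
  results <- as.data.frame(constraints)
  results$observed <- rep(NA_real_, nrow(results))
  results$satisfied <- rep(FALSE, nrow(results))
  results$reason <- rep("", nrow(results))
  for (i in seq_len(nrow(constraints))) {
    x <- table[[constraints$a[i]]]
    y <- table[[constraints$b[i]]]
    if (is.null(x) || is.null(y)) {
      results$reason[i] <- "column not found"
      next
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      results$reason[i] <- "constant column: correlation undefined"
      next
    }
    rho <- spearman(x, y)
    results$observed[i] <- rho
    results$satisfied[i] <- if (constraints$cmp[i] == ">")
      rho > constraints$rho[i] else rho < constraints$rho[i]
  }
  structure(list(results = as.data.frame(results),
                 pass = nrow(results) == 0 || all(results$satisfied)),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("<constraint_report> overall: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  print(x$results)
  invisible(x)
}

#' Sample until the constraint set is satisfied
#'
#' Repeatedly draws synthetic tables from the model, advancing a
#' deterministic seed sequence (`seed, seed + 1, ...`), and returns the
#' first table whose [check_constraints()] report passes. Errors when
#' `max_retries` draws are exhausted, carrying the last report.
#'
#' @param model A fitted [fit_synthesizer()] model.
#' @param constraints A [constraint_set()] (empty set returns the first
#'   sample).
#' @param max_retries Maximum number of draws (>= 1, default 10).
#' @param seed Integer seed of the first draw.
#' @return A synthetic gait table; attributes `"constraint_report"` and
#'   `"attempts"` record the validation.
#' @export
generate_validated <- function(model, constraints = gait_constraints(),
                               max_retries = 10, seed = 1) {
  stopifnot(max_retries >= 1)
  report <- NULL
  for (attempt in seq_len(max_retries)) {
    tab <- sample_synthetic(model, seed = seed + attempt - 1L)
    report <- check_constraints(tab, constraints)
    if (report$pass) {
      attr(tab, "constraint_report") <- report
      attr(tab, "attempts") <- attempt
      return(tab)
    }
  }
  msg <- paste(utils::capture.output(print(report)), collapse = "\n")
  stop(sprintf("constraints not satisfied after %d attempts:\n%s",
               max_retries, msg), call. = FALSE)
}
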