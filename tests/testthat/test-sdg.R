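test_that("metadata captures bounds, entities and the fixture correlation", {
  tab <- small_gait_table(seed = 30)
  md <- derive_metadata(tab)
  expect_equal(md$bounds$Step_Width, range(tab$Step_Width))
  expect_equal(md$n_entities, 6)
  expect_true(all(abs(vapply(md$frequencies, sum, 0) - 1) < 1e-12))
  expect_error(derive_metadata(tab[1, ]), "two rows")

  tab14 <- simulate_gait_table(fixture_spec(), seed = 31)
  md14 <- derive_metadata(tab14)
  expect_equal(md14$n_entities, 14)
  # Pearson on near-linear marginals tracks the Spearman target loosely
  expect_equal(md14$correlation["Step_Width", "MoS"], 0.768,
               tolerance = 0.05 / 0.768)

  toy <- tab[1:3, ]
  toy$Step_Width <- c(1, 2, 3)
  expect_equal(derive_metadata(toy)$bounds$Step_Width, c(1, 3))
})

test_that("fitting is deterministic and sampling preserves shape exactly", {
  tab <- small_gait_table(seed = 32)
  md <- derive_metadata(tab)
  m1 <- fit_synthesizer(tab, md, seed = 5)
  m2 <- fit_synthesizer(tab, md, seed = 5)
  expect_identical(m1, m2)

  syn <- sample_synthetic(m1, seed = 6)
  expect_equal(nrow(syn), nrow(tab))
  expect_equal(sort(unique(syn$ID)), sort(unique(tab$ID)))
  expect_equal(as.vector(table(syn$ID)), as.vector(table(tab$ID)))
  expect_identical(sample_synthetic(m1, seed = 6), syn)
  expect_false(identical(sample_synthetic(m1, seed = 7), syn))

  # timestamps are copied from the training grid (multiset identity)
  expect_equal(sort(syn$Timestamp), sort(tab$Timestamp))
  expect_equal(ks_complement(tab$Timestamp, syn$Timestamp), 1.0)
})

test_that("synthetic values always respect the metadata bounds", {
  for (seed in 1:4) {
    tab <- small_gait_table(seed = seed)
    m <- fit_synthesizer(tab, derive_metadata(tab), seed = seed)
    syn <- sample_synthetic(m, seed = seed + 100)
    for (col in c("Step_Width", "MoS", "CoM_Velocity",
                  "X_Coordinate_CoM", "Y_Coordinate_CoM")) {
      b <- m$metadata$bounds[[col]]
      expect_gte(min(syn[[col]]), b[1])
      expect_lte(max(syn[[col]]), b[2])
    }
  }
})

test_that("marginals and rank dependence are recovered at fixture scale", {
  tab <- simulate_gait_table(fixture_spec(n_participants = 14,
                                          total_rows = 5000), seed = 33)
  m <- fit_synthesizer(tab, derive_metadata(tab), seed = 8)
  syn <- sample_synthetic(m, seed = 9)
  for (col in c("Step_Width", "MoS", "CoM_Velocity")) {
    expect_gte(ks_complement(tab[[col]], syn[[col]]), 0.9)
  }
  for (pair in list(c("Step_Width", "MoS"), c("CoM_Velocity", "MoS"))) {
    rho_train <- suppressWarnings(
      cor(tab[[pair[1]]], tab[[pair[2]]], method = "spearman"))
    rho_syn <- suppressWarnings(
      cor(syn[[pair[1]]], syn[[pair[2]]], method = "spearman"))
    expect_lte(abs(rho_syn - rho_train), 0.1)
  }
})

test_that("lag-1 temporal coupling is learned and reproduced", {
  # hand-built AR(1) series with known phi, wrapped as a gait table
  set.seed(40)
  phi <- 0.8
  make_ar <- function(n) {
    x <- numeric(n); x[1] <- rnorm(1)
    for (i in 2:n) x[i] <- phi * x[i - 1] + sqrt(1 - phi^2) * rnorm(1)
    x
  }
  rows <- lapply(sprintf("E%02d", 1:5), function(id) {
    n <- 400
    data.frame(ID = id, Timestamp = (1:n - 1) / 30,
               X_Coordinate_CoM = make_ar(n), Y_Coordinate_CoM = make_ar(n),
               CoM_Velocity = make_ar(n), Step_Width = make_ar(n),
               MoS = make_ar(n), Age = 0, BMI = 1, Fall_History = 0)
  })
  tab <- do.call(rbind, rows)
  m <- fit_synthesizer(tab, derive_metadata(tab), seed = 41)
  expect_equal(unname(m$phi["MoS"]), phi, tolerance = 0.1 / phi)

  syn <- sample_synthetic(m, seed = 42)
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  per_entity <- vapply(split(syn$MoS, syn$ID), lag1, 0)
  expect_equal(mean(per_entity), phi, tolerance = 0.1 / phi)
})

test_that("constraint checking compares Spearman rho with strict thresholds", {
  n <- 1000
  tab <- data.frame(x = 1:n, y = (1:n)^2, z = -(1:n))
  cs <- constraint_set(list(a = "x", b = "y", cmp = ">", rho = 0.7),
                       list(a = "z", b = "y", cmp = "<", rho = -0.3))
  rep <- check_constraints(tab, cs)
  expect_true(rep$pass)
  expect_equal(rep$results$observed, c(1, -1))

  set.seed(43)
  ind <- data.frame(Step_Width = rnorm(n), MoS = rnorm(n),
                    CoM_Velocity = rnorm(n))
  rep2 <- check_constraints(ind, gait_constraints())
  expect_false(rep2$pass)
  expect_true(all(!rep2$results$satisfied))

  const <- data.frame(x = rep(1, 10), y = 1:10)
  rep3 <- check_constraints(const,
                            constraint_set(list(a = "x", b = "y",
                                                cmp = ">", rho = 0.5)))
  expect_false(rep3$pass)
  expect_match(rep3$results$reason[1], "constant")
})

test_that("validated generation retries deterministically and errors when exhausted", {
  tab <- small_gait_table(seed = 44)
  m <- fit_synthesizer(tab, derive_metadata(tab), seed = 10)

  syn <- generate_validated(m, gait_constraints(), max_retries = 10,
                            seed = 11)
  rep <- check_constraints(syn, gait_constraints())
  expect_true(rep$pass)
  expect_identical(generate_validated(m, gait_constraints(),
                                      max_retries = 10, seed = 11), syn)

  # empty constraint set returns the first draw
  syn0 <- generate_validated(m, constraint_set(), max_retries = 3, seed = 12)
  expect_equal(syn0$MoS, sample_synthetic(m, seed = 12)$MoS,
               ignore_attr = TRUE)

  impossible <- constraint_set(list(a = "Step_Width", b = "MoS",
                                    cmp = ">", rho = 0.995))
  expect_error(generate_validated(m, impossible, max_retries = 3, seed = 13),
               "after 3 attempts")
})
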