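test_that("trait scaling maps columns to [0,1] and zeroes constants", {
  m <- matrix(c(0, 5, 10, 7, 7, 7), 3, 2,
              dimnames = list(paste0("t", 1:3), c("g1", "g2")))
  expect_warning(sc <- scale_traits(m), class = "microsucc_scaling_warning")
  expect_equal(unname(sc[, 1]), c(0, 0.5, 1))
  expect_equal(unname(sc[, 2]), c(0, 0, 0))
  withr::with_seed(13, {
    r <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("t", 1:10), paste0("g", 1:5)))
  })
  sr <- scale_traits(r)
  expect_true(all(sr >= 0 & sr <= 1))
})

test_that("functional distances are max-scaled per metacommunity", {
  # 3-4-5 right triangle: raw distances 3, 4, 5 -> max-scaled 0.6, 0.8, 1
  tr <- matrix(c(0, 0, 4, 0, 3, 0), 3, 2,
               dimnames = list(c("t1", "t2", "t3"), c("g1", "g2")))
  d <- as.matrix(dist(tr))
  d <- d / max(d)
  expect_equal(unname(sort(d[upper.tri(d)])), c(0.6, 0.8, 1))
  # identical traits -> zero distances, degenerate flag
  same <- matrix(1, 2, 3, dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  dd <- suppressWarnings(functional_distances(same))
  expect_true(attr(dd, "degenerate"))
  expect_equal(max(dd), 0)
  # two distinct taxa -> distance forced to 1
  two <- matrix(c(0, 9, 1, 5), 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  d2 <- functional_distances(two)
  expect_equal(d2["a", "b"], 1)
})

test_that("rao_q matches the brute-force double sum", {
  expect_equal(rao_q(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2)), 0.5)
  expect_equal(rao_q(c(1, 0), matrix(0, 2, 2)), 0)
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 1.0
  d[2, 3] <- d[3, 2] <- 0.5
  expect_equal(rao_q(c(0.5, 0.3, 0.2), d), 0.32)
  expect_error(rao_q(c(0.5, 0.5), matrix(c(0, 2, 2, 0), 2)),
               class = "microsucc_scaling_violation_error")
})

test_that("ternary decomposition closes and hits its limiting cases", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 1.0
  d[2, 3] <- d[3, 2] <- 0.5
  tc <- ternary_decompose(c(0.5, 0.3, 0.2), d)
  expect_equal(tc$D, 0.38)
  expect_equal(tc$Q, 0.32)
  expect_equal(tc$R, 0.30)
  expect_equal(tc$U, 0.32 / 0.62, tolerance = 1e-9)
  one <- ternary_decompose(1, matrix(0, 1, 1))
  expect_equal(one$D, 1)
  expect_true(is.na(one$U))
  ident <- ternary_decompose(c(0.6, 0.4), matrix(0, 2, 2))
  expect_equal(ident$Q, 0)
  expect_equal(ident$R, 1 - ident$D)
  # Q invariant to adding a zero-abundance taxon
  d4 <- rbind(cbind(d, 0.7), 0.7)
  diag(d4) <- 0
  expect_equal(rao_q(c(0.5, 0.3, 0.2, 0), d4), 0.32)
})

test_that("decoupling regression recovers constructed slopes and their difference", {
  withr::with_seed(17, {
    n <- 30
    tax <- runif(2 * n, 2, 4)
    eco <- rep(c("grassland", "forest"), each = n)
    fun <- ifelse(eco == "grassland", 0.5 * tax, 0.5 * tax) + rnorm(2 * n, 0, 1e-4)
  })
  df <- tibble::tibble(sample_id = as.character(1:60), tax_H = tax,
                       fun_H = fun, ecosystem = eco)
  dec <- decoupling_regression(df)
  expect_equal(dec$per_ecosystem$slope, c(0.5, 0.5), tolerance = 1e-3)
  expect_true(all(dec$per_ecosystem$p_slope < 1e-6))
  expect_gt(dec$p_difference, 0.05) # identical slopes -> no interaction
  # differing slopes flagged
  df2 <- df
  df2$fun_H <- ifelse(eco == "grassland", 0.2 * tax, 0.8 * tax) + rnorm(60, 0, 0.01)
  dec2 <- decoupling_regression(df2)
  expect_lt(dec2$p_difference, 0.001)
  expect_error(decoupling_regression(df[1:5, ]),
               class = "microsucc_insufficient_data_error")
})

test_that("hierarchical partitioning matches the orderings oracle and sums to R2", {
  withr::with_seed(23, {
    n <- 60
    x <- as.data.frame(matrix(rnorm(n * 3), n, 3))
    y <- 1.5 * x[[1]] - 0.7 * x[[2]] + rnorm(n, 0, 0.8)
  })
  hp <- hierarchical_partitioning(y, x)
  oracle <- hp_oracle(y, x)
  expect_equal(hp$independent_contribution, oracle, tolerance = 1e-10)
  expect_equal(sum(hp$independent_contribution),
               attr(hp, "full_r_squared"), tolerance = 1e-10)
  # single predictor: contribution is its own R2
  hp1 <- hierarchical_partitioning(y, x[1])
  expect_equal(hp1$independent_contribution,
               summary(lm(y ~ x[[1]]))$r.squared, tolerance = 1e-12)
  # orthogonal designs split additively
  n2 <- 64
  a <- rep(c(-1, 1), n2 / 2)
  b <- rep(c(-1, -1, 1, 1), n2 / 4)
  y2 <- a + 0.8 * b
  hp2 <- hierarchical_partitioning(y2, data.frame(a, b))
  expect_equal(hp2$independent_contribution,
               c(summary(lm(y2 ~ a))$r.squared, summary(lm(y2 ~ b))$r.squared),
               tolerance = 1e-10)
  expect_error(hierarchical_partitioning(y, cbind(x, x, x)[, 1:7]),
               class = "microsucc_config_error")
})
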