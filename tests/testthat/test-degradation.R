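sir_fix <- function(rates, basal = 1) {
  subs <- c("glucose", "glycine", "oxalic_acid", "yeast", "lignin", "chitin")
  out <- tibble::tibble(sample_id = paste0("s", seq_len(nrow(rates))),
                        basal = basal)
  for (i in seq_along(subs)) out[[subs[i]]] <- rates[, i]
  out
}

test_that("net rates subtract basal and keep flagged negatives", {
  prof <- sir_fix(matrix(c(3, 1, 0.8, 2, 1, 1, 1, 1, 1, 1, 1, 1), 2, 6), basal = 1)
  net <- net_sir(prof)
  expect_equal(net$glucose, c(2, 0))
  expect_equal(net$glycine, c(-0.2, 1))
  flags <- attr(net, "negative_net")
  expect_equal(flags$substrate, "glycine")
  expect_equal(flags$net_rate, -0.2)
  bad <- prof[, setdiff(names(prof), "chitin")]
  expect_error(net_sir(bad), "chitin", class = "microsucc_format_error")
})

test_that("MSIR is the basal-corrected sum, order-invariant and linear", {
  prof <- sir_fix(matrix(c(3.0, 2.0, 2.0, 1.5, 1.2, 1.1), 1, 6), basal = 1)
  expect_equal(msir(prof)$msir, 4.8)
  flat <- sir_fix(matrix(1, 1, 6), basal = 1)
  expect_equal(msir(flat)$msir, 0)
  # permuting substrate columns leaves MSIR unchanged
  perm <- prof[, c("sample_id", "basal", sample(c("glucose", "glycine",
                                                  "oxalic_acid", "yeast",
                                                  "lignin", "chitin")))]
  expect_equal(msir(perm)$msir, 4.8)
  # adding c to every rate adds 6c
  plus <- prof
  for (s in c("glucose", "glycine", "oxalic_acid", "yeast", "lignin", "chitin")) {
    plus[[s]] <- plus[[s]] + 0.25
  }
  expect_equal(msir(plus)$msir, 4.8 + 6 * 0.25)
  # composition with net_sir: summing net rates gives the same number
  net <- net_sir(prof)
  expect_equal(sum(as.matrix(net[, c("glucose", "glycine", "oxalic_acid",
                                     "yeast", "lignin", "chitin")])),
               msir(prof)$msir)
})

test_that("substrate effect sizes are oriented forest-minus-grassland", {
  np <- 5
  sf <- sample_frame(data.frame(
    sample_id = paste0("s", 1:(2 * np)),
    site_id = paste0("x", 1:(2 * np)),
    pair_id = rep(paste0("P", 1:np), 2),
    stage = rep(c("managed", "forest"), each = np)
  ))
  withr::with_seed(3, {
    base <- matrix(rnorm(2 * np * 6, 2, 0.2), 2 * np, 6)
  })
  base[(np + 1):(2 * np), 5] <- base[(np + 1):(2 * np), 5] + 3 # forest lignin up
  prof <- sir_fix(base, basal = 0.5)
  prof$sample_id <- sf$sample_id
  es <- substrate_effect_sizes(prof, sf)
  lig <- es[es$substrate == "lignin", ]
  expect_gt(lig$estimate, 0) # forest higher -> positive
  expect_lt(lig$ci_low, lig$estimate)
  # identical paired values -> g = 0 everywhere
  same <- sir_fix(matrix(rep(seq(1, 2, length.out = 2 * np), 6), 2 * np, 6),
                  basal = 0)
  same$sample_id <- sf$sample_id
  same[(np + 1):(2 * np), -1] <- same[1:np, -1]
  es0 <- substrate_effect_sizes(same, sf)
  expect_true(all(abs(es0$estimate) < 1e-12))
})

test_that("MSIR regressions recover constructed couplings", {
  withr::with_seed(41, {
    n <- 40
    sf <- sample_frame(data.frame(
      sample_id = paste0("s", 1:n), site_id = paste0("x", 1:n),
      pair_id = NA, stage = rep(c("managed", "forest"), each = n / 2)
    ))
    h <- runif(n, 1, 3)
    m <- tibble::tibble(sample_id = sf$sample_id, msir = 2 + 1 * h + rnorm(n, 0, 1e-3))
  })
  div <- tibble::tibble(sample_id = sf$sample_id, c_gene_H = h)
  reg <- msir_diversity_regression(m, div, sf)
  pooled <- reg$fits[reg$fits$scope == "pooled", ]
  expect_equal(pooled$slope, 1, tolerance = 1e-2)
  expect_lt(pooled$p_slope, 1e-6)
  expect_gt(reg$interactions$p_interaction, 0.05)
  # standardized predictor and response: slope equals Pearson r
  zs <- function(x) (x - mean(x)) / sd(x)
  m2 <- tibble::tibble(sample_id = sf$sample_id, msir = zs(m$msir))
  div2 <- tibble::tibble(sample_id = sf$sample_id, c_gene_H = zs(h))
  reg2 <- msir_diversity_regression(m2, div2, sf)
  p2 <- reg2$fits[reg2$fits$scope == "pooled", ]
  expect_equal(p2$slope, p2$pearson_r, tolerance = 1e-12)
  expect_error(
    msir_diversity_regression(m, tibble::tibble(sample_id = sf$sample_id,
                                                c_gene_H = 1), sf),
    class = "microsucc_domain_error")
})
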