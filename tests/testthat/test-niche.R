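test_that("LOQ filter implements the signal-to-noise rule", {
  # constant feature: SE = 0 -> retained; single-occupancy feature removed
  m <- rbind(rep(50, 20), c(100, rep(0, 19)), rep(c(20, 30), 10))
  dimnames(m) <- list(c("even", "once", "mixed"), paste0("s", 1:20))
  # make columns comparable: work in relative terms by equal depth
  ft <- ft_fix(m, kind = "gene", marker = "metagenome")
  out <- loq_filter(ft, q = 1.65)
  rep <- attr(out, "loq_report")
  expect_true(rep$retained[rep$feature_id == "even"])
  expect_false(rep$retained[rep$feature_id == "once"])
  # hand check of the single-occupancy feature's S/N on its relative vector
  rel <- unclass(to_relative(ft))["once", ]
  expect_equal(unname(rep$snr[rep$feature_id == "once"]),
               mean(rel) / (sd(rel) / sqrt(20)))
  # q = 0 keeps everything
  expect_equal(nrow(loq_filter(ft, 0)), 3)
})

test_that("Levins breadth matches direct evaluation and its bounds", {
  even <- levins_breadth(rep(3, 4))
  expect_equal(even$breadth_B, 4)
  expect_equal(even$breadth_std, 1)
  single <- levins_breadth(c(0, 7, 0, 0))
  expect_equal(single$breadth_B, 1)
  expect_equal(single$breadth_std, 0)
  hand <- levins_breadth(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(hand$breadth_B, 10 / 3, tolerance = 1e-9)
  expect_equal(hand$breadth_std, (10 / 3 - 1) / 3, tolerance = 1e-9)
  expect_warning(nb <- levins_breadth(c(0, 0)), class = "microsucc_breadth_warning")
  expect_true(is.na(nb$breadth_B))
  # standardized breadth stays in [0,1] and rises under evening transfers
  withr::with_seed(6, {
    for (i in 1:20) {
      x <- runif(8)
      b1 <- levins_breadth(x)$breadth_std
      expect_gte(b1, 0); expect_lte(b1, 1)
      # Dalton-style transfer from the largest to the smallest entry
      hi <- which.max(x); lo <- which.min(x)
      eps <- (x[hi] - x[lo]) / 4
      y <- x; y[hi] <- y[hi] - eps; y[lo] <- y[lo] + eps
      expect_gte(levins_breadth(y)$breadth_std, b1 - 1e-12)
    }
  })
})

test_that("Levins overlap matches direct evaluation and is permutation-invariant", {
  same <- levins_overlap(c(0.2, 0.8), c(0.2, 0.8))
  expect_equal(same$O_fg, 1)
  expect_equal(same$O_gf, 1)
  expect_equal(levins_overlap(c(1, 0), c(0, 1))$symmetric, 0)
  ov <- levins_overlap(c(0.5, 0.5, 0), c(0, 0.5, 0.5))
  expect_equal(ov$O_fg, 0.5)
  expect_equal(ov$O_gf, 0.5)
  withr::with_seed(8, {
    f <- runif(6); g <- runif(6)
    perm <- sample(6)
  })
  expect_equal(levins_overlap(f[perm], g[perm])$symmetric,
               levins_overlap(f, g)$symmetric)
  expect_error(levins_overlap(c(0, 0), c(1, 1)), class = "microsucc_domain_error")
})

test_that("stage overlap summaries hit the identical/disjoint limits", {
  sf <- sf_fix(rep(c("managed", "forest"), each = 3))
  # class A: two identical-occupancy features -> overlap 1
  # class B: two disjoint features -> overlap 0
  m <- rbind(a1 = c(1, 2, 3, 1, 2, 3), a2 = c(2, 4, 6, 2, 4, 6),
             a3 = c(3, 6, 9, 3, 6, 9),
             b1 = c(5, 5, 0, 5, 5, 0), b2 = c(0, 0, 3, 0, 0, 3))
  colnames(m) <- sf$sample_id
  ft <- ft_fix(m, kind = "gene", marker = "metagenome")
  cls <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  ov <- stage_overlap_summary(ft, sf, class_map = cls, loq = NULL)
  s <- ov$summary
  expect_equal(s$mean_overlap[s$class == "A"], c(1, 1))
  expect_equal(s$mean_overlap[s$class == "B"], c(0, 0))
  expect_equal(s$sd_overlap[s$class == "A"], c(0, 0))
})

test_that("overlap trends select the constructed model", {
  stages <- c("managed", "recent", "late", "forest")
  lin <- overlap_trend(tibble::tibble(stage = stages,
                                      mean_overlap = c(0.8, 0.7, 0.6, 0.5)))
  expect_equal(lin$selected, "linear")
  expect_equal(lin$slope, -0.1, tolerance = 1e-9)
  expect_equal(lin$r_squared_linear, 1, tolerance = 1e-9)
  x <- 1:4
  par <- overlap_trend(tibble::tibble(stage = stages,
                                      mean_overlap = 0.9 - 0.1 * (x - 2.5)^2))
  expect_equal(par$selected, "quadratic")
  expect_equal(par$r_squared_quadratic, 1, tolerance = 1e-9)
  cst <- overlap_trend(tibble::tibble(stage = stages, mean_overlap = rep(0.5, 4)))
  expect_equal(cst$selected, "linear")
  expect_equal(cst$slope, 0)
  expect_error(overlap_trend(tibble::tibble(stage = stages[1:2],
                                            mean_overlap = c(0.5, 0.4))),
               class = "microsucc_insufficient_data_error")
})
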