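test_that("shannon and simpson match closed forms and respect richness bounds", {
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(c(2, 1, 1) / 4), 1.039721, tolerance = 1e-6)
  expect_equal(simpson_dominance(1), 1)
  expect_equal(simpson_dominance(rep(1 / 7, 7)), 1 / 7)
  expect_equal(simpson_dominance(c(0.5, 0.3, 0.2)), 0.38)
  expect_error(shannon(c(0.5, 0.6)), class = "microsucc_domain_error")
  expect_error(shannon(c(-0.1, 1.1)), class = "microsucc_domain_error")
  # H <= ln(richness) across random tables
  withr::with_seed(2, {
    for (i in 1:25) {
      p <- runif(sample(2:30, 1))
      p <- p / sum(p)
      expect_lte(shannon(p), log(length(p)) + 1e-12)
    }
  })
})

test_that("Bray-Curtis matches direct evaluation and vegan on matrices", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(1, 2, 1)), 3 / 7)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), class = "microsucc_domain_error")
  withr::with_seed(9, {
    m <- matrix(rpois(40, 10), 8, 5)
  })
  ft <- ft_fix(m)
  d <- as.matrix(bray_curtis_matrix(ft))
  expect_equal(d[1, 2], bray_curtis(m[, 1], m[, 2]))
  expect_equal(d[3, 5], bray_curtis(m[, 3], m[, 5]))
})

test_that("PCoA recovers 1-D configurations and reports its eigenvalues", {
  x <- c(0, 3, 4)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:3)
  fit <- pcoa(d, k = 2)
  rec <- fit$coordinates$PCo1
  # recovery up to sign and centering
  expect_equal(abs(cor(rec, x)), 1, tolerance = 1e-9)
  expect_equal(sort(abs(diff(sort(rec)))), sort(abs(diff(sort(x)))),
               tolerance = 1e-9)
  # eigenvalue sum equals trace of the double-centered matrix
  g <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  expect_equal(sum(fit$eigenvalues), sum(diag(g)), tolerance = 1e-9)
  expect_error(pcoa(d, k = 3), class = "microsucc_domain_error")
})

test_that("BH adjustment is monotone, order-preserving and matches the toy case", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(4, p <- runif(20))
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), class = "microsucc_domain_error")
})

test_that("stage comparisons match the hand-ranked Kruskal-Wallis toy", {
  sf <- sf_fix(c("managed", "managed", "forest", "forest"))
  kw <- stage_comparisons(c(1, 2, 3, 4), sf, "kruskal_wallis")
  expect_equal(kw$statistic, 2.4)
  pw <- stage_comparisons(c(1, 2, 3, 4), sf, "wilcoxon_pairwise")
  expect_equal(nrow(pw), 1)
  deg <- stage_comparisons(rep(1, 4), sf, "kruskal_wallis")
  expect_true(deg$degenerate)
})

test_that("response-shape classifier identifies constructed shapes", {
  withr::with_seed(21, {
    sf <- sf_fix(rep(c("managed", "recent", "late", "forest"), each = 10))
    x <- as.integer(sf$stage)
    flat <- response_shape(rnorm(40, 5, 0.5), sf)
    lin <- response_shape(x + rnorm(40, 0, 0.05), sf)
    thr <- response_shape(ifelse(x == 4, 3, 1) + rnorm(40, 0, 0.1), sf)
    uni <- response_shape(-(x - 2.5)^2 + rnorm(40, 0, 0.05), sf)
  })
  expect_equal(flat$shape, "flat")
  expect_equal(lin$shape, "linear")
  expect_equal(thr$shape, "threshold")
  expect_equal(uni$shape, "unimodal")
  sf3 <- sf_fix(c("managed", "recent", "late"))
  expect_error(response_shape(1:3, sf3), class = "microsucc_insufficient_data_error")
})
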