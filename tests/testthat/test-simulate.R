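test_that("config validation catches impossible settings", {
  expect_error(sim_config(n_pairs = 1), class = "microsucc_config_error")
  expect_error(sim_config(disjointness = 1.2), class = "microsucc_config_error")
  expect_error(sim_config(response_shape = list(pH = "wiggly")),
               class = "microsucc_config_error")
  expect_error(sim_config(gene_families = c(C = 5, N = 30, P = 30),
                          n_blocks = 12),
               class = "microsucc_config_error")
})

test_that("environment simulation respects shapes and is seed-deterministic", {
  cfg_flat <- null_config(n_pairs = 12, seed = 2)
  env <- simulate_environment(cfg_flat)
  agg <- tapply(env$pH, as.character(env$stage), mean)
  # flat: all stage means near the common baseline
  expect_true(all(abs(agg - 6.2) < 0.4))

  cfg_thr <- sim_config(n_pairs = 30, seed = 2,
                        env_noise_sd = c(pH = 0.01, CN_ratio = 1.5,
                                         SOC = 0.8, LDMC_cwm = 15))
  envt <- simulate_environment(cfg_thr)
  m <- tapply(envt$pH, as.character(envt$stage), mean)
  expect_true(all(abs(m[c("managed", "recent", "late")] - 6.2) < 0.05))
  expect_lt(abs(m[["forest"]] - 4.5), 0.05)

  expect_identical(simulate_environment(cfg_thr), simulate_environment(cfg_thr))
  expect_true(all(env$pair_distance_km < 6.5))
  # each pair has one grassland and one forest member
  expect_equal(sort(suppressWarnings(paired_ids(env))), sort(unique(env$pair_id)))
})

test_that("taxa simulation builds the programmed repertoire structure", {
  # disjointness 1, two specialists -> no shared families
  cfg <- sim_config(taxa_pool = 10, generalist_fraction = 0.8,
                    disjointness = 1, n_blocks = 2,
                    gene_families = c(C = 24, N = 12, P = 12), seed = 5)
  tx <- simulate_taxa(cfg)
  spec <- tx$niche$taxon[tx$niche$guild == "specialist"]
  expect_length(spec, 2)
  r1 <- unclass(tx$traits)[spec[1], ] > 0
  r2 <- unclass(tx$traits)[spec[2], ] > 0
  expect_equal(sum(r1 & r2), 0)

  # disjointness 0: specialists follow the generalist rule exactly, so
  # repertoires are nested and Jaccard structure matches the generalists'
  cfg0 <- sim_config(taxa_pool = 10, generalist_fraction = 0.8,
                     disjointness = 0, n_blocks = 2,
                     gene_families = c(C = 24, N = 12, P = 12), seed = 5)
  tx0 <- simulate_taxa(cfg0)
  m0 <- unclass(tx0$traits) > 0
  sizes <- rowSums(m0)
  for (a in 1:9) for (b in (a + 1):10) {
    expect_equal(sum(m0[a, ] & m0[b, ]), min(sizes[a], sizes[b])) # nested
  }

  # zero genome-size spread -> identical repertoire sizes within guild
  cfgz <- sim_config(genome_size_lognormal = c(meanlog = log(0.25), sdlog = 0),
                     specialist_size_multiplier = 1, disjointness = 0, seed = 1)
  txz <- simulate_taxa(cfgz)
  expect_equal(length(unique(txz$niche$repertoire_size)), 1)
  # generalists sit at high pH, specialists at low pH
  tx2 <- simulate_taxa(sim_config(seed = 9))
  opt <- tapply(tx2$niche$pH_optimum, tx2$niche$guild, mean)
  expect_gt(opt[["generalist"]], opt[["specialist"]])
})

test_that("count simulation respects niche filtering limits", {
  cfg <- sim_config(n_pairs = 6, seed = 3)
  env <- simulate_environment(cfg)
  tx <- simulate_taxa(cfg)
  counts <- simulate_counts(cfg, env, tx)
  expect_equal(dim(counts), c(cfg$taxa_pool, nrow(env)))
  expect_true(all(colSums(counts) >= 100))
  # infinite niche width: guild filtering off, composition similar across stages
  cfgw <- sim_config(n_pairs = 20, niche_width = 1e6, taxon_sample_sd = 0.1,
                     seed = 3)
  envw <- simulate_environment(cfgw)
  txw <- simulate_taxa(cfgw)
  cw <- simulate_counts(cfgw, envw, txw)
  rel <- unclass(to_relative(cw))
  spec_ids <- txw$niche$guild == "specialist"
  spec_share <- colSums(rel[spec_ids, ])
  by_eco <- tapply(spec_share, envw$ecosystem, mean)
  expect_lt(abs(by_eco[["forest"]] - by_eco[["grassland"]]), 0.05)
})

test_that("metagenome derivation is the exact linear map at zero noise", {
  tr <- trait_matrix(matrix(c(2, 0, 1), 1, 3,
                            dimnames = list("t1", c("C1", "C2", "N1"))),
                     c(C1 = "C", C2 = "C", N1 = "N"))
  otu <- ft_fix(matrix(10, 1, 1, dimnames = list("t1", "s1")))
  g <- simulate_metagenome(otu, tr, gene_noise = 0)
  expect_equal(unname(unclass(g)[, 1]), c(20, 0, 10))
  # all-zero OTU column stays all-zero
  otu2 <- ft_fix(matrix(c(10, 0), 1, 2, dimnames = list("t1", c("s1", "s2"))))
  g2 <- simulate_metagenome(otu2, tr, gene_noise = 0)
  expect_equal(unname(unclass(g2)[, 2]), c(0, 0, 0))
  # random small case equals the brute-force product
  withr::with_seed(19, {
    tm <- matrix(rpois(12, 2), 4, 3,
                 dimnames = list(paste0("t", 1:4), paste0("g", 1:3)))
    cm <- matrix(rpois(8, 50), 4, 2,
                 dimnames = list(paste0("t", 1:4), paste0("s", 1:2)))
  })
  trr <- trait_matrix(tm, setNames(rep("C", 3), paste0("g", 1:3)))
  gg <- simulate_metagenome(ft_fix(cm), trr, gene_noise = 0)
  brute <- matrix(0, 3, 2)
  for (f in 1:3) for (s in 1:2) brute[f, s] <- sum(cm[, s] * tm[, f])
  expect_equal(unname(bare(gg)), brute)
  # misaligned taxa rejected
  bad <- ft_fix(matrix(1, 1, 1, dimnames = list("zz", "s1")))
  expect_error(simulate_metagenome(bad, tr), class = "microsucc_alignment_error")
})

test_that("SIR simulation couples rates to class diversity as programmed", {
  cfg <- sim_config(n_pairs = 10, sir_coupling_beta = 0, sir_noise_sd = 0.01,
                    seed = 4)
  sim <- simulate_dataset(cfg)
  cd <- c_gene_diversity(sim$gene)
  m <- msir(sim$sir)
  fit <- lm(m$msir ~ cd$c_class_H_sum)
  expect_gt(summary(fit)$coefficients[2, 4], 0.01) # beta 0 -> no slope
  # beta 1, tiny noise: rate difference tracks class-H difference one-to-one
  cfg1 <- sim_config(n_pairs = 10, sir_coupling_beta = 1, sir_noise_sd = 1e-6,
                     sir_basal = c(mean = 1, sd = 0), seed = 4)
  sim1 <- simulate_dataset(cfg1)
  h <- microsucc:::class_shannon(sim1$gene, attr(sim1$gene, "substrate_class"))
  net <- net_sir(sim1$sir)
  d_rate <- net$glucose[1] - net$glucose[2]
  d_h <- unname(h[1, "glucose"] - h[2, "glucose"])
  expect_equal(d_rate, d_h, tolerance = 1e-4)
})

test_that("identical config and seed give byte-identical datasets on disk", {
  cfg <- sim_config(n_pairs = 4, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
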