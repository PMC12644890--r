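#' Configuration for the paired-site succession simulator
#'
#' The generator emulates the paired grassland-forest design: `n_pairs`
#' site pairs, each with one grassland sample (stage managed, recent or late,
#' assigned round-robin) and one adjacent forest sample. Environmental
#' covariates follow per-covariate response shapes over the ordered stages;
#' taxa belong to a generalist guild (shared, nested "core-first" gene
#' repertoires, pH optima near the grassland mean) or a specialist guild
#' (repertoires mixing the shared core with private gene blocks in proportion
#' `disjointness`, larger genomes, pH optima near the forest mean).
#' Communities arise from Gaussian environmental filtering on pH plus
#' lognormal taxon and taxon-by-sample effects, sequenced as multinomial
#' counts at negative-binomial depth; gene tables are the taxon-by-gene copy
#' product with optional Poisson resampling; substrate-induced respiration
#' couples each substrate's rate to the Shannon diversity of that substrate
#' class's C-cycling genes with slope `sir_coupling_beta`.
#'
#' @param n_pairs Number of grassland-forest site pairs (>= 2).
#' @param taxa_pool Total number of taxa across both guilds.
#' @param generalist_fraction Fraction of taxa in the generalist guild.
#' @param disjointness Specialist gene-pool disjointness in \[0, 1\]; 0 makes
#'   specialists draw from the shared pool exactly like generalists, 1 makes
#'   their repertoires fully private.
#' @param n_blocks Number of private specialist gene blocks per nutrient
#'   class (specialists are assigned round-robin; two specialists in
#'   different blocks share no private families). The default `NULL` gives
#'   every specialist its own block, so at disjointness 1 any two
#'   specialists share no gene families at all; block capacity then caps the
#'   private part of a repertoire at roughly pool size / number of
#'   specialists.
#' @param gene_families Named integer vector: families per nutrient class.
#' @param response_shape Named list/character: shape per covariate, each of
#'   `"flat"`, `"linear"`, `"unimodal"`, `"threshold"`.
#' @param effect_sizes Named numeric: full-gradient effect per covariate (the
#'   mean shift reached at the forest stage).
#' @param threshold_stage Stage at which threshold covariates step.
#' @param baseline Named numeric: grassland (managed) covariate means.
#' @param env_noise_sd Named numeric: per-covariate sample noise SD.
#' @param niche_width Gaussian pH-filter width (pH units).
#' @param optimum_sd SD of per-taxon pH optima around the guild mean.
#' @param taxon_sd SD of the per-taxon lognormal abundance effect.
#' @param taxon_sample_sd SD of the per-taxon-per-sample lognormal noise.
#' @param genome_size_lognormal `c(meanlog, sdlog)` of the repertoire-size
#'   fraction (fraction of each class pool carried by a taxon).
#' @param specialist_size_multiplier Multiplier on specialist repertoire
#'   sizes (larger genomes).
#' @param depth_model `c(mean, dispersion)` of the negative-binomial read
#'   depth per sample.
#' @param gene_noise Non-negative; > 0 Poisson-resamples the gene table.
#' @param sir_coupling_beta Slope linking substrate rates to substrate-class
#'   gene Shannon diversity.
#' @param sir_basal `c(mean, sd)` of per-sample basal respiration.
#' @param sir_alpha Per-substrate rate offset (single value recycled).
#' @param sir_noise_sd SD of the rate measurement noise.
#' @param seed Integer seed; every draw of the generator flows through it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 20,
                       taxa_pool = 120,
                       generalist_fraction = 0.7,
                       disjointness = 0.8,
                       n_blocks = NULL,
                       gene_families = c(C = 60, N = 30, P = 30),
                       response_shape = list(pH = "threshold",
                                             CN_ratio = "threshold",
                                             SOC = "linear",
                                             LDMC_cwm = "linear"),
                       effect_sizes = c(pH = -1.7, CN_ratio = 8,
                                        SOC = 2, LDMC_cwm = 60),
                       threshold_stage = "forest",
                       baseline = c(pH = 6.2, CN_ratio = 12,
                                    SOC = 4, LDMC_cwm = 180),
                       env_noise_sd = c(pH = 0.25, CN_ratio = 1.5,
                                        SOC = 0.8, LDMC_cwm = 15),
                       niche_width = 0.5,
                       optimum_sd = 0.3,
                       taxon_sd = 0.5,
                       taxon_sample_sd = 1,
                       genome_size_lognormal = c(meanlog = log(0.25), sdlog = 0.2),
                       specialist_size_multiplier = 1.3,
                       depth_model = c(mean = 4000, dispersion = 10),
                       gene_noise = 1,
                       sir_coupling_beta = 1,
                       sir_basal = c(mean = 1, sd = 0.2),
                       sir_alpha = 0.5,
                       sir_noise_sd = 0.1,
                       seed = 1L) {
  cfg <- list(n_pairs = n_pairs, taxa_pool = taxa_pool,
              generalist_fraction = generalist_fraction,
              disjointness = disjointness, n_blocks = n_blocks,
              gene_families = gene_families,
              response_shape = response_shape, effect_sizes = effect_sizes,
              threshold_stage = threshold_stage, baseline = baseline,
              env_noise_sd = env_noise_sd, niche_width = niche_width,
              optimum_sd = optimum_sd, taxon_sd = taxon_sd,
              taxon_sample_sd = taxon_sample_sd,
              genome_size_lognormal = genome_size_lognormal,
              specialist_size_multiplier = specialist_size_multiplier,
              depth_model = depth_model, gene_noise = gene_noise,
              sir_coupling_beta = sir_coupling_beta, sir_basal = sir_basal,
              sir_alpha = sir_alpha, sir_noise_sd = sir_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pairs < 2) ms_abort("n_pairs must be >= 2.", "config_error")
  for (p in c("generalist_fraction", "disjointness")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      ms_abort(paste0(p, " must lie in [0, 1]."), "config_error")
    }
  }
  shapes <- unlist(cfg$response_shape)
  bad <- setdiff(shapes, c("flat", "linear", "unimodal", "threshold"))
  if (length(bad)) {
    ms_abort(paste0("unknown response shape(s): ", paste(bad, collapse = ", ")),
             "config_error")
  }
  if (!is.null(cfg$n_blocks) && any(cfg$gene_families < cfg$n_blocks)) {
    ms_abort("each class needs at least n_blocks gene families.", "config_error")
  }
  if (cfg$niche_width <= 0 || cfg$taxa_pool < 2) {
    ms_abort("niche_width must be > 0 and taxa_pool >= 2.", "config_error")
  }
  invisible(cfg)
}

#' A null configuration with no succession signal
#'
#' All covariate shapes flat, specialist disjointness 0, SIR coupling 0, and
#' homogeneous genomes (repertoire-size sdlog 0, specialist size multiplier
#' 1, so every taxon carries the identical core repertoire). The last point
#' matters: the scientific null of the decoupling analysis is perfect
#' functional redundancy, under which replacing taxa leaves the functional
#' gene pool unchanged; genome-size heterogeneity is itself a mild
#' specialization signal and would couple functional to taxonomic diversity
#' even without guild structure. Under this configuration grassland and
#' forest samples are exchangeable and downstream tests reject at no more
#' than their nominal level.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @export
null_config <- function(...) {
  sim_config(response_shape = list(pH = "flat", CN_ratio = "flat",
                                   SOC = "flat", LDMC_cwm = "flat"),
             disjointness = 0, sir_coupling_beta = 0,
             genome_size_lognormal = c(meanlog = log(0.25), sdlog = 0),
             specialist_size_multiplier = 1, ...)
}

# stage means for one covariate under a response shape
stage_means <- function(base, effect, shape, threshold_stage) {
  r <- seq_along(stage_levels())
  off <- switch(shape,
    flat = rep(0, 4),
    linear = effect * (r - 1) / 3,
    unimodal = effect * (1 - ((r - 2.5) / 1.5)^2),
    threshold = effect * as.numeric(r >= match(threshold_stage, stage_levels()))
  )
  stats::setNames(base + off, stage_levels())
}

#' Simulate the paired-site environment
#'
#' One grassland sample (stage assigned round-robin over managed/recent/late)
#' and one forest sample per pair; covariates are Normal around
#' shape-dependent stage means; pair distance is Uniform(0.1, 6.5) km and
#' shared within a pair, as are climate and parent material.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default derived from `cfg$seed`).
#' @return A sample frame tibble (see [sample_frame()]).
#' @export
simulate_environment <- function(cfg, seed = cfg$seed) {
  with_rng(seed, {
    np <- cfg$n_pairs
    g_stage <- rep(c("managed", "recent", "late"), length.out = np)
    sf <- tibble(
      sample_id = c(sprintf("P%02d_G", seq_len(np)), sprintf("P%02d_F", seq_len(np))),
      site_id = c(sprintf("S%02dg", seq_len(np)), sprintf("S%02df", seq_len(np))),
      pair_id = rep(sprintf("P%02d", seq_len(np)), 2),
      stage = c(g_stage, rep("forest", np))
    )
    dist_km <- stats::runif(np, 0.1, 6.5)
    mat <- stats::rnorm(np, 6, 2)
    map <- stats::rnorm(np, 600, 100)
    pm <- sample(c("till", "sediment", "peat"), np, replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
    idx <- rep(seq_len(np), 2)
    sf$pair_distance_km <- dist_km[idx]
    sf$MAT <- mat[idx]
    sf$MAP <- map[idx]
    sf$parent_material <- pm[idx]
    covs <- names(cfg$baseline)
    for (cv in covs) {
      mu <- stage_means(cfg$baseline[[cv]], cfg$effect_sizes[[cv]],
                        cfg$response_shape[[cv]] %||% "flat",
                        cfg$threshold_stage)
      sf[[cv]] <- stats::rnorm(nrow(sf), mu[as.character(sf$stage)],
                               cfg$env_noise_sd[[cv]])
    }
    sf$total_N <- sf$SOC / pmax(sf$CN_ratio, 1)
    sf$stand_age <- ifelse(sf$stage == "forest",
                           round(stats::runif(nrow(sf), 30, 120)), NA)
    sf$stand_evenness <- ifelse(sf$stage == "forest",
                                stats::runif(nrow(sf), 0.2, 1), NA)
    sf$AGS <- stats::rlnorm(nrow(sf), log(4e6), 0.1)
    sample_frame(sf)
  })
}

#' Simulate taxa, guilds and gene repertoires
#'
#' Gene families of each nutrient class form an ordered pool; generalists
#' carry the first `r_t` families ("core-first" nesting, so repertoire
#' overlap is high). Specialists carry a fraction `1 - disjointness` of
#' theirs from the same core order and the rest from a private block (their
#' block's families taken from the tail of the pool), so at disjointness 0
#' they are indistinguishable from generalists and at disjointness 1 two
#' specialists in different blocks share no families. Copy numbers are a
#' per-family property (1 + Poisson(1)). Repertoire sizes are lognormal
#' fractions of the class pool, specialists scaled up by
#' `specialist_size_multiplier`. Generalist pH optima are Normal around the
#' grassland baseline pH, specialist optima around baseline + the pH effect
#' (4.5 under the default gradient).
#'
#' @inheritParams simulate_environment
#' @return A list: `traits` (a [trait_matrix()]), `niche` (tibble of taxon,
#'   guild, block, pH optimum, repertoire size), `copy_number` (per-family).
#' @export
simulate_taxa <- function(cfg, seed = cfg$seed + 1L) {
  with_rng(seed, {
    nt <- cfg$taxa_pool
    n_gen <- round(cfg$generalist_fraction * nt)
    n_spec <- nt - n_gen
    guild <- rep(c("generalist", "specialist"), c(n_gen, n_spec))
    taxa <- sprintf("t%03d", seq_len(nt))
    classes <- names(cfg$gene_families)
    fam_ids <- unlist(lapply(classes, function(cl) {
      sprintf("%s%03d", cl, seq_len(cfg$gene_families[[cl]]))
    }))
    fam_class <- stats::setNames(rep(classes, cfg$gene_families), fam_ids)
    copy_number <- stats::setNames(1 + stats::rpois(length(fam_ids), 1), fam_ids)

    gl <- cfg$genome_size_lognormal
    frac <- stats::rlnorm(nt, gl[["meanlog"]], gl[["sdlog"]])
    frac <- frac * ifelse(guild == "specialist", cfg$specialist_size_multiplier, 1)
    frac <- pmin(pmax(frac, 0.02), 0.95)

    nb <- cfg$n_blocks %||% max(1L, n_spec)
    block_of <- integer(nt)
    block_of[guild == "specialist"] <- rep_len(seq_len(nb), n_spec)

    tm <- matrix(0, nt, length(fam_ids), dimnames = list(taxa, fam_ids))
    for (cl in classes) {
      fams <- fam_ids[fam_class == cl]
      nf <- length(fams)
      nb_cl <- min(nb, nf) # a class cannot host more blocks than families
      # private block orders: interleaved families, taken from the pool tail
      block_members <- lapply(seq_len(nb_cl), function(b) {
        rev(fams[seq(b, nf, by = nb_cl)])
      })
      for (t in seq_len(nt)) {
        r <- max(1L, round(frac[t] * nf))
        if (guild[t] == "generalist" || cfg$disjointness == 0) {
          pick <- fams[seq_len(min(r, nf))]
        } else {
          n_priv <- round(cfg$disjointness * r)
          n_core <- r - n_priv
          priv <- block_members[[(block_of[t] - 1L) %% nb_cl + 1L]]
          pick <- c(if (n_core > 0) fams[seq_len(min(n_core, nf))],
                    priv[seq_len(min(n_priv, length(priv)))])
          pick <- unique(pick)
        }
        tm[t, pick] <- copy_number[pick]
      }
    }
    pH_grass <- cfg$baseline[["pH"]]
    pH_forest <- pH_grass + cfg$effect_sizes[["pH"]]
    optimum <- stats::rnorm(nt,
                            ifelse(guild == "generalist", pH_grass, pH_forest),
                            cfg$optimum_sd)
    subs <- sir_substrates()
    c_fams <- fam_ids[fam_class == "C"]
    substrate_class <- stats::setNames(rep_len(subs, length(c_fams)), c_fams)
    list(
      traits = trait_matrix(tm, fam_class, substrate_class),
      niche = tibble(taxon = taxa, guild = guild,
                     block = ifelse(guild == "specialist", block_of, NA_integer_),
                     pH_optimum = optimum,
                     repertoire_size = rowSums(tm > 0)),
      copy_number = copy_number
    )
  })
}

#' Simulate OTU counts under Gaussian pH filtering
#'
#' Expected relative abundance of taxon t in sample s is
#' `exp(-(pH_s - opt_t)^2 / (2 w^2))` times a lognormal per-taxon effect and
#' a lognormal taxon-by-sample noise; counts are one multinomial draw per
#' sample at negative-binomial depth.
#'
#' @inheritParams simulate_environment
#' @param env Sample frame from [simulate_environment()].
#' @param taxa Output of [simulate_taxa()].
#' @return A `feature_table` of OTU counts (`kind = "otu"`).
#' @export
simulate_counts <- function(cfg, env, taxa, seed = cfg$seed + 2L) {
  with_rng(seed, {
    nt <- nrow(taxa$niche)
    ns <- nrow(env)
    taxon_eff <- stats::rnorm(nt, 0, cfg$taxon_sd)
    opt <- taxa$niche$pH_optimum
    w2 <- 2 * cfg$niche_width^2
    logw <- -outer(opt, env$pH, function(o, p) (p - o)^2) / w2 +
      taxon_eff +
      matrix(stats::rnorm(nt * ns, 0, cfg$taxon_sample_sd), nt, ns)
    pr <- exp(sweep(logw, 2, apply(logw, 2, max))) # stabilise
    depth <- pmax(stats::rnbinom(ns, mu = cfg$depth_model[["mean"]],
                                 size = cfg$depth_model[["dispersion"]]), 100L)
    counts <- vapply(seq_len(ns), function(s) {
      stats::rmultinom(1, depth[s], pr[, s])[, 1]
    }, numeric(nt))
    dimnames(counts) <- list(taxa$niche$taxon, env$sample_id)
    feature_table(counts, kind = "otu", marker = "16S")
  })
}

#' Derive a gene-family table from OTU counts and gene repertoires
#'
#' Gene abundance is the linear map `t(traits) %*% counts` (copies times
#' taxon counts), optionally Poisson-resampled around that expectation when
#' `gene_noise > 0` (sequencing noise stand-in). `gene_noise = 0` returns the
#' exact product.
#'
#' @param otu OTU `feature_table`.
#' @param traits A [trait_matrix()] over the same taxa.
#' @param gene_noise Non-negative scalar (see above).
#' @param seed Integer seed.
#' @return A `feature_table` (`kind = "gene"`, `marker = "metagenome"`)
#'   carrying the trait matrix's class maps as attributes `family_class` and
#'   `substrate_class`.
#' @export
simulate_metagenome <- function(otu, traits, gene_noise = 1, seed = 1L) {
  if (!identical(rownames(traits), feature_ids(otu))) {
    ms_abort("trait matrix taxa must match the OTU table's features.",
             "alignment_error")
  }
  g <- t(unclass(traits)) %*% unclass(otu)
  if (gene_noise > 0) {
    g[] <- with_rng(seed, stats::rpois(length(g), lambda = g))
  }
  out <- feature_table(g, kind = "gene", marker = "metagenome")
  attr(out, "family_class") <- family_classes(traits)
  attr(out, "substrate_class") <- substrate_classes(traits)
  out
}

# Shannon diversity of each substrate class's genes, per sample
class_shannon <- function(gene, substrate_class) {
  m <- unclass(gene)
  subs <- sir_substrates()
  out <- matrix(0, ncol(m), length(subs),
                dimnames = list(colnames(m), subs))
  for (s in subs) {
    fams <- names(substrate_class)[substrate_class == s]
    fams <- intersect(fams, rownames(m))
    sub <- m[fams, , drop = FALSE]
    tot <- colSums(sub)
    out[, s] <- vapply(seq_len(ncol(sub)), function(j) {
      if (tot[j] == 0) return(0)
      shannon(sub[, j] / tot[j])
    }, numeric(1))
  }
  out
}

#' Simulate substrate-induced respiration coupled to gene diversity
#'
#' `rate_s = basal + alpha_s + beta * H'(substrate-class C genes) + noise`
#' per sample and substrate, with per-sample basal rates. With `beta = 0`
#' rates are independent of gene diversity.
#'
#' @param gene Gene `feature_table` from [simulate_metagenome()] (must carry
#'   a `substrate_class` attribute).
#' @inheritParams simulate_environment
#' @return A tibble: `sample_id`, `basal`, one column per substrate (raw
#'   rates, basal not yet subtracted).
#' @export
simulate_sir <- function(gene, cfg, seed = cfg$seed + 4L) {
  sc <- attr(gene, "substrate_class")
  if (is.null(sc)) ms_abort("gene table lacks a substrate_class map.", "config_error")
  with_rng(seed, {
    ns <- ncol(gene)
    h <- class_shannon(gene, sc)
    basal <- pmax(stats::rnorm(ns, cfg$sir_basal[["mean"]], cfg$sir_basal[["sd"]]),
                  0.05)
    subs <- sir_substrates()
    rates <- sapply(subs, function(s) {
      unname(basal + cfg$sir_alpha + cfg$sir_coupling_beta * h[, s] +
               stats::rnorm(ns, 0, cfg$sir_noise_sd))
    })
    out <- tibble(sample_id = sample_ids(gene), basal = basal)
    for (s in subs) out[[s]] <- rates[, s]
    out
  })
}

#' Simulate a complete paired-site dataset
#'
#' Runs environment, taxa, counts, metagenome and SIR generation under one
#' base seed (each stage on a fixed offset of it, so standalone calls with
#' the defaults reproduce the pipeline's tables) and attaches the ground
#' truth needed for recovery tests.
#'
#' @inheritParams simulate_environment
#' @return A list: `sf`, `otu`, `gene`, `traits`, `sir`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  sf <- simulate_environment(cfg)
  taxa <- simulate_taxa(cfg)
  otu <- simulate_counts(cfg, sf, taxa)
  gene <- simulate_metagenome(otu, taxa$traits, gene_noise = cfg$gene_noise,
                              seed = cfg$seed + 3L)
  sir <- simulate_sir(gene, cfg)
  truth <- list(
    stage_covariate_means = lapply(names(cfg$baseline), function(cv) {
      as.list(stage_means(cfg$baseline[[cv]], cfg$effect_sizes[[cv]],
                          cfg$response_shape[[cv]] %||% "flat",
                          cfg$threshold_stage))
    }) |> stats::setNames(names(cfg$baseline)),
    niche = taxa$niche,
    sir_coupling_beta = cfg$sir_coupling_beta,
    disjointness = cfg$disjointness,
    expected_orderings = list(
      shannon_grassland_gt_forest = cfg$response_shape[["pH"]] != "flat",
      Q_forest_gt_grassland = cfg$disjointness > 0.5 &&
        cfg$response_shape[["pH"]] != "flat",
      R_grassland_gt_forest = cfg$disjointness > 0.5 &&
        cfg$response_shape[["pH"]] != "flat"
    )
  )
  list(sf = sf, otu = otu, gene = gene, traits = taxa$traits, sir = sir,
       truth = truth, config = cfg)
}

#' Write a simulated dataset to a directory
#'
#' Emits `otu.tsv`, `genes.tsv`, `traits.tsv` (+ class map), `samples.tsv`,
#' `sir.tsv` and `truth.json`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(sim$otu, file.path(dir, "otu.tsv"))
  write_feature_table(sim$gene, file.path(dir, "genes.tsv"))
  write_trait_matrix(sim$traits, file.path(dir, "traits.tsv"))
  write_sample_frame(sim$sf, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$sir, file.path(dir, "sir.tsv"))
  truth <- sim$truth
  truth$niche <- as.list(truth$niche)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
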