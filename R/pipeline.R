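#' Pipeline run configuration
#'
#' Either a `simulate` block (arguments for [sim_config()]) or a set of
#' input paths (`otu`, `genes`, `traits`, `samples`, `sir`) must be given.
#' Defaults follow the study conventions: SRS at `cmin` 3000 (16S-like) for
#' OTU tables with rarefaction for functional tables, LOQ threshold 1.65,
#' 10000 community permutations, 9999 ternary permutations, alpha 0.05.
#'
#' @param simulate Named list of [sim_config()] overrides, or `NULL`.
#' @param inputs Named list of file paths, or `NULL`.
#' @param cmin_otu,cmin_gene Normalization depths; `NULL` uses the observed
#'   minimum column sum.
#' @param loq LOQ signal-to-noise threshold.
#' @param n_perm_community,n_perm_ternary Permutation counts.
#' @param alpha Test level.
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       cmin_otu = NULL, cmin_gene = NULL,
                       loq = 1.65, n_perm_community = 10000,
                       n_perm_ternary = 9999, alpha = 0.05,
                       seed = 1L, out_dir = tempfile("microsucc_run_")) {
  if (is.null(simulate) && is.null(inputs)) {
    ms_abort("config needs either a `simulate` block or `inputs` paths.",
             "config_error")
  }
  structure(list(simulate = simulate, inputs = inputs,
                 cmin_otu = cmin_otu, cmin_gene = cmin_gene, loq = loq,
                 n_perm_community = n_perm_community,
                 n_perm_ternary = n_perm_ternary, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields above.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_tsv_stable <- function(df, path) {
  # fixed 15-significant-digit formatting so identical runs are byte-identical
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    }
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the full succession analysis pipeline
#'
#' Stages, in order: simulate (or load), preprocess (SRS for the OTU table,
#' rarefaction for the gene table), per-sample diversity + stage tests +
#' paired effect sizes + response shapes, community perMANOVA and PCoA,
#' LOQ filtering + niche-overlap summaries + trend fits, ternary redundancy
#' coordinates + group test + decoupling regressions, SIR effect sizes +
#' MSIR regressions, then a markdown report and a JSON manifest (config,
#' seed, row counts, output checksums). Each stage's outputs are on disk
#' before the next starts. Identical config + seed gives byte-identical
#' outputs.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the stage results and the manifest.
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  res <- list()

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    say("stage simulate")
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    sim <- simulate_dataset(sc)
    write_simulation(sim, file.path(cfg$out_dir, "data"))
    otu <- sim$otu; gene <- sim$gene; traits <- sim$traits
    sf <- sim$sf; sir_tbl <- sim$sir
  } else {
    say("stage load")
    otu <- read_feature_table(cfg$inputs$otu, kind = "otu")
    gene <- read_feature_table(cfg$inputs$genes, kind = "gene",
                               marker = "metagenome")
    traits <- read_trait_matrix(cfg$inputs$traits)
    sf <- read_sample_frame(cfg$inputs$samples)
    sir_tbl <- read_sir(cfg$inputs$sir)
    attr(gene, "family_class") <- family_classes(traits)[feature_ids(gene)]
    sc_map <- substrate_classes(traits)
    attr(gene, "substrate_class") <- sc_map
  }

  # --- preprocess ---------------------------------------------------------
  say("stage preprocess")
  cmin_otu <- cfg$cmin_otu %||% min(colSums(otu))
  cmin_gene <- cfg$cmin_gene %||% min(colSums(gene))
  otu_n <- srs_normalize(otu, normalization_spec("srs", cmin = cmin_otu))
  gene_n <- rarefy_table(gene, cmin = cmin_gene, seed = cfg$seed + 11L)
  for (a in c("family_class", "substrate_class")) {
    attr(gene_n, a) <- attr(gene, a)
  }
  write_feature_table(otu_n, file.path(cfg$out_dir, "otu_normalized.tsv"))
  write_feature_table(gene_n, file.path(cfg$out_dir, "genes_normalized.tsv"))

  # --- diversity ----------------------------------------------------------
  say("stage diversity")
  div_tax <- diversity_profile(otu_n)
  div_fun <- diversity_profile(gene_n)
  div <- div_tax |>
    left_join(div_fun, by = "sample_id", suffix = c("_tax", "_fun")) |>
    left_join(sf |> select("sample_id", "stage", "ecosystem", "pair_id"),
              by = "sample_id")
  kw <- stage_comparisons(div$shannon_H_tax, sf, "kruskal_wallis")
  covs <- intersect(c("pH", "CN_ratio", "SOC", "LDMC_cwm"), names(sf))
  shapes <- purrr::map(covs, function(cv) {
    response_shape(sf[[cv]], sf, alpha = cfg$alpha) |>
      mutate(covariate = cv, .before = 1)
  }) |> purrr::list_rbind()
  omega <- purrr::map(setdiff(stage_levels(), "forest"), function(gs) {
    paired_anova_omega(div$shannon_H_tax, sf, gs, n_boot = 500,
                       seed = cfg$seed + 21L)
  }) |> purrr::list_rbind()
  d_bc <- bray_curtis_matrix(otu_n)
  pmv <- permanova(d_bc, sf$ecosystem, n_perm = cfg$n_perm_community,
                   seed = cfg$seed + 22L)
  ord <- pcoa(d_bc, k = 2)
  write_tsv_stable(div, file.path(cfg$out_dir, "diversity.tsv"))
  write_tsv_stable(shapes, file.path(cfg$out_dir, "response_shapes.tsv"))
  write_tsv_stable(omega, file.path(cfg$out_dir, "effect_sizes_alpha.tsv"))
  write_tsv_stable(ord$coordinates, file.path(cfg$out_dir, "pcoa.tsv"))
  write_tsv_stable(glance(pmv), file.path(cfg$out_dir, "permanova_community.tsv"))
  res$diversity <- list(table = div, kruskal = kw, shapes = shapes,
                        omega = omega, permanova = pmv, pcoa = ord)

  # --- niche overlap ------------------------------------------------------
  say("stage niche")
  ov <- stage_overlap_summary(to_relative(gene_n), sf, loq = cfg$loq)
  trends <- ov$summary |> group_by(.data$class) |>
    group_modify(~ overlap_trend(.x, alpha = cfg$alpha)) |> ungroup()
  write_tsv_stable(ov$summary, file.path(cfg$out_dir, "overlap_summary.tsv"))
  write_tsv_stable(trends, file.path(cfg$out_dir, "overlap_trends.tsv"))
  res$niche <- list(summary = ov$summary, tests = ov$tests, trends = trends)

  # --- redundancy ---------------------------------------------------------
  say("stage redundancy")
  coords <- ternary_coordinates(otu_n, traits, sf)
  tern_test <- ternary_group_test(coords, n_perm = cfg$n_perm_ternary,
                                  seed = cfg$seed + 31L)
  dec <- decoupling_regression(
    div |> transmute(.data$sample_id, tax_H = .data$shannon_H_tax,
                     fun_H = .data$shannon_H_fun, .data$ecosystem))
  write_tsv_stable(coords, file.path(cfg$out_dir, "ternary.tsv"))
  write_tsv_stable(glance(tern_test), file.path(cfg$out_dir, "ternary_test.tsv"))
  write_tsv_stable(tidy(dec), file.path(cfg$out_dir, "decoupling.tsv"))
  res$redundancy <- list(coords = coords, test = tern_test, decoupling = dec)

  # --- degradation --------------------------------------------------------
  say("stage sir")
  msir_tbl <- msir(sir_tbl)
  ses <- substrate_effect_sizes(sir_tbl, sf)
  cdiv <- c_gene_diversity(gene_n)
  reg <- msir_diversity_regression(
    msir_tbl,
    div_tax |> transmute(.data$sample_id, tax_H = .data$shannon_H) |>
      left_join(cdiv, by = "sample_id"),
    sf)
  write_tsv_stable(msir_tbl, file.path(cfg$out_dir, "msir.tsv"))
  write_tsv_stable(ses, file.path(cfg$out_dir, "sir_effect_sizes.tsv"))
  write_tsv_stable(reg$fits, file.path(cfg$out_dir, "msir_regressions.tsv"))
  res$sir <- list(msir = msir_tbl, effect_sizes = ses, regressions = reg)

  # --- report + manifest --------------------------------------------------
  say("stage report")
  make_report(res, file.path(cfg$out_dir, "report.md"))
  manifest <- list(
    package = "microsucc",
    version = as.character(utils::packageVersion("microsucc")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_samples = ncol(otu),
    n_taxa = nrow(otu),
    n_gene_families = nrow(gene),
    checksums = as.list(tools::md5sum(
      sort(list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE,
                      recursive = TRUE))))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Shannon diversity of C-cycling genes per sample
#'
#' Convenience accessor used by the MSIR regressions: summed substrate-class
#' Shannon diversity (the aggregate matching the per-substrate coupling) and
#' the pooled C-gene Shannon diversity.
#'
#' @param gene Gene `feature_table` carrying `family_class` /
#'   `substrate_class` attributes.
#' @return Tibble: `sample_id`, `c_gene_H`, `c_class_H_sum`.
#' @export
c_gene_diversity <- function(gene) {
  fc <- attr(gene, "family_class")
  sc <- attr(gene, "substrate_class")
  if (is.null(fc)) ms_abort("gene table lacks a family_class map.", "config_error")
  cf <- names(fc)[fc == "C"]
  sub <- unclass(gene)[intersect(cf, rownames(gene)), , drop = FALSE]
  rel <- sweep(sub, 2, colSums(sub), "/")
  pooled <- apply(rel, 2, shannon)
  out <- tibble(sample_id = sample_ids(gene), c_gene_H = pooled)
  if (!is.null(sc)) {
    h <- class_shannon(gene, sc)
    out$c_class_H_sum <- rowSums(h)
  }
  out
}

#' Render a markdown report of pipeline results
#'
#' One section per stage; stages absent from `res` are marked "not run".
#'
#' @param res Stage results from [run_pipeline()].
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
make_report <- function(res, path) {
  num <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c("# Succession pipeline report", "")
  sec <- function(title, body) c(paste("##", title), "", body, "")
  if (!is.null(res$diversity)) {
    d <- res$diversity
    by_stage <- d$table |> group_by(.data$stage) |>
      summarise(mean_H = mean(.data$shannon_H_tax), n = n())
    lines <- c(lines, sec("Taxonomic diversity", c(
      paste0("Mean Shannon H' by stage: ",
             paste(sprintf("%s = %s (n=%d)", by_stage$stage,
                           num(by_stage$mean_H), by_stage$n), collapse = ", ")),
      sprintf("Community perMANOVA (ecosystem): pseudo-F = %s, R2 = %s, p = %s",
              num(d$permanova$pseudo_F), num(d$permanova$R2), num(d$permanova$p)),
      paste0("Paired partial omega-squared (alpha diversity): ",
             paste(sprintf("%s = %s", d$omega$stage, num(d$omega$estimate)),
                   collapse = ", ")))))
  } else lines <- c(lines, sec("Taxonomic diversity", "not run"))
  if (!is.null(res$niche)) {
    s <- res$niche$summary |> group_by(.data$stage) |>
      summarise(m = mean(.data$mean_overlap, na.rm = TRUE))
    lines <- c(lines, sec("Niche overlap", c(
      paste0("Mean Levin overlap by stage: ",
             paste(sprintf("%s = %s", s$stage, num(s$m)), collapse = ", ")),
      paste0("Trend fits: ",
             paste(sprintf("%s %s (slope %s)", res$niche$trends$class,
                           res$niche$trends$selected,
                           num(res$niche$trends$slope)), collapse = "; ")))))
  } else lines <- c(lines, sec("Niche overlap", "not run"))
  if (!is.null(res$redundancy)) {
    r <- res$redundancy
    by_eco <- r$coords |> group_by(.data$ecosystem) |>
      summarise(D = mean(.data$D), Q = mean(.data$Q), R = mean(.data$R))
    lines <- c(lines, sec("Redundancy framework", c(
      paste0("Mean (D, Q, R) by ecosystem: ",
             paste(sprintf("%s = (%s, %s, %s)", by_eco$ecosystem, num(by_eco$D),
                           num(by_eco$Q), num(by_eco$R)), collapse = "; ")),
      sprintf("Ternary perMANOVA: pseudo-F = %s, p = %s",
              num(r$test$pseudo_F), num(r$test$p)),
      sprintf("Decoupling slope difference: F = %s, p = %s",
              num(r$decoupling$slope_difference_F),
              num(r$decoupling$p_difference)))))
  } else lines <- c(lines, sec("Redundancy framework", "not run"))
  if (!is.null(res$sir)) {
    f <- res$sir$regressions$fits
    pick <- f[f$scope == "pooled", , drop = FALSE]
    lines <- c(lines, sec("Substrate degradation", c(
      paste0("Pooled MSIR regressions: ",
             paste(sprintf("%s slope %s (p = %s)", pick$predictor,
                           num(pick$slope), num(pick$p_slope)), collapse = "; ")))))
  } else lines <- c(lines, sec("Substrate degradation", "not run"))
  writeLines(lines, path)
  invisible(path)
}
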