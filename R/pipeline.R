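with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

matrix_to_df <- function(M) {
  data.frame(id = rownames(M), as.data.frame(unclass(M)),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the full conservation-genetics pipeline
#'
#' Orchestrates simulate/load -> QC -> diversity -> ROH/F_ROH ->
#' relatedness (G, IBS, PCA) -> NJ tree -> family partition, writing every
#' result as tab-separated text (plus Newick trees) under `outdir`, each
#' file carrying a provenance header with the package version, seed and a
#' config checksum. Given the same config and seed the outputs are
#' byte-identical across runs.
#'
#' The configuration is a nested list (or path to an equivalent YAML file)
#' with blocks:
#' \describe{
#'   \item{input}{either `list(vcf = path)` or `list(ped = path, map =
#'     path)`; mutually exclusive with `sim`.}
#'   \item{sim}{arguments for [sim_config()]; used when no `input` is
#'     given.}
#'   \item{qc}{arguments for [qc_config()].}
#'   \item{roh}{arguments for [roh_params()].}
#'   \item{diversity}{`pn_threshold` (default 0.05), `ne` (logical, default
#'     `TRUE`), plus [ne_from_ld()] arguments.}
#'   \item{families}{`threshold` (default 0.1).}
#' }
#' Omitted blocks take the documented defaults.
#'
#' @param config nested list or YAML file path (see Details).
#' @param outdir output directory, created if needed.
#' @param seed integer seed for every stochastic step (simulation); also
#'   the default `sim$seed`.
#' @return A list of class `run_report`: `qc`, `diversity`, `roh`
#'   (summaries), `families`, `files` (named vector of written paths) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = list(), outdir = "popconserve_run",
                         seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$input) && !is.null(config$sim))
    stop("config error: give exactly one of 'input' and 'sim'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(outdir, "run_config.yaml")
  yaml::write_yaml(c(config, list(seed = seed)), cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  prov <- c(paste0("# popconserve ",
                   as.character(utils::packageVersion("popconserve"))),
            paste0("# seed: ", seed),
            paste0("# config_md5: ", cfg_md5))
  files <- c(config = cfg_path)

  # ---- input / simulation -------------------------------------------------
  sim_cfg <- NULL
  gm <- with_stage("input", {
    if (!is.null(config$input)) {
      inp <- config$input
      if (!is.null(inp$vcf)) read_vcf(inp$vcf)
      else if (!is.null(inp$ped) && !is.null(inp$map))
        read_plink_text(inp$ped, inp$map)
      else stop("input block needs 'vcf' or 'ped'+'map'")
    } else {
      sim_args <- if (is.null(config$sim)) list() else config$sim
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      sim_cfg <- do.call(sim_config, sim_args)
      simulate_population(sim_cfg)$genotypes
    }
  })

  autosomes <- if (!is.null(config$qc$autosomes)) config$qc$autosomes
    else if (!is.null(sim_cfg)) as.character(seq_len(sim_cfg$n_chrom))
    else as.character(1:30)

  # ---- qc -----------------------------------------------------------------
  qc_res <- with_stage("qc", {
    qc_args <- if (is.null(config$qc)) list() else config$qc
    qc_args$autosomes <- autosomes
    qcc <- do.call(qc_config, qc_args)
    res <- apply_qc(gm, qcc)
    if (ncol(res$genotypes$dosage) == 0)
      stop("no SNPs survive quality control")
    res
  })
  gmq <- qc_res$genotypes
  files["qc_report"] <- write_tsv_prov(qc_report_table(qc_res$report),
                                       file.path(outdir, "qc_report.tsv"),
                                       prov)

  # ---- diversity ----------------------------------------------------------
  div <- with_stage("diversity", {
    da <- if (is.null(config$diversity)) list() else config$diversity
    pn_thr <- if (is.null(da$pn_threshold)) 0.05 else da$pn_threshold
    want_ne <- if (is.null(da$ne)) TRUE else isTRUE(da$ne)
    ne_args <- da[intersect(names(da),
                            c("recomb_rate_per_bp", "max_pair_dist",
                              "maf_floor", "r2_floor", "method"))]
    do.call(diversity_summary,
            c(list(gmq, pn_threshold = pn_thr, ne = want_ne,
                   autosomes = autosomes), ne_args))
  })
  files["locus_stats"] <- write_tsv_prov(
    locus_stats(gmq, autosomes = autosomes),
    file.path(outdir, "locus_stats.tsv"), prov)
  files["diversity"] <- write_tsv_prov(
    data.frame(statistic = c("Effective Population Size (Ne)",
                             "Proportion of Polymorphic Markers (PN)",
                             "Expected Heterozygosity (He)",
                             "Observed Heterozygosity (Ho)",
                             "Polymorphism Information Content (PIC)",
                             "Effective Numbers of Alleles",
                             "Minor Allele Frequency (MAF)"),
               value = round(c(div$ne_ld, div$pn, div$mean_he, div$mean_ho,
                               div$mean_pic, div$mean_ae, div$mean_maf), 4),
               stringsAsFactors = FALSE),
    file.path(outdir, "diversity_summary.tsv"), prov)

  # ---- roh ----------------------------------------------------------------
  roh_res <- with_stage("roh", {
    ra <- if (is.null(config$roh)) list() else config$roh
    if (is.null(ra$autosome_length_kb) && !is.null(sim_cfg))
      ra$autosome_length_kb <-
        sim_cfg$n_chrom * sim_cfg$chrom_length_bp / 1000
    rp <- do.call(roh_params, ra)
    segs <- detect_roh_all(gmq, params = rp, autosomes = autosomes)
    list(segments = segs,
         summaries = roh_summaries(segs, gmq$samples$id,
                                   L = rp$autosome_length_kb),
         params = rp)
  })
  files["roh_segments"] <- write_tsv_prov(
    roh_res$segments, file.path(outdir, "roh_segments.tsv"), prov)
  files["froh"] <- write_tsv_prov(
    roh_res$summaries$froh, file.path(outdir, "froh.tsv"), prov)

  # ---- relatedness --------------------------------------------------------
  rel <- with_stage("relatedness", {
    G <- grm_vanraden(gmq)
    D <- ibs_distance(gmq)
    pca <- pca_genotypes(gmq, k = min(2, nrow(gmq$samples) - 1))
    list(G = G, D = D, pca = pca)
  })
  files["grm"] <- write_tsv_prov(matrix_to_df(rel$G),
                                 file.path(outdir, "grm.tsv"), prov)
  files["ibs"] <- write_tsv_prov(matrix_to_df(rel$D),
                                 file.path(outdir, "ibs_distance.tsv"), prov)
  files["pca"] <- write_tsv_prov(
    data.frame(id = rownames(rel$pca$coords), rel$pca$coords,
               stringsAsFactors = FALSE),
    file.path(outdir, "pca_coords.tsv"), prov)

  # ---- tree + families ----------------------------------------------------
  fam <- with_stage("families", {
    thr <- if (is.null(config$families$threshold)) 0.1
           else config$families$threshold
    tree <- nj_tree(rel$D)
    tree_path <- file.path(outdir, "nj_tree.nwk")
    # bare Newick, no provenance header: comment lines break Newick parsers
    writeLines(ape::write.tree(tree), tree_path)
    fa <- build_families(rel$G, gmq, threshold = thr)
    list(assignment = fa, tree = tree, tree_path = tree_path)
  })
  files["tree"] <- fam$tree_path
  files["families"] <- write_tsv_prov(
    family_table(fam$assignment), file.path(outdir, "families.tsv"), prov)

  structure(list(qc = qc_res$report, diversity = div,
                 roh = roh_res$summaries, families = fam$assignment,
                 tree = fam$tree, genotypes = gmq, files = files,
                 provenance = list(seed = seed, config_md5 = cfg_md5)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("popconserve run (seed ", x$provenance$seed, ")\n\n", sep = "")
  print(x$qc); cat("\n")
  print(x$diversity); cat("\n")
  cat("ROH: ", x$roh$n_segments, " segments, mean length ",
      sprintf("%.2f", x$roh$mean_length_mb), " Mb, mean F_ROH ",
      sprintf("%.4f", mean(x$roh$froh$froh)), "\n\n", sep = "")
  print(x$families)
  cat("\nfiles:\n")
  for (f in x$files) cat("  ", f, "\n", sep = "")
  invisible(x)
}
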