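# End-to-end pipeline: simulate -> quantify -> contrast -> scan -> classify,
# with a deterministic run manifest.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. The defaults are the
#' package's reference study conditions: 500 genes, 10 planted promoters per
#' type, 3 replicates per strain at 2e6 expected reads each, dispersion 10,
#' pseudocount 0.5 RPKM, four-fold (`t_major = 2`) and two-fold
#' (`t_bypass = 1`) calling thresholds, BH alpha 0.05, default motif models
#' and footprint geometry.
#'
#' @param seed master seed; the count simulation uses `seed + 1`.
#' @param n_genes number of genes.
#' @param n_planted_per_type named vector of planted promoter counts.
#' @param depth expected reads per sample.
#' @param n_replicates replicates per strain.
#' @param dispersion negative-binomial size.
#' @param pseudocount RPKM pseudocount inside logs.
#' @param t_major,t_bypass,alpha calling thresholds, see [classify_gene()].
#' @param sigma54_threshold,sigma70_threshold motif scan thresholds.
#' @param pad_upstream,pad_downstream sigma-70 footprint pads.
#' @param distal_cutoff class III/IV boundary (bp).
#' @param window_upstream,window_downstream site-to-gene assignment windows.
#' @param sim a [sim_params()] object.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            n_genes = 500L,
                            n_planted_per_type = c(
                              sigma54_activator_dependent = 10L,
                              sigma54_bypass = 10L,
                              sigma70_constitutive = 10L,
                              sigma70_repressed_by_sigma54 = 10L),
                            depth = 2e6,
                            n_replicates = 3L,
                            dispersion = 10,
                            pseudocount = 0.5,
                            t_major = 2,
                            t_bypass = 1,
                            alpha = 0.05,
                            sigma54_threshold = 2,
                            sigma70_threshold = 3,
                            pad_upstream = 5L,
                            pad_downstream = 20L,
                            distal_cutoff = 100L,
                            window_upstream = 400L,
                            window_downstream = 300L,
                            sim = sim_params()) {
  stopifnot(t_major > 0, t_bypass > 0, alpha > 0,
            sigma54_threshold >= 0, sigma70_threshold >= 0,
            distal_cutoff > 0, pseudocount > 0)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_planted_per_type = n_planted_per_type, depth = depth,
         n_replicates = as.integer(n_replicates), dispersion = dispersion,
         pseudocount = pseudocount, t_major = t_major, t_bypass = t_bypass,
         alpha = alpha, sigma54_threshold = sigma54_threshold,
         sigma70_threshold = sigma70_threshold,
         pad_upstream = as.integer(pad_upstream),
         pad_downstream = as.integer(pad_downstream),
         distal_cutoff = as.integer(distal_cutoff),
         window_upstream = as.integer(window_upstream),
         window_downstream = as.integer(window_downstream),
         sim = sim),
    class = "pipeline_config"
  )
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$n_planted_per_type <- as.list(out$n_planted_per_type)
  out$sim <- unclass(out$sim)
  out
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_as_list(config), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate -> quantify -> contrast -> scan -> classify, writing
#' all stage outputs plus a YAML run manifest (config hash, seed, package
#' version, per-stage file list with MD5 checksums) under `outdir`.
#' Identical configurations produce byte-identical stage outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param quiet suppress stage progress messages on stderr.
#' @return invisibly, a list with every stage result (`genome`, `counts`,
#'   `expr`, `calls`, `sites54`, `sites70`, `site_classes`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[rpoNscan] ", ...)

  say("stage simulate")
  genome <- run_stage("simulate", build_genome(
    config$n_genes, config$n_planted_per_type, seed = config$seed,
    params = config$sim))
  counts <- run_stage("simulate", simulate_counts(
    genome, depth = config$depth, n_replicates = config$n_replicates,
    dispersion = config$dispersion, seed = config$seed + 1L))
  run_stage("simulate", write_fixture(genome, counts, outdir))

  say("stage quantify")
  expr <- run_stage("quantify", quantify_expression(
    counts, genome, pseudocount = config$pseudocount))
  expr_path <- file.path(outdir, "expression.tsv")
  utils::write.table(as.data.frame(expr), expr_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage contrast")
  calls <- run_stage("contrast", call_genome(
    expr, t_major = config$t_major, t_bypass = config$t_bypass,
    alpha = config$alpha))
  calls_path <- file.path(outdir, "calls.tsv")
  utils::write.table(calls$calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("stage scan")
  sites54 <- run_stage("scan", scan_motif(
    genome$sequence, sigma54_motif(config$sigma54_threshold)))
  sites70 <- run_stage("scan", scan_motif(
    genome$sequence, sigma70_motif(config$sigma70_threshold)))
  s54_path <- file.path(outdir, "sites_sigma54.tsv")
  s70_path <- file.path(outdir, "sites_sigma70.tsv")
  utils::write.table(sites54, s54_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sites70, s70_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  run_stage("scan", write_sites_bed(
    sites54, file.path(outdir, "sites_sigma54.bed")))
  run_stage("scan", write_sites_bed(
    sites70, file.path(outdir, "sites_sigma70.bed")))

  say("stage classify")
  site_classes <- run_stage("classify", classify_repressed_set(
    calls, sites54, sites70, genome,
    pad_upstream = config$pad_upstream,
    pad_downstream = config$pad_downstream,
    distal_cutoff = config$distal_cutoff,
    window_upstream = config$window_upstream,
    window_downstream = config$window_downstream))
  classes_path <- file.path(outdir, "site_classes.tsv")
  utils::write.table(site_classes$classes, classes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage report")
  ma_paths <- character()
  for (cn in names(CONTRASTS)) {
    p <- file.path(outdir, paste0("ma_", cn, ".tsv"))
    export_ma_plot_data(expr, cn, path = p)
    ma_paths <- c(ma_paths, p)
  }

  stage_files <- list(
    simulate = c("genome.fa", "genes.gff3", "truth_sites.bed",
                 "promoters.tsv", "counts.tsv"),
    quantify = basename(expr_path),
    contrast = basename(calls_path),
    scan = c(basename(s54_path), basename(s70_path),
             "sites_sigma54.bed", "sites_sigma70.bed"),
    classify = basename(classes_path),
    report = basename(ma_paths)
  )
  all_files <- file.path(outdir, unlist(stage_files, use.names = FALSE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rpoNscan")),
    config = config_as_list(config),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = stage_files,
    md5 = as.list(stats::setNames(unname(tools::md5sum(all_files)),
                                  basename(all_files)))
  )
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))

  invisible(list(genome = genome, counts = counts, expr = expr,
                 calls = calls, sites54 = sites54, sites70 = sites70,
                 site_classes = site_classes, manifest = manifest))
}

#' Export MA-plot data for one contrast
#'
#' One row per gene with its A and M statistics and a flag marking genes
#' outside the four-fold band (`|M| > 2`); genes with `|M| <= 2` lie inside
#' the shaded "less than or equal to four-fold" region of an MA plot.
#'
#' @param expr an `expression_table`.
#' @param contrast one of `"WT_vs_none"`, `"WT_vs_dRI"`, `"dRI_vs_none"`.
#' @param path optional TSV output path.
#' @return data frame `gene_id`, `A`, `M`, `four_fold_flag` (invisibly when
#'   `path` is given).
#' @export
export_ma_plot_data <- function(expr, contrast, path = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  if (!contrast %in% names(CONTRASTS)) {
    stop("unknown contrast: ", contrast, " (expected one of ",
         paste(names(CONTRASTS), collapse = ", "), ")")
  }
  st <- expr$stats
  out <- data.frame(
    gene_id = st$gene_id,
    A = st[[paste0("A_", contrast)]],
    M = st[[paste0("M_", contrast)]],
    stringsAsFactors = FALSE
  )
  out$four_fold_flag <- abs(out$M) > 2
  if (nrow(st) == 0) {
    out <- data.frame(gene_id = character(), A = numeric(), M = numeric(),
                      four_fold_flag = logical(), stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
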