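# Fixture writing and reading: FASTA + GFF3 + BED truth + counts TSV +
# YAML manifest, round-trippable through the package readers.

SEQNAME <- "synthetic_genome"

PROMOTER_COL_CLASSES <- c(
  promoter_id = "character", promoter_type = "character",
  target_gene_id = "character", strand = "character", tss = "integer",
  elem1_start = "integer", elem1_end = "integer",
  elem2_start = "integer", elem2_end = "integer",
  minus12_base = "character", site_class = "character",
  s54_strand = "character", s54_tss = "integer",
  s54_elem1_start = "integer", s54_elem1_end = "integer",
  s54_elem2_start = "integer", s54_elem2_end = "integer",
  activity_WT = "numeric", activity_dRI = "numeric",
  activity_none = "numeric"
)

#' Write a genome/counts fixture to disk
#'
#' Emits `genome.fa` (70-column FASTA), `genes.gff3` (gene features, `ID`
#' attribute), `truth_sites.bed` (BED6, one record per planted element span;
#' name = promoter type, repressive sigma-54 sites as
#' `sigma54_repressor_site_class_<class>`; score 0), `promoters.tsv` (the
#' full truth table), `counts.tsv` (`gene_id` then `WT_1 ... none_R`
#' columns) and `manifest.yaml` (seed, parameters, file list with MD5
#' checksums). The combination round-trips losslessly through
#' [read_fixture()].
#'
#' @param genome a `genome_model`.
#' @param counts a `count_matrix` (optional; `NULL` skips `counts.tsv`).
#' @param outdir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(genome, counts = NULL, outdir) {
  stopifnot(inherits(genome, "genome_model"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- list(
    fasta = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "genes.gff3"),
    bed = file.path(outdir, "truth_sites.bed"),
    promoters = file.path(outdir, "promoters.tsv"),
    counts = if (!is.null(counts)) file.path(outdir, "counts.tsv")
  )

  dna <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, SEQNAME))
  Biostrings::writeXStringSet(dna, paths$fasta, width = 70L)

  gr <- GenomicRanges::GRanges(
    seqnames = SEQNAME,
    ranges = IRanges::IRanges(genome$genes$start, genome$genes$end),
    strand = genome$genes$strand,
    type = "gene", ID = genome$genes$gene_id
  )
  rtracklayer::export(gr, paths$gff3, format = "gff3")

  bed_gr <- truth_bed_ranges(genome$promoters)
  rtracklayer::export(bed_gr, paths$bed, format = "bed")

  utils::write.table(genome$promoters, paths$promoters, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  if (!is.null(counts)) {
    stopifnot(inherits(counts, "count_matrix"))
    df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, paths$counts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  files <- unlist(Filter(Negate(is.null), paths))
  manifest <- list(
    seed = genome$seed,
    n_genes = nrow(genome$genes),
    n_planted_per_type = as.list(genome$n_planted_per_type),
    params = unclass(genome$params),
    counts = if (!is.null(counts)) list(
      depth = counts$depth, n_replicates = counts$n_replicates,
      dispersion = counts$dispersion, seed = counts$seed
    ),
    files = as.list(basename(files)),
    md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                  basename(files)))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

truth_bed_ranges <- function(promoters) {
  if (nrow(promoters) == 0) {
    return(GenomicRanges::GRanges(seqnames = factor(levels = SEQNAME),
                                  name = character(), score = numeric()))
  }
  starts <- integer(); ends <- integer(); strands <- character()
  names <- character()
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    starts <- c(starts, min(p$elem1_start, p$elem2_start))
    ends <- c(ends, max(p$elem1_end, p$elem2_end))
    strands <- c(strands, p$strand)
    names <- c(names, p$promoter_type)
    if (!is.na(p$s54_elem1_start)) {
      starts <- c(starts, min(p$s54_elem1_start, p$s54_elem2_start))
      ends <- c(ends, max(p$s54_elem1_end, p$s54_elem2_end))
      strands <- c(strands, p$s54_strand)
      names <- c(names, paste0("sigma54_repressor_site_class_", p$site_class))
    }
  }
  GenomicRanges::GRanges(
    seqnames = SEQNAME, ranges = IRanges::IRanges(starts, ends),
    strand = strands, name = names, score = 0
  )
}

#' Read a fixture directory back into package objects
#'
#' Reconstructs the `genome_model` (sequence from FASTA, genes from GFF3,
#' truth table from `promoters.tsv`, parameters from the manifest; gene
#' activities are re-derived from the truth table) and, when present, the
#' `count_matrix` from `counts.tsv`.
#'
#' @param dir a directory written by [write_fixture()].
#' @return list with `genome`, `counts` (or `NULL`) and `manifest`.
#' @export
read_fixture <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(mpath)

  dna <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  sequence <- as.character(dna[[1]])

  gr <- rtracklayer::import(file.path(dir, "genes.gff3"))
  genes <- data.frame(
    gene_id = as.character(gr$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$start), , drop = FALSE]
  genes$length_bp <- genes$end - genes$start + 1L
  rownames(genes) <- NULL

  promoters <- utils::read.delim(
    file.path(dir, "promoters.tsv"),
    colClasses = unname(PROMOTER_COL_CLASSES[
      names(utils::read.delim(file.path(dir, "promoters.tsv"), nrows = 1))]),
    stringsAsFactors = FALSE
  )
  genes <- annotate_gene_activities(genes, promoters)

  params <- as_sim_params(manifest$params)
  genome <- structure(
    list(sequence = sequence, genes = genes, promoters = promoters,
         params = params, seed = as.integer(manifest$seed),
         n_planted_per_type = stats::setNames(
           as.integer(unlist(manifest$n_planted_per_type)),
           names(manifest$n_planted_per_type))),
    class = "genome_model"
  )

  counts <- NULL
  cpath <- file.path(dir, "counts.tsv")
  if (file.exists(cpath) && !is.null(manifest$counts)) {
    df <- utils::read.delim(cpath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$gene_id
    storage.mode(mat) <- "integer"
    parts <- strsplit(colnames(mat), "_")
    samples <- data.frame(
      sample = colnames(mat),
      strain = vapply(parts, `[`, character(1), 1),
      replicate = as.integer(vapply(parts, `[`, character(1), 2)),
      stringsAsFactors = FALSE
    )
    counts <- structure(
      list(counts = mat, samples = samples,
           depth = manifest$counts$depth,
           n_replicates = as.integer(manifest$counts$n_replicates),
           dispersion = manifest$counts$dispersion,
           seed = as.integer(manifest$counts$seed)),
      class = "count_matrix"
    )
  }
  list(genome = genome, counts = counts, manifest = manifest)
}

#' Write a promoter site table as BED6
#'
#' One record per site; name is the motif id, score the match score scaled
#' to 0-1000.
#'
#' @param sites `promoter_sites` data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- if (nrow(sites) == 0) {
    GenomicRanges::GRanges(seqnames = factor(levels = SEQNAME),
                           name = character(), score = numeric())
  } else {
    GenomicRanges::GRanges(
      seqnames = SEQNAME,
      ranges = IRanges::IRanges(sites$start, sites$end),
      strand = sites$strand,
      name = sites$motif_id, score = round(1000 * sites$score)
    )
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
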