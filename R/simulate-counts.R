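# Negative-binomial three-strain count simulation.

#' Simulate per-gene read counts for the three strains
#'
#' Counts are negative-binomial with mean
#' `mu(g, strain) = depth * length_kb(g) * activity(g, strain) / normaliser`
#' where the per-strain normaliser is `sum_g length_kb(g) * activity(g,
#' strain)`, so every strain's expected total equals `depth` exactly
#' (sequencing yields near-equivalent totals per sample). Variance follows
#' the `(mu, k)` parameterisation `mu + mu^2 / k` with dispersion `k` shared
#' across genes.
#'
#' @param genome a [build_genome()] result (its gene activities are used).
#' @param depth expected total reads per sample (> 0).
#' @param n_replicates replicates per strain (>= 1; with 1 the downstream
#'   ANOVA stage is disabled).
#' @param dispersion negative-binomial size `k` (> 0); larger is closer to
#'   Poisson.
#' @param seed RNG seed.
#' @return an object of class `count_matrix`: integer matrix `counts`
#'   (genes x samples, columns `WT_1 ... none_R`), `samples` data frame,
#'   and the simulation settings.
#' @export
simulate_counts <- function(genome, depth, n_replicates = 3L, dispersion = 10,
                            seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0")
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be > 0")
  }
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L)

  genes <- genome$genes
  n <- nrow(genes)
  act <- as.matrix(genes[, c("activity_WT", "activity_dRI", "activity_none")])
  colnames(act) <- STRAINS
  lkb <- genes$length_bp / 1000

  set.seed(as.integer(seed))
  cols <- list()
  for (s in STRAINS) {
    w <- lkb * act[, s]
    mu <- depth * w / sum(w)
    for (r in seq_len(n_replicates)) {
      cols[[paste(s, r, sep = "_")]] <-
        stats::rnbinom(n, size = dispersion, mu = mu)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes$gene_id
  storage.mode(counts) <- "integer"
  samples <- data.frame(
    sample = colnames(counts),
    strain = rep(STRAINS, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(STRAINS)),
    stringsAsFactors = FALSE
  )
  structure(
    list(counts = counts, samples = samples, depth = depth,
         n_replicates = n_replicates, dispersion = dispersion,
         seed = as.integer(seed)),
    class = "count_matrix"
  )
}

#' Per-sample library sizes (column sums) of a count matrix
#' @param x a `count_matrix` or integer matrix.
#' @return named numeric vector of total counts per sample.
#' @export
library_sizes <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  colSums(m)
}

#' Expected negative-binomial means used by [simulate_counts()]
#' @param genome a `genome_model`.
#' @param depth expected total reads per sample.
#' @return genes x strains matrix of means.
#' @export
expected_counts <- function(genome, depth) {
  genes <- genome$genes
  act <- as.matrix(genes[, c("activity_WT", "activity_dRI", "activity_none")])
  colnames(act) <- STRAINS
  lkb <- genes$length_bp / 1000
  mu <- vapply(STRAINS, function(s) {
    w <- lkb * act[, s]
    depth * w / sum(w)
  }, numeric(nrow(genes)))
  rownames(mu) <- genes$gene_id
  mu
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", x$n_replicates, " replicates/strain, depth ",
      format(x$depth, scientific = FALSE), ", dispersion ", x$dispersion,
      ")\n", sep = "")
  invisible(x)
}
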