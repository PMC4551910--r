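# RPKM quantification, MA contrast statistics and one-way ANOVA.

CONTRASTS <- list(
  WT_vs_none = c("WT", "none"),
  WT_vs_dRI = c("WT", "dRI"),
  dRI_vs_none = c("dRI", "none")
)

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (gene_length_bp * library_size)`, i.e. counts
#' normalised for both transcript length and sequencing depth.
#'
#' @param count read count(s), >= 0.
#' @param gene_length_bp gene length(s) in bp, > 0.
#' @param library_size total mapped reads in the sample, > 0.
#' @return RPKM value(s); vectorised with recycling.
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(!is.finite(gene_length_bp)) || any(gene_length_bp <= 0)) {
    stop("gene_length_bp must be > 0")
  }
  if (any(!is.finite(library_size)) || any(library_size <= 0)) {
    stop("library_size must be > 0")
  }
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e9 / (gene_length_bp * library_size)
}

#' MA statistics for a pair of expression values
#'
#' For strains 1 and 2, `M = log2(rpkm1 + eps) - log2(rpkm2 + eps)` (positive
#' M means higher expression in strain 1) and
#' `A = 0.5 * (log2(rpkm1 + eps) + log2(rpkm2 + eps))`. The pseudocount
#' `eps` keeps M finite for genes with zero reads; raw RPKM values are never
#' shifted, the offset lives inside the logs only.
#'
#' @param rpkm1,rpkm2 RPKM values, >= 0 (vectorised).
#' @param pseudocount `eps` > 0 (default 0.5).
#' @return data frame with columns `M` and `A`.
#' @export
ma_stats <- function(rpkm1, rpkm2, pseudocount = 0.5) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0")
  }
  if (any(rpkm1 < 0) || any(rpkm2 < 0)) stop("rpkm values must be >= 0")
  l1 <- log2(rpkm1 + pseudocount)
  l2 <- log2(rpkm2 + pseudocount)
  data.frame(M = l1 - l2, A = 0.5 * (l1 + l2))
}

#' Classical one-way ANOVA for one gene
#'
#' Equal-variance one-way ANOVA across strain groups:
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom and
#' the p-value from the F distribution. With all group means identical the F
#' statistic is 0 and p is 1; when the within-group variance is exactly zero
#' but means differ, F is `Inf` and p is 0. With fewer than 2 observations
#' in any group the statistic is flagged as not computable rather than
#' fabricated.
#'
#' @param groups list of numeric vectors, one per strain (>= 2 groups).
#' @return list with `F`, `p`, `df` (numerator, denominator) and
#'   `computable`.
#' @export
anova_one_way <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("one-way ANOVA needs at least 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2)) {
    return(list(F = NA_real_, p = NA_real_, df = c(k - 1, sum(n_i) - k),
                computable = FALSE))
  }
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in ANOVA input")
  N <- length(x)
  gmeans <- vapply(groups, mean, numeric(1))
  grand <- mean(x)
  ssb <- sum(n_i * (gmeans - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw <= 0) {
    if (ssb <= 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p = p, df = c(df1, df2), computable = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: step-up false
#' discovery rate control, monotone after sorting by p and capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  obs <- p_values[!is.na(p_values)]
  if (any(obs < 0 | obs > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Quantify a three-strain count matrix
#'
#' Computes per-sample RPKM, per-strain mean RPKM, the three pairwise MA
#' contrasts (`WT_vs_none`, `WT_vs_dRI`, `dRI_vs_none`, computed on strain
#' mean RPKM with the pseudocount inside the logs) and, when every strain has
#' at least two replicates, a per-gene one-way ANOVA on `log2(rpkm +
#' pseudocount)` across the three strains with Benjamini-Hochberg adjusted
#' q-values. With single replicates the F/p/q columns are `NA` and
#' `anova_computed` is `FALSE` (contrasts remain available).
#'
#' @param counts a [simulate_counts()] result, or an integer matrix whose
#'   column names follow `strain_replicate` (e.g. `WT_1`).
#' @param genes a `genome_model` or a data frame with `gene_id` and
#'   `length_bp` covering all count rows.
#' @param pseudocount `eps` added inside logs (default 0.5 RPKM).
#' @return an object of class `expression_table` with `genes`, `samples`,
#'   per-sample `rpkm`, per-strain `rpkm_mean` and a `stats` data frame
#'   (`gene_id`, M/A per contrast, `F`, `p`, `q`).
#' @export
quantify_expression <- function(counts, genes, pseudocount = 0.5) {
  if (inherits(counts, "count_matrix")) {
    mat <- counts$counts
    samples <- counts$samples
  } else {
    mat <- as.matrix(counts)
    parts <- strsplit(colnames(mat), "_")
    samples <- data.frame(
      sample = colnames(mat),
      strain = vapply(parts, `[`, character(1), 1),
      replicate = as.integer(vapply(parts, `[`, character(1), 2)),
      stringsAsFactors = FALSE
    )
  }
  if (!all(samples$strain %in% STRAINS)) {
    stop("sample strains must be among: ", paste(STRAINS, collapse = ", "))
  }
  if (inherits(genes, "genome_model")) genes <- genes$genes
  idx <- match(rownames(mat), genes$gene_id)
  if (any(is.na(idx))) stop("count rows missing from the gene table")
  lens <- genes$length_bp[idx]

  libs <- colSums(mat)
  if (any(libs <= 0)) stop("a sample has zero total counts")
  rpkm_mat <- mat * 1e9 / outer(lens, libs)
  rpkm_mean <- vapply(STRAINS, function(s) {
    cols <- samples$sample[samples$strain == s]
    rowMeans(rpkm_mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))

  stats_df <- data.frame(gene_id = rownames(mat), stringsAsFactors = FALSE)
  for (cn in names(CONTRASTS)) {
    pair <- CONTRASTS[[cn]]
    ma <- ma_stats(rpkm_mean[, pair[1]], rpkm_mean[, pair[2]], pseudocount)
    stats_df[[paste0("M_", cn)]] <- ma$M
    stats_df[[paste0("A_", cn)]] <- ma$A
  }

  n_rep <- min(table(samples$strain))
  anova_computed <- n_rep >= 2
  if (anova_computed) {
    x <- log2(rpkm_mat + pseudocount)
    k <- length(STRAINS)
    N <- ncol(x)
    group_cols <- lapply(STRAINS, function(s)
      samples$sample[samples$strain == s])
    gm <- lapply(group_cols, function(cc) rowMeans(x[, cc, drop = FALSE]))
    grand <- rowMeans(x)
    ssb <- Reduce(`+`, Map(function(m, cc) length(cc) * (m - grand)^2,
                           gm, group_cols))
    ssw <- Reduce(`+`, Map(function(m, cc)
      rowSums((x[, cc, drop = FALSE] - m)^2), gm, group_cols))
    df1 <- k - 1; df2 <- N - k
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    zero_b <- ssb <= 0
    zero_w <- ssw <= 0
    f[zero_w & zero_b] <- 0; p[zero_w & zero_b] <- 1
    f[zero_w & !zero_b] <- Inf; p[zero_w & !zero_b] <- 0
    stats_df$F <- f
    stats_df$p <- p
    stats_df$q <- bh_adjust(p)
  } else {
    stats_df$F <- NA_real_
    stats_df$p <- NA_real_
    stats_df$q <- NA_real_
  }

  structure(
    list(
      genes = data.frame(gene_id = rownames(mat), length_bp = lens,
                         stringsAsFactors = FALSE),
      samples = samples, rpkm = rpkm_mat, rpkm_mean = rpkm_mean,
      stats = stats_df, pseudocount = pseudocount,
      anova_computed = anova_computed
    ),
    class = "expression_table"
  )
}

#' @export
as.data.frame.expression_table <- function(x, ...) {
  out <- cbind(x$genes,
               as.data.frame(x$rpkm_mean)[
                 , , drop = FALSE],
               x$stats[, -1, drop = FALSE])
  names(out)[3:5] <- paste0("rpkm_", STRAINS)
  rownames(out) <- NULL
  out
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table: ", nrow(x$rpkm), " genes x ", ncol(x$rpkm),
      " samples; ANOVA ",
      if (x$anova_computed) "computed" else "not computable (single replicate)",
      "; pseudocount ", x$pseudocount, " RPKM\n", sep = "")
  invisible(x)
}
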