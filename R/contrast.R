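# Regulatory categorisation of genes from contrast statistics.

GENE_CATEGORIES <- c("RI_dependent", "bypass", "sigma54_repressed", "unchanged")

category_ladder <- function(M_wt_dRI, M_dRI_none, M_wt_none, q,
                            t_major, t_bypass, alpha) {
  gate <- is.na(q) | q <= alpha
  ifelse(gate & M_wt_dRI >= t_major & M_wt_none >= t_major, "RI_dependent",
  ifelse(gate & M_dRI_none >= t_bypass, "bypass",
  ifelse(gate & -M_wt_none >= t_major & -M_dRI_none >= t_major,
         "sigma54_repressed", "unchanged")))
}

#' Categorise one gene from its three contrast M values
#'
#' Decision ladder, evaluated in order:
#' 1. `RI_dependent` - more reads with wild-type sigma-54 than with either
#'    the bypass allele or no sigma-54 (`M_wt_dRI >= t_major` and
#'    `M_wt_none >= t_major`): a canonical activator-driven promoter whose
#'    output requires Region I.
#' 2. `bypass` - more reads with the Region-I-deleted form than with no
#'    sigma-54 (`M_dRI_none >= t_bypass`): low-level activator-independent
#'    transcription, hence `t_bypass < t_major` by default.
#' 3. `sigma54_repressed` - more reads when sigma-54 is absent than with
#'    either allele (`-M_wt_none >= t_major` and `-M_dRI_none >= t_major`).
#' 4. otherwise `unchanged`.
#'
#' When a q-value is supplied, categories 1-3 additionally require
#' `q <= alpha`; genes failing the gate fall through to `unchanged`.
#'
#' @param M_wt_dRI,M_dRI_none,M_wt_none finite per-gene M statistics for the
#'   WT-vs-dRI, dRI-vs-none and WT-vs-none contrasts.
#' @param q optional ANOVA q-value (`NA` skips the significance gate, the
#'   single-replicate mode).
#' @param t_major log2 threshold for categories 1 and 3 (default 2,
#'   four-fold).
#' @param t_bypass log2 threshold for category 2 (default 1, two-fold).
#' @param alpha q-value cutoff (default 0.05).
#' @return a one-row data frame (`gene call`): `category`, the M values, `q`
#'   and the thresholds used.
#' @export
classify_gene <- function(M_wt_dRI, M_dRI_none, M_wt_none, q = NA_real_,
                          t_major = 2, t_bypass = 1, alpha = 0.05) {
  stopifnot(t_major > 0, t_bypass > 0, alpha > 0)
  if (!all(is.finite(c(M_wt_dRI, M_dRI_none, M_wt_none)))) {
    stop("M values must be finite")
  }
  data.frame(
    category = category_ladder(M_wt_dRI, M_dRI_none, M_wt_none, q,
                               t_major, t_bypass, alpha),
    M_WT_vs_dRI = M_wt_dRI, M_dRI_vs_none = M_dRI_none,
    M_WT_vs_none = M_wt_none, q = q,
    t_major = t_major, t_bypass = t_bypass, alpha = alpha,
    stringsAsFactors = FALSE
  )
}

#' Categorise every gene of an expression table
#'
#' Vectorised application of the [classify_gene()] ladder. The significance
#' gate uses the table's BH q-values when the ANOVA was computable and
#' `use_q = TRUE`; otherwise the ladder runs on M values alone.
#'
#' @param expr an [quantify_expression()] result.
#' @param t_major,t_bypass,alpha see [classify_gene()].
#' @param use_q apply the `q <= alpha` gate when q-values exist.
#' @return list with `calls` (one row per gene: `gene_id`, `category`, M
#'   values, `q`) and `summary` (named category counts, summing to the number
#'   of genes).
#' @export
call_genome <- function(expr, t_major = 2, t_bypass = 1, alpha = 0.05,
                        use_q = TRUE) {
  stopifnot(inherits(expr, "expression_table"))
  st <- expr$stats
  needed <- c("M_WT_vs_dRI", "M_dRI_vs_none", "M_WT_vs_none")
  if (!all(needed %in% names(st))) stop("expression table misses contrasts: ",
                                        paste(setdiff(needed, names(st)),
                                              collapse = ", "))
  if (nrow(st) == 0) {
    calls <- data.frame(gene_id = character(), category = character(),
                        M_WT_vs_dRI = numeric(), M_dRI_vs_none = numeric(),
                        M_WT_vs_none = numeric(), q = numeric(),
                        stringsAsFactors = FALSE)
    return(list(calls = calls,
                summary = stats::setNames(rep(0L, 4), GENE_CATEGORIES),
                thresholds = c(t_major = t_major, t_bypass = t_bypass,
                               alpha = alpha)))
  }
  if (!all(is.finite(st$M_WT_vs_dRI)) || !all(is.finite(st$M_dRI_vs_none)) ||
      !all(is.finite(st$M_WT_vs_none))) {
    stop("M values must be finite")
  }
  q <- if (use_q && expr$anova_computed) st$q else rep(NA_real_, nrow(st))
  category <- category_ladder(st$M_WT_vs_dRI, st$M_dRI_vs_none,
                              st$M_WT_vs_none, q, t_major, t_bypass, alpha)
  calls <- data.frame(
    gene_id = st$gene_id, category = category,
    M_WT_vs_dRI = st$M_WT_vs_dRI, M_dRI_vs_none = st$M_dRI_vs_none,
    M_WT_vs_none = st$M_WT_vs_none, q = q,
    stringsAsFactors = FALSE
  )
  summary <- vapply(GENE_CATEGORIES, function(cc) sum(category == cc),
                    integer(1))
  list(calls = calls, summary = summary,
       thresholds = c(t_major = t_major, t_bypass = t_bypass, alpha = alpha))
}
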