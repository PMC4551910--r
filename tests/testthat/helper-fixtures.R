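# Shared fixture builders (all generated in code at test time).

# 60-gene genome with every planted type and all four repressive site classes
small_planted_genome <- function(seed = 1) {
  build_genome(
    60,
    c(sigma54_activator_dependent = 2, sigma54_bypass = 2,
      sigma70_constitutive = 2, sigma70_repressed_by_sigma54 = 4),
    seed = seed
  )
}

# one-row promoter-site entry for classifier tests
make_site <- function(motif_id, strand, elem1_start, elem1_end,
                      elem2_start, elem2_end, tss, score = 1,
                      aligned_seq = NA_character_,
                      minus12_base = NA_character_) {
  data.frame(
    motif_id = motif_id, strand = strand,
    start = min(elem1_start, elem2_start), end = max(elem1_end, elem2_end),
    elem1_start = elem1_start, elem1_end = elem1_end,
    elem2_start = elem2_start, elem2_end = elem2_end,
    spacer = NA_integer_, mismatch_weight = 0, score = score,
    matched_seq = NA_character_, aligned_seq = aligned_seq,
    minus12_base = minus12_base, tss = as.integer(tss),
    stringsAsFactors = FALSE
  )
}

empty_sites_for_tests <- function() {
  make_site("sigma54", "+", 1L, 7L, 12L, 16L, 28L)[0, ]
}

empty_expression_table <- function() {
  stats_df <- data.frame(gene_id = character())
  for (cn in c("WT_vs_none", "WT_vs_dRI", "dRI_vs_none")) {
    stats_df[[paste0("M_", cn)]] <- numeric()
    stats_df[[paste0("A_", cn)]] <- numeric()
  }
  stats_df$F <- numeric(); stats_df$p <- numeric(); stats_df$q <- numeric()
  structure(
    list(
      genes = data.frame(gene_id = character(), length_bp = integer()),
      samples = data.frame(sample = character(), strain = character(),
                           replicate = integer()),
      rpkm = matrix(numeric(), 0, 0),
      rpkm_mean = matrix(numeric(), 0, 3,
                         dimnames = list(NULL, c("WT", "dRI", "none"))),
      stats = stats_df, pseudocount = 0.5, anova_computed = TRUE
    ),
    class = "expression_table"
  )
}

# counts matrix with an engineered exact fold change between WT and none for
# gene_a, equal library sizes everywhere (single replicate per strain)
fold_change_counts <- function(fold = 4, base = 100, lib = 1000) {
  m <- matrix(
    c(base * fold, lib - base * fold,   # WT_1
      base, lib - base,                 # dRI_1
      base, lib - base),                # none_1
    nrow = 2,
    dimnames = list(c("gene_a", "gene_b"), c("WT_1", "dRI_1", "none_1"))
  )
  storage.mode(m) <- "integer"
  m
}

two_gene_table <- function() {
  data.frame(gene_id = c("gene_a", "gene_b"),
             length_bp = c(1000L, 1000L), stringsAsFactors = FALSE)
}
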