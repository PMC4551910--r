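# Synthetic genome construction with planted promoters and ground truth.

SIGMA54_M24 <- "TGGCACG"
SIGMA70_M35 <- "TTGACA"
SIGMA70_M10 <- "TATAAT"

sigma54_m12_element <- function(minus12_base) paste0("TTG", minus12_base, "T")

# Element coordinates (plus frame, 1-based inclusive) for a sigma-54 promoter
# with its tss at `tss` on `strand`. The -12 C consensus position sits 12 nt
# upstream of the tss; the -12 element is TTGCW with the C at index 4.
place_sigma54 <- function(tss, strand, spacer, minus12_index = 4L) {
  w2 <- 5L
  if (strand == "+") {
    c_pos <- tss - 12L
    e2 <- c(c_pos - (minus12_index - 1L), c_pos + (w2 - minus12_index))
    e1 <- c(e2[1] - spacer - 7L, e2[1] - spacer - 1L)
  } else {
    c_pos <- tss + 12L
    e2 <- c(c_pos - (w2 - minus12_index), c_pos + (minus12_index - 1L))
    e1 <- c(e2[2] + spacer + 1L, e2[2] + spacer + 7L)
  }
  list(elem1 = as.integer(e1), elem2 = as.integer(e2),
       span = as.integer(range(c(e1, e2))))
}

# Same for a sigma-70 promoter: tss 7 nt downstream of the -10 element start.
place_sigma70 <- function(tss, strand, spacer) {
  if (strand == "+") {
    e2 <- c(tss - 7L, tss - 2L)
    e1 <- c(e2[1] - spacer - 6L, e2[1] - spacer - 1L)
  } else {
    e2 <- c(tss + 2L, tss + 7L)
    e1 <- c(e2[2] + spacer + 1L, e2[2] + spacer + 6L)
  }
  list(elem1 = as.integer(e1), elem2 = as.integer(e2),
       span = as.integer(range(c(e1, e2))))
}

# Element coordinates for a sigma-54 site occupying the 16 bp span
# [span_start, span_start + 15] (spacer 4) on `site_strand`.
sigma54_elements_in_span <- function(span_start, site_strand) {
  if (site_strand == "+") {
    list(elem1 = c(span_start, span_start + 6L),
         elem2 = c(span_start + 11L, span_start + 15L))
  } else {
    list(elem1 = c(span_start + 9L, span_start + 15L),
         elem2 = c(span_start, span_start + 4L))
  }
}

sigma54_tss_from_elem2 <- function(elem2, site_strand, minus12_index = 4L) {
  if (site_strand == "+") {
    c_pos <- elem2[1] + minus12_index - 1L
    c_pos + 12L
  } else {
    c_pos <- elem2[2] - (minus12_index - 1L)
    c_pos - 12L
  }
}

opposite_strand <- function(s) ifelse(s == "+", "-", "+")

# Repressive sigma-54 site span relative to the sigma-70 tss (local offsets
# along the gene orientation; sigma-70 tss = offset 0):
#   I   same strand, span just downstream of the tss (inside the likely
#       sigma-70 footprint, clear of the -10/-35 elements themselves)
#   II  as I but on the opposite strand
#   III same strand, upstream of the footprint, within ~100 bp
#   IV  opposite strand, 150 bp downstream of the tss (convergent/distal)
repressed_site_layout <- function(site_class, gene_strand, pad_upstream = 5L,
                                  spacer70 = 17L) {
  footprint_local_start <- -(7L + spacer70 + 6L) - pad_upstream  # -35 start - pad
  local <- switch(site_class,
    I = list(offsets = c(1L, 16L), strand = gene_strand),
    II = list(offsets = c(1L, 16L), strand = opposite_strand(gene_strand)),
    III = list(offsets = c(footprint_local_start - 46L,
                           footprint_local_start - 31L),
               strand = gene_strand),
    IV = list(offsets = c(150L, 165L), strand = opposite_strand(gene_strand)),
    stop("unknown site class: ", site_class)
  )
  local
}

local_to_plus <- function(tss, gene_strand, offsets) {
  if (gene_strand == "+") as.integer(tss + offsets)
  else as.integer(sort(tss - offsets))
}

write_element <- function(chars, start, end, element, strand) {
  el <- strsplit(element, "")[[1]]
  stopifnot(end - start + 1L == length(el))
  chars[start:end] <- if (strand == "+") el else revcomp_chars(el)
  chars
}

sample_background <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Build a synthetic genome with planted promoters
#'
#' Lays out non-overlapping genes separated by intergenic gaps on an i.i.d.
#' background sequence, plants promoter elements verbatim for the requested
#' promoter types, and records an exhaustive truth table. Any background
#' window that spuriously contains a zero-mismatch sigma-54 or sigma-70
#' consensus core is rejection-resampled, so the truth table is complete at
#' zero mismatches.
#'
#' Planted types and their strain activity multipliers come from
#' [sim_params()]. Repressed promoters additionally receive a sigma-54 site
#' placed per positional class (cycling `params$repressed_classes`): classes
#' I/II overlap the likely sigma-70 footprint on the same/opposite strand,
#' class III sits upstream within ~100 bp, class IV is placed on the opposite
#' strand 150 bp downstream of the sigma-70 tss (convergent/distal).
#'
#' @param n_genes number of genes (>= 4x the total planted promoters).
#' @param n_planted_per_type named integer vector/list over
#'   `sigma54_activator_dependent`, `sigma54_bypass`, `sigma70_constitutive`,
#'   `sigma70_repressed_by_sigma54`; missing types default to 0.
#' @param seed RNG seed; identical `(params, seed)` give identical genomes.
#' @param params a [sim_params()] object.
#' @return an object of class `genome_model`: `sequence` (character string),
#'   `genes` (data frame with coordinates, strand, planted type and per-strain
#'   activities), `promoters` (truth table with element coordinates, -12 base,
#'   site class and sigma-54 site coordinates for repressed promoters),
#'   `params`, `seed`.
#' @export
build_genome <- function(n_genes, n_planted_per_type = NULL, seed = 1L,
                         params = sim_params()) {
  stopifnot(n_genes >= 1)
  npt <- stats::setNames(rep(0L, length(PROMOTER_TYPES)), PROMOTER_TYPES)
  if (!is.null(n_planted_per_type)) {
    n_planted_per_type <- unlist(n_planted_per_type)
    bad <- setdiff(names(n_planted_per_type), PROMOTER_TYPES)
    if (length(bad) > 0) stop("unknown promoter type(s): ",
                              paste(bad, collapse = ", "))
    npt[names(n_planted_per_type)] <- as.integer(n_planted_per_type)
  }
  total <- sum(npt)
  if (total > 0 && n_genes < 4L * total) {
    stop("n_genes must be at least 4x the total planted promoters (",
         4L * total, ")")
  }

  set.seed(as.integer(seed))

  lens <- sample(seq(params$gene_length_range[1], params$gene_length_range[2]),
                 n_genes, replace = TRUE)
  gaps <- sample(seq(params$intergenic_range[1], params$intergenic_range[2]),
                 n_genes + 1L, replace = TRUE)
  starts <- integer(n_genes); ends <- integer(n_genes)
  cursor <- 0L
  for (i in seq_len(n_genes)) {
    starts[i] <- cursor + gaps[i] + 1L
    ends[i] <- starts[i] + lens[i] - 1L
    cursor <- ends[i]
  }
  L <- cursor + gaps[n_genes + 1L]
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    start = as.integer(starts), end = as.integer(ends),
    strand = strand, length_bp = as.integer(lens),
    stringsAsFactors = FALSE
  )

  chars <- sample_background(L, params$gc)

  # choose target genes and plant
  promoters <- empty_promoters()
  jobs <- list()  # element write jobs: start, end, seq, strand
  if (total > 0) {
    targets <- sample.int(n_genes, total)
    types <- rep(PROMOTER_TYPES, times = npt[PROMOTER_TYPES])
    n_rep <- npt[["sigma70_repressed_by_sigma54"]]
    classes <- rep(params$repressed_classes, length.out = max(n_rep, 1L))
    rep_i <- 0L
    for (k in seq_len(total)) {
      g <- targets[k]; type <- types[k]
      gs <- genes$strand[g]
      tss <- if (gs == "+") genes$start[g] else genes$end[g]
      act <- activity_for_type(params, type)
      row <- list(
        promoter_id = sprintf("prom_%03d", k), promoter_type = type,
        target_gene_id = genes$gene_id[g], strand = gs, tss = as.integer(tss),
        elem1_start = NA_integer_, elem1_end = NA_integer_,
        elem2_start = NA_integer_, elem2_end = NA_integer_,
        minus12_base = NA_character_, site_class = NA_character_,
        s54_strand = NA_character_, s54_tss = NA_integer_,
        s54_elem1_start = NA_integer_, s54_elem1_end = NA_integer_,
        s54_elem2_start = NA_integer_, s54_elem2_end = NA_integer_,
        activity_WT = act[["WT"]], activity_dRI = act[["dRI"]],
        activity_none = act[["none"]]
      )
      if (type %in% c("sigma54_activator_dependent", "sigma54_bypass")) {
        m12 <- if (type == "sigma54_bypass") params$bypass_minus12 else "C"
        pos <- place_sigma54(tss, gs, params$spacer54)
        row$elem1_start <- pos$elem1[1]; row$elem1_end <- pos$elem1[2]
        row$elem2_start <- pos$elem2[1]; row$elem2_end <- pos$elem2[2]
        row$minus12_base <- m12
        jobs[[length(jobs) + 1L]] <- list(pos$elem1, SIGMA54_M24, gs)
        jobs[[length(jobs) + 1L]] <- list(pos$elem2, sigma54_m12_element(m12), gs)
      } else {
        pos <- place_sigma70(tss, gs, params$spacer70)
        row$elem1_start <- pos$elem1[1]; row$elem1_end <- pos$elem1[2]
        row$elem2_start <- pos$elem2[1]; row$elem2_end <- pos$elem2[2]
        jobs[[length(jobs) + 1L]] <- list(pos$elem1, SIGMA70_M35, gs)
        jobs[[length(jobs) + 1L]] <- list(pos$elem2, SIGMA70_M10, gs)
        if (type == "sigma70_repressed_by_sigma54") {
          rep_i <- rep_i + 1L
          cls <- classes[rep_i]
          lay <- repressed_site_layout(cls, gs, spacer70 = params$spacer70)
          span <- local_to_plus(tss, gs, lay$offsets)
          if (cls == "IV" &&
              (span[1] < genes$start[g] || span[2] > genes$end[g])) {
            stop("class IV sigma-54 site for ", genes$gene_id[g],
                 " runs outside the gene body; increase gene length")
          }
          el <- sigma54_elements_in_span(span[1], lay$strand)
          row$site_class <- cls
          row$s54_strand <- lay$strand
          row$s54_elem1_start <- el$elem1[1]; row$s54_elem1_end <- el$elem1[2]
          row$s54_elem2_start <- el$elem2[1]; row$s54_elem2_end <- el$elem2[2]
          row$s54_tss <- as.integer(
            sigma54_tss_from_elem2(el$elem2, lay$strand))
          row$minus12_base <- "C"  # repression-competent consensus C
          jobs[[length(jobs) + 1L]] <- list(el$elem1, SIGMA54_M24, lay$strand)
          jobs[[length(jobs) + 1L]] <- list(el$elem2, sigma54_m12_element("C"),
                                            lay$strand)
        }
      }
      promoters <- rbind(promoters, as.data.frame(row, stringsAsFactors = FALSE))
    }
  }

  # validate and write planted elements
  if (length(jobs) > 0) {
    ivs <- do.call(rbind, lapply(jobs, function(j) j[[1]]))
    if (any(ivs[, 1] < 1L) || any(ivs[, 2] > L)) {
      stop("planted elements run off the sequence")
    }
    o <- order(ivs[, 1])
    if (any(ivs[o, 1][-1] <= cummax(ivs[o, 2])[-nrow(ivs)])) {
      stop("planted elements overlap")
    }
    for (j in jobs) {
      chars <- write_element(chars, j[[1]][1], j[[1]][2], j[[2]], j[[3]])
    }
  }

  chars <- resample_spurious_cores(chars, promoters, params)

  rownames(promoters) <- NULL
  genes <- annotate_gene_activities(genes, promoters)
  structure(
    list(sequence = chars_to_seq(chars), genes = genes, promoters = promoters,
         params = params, seed = as.integer(seed),
         n_planted_per_type = npt),
    class = "genome_model"
  )
}

empty_promoters <- function() {
  data.frame(
    promoter_id = character(), promoter_type = character(),
    target_gene_id = character(), strand = character(), tss = integer(),
    elem1_start = integer(), elem1_end = integer(),
    elem2_start = integer(), elem2_end = integer(),
    minus12_base = character(), site_class = character(),
    s54_strand = character(), s54_tss = integer(),
    s54_elem1_start = integer(), s54_elem1_end = integer(),
    s54_elem2_start = integer(), s54_elem2_end = integer(),
    activity_WT = numeric(), activity_dRI = numeric(),
    activity_none = numeric(),
    stringsAsFactors = FALSE
  )
}

# Attach planted type and per-strain activity multipliers to the gene table.
# Genes without a planted promoter are constitutive baseline.
annotate_gene_activities <- function(genes, promoters) {
  genes$promoter_type <- "none"
  genes$activity_WT <- 1
  genes$activity_dRI <- 1
  genes$activity_none <- 1
  if (nrow(promoters) > 0) {
    idx <- match(promoters$target_gene_id, genes$gene_id)
    genes$promoter_type[idx] <- promoters$promoter_type
    genes$activity_WT[idx] <- promoters$activity_WT
    genes$activity_dRI[idx] <- promoters$activity_dRI
    genes$activity_none[idx] <- promoters$activity_none
  }
  genes
}

# All planted element intervals plus the zero-mismatch-discoverable span keys.
planted_truth_spans <- function(promoters) {
  if (nrow(promoters) == 0) {
    return(list(intervals = matrix(integer(), ncol = 2), keys = character()))
  }
  ivs <- list(); keys <- character()
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    motif <- if (p$promoter_type %in%
                 c("sigma54_activator_dependent", "sigma54_bypass"))
      "sigma54" else "sigma70"
    span <- c(min(p$elem1_start, p$elem2_start), max(p$elem1_end, p$elem2_end))
    ivs[[length(ivs) + 1L]] <- span
    keys <- c(keys, paste(motif, p$strand, span[1], sep = ":"))
    if (!is.na(p$s54_elem1_start)) {
      span54 <- c(min(p$s54_elem1_start, p$s54_elem2_start),
                  max(p$s54_elem1_end, p$s54_elem2_end))
      ivs[[length(ivs) + 1L]] <- span54
      keys <- c(keys, paste("sigma54", p$s54_strand, span54[1], sep = ":"))
    }
  }
  list(intervals = do.call(rbind, ivs), keys = keys)
}

# Zero-mismatch consensus-core occurrences (both strands, plus-frame
# coordinates) found by exact IUPAC matching; the spacer is encoded as N in
# the pattern. Equivalent to scan_motif at threshold 0 on N-free sequence,
# but fast enough for repeated whole-genome passes.
find_consensus_cores <- function(dna, model) {
  hits <- list()
  for (sp in model$spacer_range) {
    pat <- paste0(model$elements[1], strrep("N", sp), model$elements[2])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp(pat)
      m <- Biostrings::matchPattern(p, dna, fixed = FALSE)
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = model$motif_id, strand = strand,
          start = Biostrings::start(m), end = Biostrings::end(m),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif_id = character(), strand = character(),
                      start = integer(), end = integer()))
  }
  do.call(rbind, hits)
}

# Rejection-resample background windows that spuriously contain a
# zero-mismatch sigma-54 or sigma-70 consensus core, so that the truth table
# is exhaustive at zero mismatches.
resample_spurious_cores <- function(chars, promoters, params,
                                    max_iter = 25L) {
  truth <- planted_truth_spans(promoters)
  mask <- rep(FALSE, length(chars))
  if (nrow(truth$intervals) > 0) {
    for (i in seq_len(nrow(truth$intervals))) {
      mask[truth$intervals[i, 1]:truth$intervals[i, 2]] <- TRUE
    }
  }
  models <- list(sigma54_motif(score_threshold = 0),
                 sigma70_motif(score_threshold = 0))
  for (iter in seq_len(max_iter)) {
    dna <- Biostrings::DNAString(chars_to_seq(chars))
    hits <- do.call(rbind, lapply(models, find_consensus_cores, dna = dna))
    if (nrow(hits) > 0) {
      key <- paste(hits$motif_id, hits$strand, hits$start, sep = ":")
      hits <- hits[!key %in% truth$keys, , drop = FALSE]
    }
    if (nrow(hits) == 0) return(chars)
    for (i in seq_len(nrow(hits))) {
      idx <- hits$start[i]:hits$end[i]
      free <- idx[!mask[idx]]
      if (length(free) == 0) {
        stop("spurious consensus core fully inside planted elements; ",
             "cannot resample")
      }
      chars[free] <- sample_background(length(free), params$gc)
    }
  }
  stop("failed to purge spurious consensus cores after ", max_iter,
       " resampling rounds")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model: ", nchar(x$sequence), " bp, ", nrow(x$genes), " genes, ",
      nrow(x$promoters), " planted promoters (seed ", x$seed, ")\n", sep = "")
  if (nrow(x$promoters) > 0) {
    print(table(x$promoters$promoter_type))
  }
  invisible(x)
}
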