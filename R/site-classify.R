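# Positional classification of repressive sigma-54 sites relative to the
# active sigma-70 promoter (classes I-IV).

SITE_CLASSES <- c("I", "II", "III", "IV")

#' Likely sigma-70 RNA polymerase footprint around a promoter
#'
#' The interval from `pad_upstream` bp upstream of the -35 element through
#' `pad_downstream` bp downstream of the tss, expressed in plus-strand
#' coordinates (1-based inclusive). On the minus strand the interval is
#' mirrored, its end anchored at the -35 element.
#'
#' @param site a one-row sigma-70 `promoter_sites` entry (or any list with
#'   `motif_id`, `strand`, `elem1_start`, `elem1_end`, `tss`).
#' @param pad_upstream,pad_downstream pads in bp (defaults 5 and 20).
#' @return list with `start`, `end`, `strand`.
#' @export
sigma70_footprint <- function(site, pad_upstream = 5L, pad_downstream = 20L) {
  if (!identical(as.character(site$motif_id), "sigma70")) {
    stop("footprint is defined for sigma-70 sites only")
  }
  stopifnot(pad_upstream >= 0, pad_downstream >= 0)
  if (site$strand == "+") {
    list(start = as.integer(site$elem1_start - pad_upstream),
         end = as.integer(site$tss + pad_downstream - 1L),
         strand = "+")
  } else {
    list(start = as.integer(site$tss - pad_downstream + 1L),
         end = as.integer(site$elem1_end + pad_upstream),
         strand = "-")
  }
}

interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

interval_gap <- function(s1, e1, s2, e2) {
  # 0 when overlapping/adjacent, else bp of separation
  max(0L, max(s1, s2) - min(e1, e2) - 1L)
}

#' Classify one sigma-54 site against one sigma-70 promoter
#'
#' Positional classes of a repressive sigma-54 recognition site relative to
#' the active sigma-70 promoter:
#' * **I** - the sigma-54 element span (-24 element start through -12 element
#'   end) overlaps the sigma-70 footprint, both sites on the same strand
#'   (direct binding competition);
#' * **II** - overlaps the footprint on the opposite strand;
#' * **III** - no overlap, but within `distal_cutoff` bp of the footprint;
#' * **IV** - farther than `distal_cutoff` (distal/convergent configuration,
#'   repression plausibly via interference between convergent polymerases
#'   rather than promoter occlusion).
#'
#' @param s54 one-row sigma-54 `promoter_sites` entry.
#' @param s70 one-row sigma-70 `promoter_sites` entry.
#' @param footprint optional precomputed [sigma70_footprint()]; computed with
#'   default pads when `NULL`.
#' @param distal_cutoff bp separating class III from IV (default 100).
#' @return one-row data frame: `site_class`, `offset_bp` (signed distance
#'   from the sigma-54 -12 element midpoint to the sigma-70 tss, positive
#'   downstream of the tss in the sigma-70 orientation), `overlap_bp`,
#'   `distance_bp`.
#' @export
classify_site <- function(s54, s70, footprint = NULL, distal_cutoff = 100L) {
  if (!identical(as.character(s54$motif_id), "sigma54")) {
    stop("s54 must be a sigma-54 site")
  }
  if (is.null(footprint)) footprint <- sigma70_footprint(s70)
  span54 <- c(min(s54$elem1_start, s54$elem2_start),
              max(s54$elem1_end, s54$elem2_end))
  ov <- interval_overlap(span54[1], span54[2], footprint$start, footprint$end)
  gap <- interval_gap(span54[1], span54[2], footprint$start, footprint$end)
  same <- identical(as.character(s54$strand), as.character(s70$strand))
  cls <- if (ov > 0) {
    if (same) "I" else "II"
  } else if (gap <= distal_cutoff) "III" else "IV"
  mid12 <- (s54$elem2_start + s54$elem2_end) / 2
  offset <- mid12 - s70$tss
  if (s70$strand == "-") offset <- -offset
  data.frame(site_class = cls, offset_bp = offset,
             overlap_bp = as.integer(ov), distance_bp = as.integer(gap),
             stringsAsFactors = FALSE)
}

#' Classify the sigma-54 sites of all sigma-54-repressed genes
#'
#' For every gene called `sigma54_repressed`, picks the best-scoring assigned
#' sigma-54 site and sigma-70 site (ties broken by coordinate order), runs
#' [classify_site()] and summarises per-class counts and consensus motifs.
#' Genes missing either site type are reported as unclassifiable rather than
#' dropped. Site-to-gene assignment windows default to 400 bp upstream /
#' 300 bp downstream of the gene 5' end so that distal (class IV) sites in
#' the gene body are still attributed to their gene.
#'
#' @param calls gene calls from [call_genome()] (the `calls` data frame or
#'   the full list).
#' @param sites54,sites70 `promoter_sites` from sigma-54 and sigma-70 scans
#'   of the same sequence.
#' @param genes gene data frame (or `genome_model`).
#' @param pad_upstream,pad_downstream footprint pads, see
#'   [sigma70_footprint()].
#' @param distal_cutoff class III/IV boundary in bp.
#' @param window_upstream,window_downstream assignment windows in bp.
#' @return list with `classes` (one row per repressed gene: ids, class,
#'   offsets, site coordinates; unclassifiable genes carry `NA` class and a
#'   `reason`), `counts` (named I-IV counts), `consensus` (per-class
#'   [build_consensus()] for classes with >= 2 members) and the parameters
#'   used.
#' @export
classify_repressed_set <- function(calls, sites54, sites70, genes,
                                   pad_upstream = 5L, pad_downstream = 20L,
                                   distal_cutoff = 100L,
                                   window_upstream = 400L,
                                   window_downstream = 300L) {
  if (is.list(calls) && !is.data.frame(calls) && !is.null(calls$calls)) {
    calls <- calls$calls
  }
  if (inherits(genes, "genome_model")) genes <- genes$genes
  rep_ids <- calls$gene_id[calls$category == "sigma54_repressed"]
  empty <- data.frame(
    gene_id = character(), site_class = character(), offset_bp = numeric(),
    overlap_bp = integer(), distance_bp = integer(),
    s54_start = integer(), s54_end = integer(), s54_strand = character(),
    s70_start = integer(), s70_end = integer(), s70_strand = character(),
    s54_score = numeric(), aligned_seq = character(), reason = character(),
    stringsAsFactors = FALSE
  )
  params <- list(pad_upstream = pad_upstream, pad_downstream = pad_downstream,
                 distal_cutoff = distal_cutoff,
                 window_upstream = window_upstream,
                 window_downstream = window_downstream)
  if (length(rep_ids) == 0) {
    return(list(classes = empty,
                counts = stats::setNames(rep(0L, 4), SITE_CLASSES),
                consensus = list(), params = params))
  }
  a54 <- assign_sites_to_genes(sites54, genes, window_upstream,
                               window_downstream)
  a70 <- assign_sites_to_genes(sites70, genes, window_upstream,
                               window_downstream)
  rows <- list()
  for (g in rep_ids) {
    s54g <- a54[!is.na(a54$target_gene_id) & a54$target_gene_id == g, ,
                drop = FALSE]
    s70g <- a70[!is.na(a70$target_gene_id) & a70$target_gene_id == g, ,
                drop = FALSE]
    if (nrow(s54g) == 0 || nrow(s70g) == 0) {
      reason <- if (nrow(s54g) == 0 && nrow(s70g) == 0) {
        "no sigma-54 or sigma-70 site assigned"
      } else if (nrow(s54g) == 0) "no sigma-54 site assigned"
      else "no sigma-70 site assigned"
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, site_class = NA_character_, offset_bp = NA_real_,
        overlap_bp = NA_integer_, distance_bp = NA_integer_,
        s54_start = NA_integer_, s54_end = NA_integer_,
        s54_strand = NA_character_, s70_start = NA_integer_,
        s70_end = NA_integer_, s70_strand = NA_character_,
        s54_score = NA_real_, aligned_seq = NA_character_, reason = reason,
        stringsAsFactors = FALSE
      )
      next
    }
    # best-scoring site wins; ties by coordinate order (scan output order)
    s54b <- s54g[which.max(s54g$score), , drop = FALSE]
    s70b <- s70g[which.max(s70g$score), , drop = FALSE]
    fp <- sigma70_footprint(s70b, pad_upstream, pad_downstream)
    cl <- classify_site(s54b, s70b, fp, distal_cutoff)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, site_class = cl$site_class, offset_bp = cl$offset_bp,
      overlap_bp = cl$overlap_bp, distance_bp = cl$distance_bp,
      s54_start = s54b$start, s54_end = s54b$end, s54_strand = s54b$strand,
      s70_start = s70b$start, s70_end = s70b$end, s70_strand = s70b$strand,
      s54_score = s54b$score, aligned_seq = s54b$aligned_seq,
      reason = NA_character_, stringsAsFactors = FALSE
    )
  }
  classes <- do.call(rbind, rows)
  rownames(classes) <- NULL
  counts <- vapply(SITE_CLASSES, function(cc)
    sum(!is.na(classes$site_class) & classes$site_class == cc), integer(1))
  consensus <- list()
  for (cc in SITE_CLASSES) {
    members <- classes$aligned_seq[!is.na(classes$site_class) &
                                     classes$site_class == cc]
    if (length(members) >= 2) consensus[[cc]] <- build_consensus(members)
  }
  list(classes = classes, counts = counts, consensus = consensus,
       params = params)
}
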