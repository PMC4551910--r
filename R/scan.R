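# Motif scanning, consensus construction, -12 C conservation and
# site-to-gene assignment.

DNA_CODE_LEVELS <- c("A", "C", "G", "T", "N")

encode_dna <- function(chars) match(chars, DNA_CODE_LEVELS)

# complement in code space: A<->T, C<->G, N->N
COMP_CODE <- c(4L, 3L, 2L, 1L, 5L)

# logical lookup over base codes for one consensus letter; a sequence N
# (code 5) never matches
allowed_codes <- function(cons_char) {
  v <- rep(FALSE, 5L)
  v[match(IUPAC_SETS[[cons_char]], DNA_CODE_LEVELS[1:4])] <- TRUE
  v
}

# Scan one strand of an integer-encoded sequence; returns span starts
# (1-based, in the scanned frame), spacer and weighted mismatch per hit.
scan_chars_one_strand <- function(code, model) {
  L <- length(code)
  n1 <- length(model$element_chars[[1]])
  n2 <- length(model$element_chars[[2]])
  cons_all <- c(model$element_chars[[1]], model$element_chars[[2]])
  allow <- lapply(cons_all, allowed_codes)
  w_all <- c(model$weights[[1]], model$weights[[2]])
  out <- list()
  for (sp in model$spacer_range) {
    span <- n1 + sp + n2
    if (span > L) next
    starts <- seq_len(L - span + 1L)
    offsets <- c(seq_len(n1) - 1L, n1 + sp + seq_len(n2) - 1L)
    wmm <- numeric(length(starts))
    for (j in seq_along(offsets)) {
      wmm <- wmm + w_all[j] * !allow[[j]][code[starts + offsets[j]]]
    }
    keep <- which(wmm <= model$score_threshold)
    if (length(keep) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        start = starts[keep], spacer = sp, mismatch_weight = wmm[keep]
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), spacer = integer(),
                      mismatch_weight = numeric()))
  }
  do.call(rbind, out)
}

empty_sites <- function() {
  data.frame(
    motif_id = character(), strand = character(),
    start = integer(), end = integer(),
    elem1_start = integer(), elem1_end = integer(),
    elem2_start = integer(), elem2_end = integer(),
    spacer = integer(), mismatch_weight = numeric(), score = numeric(),
    matched_seq = character(), aligned_seq = character(),
    minus12_base = character(), tss = integer(),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for promoter motif occurrences
#'
#' Slides a two-element [motif_model()] over a DNA sequence and reports every
#' window whose weighted mismatch count is at most the model threshold.
#' Minus-strand hits are found by scanning the reverse complement and are
#' reported in plus-strand coordinates (1-based, inclusive) with
#' `strand == "-"`. `N` bases in the sequence never match any consensus
#' position.
#'
#' @param sequence a DNA string (character or `DNAString`) over
#'   `A`,`C`,`G`,`T`,`N`.
#' @param model a [motif_model()].
#' @param both_strands scan the minus strand too (default `TRUE`).
#' @return a data frame of class `promoter_sites`, one row per hit, sorted by
#'   span start: element coordinates, spacer length, `mismatch_weight`,
#'   `score` (fraction of total weight matched, 1 = perfect),
#'   `matched_seq`/`aligned_seq` on the motif strand (aligned = elements
#'   concatenated, spacer dropped), the base at the -12 C consensus position
#'   (`minus12_base`, sigma-54 models only) and the inferred `tss`. The
#'   sigma-54 tss convention is 12 nt downstream of the -12 C position; the
#'   sigma-70 tss is 7 nt downstream of the -10 element start.
#' @export
scan_motif <- function(sequence, model, both_strands = TRUE) {
  stopifnot(inherits(model, "motif_model"))
  chars <- seq_to_chars(sequence)
  check_dna_alphabet(chars)
  L <- length(chars)
  n1 <- length(model$element_chars[[1]])
  n2 <- length(model$element_chars[[2]])
  if (n1 + min(model$spacer_range) + n2 > L) {
    stop("motif span exceeds sequence length")
  }

  rows <- list()
  add_hits <- function(hits, strand, frame_chars) {
    if (nrow(hits) == 0) return()
    for (i in seq_len(nrow(hits))) {
      p <- hits$start[i]; sp <- hits$spacer[i]
      span <- n1 + sp + n2
      # coordinates in the scanned frame
      e1 <- c(p, p + n1 - 1L)
      e2 <- c(p + n1 + sp, p + span - 1L)
      matched <- chars_to_seq(frame_chars[p:(p + span - 1L)])
      aligned <- chars_to_seq(frame_chars[c(e1[1]:e1[2], e2[1]:e2[2])])
      if (strand == "+") {
        elem1 <- e1; elem2 <- e2
        span_start <- p; span_end <- p + span - 1L
      } else {
        # map [a, b] in revcomp frame to plus frame [L - b + 1, L - a + 1]
        elem1 <- c(L - e1[2] + 1L, L - e1[1] + 1L)
        elem2 <- c(L - e2[2] + 1L, L - e2[1] + 1L)
        span_start <- L - (p + span - 1L) + 1L
        span_end <- L - p + 1L
      }
      if (!is.na(model$minus12_index)) {
        m12 <- frame_chars[e2[1] + model$minus12_index - 1L]
        c_pos <- if (strand == "+") elem2[1] + model$minus12_index - 1L
                 else elem2[2] - (model$minus12_index - 1L)
        tss <- if (strand == "+") c_pos + 12L else c_pos - 12L
      } else {
        m12 <- NA_character_
        tss <- if (strand == "+") elem2[1] + 7L else elem2[2] - 7L
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        motif_id = model$motif_id, strand = strand,
        start = as.integer(span_start), end = as.integer(span_end),
        elem1_start = as.integer(elem1[1]), elem1_end = as.integer(elem1[2]),
        elem2_start = as.integer(elem2[1]), elem2_end = as.integer(elem2[2]),
        spacer = as.integer(sp), mismatch_weight = hits$mismatch_weight[i],
        score = (model$total_weight - hits$mismatch_weight[i]) /
          model$total_weight,
        matched_seq = matched, aligned_seq = aligned,
        minus12_base = m12, tss = as.integer(tss),
        stringsAsFactors = FALSE
      )
    }
  }

  code <- encode_dna(chars)
  add_hits(scan_chars_one_strand(code, model), "+", chars)
  if (both_strands) {
    rc_code <- rev(COMP_CODE[code])
    add_hits(scan_chars_one_strand(rc_code, model), "-",
             DNA_CODE_LEVELS[rc_code])
  }
  if (length(rows) == 0) {
    res <- empty_sites()
  } else {
    res <- do.call(rbind, rows)
    res <- res[order(res$start, res$strand, res$spacer), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("promoter_sites", class(res))
  res
}

#' Fraction of sigma-54 sites with the consensus C at -12
#'
#' The C of the -12 GC element is the key repressive consensus position;
#' its conservation across a hit set distinguishes canonical (repression
#' competent) sites from bypass-permissive ones.
#'
#' @param sites a `promoter_sites` data frame from a sigma-54 scan.
#' @return fraction of sites whose `minus12_base` is `"C"`, in `[0, 1]`.
#' @export
minus12_conservation <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0) {
    stop("minus12_conservation is undefined for an empty site list")
  }
  if (any(is.na(sites$minus12_base))) {
    stop("sites lack a -12 base (not from a sigma-54 model?)")
  }
  mean(sites$minus12_base == "C")
}

#' Build a per-position frequency matrix and IUPAC consensus
#'
#' Sites are aligned on their concatenated elements (spacer dropped), so all
#' inputs must come from the same motif model. The consensus letter for a
#' column is the majority base when a single base reaches frequency >= 0.75,
#' otherwise the IUPAC code covering all bases with frequency >= 0.25.
#'
#' @param x a `promoter_sites` data frame (its `aligned_seq` column is used)
#'   or a character vector of equal-width aligned sequences.
#' @return a list of class `motif_consensus` with `freq` (4 x width matrix,
#'   rows `A`,`C`,`G`,`T`, columns summing to 1), `consensus` (IUPAC string)
#'   and `n_sites`.
#' @export
build_consensus <- function(x) {
  seqs <- if (is.data.frame(x)) x$aligned_seq else x
  if (length(seqs) == 0) stop("cannot build a consensus from zero sites")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences have mixed widths: ",
         paste(unique(widths), collapse = ", "))
  }
  W <- widths[1]
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T"))
  if (length(bad) > 0) stop("non-ACGT base in aligned sequences: ",
                            paste(bad, collapse = ", "))
  freq <- vapply(seq_len(W), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(seqs)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  consensus <- vapply(seq_len(W), function(j) {
    f <- freq[, j]
    if (max(f) >= 0.75) return(names(which.max(f)))
    set <- names(f)[f >= 0.25]
    unname(IUPAC_FROM_SET[paste(sort(set), collapse = "")])
  }, character(1))
  structure(
    list(freq = freq, consensus = paste(consensus, collapse = ""),
         n_sites = length(seqs)),
    class = "motif_consensus"
  )
}

#' @export
print.motif_consensus <- function(x, ...) {
  cat("motif_consensus over", x$n_sites, "sites:", x$consensus, "\n")
  invisible(x)
}

#' Assign promoter sites to nearby genes
#'
#' A site is assigned to a gene when its inferred tss lies within
#' `window_upstream` bp upstream to `window_downstream` bp downstream of the
#' gene's 5' end, measured along the gene's orientation (site strand is not
#' required to match: repressive sigma-54 sites may sit on either strand).
#' When several genes qualify, the nearest wins; remaining ties go to the
#' gene with the smaller start coordinate.
#'
#' @param sites `promoter_sites` data frame.
#' @param genes data frame with `gene_id`, `start`, `end`, `strand`.
#' @param window_upstream,window_downstream window sizes in bp (>= 0).
#' @return `sites` with a `target_gene_id` column (`NA` when unassigned).
#' @export
assign_sites_to_genes <- function(sites, genes, window_upstream = 300,
                                  window_downstream = 100) {
  stopifnot(window_upstream >= 0, window_downstream >= 0)
  if (nrow(sites) == 0) {
    sites$target_gene_id <- character(0)
    return(sites)
  }
  tss5 <- gene_tss(genes)
  target <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    t <- sites$tss[i]
    ok <- ifelse(
      genes$strand == "+",
      t >= tss5 - window_upstream & t <= tss5 + window_downstream - 1L,
      t <= tss5 + window_upstream & t >= tss5 - window_downstream + 1L
    )
    if (!any(ok)) next
    cand <- which(ok)
    d <- abs(t - tss5[cand])
    cand <- cand[d == min(d)]
    if (length(cand) > 1L) cand <- cand[which.min(genes$start[cand])]
    target[i] <- genes$gene_id[cand]
  }
  sites$target_gene_id <- target
  sites
}
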