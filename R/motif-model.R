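# Promoter motif models: two sequence elements separated by a variable spacer,
# scored by weighted mismatch count against an IUPAC consensus.

#' Construct a two-element promoter motif model
#'
#' A motif model is two consensus elements (IUPAC alphabet) separated by a
#' spacer whose length may take any value in `spacer_range`. A candidate
#' window matches when its total weighted mismatch count against the
#' consensus is at most `score_threshold`. Degenerate IUPAC letters in the
#' consensus match any base of their set at zero cost; an `N` in the
#' *scanned sequence* never matches.
#'
#' @param motif_id identifier, e.g. `"sigma54"` or `"sigma70"`.
#' @param elements named character vector of length 2 with the upstream and
#'   downstream consensus elements, 5' to 3' on the motif strand.
#' @param weights list of two numeric vectors of per-position mismatch
#'   weights (defaults to 1 everywhere). Higher weight marks positions whose
#'   identity matters more (invariant consensus positions).
#' @param spacer_range integer vector of allowed spacer lengths between the
#'   two elements.
#' @param score_threshold maximum total weighted mismatches for a hit.
#' @param minus12_index for sigma-54 models, the 1-based position of the
#'   -12 C consensus within the second element; `NA` otherwise.
#' @return an object of class `motif_model`.
#' @seealso [sigma54_motif()], [sigma70_motif()], [scan_motif()]
#' @export
motif_model <- function(motif_id, elements, weights = NULL, spacer_range,
                        score_threshold, minus12_index = NA_integer_) {
  stopifnot(is.character(elements), length(elements) == 2L)
  elements <- toupper(elements)
  el_chars <- lapply(elements, function(e) strsplit(e, "")[[1]])
  for (ch in unlist(el_chars)) {
    if (!ch %in% names(IUPAC_SETS)) {
      stop("consensus contains non-IUPAC letter: ", ch)
    }
  }
  if (is.null(weights)) weights <- lapply(el_chars, function(e) rep(1, length(e)))
  stopifnot(length(weights) == 2L)
  for (i in 1:2) {
    if (length(weights[[i]]) != length(el_chars[[i]])) {
      stop("weights[[", i, "]] length does not match element width")
    }
    if (any(weights[[i]] <= 0)) stop("weights must be > 0")
  }
  spacer_range <- sort(unique(as.integer(spacer_range)))
  if (length(spacer_range) == 0L || any(spacer_range < 0L)) {
    stop("spacer_range must be a non-empty set of non-negative lengths")
  }
  if (!is.numeric(score_threshold) || score_threshold < 0) {
    stop("score_threshold must be >= 0")
  }
  structure(
    list(
      motif_id = motif_id,
      elements = elements,
      element_chars = el_chars,
      weights = weights,
      spacer_range = spacer_range,
      score_threshold = score_threshold,
      minus12_index = as.integer(minus12_index),
      total_weight = sum(unlist(weights))
    ),
    class = "motif_model"
  )
}

#' Default sigma-54 -24/-12 promoter model
#'
#' Canonical -24/-12 consensus operationalised as `TGGCACG` (-24 region) and
#' `TTGCW` (-12 region) with a 4-5 nt spacer. The invariant GG of the -24
#' element and GC of the -12 element carry mismatch weight 2; all other
#' positions weight 1. The C of `TTGC` is the -12 C consensus position whose
#' conservation is reported by [minus12_conservation()].
#'
#' @param score_threshold maximum weighted mismatches (default 2).
#' @return a `motif_model`.
#' @export
sigma54_motif <- function(score_threshold = 2) {
  motif_model(
    motif_id = "sigma54",
    elements = c(minus24 = "TGGCACG", minus12 = "TTGCW"),
    weights = list(c(1, 2, 2, 1, 1, 1, 1), c(1, 1, 2, 2, 1)),
    spacer_range = 4:5,
    score_threshold = score_threshold,
    minus12_index = 4L
  )
}

#' Default sigma-70 -35/-10 promoter model
#'
#' `TTGACA` (-35) and `TATAAT` (-10) with a 16-18 nt spacer, uniform weights.
#'
#' @param score_threshold maximum mismatches (default 3).
#' @return a `motif_model`.
#' @export
sigma70_motif <- function(score_threshold = 3) {
  motif_model(
    motif_id = "sigma70",
    elements = c(minus35 = "TTGACA", minus10 = "TATAAT"),
    spacer_range = 16:18,
    score_threshold = score_threshold
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model <", x$motif_id, ">: ",
      x$elements[1], " [", min(x$spacer_range), "-", max(x$spacer_range),
      " nt] ", x$elements[2],
      "; weighted-mismatch threshold ", x$score_threshold, "\n", sep = "")
  invisible(x)
}
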