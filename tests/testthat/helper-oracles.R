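# Independent oracles, deliberately written against the problem statement
# rather than the package internals.

# Brute-force motif enumerator: walks every window position by position and
# tallies weighted mismatches against the consensus with its own IUPAC
# table. Returns every window (both strands, plus-frame span starts) with
# its weighted mismatch count; counts above `cap` are recorded as Inf (the
# walk stops early), so the result is exact for any threshold <= cap.
oracle_scan_all <- function(sequence, elements, weights, spacer_range,
                            cap = Inf) {
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  n1 <- nchar(elements[1]); n2 <- nchar(elements[2])
  cons <- c(strsplit(elements[1], "")[[1]], strsplit(elements[2], "")[[1]])
  w <- unlist(weights)
  allow <- lapply(cons, function(cc) iupac[[cc]])
  res <- list()
  for (strand_lab in c("+", "-")) {
    sc <- if (strand_lab == "+") chars else rev(unname(comp[chars]))
    for (sp in spacer_range) {
      offs <- c(0:(n1 - 1), n1 + sp + 0:(n2 - 1))
      span <- n1 + sp + n2
      ns <- L - span + 1L
      wmm <- numeric(ns)
      for (p in seq_len(ns)) {
        tot <- 0
        for (j in seq_along(offs)) {
          if (!sc[p + offs[j]] %in% allow[[j]]) {
            tot <- tot + w[j]
            if (tot > cap) { tot <- Inf; break }
          }
        }
        wmm[p] <- tot
      }
      start <- if (strand_lab == "+") seq_len(ns)
               else L - (seq_len(ns) + span - 1L) + 1L
      res[[length(res) + 1L]] <- data.frame(
        strand = strand_lab, start = start, spacer = sp, wmm = wmm,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}

# canonical hit keys for set comparison between scanner and oracle
hit_keys <- function(start, strand, spacer, wmm) {
  sort(paste(start, strand, spacer, wmm, sep = ":"))
}

# one-way ANOVA oracle: R's own equal-variance test
oracle_anova <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
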