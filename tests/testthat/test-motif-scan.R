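sigma54_core <- "TGGCACGGAACTTGCT"  # -24 element, 4 nt spacer, -12 element

test_that("a planted sigma-54 consensus core is found exactly once", {
  set.seed(41)
  bg <- random_dna(2000)
  seq <- paste0(substr(bg, 1, 100), sigma54_core,
                substr(bg, 117, 2000))
  hits <- scan_motif(seq, sigma54_motif(0))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 101)
  expect_equal(hits$elem1_start, 101)
  expect_equal(hits$score, 1)  # perfect match scores the maximum
  expect_equal(hits$matched_seq, sigma54_core)
  expect_equal(hits$minus12_base, "C")
  # tss = 12 nt downstream of the -12 C (the C of TTGC)
  expect_equal(hits$tss, 101 + 14 + 12)
})

test_that("a reverse-complemented core is reported on the minus strand", {
  set.seed(42)
  bg <- random_dna(2000)
  rc_core <- revcomp(sigma54_core)
  seq <- paste0(substr(bg, 1, 100), rc_core, substr(bg, 117, 2000))
  hits <- scan_motif(seq, sigma54_motif(0))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 101)
  expect_equal(hits$end, 116)
  # element order mirrors: -24 element is the rightmost block in plus frame
  expect_equal(hits$elem1_end, 116)
  expect_equal(hits$elem2_start, 101)
  expect_equal(hits$minus12_base, "C")
  expect_equal(hits$matched_seq, sigma54_core)
})

test_that("N in the scanned sequence never matches", {
  seq <- paste0(strrep("A", 50), sigma54_core, strrep("A", 50))
  seq_n <- sub("TGGCACG", "TGGNACG", seq, fixed = TRUE)
  expect_equal(nrow(scan_motif(seq_n, sigma54_motif(0))), 0)
  # the N costs exactly that position's weight (1 here)
  hits <- scan_motif(seq_n, sigma54_motif(1))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatch_weight, 1)
})

test_that("scanner output equals the brute-force enumerator", {
  set.seed(43)
  m54 <- sigma54_motif()
  for (rep in 1:10) {
    seq <- random_dna(2000)
    all_windows <- oracle_scan_all(seq, m54$elements, m54$weights,
                                   m54$spacer_range, cap = 4)
    for (thr in 0:3) {
      impl <- scan_motif(seq, sigma54_motif(thr))
      want <- all_windows[all_windows$wmm <= thr, ]
      expect_identical(
        hit_keys(impl$start, impl$strand, impl$spacer, impl$mismatch_weight),
        hit_keys(want$start, want$strand, want$spacer, want$wmm)
      )
    }
  }
  m70 <- sigma70_motif()
  for (rep in 1:3) {
    seq <- random_dna(2000)
    all_windows <- oracle_scan_all(seq, m70$elements, m70$weights,
                                   m70$spacer_range, cap = 4)
    for (thr in c(0, 2, 4)) {
      impl <- scan_motif(seq, sigma70_motif(thr))
      want <- all_windows[all_windows$wmm <= thr, ]
      expect_identical(
        hit_keys(impl$start, impl$strand, impl$spacer, impl$mismatch_weight),
        hit_keys(want$start, want$strand, want$spacer, want$wmm)
      )
    }
  }
})

test_that("lowering the threshold never adds hits", {
  set.seed(44)
  seq <- random_dna(5000)
  keys <- lapply(0:4, function(thr) {
    h <- scan_motif(seq, sigma54_motif(thr))
    hit_keys(h$start, h$strand, h$spacer, h$mismatch_weight)
  })
  for (i in 1:4) expect_true(all(keys[[i]] %in% keys[[i + 1]]))
})

test_that("scanning the reverse complement mirrors strands and coordinates", {
  set.seed(45)
  for (rep in 1:5) {
    seq <- random_dna(3000)
    L <- nchar(seq)
    a <- scan_motif(seq, sigma54_motif(2))
    b <- scan_motif(revcomp(seq), sigma54_motif(2))
    mirrored <- hit_keys(L - b$end + 1L, ifelse(b$strand == "+", "-", "+"),
                         b$spacer, b$mismatch_weight)
    expect_identical(hit_keys(a$start, a$strand, a$spacer, a$mismatch_weight),
                     mirrored)
  }
})

test_that("minus12_conservation computes the C fraction and rejects emptiness", {
  all_c <- data.frame(minus12_base = rep("C", 10))
  expect_equal(minus12_conservation(all_c), 1.0)
  mixed <- data.frame(minus12_base = c(rep("C", 24), "A"))
  expect_equal(minus12_conservation(mixed), 0.96)
  expect_error(minus12_conservation(data.frame(minus12_base = character())),
               "empty")
})

test_that("build_consensus yields normalised columns and IUPAC letters", {
  same <- rep("TGGCAC", 4)
  cons <- build_consensus(same)
  expect_equal(cons$consensus, "TGGCAC")
  expect_true(all(apply(cons$freq, 2, max) == 1))

  two <- c("AAAA", "CAAA")
  cons2 <- build_consensus(two)
  expect_equal(cons2$consensus, "MAAA")
  expect_equal(unname(cons2$freq["A", 1]), 0.5)
  expect_equal(unname(cons2$freq["C", 1]), 0.5)

  set.seed(46)
  seqs <- vapply(1:20, function(i) random_dna(8), character(1))
  cons3 <- build_consensus(seqs)
  expect_true(all(abs(colSums(cons3$freq) - 1) < 1e-12))

  expect_error(build_consensus(c("AAA", "AAAA")), "mixed widths")
  expect_error(build_consensus(character()), "zero sites")
})

test_that("sites map to genes through the upstream/downstream window", {
  genes <- data.frame(
    gene_id = c("g1", "g2"), start = c(1000L, 1100L), end = c(1900L, 2500L),
    strand = c("+", "+"), stringsAsFactors = FALSE
  )
  site <- function(tss) make_site("sigma54", "+", tss - 26, tss - 20,
                                  tss - 15, tss - 11, tss)
  near <- assign_sites_to_genes(site(950), genes, 300, 100)
  expect_equal(near$target_gene_id, "g1")
  far <- assign_sites_to_genes(site(500), genes, 300, 100)
  expect_true(is.na(far$target_gene_id))
  # equidistant between the two 5' ends: smaller start coordinate wins
  tie <- assign_sites_to_genes(site(1050), genes, 300, 100)
  expect_equal(tie$target_gene_id, "g1")
})
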