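plus70 <- function(m35_start = 100L, spacer = 17L) {
  # -35 start, then -10 at m35_start + 6 + spacer, tss 7 nt further
  m10 <- m35_start + 6L + spacer
  make_site("sigma70", "+", m35_start, m35_start + 5L, m10, m10 + 5L,
            tss = m10 + 7L)
}

test_that("the sigma-70 footprint covers -35 pad through tss pad", {
  s <- make_site("sigma70", "+", 100L, 105L, 123L, 128L, tss = 141L)
  fp <- sigma70_footprint(s, 5, 20)
  expect_equal(fp$start, 95L)
  expect_equal(fp$end, 160L)
  fp0 <- sigma70_footprint(s, 0, 0)
  expect_equal(fp0$start, 100L)
  expect_equal(fp0$end, 140L)
  expect_error(sigma70_footprint(make_site("sigma54", "+", 1, 7, 12, 16, 28)),
               "sigma-70")
})

test_that("minus-strand footprints mirror with the end anchored at -35", {
  # mirror image of the plus case: -35 element rightmost, tss leftmost
  s <- make_site("sigma70", "-", 200L, 205L, 177L, 182L, tss = 175L)
  fp <- sigma70_footprint(s, 5, 20)
  expect_equal(fp$start, 156L)  # tss - 20 + 1
  expect_equal(fp$end, 210L)    # -35 end + 5
  expect_equal(fp$strand, "-")
})

test_that("classify_site distinguishes the four positional classes", {
  s70 <- plus70(100L)   # footprint with default pads: [95, 150]
  tss70 <- s70$tss
  s54_at <- function(span_start, strand) {
    el <- if (strand == "+") {
      list(e1 = c(span_start, span_start + 6L),
           e2 = c(span_start + 11L, span_start + 15L))
    } else {
      list(e1 = c(span_start + 9L, span_start + 15L),
           e2 = c(span_start, span_start + 4L))
    }
    make_site("sigma54", strand, el$e1[1], el$e1[2], el$e2[1], el$e2[2],
              tss = span_start)
  }
  # inside the footprint, same strand
  cl1 <- classify_site(s54_at(tss70 + 1L, "+"), s70)
  expect_equal(cl1$site_class, "I")
  expect_gt(cl1$overlap_bp, 0)
  # inside the footprint, opposite strand
  expect_equal(classify_site(s54_at(tss70 + 1L, "-"), s70)$site_class, "II")
  # upstream of the footprint within the distal cutoff
  cl3 <- classify_site(s54_at(44L, "+"), s70)
  expect_equal(cl3$site_class, "III")
  expect_equal(cl3$overlap_bp, 0)
  expect_lte(cl3$distance_bp, 100)
  # far downstream on the opposite strand
  cl4 <- classify_site(s54_at(tss70 + 500L, "-"), s70, distal_cutoff = 100)
  expect_equal(cl4$site_class, "IV")
  expect_gt(cl4$distance_bp, 100)
  expect_equal(cl4$overlap_bp, 0)
  expect_error(classify_site(s70, s70), "sigma-54")
})

test_that("classification is invariant under coordinate translation", {
  s70 <- plus70(100L)
  s54 <- make_site("sigma54", "-", 130L, 136L, 121L, 125L, tss = 121L)
  base <- classify_site(s54, s70)
  shift <- 10000L
  shift_site <- function(s) {
    for (cc in c("start", "end", "elem1_start", "elem1_end",
                 "elem2_start", "elem2_end", "tss")) s[[cc]] <- s[[cc]] + shift
    s
  }
  moved <- classify_site(shift_site(s54), shift_site(s70))
  expect_identical(moved$site_class, base$site_class)
  expect_identical(moved$overlap_bp, base$overlap_bp)
  expect_identical(moved$offset_bp, base$offset_bp)
})

test_that("a genome planting all four configurations yields all four classes", {
  g <- build_genome(40, c(sigma70_repressed_by_sigma54 = 4), seed = 13)
  truth <- g$promoters
  calls <- data.frame(gene_id = truth$target_gene_id,
                      category = "sigma54_repressed",
                      stringsAsFactors = FALSE)
  s54 <- scan_motif(g$sequence, sigma54_motif(2))
  s70 <- scan_motif(g$sequence, sigma70_motif(0))
  res <- classify_repressed_set(calls, s54, s70, g)
  expect_equal(nrow(res$classes), 4)
  expect_true(all(is.na(res$classes$reason)))
  got <- res$classes$site_class[match(truth$target_gene_id,
                                      res$classes$gene_id)]
  expect_identical(got, truth$site_class)
  expect_equal(sum(res$counts), 4)
  expect_identical(unname(res$counts), rep(1L, 4))
})

test_that("per-class consensus motifs are built once a class has members", {
  g <- build_genome(60, c(sigma70_repressed_by_sigma54 = 8), seed = 23)
  calls <- data.frame(gene_id = g$promoters$target_gene_id,
                      category = "sigma54_repressed",
                      stringsAsFactors = FALSE)
  res <- classify_repressed_set(calls,
                                scan_motif(g$sequence, sigma54_motif(2)),
                                scan_motif(g$sequence, sigma70_motif(0)), g)
  expect_identical(unname(res$counts), rep(2L, 4))
  expect_setequal(names(res$consensus), c("I", "II", "III", "IV"))
  for (cons in res$consensus) {
    expect_equal(cons$n_sites, 2)
    expect_true(all(abs(colSums(cons$freq) - 1) < 1e-12))
    # planted repressive sites carry the consensus C at -12
    expect_equal(cons$consensus, "TGGCACGTTGCT")
  }
})

test_that("reverse-complementing the genome preserves the class multiset", {
  g <- build_genome(40, c(sigma70_repressed_by_sigma54 = 4), seed = 27)
  calls <- data.frame(gene_id = g$promoters$target_gene_id,
                      category = "sigma54_repressed",
                      stringsAsFactors = FALSE)
  classify <- function(sequence, genes) {
    classify_repressed_set(
      calls, scan_motif(sequence, sigma54_motif(2)),
      scan_motif(sequence, sigma70_motif(0)), genes)
  }
  fwd <- classify(g$sequence, g$genes)
  L <- nchar(g$sequence)
  genes_rc <- g$genes
  genes_rc$start <- L - g$genes$end + 1L
  genes_rc$end <- L - g$genes$start + 1L
  genes_rc$strand <- ifelse(g$genes$strand == "+", "-", "+")
  rev_ <- classify(revcomp(g$sequence), genes_rc)
  expect_identical(fwd$counts, rev_$counts)
  m <- merge(fwd$classes, rev_$classes, by = "gene_id")
  expect_identical(m$site_class.x, m$site_class.y)
})

test_that("best-scoring sites win and missing sites are reported, not dropped", {
  genes <- data.frame(gene_id = c("gA", "gB"), start = c(1000L, 5000L),
                      end = c(1800L, 5900L), strand = c("+", "+"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = c("gA", "gB"),
                      category = "sigma54_repressed",
                      stringsAsFactors = FALSE)
  s70 <- plus70(970L)
  weak <- make_site("sigma54", "+", 940L, 946L, 951L, 955L, tss = 966L,
                    score = 0.7, aligned_seq = "TGGCACGTTGAT")
  strong <- make_site("sigma54", "+", 900L, 906L, 911L, 915L, tss = 926L,
                      score = 1, aligned_seq = "TGGCACGTTGCT")
  res <- classify_repressed_set(calls, rbind(weak, strong), s70, genes)
  row_a <- res$classes[res$classes$gene_id == "gA", ]
  expect_equal(row_a$s54_start, strong$start)
  row_b <- res$classes[res$classes$gene_id == "gB", ]
  expect_true(is.na(row_b$site_class))
  expect_match(row_b$reason, "no sigma-54 or sigma-70 site")
  expect_equal(sum(res$counts), 1)
})

test_that("no repressed genes produces empty output with zero counts", {
  res <- classify_repressed_set(
    data.frame(gene_id = character(), category = character()),
    empty_sites_for_tests(), empty_sites_for_tests(),
    data.frame(gene_id = character(), start = integer(), end = integer(),
               strand = character()))
  expect_equal(nrow(res$classes), 0)
  expect_identical(unname(res$counts), rep(0L, 4))
})
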