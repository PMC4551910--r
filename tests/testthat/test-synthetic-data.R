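test_that("genome construction is deterministic and respects coordinate contracts", {
  g1 <- small_planted_genome(5)
  g2 <- small_planted_genome(5)
  expect_identical(g1, g2)

  L <- nchar(g1$sequence)
  expect_true(all(g1$genes$start < g1$genes$end))
  expect_true(all(g1$genes$length_bp >= 50))
  expect_true(all(g1$genes$start >= 1) && all(g1$genes$end <= L))
  # genes laid out without overlap
  expect_true(all(g1$genes$start[-1] > g1$genes$end[-nrow(g1$genes)]))
  # promoter element coordinates within bounds
  p <- g1$promoters
  coords <- c(p$elem1_start, p$elem1_end, p$elem2_start, p$elem2_end,
              p$s54_elem1_start, p$s54_elem2_end)
  coords <- coords[!is.na(coords)]
  expect_true(all(coords >= 1 & coords <= L))
})

test_that("genome construction rejects impossible requests", {
  expect_error(build_genome(10, c(sigma54_bypass = 5), seed = 1),
               "at least 4x")
  expect_error(build_genome(20, c(not_a_type = 1), seed = 1),
               "unknown promoter type")
  expect_error(sim_params(gc = 0), "gc")
})

test_that("every planted element is rediscoverable at its truth coordinates", {
  g <- small_planted_genome(1)
  s54 <- scan_motif(g$sequence, sigma54_motif(2))
  s70 <- scan_motif(g$sequence, sigma70_motif(0))
  for (i in seq_len(nrow(g$promoters))) {
    pr <- g$promoters[i, ]
    if (pr$promoter_type %in% c("sigma54_activator_dependent",
                                "sigma54_bypass")) {
      hit <- s54[s54$elem1_start == pr$elem1_start &
                   s54$strand == pr$strand, ]
      expect_equal(nrow(hit), 1)
      expect_identical(hit$minus12_base, pr$minus12_base)
      # consensus-C sites match perfectly, bypass sites miss only the
      # weight-2 C position
      expect_equal(hit$mismatch_weight,
                   if (pr$minus12_base == "C") 0 else 2)
      expect_equal(hit$tss, pr$tss)
      expect_equal(hit$elem2_end, pr$elem2_end)
    } else {
      hit <- s70[s70$elem1_start == pr$elem1_start &
                   s70$strand == pr$strand, ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$mismatch_weight, 0)
      expect_equal(hit$tss, pr$tss)
      if (!is.na(pr$s54_elem1_start)) {
        h2 <- s54[s54$elem1_start == pr$s54_elem1_start &
                    s54$strand == pr$s54_strand, ]
        expect_gte(nrow(h2), 1)
        expect_true(any(h2$mismatch_weight == 0))
        expect_true(any(h2$tss == pr$s54_tss))
      }
    }
  }
})

test_that("class IV repressed sites are distal convergent configurations", {
  g <- small_planted_genome(3)
  p4 <- g$promoters[!is.na(g$promoters$site_class) &
                      g$promoters$site_class == "IV", ]
  expect_gte(nrow(p4), 1)
  for (i in seq_len(nrow(p4))) {
    pr <- p4[i, ]
    expect_false(pr$s54_strand == pr$strand)
    span <- c(min(pr$s54_elem1_start, pr$s54_elem2_start),
              max(pr$s54_elem1_end, pr$s54_elem2_end))
    downstream_gap <- if (pr$strand == "+") span[1] - pr$tss
                      else pr$tss - span[2]
    expect_gt(downstream_gap, 100)
  }
})

test_that("count simulation is deterministic with integer non-negative counts", {
  g <- small_planted_genome(2)
  cm1 <- simulate_counts(g, depth = 1e5, n_replicates = 3, seed = 4)
  cm2 <- simulate_counts(g, depth = 1e5, n_replicates = 3, seed = 4)
  expect_identical(cm1, cm2)
  expect_true(is.integer(cm1$counts))
  expect_true(all(cm1$counts >= 0))
  expect_identical(colnames(cm1$counts),
                   paste(rep(c("WT", "dRI", "none"), each = 3), 1:3,
                         sep = "_"))
  expect_equal(unname(library_sizes(cm1)), unname(colSums(cm1$counts)))
  expect_error(simulate_counts(g, depth = 0), "depth")
  expect_error(simulate_counts(g, depth = 1e5, dispersion = 0), "dispersion")
})

test_that("counts match the negative-binomial mean and variance model", {
  g <- build_genome(8, c(sigma70_repressed_by_sigma54 = 1,
                         sigma54_activator_dependent = 1),
                    seed = 3, params = sim_params(repressed_classes = "I"))
  mu <- expected_counts(g, 1e5)

  # near-Poisson limit: empirical means within 3 standard errors
  cm <- simulate_counts(g, depth = 1e5, n_replicates = 200,
                        dispersion = 1e9, seed = 6)
  wt_cols <- cm$samples$sample[cm$samples$strain == "WT"]
  for (gid in rownames(mu)) {
    obs <- cm$counts[gid, wt_cols]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - mu[gid, "WT"]), 3 * se)
  }

  # per-strain totals track depth
  expect_lt(abs(mean(library_sizes(cm)) / 1e5 - 1), 0.02)

  # repressed gene: none/WT mean ratio recovers the 8x activity difference
  rep_gene <- g$genes$gene_id[g$genes$promoter_type ==
                                "sigma70_repressed_by_sigma54"]
  # activity ratio is 8 by construction; the realised count-mean ratio is
  # 8 scaled by the per-strain depth normalisers, which the means obey
  expect_equal(g$genes[g$genes$gene_id == rep_gene, "activity_none"] /
                 g$genes[g$genes$gene_id == rep_gene, "activity_WT"], 8)
  none_cols <- cm$samples$sample[cm$samples$strain == "none"]
  m_wt <- mean(cm$counts[rep_gene, wt_cols])
  m_none <- mean(cm$counts[rep_gene, none_cols])
  ratio <- m_none / m_wt
  se_ratio <- ratio * sqrt(1 / (200 * m_wt) + 1 / (200 * m_none))
  true_ratio <- mu[rep_gene, "none"] / mu[rep_gene, "WT"]
  expect_lt(abs(ratio - true_ratio), 3 * se_ratio)

  # overdispersed regime: sample variance tracks mu + mu^2 / k
  k <- 5
  cm2 <- simulate_counts(g, depth = 1e5, n_replicates = 500,
                         dispersion = k, seed = 7)
  gid <- rownames(mu)[which.max(mu[, "WT"])]
  obs <- cm2$counts[gid, cm2$samples$sample[cm2$samples$strain == "WT"]]
  expected_var <- mu[gid, "WT"] + mu[gid, "WT"]^2 / k
  expect_lt(abs(stats::var(obs) / expected_var - 1), 0.3)
})
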