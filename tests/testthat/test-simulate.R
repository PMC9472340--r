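test_that("genome layout is even, ordered, and deterministic", {
  p <- sim_params(n_pairs = 10, n_chrom_pairs = 2, seed = 1)
  g <- simulate_genome(p)
  expect_equal(nrow(g$pairs), 10)
  expect_equal(sort(unique(g$pairs$chrom_pair)), c("cp01", "cp02"))
  for (cp in c("cp01", "cp02")) {
    expect_equal(g$pairs$order_index[g$pairs$chrom_pair == cp], 0:4)
  }
  # genes non-overlapping per chromosome
  for (chrom in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == chrom, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  g2 <- simulate_genome(p)
  expect_identical(g, g2)
  expect_error(simulate_genome(sim_params(n_pairs = 1, n_chrom_pairs = 2)),
               "n_pairs")
})

test_that("planted effects obey the cis/trans model identity at high depth", {
  all_conserved <- c(conserved = 1, cis_only = 0, trans_only = 0,
                     cis_plus_trans = 0, cis_x_trans = 0, compensatory = 0,
                     ambiguous = 0)
  p <- sim_params(n_pairs = 40, n_chrom_pairs = 1, depth_mean = 1e6,
                  nb_dispersion = 0, baseline_sdlog = 0,
                  category_proportions = all_conserved, seed = 7)
  g <- simulate_genome(p)
  e <- simulate_expression(g$pairs, p)
  ratios <- homoeolog_ratios(normalize_counts(e$counts), g$pairs)
  expect_true(all(abs(ratios$log2rc) < 0.05))

  all_cis <- c(conserved = 0, cis_only = 1, trans_only = 0,
               cis_plus_trans = 0, cis_x_trans = 0, compensatory = 0,
               ambiguous = 0)
  p2 <- sim_params(n_pairs = 40, n_chrom_pairs = 1, depth_mean = 1e6,
                   nb_dispersion = 0, baseline_sdlog = 0,
                   category_proportions = all_cis,
                   trans_compensation_F22 = 1, seed = 8)
  g2 <- simulate_genome(p2)
  e2 <- simulate_expression(g2$pairs, p2)
  # the model identity is a generator property: read it off the raw scale
  # (total-count normalization is only neutral when most genes are balanced)
  raw <- dplyr::mutate(e2$counts, norm_factor = 1, norm_count = count)
  r2 <- homoeolog_ratios(raw, g2$pairs)
  for (grp in c("parental", "F1")) {
    x <- r2[r2$group == grp, ]
    expect_true(all(abs(abs(x$log2rc) - 2) < 0.05), label = grp)
  }
  # full trans compensation drives F22 back to balance
  expect_true(all(abs(r2$log2rc[r2$group == "F22"]) < 0.05))
  # signs of realized P match the planted cis direction
  par <- r2[r2$group == "parental", ]
  expect_equal(sign(par$log2rc),
               sign(e2$truth$true_cis[match(par$pair_id,
                                            e2$truth$pair_id)]))
})

test_that("methylation planting is realized and deterministic", {
  p <- sim_params(n_pairs = 30, n_chrom_pairs = 1, meth_depth = 1000,
                  dm_fraction = 1, dm_effect = 0.7, dm_hybrid_effect = 0,
                  p0_error = 0.01, cytosines_per_region = 40, seed = 3)
  g <- simulate_genome(p)
  m <- simulate_methylation(g$pairs, g$genes, p)
  expect_true(all(m$cytosines$k_meth <= m$cytosines$n_total))
  lv <- region_levels(m$cytosines, g$genes, regions = "up2k")
  key <- paste(lv$group, lv$gene_id)
  ml <- setNames(lv$mean_ml, key)
  dm_obs <- unname(ml[paste("parent_R", g$pairs$r_gene)]) -
    unname(ml[paste("parent_C", g$pairs$c_gene)])
  expect_true(all(abs(dm_obs - 0.7) < 0.03))
  m2 <- simulate_methylation(g$pairs, g$genes, p)
  expect_identical(m$cytosines, m2$cytosines)
})

test_that("copy-number segments shift the planted depth ratio", {
  seg <- tibble::tibble(chrom_pair = "cp01", start_index = 10L,
                        n_genes = 5L, r_copies = 3, c_copies = 1)
  p <- sim_params(n_pairs = 40, n_chrom_pairs = 1, depth_mean = 1e4,
                  hr_segments = seg, seed = 5)
  g <- simulate_genome(p)
  cn <- simulate_copy_number(g$pairs, p, genes = g$genes)
  rec <- copy_ratio_records(cn$depth)
  inside <- rec$order_index >= 10 & rec$order_index <= 14
  expect_true(all(abs(rec$log10_ratio[inside] - log10(3)) < 0.05))
  expect_true(all(abs(rec$log10_ratio[!inside]) < 0.05))

  p0 <- sim_params(n_pairs = 40, n_chrom_pairs = 1, depth_mean = 1e4,
                   seed = 5)
  cn0 <- simulate_copy_number(g$pairs, p0, genes = g$genes)
  expect_true(all(abs(copy_ratio_records(cn0$depth)$log10_ratio) < 0.05))

  segrm <- tibble::tibble(chrom_pair = "cp01", start_index = 5L,
                          n_genes = 3L, r_copies = 0, c_copies = 4)
  prm <- sim_params(n_pairs = 40, n_chrom_pairs = 1, hr_segments = segrm,
                    seed = 6)
  cnrm <- simulate_copy_number(g$pairs, prm, genes = g$genes)
  expect_true(all(cnrm$depth$r_reads[6:8] == 0))

  overlap <- tibble::tibble(chrom_pair = "cp01",
                            start_index = c(5L, 7L), n_genes = c(3L, 3L),
                            r_copies = 3, c_copies = 1)
  pov <- sim_params(n_pairs = 40, n_chrom_pairs = 1, hr_segments = overlap)
  expect_error(simulate_copy_number(g$pairs, pov), "overlapping")
})

test_that("SV intensity tracks TE density only when the slope is non-zero", {
  p0 <- sim_params(n_pairs = 400, n_chrom_pairs = 2, window_size = 2e4,
                   sv_te_slope = 0, seed = 11)
  g <- simulate_genome(p0)
  s0 <- simulate_sv(g$te, g$chrom_sizes, p0)
  expect_gt(nrow(s0$windows), 300)
  expect_lt(abs(cor(s0$windows$te_density, s0$windows$sv_count)), 0.1)

  p3 <- sim_params(n_pairs = 400, n_chrom_pairs = 2, window_size = 2e4,
                   sv_te_slope = 3, seed = 11)
  s3 <- simulate_sv(g$te, g$chrom_sizes, p3)
  ct <- sv_te_correlation(s3$windows)
  expect_gt(ct$r, 0)
  expect_lt(ct$p, 0.001)
  s3b <- simulate_sv(g$te, g$chrom_sizes, p3)
  expect_identical(s3$sv, s3b$sv)
})

test_that("every pair appears in ground truth exactly once", {
  p <- sim_params(n_pairs = 50, n_chrom_pairs = 2, seed = 2)
  g <- simulate_genome(p)
  e <- simulate_expression(g$pairs, p)
  m <- simulate_methylation(g$pairs, g$genes, p)
  cn <- simulate_copy_number(g$pairs, p, genes = g$genes)
  for (tr in list(e$truth, m$truth, cn$truth)) {
    expect_setequal(tr$pair_id, g$pairs$pair_id)
    expect_equal(anyDuplicated(tr$pair_id), 0L)
  }
})
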