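test_that("binomial 5mC p-values equal the exact upper tail", {
  expect_equal(call_5mc(0, 10, 0.01), 1)
  expect_equal(call_5mc(5, 5, 0.01), 1e-10)
  expect_equal(call_5mc(1, 10, 0.01), 1 - 0.99^10)
  # direct-summation oracle over all (k, n) up to 50
  for (n in c(1, 7, 23, 50)) {
    k <- 0:n
    direct <- vapply(k, function(ki)
      sum(choose(n, ki:n) * 0.01^(ki:n) * 0.99^(n - (ki:n))), numeric(1))
    expect_equal(call_5mc(k, n, 0.01), direct, tolerance = 1e-12)
    # monotone non-increasing in k
    expect_true(all(diff(call_5mc(k, n, 0.01)) <= 1e-15))
  }
  expect_error(call_5mc(11, 10, 0.01), "k_meth")
})

test_that("batch calling gates on depth and controls the FDR", {
  cy <- tibble::tibble(k_meth = c(4, 30, 0), n_total = c(4, 30, 30))
  out <- call_5mc_batch(cy)
  expect_false(out$tested[1])
  expect_true(is.na(out$q[1]))
  expect_true(out$is_methylated[2])
  expect_false(out$is_methylated[3])

  set.seed(5)
  n <- 2e4
  depth <- rpois(n, 30)
  truth <- runif(n) < 0.2
  prob <- ifelse(truth, 0.8, 0.01)
  null_cy <- tibble::tibble(k_meth = rbinom(n, depth, prob), n_total = depth)
  calls <- call_5mc_batch(null_cy)
  called <- which(calls$is_methylated)
  fdp <- if (length(called)) mean(!truth[called]) else 0
  expect_lte(fdp, 0.07)
  expect_gt(mean(calls$is_methylated[truth & calls$tested]), 0.9)
})

test_that("window profiles are strand-aware and conserve coverage", {
  gene <- tibble::tibble(gene_id = "g", chrom = "c1", start = 10000,
                         end = 12000, strand = "+")
  cy <- tibble::tibble(chrom = "c1", pos = seq(10010, 11990, by = 40),
                       strand = "+", context = "CpG",
                       k_meth = 5, n_total = 10)
  pr <- region_profile(cy, gene, "body")
  expect_equal(length(pr$window_ml), 20)
  expect_equal(pr$window_ml, rep(0.5, 20))
  expect_equal(pr$mean_ml, 0.5)
  # coverage-weighted window mean equals the region mean
  cy2 <- cy; cy2$k_meth <- rep(c(2, 9), length.out = nrow(cy2))
  pr2 <- region_profile(cy2, gene, "body")
  w_n <- tapply(cy2$n_total,
                findInterval(cy2$pos, seq(10000, 12000, length.out = 21),
                             rightmost.closed = TRUE), sum)
  expect_equal(sum(pr2$window_ml * w_n) / sum(w_n), pr2$mean_ml,
               tolerance = 1e-9)

  # minus-strand genes reverse the window order
  up <- cy[1:10, ]
  gene_m <- gene; gene_m$strand <- "-"
  asc <- cy; asc$k_meth <- round(seq(0, 10, length.out = nrow(cy)))
  pr_p <- region_profile(asc, gene, "body")
  pr_m <- region_profile(asc, gene_m, "body")
  expect_equal(pr_m$window_ml, rev(pr_p$window_ml))

  empty <- region_profile(cy[0, ], gene, "body")
  expect_true(all(is.na(empty$window_ml)))
  expect_true(is.na(empty$mean_ml))
})

test_that("upstream regions follow the strand", {
  gene_p <- tibble::tibble(gene_id = "gp", chrom = "c1", start = 5000,
                           end = 6000, strand = "+")
  gene_m <- tibble::tibble(gene_id = "gm", chrom = "c1", start = 5000,
                           end = 6000, strand = "-")
  cy_up <- tibble::tibble(chrom = "c1", pos = seq(3000, 4999, by = 25),
                          strand = "+", context = "CpG", k_meth = 8,
                          n_total = 10)
  expect_equal(region_profile(cy_up, gene_p, "up2k")$mean_ml, 0.8)
  expect_equal(region_profile(cy_up, gene_m, "up2k")$n_cytosines, 0)
  expect_equal(region_profile(cy_up, gene_m, "down2k")$mean_ml, 0.8)
})

test_that("methylation differences and the region test behave", {
  expect_equal(dm_value(0.8, 0.2), 0.6)
  expect_equal(dm_value(0.5, 0.5), 0)
  expect_equal(dm_value(0.3, 0.9), -dm_value(0.9, 0.3))
  expect_error(dm_value(1.2, 0.5), "0, 1")

  same <- dmr_test(50, 100, 50, 100)
  expect_equal(same$p, 1)
  expect_false(same$is_dmr)
  strong <- dmr_test(90, 100, 10, 100)
  expect_lt(strong$p, 1e-5)
  expect_true(strong$is_dmr)
  weak <- dmr_test(55, 100, 45, 100)
  expect_false(weak$is_dmr)  # |dm| = 0.1 fails the strict effect gate
  expect_error(dmr_test(0, 0, 5, 10), "zero")
})

test_that("DMG classes reproduce the printed decision boundaries", {
  expect_equal(classify_dmg(0.7, 0.1), "hyper_dmg")
  expect_equal(classify_dmg(0.5, 0.1), "hypo_dmg")
  expect_equal(classify_dmg(0.7, 0.5), "none")
  # boundary straddles around 0.6 (parents) and 0.3 / 0.2 (hybrid)
  eps <- 1e-6
  expect_equal(classify_dmg(0.6 + eps, 0.1), "hyper_dmg")
  expect_equal(classify_dmg(0.6 - eps, 0.1), "hypo_dmg")
  expect_equal(classify_dmg(0.6, 0.1), "none")  # 0.6: neither > 0.6 nor < 0.6
  expect_equal(classify_dmg(0.7, 0.3 - eps), "hyper_dmg")
  expect_equal(classify_dmg(0.7, 0.3), "none")          # 0.3 not < 0.3
  expect_equal(classify_dmg(0.5, 0.2 - eps), "hypo_dmg")
  expect_equal(classify_dmg(0.5, 0.2), "none")
  expect_equal(classify_dmg(0, 0.1), "none")            # requires dm > 0
  # magnitudes are used, signs ignored
  expect_equal(classify_dmg(-0.7, -0.1), "hyper_dmg")
})

test_that("MRG calls require large discordant changes", {
  expect_true(detect_mrg(0.5, -2.5)$is_mrg)
  expect_false(detect_mrg(0.5, 2.5)$is_mrg)   # concordant
  expect_false(detect_mrg(0.3, -3)$is_mrg)    # dm gate
  eps <- 1e-6
  expect_false(detect_mrg(0.4, -2.5)$is_mrg)  # 0.4 not > 0.4
  expect_true(detect_mrg(0.4 + eps, -2.5)$is_mrg)
  expect_false(detect_mrg(0.5, -2)$is_mrg)    # fold change 4 not > 4
  expect_true(detect_mrg(0.5, -(2 + eps))$is_mrg)
  expect_true(detect_mrg(-0.5, 2.5)$is_mrg)   # hypomethylated, up
})

test_that("planted parental differences classify as hyper-DMGs", {
  p <- sim_params(n_pairs = 60, n_chrom_pairs = 1, meth_depth = 30,
                  cytosines_per_region = 50, dm_fraction = 0.5,
                  dm_effect = 0.7, dm_hybrid_effect = 0.05, seed = 13)
  g <- simulate_genome(p)
  m <- simulate_methylation(g$pairs, g$genes, p)
  lv <- region_levels(m$cytosines, g$genes, regions = "up2k")
  ml <- setNames(lv$mean_ml, paste(lv$group, lv$gene_id))
  dm_par <- unname(ml[paste("parent_R", g$pairs$r_gene)]) -
    unname(ml[paste("parent_C", g$pairs$c_gene)])
  dm_hyb <- unname(ml[paste("F1", g$pairs$r_gene)]) -
    unname(ml[paste("F1", g$pairs$c_gene)])
  cls <- classify_dmg(dm_par, dm_hyb)
  planted <- m$truth$true_dm_parents > 0
  expect_gte(mean(cls[planted] == "hyper_dmg"), 0.9)
  expect_lte(mean(cls[!planted] == "hyper_dmg"), 0.05)
})
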