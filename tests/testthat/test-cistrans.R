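test_that("count test combines a Welch p-value with the fold-change gate", {
  same <- count_diff_test(c(50, 60, 55), c(50, 60, 55))
  expect_equal(same$log2fc, 0)
  expect_false(same$significant)

  strong <- count_diff_test(c(100, 110, 90), c(10, 11, 9))
  expect_gt(abs(strong$log2fc), 2)
  expect_lt(strong$p, 0.01)
  expect_true(strong$significant)

  gated <- count_diff_test(c(100, 110, 90), c(60, 66, 54))
  expect_lt(abs(gated$log2fc), 2)
  expect_false(gated$significant)  # fold-change gate, regardless of p

  expect_error(count_diff_test(c(1, 2), 3), "2 replicates")
})

test_that("ratio test behaves on degenerate and unequal inputs", {
  flat <- ratio_diff_test(c(1, 1, 1), c(1, 1, 1))
  expect_gt(flat$p, 0.9)
  expect_false(flat$significant)

  shift <- ratio_diff_test(c(2.0, 2.1, 1.9), c(0.0, 0.1, -0.1))
  expect_lt(shift$p, 0.01)
  expect_true(shift$significant)

  uneq <- ratio_diff_test(c(2, 2), c(0, 0, 0))
  expect_true(is.finite(uneq$p))
  expect_error(ratio_diff_test(c(1, Inf), c(0, 0)), "non-finite")
})

test_that("seven-way rule matches an exhaustive independent oracle", {
  # independent truth table: conserved (no signal); cis_only (parent and
  # hybrid diverge, ratio unchanged); trans_only (parent diverges, hybrid
  # does not, ratio shifts); both cis and trans with sign agreement
  # (enhancing) or opposition (antagonistic); compensatory (hybrid-only
  # divergence with a ratio shift); everything else ambiguous
  oracle <- function(sp, sh, st, h, t) {
    sgn <- function(x) if (x > 1e-9) 1 else if (x < -1e-9) -1 else 0
    if (!sp && !sh && !st) return("conserved")
    if (sp && sh && !st) return("cis_only")
    if (sp && !sh && st) return("trans_only")
    if (sp && sh && st) {
      if (sgn(h) == 0 || sgn(t) == 0) return("ambiguous")
      return(if (sgn(h) == sgn(t)) "cis_plus_trans" else "cis_x_trans")
    }
    if (!sp && sh && st) return("compensatory")
    "ambiguous"
  }
  grid <- expand.grid(sp = c(FALSE, TRUE), sh = c(FALSE, TRUE),
                      st = c(FALSE, TRUE),
                      h = c(-1.5, -0.5, 0, 0.5, 1.5),
                      t = c(-2, 0, 2))
  got <- classify7(grid$sp, grid$sh, grid$st, grid$h, grid$t)
  want <- mapply(oracle, grid$sp, grid$sh, grid$st, grid$h, grid$t)
  expect_equal(got, unname(want))
  # exactly one label everywhere
  expect_true(all(got %in% c("conserved", "cis_only", "trans_only",
                             "cis_plus_trans", "cis_x_trans",
                             "compensatory", "ambiguous")))
})

test_that("13-way subpatterns split by the driving component", {
  s <- subpattern13("cis_only", p = 2.5, h = 2.5)
  expect_equal(s$subpattern13, "cis_only_toR")
  expect_true(s$strong)  # |2.5| > log2(4)

  s <- subpattern13("trans_only", p = -2.2, h = 0.1)
  expect_equal(s$subpattern13, "trans_only_toC")  # T = -2.3 drives

  s <- subpattern13("conserved", p = 5, h = 5)
  expect_equal(s$subpattern13, "conserved")

  s <- subpattern13("cis_only", p = 1.5, h = 1.5, dm = 0.5)
  expect_true(s$strong)  # methylation difference above 0.3
  s <- subpattern13("cis_only", p = 1.5, h = 1.5, dm = 0.1)
  expect_false(s$strong)

  # the label space is conserved + 6 categories x 2 directions = 13
  cats <- c("cis_only", "trans_only", "cis_plus_trans", "cis_x_trans",
            "compensatory", "ambiguous")
  labs <- unique(c("conserved",
                   subpattern13(rep(cats, 2),
                                p = rep(c(3, -3), each = 6),
                                h = rep(c(2, -2), each = 6))$subpattern13))
  expect_equal(length(labs), 13)
})

test_that("planted regulatory architectures are recovered from counts", {
  p <- sim_params(n_pairs = 300, n_chrom_pairs = 1, seed = 21)
  g <- simulate_genome(p)
  e <- simulate_expression(g$pairs, p)
  counts <- normalize_counts(e$counts)
  calls <- classify_pairs(counts, g$pairs, "F1")
  j <- dplyr::inner_join(tidy(calls), e$truth, by = "pair_id")
  for (cat in c("cis_only", "trans_only", "compensatory")) {
    expect_gt(mean(j$category7[j$true_category7 == cat] == cat), 0.7,
              label = cat)
  }
  expect_lt(mean(j$category7[j$true_category7 == "conserved"] !=
                   "conserved"), 0.05)
  # H tracks planted cis for cis_only pairs
  ci <- j[j$true_category7 == "cis_only", ]
  expect_lt(median(abs(ci$H - ci$true_cis)), 0.5)
  # compensatory pairs have parental ratio near zero
  cp <- j[j$true_category7 == "compensatory", ]
  expect_lt(median(abs(cp$P)), 0.5)
  # tidiers
  gl <- glance(calls)
  expect_equal(gl$n, nrow(calls))
  expect_equal(sum(unlist(gl[grep("frac_", names(gl))])), 1)
})

test_that("R/C relabeling mirrors the classification", {
  p <- sim_params(n_pairs = 120, n_chrom_pairs = 1, seed = 31)
  g <- simulate_genome(p)
  e <- simulate_expression(g$pairs, p)
  counts <- normalize_counts(e$counts)
  fwd <- classify_pairs(counts, g$pairs, "F1")
  sw_pairs <- g$pairs
  sw_pairs$r_gene <- g$pairs$c_gene; sw_pairs$c_gene <- g$pairs$r_gene
  sw_counts <- counts
  sw_counts$role[counts$role == "parent_R"] <- "parent_C"
  sw_counts$role[counts$role == "parent_C"] <- "parent_R"
  rev <- classify_pairs(sw_counts, sw_pairs, "F1")
  m <- match(fwd$pair_id, rev$pair_id)
  expect_equal(rev$P[m], -fwd$P)
  expect_equal(rev$H[m], -fwd$H)
  expect_equal(rev$category7[m], fwd$category7)
  flip <- function(x) ifelse(grepl("_toR$", x), sub("_toR$", "_toC", x),
                             sub("_toC$", "_toR", x))
  expect_equal(rev$subpattern13[m],
               ifelse(fwd$subpattern13 == "conserved", "conserved",
                      flip(fwd$subpattern13)))
})

test_that("Ka/Ks group statistics detect shifted categories", {
  calls <- tibble::tibble(pair_id = paste0("p", 1:400),
                          category7 = rep(c("cis_only", "conserved"), 200))
  set.seed(1)
  kaks <- tibble::tibble(
    pair_id = calls$pair_id,
    ks = rep(0.3, 400),
    ka = ifelse(calls$category7 == "cis_only",
                rlnorm(400, log(0.12), 0.3), rlnorm(400, log(0.06), 0.3)))
  kaks$ka_ks <- kaks$ka / kaks$ks
  st <- kaks_group_stats(kaks, calls)
  expect_lt(st$tests$p[st$tests$group == "cis_only"], 0.05)
  expect_gt(st$summary$mean_ka_ks[st$summary$category7 == "cis_only"],
            st$summary$mean_ka_ks[st$summary$category7 == "conserved"])

  # same distribution: no signal
  flat <- kaks
  flat$ka_ks <- rep(kaks$ka_ks[calls$category7 == "conserved"], 2)[1:400]
  stf <- kaks_group_stats(flat, calls)
  expect_gt(stf$tests$p[stf$tests$group == "cis_only"], 0.05)

  # single-member category: summary only, no test row
  single <- calls; single$category7[1] <- "trans_only"
  single$category7[2:400] <- "conserved"
  sts <- kaks_group_stats(kaks, single)
  expect_false("trans_only" %in% sts$tests$group)
  expect_true("trans_only" %in% sts$summary$category7)
})

test_that("binary association matches expectation on canonical inputs", {
  expect_equal(binary_association(c(1, 0, 1, 0) > 0,
                                  c(1, 0, 1, 0) > 0)$phi, 1)
  expect_equal(binary_association(c(1, 0, 1, 0) > 0,
                                  c(0, 1, 0, 1) > 0)$phi, -1)
  expect_error(binary_association(c(TRUE, TRUE, TRUE),
                                  c(TRUE, FALSE, TRUE)), "constant")
  set.seed(2)
  a <- runif(1000) < 0.3; b <- runif(1000) < 0.3
  expect_lt(abs(binary_association(a, b)$phi), 0.1)
})
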