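# deterministic tie rule for signs near zero
sign3 <- function(x, eps = 1e-9) {
  ifelse(x > eps, 1, ifelse(x < -eps, -1, 0))
}

# zero-variance guard: spread a deterministic 1e-9 jitter before a t-test
jitter_if_constant <- function(x) {
  if (length(x) >= 2 && stats::var(x) == 0) {
    x + (seq_along(x) - mean(seq_along(x))) * 1e-9
  } else x
}

#' Replicate-level expression difference test
#'
#' Welch two-sided t-test on `log2(count + 0.5)` replicate values with a
#' fold-change gate: the difference is significant when `p <
#' alpha_count_test` and `|log2FC| > log2(fc_threshold)` (default 4-fold,
#' p < 0.01). `log2FC` uses a 0.5 pseudocount on the replicate means.
#'
#' @param counts_a,counts_b Normalized replicate counts (>= 2 each).
#' @param config An [hs_config()].
#'
#' @return A list: `log2fc`, `p`, `significant`.
#' @export
count_diff_test <- function(counts_a, counts_b, config = hs_config()) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    stop("need at least 2 replicates per side", call. = FALSE)
  }
  log2fc <- log2((mean(counts_a) + 0.5) / (mean(counts_b) + 0.5))
  la <- jitter_if_constant(log2(counts_a + 0.5))
  lb <- jitter_if_constant(log2(counts_b + 0.5))
  p <- stats::t.test(la, lb)$p.value
  list(log2fc = log2fc, p = p,
       significant = p < config$alpha_count_test &&
         abs(log2fc) > log2(config$fc_threshold))
}

#' Parental-versus-hybrid ratio difference test
#'
#' Welch two-sided two-sample t-test on per-replicate log2(R/C) values;
#' significant when `p < alpha_ratio_test` (default 0.01).
#'
#' @param parent_ratios,hybrid_ratios Per-replicate log2 ratios (>= 2 each).
#' @param config An [hs_config()].
#'
#' @return A list: `p`, `significant`.
#' @export
ratio_diff_test <- function(parent_ratios, hybrid_ratios,
                            config = hs_config()) {
  if (any(!is.finite(parent_ratios)) || any(!is.finite(hybrid_ratios))) {
    stop("non-finite log2 ratio; filter pairs first", call. = FALSE)
  }
  if (length(parent_ratios) < 2 || length(hybrid_ratios) < 2) {
    stop("need at least 2 ratios per side", call. = FALSE)
  }
  a <- jitter_if_constant(parent_ratios)
  b <- jitter_if_constant(hybrid_ratios)
  p <- stats::t.test(a, b)$p.value
  list(p = p, significant = p < config$alpha_ratio_test)
}

#' Seven-way cis/trans regulatory classification
#'
#' Maps the three significance flags (parental divergence, hybrid homoeolog
#' divergence, parental-vs-hybrid ratio shift) and the signs of the hybrid
#' ratio `H` and the trans component `T = P - H` onto the seven standard
#' regulatory patterns:
#'
#' * no test significant: conserved
#' * parental + hybrid significant, ratio shift not: cis_only
#' * parental + ratio shift significant, hybrid not: trans_only
#' * all three significant: cis_plus_trans when `sign(H) == sign(T)`,
#'   cis_x_trans when opposite
#' * hybrid + ratio shift significant, parental not: compensatory
#' * any other combination: ambiguous
#'
#' A sign that is needed but numerically zero (|x| <= 1e-9) sends the pair
#' to ambiguous.
#'
#' @param sig_p,sig_h,sig_t Logical significance flags.
#' @param h,t Hybrid log2 ratio and trans component (log2 units).
#'
#' @return Character vector of category labels.
#' @export
classify7 <- function(sig_p, sig_h, sig_t, h, t) {
  n <- max(length(sig_p), length(sig_h), length(sig_t), length(h), length(t))
  sig_p <- rep_len(sig_p, n); sig_h <- rep_len(sig_h, n)
  sig_t <- rep_len(sig_t, n); h <- rep_len(h, n); t <- rep_len(t, n)
  if (any(!is.finite(h)) || any(!is.finite(t))) {
    stop("H and T must be finite", call. = FALSE)
  }
  sh <- sign3(h); st <- sign3(t)
  out <- character(n)
  for (i in seq_len(n)) {
    key <- paste0(as.integer(sig_p[i]), as.integer(sig_h[i]),
                  as.integer(sig_t[i]))
    out[i] <- switch(
      key,
      "000" = "conserved",
      "110" = "cis_only",
      "101" = "trans_only",
      "111" = if (sh[i] == 0 || st[i] == 0) "ambiguous"
              else if (sh[i] == st[i]) "cis_plus_trans" else "cis_x_trans",
      "011" = "compensatory",
      "ambiguous")
  }
  out
}

#' Thirteen-way directional subpatterns
#'
#' Conserved stays a single label; each other category splits into `_toR` /
#' `_toC` by the sign of its driving component: the hybrid ratio `H` for
#' cis-driven categories (cis_only, cis_plus_trans, cis_x_trans, ambiguous)
#' and the trans component `T = P - H` for trans-driven ones (trans_only,
#' compensatory). A `strong` flag marks pairs whose parental or hybrid
#' ratio exceeds log2(4) in magnitude, or whose methylation difference
#' exceeds `dm_subpattern` (0.3) when supplied.
#'
#' @param category7 Labels from [classify7()].
#' @param p,h Parental and hybrid log2 ratios.
#' @param dm Optional methylation difference for the same comparison.
#' @param config An [hs_config()].
#'
#' @return A tibble: `subpattern13`, `strong`.
#' @export
subpattern13 <- function(category7, p, h, dm = NA_real_,
                         config = hs_config()) {
  n <- length(category7)
  p <- rep_len(p, n); h <- rep_len(h, n); dm <- rep_len(dm, n)
  t <- p - h
  driver <- ifelse(category7 %in% c("trans_only", "compensatory"), t, h)
  # fall back to the other component when the driver is numerically zero
  fallback <- ifelse(category7 %in% c("trans_only", "compensatory"), h, t)
  d <- sign3(driver)
  d <- ifelse(d == 0, sign3(fallback), d)
  suffix <- ifelse(d >= 0, "_toR", "_toC")
  label <- ifelse(category7 == "conserved", "conserved",
                  paste0(category7, suffix))
  strong <- pmax(abs(p), abs(h)) > log2(4) |
    (!is.na(dm) & abs(dm) > config$dm_subpattern)
  tibble(subpattern13 = label, strong = strong)
}

# limma-trend moderated two-group comparison on a (pairs x replicates)
# value matrix; returns per-row p and mean difference (a - b)
moderated_two_group <- function(mat_a, mat_b) {
  e <- cbind(mat_a, mat_b)
  design <- cbind(intercept = 1,
                  a_vs_b = rep(c(1, 0), c(ncol(mat_a), ncol(mat_b))))
  fit <- limma::lmFit(e, design)
  fit <- limma::eBayes(fit, trend = TRUE)
  list(p = fit$p.value[, "a_vs_b"], diff = fit$coefficients[, "a_vs_b"])
}

#' Classify every eligible homoeolog pair
#'
#' Runs the three tests per pair and generation: parental ortholog
#' divergence (parent_R vs parent_C replicates), hybrid homoeolog
#' divergence (R vs C replicates within the hybrid group), and the
#' parental-vs-hybrid ratio shift. Assembles `P`, `H`, `T = P - H`, the
#' seven-way category and the 13-way subpattern. Pairs ineligible in the
#' parents or the hybrid group are skipped.
#'
#' With `method = "moderated"` (default) all three tests are
#' variance-moderated across pairs (limma-trend on `log2(count + 0.5)`
#' values and on per-replicate log2 ratios), the standard remedy for
#' three-replicate designs where per-gene variance estimates are too noisy
#' for a plain t-test; significance is `p < alpha`. With `method = "welch"`
#' each pair is tested in isolation via [count_diff_test()] (including its
#' fold-change gate) and [ratio_diff_test()].
#'
#' @param counts Normalized long count tibble.
#' @param pairs Homoeolog pair tibble.
#' @param generation Hybrid group label to classify (e.g. `"F1"`).
#' @param config An [hs_config()].
#' @param dm Optional tibble `pair_id`, `dm` feeding the subpattern strong
#'   flag.
#' @param method `"moderated"` or `"welch"` (see Details).
#'
#' @return A tibble of class `hs_cistrans`: `pair_id`, `generation`, `P`,
#'   `H`, `T`, `p_P`, `p_H`, `p_T`, `fc_P`, `fc_H`, `category7`,
#'   `subpattern13`, `strong`.
#' @export
classify_pairs <- function(counts, pairs, generation = "F1",
                           config = hs_config(), dm = NULL,
                           method = c("moderated", "welch")) {
  method <- match.arg(method)
  elig <- filter_pairs(counts, pairs, config)
  ok <- elig |>
    dplyr::filter(.data$group %in% c("parental", generation)) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(keep = all(.data$eligible) & dplyr::n() == 2,
                     .groups = "drop")
  keep_ids <- ok$pair_id[ok$keep]
  use <- pairs[pairs$pair_id %in% keep_ids, ]
  if (nrow(use) == 0) {
    stop("no pair eligible in both parents and ", generation, call. = FALSE)
  }
  ratios <- homoeolog_ratios(counts, use)
  par_r <- ratios[ratios$group == "parental", ]
  hyb_r <- ratios[ratios$group == generation, ]
  par_r <- par_r[match(use$pair_id, par_r$pair_id), ]
  hyb_r <- hyb_r[match(use$pair_id, hyb_r$pair_id), ]

  rep_counts <- function(genes, role_sel, group_sel = NULL) {
    x <- counts |>
      dplyr::filter(.data$role == role_sel,
                    if (!is.null(group_sel)) .data$group == group_sel else TRUE) |>
      dplyr::arrange(.data$replicate)
    m <- tidyr::pivot_wider(x[c("gene_id", "replicate", "norm_count")],
                            names_from = "replicate",
                            values_from = "norm_count")
    mat <- as.matrix(m[-1]); rownames(mat) <- m$gene_id
    mat[genes, , drop = FALSE]
  }
  pr <- rep_counts(use$r_gene, "parent_R")
  pc <- rep_counts(use$c_gene, "parent_C")
  hr <- rep_counts(use$r_gene, "hybrid", generation)
  hc <- rep_counts(use$c_gene, "hybrid", generation)

  n <- nrow(use)
  if (method == "moderated") {
    tp <- moderated_two_group(log2(pr + 0.5), log2(pc + 0.5))
    th <- moderated_two_group(log2(hr + 0.5), log2(hc + 0.5))
    rmat_p <- t(vapply(par_r$rep_log2rc, identity,
                       numeric(length(par_r$rep_log2rc[[1]]))))
    rmat_h <- t(vapply(hyb_r$rep_log2rc, identity,
                       numeric(length(hyb_r$rep_log2rc[[1]]))))
    tt <- moderated_two_group(rmat_p, rmat_h)
    p_P <- unname(tp$p); p_H <- unname(th$p); p_T <- unname(tt$p)
    fc_P <- 2^abs(tp$diff); fc_H <- 2^abs(th$diff)
    sig_P <- p_P < config$alpha_count_test
    sig_H <- p_H < config$alpha_count_test
    sig_T <- p_T < config$alpha_ratio_test
  } else {
    p_P <- p_H <- p_T <- fc_P <- fc_H <- numeric(n)
    sig_P <- sig_H <- sig_T <- logical(n)
    for (i in seq_len(n)) {
      tp <- count_diff_test(pr[i, ], pc[i, ], config)
      th <- count_diff_test(hr[i, ], hc[i, ], config)
      tt <- ratio_diff_test(par_r$rep_log2rc[[i]], hyb_r$rep_log2rc[[i]],
                            config)
      p_P[i] <- tp$p; p_H[i] <- th$p; p_T[i] <- tt$p
      fc_P[i] <- 2^abs(tp$log2fc); fc_H[i] <- 2^abs(th$log2fc)
      sig_P[i] <- tp$significant; sig_H[i] <- th$significant
      sig_T[i] <- tt$significant
    }
  }
  P <- par_r$log2rc; H <- hyb_r$log2rc
  out <- tibble(
    pair_id = use$pair_id, generation = generation,
    P = P, H = H, T = P - H,
    p_P = p_P, p_H = p_H, p_T = p_T,
    fc_P = unname(fc_P), fc_H = unname(fc_H),
    category7 = classify7(sig_P, sig_H, sig_T, H, P - H))
  dm_vec <- NA_real_
  if (!is.null(dm)) {
    dm_vec <- dm$dm[match(out$pair_id, dm$pair_id)]
  }
  sp <- subpattern13(out$category7, out$P, out$H, dm_vec, config)
  out <- dplyr::bind_cols(out, sp)
  class(out) <- c("hs_cistrans", class(out))
  out
}

#' Ka/Ks summaries per regulatory category
#'
#' Reports mean/median Ka/Ks per category and Welch t-tests of the cis_only
#' and trans_only groups against all classified genes.
#'
#' @param kaks Tibble `pair_id`, `ka`, `ks`, `ka_ks`.
#' @param calls Output of [classify_pairs()].
#'
#' @return A list: `summary` (per-category tibble) and `tests` (tibble of
#'   group-vs-all Welch t results; groups with < 2 members are skipped).
#' @export
kaks_group_stats <- function(kaks, calls) {
  joined <- dplyr::inner_join(kaks, calls[c("pair_id", "category7")],
                              by = "pair_id")
  summary <- joined |>
    dplyr::group_by(.data$category7) |>
    dplyr::summarise(n = dplyr::n(), mean_ka_ks = mean(.data$ka_ks),
                     median_ka_ks = median(.data$ka_ks), .groups = "drop")
  all_vals <- joined$ka_ks
  tests <- list()
  for (g in c("cis_only", "trans_only")) {
    v <- joined$ka_ks[joined$category7 == g]
    if (length(v) >= 2) {
      tt <- stats::t.test(v, all_vals)
      tests[[g]] <- tibble(group = g, n = length(v), mean = mean(v),
                           mean_all = mean(all_vals), p = tt$p.value)
    }
  }
  list(summary = summary,
       tests = if (length(tests)) dplyr::bind_rows(tests)
               else tibble(group = character(), n = integer(),
                           mean = numeric(), mean_all = numeric(),
                           p = numeric()))
}

#' Association between two binary gene sets
#'
#' Phi coefficient (Pearson correlation of the 0/1 indicators) with a
#' continuity-corrected chi-square p-value on the 2x2 table. Used to test
#' whether methylation-regulated genes coincide with cis-only or trans-only
#' genes.
#'
#' @param flags_a,flags_b Logical vectors of equal length (>= 3), neither
#'   constant.
#'
#' @return A list: `phi`, `p`, `table`.
#' @export
binary_association <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b) || length(flags_a) < 3) {
    stop("need equal-length vectors of >= 3 flags", call. = FALSE)
  }
  a <- as.integer(flags_a); b <- as.integer(flags_b)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("undefined association: constant vector", call. = FALSE)
  }
  phi <- stats::cor(a, b)
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  list(phi = phi, p = p, table = tab)
}
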