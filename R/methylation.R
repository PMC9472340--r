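#' Binomial 5mC site test
#'
#' One-sided upper-tail binomial probability `P(X >= k | n, p0)`: the chance
#' of seeing at least `k` methylated reads out of `n` if the site were
#' unmethylated with error/non-conversion rate `p0`.
#'
#' @param k_meth Methylated read count(s).
#' @param n_total Total read count(s).
#' @param p0_error Null methylation probability in (0, 1).
#'
#' @return Vector of p-values.
#' @export
call_5mc <- function(k_meth, n_total, p0_error = 0.01) {
  if (any(k_meth < 0) || any(k_meth > n_total)) {
    stop("require 0 <= k_meth <= n_total", call. = FALSE)
  }
  if (p0_error <= 0 || p0_error >= 1) {
    stop("p0_error must be in (0, 1)", call. = FALSE)
  }
  pbinom(k_meth - 1, n_total, p0_error, lower.tail = FALSE)
}

#' Batch 5mC calling with FDR control
#'
#' Sites with depth below `min_depth_5mc` (default 5, i.e. depth > 4X) are
#' untested (`q` is `NA`); Benjamini-Hochberg adjustment runs across all
#' tested sites and a site is called methylated when `q < fdr_5mc`.
#'
#' @param cytosines Tibble with `k_meth`, `n_total` (plus any site columns).
#' @param config An [hs_config()].
#'
#' @return The input with `p`, `q`, `tested`, `is_methylated` columns.
#' @export
call_5mc_batch <- function(cytosines, config = hs_config()) {
  if (nrow(cytosines) == 0) stop("no cytosine records", call. = FALSE)
  out <- as_tibble(cytosines)
  out$tested <- out$n_total >= config$min_depth_5mc
  out$p <- call_5mc(out$k_meth, out$n_total, config$p0_error)
  out$q <- NA_real_
  out$q[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out$is_methylated <- !is.na(out$q) & out$q < config$fdr_5mc
  out
}

#' 20-window methylation profile of a gene region
#'
#' The region (2 kb upstream of the TSS, gene body, or 2 kb downstream of
#' the TTS) is split into `n_windows` equal-width windows ordered 5' to 3'
#' (reversed on "-" strand genes). Window methylation is the
#' coverage-weighted level `sum(k_meth) / sum(n_total)` over CpG records in
#' the window; empty windows are `NA` and excluded from `mean_ml`.
#'
#' @param cytosines CpG records (`chrom`, `pos`, `context`, `k_meth`,
#'   `n_total`); non-CpG contexts are dropped.
#' @param gene One-row gene model tibble (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param region `"up2k"`, `"body"`, or `"down2k"`.
#' @param config An [hs_config()].
#'
#' @return A list: `gene_id`, `region`, `window_ml` (numeric of length
#'   `n_windows`), `mean_ml`, `n_cytosines`.
#' @export
region_profile <- function(cytosines, gene, region = "body",
                           config = hs_config()) {
  span <- region_span(gene, region)
  nw <- config$n_windows
  if (span[2] - span[1] < nw) {
    warning("region shorter than ", nw, " bp; using a single window",
            call. = FALSE)
    nw <- 1L
  }
  cg <- cytosines[cytosines$context == "CpG" &
                    cytosines$chrom == gene$chrom &
                    cytosines$pos >= span[1] & cytosines$pos < span[2], ]
  edges <- seq(span[1], span[2], length.out = nw + 1)
  win <- findInterval(cg$pos, edges, rightmost.closed = TRUE)
  k <- tapply(cg$k_meth, factor(win, levels = seq_len(nw)), sum)
  n <- tapply(cg$n_total, factor(win, levels = seq_len(nw)), sum)
  k[is.na(k)] <- 0; n[is.na(n)] <- 0
  window_ml <- ifelse(n > 0, k / n, NA_real_)
  if (gene$strand == "-") window_ml <- rev(window_ml)
  tot_n <- sum(cg$n_total)
  list(gene_id = gene$gene_id, region = region,
       window_ml = as.numeric(window_ml),
       mean_ml = if (tot_n > 0) sum(cg$k_meth) / tot_n else NA_real_,
       n_cytosines = nrow(cg))
}

#' Region methylation levels for many genes
#'
#' Coverage-weighted CpG methylation per gene and region, optionally per
#' group column in the cytosine records.
#'
#' @param cytosines CpG records; a `group` column is honoured if present.
#' @param genes Gene model tibble.
#' @param regions Character subset of up2k/body/down2k.
#' @param config An [hs_config()].
#'
#' @return A tibble: `group` (if present), `gene_id`, `region`, `mean_ml`,
#'   `n_cytosines`.
#' @export
region_levels <- function(cytosines, genes,
                          regions = c("up2k", "body", "down2k"),
                          config = hs_config()) {
  cg <- cytosines[cytosines$context == "CpG", ]
  has_group <- "group" %in% names(cg)
  if (!has_group) cg$group <- "all"
  out <- list()
  for (region in regions) {
    spans <- t(vapply(seq_len(nrow(genes)), function(i)
      region_span(genes[i, ], region), numeric(2)))
    hits <- list()
    for (chrom in unique(genes$chrom)) {
      gsel <- which(genes$chrom == chrom)
      csel <- which(cg$chrom == chrom)
      if (!length(gsel) || !length(csel)) next
      ir_span <- IRanges::IRanges(start = spans[gsel, 1] + 1,
                                  end = spans[gsel, 2])
      ir_pos <- IRanges::IRanges(start = cg$pos[csel] + 1, width = 1)
      ov <- IRanges::findOverlaps(ir_pos, ir_span)
      hits[[chrom]] <- tibble(
        gene_id = genes$gene_id[gsel[S4Vectors::subjectHits(ov)]],
        group = cg$group[csel[S4Vectors::queryHits(ov)]],
        k_meth = cg$k_meth[csel[S4Vectors::queryHits(ov)]],
        n_total = cg$n_total[csel[S4Vectors::queryHits(ov)]])
    }
    out[[region]] <- dplyr::bind_rows(hits) |>
      dplyr::group_by(.data$group, .data$gene_id) |>
      dplyr::summarise(mean_ml = sum(.data$k_meth) / sum(.data$n_total),
                       n_cytosines = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(region = region)
  }
  res <- dplyr::bind_rows(out)
  if (!has_group) res$group <- NULL
  dplyr::relocate(res, dplyr::any_of("region"), .after = "gene_id")
}

#' Methylation-level difference
#'
#' @param ml_first,ml_second Methylation levels in `[0, 1]`.
#' @return `ml_first - ml_second`.
#' @export
dm_value <- function(ml_first, ml_second) {
  if (any(ml_first < 0 | ml_first > 1 | ml_second < 0 | ml_second > 1,
          na.rm = TRUE)) {
    stop("methylation levels must lie in [0, 1]", call. = FALSE)
  }
  ml_first - ml_second
}

#' Simplified region-level differential-methylation test
#'
#' A simplified DMR surrogate: two-sided Fisher exact test on the pooled
#' region counts `[[kA, nA-kA], [kB, nB-kB]]`, flagged as a DMR when
#' `p < dmr_alpha` (default 1e-5) and the methylation-level difference
#' exceeds 0.1 in magnitude.
#'
#' @param k_a,n_a Pooled methylated and total counts, first sample.
#' @param k_b,n_b Pooled methylated and total counts, second sample.
#' @param config An [hs_config()].
#'
#' @return A list: `p`, `dm`, `is_dmr`.
#' @export
dmr_test <- function(k_a, n_a, k_b, n_b, config = hs_config()) {
  if (n_a <= 0 || n_b <= 0) stop("zero region coverage", call. = FALSE)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  dm <- k_a / n_a - k_b / n_b
  list(p = p, dm = dm, is_dmr = p < config$dmr_alpha && abs(dm) > 0.1)
}

#' Hyper-/hypo-DMG classification
#'
#' A pair is a hyper-DMG when the parental ortholog methylation difference
#' exceeds 0.6 in magnitude while the hybrid homoeolog difference stays
#' below 0.3; a hypo-DMG when the parental difference is strictly between 0
#' and 0.6 and the hybrid difference below 0.2.
#'
#' @param dm_parents,dm_hybrid Absolute methylation differences in `[0, 1]`
#'   (signed input is accepted; magnitudes are used).
#' @param config An [hs_config()].
#'
#' @return Character vector over `hyper_dmg`, `hypo_dmg`, `none`.
#' @export
classify_dmg <- function(dm_parents, dm_hybrid, config = hs_config()) {
  dp <- abs(dm_parents); dh <- abs(dm_hybrid)
  if (any(dp > 1 | dh > 1, na.rm = TRUE)) {
    stop("methylation differences must lie in [-1, 1]", call. = FALSE)
  }
  dplyr::case_when(
    dp > config$dm_dmg_hyper & dh < config$dm_dmg_hybrid_hyper ~ "hyper_dmg",
    dp > 0 & dp < config$dm_dmg_hyper & dh < config$dm_dmg_hybrid_hypo ~ "hypo_dmg",
    TRUE ~ "none")
}

#' Methylation-regulated gene call
#'
#' A gene is a potential methylation-regulated gene (MRG) when its promoter
#' methylation difference and its expression fold change are both large and
#' discordant in sign: `|dm| > 0.4`, `|log2fc| > log2(4)`, and
#' `sign(dm) != sign(log2fc)` (hypermethylation with lower expression).
#'
#' @param dm Promoter (up2k) methylation difference.
#' @param log2fc Expression log2 fold change over the same comparison.
#' @param config An [hs_config()].
#'
#' @return A tibble: `dm`, `log2fc`, `is_mrg`.
#' @export
detect_mrg <- function(dm, log2fc, config = hs_config()) {
  if (any(!is.finite(dm)) || any(!is.finite(log2fc))) {
    stop("dm and log2fc must be finite", call. = FALSE)
  }
  is_mrg <- abs(dm) > config$mrg_dm &
    abs(log2fc) > log2(config$mrg_fc) &
    sign(dm) != sign(log2fc) & sign(dm) != 0 & sign(log2fc) != 0
  tibble(dm = dm, log2fc = log2fc, is_mrg = is_mrg)
}
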