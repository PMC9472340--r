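#' Normalize counts by total mapped reads
#'
#' Each sample's counts are scaled by (mean library total across all
#' samples) / (that sample's total), so scaled library totals are equal
#' across samples. Raw counts are retained in `count`; scaled values are
#' added as `norm_count` with the per-sample factor in `norm_factor`.
#'
#' @param counts Long count tibble (`gene_id`, `sample`, `count`, metadata),
#'   as returned by [read_counts()] or [simulate_expression()].
#'
#' @return The input tibble with `norm_factor` and `norm_count` columns.
#' @export
normalize_counts <- function(counts) {
  totals <- counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample[totals$total == 0]
  if (length(zero)) {
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  ref <- mean(totals$total)
  totals$norm_factor <- ref / totals$total
  counts |>
    dplyr::select(-dplyr::any_of(c("norm_factor", "norm_count"))) |>
    dplyr::left_join(totals[c("sample", "norm_factor")], by = "sample") |>
    dplyr::mutate(norm_count = .data$count * .data$norm_factor)
}

#' Filter homoeolog pairs on replicate-level read support
#'
#' A pair is eligible in a group when both homoeologs have at least
#' `min_reads` raw counts in every replicate of that group. For parental
#' roles, the R gene is assessed in the `parent_R` samples and the C gene in
#' the `parent_C` samples; in hybrid groups both homoeologs are assessed in
#' the same samples.
#'
#' @param counts Long count tibble (raw counts).
#' @param pairs Homoeolog pair tibble.
#' @param config An [hs_config()]; `min_reads` defaults to 5.
#'
#' @return A tibble `pair_id`, `group`, `eligible`. The parental reference
#'   appears as group `"parental"` (R gene in parent_R plus C gene in
#'   parent_C samples).
#' @export
filter_pairs <- function(counts, pairs, config = hs_config()) {
  known <- unique(counts$gene_id)
  miss <- setdiff(c(pairs$r_gene, pairs$c_gene), known)
  if (length(miss)) {
    stop("pair gene(s) absent from count table: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  min_per_gene_group <- counts |>
    dplyr::group_by(.data$gene_id, .data$group, .data$role) |>
    dplyr::summarise(min_count = min(.data$count), .groups = "drop")
  hyb_groups <- unique(min_per_gene_group$group[
    min_per_gene_group$role == "hybrid"])
  rows <- list()
  pr_group <- unique(min_per_gene_group$group[
    min_per_gene_group$role == "parent_R"])
  pc_group <- unique(min_per_gene_group$group[
    min_per_gene_group$role == "parent_C"])
  mg <- min_per_gene_group
  key <- paste(mg$gene_id, mg$group)
  mins <- setNames(mg$min_count, key)
  get_min <- function(gene, group) {
    v <- mins[paste(gene, group)]
    ifelse(is.na(v), -Inf, v)
  }
  if (length(pr_group) && length(pc_group)) {
    rows$parental <- tibble(
      pair_id = pairs$pair_id, group = "parental",
      eligible = get_min(pairs$r_gene, pr_group[1]) >= config$min_reads &
        get_min(pairs$c_gene, pc_group[1]) >= config$min_reads)
  }
  for (g in hyb_groups) {
    rows[[g]] <- tibble(
      pair_id = pairs$pair_id, group = g,
      eligible = get_min(pairs$r_gene, g) >= config$min_reads &
        get_min(pairs$c_gene, g) >= config$min_reads)
  }
  dplyr::bind_rows(rows)
}

#' log2 expression ratio of R over C
#'
#' @param r_mean,c_mean Positive normalized expression means.
#' @return `log2(r_mean / c_mean)`.
#' @export
log2_ratio <- function(r_mean, c_mean) {
  if (any(r_mean <= 0) || any(c_mean <= 0)) {
    stop("log2_ratio requires positive means; filter pairs first",
         call. = FALSE)
  }
  log2(r_mean / c_mean)
}

#' Homoeolog expression bias category
#'
#' `|log2(R/C)| > heb_threshold` is called biased toward the sign's
#' subgenome; `0 < |log2(R/C)| <= threshold` is a potential bias; exactly 0
#' is balanced. The threshold comparison is strict.
#'
#' @param log2rc Numeric vector of log2(R/C) values.
#' @param config An [hs_config()]; `heb_threshold` defaults to 1.
#'
#' @return Character vector over `R_biased`, `C_biased`, `potential_R`,
#'   `potential_C`, `balanced`.
#' @export
heb_call <- function(log2rc, config = hs_config()) {
  if (any(!is.finite(log2rc))) stop("log2rc must be finite", call. = FALSE)
  th <- config$heb_threshold
  dplyr::case_when(
    log2rc >  th ~ "R_biased",
    log2rc < -th ~ "C_biased",
    log2rc > 0   ~ "potential_R",
    log2rc < 0   ~ "potential_C",
    TRUE         ~ "balanced"
  )
}

#' Per-pair homoeolog expression ratios
#'
#' For hybrid groups the ratio contrasts the two homoeologs within the same
#' samples; the parental reference ("in silico hybrid") contrasts the R
#' ortholog in parent_R samples with the C ortholog in parent_C samples,
#' pairing replicates in sample-sheet order. The headline `log2rc` is the
#' ratio of replicate-mean normalized counts; per-replicate ratios are kept
#' for downstream t-tests.
#'
#' @param counts Normalized long count tibble (see [normalize_counts()]).
#' @param pairs Homoeolog pair tibble.
#' @param eligible Optional output of [filter_pairs()]; when given, only
#'   eligible (pair, group) combinations are returned.
#'
#' @return A tibble: `pair_id`, `group`, `r_mean`, `c_mean`, `log2rc`, and
#'   list-column `rep_log2rc`.
#' @export
homoeolog_ratios <- function(counts, pairs, eligible = NULL) {
  if (!"norm_count" %in% names(counts)) {
    stop("counts must be normalized first (normalize_counts)", call. = FALSE)
  }
  per_rep <- counts |>
    dplyr::select("gene_id", "group", "role", "replicate", "norm_count")
  grab <- function(genes, group_sel, role_sel) {
    x <- per_rep |>
      dplyr::filter(.data$role == role_sel,
                    if (!is.null(group_sel)) .data$group == group_sel else TRUE) |>
      dplyr::arrange(.data$replicate)
    m <- tidyr::pivot_wider(x, id_cols = "gene_id", names_from = "replicate",
                            values_from = "norm_count")
    mat <- as.matrix(m[-1])
    rownames(mat) <- m$gene_id
    mat[genes, , drop = FALSE]
  }
  hyb_groups <- unique(counts$group[counts$role == "hybrid"])
  out <- list()
  r_par <- grab(pairs$r_gene, NULL, "parent_R")
  c_par <- grab(pairs$c_gene, NULL, "parent_C")
  if (ncol(r_par) != ncol(c_par)) {
    stop("parents have unequal replicate numbers", call. = FALSE)
  }
  out$parental <- tibble(
    pair_id = pairs$pair_id, group = "parental",
    r_mean = unname(rowMeans(r_par)), c_mean = unname(rowMeans(c_par)),
    rep_log2rc = lapply(seq_len(nrow(pairs)), function(i)
      unname(log2(r_par[i, ] / c_par[i, ]))))
  for (g in hyb_groups) {
    r_h <- grab(pairs$r_gene, g, "hybrid")
    c_h <- grab(pairs$c_gene, g, "hybrid")
    out[[g]] <- tibble(
      pair_id = pairs$pair_id, group = g,
      r_mean = unname(rowMeans(r_h)), c_mean = unname(rowMeans(c_h)),
      rep_log2rc = lapply(seq_len(nrow(pairs)), function(i)
        unname(log2(r_h[i, ] / c_h[i, ]))))
  }
  res <- dplyr::bind_rows(out)
  if (!is.null(eligible)) {
    keep <- eligible[eligible$eligible, c("pair_id", "group")]
    res <- dplyr::semi_join(res, keep, by = c("pair_id", "group"))
  }
  res$log2rc <- ifelse(res$r_mean > 0 & res$c_mean > 0,
                       log2(res$r_mean / res$c_mean), NA_real_)
  dplyr::relocate(res, "log2rc", .after = "c_mean")
}

#' Summarise the bias distribution of one group
#'
#' @param ratios Ratio records for a single group (from
#'   [homoeolog_ratios()]).
#' @param config An [hs_config()].
#'
#' @return A one-row tibble: `group`, `n`, `mean_log2rc`, `mean_abs_log2rc`,
#'   and one count column per bias category.
#' @export
heb_distribution <- function(ratios, config = hs_config()) {
  ratios <- ratios[is.finite(ratios$log2rc), ]
  if (nrow(ratios) == 0) stop("no finite ratio records", call. = FALSE)
  if (length(unique(ratios$group)) != 1) {
    stop("heb_distribution expects a single group", call. = FALSE)
  }
  cats <- heb_call(ratios$log2rc, config)
  lv <- c("R_biased", "C_biased", "potential_R", "potential_C", "balanced")
  tally <- table(factor(cats, levels = lv))
  dplyr::bind_cols(
    tibble(group = ratios$group[1], n = nrow(ratios),
           mean_log2rc = mean(ratios$log2rc),
           mean_abs_log2rc = mean(abs(ratios$log2rc))),
    as_tibble(as.list(tally)))
}

#' Silencing state of a gene in a group
#'
#' All replicate counts zero means silenced; all at least 5 reads means
#' expressed; anything else is indeterminate.
#'
#' @param counts Long raw count tibble.
#' @param expressed_min Read floor for the expressed state (default 5).
#'
#' @return A tibble `gene_id`, `group`, `state`.
#' @export
silencing_call <- function(counts, expressed_min = 5) {
  counts |>
    dplyr::group_by(.data$gene_id, .data$group) |>
    dplyr::summarise(
      state = if (all(.data$count == 0)) "silenced"
              else if (all(.data$count >= expressed_min)) "expressed"
              else "indeterminate",
      .groups = "drop")
}

#' Parental reference ratios (in silico hybrid)
#'
#' Convenience wrapper returning only the parental rows of
#' [homoeolog_ratios()]: per pair, `P = log2(mean parent_R ortholog / mean
#' parent_C ortholog)` with per-replicate ratios paired in sheet order.
#'
#' @inheritParams homoeolog_ratios
#' @return Ratio records with `group == "parental"`.
#' @export
in_silico_hybrid <- function(counts, pairs, eligible = NULL) {
  res <- homoeolog_ratios(counts, pairs, eligible)
  res[res$group == "parental", ]
}
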