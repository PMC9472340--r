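#' Length-normalized log10 depth ratio
#'
#' `log10((r_reads / r_len) / (c_reads / c_len))`, the copy-ratio statistic
#' for detecting unequal homoeologous recombination. Zero counts yield
#' sentinels rather than pseudocount ratios: `-Inf` when only R is absent,
#' `+Inf` when only C is absent, `NA` (untestable) when both are zero. With
#' `pseudocount = TRUE` 0.5 reads are added to both counts instead.
#'
#' @param r_reads,c_reads Mapped read counts (>= 0).
#' @param r_len,c_len Gene lengths in bp (> 0).
#' @param pseudocount Add 0.5 reads to each side instead of emitting
#'   sentinels.
#'
#' @return Numeric vector of log10 ratios (may contain `Inf`/`-Inf`/`NA`).
#' @export
copy_ratio <- function(r_reads, r_len, c_reads, c_len, pseudocount = FALSE) {
  if (any(r_len <= 0) || any(c_len <= 0)) {
    stop("gene lengths must be > 0", call. = FALSE)
  }
  if (any(r_reads < 0) || any(c_reads < 0)) {
    stop("read counts must be >= 0", call. = FALSE)
  }
  if (pseudocount) {
    r_reads <- r_reads + 0.5
    c_reads <- c_reads + 0.5
  }
  ratio <- log10((r_reads / r_len) / (c_reads / c_len))
  ratio[r_reads == 0 & c_reads == 0] <- NA_real_
  ratio
}

#' Copy-state call from a log10 depth ratio
#'
#' Thresholds are the printed decision lines log10(2) = 0.30103 and
#' log10(0.5) = -0.30103; comparisons are strict, so a ratio exactly on the
#' line is balanced. Sentinel ratios map to the absent states.
#'
#' @param log10_ratio Numeric vector (finite, `Inf`, `-Inf`, or `NA`).
#' @param config An [hs_config()]; `copy_log10_threshold` defaults to
#'   log10(2).
#'
#' @return Character vector over `balanced`, `R_gain`, `C_gain`,
#'   `R_absent`, `C_absent`, `untestable`.
#' @export
call_copy_state <- function(log10_ratio, config = hs_config()) {
  th <- config$copy_log10_threshold
  dplyr::case_when(
    is.na(log10_ratio)          ~ "untestable",
    is.infinite(log10_ratio) & log10_ratio < 0 ~ "R_absent",
    is.infinite(log10_ratio) & log10_ratio > 0 ~ "C_absent",
    log10_ratio >  th           ~ "R_gain",
    log10_ratio < -th           ~ "C_gain",
    TRUE                        ~ "balanced")
}

#' Per-pair copy-ratio records
#'
#' @param depth Tibble with `pair_id`, `chrom_pair`, `order_index`,
#'   `r_reads`, `c_reads`, `r_len`, `c_len`, and optionally `sample`.
#' @param config An [hs_config()].
#' @param pseudocount Passed to [copy_ratio()].
#'
#' @return The input with `log10_ratio` and `state` columns.
#' @export
copy_ratio_records <- function(depth, config = hs_config(),
                               pseudocount = FALSE) {
  out <- as_tibble(depth)
  out$log10_ratio <- copy_ratio(out$r_reads, out$r_len, out$c_reads,
                                out$c_len, pseudocount)
  out$state <- call_copy_state(out$log10_ratio, config)
  out
}

# direction of a state: +1 toward_R, -1 toward_C, 0 neither
state_direction <- function(state) {
  dplyr::case_when(
    state %in% c("R_gain", "C_absent") ~ 1,
    state %in% c("C_gain", "R_absent") ~ -1,
    TRUE ~ 0)
}

#' Detect unequal homoeologous-recombination segments
#'
#' Scans each chromosome pair (per sample) for maximal runs of consecutive
#' `order_index` whose copy states all point to the same gaining subgenome
#' (`R_gain`/`C_absent` toward R; `C_gain`/`R_absent` toward C). Runs of at
#' least `min_run` genes (default 3, "three contiguous genes") become
#' segments; balanced or untestable genes break runs, as do gaps in
#' `order_index`.
#'
#' @param records Copy-ratio records from [copy_ratio_records()], sorted by
#'   `order_index` within `chrom_pair`; a single sample unless a `sample`
#'   column distinguishes tracks.
#' @param config An [hs_config()].
#'
#' @return A tibble of class `hs_segments`: `sample`, `chrom_pair`,
#'   `start_index`, `end_index`, `n_genes`, `direction`.
#' @export
detect_segments <- function(records, config = hs_config()) {
  if (!"sample" %in% names(records)) records$sample <- "S1"
  out <- list()
  for (key in split(seq_len(nrow(records)),
                    paste(records$sample, records$chrom_pair))) {
    tr <- records[key, ]
    if (is.unsorted(tr$order_index)) {
      stop("records must be sorted by order_index within chrom_pair",
           call. = FALSE)
    }
    dir <- state_direction(tr$state)
    # break runs at order_index gaps
    gap <- c(TRUE, diff(tr$order_index) != 1)
    run_id <- cumsum(gap | dir != dplyr::lag(dir, default = 0) |
                       dir == 0)
    for (ri in split(seq_len(nrow(tr)), run_id)) {
      d <- dir[ri[1]]
      if (d == 0 || length(ri) < config$min_run) next
      out[[length(out) + 1]] <- tibble(
        sample = tr$sample[1], chrom_pair = tr$chrom_pair[1],
        start_index = tr$order_index[ri[1]],
        end_index = tr$order_index[ri[length(ri)]],
        n_genes = length(ri),
        direction = if (d > 0) "toward_R" else "toward_C")
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(sample = character(), chrom_pair = character(),
           start_index = integer(), end_index = integer(),
           n_genes = integer(), direction = character())
  res <- dplyr::arrange(res, .data$sample, .data$chrom_pair,
                        .data$start_index)
  class(res) <- c("hs_segments", class(res))
  res
}

#' Compare recombination segments across samples
#'
#' Segments from different samples on the same chromosome pair are classed
#' shared when their index ranges reciprocally overlap by at least 50%
#' (boundary inclusive), otherwise sample-specific.
#'
#' @param segments Segment tibble covering >= 2 samples.
#'
#' @return A list: `segments` (input with a `class` column) and `summary`
#'   (counts per sample and class).
#' @export
compare_samples <- function(segments) {
  samples <- unique(segments$sample)
  if (length(samples) < 2) stop("need segments from >= 2 samples", call. = FALSE)
  seg <- as_tibble(segments)
  seg$class <- "sample_specific"
  for (i in seq_len(nrow(seg))) {
    a <- seg[i, ]
    others <- seg[seg$sample != a$sample & seg$chrom_pair == a$chrom_pair, ]
    if (nrow(others) == 0) next
    ov_lo <- pmax(a$start_index, others$start_index)
    ov_hi <- pmin(a$end_index, others$end_index)
    ov <- pmax(0, ov_hi - ov_lo + 1)
    recip <- ov / a$n_genes >= 0.5 & ov / others$n_genes >= 0.5
    if (any(recip)) seg$class[i] <- "shared"
  }
  summary <- seg |>
    dplyr::count(.data$sample, .data$class, name = "n_segments")
  list(segments = seg, summary = summary)
}
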