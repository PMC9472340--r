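#' Fraction of a span covered by TEs
#'
#' Union (merged) coverage of the TE intervals intersected with the span,
#' divided by the span length; overlapping or duplicated annotations are
#' never double-counted.
#'
#' @param te TE interval tibble (`chrom`, `start`, `end`).
#' @param chrom,start,end The span (0-based half-open).
#'
#' @return Fraction in `[0, 1]`.
#' @export
te_fraction <- function(te, chrom, start, end) {
  if (end <= start) stop("span must have positive length", call. = FALSE)
  sel <- te[te$chrom == chrom & te$end > start & te$start < end, ]
  if (nrow(sel) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(sel$start, start) + 1, end = pmin(sel$end, end)))
  sum(IRanges::width(ir)) / (end - start)
}

#' Tile chromosomes into windows with TE density and SV counts
#'
#' @param te TE interval tibble.
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param sv Optional SV position tibble (`chrom`, `pos`).
#' @param window_size Window width in bp.
#' @param superfamily Optional TE superfamily (matches the `name` column) to
#'   restrict the density track.
#'
#' @return A tibble: `chrom`, `start`, `end`, `te_density`, and `sv_count`
#'   when `sv` is given.
#' @export
window_track <- function(te, chrom_sizes, sv = NULL, window_size = 1e5,
                         superfamily = NULL) {
  if (!is.null(superfamily)) te <- te[te$name %in% superfamily, ]
  out <- list()
  for (i in seq_len(nrow(chrom_sizes))) {
    chrom <- chrom_sizes$chrom[i]; size <- chrom_sizes$size[i]
    w_start <- seq(0, size - 1, by = window_size)
    w_end <- pmin(w_start + window_size, size)
    dens <- vapply(seq_along(w_start), function(w)
      te_fraction(te, chrom, w_start[w], w_end[w]), numeric(1))
    tr <- tibble(chrom = chrom, start = w_start, end = w_end,
                 te_density = dens)
    if (!is.null(sv)) {
      pos <- sv$pos[sv$chrom == chrom]
      tr$sv_count <- vapply(seq_along(w_start), function(w)
        sum(pos >= w_start[w] & pos < w_end[w]), numeric(1))
    }
    out[[i]] <- tr
  }
  dplyr::bind_rows(out)
}

#' Per-chromosome-pair divergence summary
#'
#' Orthologous fractions (`n_orthologs / n_genes` on each side) and the TE
#' fraction difference between the two parental chromosomes.
#'
#' @param genes_a,genes_b Gene model tibbles for the two parents.
#' @param ortholog_map Tibble `gene_a`, `gene_b`, `chrom_pair` linking
#'   orthologs, with `chrom_a`, `chrom_b` naming the member chromosomes.
#' @param te_a,te_b TE interval tibbles for the two parents.
#' @param chrom_sizes_a,chrom_sizes_b Tibbles `chrom`, `size`.
#'
#' @return A tibble: one row per chromosome pair with gene counts, ortholog
#'   counts and fractions, TE fractions and `te_difference` (A minus B).
#' @export
ocp_summary <- function(genes_a, genes_b, ortholog_map, te_a, te_b,
                        chrom_sizes_a, chrom_sizes_b) {
  miss <- setdiff(c(ortholog_map$gene_a, ortholog_map$gene_b),
                  c(genes_a$gene_id, genes_b$gene_id))
  if (length(miss)) {
    stop("ortholog map references unknown gene(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  cps <- dplyr::distinct(ortholog_map[c("chrom_pair", "chrom_a", "chrom_b")])
  rows <- lapply(seq_len(nrow(cps)), function(i) {
    cp <- cps[i, ]
    ga <- genes_a[genes_a$chrom == cp$chrom_a, ]
    gb <- genes_b[genes_b$chrom == cp$chrom_b, ]
    om <- ortholog_map[ortholog_map$chrom_pair == cp$chrom_pair, ]
    size_a <- chrom_sizes_a$size[chrom_sizes_a$chrom == cp$chrom_a]
    size_b <- chrom_sizes_b$size[chrom_sizes_b$chrom == cp$chrom_b]
    tf_a <- te_fraction(te_a, cp$chrom_a, 0, size_a)
    tf_b <- te_fraction(te_b, cp$chrom_b, 0, size_b)
    tibble(
      chrom_pair = cp$chrom_pair,
      n_genes_A = nrow(ga), n_genes_B = nrow(gb),
      n_orthologs = nrow(om),
      ortho_fraction_A = if (nrow(ga)) nrow(om) / nrow(ga) else NA_real_,
      ortho_fraction_B = if (nrow(gb)) nrow(om) / nrow(gb) else NA_real_,
      te_fraction_A = tf_a, te_fraction_B = tf_b,
      te_difference = tf_a - tf_b)
  })
  dplyr::bind_rows(rows)
}

#' Classify structural variants by TE proximity
#'
#' A variant is `TE_proximal` when its distance to the nearest TE interval
#' is strictly below `te_proximity` (default 1000 bp; distance 0 inside a
#' TE), otherwise `no_TE`.
#'
#' @param sv SV position tibble (`chrom`, `pos`).
#' @param te TE interval tibble.
#' @param config An [hs_config()].
#'
#' @return The input with `distance` and `te_class` columns.
#' @export
sv_te_classify <- function(sv, te, config = hs_config()) {
  out <- as_tibble(sv)
  out$distance <- NA_real_
  for (chrom in unique(out$chrom)) {
    tsel <- te[te$chrom == chrom, ]
    psel <- out$chrom == chrom
    if (nrow(tsel) == 0) { out$distance[psel] <- Inf; next }
    tir <- IRanges::reduce(IRanges::IRanges(start = tsel$start + 1,
                                            end = tsel$end))
    pir <- IRanges::IRanges(start = out$pos[psel] + 1, width = 1)
    d <- IRanges::distanceToNearest(pir, tir)
    dist <- rep(Inf, sum(psel))
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    out$distance[psel] <- dist
  }
  out$te_class <- ifelse(out$distance < config$te_proximity,
                         "TE_proximal", "no_TE")
  out
}

#' TE density versus SV count correlation across windows
#'
#' Pearson correlation with significance from `t = r * sqrt(n-2) /
#' sqrt(1-r^2)` on `n - 2` degrees of freedom (two-sided). Alongside, a
#' Welch t-test compares per-window SV counts between TE-dense and TE-poor
#' windows (split at the median density), covering both readings of a
#' class-versus-correlation test.
#'
#' @param track Window tibble with `te_density`, `sv_count` (>= 3 rows,
#'   density non-constant).
#'
#' @return A list: `r`, `t`, `df`, `p`, `n`, and `class_test` (list with
#'   `p`, `mean_dense`, `mean_sparse`).
#' @export
sv_te_correlation <- function(track) {
  n <- nrow(track)
  if (n < 3) stop("need >= 3 windows", call. = FALSE)
  if (stats::var(track$te_density) == 0) {
    stop("undefined correlation: constant TE density", call. = FALSE)
  }
  r <- stats::cor(track$te_density, track$sv_count)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  dense <- track$te_density > median(track$te_density)
  ct <- if (length(unique(dense)) == 2 && sum(dense) >= 2 &&
            sum(!dense) >= 2) {
    tt <- stats::t.test(track$sv_count[dense], track$sv_count[!dense])
    list(p = tt$p.value, mean_dense = mean(track$sv_count[dense]),
         mean_sparse = mean(track$sv_count[!dense]))
  } else list(p = NA_real_, mean_dense = NA_real_, mean_sparse = NA_real_)
  list(r = r, t = tstat, df = n - 2, p = p, n = n, class_test = ct)
}
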