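# run code under a local RNG state so generators are pure in (params, seed)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation parameters
#'
#' Defines the generative model used to validate the pipeline: negative
#' binomial homoeolog counts with planted cis/trans architecture across
#' generations, beta/binomial cytosine counts with planted promoter
#' methylation differences, Poisson read depth under planted copy-number
#' segments, and TE-density-driven structural-variant placement.
#'
#' The cis/trans generative identity is: parental log2 ratio `P = cis +
#' trans`, F1 hybrid ratio `H = cis` (cis effects are allele-linked and
#' survive in the hybrid; trans effects equalise), and the advanced
#' generation F22 has `H' = cis * (1 - trans_compensation_F22)`,
#' a tunable attenuation of residual bias.
#'
#' @param n_pairs Number of homoeolog pairs.
#' @param n_chrom_pairs Number of homoeologous chromosome pairs.
#' @param replicates Biological replicates per group (>= 2).
#' @param depth_mean Median expected counts per gene.
#' @param nb_dispersion Negative binomial dispersion shared across genes;
#'   values below 1e-12 switch to Poisson sampling.
#' @param category_proportions Named fractions over the seven regulatory
#'   categories, summing to 1; `ambiguous` must have zero mass (it is a
#'   diagnostic outcome, not a plantable architecture).
#' @param cis_effect,trans_effect Planted effect magnitudes (log2 units).
#' @param trans_compensation_F22 Fraction in `[0,1]` by which residual cis
#'   bias is attenuated in F22.
#' @param meth_depth Mean per-cytosine bisulfite depth (Poisson).
#' @param cytosines_per_region CpG sites simulated per gene region.
#' @param dm_effect Planted parental methylation difference (up2k region).
#' @param dm_fraction Fraction of pairs carrying the planted difference.
#' @param dm_hybrid_effect Planted hybrid homoeolog methylation difference
#'   for the same pairs.
#' @param hr_segments Data frame of planted copy-number segments with
#'   columns `chrom_pair`, `start_index`, `n_genes`, `r_copies`, `c_copies`;
#'   `NULL` for none.
#' @param sv_te_slope Log-linear coefficient of SV intensity on TE density.
#' @param window_size Window width (bp) for TE density and SV placement.
#' @param p0_error Bisulfite non-conversion/error rate added to every
#'   cytosine's methylation probability.
#' @param baseline_sdlog Log-normal sd of the per-pair expression baseline.
#' @param seed Integer seed; every generator is a pure function of
#'   (params, seed).
#'
#' @return An object of class `hs_sim_params`.
#' @export
sim_params <- function(n_pairs = 500L,
                       n_chrom_pairs = 2L,
                       replicates = 3L,
                       depth_mean = 100,
                       nb_dispersion = 0.05,
                       category_proportions = c(
                         conserved = 0.70, cis_only = 0.10, trans_only = 0.10,
                         cis_plus_trans = 0.05, cis_x_trans = 0.025,
                         compensatory = 0.025, ambiguous = 0),
                       cis_effect = 2,
                       trans_effect = 2,
                       trans_compensation_F22 = 0.5,
                       meth_depth = 30,
                       cytosines_per_region = 50L,
                       dm_effect = 0.7,
                       dm_fraction = 0.2,
                       dm_hybrid_effect = 0.05,
                       hr_segments = NULL,
                       sv_te_slope = 3,
                       window_size = 1e5,
                       p0_error = 0.01,
                       baseline_sdlog = 0.5,
                       seed = 1L) {
  cats <- c("conserved", "cis_only", "trans_only", "cis_plus_trans",
            "cis_x_trans", "compensatory", "ambiguous")
  if (!all(cats %in% names(category_proportions))) {
    stop("category_proportions must name all seven categories", call. = FALSE)
  }
  category_proportions <- category_proportions[cats]
  if (abs(sum(category_proportions) - 1) > 1e-9) {
    stop("category_proportions must sum to 1", call. = FALSE)
  }
  if (category_proportions[["ambiguous"]] > 0) {
    stop("'ambiguous' cannot receive planted mass", call. = FALSE)
  }
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  if (cis_effect < 0 || trans_effect < 0) {
    stop("effects must be >= 0", call. = FALSE)
  }
  if (trans_compensation_F22 < 0 || trans_compensation_F22 > 1) {
    stop("trans_compensation_F22 must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_pairs = as.integer(n_pairs), n_chrom_pairs = as.integer(n_chrom_pairs),
    replicates = as.integer(replicates), depth_mean = depth_mean,
    nb_dispersion = nb_dispersion,
    category_proportions = category_proportions,
    cis_effect = cis_effect, trans_effect = trans_effect,
    trans_compensation_F22 = trans_compensation_F22,
    meth_depth = meth_depth,
    cytosines_per_region = as.integer(cytosines_per_region),
    dm_effect = dm_effect, dm_fraction = dm_fraction,
    dm_hybrid_effect = dm_hybrid_effect,
    hr_segments = hr_segments, sv_te_slope = sv_te_slope,
    window_size = window_size, p0_error = p0_error,
    baseline_sdlog = baseline_sdlog, seed = as.integer(seed)
  ), class = "hs_sim_params")
}

#' Simulate a homoeologous genome layout
#'
#' Pairs are distributed evenly over chromosome pairs with consecutive
#' `order_index`; gene lengths are log-uniform in 500-5000 bp and genes do
#' not overlap on a chromosome. TE intervals are laid out so each window of
#' `window_size` bp has a planted density uniform in `[0, 0.6]`.
#'
#' @param params An [sim_params()] object.
#'
#' @return A list with tibbles `genes` (gene models, both subgenomes),
#'   `pairs` (homoeolog map), `te` (TE intervals with superfamily names),
#'   `chrom_sizes`, and `te_truth` (planted per-window density).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "hs_sim_params"))
  if (params$n_pairs < params$n_chrom_pairs) {
    stop("n_pairs must be >= n_chrom_pairs", call. = FALSE)
  }
  with_seed(params$seed, {
    per_cp <- diff(round(seq(0, params$n_pairs,
                             length.out = params$n_chrom_pairs + 1)))
    genes <- list(); pairs <- list()
    for (cp in seq_len(params$n_chrom_pairs)) {
      n <- per_cp[cp]
      cp_id <- sprintf("cp%02d", cp)
      lens_r <- round(exp(runif(n, log(500), log(5000))))
      lens_c <- round(exp(runif(n, log(500), log(5000))))
      # gaps exceed both 2 kb flanks so the up2k/down2k regions of adjacent
      # genes never overlap and planted region signals stay gene-exclusive
      gaps_r <- round(runif(n, 4500, 8000))
      gaps_c <- round(runif(n, 4500, 8000))
      start_r <- cumsum(gaps_r) + c(0, cumsum(lens_r)[-n])
      start_c <- cumsum(gaps_c) + c(0, cumsum(lens_c)[-n])
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rg <- sprintf("%s_g%04d_R", cp_id, seq_len(n))
      cg <- sprintf("%s_g%04d_C", cp_id, seq_len(n))
      genes[[2 * cp - 1]] <- tibble(
        gene_id = rg, chrom = sprintf("chrR%02d", cp),
        start = start_r, end = start_r + lens_r, strand = strand)
      genes[[2 * cp]] <- tibble(
        gene_id = cg, chrom = sprintf("chrC%02d", cp),
        start = start_c, end = start_c + lens_c, strand = strand)
      pairs[[cp]] <- tibble(
        pair_id = sprintf("%s_p%04d", cp_id, seq_len(n)),
        r_gene = rg, c_gene = cg, chrom_pair = cp_id,
        order_index = seq_len(n) - 1L)
    }
    genes <- dplyr::bind_rows(genes)
    pairs <- dplyr::bind_rows(pairs)
    chrom_sizes <- genes |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(size = max(.data$end) + 2500, .groups = "drop")
    te <- list(); te_truth <- list()
    fams <- c("CACTA", "hAT", "LTR-Gypsy", "Tc1-Mariner")
    for (i in seq_len(nrow(chrom_sizes))) {
      chrom <- chrom_sizes$chrom[i]
      size <- chrom_sizes$size[i]
      w_start <- seq(0, size - 1, by = params$window_size)
      w_end <- pmin(w_start + params$window_size, size)
      dens <- runif(length(w_start), 0, 0.6)
      rows <- list()
      for (w in seq_along(w_start)) {
        wl <- w_end[w] - w_start[w]
        target <- dens[w] * wl
        if (target < 200) next
        lens <- numeric(0)
        while (sum(lens) < target) lens <- c(lens, runif(1, 200, 2000))
        lens <- lens * (target / sum(lens))
        k <- length(lens)
        gap <- (wl - target) / (k + 1)
        starts <- w_start[w] + gap * seq_len(k) + c(0, cumsum(lens)[-k])
        rows[[w]] <- tibble(
          chrom = chrom, start = round(starts),
          end = round(starts + lens),
          name = sample(fams, k, replace = TRUE))
      }
      te[[i]] <- dplyr::bind_rows(rows)
      te_truth[[i]] <- tibble(chrom = chrom, win_start = w_start,
                              win_end = w_end, te_density = dens)
    }
    list(genes = genes, pairs = pairs, te = dplyr::bind_rows(te),
         chrom_sizes = chrom_sizes, te_truth = dplyr::bind_rows(te_truth))
  })
}

# category -> planted (cis, trans) with random shared sign
plant_effects <- function(category, ce, te) {
  s <- sample(c(-1, 1), length(category), replace = TRUE)
  cis <- trans <- numeric(length(category))
  cis[category == "cis_only"] <- (s * ce)[category == "cis_only"]
  trans[category == "trans_only"] <- (s * te)[category == "trans_only"]
  i <- category == "cis_plus_trans"
  cis[i] <- (s * ce)[i]; trans[i] <- (s * te)[i]
  i <- category == "cis_x_trans"
  cis[i] <- (s * ce)[i]; trans[i] <- (-s * te)[i]
  i <- category == "compensatory"
  cis[i] <- (s * ce)[i]; trans[i] <- (-s * ce)[i]
  list(cis = cis, trans = trans)
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate homoeolog expression across generations
#'
#' Per pair a regulatory category is drawn and (cis, trans) effects planted;
#' parental means split the baseline symmetrically as `b * 2^(+/-P/2)` with
#' `P = cis + trans`, F1 homoeolog means use `H = cis`, and F22 uses
#' `H' = cis * (1 - trans_compensation_F22)`. Counts are negative binomial
#' around these means; the baseline is log-normal with median `depth_mean`.
#'
#' @param pairs Homoeolog pair tibble from [simulate_genome()].
#' @param params An [sim_params()] object.
#'
#' @return A list: `counts` (long count tibble with sample metadata),
#'   `samples` (sample sheet), `truth` (per-pair planted category and
#'   effects).
#' @export
simulate_expression <- function(pairs, params) {
  stopifnot(inherits(params, "hs_sim_params"))
  n <- nrow(pairs)
  reps <- params$replicates
  with_seed(params$seed + 1L, {
    category <- sample(names(params$category_proportions), n, replace = TRUE,
                       prob = params$category_proportions)
    eff <- plant_effects(category, params$cis_effect, params$trans_effect)
    P <- eff$cis + eff$trans
    H1 <- eff$cis
    H22 <- eff$cis * (1 - params$trans_compensation_F22)
    b <- rlnorm(n, meanlog = log(params$depth_mean),
                sdlog = params$baseline_sdlog)
    groups <- list(
      parent_R = list(role = "parent_R", genes = pairs$r_gene, mu = b * 2^(P / 2)),
      parent_C = list(role = "parent_C", genes = pairs$c_gene, mu = b * 2^(-P / 2)),
      F1_R  = list(role = "hybrid", group = "F1",  genes = pairs$r_gene, mu = b * 2^(H1 / 2)),
      F1_C  = list(role = "hybrid", group = "F1",  genes = pairs$c_gene, mu = b * 2^(-H1 / 2)),
      F22_R = list(role = "hybrid", group = "F22", genes = pairs$r_gene, mu = b * 2^(H22 / 2)),
      F22_C = list(role = "hybrid", group = "F22", genes = pairs$c_gene, mu = b * 2^(-H22 / 2))
    )
    rows <- list()
    for (nm in names(groups)) {
      g <- groups[[nm]]
      grp <- if (is.null(g$group)) nm else g$group
      for (r in seq_len(reps)) {
        rows[[paste(nm, r)]] <- tibble(
          gene_id = g$genes,
          sample = sprintf("%s_rep%d", grp, r),
          count = as.numeric(rcounts(n, g$mu, params$nb_dispersion)),
          group = grp, role = g$role, replicate = r, tissue = "sim")
      }
    }
    counts <- dplyr::bind_rows(rows)
    samples <- dplyr::distinct(counts[c("sample", "group", "role",
                                        "replicate", "tissue")])
    truth <- tibble(
      pair_id = pairs$pair_id, true_category7 = category,
      true_cis = eff$cis, true_trans = eff$trans,
      true_P = P, true_H_F1 = H1, true_H_F22 = H22)
    list(counts = counts, samples = samples, truth = truth)
  })
}

# strand-aware region spans in 0-based half-open coordinates
region_span <- function(gene, region, flank = 2000) {
  stopifnot(region %in% c("up2k", "body", "down2k"))
  if (region == "body") {
    c(gene$start, gene$end)
  } else if ((region == "up2k") == (gene$strand == "+")) {
    c(max(0, gene$start - flank), gene$start)
  } else {
    c(gene$end, gene$end + flank)
  }
}

#' Simulate bisulfite cytosine counts with planted promoter differences
#'
#' Base methylation per gene region is Beta(2,2); a `dm_fraction` subset of
#' pairs carries a planted parental difference `dm_effect` on the up2k
#' (promoter) region, with hybrid homoeologs at mid-parent level split by
#' `dm_hybrid_effect`. Per cytosine, depth is Poisson(`meth_depth`) and
#' methylated reads binomial with probability `clamp(ML + p0_error, 0, 1)`.
#'
#' @param pairs,genes Tibbles from [simulate_genome()].
#' @param params An [sim_params()] object.
#'
#' @return A list: `cytosines` (records with `group` column over parent_R,
#'   parent_C, F1) and `truth` (per-pair planted `true_dm_parents`,
#'   `true_dm_hybrid`).
#' @export
simulate_methylation <- function(pairs, genes, params) {
  stopifnot(inherits(params, "hs_sim_params"))
  n <- nrow(pairs)
  gidx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  with_seed(params$seed + 2L, {
    planted <- runif(n) < params$dm_fraction
    # planted pairs draw the low-parent level from Beta(2,2) truncated to
    # [0, 1 - dm_effect] so the planted shift is realized exactly, unclamped
    u <- runif(n)
    base_ml <- ifelse(
      planted,
      stats::qbeta(u * stats::pbeta(1 - params$dm_effect, 2, 2), 2, 2),
      stats::qbeta(u, 2, 2))
    dm_par <- ifelse(planted, params$dm_effect, 0)
    dm_hyb <- ifelse(planted, params$dm_hybrid_effect, 0)
    ml_r_parent <- base_ml + dm_par
    ml_c_parent <- base_ml
    mid <- (ml_r_parent + ml_c_parent) / 2
    ml_r_hyb <- clamp01(mid + dm_hyb / 2)
    ml_c_hyb <- clamp01(mid - dm_hyb / 2)
    tracks <- list(
      list(group = "parent_R", gene = pairs$r_gene, up = ml_r_parent),
      list(group = "parent_C", gene = pairs$c_gene, up = ml_c_parent),
      list(group = "F1", gene = pairs$r_gene, up = ml_r_hyb),
      list(group = "F1", gene = pairs$c_gene, up = ml_c_hyb))
    out <- list()
    for (tr in tracks) {
      gm <- genes[gidx[tr$gene], ]
      for (region in c("up2k", "body", "down2k")) {
        ml <- if (region == "up2k") tr$up else base_ml
        spans <- t(vapply(seq_len(n), function(i)
          region_span(gm[i, ], region), numeric(2)))
        k_sites <- params$cytosines_per_region
        pos <- lapply(seq_len(n), function(i)
          sort(unique(floor(runif(k_sites, spans[i, 1], spans[i, 2])))))
        npos <- lengths(pos)
        depth <- rpois(sum(npos), params$meth_depth)
        prob <- clamp01(rep(ml, npos) + params$p0_error)
        km <- rbinom(sum(npos), depth, prob)
        out[[paste(tr$group, tr$gene[1], region)]] <- tibble(
          chrom = rep(gm$chrom, npos),
          pos = unlist(pos),
          strand = "+", context = "CpG",
          k_meth = km, n_total = depth,
          group = tr$group,
          gene_id = rep(gm$gene_id, npos),
          region = region)
      }
    }
    truth <- tibble(pair_id = pairs$pair_id,
                    true_dm_parents = dm_par, true_dm_hybrid = dm_hyb)
    list(cytosines = dplyr::bind_rows(out), truth = truth)
  })
}

#' Simulate read depth under planted copy-number segments
#'
#' Default copy state is (2, 2); within each planted segment the specified
#' (r_copies, c_copies) applies, including complete replacement (0, 4).
#' Per-gene read counts are Poisson with mean
#' `depth_mean * copies/2 * length/1000`.
#'
#' @param pairs Pair tibble from [simulate_genome()].
#' @param params An [sim_params()] object; `params$hr_segments` holds the
#'   planted segments.
#' @param genes Optional gene models supplying homoeolog lengths; lengths
#'   are drawn log-uniform in 500-5000 bp when absent.
#' @param sample_id Sample label for the emitted track.
#'
#' @return A list: `depth` (per-pair read counts and lengths) and `truth`
#'   (per-pair planted copy states).
#' @export
simulate_copy_number <- function(pairs, params, genes = NULL,
                                 sample_id = "S1") {
  stopifnot(inherits(params, "hs_sim_params"))
  n <- nrow(pairs)
  segs <- params$hr_segments
  if (!is.null(segs)) {
    segs <- as_tibble(segs)
    for (cp in unique(segs$chrom_pair)) {
      s <- segs[segs$chrom_pair == cp, ]
      s <- s[order(s$start_index), ]
      if (nrow(s) > 1 &&
          any(s$start_index[-1] < (s$start_index + s$n_genes)[-nrow(s)])) {
        stop("overlapping hr_segments on ", cp, call. = FALSE)
      }
      idx <- pairs$order_index[pairs$chrom_pair == cp]
      if (!nrow(s) == 0 && any(s$start_index + s$n_genes - 1 > max(idx))) {
        stop("hr_segment exceeds gene range on ", cp, call. = FALSE)
      }
    }
  }
  with_seed(params$seed + 3L, {
    if (!is.null(genes)) {
      gl <- setNames(genes$end - genes$start, genes$gene_id)
      r_len <- unname(gl[pairs$r_gene]); c_len <- unname(gl[pairs$c_gene])
    } else {
      r_len <- round(exp(runif(n, log(500), log(5000))))
      c_len <- round(exp(runif(n, log(500), log(5000))))
    }
    r_cop <- rep(2, n); c_cop <- rep(2, n)
    if (!is.null(segs)) {
      for (i in seq_len(nrow(segs))) {
        sel <- pairs$chrom_pair == segs$chrom_pair[i] &
          pairs$order_index >= segs$start_index[i] &
          pairs$order_index < segs$start_index[i] + segs$n_genes[i]
        r_cop[sel] <- segs$r_copies[i]
        c_cop[sel] <- segs$c_copies[i]
      }
    }
    depth <- tibble(
      pair_id = pairs$pair_id, chrom_pair = pairs$chrom_pair,
      order_index = pairs$order_index,
      r_reads = rpois(n, params$depth_mean * r_cop / 2 * r_len / 1000),
      c_reads = rpois(n, params$depth_mean * c_cop / 2 * c_len / 1000),
      r_len = r_len, c_len = c_len, sample = sample_id)
    truth <- tibble(pair_id = pairs$pair_id, r_copies = r_cop,
                    c_copies = c_cop)
    list(depth = depth, truth = truth)
  })
}

#' Simulate structural-variant positions driven by TE density
#'
#' Per window the SV count is Poisson with log-intensity
#' `alpha + sv_te_slope * te_density`; `alpha` is set so the genome-wide
#' mean SV count per window is 2. Positions are uniform within the window.
#'
#' @param te TE interval tibble.
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param params An [sim_params()] object.
#'
#' @return A list: `sv` (positions), `windows` (per-window TE density and
#'   SV count).
#' @export
simulate_sv <- function(te, chrom_sizes, params) {
  stopifnot(inherits(params, "hs_sim_params"))
  tracks <- window_track(te, chrom_sizes, sv = NULL,
                         window_size = params$window_size)
  with_seed(params$seed + 4L, {
    alpha <- log(2) - log(mean(exp(params$sv_te_slope * tracks$te_density)))
    lambda <- exp(alpha + params$sv_te_slope * tracks$te_density)
    counts <- rpois(nrow(tracks), lambda)
    sv <- tibble(
      chrom = rep(tracks$chrom, counts),
      pos = floor(runif(sum(counts),
                        rep(tracks$start, counts),
                        rep(tracks$end, counts))))
    tracks$sv_count <- counts
    list(sv = sv, windows = tracks)
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator and writes the standard file set: `counts.tsv`,
#' `samples.tsv`, `genes.bed`, `pairs.tsv`, `cytosines.tsv`, `te.bed`,
#' `sv.bed`, `copy_depth.tsv`, and `truth_*.tsv` tables.
#'
#' @param params An [sim_params()] object.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_dataset <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- simulate_genome(params)
  expr <- simulate_expression(genome$pairs, params)
  meth <- simulate_methylation(genome$pairs, genome$genes, params)
  if (is.null(params$hr_segments)) {
    params$hr_segments <- tibble(
      chrom_pair = genome$pairs$chrom_pair[1], start_index = 10L,
      n_genes = 5L, r_copies = 3, c_copies = 1)
  }
  cn <- simulate_copy_number(genome$pairs, params, genes = genome$genes)
  sv <- simulate_sv(genome$te, genome$chrom_sizes, params)

  wide <- tidyr::pivot_wider(expr$counts[c("gene_id", "sample", "count")],
                             names_from = "sample", values_from = "count",
                             values_fill = 0)
  write_records(wide, file.path(dir, "counts.tsv"))
  write_records(expr$samples, file.path(dir, "samples.tsv"))
  bed <- genome$genes
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", bed$chrom, bed$start, bed$end,
                     bed$gene_id, bed$strand), file.path(dir, "genes.bed"))
  write_records(genome$pairs, file.path(dir, "pairs.tsv"))
  write_records(meth$cytosines[c("chrom", "pos", "strand", "context",
                                 "k_meth", "n_total", "group")],
                file.path(dir, "cytosines.tsv"))
  writeLines(sprintf("%s\t%d\t%d\t%s", genome$te$chrom, genome$te$start,
                     genome$te$end, genome$te$name), file.path(dir, "te.bed"))
  writeLines(sprintf("%s\t%d\t%d\tsv", sv$sv$chrom, sv$sv$pos,
                     sv$sv$pos + 1), file.path(dir, "sv.bed"))
  write_records(cn$depth, file.path(dir, "copy_depth.tsv"))
  write_records(expr$truth, file.path(dir, "truth_expression.tsv"))
  write_records(meth$truth, file.path(dir, "truth_methylation.tsv"))
  write_records(cn$truth, file.path(dir, "truth_copy.tsv"))
  write_records(sv$windows, file.path(dir, "truth_windows.tsv"))
  invisible(list(genome = genome, expression = expr, methylation = meth,
                 copy = cn, sv = sv, params = params))
}
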