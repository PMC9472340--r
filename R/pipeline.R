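# shared file-name layout used by the step runners and the CLI
hs_files <- function(dir) {
  list(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.bed"),
    pairs = file.path(dir, "pairs.tsv"),
    cytosines = file.path(dir, "cytosines.tsv"),
    te = file.path(dir, "te.bed"),
    sv = file.path(dir, "sv.bed"),
    depth = file.path(dir, "copy_depth.tsv"),
    kaks = file.path(dir, "kaks.tsv"))
}

load_expression_inputs <- function(dir) {
  f <- hs_files(dir)
  counts <- read_counts(f$counts, f$samples)
  pairs <- read_pairs(f$pairs)
  list(counts = normalize_counts(counts), pairs = pairs)
}

#' Homoeolog expression bias step
#'
#' Reads counts/samples/pairs from `dir`, normalizes, filters, and writes
#' `ratios.tsv`, `heb.tsv`, `silencing.tsv`, `heb_summary.tsv` to `out_dir`.
#'
#' @param dir Input directory (layout of [simulate_dataset()]).
#' @param out_dir Output directory.
#' @param config An [hs_config()].
#'
#' @return Invisibly, the ratio records.
#' @export
run_step_heb <- function(dir, out_dir = dir, config = hs_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- load_expression_inputs(dir)
  elig <- filter_pairs(inp$counts, inp$pairs, config)
  ratios <- homoeolog_ratios(inp$counts, inp$pairs, elig)
  ratios_flat <- dplyr::select(ratios, -"rep_log2rc")
  write_records(ratios_flat, file.path(out_dir, "ratios.tsv"))
  heb <- tibble(pair_id = ratios$pair_id, group = ratios$group,
                category = heb_call(ratios$log2rc, config))
  write_records(heb, file.path(out_dir, "heb.tsv"))
  sil <- silencing_call(inp$counts)
  write_records(sil, file.path(out_dir, "silencing.tsv"))
  summ <- ratios |>
    dplyr::group_split(.data$group) |>
    purrr::map(heb_distribution, config = config) |>
    dplyr::bind_rows()
  write_records(summ, file.path(out_dir, "heb_summary.tsv"))
  invisible(ratios)
}

#' Cis/trans classification step
#'
#' Classifies every eligible pair in each hybrid generation found in the
#' sample sheet and writes `calls.tsv` plus `category_counts.tsv`; when a
#' `kaks.tsv` is present also writes `kaks_stats.tsv`.
#'
#' @inheritParams run_step_heb
#' @return Invisibly, the combined regulatory calls.
#' @export
run_step_cistrans <- function(dir, out_dir = dir, config = hs_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- load_expression_inputs(dir)
  gens <- unique(inp$counts$group[inp$counts$role == "hybrid"])
  calls <- dplyr::bind_rows(lapply(gens, function(g)
    classify_pairs(inp$counts, inp$pairs, g, config)))
  write_records(calls, file.path(out_dir, "calls.tsv"))
  tally <- calls |>
    dplyr::count(.data$generation, .data$category7, name = "n_pairs")
  write_records(tally, file.path(out_dir, "category_counts.tsv"))
  f <- hs_files(dir)
  if (file.exists(f$kaks)) {
    kk <- read_kaks(f$kaks)
    st <- kaks_group_stats(kk, calls[calls$generation == gens[1], ])
    write_records(st$summary, file.path(out_dir, "kaks_stats.tsv"))
    if (nrow(st$tests)) {
      write_records(st$tests, file.path(out_dir, "kaks_tests.tsv"))
    }
  }
  invisible(calls)
}

#' Methylation step
#'
#' Calls 5mC sites, computes per-gene region methylation levels per group,
#' derives parental and hybrid promoter differences per pair, classifies
#' hyper-/hypo-DMGs, and flags methylation-regulated genes against the
#' hybrid expression ratio. Writes `calls_5mc.tsv`, `profiles.tsv`,
#' `dm.tsv`, `dmg.tsv`, `mrg.tsv`.
#'
#' @inheritParams run_step_heb
#' @param hybrid_group Hybrid group whose expression ratio feeds the MRG
#'   test.
#' @return Invisibly, the per-pair DM table.
#' @export
run_step_methylate <- function(dir, out_dir = dir, config = hs_config(),
                               hybrid_group = "F1") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f <- hs_files(dir)
  cyto <- read_cytosines(f$cytosines)
  genes <- read_gene_annotation(f$genes, "bed")
  pairs <- read_pairs(f$pairs)
  n_non_cpg <- sum(cyto$context != "CpG")
  if (n_non_cpg) {
    message(n_non_cpg, " non-CpG record(s) parsed and excluded from profiles")
  }
  calls <- call_5mc_batch(cyto, config)
  write_records(
    dplyr::select(calls, dplyr::any_of(c(
      "chrom", "pos", "strand", "context", "k_meth", "n_total", "group",
      "p", "q", "tested", "is_methylated"))),
    file.path(out_dir, "calls_5mc.tsv"))
  lv <- region_levels(cyto, genes, config = config)
  write_records(lv, file.path(out_dir, "profiles.tsv"))

  up <- lv[lv$region == "up2k", ]
  key <- paste(up$group, up$gene_id)
  mls <- setNames(up$mean_ml, key)
  dm <- tibble(
    pair_id = pairs$pair_id,
    dm_parents = unname(mls[paste("parent_R", pairs$r_gene)]) -
      unname(mls[paste("parent_C", pairs$c_gene)]),
    dm_hybrid = unname(mls[paste(hybrid_group, pairs$r_gene)]) -
      unname(mls[paste(hybrid_group, pairs$c_gene)]))
  dm <- dm[stats::complete.cases(dm), ]
  dm$dmg_class <- classify_dmg(dm$dm_parents, dm$dm_hybrid, config)
  write_records(dm, file.path(out_dir, "dm.tsv"))
  write_records(dm[c("pair_id", "dmg_class")], file.path(out_dir, "dmg.tsv"))

  inp <- load_expression_inputs(dir)
  ratios <- homoeolog_ratios(inp$counts, inp$pairs,
                             filter_pairs(inp$counts, inp$pairs, config))
  hyb <- ratios[ratios$group == hybrid_group, c("pair_id", "log2rc")]
  mrg_in <- dplyr::inner_join(dm, hyb, by = "pair_id")
  mrg_in <- mrg_in[is.finite(mrg_in$log2rc), ]
  mrg <- dplyr::bind_cols(
    mrg_in["pair_id"],
    detect_mrg(mrg_in$dm_hybrid, mrg_in$log2rc, config))
  write_records(mrg, file.path(out_dir, "mrg.tsv"))
  invisible(dm)
}

#' Homoeologous-recombination scan step
#'
#' Computes copy ratios and states from the depth track and writes
#' `copy_ratios.tsv` and `segments.tsv`.
#'
#' @inheritParams run_step_heb
#' @return Invisibly, the segment tibble.
#' @export
run_step_hrscan <- function(dir, out_dir = dir, config = hs_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f <- hs_files(dir)
  depth <- read_records(f$depth)
  rec <- copy_ratio_records(depth, config)
  write_records(rec, file.path(out_dir, "copy_ratios.tsv"))
  segs <- detect_segments(rec, config)
  write_records(segs, file.path(out_dir, "segments.tsv"),
                allow_empty = TRUE)
  invisible(segs)
}

#' TE / structural-variant association step
#'
#' Builds the window track from the TE and SV files and writes
#' `sv_te_windows.tsv`, `sv_te_class.tsv`, and `sv_te_stats.tsv`.
#'
#' @inheritParams run_step_heb
#' @param window_size Window width in bp.
#' @return Invisibly, the correlation result list.
#' @export
run_step_tesv <- function(dir, out_dir = dir, config = hs_config(),
                          window_size = 1e5) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f <- hs_files(dir)
  te <- read_intervals(f$te)
  sv_iv <- read_intervals(f$sv)
  sv <- tibble(chrom = sv_iv$chrom, pos = sv_iv$start)
  genes <- read_gene_annotation(f$genes, "bed")
  chrom_sizes <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(size = max(.data$end) + 2500, .groups = "drop")
  track <- window_track(te, chrom_sizes, sv, window_size)
  write_records(track, file.path(out_dir, "sv_te_windows.tsv"))
  cls <- sv_te_classify(sv, te, config)
  write_records(cls, file.path(out_dir, "sv_te_class.tsv"))
  res <- sv_te_correlation(track)
  stats_tb <- tibble(
    statistic = c("pearson_r", "t", "df", "p_correlation", "p_class_welch"),
    value = c(res$r, res$t, res$df, res$p, res$class_test$p))
  write_records(stats_tb, file.path(out_dir, "sv_te_stats.tsv"))
  invisible(res)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates the default synthetic dataset into `out_dir/sim` and runs every
#' analysis step on it, writing all result tables into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config An [hs_config()].
#' @param params An [sim_params()] object for the generator.
#'
#' @return Invisibly, a list with the simulation objects and the paths of
#'   every written table.
#' @export
run_pipeline <- function(out_dir, config = hs_config(),
                         params = sim_params(seed = config$seed)) {
  sim_dir <- file.path(out_dir, "sim")
  sim <- simulate_dataset(params, sim_dir)
  # a Ka/Ks table consistent with neutral-ish divergence, consumed as input
  with_seed(params$seed + 5L, {
    ks <- rlnorm(nrow(sim$genome$pairs), log(0.3), 0.4)
    ka <- ks * rbeta(nrow(sim$genome$pairs), 2, 8)
    write_records(tibble(pair_id = sim$genome$pairs$pair_id, ka = ka,
                         ks = ks, ka_ks = ka / ks),
                  file.path(sim_dir, "kaks.tsv"))
  })
  run_step_heb(sim_dir, out_dir, config)
  run_step_cistrans(sim_dir, out_dir, config)
  run_step_methylate(sim_dir, out_dir, config)
  run_step_hrscan(sim_dir, out_dir, config)
  run_step_tesv(sim_dir, out_dir, config, params$window_size)
  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  invisible(list(sim = sim, outputs = outputs))
}
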