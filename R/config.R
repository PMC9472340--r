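#' Analysis configuration
#'
#' Bundles every decision threshold used across the pipeline. Defaults are
#' the published analytic thresholds of the homoeolog framework: eligibility
#' requires >= 5 reads per homoeolog in every replicate, strong homoeolog
#' expression bias is |log2(R/C)| > 1, copy-ratio calls use +/- log10(2) =
#' 0.30103, unequal-recombination segments need >= 3 contiguous genes,
#' count/ratio tests use p < 0.01 with a 4-fold-change gate, hyper-/hypo-DMG
#' classification uses 0.6/0.3 and 0.6/0.2 methylation differences, and
#' methylation-regulated genes require DM > 0.4 with a discordant 4-fold
#' expression change.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @return An object of class `hs_config`: a named list with fields
#'   `min_reads`, `heb_threshold`, `copy_log10_threshold`, `min_run`,
#'   `alpha_count_test`, `alpha_ratio_test`, `fc_threshold`,
#'   `dm_dmg_hyper`, `dm_dmg_hybrid_hyper`, `dm_dmg_hybrid_hypo`,
#'   `dm_subpattern`, `mrg_dm`, `mrg_fc`, `p0_error`, `fdr_5mc`,
#'   `min_depth_5mc`, `te_proximity`, `n_windows`, `dmr_alpha`, `seed`.
#' @export
#' @examples
#' cfg <- hs_config(min_reads = 10)
#' cfg$min_reads
hs_config <- function(...) {
  defaults <- list(
    min_reads            = 5L,
    heb_threshold        = 1,
    copy_log10_threshold = log10(2),
    min_run              = 3L,
    alpha_count_test     = 0.01,
    alpha_ratio_test     = 0.01,
    fc_threshold         = 4,
    dm_dmg_hyper         = 0.6,
    dm_dmg_hybrid_hyper  = 0.3,
    dm_dmg_hybrid_hypo   = 0.2,
    dm_subpattern        = 0.3,
    mrg_dm               = 0.4,
    mrg_fc               = 4,
    p0_error             = 0.01,
    fdr_5mc              = 0.05,
    min_depth_5mc        = 5L,
    te_proximity         = 1000,
    n_windows            = 20L,
    dmr_alpha            = 1e-5,
    seed                 = 1L
  )
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides))) {
    stop("hs_config() overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_config(cfg)
  structure(cfg, class = "hs_config")
}

validate_config <- function(cfg) {
  probs <- c("alpha_count_test", "alpha_ratio_test", "p0_error",
             "fdr_5mc", "dmr_alpha")
  for (key in probs) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      stop("config key '", key, "' must be a probability in (0, 1), got ",
           format(v), call. = FALSE)
    }
  }
  pos <- c("heb_threshold", "copy_log10_threshold", "fc_threshold",
           "dm_dmg_hyper", "dm_dmg_hybrid_hyper", "dm_dmg_hybrid_hypo",
           "dm_subpattern", "mrg_dm", "mrg_fc", "te_proximity", "n_windows",
           "min_depth_5mc")
  for (key in pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop("config key '", key, "' must be > 0, got ", format(v),
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$min_reads) || cfg$min_reads < 0) {
    stop("config key 'min_reads' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(cfg$min_run) || cfg$min_run < 1) {
    stop("config key 'min_run' must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Read an analysis configuration from a flat YAML file
#'
#' Unspecified keys keep their defaults; unknown keys are an error, as is any
#' out-of-range value.
#'
#' @param path Path to a YAML file of flat `key: value` pairs matching the
#'   fields of [hs_config()]. An empty file yields the default configuration.
#'
#' @return An `hs_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("failed to parse config '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop("config '", path, "' must be a flat key: value document",
         call. = FALSE)
  }
  do.call(hs_config, vals)
}
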