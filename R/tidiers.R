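#' Tidy a cis/trans classification result
#'
#' @param x An `hs_cistrans` object from [classify_pairs()].
#' @param ... Ignored.
#' @return A plain tibble of per-pair calls.
#' @method tidy hs_cistrans
#' @export
tidy.hs_cistrans <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a cis/trans classification result
#'
#' @param x An `hs_cistrans` object.
#' @param ... Ignored.
#' @return A tibble with the number of classified pairs, mean |P| and |H|,
#'   and the fraction of pairs in each regulatory category.
#' @method glance hs_cistrans
#' @export
glance.hs_cistrans <- function(x, ...) {
  cats <- c("conserved", "cis_only", "trans_only", "cis_plus_trans",
            "cis_x_trans", "compensatory", "ambiguous")
  fr <- as.list(prop.table(table(factor(x$category7, levels = cats))))
  names(fr) <- paste0("frac_", names(fr))
  dplyr::bind_cols(
    tibble(n = nrow(x), mean_abs_P = mean(abs(x$P)),
           mean_abs_H = mean(abs(x$H))),
    as_tibble(fr))
}

#' Tidy a recombination segment set
#'
#' @param x An `hs_segments` object from [detect_segments()].
#' @param ... Ignored.
#' @return A plain tibble of segments.
#' @method tidy hs_segments
#' @export
tidy.hs_segments <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a recombination segment set
#'
#' @param x An `hs_segments` object.
#' @param ... Ignored.
#' @return A tibble with segment count, genes covered, and counts per
#'   direction.
#' @method glance hs_segments
#' @export
glance.hs_segments <- function(x, ...) {
  tibble(n_segments = nrow(x),
         n_genes = sum(x$n_genes),
         n_toward_R = sum(x$direction == "toward_R"),
         n_toward_C = sum(x$direction == "toward_C"))
}
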