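#' Read gene models from BED or GFF3
#'
#' Coordinates are held internally as 0-based half-open intervals. BED input
#' is used as-is; GFF3 start positions (1-based inclusive) are decremented by
#' one at the boundary so both dialects yield identical gene models for the
#' same locus. A missing strand becomes `"+"` with a warning.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` or `"gff3"`.
#'
#' @return A tibble of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(tolower(dialect), c("bed", "gff3"))
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (dialect == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                     !startsWith(lines, "track")]
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4)) {
      stop("BED line ", which(nf < 4)[1], ": need at least 4 fields",
           call. = FALSE)
    }
    genes <- tibble(
      gene_id = vapply(fields, `[`, "", 4),
      chrom   = vapply(fields, `[`, "", 1),
      start   = as.numeric(vapply(fields, `[`, "", 2)),
      end     = as.numeric(vapply(fields, `[`, "", 3)),
      strand  = vapply(fields, function(f) if (length(f) >= 6) f[6] else NA_character_, "")
    )
  } else {
    cols <- readr::read_tsv(
      path, comment = "#", col_names = c(
        "chrom", "source", "type", "start", "end", "score", "strand",
        "phase", "attributes"),
      col_types = "cccnncccc", progress = FALSE
    )
    cols <- dplyr::filter(cols, .data$type %in% c("gene", "mRNA", "transcript"))
    ids <- sub(".*ID=([^;]+).*", "\\1", cols$attributes)
    no_id <- !grepl("ID=", cols$attributes)
    if (any(no_id)) ids[no_id] <- sub(".*Name=([^;]+).*", "\\1", cols$attributes[no_id])
    genes <- tibble(
      gene_id = ids,
      chrom   = cols$chrom,
      start   = cols$start - 1,   # 1-based inclusive -> 0-based half-open
      end     = cols$end,
      strand  = ifelse(cols$strand %in% c("+", "-"), cols$strand, NA_character_)
    )
  }
  if (anyNA(genes$strand) || any(!genes$strand %in% c("+", "-"))) {
    bad <- is.na(genes$strand) | !genes$strand %in% c("+", "-")
    warning(sum(bad), " record(s) without strand; assuming '+'", call. = FALSE)
    genes$strand[bad] <- "+"
  }
  bad <- which(!(genes$start >= 0 & genes$end > genes$start))
  if (length(bad)) {
    stop("invalid interval at record ", bad[1], " (", genes$gene_id[bad[1]],
         "): start=", genes$start[bad[1]], " end=", genes$end[bad[1]],
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1], call. = FALSE)
  }
  genes
}

#' Read a homoeolog count table with its sample sheet
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @param sample_sheet TSV mapping every count column to its metadata;
#'   columns `sample`, `group`, `role` (one of `parent_R`, `parent_C`,
#'   `hybrid`), `replicate`, and optionally `tissue`.
#'
#' @return A long tibble: `gene_id`, `sample`, `count`, `group`, `role`,
#'   `replicate`, `tissue`.
#' @export
read_counts <- function(path, sample_sheet) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  sheet <- readr::read_tsv(sample_sheet, col_types = readr::cols(),
                           progress = FALSE)
  req <- c("sample", "group", "role", "replicate")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"tissue" %in% names(sheet)) sheet$tissue <- NA_character_
  sample_cols <- setdiff(names(wide), "gene_id")
  missing <- setdiff(sample_cols, sheet$sample)
  if (length(missing)) {
    stop("count column(s) absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"gene_id", names_to = "sample",
                              values_to = "count")
  if (any(long$count < 0, na.rm = TRUE)) {
    stop("negative count in ", path, call. = FALSE)
  }
  if (any(long$count != floor(long$count), na.rm = TRUE)) {
    stop("non-integer count in ", path, call. = FALSE)
  }
  dplyr::left_join(long, sheet[c("sample", "group", "role", "replicate",
                                 "tissue")], by = "sample")
}

#' Read per-cytosine methylation counts
#'
#' @param path bedGraph-like TSV with header: `chrom`, `pos` (0-based),
#'   `strand`, `context` (CpG/CHG/CHH), `k_meth`, `n_total`, and optionally
#'   `group`.
#'
#' @return A tibble of cytosine records.
#' @export
read_cytosines <- function(path) {
  cy <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("chrom", "pos", "strand", "context", "k_meth", "n_total")
  if (!all(req %in% names(cy))) {
    stop("cytosine file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(cy$k_meth < 0 | cy$n_total < 0)) {
    stop("negative methylation count in ", path, call. = FALSE)
  }
  bad <- which(cy$k_meth > cy$n_total)
  if (length(bad)) {
    stop("k_meth > n_total at record ", bad[1], " of ", path, call. = FALSE)
  }
  cy
}

#' Read genomic intervals (BED-like)
#'
#' @param path BED file (chrom, start, end, optional name); 0-based
#'   half-open coordinates.
#'
#' @return A tibble: `chrom`, `start`, `end`, `name`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end   = as.numeric(vapply(fields, `[`, "", 3)),
    name  = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  )
}

#' Read a homoeolog pair map
#'
#' @param path TSV with columns `pair_id`, `r_gene`, `c_gene`, `chrom_pair`,
#'   `order_index`.
#'
#' @return A tibble of homoeolog pairs ordered by `chrom_pair` and
#'   `order_index`.
#' @export
read_pairs <- function(path) {
  pairs <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("pair_id", "r_gene", "c_gene", "chrom_pair", "order_index")
  if (!all(req %in% names(pairs))) {
    stop("pair map must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(pairs, .data$chrom_pair, .data$order_index)
}

#' Read a Ka/Ks table
#'
#' @param path TSV with columns `pair_id`, `ka`, `ks`, `ka_ks`.
#' @return A tibble.
#' @export
read_kaks <- function(path) {
  kk <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("pair_id", "ka", "ks", "ka_ks")
  if (!all(req %in% names(kk))) {
    stop("Ka/Ks table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(kk$ka < 0 | kk$ks < 0 | kk$ka_ks < 0, na.rm = TRUE)) {
    stop("negative Ka/Ks value in ", path, call. = FALSE)
  }
  kk
}

#' Write a result table as TSV
#'
#' Floating-point columns are serialised with 6 significant digits so that
#' every table round-trips through [read_records()] field-wise.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @param allow_empty Permit writing a header-only file.
#'
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, allow_empty = FALSE) {
  if (!is.data.frame(records)) stop("records must be a data frame", call. = FALSE)
  if (nrow(records) == 0 && !allow_empty) {
    stop("refusing to write an empty table (set allow_empty = TRUE)",
         call. = FALSE)
  }
  out <- as_tibble(records)
  is_dbl <- vapply(out, function(x) is.double(x) && !inherits(x, "integer"), TRUE)
  out[is_dbl] <- lapply(out[is_dbl], function(x) {
    s <- formatC(x, digits = 6, format = "g")
    s[is.na(x)] <- NA_character_
    s[is.infinite(x) & x > 0] <- "Inf"
    s[is.infinite(x) & x < 0] <- "-Inf"
    trimws(s)
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a table written by [write_records()]
#'
#' @param path TSV path.
#' @return A tibble with column types guessed from content.
#' @export
read_records <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  na = c("", "NA"))
}
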