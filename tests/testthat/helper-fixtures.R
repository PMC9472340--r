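# Small hand-built fixtures shared across test files.

# long count tibble for a single homoeolog pair across all roles;
# counts given per (role/group) as length-3 replicate vectors
pair_counts <- function(pr, pc, f1_r, f1_c, f22_r = NULL, f22_c = NULL,
                        pair_id = "p1") {
  rows <- list(
    tibble::tibble(gene_id = "gR", sample = paste0("parent_R_rep", 1:3),
                   count = pr, group = "parent_R", role = "parent_R",
                   replicate = 1:3, tissue = "t"),
    tibble::tibble(gene_id = "gC", sample = paste0("parent_C_rep", 1:3),
                   count = pc, group = "parent_C", role = "parent_C",
                   replicate = 1:3, tissue = "t"),
    tibble::tibble(gene_id = "gR", sample = paste0("F1_rep", 1:3),
                   count = f1_r, group = "F1", role = "hybrid",
                   replicate = 1:3, tissue = "t"),
    tibble::tibble(gene_id = "gC", sample = paste0("F1_rep", 1:3),
                   count = f1_c, group = "F1", role = "hybrid",
                   replicate = 1:3, tissue = "t"))
  if (!is.null(f22_r)) {
    rows <- c(rows, list(
      tibble::tibble(gene_id = "gR", sample = paste0("F22_rep", 1:3),
                     count = f22_r, group = "F22", role = "hybrid",
                     replicate = 1:3, tissue = "t"),
      tibble::tibble(gene_id = "gC", sample = paste0("F22_rep", 1:3),
                     count = f22_c, group = "F22", role = "hybrid",
                     replicate = 1:3, tissue = "t")))
  }
  dplyr::bind_rows(rows)
}

one_pair <- function(pair_id = "p1") {
  tibble::tibble(pair_id = pair_id, r_gene = "gR", c_gene = "gC",
                 chrom_pair = "cp01", order_index = 0L)
}

# copy-ratio records with given states on one chromosome pair
state_track <- function(states, chrom_pair = "cp01", sample = "S1") {
  n <- length(states)
  ratio <- dplyr::case_when(
    states == "bal" ~ 0, states == "Rg" ~ 0.5, states == "Cg" ~ -0.5,
    states == "Ra" ~ -Inf, states == "Ca" ~ Inf, TRUE ~ NA_real_)
  tibble::tibble(
    pair_id = paste0("p", seq_len(n)), chrom_pair = chrom_pair,
    order_index = seq_len(n) - 1L,
    r_reads = 100, c_reads = 100, r_len = 1000, c_len = 1000,
    sample = sample, log10_ratio = ratio,
    state = call_copy_state(ratio))
}

# independent brute-force segment finder: maximal same-direction runs
# found by extending windows gene by gene (no shared code with the package)
brute_segments <- function(states, order_index = seq_along(states) - 1L) {
  dir <- ifelse(states %in% c("R_gain", "C_absent"), 1,
                ifelse(states %in% c("C_gain", "R_absent"), -1, 0))
  res <- list()
  i <- 1
  n <- length(states)
  while (i <= n) {
    if (dir[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < n && dir[j + 1] == dir[i] &&
           order_index[j + 1] == order_index[j] + 1) j <- j + 1
    if (j - i + 1 >= 3) {
      res[[length(res) + 1]] <- data.frame(
        start_index = order_index[i], end_index = order_index[j],
        direction = if (dir[i] > 0) "toward_R" else "toward_C")
    }
    i <- j + 1
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(start_index = integer(), end_index = integer(),
               direction = character())
}
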