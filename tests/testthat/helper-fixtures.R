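# Shared fixtures, built in code at test time.

# A tiny hand-written record table with known arithmetic.
toy_records <- function() {
  tibble::tibble(
    query_gene = c("GA", "GB", "GC"),
    array_gene = c("GX", "GY", "GZ"),
    w_x = c(0.9, 1.0, 0.7),
    w_y = c(0.8, 0.7, 0.6),
    w_xy = c(0.70, 0.7, 0.5)
  )
}

# Write a small SGA-dialect TSV and return its path.
toy_sga_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy_sga.txt")
  lines <- c(
    paste("Query Strain ID", "Array Strain ID",
          "Query single mutant fitness (SMF)", "Array SMF",
          "Double mutant fitness", sep = "\t"),
    "YAL002W_sn123\tYBR001C_dma45\t0.9\t0.8\t0.70",
    "YCL003W_tsq67\tYBR002C_dma46\t1.0\t0.7\t0.7",
    "YDL004W_sn89\tYBR003C_dma47\t0.7\t0.6\t0.5"
  )
  writeLines(lines, path)
  path
}

# An annotation with processes of chosen sizes over a given gene pool.
toy_annotation <- function(sizes, genes = sprintf("G%04d", seq_len(sum(sizes)))) {
  stopifnot(length(genes) >= sum(sizes))
  idx <- 0
  purrr::imap(sizes, function(sz, k) {
    g <- genes[idx + seq_len(sz)]
    idx <<- idx + sz
    tibble::tibble(gene = g, process = sprintf("P%03d", k))
  }) |> dplyr::bind_rows()
}

# Wild-type steady state cached per test run (solving is cheap but not free).
weisse_wt_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- weisse_steady_state(weisse_params(), "root")
    cache
  }
})
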