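#' Column map for SGA-dialect double-mutant fitness tables
#'
#' Maps the five semantic fields of a double-mutant fitness table to the
#' column headers of the source file. Defaults target thecellmap.org export
#' dialect. Column naming varies across releases, so the map is
#' configuration, not code.
#'
#' @param query_id,array_id Strain identifier columns.
#' @param query_smf,array_smf Single-mutant fitness columns.
#' @param double_fitness Double-mutant fitness column.
#' @return A named list of class `sga_colmap`.
#' @export
sga_colmap <- function(query_id = "Query Strain ID",
                       array_id = "Array Strain ID",
                       query_smf = "Query single mutant fitness (SMF)",
                       array_smf = "Array SMF",
                       double_fitness = "Double mutant fitness") {
  out <- list(query_id = query_id, array_id = array_id,
              query_smf = query_smf, array_smf = array_smf,
              double_fitness = double_fitness)
  if (any(!vapply(out, is.character, TRUE)) ||
      any(lengths(out) != 1)) {
    rlang::abort("all column-map entries must be single strings")
  }
  structure(out, class = "sga_colmap")
}

#' Read an SGA-dialect double-mutant fitness table
#'
#' Reads a tab-separated file with a header row, maps columns via `colmap`,
#' derives gene identifiers from strain IDs by stripping everything from the
#' first underscore (the thecellmap strain-ID convention, e.g.
#' `"YAL002W_sn123"` is gene `"YAL002W"`; override with `gene_pattern`), and
#' drops rows with missing or non-numeric fitness fields (counted in the
#' `read_report` attribute).
#'
#' @param path Path to a tab-separated file.
#' @param colmap An [sga_colmap()].
#' @param gene_pattern Regular expression removed from strain IDs to obtain
#'   the gene identifier.
#' @return A tibble of records with columns `query_gene`, `array_gene`,
#'   `w_x` (query single-mutant fitness), `w_y` (array single-mutant
#'   fitness), `w_xy` (double-mutant fitness), and attribute `read_report`
#'   with counts of rows read and dropped.
#' @export
read_sga <- function(path, colmap = sga_colmap(), gene_pattern = "_.*$") {
  if (!file.exists(path)) {
    rlang::abort(paste0("SGA file not found: ", path))
  }
  if (file.size(path) == 0) {
    rlang::warn(paste0("empty SGA file: ", path))
    out <- tibble::tibble(query_gene = character(), array_gene = character(),
                          w_x = numeric(), w_y = numeric(), w_xy = numeric())
    attr(out, "read_report") <- list(rows_read = 0L, rows_dropped_missing = 0L,
                                     rows_retained = 0L)
    return(out)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  missing <- setdiff(unlist(colmap), names(raw))
  if (length(missing)) {
    rlang::abort(paste0(
      "column(s) named in the column map are absent from ", path, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    rlang::warn(paste0("empty SGA file: ", path))
  }
  out <- tibble::tibble(
    query_gene = sub(gene_pattern, "", raw[[colmap$query_id]]),
    array_gene = sub(gene_pattern, "", raw[[colmap$array_id]]),
    w_x = suppressWarnings(as.numeric(raw[[colmap$query_smf]])),
    w_y = suppressWarnings(as.numeric(raw[[colmap$array_smf]])),
    w_xy = suppressWarnings(as.numeric(raw[[colmap$double_fitness]]))
  )
  ok <- stats::complete.cases(out)
  res <- out[ok, , drop = FALSE]
  attr(res, "read_report") <- list(
    rows_read = nrow(raw),
    rows_dropped_missing = sum(!ok),
    rows_retained = nrow(res)
  )
  res
}

#' Write records in the SGA dialect read by [read_sga()]
#'
#' Gene identifiers are turned into strain IDs by appending a `_snN`
#' suffix, so a read/write round trip recovers the same genes.
#'
#' @param records A record tibble (`query_gene`, `array_gene`, `w_x`,
#'   `w_y`, `w_xy`).
#' @param path Output path.
#' @param colmap An [sga_colmap()] giving the headers to write.
#' @return `path`, invisibly.
#' @export
write_sga <- function(records, path, colmap = sga_colmap()) {
  check_records(records)
  out <- tibble::tibble(
    a = paste0(records$query_gene, "_sn", seq_len(nrow(records))),
    b = paste0(records$array_gene, "_dma", seq_len(nrow(records))),
    c = records$w_x, d = records$w_y, e = records$w_xy
  )
  names(out) <- unlist(colmap)[c("query_id", "array_id", "query_smf",
                                 "array_smf", "double_fitness")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

new_preprocess_report <- function(read, dropped_deleterious,
                                  dropped_additive, retained) {
  stopifnot(read == dropped_deleterious + dropped_additive + retained)
  list(rows_in = read,
       dropped_fitness_gt1 = dropped_deleterious,
       dropped_additive_domain = dropped_additive,
       retained = retained)
}

#' Preprocessing filters for double-mutant records
#'
#' `filter_deleterious()` keeps only deleterious mutations: records where
#' either single-mutant fitness exceeds 1 are removed (boundary `w = 1` is
#' kept). Double-mutant fitnesses above 1 are retained by default, since the
#' filter's purpose is to restrict to deleterious *mutations*; set
#' `strict = TRUE` to drop `w_xy > 1` as well.
#'
#' `filter_additive_domain()` removes records where the Additive law would
#' predict a negative fitness, i.e. `w_x + w_y < 1` (strict inequality:
#' `w_x + w_y = 1`, prediction exactly 0, is retained), so that all laws are
#' compared on the same consistent dataset.
#'
#' `preprocess_sga()` applies both filters and attaches a reconciling
#' `preprocess_report` attribute (rows in = dropped by filter 1 + dropped by
#' filter 2 + retained). The two filters test independent predicates, so
#' they commute and are idempotent.
#'
#' @param records A record tibble.
#' @param strict Also drop records with `w_xy > 1`?
#' @return The filtered tibble; `preprocess_sga()` adds the
#'   `preprocess_report` attribute (see [preprocess_report()]).
#' @export
filter_deleterious <- function(records, strict = FALSE) {
  check_records(records, require_genes = FALSE)
  keep <- records$w_x <= 1 & records$w_y <= 1
  if (strict) keep <- keep & records$w_xy <= 1
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @rdname filter_deleterious
#' @export
filter_additive_domain <- function(records) {
  check_records(records, require_genes = FALSE)
  keep <- records$w_x + records$w_y >= 1
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @rdname filter_deleterious
#' @export
preprocess_sga <- function(records, strict = FALSE) {
  n0 <- nrow(records)
  step1 <- filter_deleterious(records, strict = strict)
  d1 <- attr(step1, "n_dropped")
  step2 <- filter_additive_domain(step1)
  d2 <- attr(step2, "n_dropped")
  attr(step2, "n_dropped") <- NULL
  attr(step2, "preprocess_report") <-
    new_preprocess_report(n0, d1, d2, nrow(step2))
  step2
}

#' Retrieve the preprocessing report attached by [preprocess_sga()]
#'
#' @param records A preprocessed record tibble.
#' @return A list with counts `rows_in`, `dropped_fitness_gt1`,
#'   `dropped_additive_domain`, `retained`.
#' @export
preprocess_report <- function(records) {
  rep <- attr(records, "preprocess_report")
  if (is.null(rep)) rlang::abort("no preprocess_report attribute; run preprocess_sga() first")
  rep
}

#' Subdataset selectors for the SGA screen design
#'
#' The SGA screen crosses two query sets (nonessential deletions plus
#' temperature-sensitive alleles, `"deletion_ts"`; or hypomorphic DAmP
#' alleles, `"damp"`) to two arrays (`"DMA"` deletion mutant array, `"TSA"`
#' temperature-sensitive array) at two temperatures (26 or 30 degrees C).
#' `sga_selector()` builds the canonical key used by [select_subdataset()];
#' the combination `("deletion_ts", "DMA", 30)` is the primary analysis
#' subdataset.
#'
#' @param query_set `"deletion_ts"` or `"damp"`.
#' @param array `"DMA"` or `"TSA"`.
#' @param temperature 26 or 30.
#' @return A single string key, e.g. `"deletion_ts.DMA.30"`.
#' @export
sga_selector <- function(query_set = c("deletion_ts", "damp"),
                         array = c("DMA", "TSA"),
                         temperature = c(30, 26)) {
  query_set <- rlang::arg_match(query_set)
  array <- rlang::arg_match(array)
  temperature <- as.integer(temperature[1])
  if (!temperature %in% c(26L, 30L)) {
    rlang::abort("`temperature` must be 26 or 30")
  }
  paste(query_set, array, temperature, sep = ".")
}

#' Select and preprocess one subdataset from a catalog
#'
#' A catalog maps selector keys (see [sga_selector()]) to file paths or
#' in-memory record tibbles, one per combination of query set, array and
#' temperature. The selected subdataset is read (if a path) and passed
#' through [preprocess_sga()].
#'
#' @param catalog Named list: selector key -> path or record tibble.
#' @param query_set,array,temperature Passed to [sga_selector()].
#' @param colmap Column map used when reading files.
#' @param strict Passed to [preprocess_sga()].
#' @return Preprocessed records with a `preprocess_report` attribute and a
#'   `subdataset_tag` column holding the selector key.
#' @export
select_subdataset <- function(catalog, query_set, array, temperature,
                              colmap = sga_colmap(), strict = FALSE) {
  key <- sga_selector(query_set, array, temperature)
  if (!key %in% names(catalog)) {
    rlang::abort(paste0(
      "subdataset '", key, "' not in catalog; available: ",
      paste(sort(names(catalog)), collapse = ", ")
    ))
  }
  entry <- catalog[[key]]
  records <- if (is.character(entry)) read_sga(entry, colmap) else entry
  out <- preprocess_sga(records, strict = strict)
  out$subdataset_tag <- key
  out
}
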