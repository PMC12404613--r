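#' Read gene -> biological-process annotations
#'
#' `read_annotation()` reads a plain two-column tab-separated file
#' (`gene<TAB>process_id`, one association per line, no header).
#' `read_gaf()` reads GAF 2.x association files, keeping biological-process
#' (`aspect == "P"`) rows; filtering by evidence code is off by default.
#' Genes may be associated with multiple processes.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene` and `process`, one row per
#'   association (duplicates removed).
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, col_names = c("gene", "process"),
                         col_types = "cc", progress = FALSE)
  dplyr::distinct(out)
}

#' @rdname read_annotation
#' @param evidence Optional character vector of evidence codes to keep
#'   (e.g. `c("EXP", "IDA")`); `NULL` keeps all.
#' @export
read_gaf <- function(path, evidence = NULL) {
  out <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(out) < 9) rlang::abort("not a GAF 2.x file: fewer than 9 columns")
  ann <- tibble::tibble(gene = out[[3]], process = out[[5]],
                        evidence = out[[7]], aspect = out[[9]])
  ann <- dplyr::filter(ann, .data$aspect == "P")
  if (!is.null(evidence)) {
    ann <- dplyr::filter(ann, .data$evidence %in% !!evidence)
  }
  dplyr::distinct(ann[c("gene", "process")])
}

#' Select biological processes well represented in a fitness dataset
#'
#' Keeps processes annotated to at least `min_count` genes among
#' `dataset_genes` (genes appearing as query or array in the fitness data;
#' roles are not distinguished).
#'
#' @param annotation A gene/process tibble from [read_annotation()].
#' @param dataset_genes Character vector of genes present in the fitness
#'   dataset.
#' @param min_count Minimum number of annotated dataset genes (default 50).
#' @return Character vector of process identifiers (sorted).
#' @export
select_processes <- function(annotation, dataset_genes, min_count = 50) {
  stopifnot(min_count >= 1)
  if (nrow(annotation) == 0) {
    rlang::warn("empty annotation: no processes selected")
    return(character(0))
  }
  counts <- annotation |>
    dplyr::filter(.data$gene %in% dataset_genes) |>
    dplyr::distinct(.data$gene, .data$process) |>
    dplyr::count(.data$process)
  sort(counts$process[counts$n >= min_count])
}

restricted_sets <- function(processes, annotation, dataset_genes) {
  ann <- annotation |>
    dplyr::filter(.data$process %in% processes,
                  .data$gene %in% dataset_genes)
  split(ann$gene, factor(ann$process, levels = processes))
}

#' Enumerate disjoint pairs of biological processes
#'
#' Forms all unordered pairs of distinct selected processes and keeps those
#' whose gene sets (restricted to `dataset_genes`) share no genes. Pairs
#' sharing at least one gene are discarded and counted in the
#' `n_shared_discarded` attribute.
#'
#' @inheritParams select_processes
#' @param processes Character vector from [select_processes()].
#' @return A tibble with columns `process_a`, `process_b`, `n_a`, `n_b`.
#' @export
enumerate_disjoint_pairs <- function(processes, annotation, dataset_genes) {
  processes <- sort(unique(processes))
  if (length(processes) < 2) {
    out <- tibble::tibble(process_a = character(), process_b = character(),
                          n_a = integer(), n_b = integer())
    attr(out, "n_shared_discarded") <- 0L
    return(out)
  }
  sets <- restricted_sets(processes, annotation, dataset_genes)
  idx <- utils::combn(length(processes), 2)
  disjoint <- vapply(seq_len(ncol(idx)), function(k) {
    length(intersect(sets[[idx[1, k]]], sets[[idx[2, k]]])) == 0
  }, TRUE)
  out <- tibble::tibble(
    process_a = processes[idx[1, disjoint]],
    process_b = processes[idx[2, disjoint]],
    n_a = lengths(sets)[idx[1, disjoint]],
    n_b = lengths(sets)[idx[2, disjoint]]
  )
  attr(out, "n_shared_discarded") <- sum(!disjoint)
  out
}

#' Binned residual profile for one pair of biological processes
#'
#' Restricts a residual table to records whose two genes fall one in each
#' process (either orientation) and returns the binned median/quartile
#' summary. A pair covering no records returns all-empty bins.
#'
#' @param residuals A [residual_table()] (typically for a single law).
#' @param annotation Gene/process tibble.
#' @param process_a,process_b Process identifiers.
#' @inheritParams bin_residuals
#' @return A [bin_residuals()] summary with columns `process_a`,
#'   `process_b` prepended.
#' @export
pair_residual_profile <- function(residuals, annotation, process_a,
                                  process_b, n_bins = 10, lo = 0.5,
                                  hi = 1.0) {
  genes <- unique(c(residuals$query_gene, residuals$array_gene))
  sets <- restricted_sets(c(process_a, process_b), annotation, genes)
  a <- sets[[1]]; b <- sets[[2]]
  hit <- (residuals$query_gene %in% a & residuals$array_gene %in% b) |
    (residuals$query_gene %in% b & residuals$array_gene %in% a)
  sub <- residuals[hit, , drop = FALSE]
  if (!any(hit)) {
    # all-empty bins, one set per law present in the input
    sub <- residuals[0, , drop = FALSE]
    sub <- tidyr::complete(sub, law = unique(residuals$law))
    sub$residual <- numeric(nrow(sub))
    sub$max_single <- rep(NA_real_, nrow(sub))
  }
  bins <- bin_residuals(sub, n_bins = n_bins, lo = lo, hi = hi)
  dplyr::bind_cols(tibble::tibble(process_a = process_a,
                                  process_b = process_b)[rep(1, nrow(bins)), ],
                   bins)
}

#' Per-pair residual profiles for many process pairs
#'
#' @param pairs A tibble from [enumerate_disjoint_pairs()].
#' @inheritParams pair_residual_profile
#' @return One [pair_residual_profile()] per pair, row-bound. Pairs `(A,B)`
#'   and `(B,A)` give identical profiles.
#' @export
pair_profiles <- function(pairs, residuals, annotation, n_bins = 10,
                          lo = 0.5, hi = 1.0) {
  purrr::pmap(
    list(pairs$process_a, pairs$process_b),
    function(a, b) pair_residual_profile(residuals, annotation, a, b,
                                         n_bins = n_bins, lo = lo, hi = hi)
  ) |>
    dplyr::bind_rows()
}

#' Tail fractions of residuals for intra- versus inter-process gene pairs
#'
#' Classifies each record as `intra` (the two genes share at least one of
#' the selected processes) or `inter` (both genes annotated, no shared
#' process) and reports, per law and class, the fraction of residuals above
#' `+threshold` and below `-threshold`. Large residuals of either sign are
#' expected to be more likely for intra-process pairs. Records with a gene
#' lacking any selected-process annotation are excluded and counted in the
#' `n_unannotated` attribute.
#'
#' @param residuals A [residual_table()].
#' @param annotation Gene/process tibble.
#' @param threshold Positive residual magnitude defining the tails.
#' @param processes Optional subset of processes defining the comparison;
#'   default: all processes in `annotation`.
#' @return A tibble with columns `law`, `class`, `n`, `frac_above`,
#'   `frac_below`.
#' @export
intra_vs_inter_tails <- function(residuals, annotation, threshold,
                                 processes = NULL) {
  stopifnot(threshold > 0)
  if (is.null(processes)) processes <- unique(annotation$process)
  ann <- annotation[annotation$process %in% processes, ]
  procs_of <- split(ann$process, ann$gene)
  pq <- procs_of[residuals$query_gene]
  pa <- procs_of[residuals$array_gene]
  annotated <- !vapply(pq, is.null, TRUE) & !vapply(pa, is.null, TRUE)
  shared <- mapply(function(a, b) length(intersect(a, b)) > 0, pq, pa)
  dat <- residuals[annotated, , drop = FALSE]
  dat$class <- ifelse(shared[annotated], "intra", "inter")
  out <- dat |>
    dplyr::group_by(.data$law, .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_above = mean(.data$residual > threshold),
      frac_below = mean(.data$residual < -threshold),
      .groups = "drop"
    )
  attr(out, "n_unannotated") <- sum(!annotated) / max(1, length(unique(residuals$law)))
  attr(out, "threshold") <- threshold
  out
}
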