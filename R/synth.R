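#' Configuration for the synthetic double-mutant data generator
#'
#' The generator emulates the statistical structure of SGA-style screens:
#' single-mutant fitnesses on (0, 1], double-mutant fitnesses produced by a
#' known ground-truth neutrality law plus measurement noise, and multi-process
#' gene annotations with controllable overlap. It exists to make every
#' pipeline stage testable without downloads, with known ground truth.
#'
#' The default single-mutant fitness distribution is a piecewise-uniform
#' mixture (blocks `[0.44, 0.58)`, `[0.58, 0.80)`, `[0.80, 0.97)`,
#' `[0.97, 1]` with weights 0.55, 0.28, 0.15, 0.02). These blocks were
#' chosen so that, after the standard preprocessing filters, the ten
#' maximum-single-mutant-fitness bins on `[0.5, 1]` are all well populated
#' (roughly 4,000 records per bin at 50,000 pairs) — the generator's job is
#' statistical power across the whole binning range, not demographic realism.
#' A fitness distribution piled up near 1 (the shape of real screens) is
#' available as `fitness_dist = list(family = "beta", shape1 = 8,
#' shape2 = 2, point_mass = 0.25)`.
#'
#' @param n_genes Number of genes in the pool.
#' @param n_pairs Number of double-mutant records (distinct gene pairs;
#'   must not exceed `choose(n_genes, 2)`).
#' @param law Ground-truth neutrality law (one of [neutrality_laws()]).
#' @param noise_sd Standard deviation of the measurement noise on `w_xy`
#'   (truncated below at 0).
#' @param noise `"additive"` (default) or `"multiplicative"`
#'   (`w_xy = law * (1 + eps)`).
#' @param fitness_dist Single-mutant fitness distribution: either
#'   `list(family = "piecewise", breaks =, weights =)` or
#'   `list(family = "beta", shape1 =, shape2 =, point_mass =)` where
#'   `point_mass` is the probability of drawing a fitness of exactly 1.
#' @param n_processes,genes_per_process,overlap_fraction Annotation layout
#'   for [generate_annotations()]: number of processes, genes per process,
#'   and the fraction of each process's genes drawn from a common shared
#'   pool (0 = all processes disjoint, 1 = all processes identical).
#' @param sigma_intra Optional noise standard deviation used instead of
#'   `noise_sd` for records whose two genes share a process (requires an
#'   annotation; see [generate_fitness_table()]).
#' @param seed Optional integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000, n_pairs = 50000, law = "product",
                         noise_sd = 0.05,
                         noise = c("additive", "multiplicative"),
                         fitness_dist = list(
                           family = "piecewise",
                           breaks = c(0.44, 0.58, 0.80, 0.97, 1),
                           weights = c(0.55, 0.28, 0.15, 0.02)
                         ),
                         n_processes = 6, genes_per_process = 60,
                         overlap_fraction = 0, sigma_intra = NULL,
                         seed = NULL) {
  law <- match.arg(law, neutrality_laws())
  noise <- rlang::arg_match(noise)
  stopifnot(noise_sd >= 0, n_genes >= 2,
            n_pairs >= 1, n_pairs <= choose(n_genes, 2),
            overlap_fraction >= 0, overlap_fraction <= 1,
            n_processes >= 1, genes_per_process >= 1)
  if (!is.null(sigma_intra)) stopifnot(sigma_intra >= 0)
  if (identical(fitness_dist$family, "piecewise")) {
    stopifnot(length(fitness_dist$breaks) == length(fitness_dist$weights) + 1,
              abs(sum(fitness_dist$weights) - 1) < 1e-8,
              !is.unsorted(fitness_dist$breaks))
  }
  structure(
    list(n_genes = n_genes, n_pairs = n_pairs, law = law,
         noise_sd = noise_sd, noise = noise, fitness_dist = fitness_dist,
         n_processes = n_processes, genes_per_process = genes_per_process,
         overlap_fraction = overlap_fraction, sigma_intra = sigma_intra,
         seed = seed),
    class = "synth_config"
  )
}

draw_single_fitness <- function(n, dist) {
  switch(dist$family,
    piecewise = {
      k <- sample.int(length(dist$weights), n, replace = TRUE,
                      prob = dist$weights)
      stats::runif(n, dist$breaks[k], dist$breaks[k + 1])
    },
    beta = {
      w <- stats::rbeta(n, dist$shape1, dist$shape2)
      pm <- dist$point_mass %||% 0
      if (pm > 0) w[stats::runif(n) < pm] <- 1
      # fitnesses live on (0, 1]: beta draws of exactly 0 are bumped
      pmax(w, .Machine$double.eps)
    },
    rlang::abort(paste0("unknown fitness_dist family: ", dist$family))
  )
}

#' Generate a synthetic double-mutant fitness table with known ground truth
#'
#' Each gene receives one single-mutant fitness drawn i.i.d. from the
#' configured distribution; `n_pairs` distinct gene pairs are sampled and
#' the double-mutant fitness is the ground-truth law prediction plus noise,
#' truncated below at 0. With an annotation and `sigma_intra` set, records
#' whose genes share a process are given noise `sigma_intra` instead of
#' `noise_sd`, and the true intra/inter classification is recorded in the
#' `intra` column.
#'
#' Generation is byte-reproducible under a fixed `config$seed`.
#'
#' @param config A [synth_config()].
#' @param annotation Optional annotation from [generate_annotations()].
#' @return A record tibble (`query_gene`, `array_gene`, `w_x`, `w_y`,
#'   `w_xy`, `subdataset_tag`, and `intra` if an annotation was given) with
#'   attribute `true_law`.
#' @export
generate_fitness_table <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "synth_config"))
  run <- function() {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    wg <- stats::setNames(draw_single_fitness(config$n_genes,
                                              config$fitness_dist), genes)
    # sample distinct unordered gene pairs without replacement
    total <- choose(config$n_genes, 2)
    pick <- sample(total, config$n_pairs)
    j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)  # row index in upper triangle
    i <- pick - (j - 1) * (j - 2) / 2
    qg <- genes[i]; ag <- genes[j]
    w_x <- unname(wg[qg]); w_y <- unname(wg[ag])
    pred <- predict_fitness(w_x, w_y, config$law, on_divergence = "na")
    sd_rec <- rep(config$noise_sd, config$n_pairs)
    intra <- NULL
    if (!is.null(annotation)) {
      procs_of <- split(annotation$process, annotation$gene)
      pq <- procs_of[qg]; pa <- procs_of[ag]
      both <- !vapply(pq, is.null, TRUE) & !vapply(pa, is.null, TRUE)
      shared <- mapply(function(a, b) length(intersect(a, b)) > 0, pq, pa)
      intra <- ifelse(both, shared, NA)
      if (!is.null(config$sigma_intra)) {
        sd_rec[!is.na(intra) & intra] <- config$sigma_intra
      }
    }
    eps <- stats::rnorm(config$n_pairs, 0, sd_rec)
    w_xy <- if (config$noise == "additive") pred + eps else pred * (1 + eps)
    out <- tibble::tibble(
      query_gene = qg, array_gene = ag,
      w_x = w_x, w_y = w_y,
      w_xy = pmax(w_xy, 0),
      subdataset_tag = "synthetic"
    )
    if (!is.null(intra)) out$intra <- intra
    attr(out, "true_law") <- config$law
    out
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' Generate synthetic gene -> process annotations with known overlap
#'
#' Builds `n_processes` processes of `genes_per_process` genes each. A
#' fraction `overlap_fraction` of every process's genes is drawn from a
#' shared pool common to all processes (so `overlap_fraction = 0` gives
#' pairwise-disjoint processes and `overlap_fraction = 1` makes all process
#' pairs share genes); the rest are exclusive to the process. Gene names
#' match [generate_fitness_table()] for the same config.
#'
#' @param config A [synth_config()].
#' @return An annotation tibble (`gene`, `process`).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  run <- function() {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    gpp <- config$genes_per_process
    k <- round(config$overlap_fraction * gpp)
    needed <- k + config$n_processes * (gpp - k)
    if (needed > config$n_genes) {
      rlang::abort(paste0("annotation layout needs ", needed,
                          " genes but n_genes = ", config$n_genes))
    }
    shared <- genes[seq_len(max(k, 0))]
    rest <- if (k > 0) genes[-seq_len(k)] else genes
    rows <- purrr::map(seq_len(config$n_processes), function(p) {
      own <- rest[(p - 1) * (gpp - k) + seq_len(gpp - k)]
      tibble::tibble(gene = c(if (k > 0) shared[seq_len(k)], own),
                     process = sprintf("P%03d", p))
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' Write a synthetic annotation in the two-column TSV dialect
#'
#' @param annotation A tibble from [generate_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[c("gene", "process")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
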