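#' Run the empirical double-mutant analysis end to end
#'
#' Orchestrates: input (an SGA-dialect file, an in-memory record table, or
#' the synthetic generator), preprocessing filters, residuals under the
#' requested laws, binned summaries, and (optionally) the biological-process
#' pair analysis. All outputs are plain CSV/JSON; a manifest records the
#' package version, the configuration hash and the seeds, so a rerun with
#' the same manifest is byte-identical.
#'
#' @param config A list with elements:
#'   * one of `sga_path` (+ optional `colmap`), `records`, or `synth`
#'     (a [synth_config()]);
#'   * `laws` (default all four), `n_bins`, `lo`, `hi`;
#'   * optional `annotation_path` or `annotation` plus `go` = list with
#'     `min_count` (default 50) and `tail_threshold` (default 0.1) to run
#'     the process-pair stage;
#'   * optional `strict` for the preprocessing filters.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `records`, `fit`, `bins`, and (if run)
#'   `pairs`, `profiles`, `tails`; files are written under `outdir`.
#' @export
run_empirical <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, msg) {
    rlang::abort(paste0("[", stage, "] ", msg))
  }
  laws <- config[["laws"]] %||% neutrality_laws()
  n_bins <- config[["n_bins"]] %||% 10
  lo <- config[["lo"]] %||% 0.5
  hi <- config[["hi"]] %||% 1.0

  # --- input stage ---
  records <- if (!is.null(config[["records"]])) {
    dplyr::as_tibble(config[["records"]])
  } else if (!is.null(config[["sga_path"]])) {
    if (!file.exists(config[["sga_path"]])) {
      fail("input", paste0("SGA file not found: ", config[["sga_path"]]))
    }
    read_sga(config[["sga_path"]], config[["colmap"]] %||% sga_colmap())
  } else if (!is.null(config[["synth"]])) {
    generate_fitness_table(config[["synth"]])
  } else {
    fail("input", "config must provide one of records, sga_path, synth")
  }

  # --- preprocessing stage ---
  records <- preprocess_sga(records, strict = isTRUE(config[["strict"]]))
  report <- preprocess_report(records)

  # --- residual + binning stage ---
  fit <- fit_neutrality(records, laws = laws, n_bins = n_bins,
                        lo = lo, hi = hi)
  readr::write_csv(fit$residuals, file.path(outdir, "residuals.csv"),
                   progress = FALSE)
  readr::write_csv(fit$bins, file.path(outdir, "bins.csv"), progress = FALSE)
  readr::write_csv(records, file.path(outdir, "records.csv"),
                   progress = FALSE)
  jsonlite::write_json(report, file.path(outdir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)

  out <- list(records = records, fit = fit, bins = fit$bins, report = report)

  # --- optional biological-process stage ---
  go_cfg <- config[["go"]]
  annotation <- NULL
  if (!is.null(config[["annotation"]])) {
    annotation <- dplyr::as_tibble(config[["annotation"]])
  } else if (!is.null(config[["annotation_path"]])) {
    if (!file.exists(config[["annotation_path"]])) {
      fail("go_pairs", paste0("annotation file not found: ",
                              config[["annotation_path"]]))
    }
    annotation <- read_annotation(config[["annotation_path"]])
  } else if (!is.null(go_cfg)) {
    fail("go_pairs", "GO stage enabled but no annotation or annotation_path given")
  }
  if (!is.null(annotation)) {
    min_count <- (go_cfg[["min_count"]]) %||% 50
    thr <- (go_cfg[["tail_threshold"]]) %||% 0.1
    genes <- unique(c(records$query_gene, records$array_gene))
    procs <- select_processes(annotation, genes, min_count = min_count)
    pairs <- enumerate_disjoint_pairs(procs, annotation, genes)
    profiles <- pair_profiles(pairs, fit$residuals, annotation,
                              n_bins = n_bins, lo = lo, hi = hi)
    tails <- intra_vs_inter_tails(fit$residuals, annotation, threshold = thr,
                                  processes = procs)
    readr::write_csv(profiles, file.path(outdir, "go_pair_profiles.csv"),
                     progress = FALSE)
    readr::write_csv(tails, file.path(outdir, "go_tail_fractions.csv"),
                     progress = FALSE)
    out$pairs <- pairs; out$profiles <- profiles; out$tails <- tails
  }

  manifest <- list(
    package = "epineutral",
    version = as.character(utils::packageVersion("epineutral")),
    stage = "empirical",
    config_hash = rlang::hash(config),
    seed = config[["synth"]]$seed,
    laws = laws,
    n_records = nrow(records),
    preprocess = report
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Run the mechanistic growth-model analyses end to end
#'
#' Orchestrates the two-sector model scan (with the closed-form exactness
#' check recorded in the manifest), the whole-cell model pairwise deviation
#' matrix, and the gamma sweep. Every random draw flows through the seeds
#' in `config`; outputs are CSV plus a JSON manifest.
#'
#' @param config A list with elements (all optional):
#'   * `sh` = list(`n`, `seed`, `params`): two-sector scan settings;
#'   * `weisse` = list(`n`, `seed`, `params`, `mutable`): pairwise scan, or
#'     `NULL` to skip;
#'   * `gamma` = list(`values`, `n`, `seed`, `pair`): gamma sweep, or
#'     `NULL` to skip.
#' @param outdir Output directory.
#' @return Invisibly, a list with `sh_scan`, `sh_bins`, and (if run)
#'   `deviation_matrix`, `gamma_sweep`, plus the `manifest`.
#' @export
run_models <- function(config = list(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sh_cfg <- config[["sh"]] %||% list()
  sh_n <- sh_cfg[["n"]] %||% 10000
  sh_seed <- sh_cfg[["seed"]] %||% 1
  sh_par <- sh_cfg[["params"]] %||% sh_params()

  scan <- sh_sample_double_mutants(sh_par, n = sh_n, seed = sh_seed)
  closed_form_max_error <- max(abs(scan$w_xy_model - scan$w_xy_closed_form))
  long <- scan |>
    tidyr::pivot_longer(dplyr::all_of(c("w_xy_product", "w_xy_additive",
                                        "w_xy_minimum", "w_xy_closed_form")),
                        names_to = "law", names_prefix = "w_xy_",
                        values_to = "predicted") |>
    dplyr::mutate(law = sub("^closed_form$", "scott_hwa", .data$law),
                  residual = .data$w_xy_model - .data$predicted,
                  max_single = pmax(.data$w_x, .data$w_y))
  sh_bins <- bin_residuals(long)
  readr::write_csv(scan, file.path(outdir, "scott_hwa_scan.csv"),
                   progress = FALSE)
  readr::write_csv(sh_bins, file.path(outdir, "scott_hwa_bins.csv"),
                   progress = FALSE)
  out <- list(sh_scan = scan, sh_bins = sh_bins)

  manifest <- list(
    package = "epineutral",
    version = as.character(utils::packageVersion("epineutral")),
    stage = "models",
    config_hash = rlang::hash(config),
    seeds = list(sh = sh_seed),
    closed_form_max_error = closed_form_max_error
  )

  if (!is.null(config[["weisse"]])) {
    wz <- config[["weisse"]]
    mat <- weisse_scan_all(wz[["params"]] %||% weisse_params(),
                           n = wz[["n"]] %||% 200, seed = wz[["seed"]] %||% 1,
                           mutable = wz[["mutable"]] %||% weisse_mutable_params())
    readr::write_csv(mat, file.path(outdir, "weisse_deviation_matrix.csv"),
                     progress = FALSE)
    out$deviation_matrix <- mat
    manifest$seeds$weisse <- wz[["seed"]] %||% 1
  }
  if (!is.null(config[["gamma"]])) {
    gz <- config[["gamma"]]
    sweep <- weisse_gamma_sweep(gz[["params"]] %||% weisse_params(),
                                gamma_values = gz[["values"]],
                                pair = gz[["pair"]] %||% c("v_t", "n_s"),
                                n = gz[["n"]] %||% 500, seed = gz[["seed"]] %||% 1)
    ord <- order(sweep$gamma, decreasing = TRUE)
    manifest$gamma_monotone_improvement <-
      !is.unsorted(rev(sweep$median_abs_residual_product[ord]))
    readr::write_csv(sweep, file.path(outdir, "gamma_sweep.csv"),
                     progress = FALSE)
    out$gamma_sweep <- sweep
    manifest$seeds$gamma <- gz[["seed"]] %||% 1
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
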