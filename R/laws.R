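#' Neutrality functions for double-mutant fitness
#'
#' A neutrality function predicts the fitness of a double mutant from the
#' fitnesses of the two single mutants under the assumption that the two
#' mutations do not interact. Four laws are implemented:
#'
#' * `product`: \eqn{W_{xy} = W_x W_y} — a mutation's absolute effect scales
#'   with the fitness of the background strain (diminishing returns).
#' * `additive`: \eqn{W_{xy} = W_x + W_y - 1} — fitness *defects* add, so a
#'   mutation's absolute effect is background-independent.
#' * `minimum`: \eqn{W_{xy} = \min(W_x, W_y)} — the more deleterious mutation
#'   is rate limiting and the milder one has no further effect.
#' * `scott_hwa`: \eqn{W_{xy} = 1/(1/W_x + 1/W_y - 1)} — the exact
#'   double-mutant fitness of the two-sector proteome-allocation growth model
#'   with growth-optimizing feedback (see [sh_closed_form()]); equals the
#'   Product law with a perturbation and diverges as
#'   \eqn{1/W_x + 1/W_y \to 1} for beneficial mutations.
#'
#' @return `neutrality_laws()` returns the names of the four supported laws.
#' @export
neutrality_laws <- function() {
  c("product", "additive", "minimum", "scott_hwa")
}

#' Predict double-mutant fitness under a neutrality function
#'
#' Vectorised over `w_x` and `w_y`. All laws satisfy the neutral-partner
#' identity `predict_fitness(1, w, law) == w`.
#'
#' @param w_x,w_y Single-mutant relative fitnesses (wild type = 1). Must be
#'   finite and non-negative.
#' @param law One of [neutrality_laws()].
#' @param on_divergence How to handle `scott_hwa` inputs whose denominator
#'   `1/w_x + 1/w_y - 1` is not positive (only possible for beneficial
#'   fitnesses, e.g. `w_x = w_y = 2`): `"error"` (default) or `"na"`.
#' @return Numeric vector of predicted double-mutant fitnesses. Predictions
#'   are not renormalised: the additive law can return negative values when
#'   `w_x + w_y < 1` (see [filter_additive_domain()]).
#' @examples
#' predict_fitness(0.9, 0.8, "product")   # 0.72
#' predict_fitness(0.9, 0.8, "additive")  # 0.70
#' predict_fitness(0.9, 0.8, "minimum")   # 0.80
#' predict_fitness(0.9, 0.8, "scott_hwa") # 0.72/0.98
#' @export
predict_fitness <- function(w_x, w_y, law = neutrality_laws(),
                            on_divergence = c("error", "na")) {
  law <- rlang::arg_match(law)
  on_divergence <- rlang::arg_match(on_divergence)
  if (!is.numeric(w_x) || !is.numeric(w_y)) {
    rlang::abort("`w_x` and `w_y` must be numeric fitness values.")
  }
  bad <- !is.na(w_x) & !is.na(w_y) & (!is.finite(w_x) | !is.finite(w_y) |
                                        w_x < 0 | w_y < 0)
  if (any(bad)) {
    rlang::abort("fitness values must be finite and >= 0")
  }
  switch(law,
    product = w_x * w_y,
    additive = w_x + w_y - 1,
    minimum = pmin(w_x, w_y),
    scott_hwa = {
      denom <- 1 / w_x + 1 / w_y - 1
      div <- !is.na(denom) & denom <= 0
      if (any(div)) {
        if (on_divergence == "error") {
          rlang::abort(paste0(
            "scott_hwa neutrality function diverges for ", sum(div),
            " input pair(s): 1/w_x + 1/w_y - 1 <= 0 ",
            "(possible only for beneficial mutations)."
          ))
        }
        denom[div] <- NA_real_
      }
      1 / denom
    }
  )
}

#' Validate a table of double-mutant records
#'
#' @param records Data frame with numeric columns `w_x`, `w_y`, `w_xy` and
#'   (unless `require_genes = FALSE`) identifier columns `query_gene`,
#'   `array_gene`.
#' @keywords internal
#' @noRd
check_records <- function(records, require_genes = TRUE) {
  needed <- c(if (require_genes) c("query_gene", "array_gene"),
              "w_x", "w_y", "w_xy")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    rlang::abort(paste0("`records` is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (col in c("w_x", "w_y", "w_xy")) {
    v <- records[[col]]
    if (!is.numeric(v)) rlang::abort(paste0("column `", col, "` must be numeric"))
    if (any(!is.na(v) & (v < 0 | !is.finite(v)))) {
      rlang::abort(paste0("column `", col, "` must be finite and >= 0"))
    }
  }
  invisible(records)
}

#' Residuals of observed double-mutant fitness against neutrality functions
#'
#' Computes, for each record and each requested law, the predicted
#' double-mutant fitness and the residual `w_xy - predicted`
#' (observed minus predicted). A law that predicts fitnesses that are too
#' high therefore yields negative residuals. The maximum single-mutant
#' fitness `max(w_x, w_y)` is carried along as the severity axis used by
#' [bin_residuals()].
#'
#' Records for which the `scott_hwa` law diverges are excluded from that
#' law's rows, with the count reported via a message and stored in the
#' `n_divergent` attribute.
#'
#' @param records Data frame of double-mutant records with columns
#'   `query_gene`, `array_gene`, `w_x`, `w_y`, `w_xy`.
#' @param laws Character vector of laws (default: all four).
#' @return A tibble with one row per record x law and columns `query_gene`,
#'   `array_gene`, `w_x`, `w_y`, `w_xy`, `law`, `predicted`, `residual`,
#'   `max_single`.
#' @export
residual_table <- function(records, laws = neutrality_laws()) {
  laws <- match.arg(laws, neutrality_laws(), several.ok = TRUE)
  check_records(records)
  records <- dplyr::as_tibble(records)
  n_div <- integer(0)
  out <- purrr::map(laws, function(law) {
    pred <- predict_fitness(records$w_x, records$w_y, law, on_divergence = "na")
    tab <- dplyr::mutate(
      records,
      law = law,
      predicted = pred,
      residual = .data$w_xy - pred,
      max_single = pmax(.data$w_x, .data$w_y)
    )
    dropped <- sum(is.na(pred) & !is.na(records$w_x) & !is.na(records$w_y))
    if (dropped > 0) {
      rlang::inform(paste0(dropped, " record(s) excluded for law '", law,
                           "' (divergent prediction)."))
    }
    n_div[law] <<- dropped
    dplyr::filter(tab, !is.na(.data$predicted))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_divergent") <- n_div
  out
}

#' Binned median/quartile summary of residuals
#'
#' Bins residuals by the maximum single-mutant fitness into `n_bins`
#' equal-width bins on `[lo, hi]`. Bins are half-open `[lo, hi)` except the
#' last, which is closed so that `max_single = hi` is included. Records with
#' `max_single` outside `[lo, hi]` are excluded. Quartiles use linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param residuals A residual table from [residual_table()] (or any data
#'   frame with columns `law`, `residual`, `max_single`).
#' @param n_bins Number of bins (default 10).
#' @param lo,hi Bin range on the maximum single-mutant fitness axis
#'   (defaults 0.5 and 1).
#' @return A tibble of class `binned_residuals` with one row per law x bin:
#'   `law`, `bin`, `bin_lo`, `bin_hi`, `bin_mid`, `n`, `median`, `q25`,
#'   `q75`. Empty bins are reported with `n = 0` and `NA` statistics.
#' @export
bin_residuals <- function(residuals, n_bins = 10, lo = 0.5, hi = 1.0) {
  stopifnot(n_bins >= 1, lo < hi)
  if (!all(c("law", "residual", "max_single") %in% names(residuals))) {
    rlang::abort("`residuals` must have columns law, residual, max_single")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  dat <- dplyr::filter(residuals,
                       .data$max_single >= lo, .data$max_single <= hi)
  idx <- pmin(findInterval(dat$max_single, edges), n_bins)  # last bin closed
  dat$bin <- idx
  summ <- dat |>
    dplyr::group_by(.data$law, .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$residual),
      q25 = stats::quantile(.data$residual, 0.25, names = FALSE),
      q75 = stats::quantile(.data$residual, 0.75, names = FALSE),
      .groups = "drop"
    )
  full <- tidyr::expand_grid(law = unique(residuals$law), bin = seq_len(n_bins))
  out <- full |>
    dplyr::left_join(summ, by = c("law", "bin")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      bin_lo = edges[.data$bin],
      bin_hi = edges[.data$bin + 1],
      bin_mid = (.data$bin_lo + .data$bin_hi) / 2
    ) |>
    dplyr::select("law", "bin", "bin_lo", "bin_hi", "bin_mid",
                  "n", "median", "q25", "q75")
  class(out) <- c("binned_residuals", class(out))
  attr(out, "edges") <- edges
  out
}

#' Look up the bin containing a given maximum single-mutant fitness
#'
#' @param bins A [bin_residuals()] summary.
#' @param value A fitness value on the binning axis, e.g. `0.72`.
#' @return The rows of `bins` (one per law) whose bin contains `value`.
#' @export
bin_at <- function(bins, value) {
  dplyr::filter(bins, .data$bin_lo <= value,
                value < .data$bin_hi | (.data$bin_hi == max(.data$bin_hi) &
                                          value <= .data$bin_hi))
}

#' Fit and compare neutrality functions on double-mutant data
#'
#' Computes residuals for each law, bins them by maximum single-mutant
#' fitness, and summarises each law's fit. The headline statistic is the
#' mean absolute binned median (`mean_abs_bin_median`): an unbiased law has
#' bin medians near zero across the whole severity range.
#'
#' @inheritParams residual_table
#' @inheritParams bin_residuals
#' @return An object of class `neutrality_fit` with components `residuals`,
#'   `bins` and `stats`. Use [generics::tidy()] for per-law statistics,
#'   [generics::glance()] for the best-fitting law, and
#'   [ggplot2::autoplot()] for the binned-median figure.
#' @examples
#' cfg <- synth_config(n_genes = 120, n_pairs = 600, seed = 1)
#' fit <- fit_neutrality(generate_fitness_table(cfg))
#' glance(fit)$best_law
#' @export
fit_neutrality <- function(records, laws = neutrality_laws(), n_bins = 10,
                           lo = 0.5, hi = 1.0) {
  resid <- residual_table(records, laws)
  bins <- bin_residuals(resid, n_bins = n_bins, lo = lo, hi = hi)
  stats <- bins |>
    dplyr::filter(.data$n > 0) |>
    dplyr::group_by(.data$law) |>
    dplyr::summarise(
      n_bins_used = dplyr::n(),
      mean_abs_bin_median = mean(abs(.data$median)),
      max_abs_bin_median = max(abs(.data$median)),
      .groups = "drop"
    )
  overall <- resid |>
    dplyr::group_by(.data$law) |>
    dplyr::summarise(n = dplyr::n(),
                     median_residual = stats::median(.data$residual),
                     rmse = sqrt(mean(.data$residual^2)),
                     .groups = "drop")
  stats <- dplyr::left_join(overall, stats, by = "law")
  structure(
    list(residuals = resid, bins = bins, stats = stats,
         n_records = nrow(records), n_bins = n_bins, lo = lo, hi = hi),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("<neutrality_fit> ", x$n_records, " records, ",
      length(unique(x$stats$law)), " laws, ", x$n_bins,
      " bins on [", x$lo, ", ", x$hi, "]\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_neutrality
#' @param x A `neutrality_fit` object.
#' @param ... Unused.
#' @export
tidy.neutrality_fit <- function(x, ...) {
  x$stats
}

#' @rdname fit_neutrality
#' @export
glance.neutrality_fit <- function(x, ...) {
  best <- x$stats$law[which.min(x$stats$mean_abs_bin_median)]
  tibble::tibble(
    best_law = best,
    n_records = x$n_records,
    n_laws = nrow(x$stats),
    n_bins = x$n_bins
  )
}
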