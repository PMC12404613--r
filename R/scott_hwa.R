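#' Parameters of the two-sector proteome-allocation growth model
#'
#' The model partitions the proteome into a translational sector (fraction
#' `phi_t`, flux `kappa_t * phi_t`), a metabolic sector (`phi_n`, flux
#' `kappa_n * phi_n`) and a fixed housekeeping sector `phi_o`, with
#' `phi_t + phi_n + phi_o = 1`. At the growth optimum no protein is wasted,
#' so the two fluxes are equal and both equal the growth rate.
#'
#' Because fitness is a ratio of growth rates, the wild-type numeric values
#' of `kappa_t` and `kappa_n` cancel; only the mutational scale factors
#' matter. The defaults `kappa_t = kappa_n = 1` are therefore a neutral
#' choice of units.
#'
#' @param kappa_t Translational efficiency (1/time), > 0.
#' @param kappa_n Metabolic efficiency (1/time), > 0.
#' @param phi_o Housekeeping proteome fraction, in `[0, 1)`.
#' @return A list of class `sh_params`.
#' @export
sh_params <- function(kappa_t = 1, kappa_n = 1, phi_o = 0) {
  if (kappa_t <= 0 || kappa_n <= 0) {
    rlang::abort("kappa_t and kappa_n must be positive")
  }
  if (phi_o < 0 || phi_o >= 1) rlang::abort("phi_o must be in [0, 1)")
  structure(list(kappa_t = kappa_t, kappa_n = kappa_n, phi_o = phi_o),
            class = "sh_params")
}

#' Optimal growth rate of the two-sector model
#'
#' Under growth-maximising allocation the fluxes balance and
#' \eqn{\lambda = (1 - \phi_o) / (1/\kappa_t + 1/\kappa_n)}. The optimal
#' allocation is `phi_t = lambda / kappa_t`, `phi_n = lambda / kappa_n`.
#'
#' @param params An [sh_params()] object.
#' @return A list with `lambda`, `phi_t`, `phi_n`.
#' @examples
#' sh_growth(sh_params(kappa_t = 2, kappa_n = 2))$lambda  # 1
#' @export
sh_growth <- function(params) {
  stopifnot(inherits(params, "sh_params"))
  lambda <- (1 - params$phi_o) / (1 / params$kappa_t + 1 / params$kappa_n)
  list(lambda = lambda, phi_t = lambda / params$kappa_t,
       phi_n = lambda / params$kappa_n)
}

#' Numerically optimised growth rate of the two-sector model
#'
#' Maximises `min(kappa_t * phi_t, kappa_n * phi_n)` over the allocation
#' `phi_t` in `[0, 1 - phi_o]`, independently of the closed-form solution.
#' The objective is a tent function (increasing while the translational
#' flux is limiting, decreasing once the metabolic flux is), so the
#' maximiser is located by bisection on which flux is limiting, to
#' essentially machine precision. Used as the model route in mutational
#' scans so the closed form can be checked against an independent
#' optimiser.
#'
#' @inheritParams sh_growth
#' @param iter Number of bisection steps (54 halvings reach double
#'   precision on the unit interval).
#' @return The maximal growth rate (numeric scalar).
#' @export
sh_growth_numeric <- function(params, iter = 60) {
  stopifnot(inherits(params, "sh_params"))
  budget <- 1 - params$phi_o
  lo <- 0
  hi <- budget
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (params$kappa_t * mid < params$kappa_n * (budget - mid)) {
      lo <- mid   # translational flux limiting: objective still increasing
    } else {
      hi <- mid
    }
  }
  phi_t <- (lo + hi) / 2
  min(params$kappa_t * phi_t, params$kappa_n * (budget - phi_t))
}

#' Closed-form double-mutant fitness of the two-sector model
#'
#' For one mutation scaling `kappa_t` and one scaling `kappa_n`, the
#' double-mutant fitness of the growth-optimising model is exactly
#' \deqn{W_{xy} = \frac{1}{1/W_x + 1/W_y - 1}
#'             = \frac{W_x W_y}{W_x + W_y - W_x W_y},}
#' the Product law divided by a perturbation factor. The expression diverges
#' when the denominator reaches zero, which can happen only for beneficial
#' mutations (at equal fitnesses, exactly at `w_x = w_y = 2`); see
#' [sh_divergence_point()].
#'
#' @param w_x,w_y Single-mutant fitnesses.
#' @param on_divergence `"error"` or `"na"` for denominator <= 0.
#' @return Predicted double-mutant fitness.
#' @export
sh_closed_form <- function(w_x, w_y, on_divergence = c("error", "na")) {
  predict_fitness(w_x, w_y, "scott_hwa", on_divergence = on_divergence)
}

#' Divergence point of the closed form at equal single-mutant fitness
#'
#' Solves `1/w + 1/w - 1 = 0` for `w > 1` numerically: the equal
#' single-mutant fitness at which the closed-form double-mutant fitness of
#' the two-sector model diverges.
#'
#' @param interval Search interval (must bracket the root).
#' @return The divergence fitness (2 for equal fitnesses).
#' @export
sh_divergence_point <- function(interval = c(1 + 1e-9, 1e6)) {
  stats::uniroot(function(w) 2 / w - 1, interval, tol = 1e-12)$root
}

#' Growth rate with the proteome allocation frozen at the wild-type optimum
#'
#' If the growth-optimising feedback is absent, the allocation stays at the
#' wild-type optimum while the efficiencies mutate, and the growth rate is
#' the limiting flux `min(kappa_t * phi_t, kappa_n * phi_n)`. In this
#' regime the double-mutant fitness follows the Minimum neutrality function
#' exactly.
#'
#' @param params An [sh_params()] with (possibly mutated) efficiencies.
#' @param wt_allocation A list or vector with `phi_t` and `phi_n`: the
#'   optimal allocation of the unmutated parameters (from [sh_growth()]).
#' @return The growth rate under the frozen allocation.
#' @export
sh_no_feedback_growth <- function(params, wt_allocation) {
  stopifnot(inherits(params, "sh_params"))
  min(params$kappa_t * wt_allocation$phi_t,
      params$kappa_n * wt_allocation$phi_n)
}

#' Sample double mutants of the two-sector model
#'
#' Mutations multiply one efficiency by a scale factor theta: deleterious
#' mutations draw `theta ~ U(0, 1)` (open at 0, so zero growth is excluded)
#' and beneficial mutations `theta ~ U(1, theta_max)`. The two mutations of
#' a double mutant always target different parameters (one `kappa_t`, one
#' `kappa_n`); mutations hitting the same parameter are expected to
#' interact and are out of scope. The model fitness `w_xy_model` is
#' computed by numerical optimisation of the allocation
#' ([sh_growth_numeric()]), independently of the closed form.
#'
#' @param params Wild-type [sh_params()].
#' @param n Number of double mutants.
#' @param regime `"deleterious"` or `"beneficial"`.
#' @param theta_max Upper bound of the beneficial scale factor (default 2).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A tibble with columns `theta_x`, `theta_y`, `w_x`, `w_y`,
#'   `w_xy_model`, `w_xy_product`, `w_xy_additive`, `w_xy_minimum`,
#'   `w_xy_closed_form`. In the beneficial regime the closed form is `NA`
#'   where it diverges.
#' @export
sh_sample_double_mutants <- function(params = sh_params(), n = 1000,
                                     regime = c("deleterious", "beneficial"),
                                     theta_max = 2, seed = NULL) {
  regime <- rlang::arg_match(regime)
  stopifnot(n >= 1)
  draw <- function() {
    if (regime == "deleterious") stats::runif(n) else stats::runif(n, 1, theta_max)
  }
  sample_fun <- function() {
    theta_x <- draw(); theta_y <- draw()
    lam_wt <- sh_growth_numeric(params)
    w_of <- function(kt, kn) {
      sh_growth_numeric(sh_params(kt, kn, params$phi_o)) / lam_wt
    }
    w_x <- vapply(theta_x, function(t) w_of(params$kappa_t * t, params$kappa_n), 0)
    w_y <- vapply(theta_y, function(t) w_of(params$kappa_t, params$kappa_n * t), 0)
    w_xy <- vapply(seq_len(n), function(i) {
      w_of(params$kappa_t * theta_x[i], params$kappa_n * theta_y[i])
    }, 0)
    tibble::tibble(
      theta_x = theta_x, theta_y = theta_y, w_x = w_x, w_y = w_y,
      w_xy_model = w_xy,
      w_xy_product = w_x * w_y,
      w_xy_additive = w_x + w_y - 1,
      w_xy_minimum = pmin(w_x, w_y),
      w_xy_closed_form = sh_closed_form(w_x, w_y, on_divergence = "na")
    )
  }
  if (is.null(seed)) sample_fun() else withr::with_seed(seed, sample_fun())
}

#' Exact multiplicativity of housekeeping-sector mutations
#'
#' A mutation scaling the housekeeping fraction `phi_o` changes the growth
#' rate only through the prefactor `(1 - phi_o)`, so combined with a
#' mutation to either efficiency the two fitness effects multiply exactly:
#' `w_xy = w_x * w_y`.
#'
#' @param params Wild-type [sh_params()] (needs `phi_o > 0` for a
#'   non-trivial `phi_o` mutation).
#' @param theta_phi Scale factor applied to `phi_o`.
#' @param theta_kappa Scale factor applied to the chosen efficiency.
#' @param target `"kappa_t"` or `"kappa_n"`.
#' @return A list with `w_x` (the `phi_o` mutant), `w_y` (the efficiency
#'   mutant) and `w_xy` (the double mutant).
#' @export
sh_phi_o_multiplicativity <- function(params, theta_phi, theta_kappa,
                                      target = c("kappa_t", "kappa_n")) {
  target <- rlang::arg_match(target)
  new_phi <- params$phi_o * theta_phi
  if (new_phi < 0 || new_phi >= 1) rlang::abort("mutated phi_o must stay in [0, 1)")
  lam <- function(p) sh_growth(p)$lambda
  lam_wt <- lam(params)
  p_phi <- sh_params(params$kappa_t, params$kappa_n, new_phi)
  p_kap <- params
  p_kap[[target]] <- p_kap[[target]] * theta_kappa
  p_kap <- sh_params(p_kap$kappa_t, p_kap$kappa_n, p_kap$phi_o)
  p_both <- sh_params(p_kap$kappa_t, p_kap$kappa_n, new_phi)
  list(w_x = lam(p_phi) / lam_wt,
       w_y = lam(p_kap) / lam_wt,
       w_xy = lam(p_both) / lam_wt)
}
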