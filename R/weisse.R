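#' @useDynLib epineutral, .registration = TRUE
NULL

.weisse_pnames <- c("s_ext", "v_t", "K_t", "v_m", "K_m", "n_s", "w_r", "w_e",
                    "w_q", "theta_x", "theta_r", "K_q", "h_q", "k_b", "k_u",
                    "d_m", "g_max", "K_p", "M", "n_r", "n_x")

.weisse_snames <- c("s_i", "a", "r", "m_r", "m_t", "m_m", "m_q",
                    "c_r", "c_t", "c_m", "c_q", "p_t", "p_m", "p_q")

#' Parameters of the coarse-grained whole-cell growth model
#'
#' The model tracks an internal nutrient, a cellular "energy", free
#' ribosomes, and — for each of four protein classes (ribosomal `r`,
#' transporter `t`, metabolic enzyme `m`, housekeeping `q`) — free mRNA,
#' ribosome-mRNA complexes, and protein. External nutrient is imported by
#' transporters and metabolised to energy by enzymes (both Michaelis-Menten);
#' energy activates transcription (threshold `theta_r` for the ribosomal
#' class, `theta_x` for the others, with autoinhibition of the housekeeping
#' class) and sets the translation
#' elongation rate `g(a) = g_max * a / (K_p + a)`; mRNAs compete for free
#' ribosomes by mass action (`k_b`, `k_u`); the growth (dilution) rate is
#' the total translation flux over the cell mass,
#' `lambda = g(a) * sum(complexes) / M`.
#'
#' Wild-type values are read from the packaged YAML asset
#' (`system.file("extdata", "weisse_params.yaml", package = "epineutral")`)
#' and can be overridden by name.
#'
#' @param ... Named overrides, e.g. `weisse_params(theta_x = 100)`.
#' @param file Alternative YAML parameter file.
#' @return A named numeric vector of class `weisse_params`.
#' @export
weisse_params <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "weisse_params.yaml", package = "epineutral")
  }
  raw <- yaml::read_yaml(file)$params
  p <- vapply(.weisse_pnames, function(nm) as.numeric(raw[[nm]]), 0)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .weisse_pnames)
    if (length(bad)) {
      rlang::abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    p[names(over)] <- as.numeric(unlist(over))
  }
  if (any(p <= 0)) rlang::abort("all parameters must be positive")
  if (p[["h_q"]] < 1) rlang::abort("h_q must be >= 1")
  structure(p, class = "weisse_params")
}

#' Time derivatives of the whole-cell growth model
#'
#' Evaluates the right-hand side of the 14-dimensional ODE system at one
#' state (compiled implementation).
#'
#' @param state Named numeric vector of length 14 in the order
#'   `s_i, a, r, m_r, m_t, m_m, m_q, c_r, c_t, c_m, c_q, p_t, p_m, p_q`
#'   (see [weisse_init_state()]); all components must be non-negative.
#' @param params A [weisse_params()] vector.
#' @return A list with `dstate` (named derivatives) and `lambda` (the
#'   instantaneous growth rate).
#' @export
weisse_derivatives <- function(state, params) {
  state <- as.numeric(state)
  if (length(state) != 14) rlang::abort("state must have length 14")
  if (any(state < 0)) rlang::abort("state components must be non-negative")
  dy <- .Call(C_weisse_rhs, state, as.numeric(params))
  lambda <- attr(dy, "lambda")
  attributes(dy) <- NULL
  names(dy) <- .weisse_snames
  list(dstate = dy, lambda = lambda)
}

#' Standard non-zero seed state for steady-state integration
#'
#' @return A named state vector: a small inoculum with a few ribosomes,
#'   trace mRNA/complexes and some nutrient and energy, from which the
#'   model bootstraps to balanced growth.
#' @export
weisse_init_state <- function() {
  stats::setNames(c(10, 10, 10, rep(1, 8), 10, 10, 10), .weisse_snames)
}

.weisse_lambda <- function(state, params) {
  params <- as.numeric(params)
  a <- state[2]
  gam <- params[17] * a / (params[18] + a)  # g_max, K_p
  gam * sum(state[8:11]) / params[19]       # M
}

# deSolve-facing RHS wrapper
.weisse_rhs_ode <- function(t, y, parms) {
  list(.Call(C_weisse_rhs, y, parms))
}

# Damped Newton iteration on the per-capita residuals g(u) = f(exp(u))/exp(u)
# in log-state u. Returns the best iterate; `ok` when max |g| < tol.
.weisse_newton <- function(u, parms, tol = 1e-10, maxit = 60) {
  parms <- as.numeric(parms)
  best <- list(u = u, resid = Inf)
  g <- NULL
  for (it in seq_len(maxit)) {
    st <- .Call(C_weisse_newton_step, u, parms, 1e-7)
    g <- st[[1]]
    r0 <- max(abs(g))
    if (r0 < best$resid) best <- list(u = u, resid = r0)
    if (r0 < tol) break
    du <- tryCatch(solve(st[[2]], -g), error = function(e) NULL)
    if (is.null(du)) break
    du <- pmin(pmax(du, -4), 4)  # cap log-space step
    step <- 1
    n0 <- sum(g^2)
    accepted <- FALSE
    while (step > 1e-8) {
      un <- u + step * du
      yn <- exp(un)
      gn <- .Call(C_weisse_rhs, yn, parms) / yn
      if (all(is.finite(gn)) && sum(gn^2) < n0) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    u <- un
  }
  list(u = best$u, resid = best$resid, ok = best$resid < tol * 100)
}

.weisse_integrate <- function(parms, y0, tmax, rtol = 1e-10, atol = 1e-10) {
  # lsoda emits step-budget warnings on the hardest mutants; the ladder in
  # weisse_steady_state() handles those cases, so keep the console clean
  out <- suppressWarnings(
    deSolve::ode(as.numeric(y0), c(0, 0.9 * tmax, tmax), .weisse_rhs_ode,
                 as.numeric(parms), method = "lsoda",
                 rtol = rtol, atol = atol, maxsteps = 5e5)
  )
  y1 <- as.numeric(out[nrow(out) - 1, 2:15])
  y2 <- as.numeric(out[nrow(out), 2:15])
  lam1 <- .weisse_lambda(y1, parms)
  lam2 <- .weisse_lambda(y2, parms)
  drift <- abs(lam2 - lam1) / max(lam2, .Machine$double.xmin)
  list(state = y2, lambda = lam2, drift = drift)
}

#' Steady-state growth rate of the whole-cell model
#'
#' Two routes to the balanced-growth steady state:
#'
#' * `"integrate"`: stiff integration (lsoda) from `init` until the relative
#'   change of the growth rate over the last 10% of the horizon falls below
#'   `lambda_tol`, doubling the horizon on failure (at most `max_doublings`
#'   times).
#' * `"root"`: damped Newton iteration on the per-capita steady-state
#'   residuals in log-state space, seeded with the integrated state (or with
#'   `init` when it is already a steady-state guess), with an integration
#'   fallback ladder for hard cases.
#'
#' The two routes agree to well below `1e-6` relative growth rate and serve
#' as mutual checks.
#'
#' @param params A [weisse_params()] vector.
#' @param solver `"root"` (default; fast, suited to scans) or
#'   `"integrate"`.
#' @param init Optional state vector or log-state warm start (a previous
#'   steady state); defaults to [weisse_init_state()].
#' @param lambda_tol Convergence tolerance on the relative growth-rate
#'   drift for the integration route.
#' @param tmax Initial integration horizon (minutes).
#' @param max_doublings Maximum number of horizon doublings.
#' @return A list with `lambda`, `state` (named), `solver`, `converged`,
#'   and `resid` (root route: max per-capita residual; integrate route:
#'   relative lambda drift).
#' @export
weisse_steady_state <- function(params, solver = c("root", "integrate"),
                                init = NULL, lambda_tol = 1e-8,
                                tmax = 1e5, max_doublings = 3) {
  solver <- rlang::arg_match(solver)
  parms <- as.numeric(params)
  y0 <- if (is.null(init)) weisse_init_state() else as.numeric(init)
  if (solver == "integrate") {
    horizon <- tmax
    y <- y0
    for (k in 0:max_doublings) {
      res <- .weisse_integrate(parms, y, horizon)
      y <- res$state
      if (res$drift < lambda_tol) {
        return(list(lambda = res$lambda,
                    state = stats::setNames(res$state, .weisse_snames),
                    solver = "integrate", converged = TRUE,
                    resid = res$drift))
      }
      horizon <- horizon * 2
    }
    rlang::abort(paste0(
      "steady-state integration did not converge: relative lambda drift ",
      format(res$drift, digits = 3), " after horizon ", format(horizon / 2),
      " min (lambda ", format(res$lambda, digits = 6), ")"
    ))
  }
  # root route: Newton from the warm start, then an integrate+Newton ladder
  # (warm start first, then a cold start from the standard seed state)
  u0 <- log(pmax(y0, 1e-12))
  ns <- .weisse_newton(u0, parms)
  if (!ns$ok) {
    starts <- list(pmax(y0, 1e-12), pmax(weisse_init_state(), 1e-12))
    for (y in starts) {
      horizon <- tmax
      for (k in 0:(max_doublings + 2)) {
        ig <- tryCatch(.weisse_integrate(parms, y, horizon),
                       error = function(e) NULL)
        if (!is.null(ig)) {
          y <- pmax(ig$state, 1e-300)
          ns2 <- .weisse_newton(log(y), parms)
          if (ns2$resid < ns$resid) ns <- ns2
          if (ns$ok) break
          # accept a drift-converged integration even if Newton stalls
          if (ig$drift < lambda_tol) {
            return(list(lambda = ig$lambda,
                        state = stats::setNames(ig$state, .weisse_snames),
                        solver = "root", converged = TRUE, resid = ig$drift))
          }
        }
        horizon <- horizon * 4
      }
      if (ns$ok) break
    }
  }
  # a near-converged best iterate (per-capita residual below 1e-6/min,
  # i.e. growth-rate accuracy well under the dual-solver tolerance) is
  # accepted rather than discarded
  if (!ns$ok && ns$resid > 1e-6) {
    rlang::abort(paste0(
      "steady-state root solve did not converge: residual ",
      format(ns$resid, digits = 3)
    ))
  }
  state <- exp(ns$u)
  list(lambda = .weisse_lambda(state, parms),
       state = stats::setNames(state, .weisse_snames),
       solver = "root", converged = TRUE, resid = ns$resid)
}

#' @rdname weisse_steady_state
#' @param ... Passed to [weisse_steady_state()].
#' @return `weisse_growth_rate()` returns the growth rate only.
#' @export
weisse_growth_rate <- function(params, ...) {
  weisse_steady_state(params, ...)$lambda
}

#' The mutable parameters of the whole-cell model and their processes
#'
#' Nine parameters can plausibly be hit by a gene perturbation that impairs
#' growth. Each has a biological-process label (mutations within the same
#' process are expected to interact and are excluded from cross-process
#' scans) and a deleterious direction: rates and efficiencies shrink
#' (multiplied by `theta < 1`), while Michaelis constants and the
#' housekeeping transcription rate grow (divided by `theta`), so every
#' sampled mutation is growth-non-increasing. (Growing `w_q` models a
#' misregulation burden: wasteful housekeeping overexpression that drains
#' ribosomes and energy. The ribosomal transcription rate `w_r` is not
#' mutable: at the wild-type parameterisation the model is over-invested in
#' ribosomal mRNA relative to the growth optimum, so reducing `w_r` would
#' *increase* growth.)
#'
#' The default grouping treats nutrient import and catabolism as one
#' metabolic process (`v_t`, `K_t`, `v_m`, `K_m` form a serial pathway
#' whose mutations are strongly interdependent), the nutrient energy yield
#' `n_s` as its own process, and transcription (`w_e`, `w_q`) and
#' translation (`g_max`, `K_p`) as one process each. This yields 28
#' cross-process pairs. The `"sector"` grouping separates transport
#' (`v_t`, `K_t`) from metabolism (`v_m`, `K_m`, `n_s`), giving 30 pairs.
#'
#' @param grouping `"pathway"` (default, 28 cross-process pairs) or
#'   `"sector"` (30 pairs).
#' @return A tibble with columns `param`, `process`, `direction`.
#' @export
weisse_mutable_params <- function(grouping = c("pathway", "sector")) {
  grouping <- rlang::arg_match(grouping)
  params <- c("v_t", "K_t", "v_m", "K_m", "n_s", "w_e", "w_q", "g_max", "K_p")
  process <- switch(grouping,
    pathway = c("metabolism", "metabolism", "metabolism", "metabolism",
                "nutrient_quality", "transcription", "transcription",
                "translation", "translation"),
    sector = c("transport", "transport", "metabolism", "metabolism",
               "metabolism", "transcription", "transcription",
               "translation", "translation")
  )
  tibble::tibble(
    param = params,
    process = process,
    direction = ifelse(params %in% c("K_t", "K_m", "K_p", "w_q"),
                       "grow", "shrink")
  )
}

#' Apply a mutation to a model parameter
#'
#' Deleterious mutations rescale a parameter by `theta` in `(0, 1]`:
#' shrink-direction parameters are multiplied by `theta`, grow-direction
#' parameters (Michaelis constants, for which smaller is better) are divided
#' by `theta`.
#'
#' @param params A [weisse_params()] vector.
#' @param target Name of a mutable parameter (see
#'   [weisse_mutable_params()]).
#' @param theta Scale factor in `(0, 1]`.
#' @return The mutated parameter vector.
#' @export
weisse_mutate <- function(params, target, theta) {
  mutable <- weisse_mutable_params()
  if (!target %in% mutable$param) {
    rlang::abort(paste0("unknown mutable parameter '", target,
                        "'; choose one of: ",
                        paste(mutable$param, collapse = ", ")))
  }
  if (theta <= 0 || theta > 1) rlang::abort("theta must be in (0, 1]")
  dir <- mutable$direction[mutable$param == target]
  params[[target]] <- if (dir == "grow") params[[target]] / theta
                      else params[[target]] * theta
  params
}

# Solve a batch of parameter sets with warm-start continuation: sets are
# visited from mildest to most severe and each solve starts from the
# previous solution.
.weisse_solve_batch <- function(param_list, severity, u_warm) {
  ord <- order(severity, decreasing = TRUE)  # mildest (theta near 1) first
  lam <- numeric(length(param_list))
  u <- u_warm
  for (i in ord) {
    ss <- weisse_steady_state(param_list[[i]], solver = "root",
                              init = exp(u))
    lam[i] <- ss$lambda
    u <- log(pmax(ss$state, 1e-300))
  }
  lam
}

#' Pairwise mutational scan of the whole-cell model
#'
#' Samples `n` double mutants for a pair of mutable parameters from two
#' different biological processes: independent scale factors
#' `theta ~ U(0, 1)` per parameter, single- and double-mutant steady states
#' solved by warm-started Newton continuation, fitnesses relative to the
#' wild-type growth rate. Mutants whose growth rate exceeds the wild type
#' by more than the solver accuracy (relative 1e-6) are discarded and
#' counted; fitnesses within that tolerance of 1 are clamped to 1. Per-law
#' deviations are reported against the Product, Additive, Minimum and
#' closed-form two-sector (`scott_hwa`) predictions.
#'
#' @param params Wild-type [weisse_params()].
#' @param pair Character vector of two mutable parameter names.
#' @param n Number of sampled double mutants.
#' @param seed Optional integer seed.
#' @param mutable Mutable-parameter table (controls the process grouping).
#' @return An object of class `weisse_pair_scan`: a tibble with columns
#'   `theta_x`, `theta_y`, `w_x`, `w_y`, `w_xy` and attributes
#'   `deviations` (per-law mean absolute and signed deviation),
#'   `n_discarded_beneficial`, `pair`, `lambda_wt`.
#' @export
weisse_pair_scan <- function(params = weisse_params(), pair, n = 200,
                             seed = NULL,
                             mutable = weisse_mutable_params()) {
  stopifnot(length(pair) == 2, n >= 1)
  proc <- mutable$process[match(pair, mutable$param)]
  if (anyNA(proc)) {
    rlang::abort(paste0("pair must name mutable parameters; got: ",
                        paste(pair, collapse = ", ")))
  }
  if (proc[1] == proc[2]) {
    rlang::abort(paste0(
      "parameters ", pair[1], " and ", pair[2],
      " belong to the same biological process ('", proc[1],
      "'); same-process pairs are expected to interact and are excluded"
    ))
  }
  run <- function() {
    wt <- weisse_steady_state(params, solver = "root")
    u_wt <- log(pmax(wt$state, 1e-300))
    theta_x <- stats::runif(n)
    theta_y <- stats::runif(n)
    px <- lapply(theta_x, function(t) weisse_mutate(params, pair[1], t))
    py <- lapply(theta_y, function(t) weisse_mutate(params, pair[2], t))
    pxy <- lapply(seq_len(n), function(i)
      weisse_mutate(px[[i]], pair[2], theta_y[i]))
    w_x <- .weisse_solve_batch(px, theta_x, u_wt) / wt$lambda
    w_y <- .weisse_solve_batch(py, theta_y, u_wt) / wt$lambda
    w_xy <- .weisse_solve_batch(pxy, theta_x * theta_y, u_wt) / wt$lambda
    tab <- tibble::tibble(theta_x = theta_x, theta_y = theta_y,
                          w_x = w_x, w_y = w_y, w_xy = w_xy)
    beneficial <- tab$w_x > 1 + 1e-6 | tab$w_y > 1 + 1e-6 |
      tab$w_xy > 1 + 1e-6
    tab <- tab[!beneficial, , drop = FALSE]
    # fitnesses equal to 1 within solver accuracy are clamped to 1
    tab$w_x <- pmin(tab$w_x, 1)
    tab$w_y <- pmin(tab$w_y, 1)
    tab$w_xy <- pmin(tab$w_xy, 1)
    pred <- list(
      product = tab$w_x * tab$w_y,
      additive = tab$w_x + tab$w_y - 1,
      minimum = pmin(tab$w_x, tab$w_y),
      scott_hwa = sh_closed_form(tab$w_x, tab$w_y, on_divergence = "na")
    )
    devs <- purrr::imap(pred, function(p, nm) {
      tibble::tibble(law = nm,
                     mean_abs_deviation = mean(abs(tab$w_xy - p)),
                     mean_deviation = mean(tab$w_xy - p))
    }) |> dplyr::bind_rows()
    structure(tab, class = c("weisse_pair_scan", class(tab)),
              deviations = devs,
              n_discarded_beneficial = sum(beneficial),
              pair = pair, lambda_wt = wt$lambda)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Mean deviation of a pair scan from each neutrality function
#'
#' @param scan A [weisse_pair_scan()] result.
#' @return The per-law deviation tibble stored with the scan.
#' @export
scan_deviations <- function(scan) {
  attr(scan, "deviations")
}

#' Scan all cross-process parameter pairs
#'
#' Runs [weisse_pair_scan()] for every unordered pair of mutable parameters
#' belonging to different biological processes and collects the per-law
#' mean absolute (and signed) deviations — the deviation matrix behind the
#' pair-by-law heatmaps.
#'
#' @inheritParams weisse_pair_scan
#' @param seed Integer seed; each pair uses a sub-seed derived from it.
#' @return A tibble of class `weisse_scan_matrix` with one row per pair x
#'   law: `param_a`, `param_b`, `process_a`, `process_b`,
#'   `involves_translation`, `law`, `mean_abs_deviation`, `mean_deviation`,
#'   `n_used`.
#' @export
weisse_scan_all <- function(params = weisse_params(), n = 200, seed = 1,
                            mutable = weisse_mutable_params()) {
  idx <- utils::combn(nrow(mutable), 2)
  cross <- mutable$process[idx[1, ]] != mutable$process[idx[2, ]]
  idx <- idx[, cross, drop = FALSE]
  rows <- purrr::map(seq_len(ncol(idx)), function(k) {
    a <- mutable$param[idx[1, k]]
    b <- mutable$param[idx[2, k]]
    scan <- weisse_pair_scan(params, c(a, b), n = n,
                             seed = seed * 1000L + k, mutable = mutable)
    dev <- scan_deviations(scan)
    dplyr::mutate(
      dev,
      param_a = a, param_b = b,
      process_a = mutable$process[idx[1, k]],
      process_b = mutable$process[idx[2, k]],
      involves_translation = "translation" %in%
        mutable$process[c(idx[1, k], idx[2, k])],
      n_used = nrow(scan),
      .before = 1
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weisse_scan_matrix", class(out))
  out
}

#' Sweep of the transcription saturation parameter gamma
#'
#' gamma is the inverse of the transcription energy threshold `theta_x`.
#' When gamma is small, transcription responds linearly to the available
#' energy and the Product neutrality function becomes a near-exact
#' description of double-mutant fitness; when gamma is large, transcription
#' saturates and deviations appear. For each gamma the wild-type growth
#' rate is recomputed (so fitnesses are relative to the matched wild type)
#' and the same mutational scan is repeated with common random scale
#' factors across gamma values, removing Monte-Carlo noise from the
#' comparison.
#'
#' @inheritParams weisse_pair_scan
#' @param gamma_values Positive gamma values (any order; reported as given).
#' @param pair Parameter pair to scan (default `c("v_t", "n_s")`).
#' @return A tibble with one row per gamma: `gamma`, `theta_x`,
#'   `lambda_wt`, `median_abs_residual_product`, `mean_abs_deviation_product`,
#'   `n_used`.
#' @export
weisse_gamma_sweep <- function(params = weisse_params(), gamma_values,
                               pair = c("v_t", "n_s"), n = 500, seed = 1) {
  stopifnot(all(gamma_values > 0), n >= 1)
  draws <- withr::with_seed(seed, list(theta_x = stats::runif(n),
                                       theta_y = stats::runif(n)))
  rows <- purrr::map(gamma_values, function(g) {
    pg <- params
    pg[["theta_x"]] <- 1 / g
    wt <- weisse_steady_state(pg, solver = "root")
    u_wt <- log(pmax(wt$state, 1e-300))
    px <- lapply(draws$theta_x, function(t) weisse_mutate(pg, pair[1], t))
    py <- lapply(draws$theta_y, function(t) weisse_mutate(pg, pair[2], t))
    pxy <- lapply(seq_len(n), function(i)
      weisse_mutate(px[[i]], pair[2], draws$theta_y[i]))
    w_x <- .weisse_solve_batch(px, draws$theta_x, u_wt) / wt$lambda
    w_y <- .weisse_solve_batch(py, draws$theta_y, u_wt) / wt$lambda
    w_xy <- .weisse_solve_batch(pxy, draws$theta_x * draws$theta_y,
                                u_wt) / wt$lambda
    ok <- w_x <= 1 + 1e-6 & w_y <= 1 + 1e-6 & w_xy <= 1 + 1e-6
    resid <- pmin(w_xy[ok], 1) - pmin(w_x[ok], 1) * pmin(w_y[ok], 1)
    tibble::tibble(
      gamma = g, theta_x = 1 / g, lambda_wt = wt$lambda,
      median_abs_residual_product = stats::median(abs(resid)),
      mean_abs_deviation_product = mean(abs(resid)),
      n_used = sum(ok)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weisse_gamma_sweep", class(out))
  out
}
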