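test_that("derivatives obey basic scaling and degenerate-state behaviour", {
  p <- weisse_params()
  # no mRNA and no complexes: nothing translates, lambda = 0
  st0 <- weisse_init_state()
  st0[4:11] <- 0
  d0 <- weisse_derivatives(st0, p)
  expect_equal(d0$lambda, 0)
  expect_equal(unname(d0$dstate[c("p_t", "p_m", "p_q")]), c(0, 0, 0))
  # lambda is inversely proportional to cell mass at fixed state
  st <- weisse_wt_cache()$state
  l1 <- weisse_derivatives(st, p)$lambda
  l2 <- weisse_derivatives(st, weisse_params(M = 2e8))$lambda
  expect_equal(l1 / l2, 2, tolerance = 1e-12)
  expect_error(weisse_derivatives(st[-1], p), "length 14")
  expect_error(weisse_derivatives(replace(st, 1, -1), p), "non-negative")
})

test_that("energy and species fluxes balance at steady state", {
  p <- weisse_params()
  ss <- weisse_wt_cache()
  st <- ss$state
  d <- weisse_derivatives(st, p)
  # all per-capita rates vanish to solver tolerance
  expect_lt(max(abs(d$dstate / pmax(st, 1e-12))), 1e-8)
  # energy balance: production = translation consumption + dilution
  production <- p[["n_s"]] * st[["p_m"]] * p[["v_m"]] *
    st[["s_i"]] / (p[["K_m"]] + st[["s_i"]])
  gam <- p[["g_max"]] * st[["a"]] / (p[["K_p"]] + st[["a"]])
  consumption <- gam * sum(st[c("c_r", "c_t", "c_m", "c_q")])
  dilution <- d$lambda * st[["a"]]
  expect_equal(production, consumption + dilution,
               tolerance = 1e-8)
})

test_that("integration and root solving agree on random deleterious draws", {
  p0 <- weisse_params()
  wt <- weisse_wt_cache()
  mutable <- weisse_mutable_params()
  draws <- withr::with_seed(2024, {
    data.frame(param = sample(mutable$param, 20, replace = TRUE),
               theta = stats::runif(20, 0.05, 1))
  })
  for (i in seq_len(nrow(draws))) {
    pm <- weisse_mutate(p0, draws$param[i], draws$theta[i])
    root <- weisse_steady_state(pm, "root", init = wt$state)
    intg <- weisse_steady_state(pm, "integrate")
    expect_lt(abs(root$lambda - intg$lambda) / root$lambda, 1e-6)
  }
})

test_that("wild-type scan row is neutral and v_t mutations are deleterious", {
  p <- weisse_params()
  wt <- weisse_wt_cache()
  same <- weisse_steady_state(weisse_mutate(p, "v_t", 1), "root",
                              init = wt$state)
  expect_equal(same$lambda / wt$lambda, 1, tolerance = 1e-8)
  half <- weisse_steady_state(weisse_mutate(p, "v_t", 0.5), "root",
                              init = wt$state)
  expect_lt(half$lambda, wt$lambda)
})

test_that("mutations move every mutable parameter in its deleterious direction", {
  p <- weisse_params()
  expect_equal(weisse_mutate(p, "v_t", 0.5)[["v_t"]], p[["v_t"]] / 2)
  # Michaelis constants and the housekeeping transcription rate grow
  expect_equal(weisse_mutate(p, "K_p", 0.5)[["K_p"]], p[["K_p"]] * 2)
  expect_equal(weisse_mutate(p, "w_q", 0.5)[["w_q"]], p[["w_q"]] * 2)
  expect_error(weisse_mutate(p, "nope", 0.5), "mutable")
  expect_error(weisse_mutate(p, "v_t", 1.5), "theta")
  # K_p's grow direction is deleterious: growth decreases
  wt <- weisse_wt_cache()
  kp <- weisse_steady_state(weisse_mutate(p, "K_p", 0.2), "root",
                            init = wt$state)
  expect_lt(kp$lambda, wt$lambda)
})

test_that("pair scans reject same-process pairs and are reproducible", {
  expect_error(weisse_pair_scan(pair = c("g_max", "K_p"), n = 5),
               "same biological process")
  expect_error(weisse_pair_scan(pair = c("v_t", "K_m"), n = 5),
               "same biological process")
  s1 <- weisse_pair_scan(pair = c("v_m", "w_e"), n = 12, seed = 4)
  s2 <- weisse_pair_scan(pair = c("v_m", "w_e"), n = 12, seed = 4)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # fitness bounds: deleterious scans stay in (0, 1]
  expect_true(all(s1$w_x > 0 & s1$w_x <= 1))
  expect_true(all(s1$w_xy > 0 & s1$w_xy <= 1))
  devs <- scan_deviations(s1)
  expect_setequal(devs$law, neutrality_laws())
})

test_that("the mutable-set groupings expose 28 and 30 cross-process pairs", {
  count_pairs <- function(mutable) {
    idx <- utils::combn(nrow(mutable), 2)
    sum(mutable$process[idx[1, ]] != mutable$process[idx[2, ]])
  }
  expect_equal(count_pairs(weisse_mutable_params("pathway")), 28)
  expect_equal(count_pairs(weisse_mutable_params("sector")), 30)
  expect_equal(nrow(weisse_mutable_params()), 9)
})

test_that("a single-value gamma sweep returns one matched-wild-type row", {
  gs <- weisse_gamma_sweep(gamma_values = 0.05, pair = c("v_t", "n_s"),
                           n = 8, seed = 6)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$theta_x, 20)
  expect_gt(gs$lambda_wt, 0)
  expect_true(gs$n_used <= 8 && gs$n_used > 0)
})
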