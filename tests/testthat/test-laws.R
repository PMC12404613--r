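test_that("the four laws give the documented predictions on worked examples", {
  cases <- list(
    list(law = "product", w = c(0.9, 0.8), expect = 0.72),
    list(law = "additive", w = c(0.9, 0.8), expect = 0.70),
    list(law = "minimum", w = c(0.9, 0.8), expect = 0.80),
    list(law = "scott_hwa", w = c(0.9, 0.8), expect = 0.72 / 0.98),
    # scott_hwa at half/half equals the numerical optimum of the two-sector
    # model with both efficiencies halved (checked independently below)
    list(law = "scott_hwa", w = c(0.5, 0.5), expect = 1 / 3)
  )
  for (cs in cases) {
    expect_equal(predict_fitness(cs$w[1], cs$w[2], cs$law), cs$expect,
                 tolerance = 1e-12)
  }
  # independent oracle for scott_hwa(0.5, 0.5): the efficiency scale factor
  # giving a single-mutant fitness of 0.5 is theta = 1/3; numerically
  # re-optimise the allocation with both efficiencies so scaled
  lam_wt <- sh_growth_numeric(sh_params(1, 1))
  th <- stats::uniroot(function(t) {
    sh_growth_numeric(sh_params(t, 1)) / lam_wt - 0.5
  }, c(1e-6, 1), tol = 1e-14)$root
  lam_mut <- sh_growth_numeric(sh_params(th, th))
  expect_equal(predict_fitness(0.5, 0.5, "scott_hwa"), lam_mut / lam_wt,
               tolerance = 1e-9)
})

test_that("neutral-partner identity holds exactly for every law", {
  w <- seq(0.05, 1, by = 0.05)
  for (law in neutrality_laws()) {
    expect_equal(predict_fitness(rep(1, length(w)), w, law), w,
                 info = law)
    expect_equal(predict_fitness(w, rep(1, length(w)), law), w,
                 info = law)
  }
})

test_that("scott_hwa divergence and invalid inputs are rejected", {
  expect_error(predict_fitness(2, 2, "scott_hwa"), "diverge")
  expect_true(is.na(predict_fitness(2, 2, "scott_hwa", on_divergence = "na")))
  # beneficial but non-divergent inputs are computed
  expect_equal(predict_fitness(1.5, 1.5, "scott_hwa"), 3, tolerance = 1e-12)
  expect_error(predict_fitness(-0.1, 0.5, "product"), "finite")
  expect_error(predict_fitness(Inf, 0.5, "minimum"), "finite")
})

test_that("ordering and power-transform invariants hold on a grid", {
  g <- seq(0.01, 0.99, length.out = 60)
  grid <- expand.grid(w_x = g, w_y = g)
  add <- predict_fitness(grid$w_x, grid$w_y, "additive")
  prod <- predict_fitness(grid$w_x, grid$w_y, "product")
  sh <- predict_fitness(grid$w_x, grid$w_y, "scott_hwa")
  mn <- predict_fitness(grid$w_x, grid$w_y, "minimum")
  expect_true(all(add <= prod + 1e-12))
  expect_true(all(prod <= sh + 1e-12))
  expect_true(all(sh <= mn + 1e-12))
  # the product law commutes with power transforms (colony <-> liquid
  # fitness rescaling): (w_x w_y)^p = w_x^p w_y^p, checked at p = 1/2
  expect_equal(sqrt(prod),
               predict_fitness(sqrt(grid$w_x), sqrt(grid$w_y), "product"),
               tolerance = 1e-12)
})

test_that("residual_table uses the observed-minus-predicted convention", {
  rt <- residual_table(toy_records(), laws = c("product", "minimum"))
  expect_equal(nrow(rt), 6)
  r1 <- rt[rt$law == "product" & rt$query_gene == "GA", ]
  expect_equal(r1$residual, 0.70 - 0.72, tolerance = 1e-12)
  expect_equal(r1$max_single, 0.9)
  # a neutral co-mutation (w_x = 1) has zero residual under any law
  r2 <- rt[rt$query_gene == "GB", ]
  expect_equal(r2$residual, rep(0, 2), tolerance = 1e-12)
  r3 <- rt[rt$law == "minimum" & rt$query_gene == "GA", ]
  expect_equal(r3$residual, -0.10, tolerance = 1e-12)
})

test_that("divergent records are excluded from residuals with a count", {
  recs <- tibble::tibble(
    query_gene = c("A", "B"), array_gene = c("C", "D"),
    w_x = c(2, 0.9), w_y = c(2, 0.9), w_xy = c(4, 0.8)
  )
  expect_message(rt <- residual_table(recs, laws = "scott_hwa"), "excluded")
  expect_equal(nrow(rt), 1)
  expect_equal(attr(rt, "n_divergent")[["scott_hwa"]], 1L)
})

test_that("binned summaries compute medians and quartiles per bin", {
  make_rt <- function(resids, ms) {
    tibble::tibble(law = "product", residual = resids, max_single = ms)
  }
  b1 <- bin_residuals(make_rt(c(0.1, 0.1, 0.1), rep(0.52, 3)))
  expect_equal(b1$median[b1$bin == 1], 0.1)
  expect_equal(b1$q25[b1$bin == 1], 0.1)
  expect_equal(b1$q75[b1$bin == 1], 0.1)
  b2 <- bin_residuals(make_rt(c(-1, 0, 1), rep(0.52, 3)))
  expect_equal(b2$median[b2$bin == 1], 0)
  expect_true(all(b2$n[b2$bin > 1] == 0))
  expect_true(all(is.na(b2$median[b2$bin > 1])))
  # q25 <= median <= q75 in every non-empty bin; equal-width edges;
  # max_single = 1 goes in the (closed) last bin
  b3 <- bin_residuals(make_rt(stats::rnorm(100), stats::runif(100, 0.5, 1)))
  occupied <- b3[b3$n > 0, ]
  expect_true(all(occupied$q25 <= occupied$median + 1e-12))
  expect_true(all(occupied$median <= occupied$q75 + 1e-12))
  expect_equal(unique(round(diff(attr(b3, "edges")), 12)), 0.05)
  b4 <- bin_residuals(make_rt(0.3, 1.0))
  expect_equal(b4$n[b4$bin == 10], 1L)
})

test_that("bin medians of noisy product-law data are centred on zero", {
  # Monte-Carlo oracle: unbiased gaussian noise leaves every bin median
  # within ~3 sd of zero (sd of a median ~ 1.25 sigma / sqrt(n))
  cfg <- synth_config(n_genes = 400, n_pairs = 10000, law = "product",
                      noise_sd = 0.05, seed = 101)
  rt <- residual_table(preprocess_sga(generate_fitness_table(cfg)),
                       laws = "product")
  bins <- bin_residuals(rt)
  tol <- 3 * 0.05 / sqrt(bins$n[bins$n > 0])
  expect_true(all(abs(bins$median[bins$n > 0]) < pmax(tol, 0.005)))
})

test_that("fit_neutrality tidies, glances and finds the generating law", {
  cfg <- synth_config(n_genes = 300, n_pairs = 5000, law = "minimum",
                      noise_sd = 0.03, seed = 7)
  fit <- fit_neutrality(preprocess_sga(generate_fitness_table(cfg)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$law, neutrality_laws())
  expect_true(all(c("mean_abs_bin_median", "rmse") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$best_law, "minimum")
  expect_equal(gl$n_records, nrow(fit$residuals) / 4)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("bin_at returns the bin containing a given fitness", {
  rt <- tibble::tibble(law = "product", residual = rnorm(50),
                       max_single = runif(50, 0.5, 1))
  bins <- bin_residuals(rt)
  hit <- bin_at(bins, 0.72)
  expect_equal(hit$bin_lo, 0.70)
  expect_equal(hit$bin_hi, 0.75)
})
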