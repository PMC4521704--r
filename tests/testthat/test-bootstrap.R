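test_that("resampling weights follow stocks", {
  tab <- data.frame(unit_id = 1:3, gdp_ppp_usd = c(1e3, 1e4, 1e5),
                    stock = c(100, 0, 0),
                    observed_p_ext = c(0.9, 0.5, 0.1))
  set.seed(1)
  s <- weighted_resample(tab, 25)
  expect_equal(unique(s$unit_id), 1)  # degenerate weights: only unit 1
  expect_equal(nrow(s), 25)

  # stocks 300:100 -> inclusion frequency 3:1 within 3 binomial SEs
  tab2 <- data.frame(unit_id = 1:2, gdp_ppp_usd = c(1e3, 1e4),
                     stock = c(300, 100), observed_p_ext = c(0.8, 0.4))
  set.seed(2)
  n <- 1e5
  s2 <- weighted_resample(tab2, n)
  f1 <- mean(s2$unit_id == 1)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(f1 - 0.75), 3 * se)

  expect_error(weighted_resample(
    data.frame(unit_id = 1:2, stock = c(0, 0)), 10), "total stock")
})

test_that("bootstrap ensembles are seed-reproducible and sized as configured", {
  truth <- share_params(-1.2, 3.6)
  set.seed(99)
  tab <- make_table(truth, n = 40, stock = rlnorm(40, 14, 1.5))
  tab$observed_p_ext <- pmin(1, pmax(0, tab$observed_p_ext + rnorm(40, 0, 0.03)))

  e1 <- run_bootstrap(tab, "chicken_ext", bootstrap_config(n_reps = 30, seed = 7))
  e2 <- run_bootstrap(tab, "chicken_ext", bootstrap_config(n_reps = 30, seed = 7))
  expect_identical(e1$params, e2$params)
  expect_identical(e1$predictions, e2$predictions)

  single <- run_bootstrap(tab, "chicken_ext", bootstrap_config(n_reps = 1, seed = 3))
  expect_equal(nrow(single$params), 1)
  expect_equal(ncol(single$predictions), 1)
  expect_equal(nrow(single$predictions), nrow(tab))
})

test_that("ensemble median curve tracks the generating curve", {
  truth <- share_params(-1.2, 3.6)
  set.seed(11)
  tab <- make_table(truth, n = 60, stock = rlnorm(60, 14, 1.5))
  tab$observed_p_ext <- pmin(1, pmax(0, tab$observed_p_ext + rnorm(60, 0, 0.03)))
  grid <- data.frame(unit_id = paste0("g", 1:41),
                     gdp_ppp_usd = 10^seq(2.7, 4.7, by = 0.05))
  ens <- run_bootstrap(tab, "chicken_ext",
                       bootstrap_config(n_reps = 200, seed = 5),
                       newdata = grid)
  med <- apply(ens$predictions, 1, median)
  expect_lt(max(abs(med - p_ext_chicken(log10(grid$gdp_ppp_usd), truth))), 0.05)
  # every stored replicate prediction stays within the curve's range
  expect_true(all(ens$predictions > 0 & ens$predictions < 1))
})

test_that("observed values are retained or clipped at the percentile envelope", {
  ens <- fake_ensemble(seq(0.1, 0.9, by = 0.1))
  # type-7 percentiles of 0.1..0.9: p1 = 0.108, p99 = 0.892
  r <- predict_unit_share(ens, "A", 0.5)
  expect_equal(r$share, 0.5)
  expect_equal(r$provenance, "observed_retained")
  r <- predict_unit_share(ens, "A", 0.95)
  expect_equal(r$share, 0.892, tolerance = 1e-12)
  expect_equal(r$provenance, "clipped_high")
  r <- predict_unit_share(ens, "A", 0.05)
  expect_equal(r$share, 0.108, tolerance = 1e-12)
  expect_equal(r$provenance, "clipped_low")
  r <- predict_unit_share(ens, "A", NA)
  expect_equal(r$share, 0.5)  # median of the predictions
  expect_equal(r$provenance, "predicted")
  expect_error(predict_unit_share(ens, "missing"), "not in ensemble")
})

test_that("clipping is idempotent and bounded by the prediction envelope", {
  ens <- fake_ensemble(runif(50, 0.2, 0.8))
  for (obs in c(NA, 0, 0.31, 0.5, 0.99)) {
    r1 <- predict_unit_share(ens, "A", obs)
    r2 <- predict_unit_share(ens, "A", r1$share)
    expect_equal(r2$share, r1$share)
    env <- range(c(ens$predictions, if (!is.na(obs)) obs))
    expect_gte(r1$share, env[1]); expect_lte(r1$share, env[2])
    expect_gte(r1$share, 0); expect_lte(r1$share, 1)
  }
})

test_that("predict_all_units pairs units with their observations", {
  truth <- share_params(-1.2, 3.6)
  set.seed(21)
  tab <- make_table(truth, n = 30, stock = rlnorm(30, 14, 1))
  tab$observed_p_ext[1:15] <- NA  # half unobserved
  ens <- run_bootstrap(tab, "chicken_ext", bootstrap_config(n_reps = 50, seed = 2))
  out <- predict_all_units(ens, tab)
  expect_equal(nrow(out), 30)
  expect_true(all(out$provenance[1:15] == "predicted"))
  retained <- out$provenance == "observed_retained"
  expect_equal(out$final_share[retained],
               tab$observed_p_ext[retained])
})
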