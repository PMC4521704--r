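test_that("suitability mask applies the exclusion thresholds strictly", {
  elev <- matrix(c(5000, 4750, 100, 100, 100, 100), 2, 3)
  slope <- matrix(c(10, 40, 45, 10, 10, 10), 2, 3)
  urban <- matrix(c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE), 2, 3)
  snow <- matrix(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE), 2, 3)
  m <- build_mask(elev, slope, urban, snow)
  expect_false(m[1, 1])  # above 4,750 m
  expect_true(m[2, 1])   # exactly 4,750 m and 40 % stays suitable
  expect_false(m[1, 2])  # slope above 40 %
  expect_false(m[2, 2])  # urban
  expect_false(m[1, 3])  # snow/ice
  expect_true(m[2, 3])
  elev[2, 3] <- NA
  expect_false(build_mask(elev, slope, urban, snow)[2, 3])  # nodata unsuitable
  expect_error(build_mask(elev[1, , drop = FALSE], slope, urban, snow),
               "co-registered")
})

test_that("rural population zeroes urban, unsuitable and nodata pixels", {
  pop <- matrix(c(10, 20, NA, 5), 2, 2)
  urban <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(rural_population(pop, urban, mask),
               matrix(c(10, 0, 0, 0), 2, 2))
  expect_equal(rural_population(pop, matrix(TRUE, 2, 2), mask),
               matrix(0, 2, 2))
})

test_that("rescaling matches unit totals and is idempotent", {
  um <- matrix(c(1, 1, 2, 2), 2, 2)
  lv <- matrix(c(50, 150, 10, 30), 2, 2)
  out <- rescale_totals(lv, um, c(`1` = 400, `2` = 40))
  expect_equal(out, matrix(c(100, 300, 10, 30), 2, 2))
  expect_equal(rescale_totals(out, um, c(`1` = 400, `2` = 40)), out)
  out0 <- rescale_totals(lv, um, c(`1` = 0, `2` = 40))
  expect_equal(out0[um == 1], c(0, 0))
  expect_error(rescale_totals(matrix(0, 2, 2), um, c(`1` = 5, `2` = 0)),
               "cannot rescale")
})

test_that("extensive allocation spreads share x total over rural population", {
  um <- matrix(1, 1, 3)
  rural <- matrix(c(10, 30, 60), 1, 3)
  out <- allocate_extensive(rural, um, c(`1` = 0.4), c(`1` = 1000))
  expect_equal(out, matrix(c(40, 120, 240), 1, 3))  # multiplier 4
  expect_equal(sum(out), 0.4 * 1000)
  expect_equal(allocate_extensive(rural, um, c(`1` = 0), c(`1` = 1000)),
               matrix(0, 1, 3))
  one <- allocate_extensive(matrix(c(0, 0, 7), 1, 3), um, c(`1` = 0.5),
                            c(`1` = 1000))
  expect_equal(one[1, 3], 500)  # single rural pixel takes everything
  expect_error(allocate_extensive(matrix(0, 1, 3), um, c(`1` = 0.5),
                                  c(`1` = 1000)), "no rural population")
})

test_that("overflow correction reproduces the worked example and conserves", {
  total <- matrix(c(10, 140, 250), 1)
  ext <- matrix(c(20, 60, 120), 1)
  um <- matrix(1, 1, 3)
  r <- intensive_by_difference(total, ext, um)
  expect_equal(r$intensive, matrix(c(0, 80 * 200 / 210, 130 * 200 / 210), 1),
               tolerance = 1e-12)
  expect_equal(r$ledger$deficit, 10)
  expect_equal(r$ledger$pixels_overflowed, 1)
  expect_equal(sum(r$intensive) + sum(ext), 400, tolerance = 1e-12)
  expect_equal(sum(r$corrected_total), 400, tolerance = 1e-12)

  # no overflow -> plain subtraction
  r2 <- intensive_by_difference(matrix(c(30, 40), 1), matrix(c(10, 5), 1),
                                matrix(1, 1, 2))
  expect_equal(r2$intensive, matrix(c(20, 35), 1))
  # all-zero extensive -> intensive equals total
  r3 <- intensive_by_difference(matrix(c(30, 40), 1), matrix(0, 1, 2),
                                matrix(1, 1, 2))
  expect_equal(r3$intensive, matrix(c(30, 40), 1))
  # deficit beyond all commercial stock is a hard error
  expect_error(intensive_by_difference(matrix(c(1, 1), 1),
                                       matrix(c(10, 1), 1), matrix(1, 1, 2)),
               "cannot conserve")
})

test_that("vectorized overflow correction matches the scalar oracle", {
  set.seed(31)
  for (i in 1:60) {
    g <- random_overflow_grids(sample(2:10, 1), sample(2:10, 1))
    got <- intensive_by_difference(g$total, g$extensive, g$unit_map)
    want <- intensive_by_difference_oracle(g$total, g$extensive, g$unit_map)
    expect_equal(got$intensive, want$intensive, tolerance = 1e-14)
    expect_equal(got$corrected_total, want$corrected_total, tolerance = 1e-14)
    expect_true(all(got$intensive >= 0))
  }
})

test_that("pig commercial split follows unit share ratios pixelwise", {
  um <- matrix(c(1, 1, 2, 2), 2, 2)
  comm <- matrix(c(90, 30, 10, 0), 2, 2)
  shares <- data.frame(unit_id = 1:2, p_sint = c(0.25, 0), p_int = c(0.5, 0.4))
  sp <- split_pig_intensive(comm, um, shares)
  expect_equal(sp$semi_intensive[1, 1], 30)  # ratio 1:2
  expect_equal(sp$intensive[1, 1], 60)
  expect_equal(sp$semi_intensive[um == 2], c(0, 0))  # p_sint = 0
  expect_equal(sp$semi_intensive + sp$intensive, comm)  # sums back exactly
  bad <- data.frame(unit_id = 1:2, p_sint = c(0, 0), p_int = c(0.5, 0))
  expect_error(split_pig_intensive(comm, um, bad), "p_sint \\+ p_int = 0")
})

test_that("species disaggregation conserves totals and masks correctly", {
  spec <- world_spec("chicken", n_units = 6, grid_shape = c(20, 20),
                     noise_sd = 0, seed = 17)
  w <- simulate_world(spec)
  shares <- data.frame(unit_id = w$countries$unit_id,
                       p_ext = w$countries$true_p_ext, p_sint = 0,
                       p_int = w$countries$true_p_int)
  d <- disaggregate_species(w$bundle, shares, "chicken")
  expect_s3_class(d, "disaggregation")
  # per-unit extensive sums equal share x total exactly
  expect_equal(d$ledger$extensive_sum,
               shares$p_ext * w$countries$stock, tolerance = 1e-9)
  expect_true(all(d$ledger$rel_error <= 1e-6))
  # unsuitable pixels carry zero everywhere
  expect_true(all(d$extensive[!d$mask] == 0))
  expect_true(all(d$intensive[!d$mask] == 0))
  # within a unit, extensive values are proportional to rural population
  um <- w$bundle$unit_map
  px <- which(!is.na(um) & um == 1 & d$rural > 0)
  ratio <- d$extensive[px] / d$rural[px]
  expect_lt(diff(range(ratio)), 1e-9 * max(ratio))
  # a unit with p_ext = 1 has an all-zero intensive raster
  shares1 <- shares; shares1$p_ext <- 1; shares1$p_int <- 0
  d1 <- disaggregate_species(w$bundle, shares1, "chicken")
  expect_lt(max(abs(d1$intensive)), 1e-6 * max(d1$ledger$stock_total))
  expect_error(disaggregate_species(w$bundle, shares[-1, ], "chicken"),
               "missing for unit")
})

test_that("pig disaggregation yields three layers summing to the corrected total", {
  spec <- world_spec("pig", n_units = 6, grid_shape = c(20, 20),
                     noise_sd = 0, seed = 19)
  w <- simulate_world(spec)
  shares <- data.frame(unit_id = w$countries$unit_id,
                       p_ext = w$countries$true_p_ext,
                       p_sint = w$countries$true_p_sint,
                       p_int = w$countries$true_p_int)
  d <- disaggregate_species(w$bundle, shares, "pig")
  expect_false(is.null(d$semi_intensive))
  pixel_sum <- d$extensive + d$semi_intensive + d$intensive
  expect_equal(pixel_sum, d$corrected_total, tolerance = 1e-9)
  expect_true(all(d$ledger$rel_error <= 1e-6))
  expect_true(all(pixel_sum >= 0))
})
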