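# Small in-code fixtures shared across tests.

# A noise-free country table generated from known curve parameters.
make_table <- function(params, n = 30, target = "chicken_ext",
                       g_range = c(2.7, 4.7), stock = NULL,
                       int_params = NULL, form = "as_printed") {
  g <- seq(g_range[1], g_range[2], length.out = n)
  tab <- data.frame(unit_id = seq_len(n), gdp_ppp_usd = 10^g,
                    stock = if (is.null(stock)) rep(1e6, n) else stock,
                    observed_p_ext = NA_real_, observed_p_int = NA_real_)
  if (target %in% c("chicken_ext", "pig_ext")) {
    f <- if (target == "chicken_ext") p_ext_chicken else p_ext_pig
    tab$observed_p_ext <- f(g, params)
  } else {
    tab$observed_p_int <- p_int_pig(g, params, form)
  }
  if (!is.null(int_params)) tab$observed_p_int <- p_int_pig(g, int_params, form)
  tab
}

# Independent scalar-loop reference for the overflow correction: iterates
# pixel by pixel per unit, never touching the vectorized implementation.
intensive_by_difference_oracle <- function(total, extensive, unit_map) {
  total[is.na(total)] <- 0
  intensive <- matrix(0, nrow(total), ncol(total))
  corrected <- total
  for (id in sort(unique(unit_map[!is.na(unit_map)]))) {
    px <- which(!is.na(unit_map) & unit_map == id)
    D <- 0; S <- 0
    for (p in px) {
      d <- total[p] - extensive[p]
      if (d < 0) D <- D + (-d) else S <- S + d
    }
    if (D > S) stop("oracle: deficit exceeds commercial stock in unit ", id)
    scale <- if (D > 0) (S - D) / S else 1
    for (p in px) {
      d <- total[p] - extensive[p]
      if (d < 0) {
        intensive[p] <- 0
        corrected[p] <- extensive[p]
      } else {
        intensive[p] <- d * scale
        corrected[p] <- extensive[p] + d * scale
      }
    }
  }
  list(intensive = intensive, corrected_total = corrected)
}

# Random co-registered (total, extensive, unit_map) triple with guaranteed
# feasibility (unit extensive sum <= unit total sum) and frequent overflow.
random_overflow_grids <- function(nr, nc, n_units = 2) {
  unit_map <- matrix(sample.int(n_units, nr * nc, replace = TRUE), nr, nc)
  total <- matrix(stats::runif(nr * nc, 0, 100), nr, nc)
  extensive <- matrix(stats::runif(nr * nc, 0, 100), nr, nc)
  for (id in seq_len(n_units)) {
    px <- unit_map == id
    if (!any(px)) next
    frac <- stats::runif(1, 0.2, 0.95)
    extensive[px] <- extensive[px] *
      (frac * sum(total[px]) / sum(extensive[px]))
  }
  list(total = total, extensive = extensive, unit_map = unit_map)
}

# Minimal hand-built ensemble with known prediction values for one unit.
fake_ensemble <- function(preds = seq(0.1, 0.9, by = 0.1),
                          low = 1, high = 99) {
  structure(list(
    params = data.frame(replicate = seq_along(preds), mu = -1, lambda = 3.5,
                        alpha = 1, rss = 0),
    predictions = matrix(preds, nrow = 1,
                         dimnames = list("A", NULL)),
    unit_ids = "A", n_discarded = 0L, target = "chicken_ext",
    form = "as_printed",
    config = bootstrap_config(n_reps = length(preds), seed = 1,
                              percentile_low = low, percentile_high = high)),
    class = "bootstrap_ensemble")
}
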