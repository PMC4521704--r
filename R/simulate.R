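#' Specification of a synthetic world
#'
#' Describes a set of admin units with log-uniform GDP per capita,
#' heavy-tailed (log-normal) stocks, true system shares drawn from bounded
#' logistic curves, partially observed shares with bounded Gaussian noise,
#' and per-unit raster fixtures with urban cores, a rural background, an
#' unsuitable-terrain fraction, and spatially clustered commercial
#' production. These mimic the statistical structure of the real inputs
#' (national statistics, gridded livestock and population layers) without
#' reproducing any actual geography.
#'
#' @param species `"chicken"` or `"pig"`.
#' @param n_units Number of admin units.
#' @param gdp_range GDP per capita range in USD PPP (log-uniform).
#' @param chicken_params,pig_ext_params,pig_int_params True [share_params()]
#'   generating the shares.
#' @param p_int_form Intensive pig curve form (see [p_int_pig()]).
#' @param stock_meanlog,stock_sdlog Log-normal stock distribution.
#' @param obs_fraction Fraction of units with observed shares.
#' @param noise_sd SD of Gaussian observation noise (clipped to \[0, 1\]).
#' @param grid_shape Rows/cols of each unit's raster block.
#' @param urban_fraction Approximate fraction of pixels in urban cores.
#' @param unsuitable_fraction Approximate fraction of pixels failing the
#'   suitability mask.
#' @param n_intensive_clusters Commercial production clusters per unit.
#' @param seed RNG seed; the whole world is deterministic given the spec.
#' @return A `world_spec` list.
#' @export
world_spec <- function(species = c("chicken", "pig"), n_units = 60,
                       gdp_range = c(500, 60000),
                       chicken_params = share_params(-1.2, 3.9),
                       pig_ext_params = share_params(-0.7, 3.9, 0.9),
                       pig_int_params = share_params(-0.8, 4.0, 0.95),
                       p_int_form = c("as_printed", "bounded"),
                       stock_meanlog = log(2e6), stock_sdlog = 1.8,
                       obs_fraction = 0.45, noise_sd = 0.05,
                       grid_shape = c(40, 40), urban_fraction = 0.08,
                       unsuitable_fraction = 0.05,
                       n_intensive_clusters = 3, seed = 1) {
  species <- match.arg(species)
  p_int_form <- match.arg(p_int_form)
  stopifnot(n_units >= 1, gdp_range[1] > 0, gdp_range[2] > gdp_range[1],
            obs_fraction > 0, obs_fraction <= 1, noise_sd >= 0,
            all(grid_shape >= 4), urban_fraction >= 0, urban_fraction < 1,
            unsuitable_fraction >= 0, unsuitable_fraction < 1)
  structure(as.list(environment()), class = "world_spec")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a country/province table with true and observed shares
#'
#' GDP per capita is log-uniform over the spec's range, stocks are
#' log-normal, true shares follow the spec's generating curves, and a
#' fraction of units carries observed shares equal to the truth plus
#' Gaussian noise clipped to \[0, 1\]. True shares are returned alongside so
#' recovery can be scored.
#'
#' @param spec A [world_spec()].
#' @return Data frame: `unit_id`, `gdp_ppp_usd`, `stock`, `observed_p_ext`,
#'   `observed_p_int` (chickens: all `NA`), `true_p_ext`, `true_p_sint`,
#'   `true_p_int`.
#' @export
simulate_country_table <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  n <- spec$n_units
  g <- stats::runif(n, log10(spec$gdp_range[1]), log10(spec$gdp_range[2]))
  stock <- stats::rlnorm(n, spec$stock_meanlog, spec$stock_sdlog)
  if (spec$species == "chicken") {
    tr <- shares_chicken(g, spec$chicken_params)
  } else {
    tr <- shares_pig(g, spec$pig_ext_params, spec$pig_int_params,
                     spec$p_int_form)
  }
  n_obs <- min(n, max(5, round(spec$obs_fraction * n)))
  observed <- seq_len(n) %in% sample.int(n, n_obs)
  obs_ext <- ifelse(observed,
                    clip01(tr$p_ext + stats::rnorm(n, 0, spec$noise_sd)),
                    NA_real_)
  obs_int <- if (spec$species == "pig") {
    ifelse(observed,
           clip01(tr$p_int + stats::rnorm(n, 0, spec$noise_sd)),
           NA_real_)
  } else NA_real_
  data.frame(unit_id = seq_len(n), gdp_ppp_usd = 10^g, stock = stock,
             observed_p_ext = obs_ext, observed_p_int = obs_int,
             true_p_ext = tr$p_ext, true_p_sint = tr$p_sint,
             true_p_int = tr$p_int)
}

blob_mask <- function(nr, nc, n_blobs, target_fraction, radius = NULL) {
  m <- matrix(FALSE, nr, nc)
  if (target_fraction <= 0 || n_blobs < 1) return(m)
  if (is.null(radius))
    radius <- max(1, sqrt(target_fraction * nr * nc / (pi * n_blobs)))
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (b in seq_len(n_blobs)) {
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    m <- m | ((rows - cr)^2 + (cols - cc)^2 <= radius^2)
  }
  m
}

#' Simulate the raster bundle for one admin unit
#'
#' Builds a population grid with clustered urban cores over a log-normal
#' rural background; elevation, slope and snow layers with a controllable
#' unsuitable fraction; and a total livestock grid constructed as true
#' extensive stock (proportional to rural population) plus true commercial
#' stock placed in a few high-density clusters, scaled so the unit sum
#' equals the unit's stock. The true per-pixel system layers are returned
#' for recovery tests.
#'
#' @param spec A [world_spec()].
#' @param record One row of [simulate_country_table()].
#' @return List of matrices: `population`, `urban`, `elevation`, `slope`,
#'   `snow_ice`, `total`, and `truth` (list with `extensive`, `commercial`).
#' @export
simulate_unit_rasters <- function(spec, record) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  pop <- matrix(stats::rlnorm(nr * nc, meanlog = 3, sdlog = 1), nr, nc)
  urban <- blob_mask(nr, nc, n_blobs = 2, spec$urban_fraction)
  pop[urban] <- pop[urban] * 50
  elevation <- matrix(stats::runif(nr * nc, 0, 1500), nr, nc)
  elevation[blob_mask(nr, nc, 2, spec$unsuitable_fraction * 0.6)] <- 5200
  slope <- matrix(stats::runif(nr * nc, 0, 25), nr, nc)
  slope[blob_mask(nr, nc, 2, spec$unsuitable_fraction * 0.4)] <- 55
  snow <- blob_mask(nr, nc, 1, spec$unsuitable_fraction * 0.1)

  mask <- build_mask(elevation, slope, urban, snow)
  rural <- rural_population(pop, urban, mask)
  if (sum(rural) <= 0) {
    # guarantee a rural foothold so extensive stock is always placeable
    fix <- which(!urban & mask)[1]
    if (is.na(fix)) { mask[1] <- TRUE; urban[1] <- FALSE; fix <- 1L }
    rural[fix] <- 1
  }

  p_ext <- record$true_p_ext
  ext <- rural / sum(rural) * (p_ext * record$stock)
  comm_total <- (1 - p_ext) * record$stock
  comm <- matrix(0, nr, nc)
  if (comm_total > 0) {
    suitable <- which(mask)
    k <- min(spec$n_intensive_clusters, length(suitable))
    if (k >= 1) {
      centers <- sample(suitable, k)
      w <- stats::rgamma(k, shape = 2)
      comm[centers] <- w / sum(w) * comm_total
    } else {
      # no clusters requested: commercial mass follows rural population so
      # the unit sum still equals the stock
      comm <- rural / sum(rural) * comm_total
    }
  }
  total <- ext + comm
  total[!mask] <- 0
  list(population = pop, urban = urban, elevation = elevation, slope = slope,
       snow_ice = snow, total = total,
       truth = list(extensive = ext, commercial = comm))
}

#' Simulate a full synthetic world
#'
#' Generates the country table and mosaics every unit's raster block into
#' one world grid (units tiled in a square arrangement) with a unit-id map,
#' producing exactly the input bundle [disaggregate_species()] consumes plus
#' the true per-pixel system layers.
#'
#' @param spec A [world_spec()].
#' @return List: `countries` (table with truth columns), `bundle` (raster
#'   inputs incl. `unit_map` and `unit_totals`), `truth` (matrices
#'   `extensive`, `commercial`), `spec`.
#' @export
simulate_world <- function(spec) {
  countries <- simulate_country_table(spec)
  n <- spec$n_units
  nb <- ceiling(sqrt(n))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  big <- function() matrix(NA_real_, nb * nr, nb * nc)
  W <- list(population = big(), urban = big(), elevation = big(),
            slope = big(), snow_ice = big(), total = big())
  unit_map <- matrix(NA_real_, nb * nr, nb * nc)
  truth_ext <- big(); truth_comm <- big()
  for (i in seq_len(n)) {
    u <- simulate_unit_rasters(spec, countries[i, ])
    ri <- ((i - 1) %/% nb) * nr + seq_len(nr)
    ci <- ((i - 1) %% nb) * nc + seq_len(nc)
    W$population[ri, ci] <- u$population
    W$urban[ri, ci] <- u$urban
    W$elevation[ri, ci] <- u$elevation
    W$slope[ri, ci] <- u$slope
    W$snow_ice[ri, ci] <- u$snow_ice
    W$total[ri, ci] <- u$total
    truth_ext[ri, ci] <- u$truth$extensive
    truth_comm[ri, ci] <- u$truth$commercial
    unit_map[ri, ci] <- countries$unit_id[i]
  }
  W$urban <- W$urban > 0
  W$snow_ice <- W$snow_ice > 0
  bundle <- c(W, list(unit_map = unit_map,
                      unit_totals = stats::setNames(countries$stock,
                                                    countries$unit_id)))
  list(countries = countries, bundle = bundle,
       truth = list(extensive = truth_ext, commercial = truth_comm),
       spec = spec)
}
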