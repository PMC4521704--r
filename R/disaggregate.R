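as_unit_vector <- function(x, value_col = "stock") {
  if (is.data.frame(x)) {
    stopifnot("unit_id" %in% names(x), value_col %in% names(x))
    stats::setNames(x[[value_col]], as.character(x$unit_id))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else stop("expected a named numeric vector or a data frame with unit_id")
}

unit_index <- function(unit_map) {
  ids <- sort(unique(unit_map[!is.na(unit_map)]))
  lapply(stats::setNames(ids, as.character(ids)),
         function(id) which(!is.na(unit_map) & unit_map == id))
}

#' Biophysical suitability mask for monogastric production
#'
#' A pixel is suitable for chicken or pig production unless it lies above
#' 4,750 m elevation, on a slope steeper than 40 percent, inside an urban
#' area, or under permanent snow or ice. Thresholds are inclusive (a pixel
#' at exactly 4,750 m or 40 % remains suitable, since only strictly higher
#' values are excluded). Pixels with nodata in any layer are unsuitable.
#'
#' @param elevation Matrix or [lps_raster()], metres above sea level.
#' @param slope Matrix or raster, percent gradient.
#' @param urban Logical (or 0/1) matrix or raster, `TRUE` = urban.
#' @param snow_ice Logical (or 0/1) matrix or raster, `TRUE` = permanent
#'   snow/ice.
#' @param max_elevation,max_slope Exclusion thresholds (defaults 4750 m,
#'   40 %).
#' @return Logical matrix, `TRUE` = suitable.
#' @export
build_mask <- function(elevation, slope, urban, snow_ice,
                       max_elevation = 4750, max_slope = 40) {
  elevation <- raster_values(elevation); slope <- raster_values(slope)
  urban <- raster_values(urban); snow_ice <- raster_values(snow_ice)
  check_same_shape(elevation, slope, urban, snow_ice)
  m <- elevation <= max_elevation & slope <= max_slope &
    !(urban > 0) & !(snow_ice > 0)
  m[is.na(m)] <- FALSE
  m
}

#' Rural population layer
#'
#' Human population restricted to non-urban, suitable pixels; everywhere
#' else (urban, unsuitable, nodata) contributes zero. This is the ancillary
#' layer over which extensive stock is spread.
#'
#' @param population Matrix or [lps_raster()] of people per pixel.
#' @param urban Logical (or 0/1) matrix, `TRUE` = urban.
#' @param mask Logical suitability matrix from [build_mask()].
#' @return Numeric matrix of rural population, zeros elsewhere.
#' @export
rural_population <- function(population, urban, mask) {
  population <- raster_values(population); urban <- raster_values(urban)
  check_same_shape(population, urban, mask)
  out <- population
  out[is.na(out)] <- 0
  out[(urban > 0) %in% TRUE | !mask] <- 0
  out
}

#' Rescale a gridded livestock layer to match unit stock totals
#'
#' Multiplies every pixel of each admin unit by a single factor so that the
#' unit's pixel sum equals its reported stock total, harmonising the gridded
#' layer with national statistics before disaggregation. Applying it twice
#' is the same as applying it once.
#'
#' @param livestock Matrix or [lps_raster()], head per pixel.
#' @param unit_map Integer matrix of admin-unit ids (`NA` outside units).
#' @param unit_totals Named numeric vector (names = unit ids) or data frame
#'   with `unit_id` and `stock`.
#' @return Numeric matrix with per-unit sums equal to `unit_totals`.
#' @export
rescale_totals <- function(livestock, unit_map, unit_totals) {
  livestock <- raster_values(livestock)
  check_same_shape(livestock, unit_map)
  totals <- as_unit_vector(unit_totals)
  out <- livestock
  for (id in names(unit_index(unit_map))) {
    px <- which(!is.na(unit_map) & unit_map == as.numeric(id))
    if (!id %in% names(totals)) stop("no stock total for unit ", id)
    tot <- totals[[id]]
    s <- sum(out[px], na.rm = TRUE)
    if (tot > 0 && s <= 0)
      stop("unit ", id, ": stock total > 0 but gridded sum is 0; cannot rescale")
    out[px] <- if (tot == 0) 0 else out[px] * (tot / s)
  }
  out
}

#' Allocate extensive stock over the rural population
#'
#' Per admin unit, the extensive stock (share x total) is distributed
#' proportionally to rural population: every rural person in the unit
#' accounts for the same number of extensively raised animals. The unit's
#' allocated sum equals its extensive stock exactly.
#'
#' @param rural Rural population matrix from [rural_population()].
#' @param unit_map Integer matrix of admin-unit ids.
#' @param unit_shares Named numeric vector (or data frame with `unit_id`,
#'   `p_ext`) of extensive shares per unit.
#' @param unit_totals Stock totals per unit, as in [rescale_totals()].
#' @return Numeric matrix of extensively raised head per pixel.
#' @export
allocate_extensive <- function(rural, unit_map, unit_shares, unit_totals) {
  rural <- raster_values(rural)
  check_same_shape(rural, unit_map)
  shares <- as_unit_vector(unit_shares, "p_ext")
  totals <- as_unit_vector(unit_totals)
  out <- matrix(0, nrow(rural), ncol(rural))
  for (id in names(unit_index(unit_map))) {
    px <- which(!is.na(unit_map) & unit_map == as.numeric(id))
    target <- shares[[id]] * totals[[id]]
    if (target == 0) next
    rs <- sum(rural[px])
    if (rs <= 0)
      stop("unit ", id, ": extensive stock > 0 but no rural population")
    out[px] <- rural[px] * (target / rs)
  }
  out
}

#' Commercial stock by difference, with overflow correction
#'
#' The commercially raised layer is the gridded total minus the allocated
#' extensive layer. In the rare pixels where extensive allocation exceeds
#' the total, the total is raised to the extensive value (commercial set to
#' 0 there); the resulting per-unit deficit is then removed pro-rata from
#' the commercial stock of the unit's remaining pixels, so the unit total is
#' conserved. A single pro-rata pass suffices because the extensive layer is
#' never modified and commercial values only shrink; a post-check asserts
#' this.
#'
#' @param total Matrix or [lps_raster()], total head per pixel (already
#'   rescaled to unit totals).
#' @param extensive Extensive layer from [allocate_extensive()].
#' @param unit_map Integer matrix of admin-unit ids.
#' @return List: `intensive` (commercial head per pixel), `corrected_total`
#'   (extensive + corrected commercial; per-unit sums equal the original
#'   totals), `ledger` (per unit: deficit, pixels_overflowed, scale applied).
#' @export
intensive_by_difference <- function(total, extensive, unit_map) {
  total <- raster_values(total); extensive <- raster_values(extensive)
  check_same_shape(total, extensive, unit_map)
  tot <- total
  tot[is.na(tot)] <- 0
  raw <- tot - extensive
  intensive <- matrix(0, nrow(tot), ncol(tot))
  corrected <- tot
  rows <- list()
  for (id in names(unit_index(unit_map))) {
    px <- which(!is.na(unit_map) & unit_map == as.numeric(id))
    r <- raw[px]
    over <- r < 0
    D <- sum(-r[over])
    S <- sum(r[!over])
    if (D > S * (1 + 1e-9) + 1e-12)
      stop("unit ", id, ": extensive overflow deficit (", signif(D, 6),
           ") exceeds available commercial stock (", signif(S, 6),
           "); cannot conserve the unit total")
    scale <- if (D > 0) max(0, S - D) / S else 1
    vals <- r
    vals[over] <- 0
    vals[!over] <- r[!over] * scale
    intensive[px] <- vals
    # corrected total = extensive + corrected commercial, so the unit sum
    # stays at the original total
    corrected[px] <- extensive[px] + vals
    if (any(intensive[px] < 0))
      stop("unit ", id, ": negative commercial stock after correction")
    rows[[id]] <- data.frame(unit_id = as.numeric(id), deficit = D,
                             pixels_overflowed = sum(over), scale = scale)
  }
  list(intensive = intensive, corrected_total = corrected,
       ledger = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Split the commercial pig layer into semi-intensive and intensive
#'
#' Semi-intensively raised pigs are assumed not to follow rural population;
#' each pixel's commercial value is split according to the unit-level ratio
#' of the semi-intensive to intensive shares, so the two layers sum back to
#' the commercial layer at every pixel.
#'
#' @param commercial Commercial (semi-intensive + intensive) pig layer.
#' @param unit_map Integer matrix of admin-unit ids.
#' @param unit_shares Data frame with `unit_id`, `p_sint`, `p_int`.
#' @return List of matrices `semi_intensive` and `intensive`.
#' @export
split_pig_intensive <- function(commercial, unit_map, unit_shares) {
  commercial <- raster_values(commercial)
  check_same_shape(commercial, unit_map)
  ps <- as_unit_vector(unit_shares, "p_sint")
  pi_ <- as_unit_vector(unit_shares, "p_int")
  semi <- matrix(0, nrow(commercial), ncol(commercial))
  intens <- matrix(0, nrow(commercial), ncol(commercial))
  for (id in names(unit_index(unit_map))) {
    px <- which(!is.na(unit_map) & unit_map == as.numeric(id))
    denom <- ps[[id]] + pi_[[id]]
    v <- commercial[px]
    if (denom <= 0) {
      if (any(v > 0))
        stop("unit ", id, ": commercial pigs present but p_sint + p_int = 0")
      next
    }
    semi[px] <- v * ps[[id]] / denom
    intens[px] <- v * pi_[[id]] / denom
  }
  list(semi_intensive = semi, intensive = intens)
}

#' Disaggregate one species into production-system rasters
#'
#' Composes the full spatial pathway: suitability masking, rural-population
#' extraction, harmonisation of the gridded total with unit stock totals,
#' allocation of extensive stock over rural population, commercial stock by
#' difference with overflow correction, and (for pigs) the semi-intensive /
#' intensive split. Emits a per-unit accounting ledger proving that the
#' system layers sum to the unit stock totals.
#'
#' @param bundle List of co-registered layers: `total`, `population`,
#'   `elevation`, `slope`, `urban`, `snow_ice`, `unit_map`, plus
#'   `unit_totals` (named vector or data frame with `unit_id`, `stock`).
#' @param shares Data frame with `unit_id`, `p_ext`, `p_sint`, `p_int` (one
#'   row per unit in `unit_map`).
#' @param species `"chicken"` (two output layers) or `"pig"` (three).
#' @return A `disaggregation` object: matrices `extensive`, `intensive`,
#'   `semi_intensive` (pigs only), `corrected_total`, logical `mask`, and a
#'   per-unit `ledger` data frame with columns `unit_id`, `stock_total`,
#'   `p_ext`, `extensive_sum`, `semi_sum`, `intensive_sum`,
#'   `overflow_deficit`, `pixels_overflowed`, `rel_error`.
#' @export
disaggregate_species <- function(bundle, shares, species = c("chicken", "pig")) {
  species <- match.arg(species)
  need <- c("total", "population", "elevation", "slope", "urban", "snow_ice",
            "unit_map", "unit_totals")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stop("bundle lacks: ", paste(miss, collapse = ", "))
  unit_map <- raster_values(bundle$unit_map)
  totals <- as_unit_vector(bundle$unit_totals)
  ids <- names(unit_index(unit_map))
  if (!all(ids %in% as.character(shares$unit_id)))
    stop("shares missing for unit(s): ",
         paste(setdiff(ids, as.character(shares$unit_id)), collapse = ", "))

  mask <- build_mask(bundle$elevation, bundle$slope, bundle$urban,
                     bundle$snow_ice)
  rural <- rural_population(bundle$population, bundle$urban, mask)
  total <- raster_values(bundle$total)
  total[!mask | is.na(total)] <- 0
  total <- rescale_totals(total, unit_map, totals)
  p_ext <- stats::setNames(shares$p_ext, as.character(shares$unit_id))
  ext <- allocate_extensive(rural, unit_map, p_ext, totals)
  ibd <- intensive_by_difference(total, ext, unit_map)

  if (species == "pig") {
    sp <- split_pig_intensive(ibd$intensive, unit_map, shares)
    semi <- sp$semi_intensive
    intens <- sp$intensive
  } else {
    semi <- NULL
    intens <- ibd$intensive
  }

  idx <- unit_index(unit_map)
  ledger <- do.call(rbind, lapply(names(idx), function(id) {
    px <- idx[[id]]
    es <- sum(ext[px])
    ss <- if (is.null(semi)) 0 else sum(semi[px])
    is_ <- sum(intens[px])
    st <- totals[[id]]
    ov <- ibd$ledger[ibd$ledger$unit_id == as.numeric(id), ]
    data.frame(unit_id = as.numeric(id), stock_total = st,
               p_ext = unname(p_ext[[id]]), extensive_sum = es,
               semi_sum = ss, intensive_sum = is_,
               overflow_deficit = ov$deficit,
               pixels_overflowed = ov$pixels_overflowed,
               rel_error = if (st > 0) abs(es + ss + is_ - st) / st
                           else abs(es + ss + is_))
  }))
  bad <- ledger$rel_error > 1e-6
  if (any(bad))
    stop("conservation violated for unit(s): ",
         paste(ledger$unit_id[bad], collapse = ", "))
  structure(list(extensive = ext, semi_intensive = semi, intensive = intens,
                 corrected_total = ibd$corrected_total, mask = mask,
                 rural = rural, ledger = ledger, species = species),
            class = "disaggregation")
}

#' @export
print.disaggregation <- function(x, ...) {
  cat(sprintf("disaggregation [%s]: %d units, max conservation error %.3g, %d pixels overflowed\n",
              x$species, nrow(x$ledger), max(x$ledger$rel_error),
              sum(x$ledger$pixels_overflowed)))
  invisible(x)
}
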