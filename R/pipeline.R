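#' Configuration of the full analysis pipeline
#'
#' Bundles everything one species run needs: the country table, the raster
#' bundle, the bootstrap settings, the intensive-curve form, whether to
#' harmonise the gridded total with unit stock totals, and the master seed
#' from which all randomness flows.
#'
#' @param species `"chicken"` or `"pig"`.
#' @param country_table Data frame (or CSV path) as in
#'   [read_country_table()].
#' @param bundle Raster bundle as in [disaggregate_species()].
#' @param bootstrap A [bootstrap_config()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param p_int_form Intensive pig curve form (see [p_int_pig()]).
#' @param rescale Kept for transparency; the gridded total is always
#'   harmonised to unit totals inside [disaggregate_species()], which is an
#'   identity when they already agree.
#' @param seed Master RNG seed.
#' @param out_dir Optional directory; if given, parameter JSON, prediction
#'   and ledger CSVs and output rasters (`.asc`) are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(species = c("chicken", "pig"), country_table,
                            bundle, bootstrap = bootstrap_config(),
                            p_int_form = c("as_printed", "bounded"),
                            rescale = TRUE, seed = 1, out_dir = NULL) {
  species <- match.arg(species)
  p_int_form <- match.arg(p_int_form)
  if (is.character(country_table))
    country_table <- read_country_table(country_table)
  country_table <- validate_country_table(country_table)
  structure(list(species = species, country_table = country_table,
                 bundle = bundle, bootstrap = bootstrap,
                 p_int_form = p_int_form, rescale = rescale, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full production-system mapping pipeline
#'
#' Executes the five-step pathway for one species: (i) bootstrap-fit the
#' share curve(s) on units with observed shares, weighting resampling by
#' stock; (ii) predict per-unit shares, retaining observed values inside the
#' bootstrap percentile envelope and clipping those outside; (iii) allocate
#' extensive stock over rural population under the suitability mask;
#' (iv) obtain commercial stock by difference; (v) correct overflow pixels
#' pro-rata so unit totals are conserved. Pigs additionally split the
#' commercial layer into semi-intensive and intensive. Fully reproducible
#' under the configured seed.
#'
#' @param config A [pipeline_config()].
#' @return List: `shares` (per-unit final shares + provenance), `ensembles`
#'   (one or two `bootstrap_ensemble`s), `disaggregation`
#'   (a [disaggregate_species()] result), `log` (per-stage diagnostics:
#'   discarded replicates, clipped units, overflow pixels).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  tab <- config$country_table
  boot <- config$bootstrap
  boot$seed <- NULL  # stream from the master seed set above

  if (config$species == "chicken") {
    ens_ext <- run_bootstrap(tab, "chicken_ext", boot, newdata = tab)
    pred_ext <- predict_all_units(ens_ext, tab)
    shares <- data.frame(unit_id = pred_ext$unit_id,
                         p_ext = pred_ext$final_share,
                         p_sint = 0,
                         p_int = 1 - pred_ext$final_share,
                         provenance_ext = pred_ext$provenance)
    ensembles <- list(ext = ens_ext)
  } else {
    ens_ext <- run_bootstrap(tab, "pig_ext", boot, newdata = tab)
    ens_int <- run_bootstrap(tab, "pig_int", boot,
                             form = config$p_int_form, newdata = tab)
    pred_ext <- predict_all_units(ens_ext, tab)
    pred_int <- predict_all_units(ens_int, tab)
    raw <- data.frame(p_ext = pred_ext$final_share,
                      p_int = pred_int$final_share)
    ps <- 1 - (raw$p_ext + raw$p_int)
    neg <- ps < 0
    if (any(neg)) {
      tot <- raw$p_ext[neg] + raw$p_int[neg]
      raw$p_ext[neg] <- raw$p_ext[neg] / tot
      raw$p_int[neg] <- raw$p_int[neg] / tot
      ps[neg] <- 0
    }
    shares <- data.frame(unit_id = pred_ext$unit_id, p_ext = raw$p_ext,
                         p_sint = ps, p_int = raw$p_int,
                         provenance_ext = pred_ext$provenance,
                         provenance_int = pred_int$provenance)
    ensembles <- list(ext = ens_ext, int = ens_int)
  }

  disagg <- disaggregate_species(config$bundle, shares, config$species)

  log <- list(
    discarded_replicates = vapply(ensembles, function(e) e$n_discarded, 0L),
    clipped_units = sum(grepl("^clipped", shares$provenance_ext)) +
      if (config$species == "pig")
        sum(grepl("^clipped", shares$provenance_int)) else 0L,
    renormalized_units = if (config$species == "pig") sum(neg) else 0L,
    pixels_overflowed = sum(disagg$ledger$pixels_overflowed),
    max_conservation_error = max(disagg$ledger$rel_error))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(shares, file.path(config$out_dir, "unit_shares.csv"),
                     row.names = FALSE)
    write_ledger_csv(disagg, file.path(config$out_dir, "ledger.csv"))
    layers <- list(extensive = disagg$extensive, intensive = disagg$intensive)
    if (!is.null(disagg$semi_intensive))
      layers$semi_intensive <- disagg$semi_intensive
    for (nm in names(layers))
      write_asc_raster(lps_raster(layers[[nm]]),
                       file.path(config$out_dir, paste0(nm, ".asc")))
  }
  list(shares = shares, ensembles = ensembles, disaggregation = disagg,
       log = log)
}
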