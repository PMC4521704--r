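#' Configuration of the stock-weighted bootstrap
#'
#' Defaults follow the published analysis: 1,000 replicates of 25 units
#' sampled with replacement with probability proportional to national stock,
#' and clipping of observed values to the 1st-99th percentile envelope of the
#' per-unit predictions.
#'
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param sample_size Units drawn per replicate (>= 4).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param percentile_low,percentile_high Envelope percentiles in \[0, 100\],
#'   `low < high`.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_reps = 1000L, sample_size = 25L, seed = NULL,
                             percentile_low = 1, percentile_high = 99) {
  stopifnot(n_reps >= 1, sample_size >= 4,
            percentile_low >= 0, percentile_high <= 100,
            percentile_low < percentile_high)
  structure(list(n_reps = as.integer(n_reps),
                 sample_size = as.integer(sample_size), seed = seed,
                 percentile_low = percentile_low,
                 percentile_high = percentile_high),
            class = "bootstrap_config")
}

#' Resample units with probability proportional to stock
#'
#' Draws `sample_size` rows with replacement, each draw selecting unit *i*
#' with probability stock_i / total stock, so populous producers dominate the
#' resampled fits. Uses the current RNG state.
#'
#' @param records Data frame with a `stock` column (head counts, >= 0).
#' @param sample_size Number of draws.
#' @return A data frame of `sample_size` resampled rows.
#' @export
weighted_resample <- function(records, sample_size) {
  stk <- records$stock
  if (is.null(stk) || any(!is.finite(stk)) || any(stk < 0))
    stop("'records$stock' must be finite and >= 0")
  if (sum(stk) <= 0) stop("total stock must be > 0 to resample")
  idx <- sample.int(nrow(records), size = sample_size, replace = TRUE,
                    prob = stk / sum(stk))
  records[idx, , drop = FALSE]
}

#' Stock-weighted bootstrap of a share-curve fit
#'
#' Repeats `config$n_reps` times: resample `config$sample_size` observed
#' units with stock-proportional probability, refit the share curve, keep the
#' replicate if the fit converged (failed or non-converged replicates are
#' discarded and counted), and evaluate the converged curve at the log10 GDP
#' of every unit in `newdata`.
#'
#' @param records Data frame with `gdp_ppp_usd`, `stock` and the observed
#'   share column for `target`; only rows with an observed value enter the
#'   resampling pool.
#' @param target,form As in [fit_share_curve()].
#' @param config A [bootstrap_config()].
#' @param newdata Units at which to evaluate each replicate curve (default:
#'   all of `records`). Must have `unit_id` and `gdp_ppp_usd`.
#' @return A `bootstrap_ensemble`: list with `params` (data frame: replicate,
#'   mu, lambda, alpha, rss, all converged), `predictions` (units x converged
#'   replicates matrix), `unit_ids`, `n_discarded`, `target`, `form`,
#'   `config`.
#' @export
run_bootstrap <- function(records, target, config = bootstrap_config(),
                          form = c("as_printed", "bounded"),
                          newdata = records) {
  form <- match.arg(form)
  info <- target_info(target)
  obs <- observed_subset(records, target)
  if (nrow(obs) == 0) stop("no records with observed shares for ", target)
  if (!is.null(config$seed)) set.seed(config$seed)
  g_new <- gdp_log10(newdata$gdp_ppp_usd)

  keep <- vector("list", config$n_reps)
  n_disc <- 0L
  for (r in seq_len(config$n_reps)) {
    samp <- weighted_resample(obs, config$sample_size)
    fit <- tryCatch(fit_share_curve(samp, target, form = form),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_disc <- n_disc + 1L
      next
    }
    keep[[r]] <- c(replicate = r, mu = fit$params$mu,
                   lambda = fit$params$lambda, alpha = fit$params$alpha,
                   rss = fit$rss)
  }
  keep <- keep[!vapply(keep, is.null, logical(1))]
  if (length(keep) < config$n_reps / 2)
    stop(sprintf("only %d of %d bootstrap replicates converged; ensemble unreliable",
                 length(keep), config$n_reps))
  par_df <- as.data.frame(do.call(rbind, keep))

  pred <- matrix(NA_real_, nrow = length(g_new), ncol = nrow(par_df),
                 dimnames = list(as.character(newdata$unit_id), NULL))
  for (k in seq_len(nrow(par_df))) {
    prm <- share_params(par_df$mu[k], par_df$lambda[k], par_df$alpha[k])
    pred[, k] <- info$fun(g_new, prm, form)
  }
  structure(list(params = par_df, predictions = pred,
                 unit_ids = newdata$unit_id, n_discarded = n_disc,
                 target = target, form = form, config = config),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap_ensemble [%s]: %d converged replicates (%d discarded), %d units\n",
              x$target, nrow(x$params), x$n_discarded, length(x$unit_ids)))
  invisible(x)
}

#' Final per-unit share from a bootstrap ensemble
#'
#' Applies the retention/clipping rule: a unit without an observed value gets
#' the median of its per-unit bootstrap predictions; an observed value is
#' retained if it falls inside the ensemble's percentile envelope (by default
#' 1st-99th, linearly interpolated between order statistics), and is
#' otherwise replaced by the nearer envelope bound. This filters extreme
#' data-mined observations while keeping credible ones.
#'
#' @param ensemble A [run_bootstrap()] result.
#' @param unit_id Unit to predict (must be in `ensemble$unit_ids`).
#' @param observed Observed proportion in \[0, 1\], or `NA`/`NULL` if
#'   unobserved.
#' @return List with `share`, `provenance` (one of `"predicted"`,
#'   `"observed_retained"`, `"clipped_low"`, `"clipped_high"`), `median`,
#'   `lower`, `upper`.
#' @export
predict_unit_share <- function(ensemble, unit_id, observed = NULL) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  i <- match(as.character(unit_id), as.character(ensemble$unit_ids))
  if (is.na(i)) stop("unit '", unit_id, "' not in ensemble")
  preds <- ensemble$predictions[i, ]
  qs <- stats::quantile(preds, c(ensemble$config$percentile_low,
                                 ensemble$config$percentile_high) / 100,
                        names = FALSE, type = 7)
  if (is.null(observed) || is.na(observed)) {
    list(share = stats::median(preds), provenance = "predicted",
         median = stats::median(preds), lower = qs[1], upper = qs[2])
  } else if (observed < qs[1]) {
    list(share = qs[1], provenance = "clipped_low",
         median = stats::median(preds), lower = qs[1], upper = qs[2])
  } else if (observed > qs[2]) {
    list(share = qs[2], provenance = "clipped_high",
         median = stats::median(preds), lower = qs[1], upper = qs[2])
  } else {
    list(share = observed, provenance = "observed_retained",
         median = stats::median(preds), lower = qs[1], upper = qs[2])
  }
}

#' Final shares for every unit of an ensemble
#'
#' Vectorised [predict_unit_share()] over all units, pairing each with its
#' observed value from `records` (matched by `unit_id`).
#'
#' @inheritParams predict_unit_share
#' @param records Data frame with `unit_id` and the observed column for the
#'   ensemble's target.
#' @return Data frame: `unit_id`, `median`, `lower`, `upper`, `final_share`,
#'   `provenance`.
#' @export
predict_all_units <- function(ensemble, records) {
  col <- target_info(ensemble$target)$col
  obs <- records[[col]][match(as.character(ensemble$unit_ids),
                              as.character(records$unit_id))]
  out <- lapply(seq_along(ensemble$unit_ids), function(i) {
    p <- predict_unit_share(ensemble, ensemble$unit_ids[i], obs[i])
    data.frame(unit_id = ensemble$unit_ids[i], median = p$median,
               lower = p$lower, upper = p$upper, final_share = p$share,
               provenance = p$provenance)
  })
  do.call(rbind, out)
}

#' Persist a bootstrap ensemble as CSV
#'
#' Writes the replicate parameter table and, optionally, the per-unit
#' prediction summary produced by [predict_all_units()].
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @param params_path CSV path for replicate parameters.
#' @param predictions_path Optional CSV path for per-unit predictions
#'   (requires `records`).
#' @param records Country table used for observed values.
#' @return `params_path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, params_path, predictions_path = NULL,
                               records = NULL) {
  utils::write.csv(ensemble$params, params_path, row.names = FALSE)
  if (!is.null(predictions_path)) {
    if (is.null(records)) stop("'records' needed to write predictions")
    utils::write.csv(predict_all_units(ensemble, records), predictions_path,
                     row.names = FALSE)
  }
  invisible(params_path)
}
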