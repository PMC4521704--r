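target_info <- function(target) {
  switch(target,
    chicken_ext = list(col = "observed_p_ext", n_par = 2L,
                       fun = function(g, p, form) p_ext_chicken(g, p)),
    pig_ext     = list(col = "observed_p_ext", n_par = 3L,
                       fun = function(g, p, form) p_ext_pig(g, p)),
    pig_int     = list(col = "observed_p_int", n_par = 3L,
                       fun = function(g, p, form) p_int_pig(g, p, form)),
    stop("unknown target: ", target))
}

observed_subset <- function(records, target) {
  info <- target_info(target)
  if (!info$col %in% names(records))
    stop("country table lacks column '", info$col, "'")
  ok <- is.finite(records[[info$col]])
  records[ok, , drop = FALSE]
}

#' Fit a share curve to observed country-level proportions
#'
#' Estimates the parameters of one bounded logistic share curve by nonlinear
#' least squares (bounded Levenberg-Marquardt via \pkg{minpack.lm}),
#' minimising the sum of squared differences between observed proportions and
#' the curve evaluated at each unit's log10 GDP per capita.
#'
#' Default starting values are `lambda` at the median observed log10 GDP,
#' `mu = -1`, and for pig curves `alpha` at the largest observed share plus
#' 0.05 (capped at 1). `alpha` is constrained to (0, 1]; `mu` and `lambda`
#' are unconstrained, so the fitted direction of the curve is determined by
#' the data. Non-convergence is reported through the `converged` flag rather
#' than an error, so ensemble callers can discard failed fits.
#'
#' @param records Data frame with columns `gdp_ppp_usd` and, depending on
#'   `target`, `observed_p_ext` or `observed_p_int` (`NA` = unobserved).
#' @param target One of `"chicken_ext"`, `"pig_ext"`, `"pig_int"`: which
#'   share the curve describes. Chicken curves have 2 free parameters
#'   (`alpha` fixed at 1); pig curves have 3.
#' @param init Optional [share_params()] starting values.
#' @param lower,upper Optional named numeric bounds on `mu`, `lambda`,
#'   `alpha` (defaults: `alpha` in \[1e-6, 1\], others unbounded).
#' @param form Intensive-curve form passed to [p_int_pig()]; ignored for the
#'   extensive targets.
#' @param ftol Relative tolerance on the residual sum of squares
#'   (default 1e-10).
#' @return An object of class `share_fit`: list with `params`
#'   ([share_params()]), `target`, `form`, `rss`, `n`, `converged`,
#'   `std_errors` (named, `NA` if unavailable), and the optimizer `message`.
#' @examples
#' tab <- data.frame(gdp_ppp_usd = 10^seq(2.8, 4.6, length.out = 30))
#' tab$observed_p_ext <- p_ext_chicken(log10(tab$gdp_ppp_usd),
#'                                     share_params(-1.2, 3.9))
#' fit_share_curve(tab, "chicken_ext")$params
#' @export
fit_share_curve <- function(records, target = c("chicken_ext", "pig_ext", "pig_int"),
                            init = NULL, lower = NULL, upper = NULL,
                            form = c("as_printed", "bounded"), ftol = 1e-10) {
  target <- match.arg(target)
  form <- match.arg(form)
  info <- target_info(target)
  obs <- observed_subset(records, target)
  g <- gdp_log10(obs$gdp_ppp_usd)
  y <- obs[[info$col]]
  if (any(!is.finite(y))) stop("observed shares must be finite")
  n_min <- if (info$n_par == 2L) 4L else 5L
  if (length(unique(g)) < n_min)
    stop(sprintf("need >= %d records with distinct GDP values to fit '%s' (got %d)",
                 n_min, target, length(unique(g))))

  free_alpha <- info$n_par == 3L
  if (is.null(init)) {
    # alpha bounds the share from above, except in the printed intensive
    # form where 1 - alpha is its floor
    a0 <- if (!free_alpha) 1
          else if (target == "pig_int" && form == "as_printed")
            min(1, 1 - min(y) + 0.05)
          else min(1, max(y) + 0.05)
    init <- share_params(mu = -1, lambda = stats::median(g), alpha = max(a0, 0.05))
  }
  lo <- c(mu = -Inf, lambda = -Inf)
  hi <- c(mu = Inf, lambda = Inf)
  if (free_alpha) {
    lo <- c(lo, alpha = 1e-6)
    hi <- c(hi, alpha = 1)
  }
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  # the alpha profile can trap the optimizer at its bound, so 3-parameter
  # fits are multi-started over a few alpha values; the best converged
  # solution wins
  alpha_starts <- if (free_alpha) {
    cand <- if (target == "pig_int" && form == "as_printed") {
      c(init$alpha, 1 - min(y), 0.95 * (1 - min(y)) + 0.05)
    } else {
      c(init$alpha, max(y), 0.9 * max(y))
    }
    unique(pmin(pmax(cand, lo[["alpha"]]), hi[["alpha"]]))
  } else NA_real_

  resid_fn <- function(p) {
    a <- if (free_alpha) p[["alpha"]] else 1
    prm <- structure(list(mu = p[["mu"]], lambda = p[["lambda"]], alpha = a),
                     class = "share_params")
    y - info$fun(g, prm, form)
  }
  res <- NULL
  for (a_start in alpha_starts) {
    par0 <- c(mu = init$mu, lambda = init$lambda)
    par0 <- pmin(pmax(par0, lo[c("mu", "lambda")]), hi[c("mu", "lambda")])
    if (free_alpha) par0 <- c(par0, alpha = a_start)
    cand <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = 1e-10, maxiter = 200)),
      error = function(e) e)
    if (inherits(cand, "error")) {
      if (is.null(res)) res <- cand
      next
    }
    if (inherits(res, "error") || is.null(res) ||
        (cand$info %in% 1:4 && cand$deviance < res$deviance - 1e-15) ||
        (!res$info %in% 1:4 && cand$info %in% 1:4))
      res <- cand
  }

  if (inherits(res, "error")) {
    return(structure(list(params = init, target = target, form = form,
                          rss = NA_real_, n = length(g), converged = FALSE,
                          std_errors = NULL, message = conditionMessage(res)),
                     class = "share_fit"))
  }
  p <- res$par
  params <- share_params(mu = unname(p[["mu"]]), lambda = unname(p[["lambda"]]),
                         alpha = if (free_alpha) unname(p[["alpha"]]) else 1)
  converged <- res$info %in% 1:4
  se <- tryCatch({
    cf <- summary(res)$coefficients
    stats::setNames(cf[, "Std. Error"], rownames(cf))
  }, error = function(e) NULL)
  if (is.null(se) && converged && length(g) > length(p)) {
    # parameters at a bound zero their hessian row; fall back to a
    # finite-difference jacobian and a pseudo-inverse of J'J
    J <- vapply(seq_along(p), function(j) {
      h <- 1e-6 * max(1, abs(p[j]))
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      (resid_fn(pp) - resid_fn(pm)) / (2 * h)
    }, numeric(length(g)))
    s2 <- res$deviance / (length(g) - length(p))
    sv <- svd(crossprod(J))
    pos <- sv$d > max(sv$d) * 1e-12
    vc <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos]) * s2
    se <- stats::setNames(sqrt(pmax(diag(vc), 0)), names(p))
  }
  structure(list(params = params, target = target, form = form,
                 rss = res$deviance, n = length(g), converged = converged,
                 std_errors = se, message = res$message),
            class = "share_fit")
}

#' @export
print.share_fit <- function(x, ...) {
  cat(sprintf("share_fit [%s%s]: mu = %.4f, lambda = %.4f, alpha = %.4f\n",
              x$target, if (x$target == "pig_int") paste0(", ", x$form) else "",
              x$params$mu, x$params$lambda, x$params$alpha))
  cat(sprintf("  n = %d, rss = %.6g, converged = %s\n", x$n, x$rss, x$converged))
  invisible(x)
}

#' Write fitted share-curve parameters to JSON
#'
#' @param fit A `share_fit` object.
#' @param path Output file path.
#' @param species Species label stored alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, species = NA_character_) {
  stopifnot(inherits(fit, "share_fit"))
  jsonlite::write_json(
    list(species = species, target = fit$target, form = fit$form,
         mu = fit$params$mu, lambda = fit$params$lambda,
         alpha = fit$params$alpha, rss = fit$rss, n = fit$n,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
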