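#' Parameters of a bounded logistic share curve
#'
#' A share curve links the log10 GDP per capita (purchasing power parity, PPP)
#' of an administrative unit to the proportion of its chicken or pig stock
#' raised under a given production system. The curve is parameterised so that
#' `mu` is the slope of the share with respect to log10-GDP at the curve's
#' midpoint, `lambda` positions the curve along the GDP axis, and `alpha` is
#' the asymptotic bound of the share (fixed to 1 for chickens, free in (0, 1]
#' for pigs).
#'
#' @param mu Midpoint slope per log10-USD. Negative for shares that decline
#'   with rising GDP (the extensive share). Must be non-zero.
#' @param lambda Position parameter, in log10-USD. Must be finite.
#' @param alpha Asymptotic bound of the share, in (0, 1]. Defaults to 1.
#' @return An object of class `share_params`.
#' @examples
#' share_params(mu = -1.2, lambda = 3.9)
#' @export
share_params <- function(mu, lambda, alpha = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (mu == 0) stop("'mu' must be non-zero")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  structure(list(mu = mu, lambda = lambda, alpha = alpha),
            class = "share_params")
}

#' @export
print.share_params <- function(x, ...) {
  cat(sprintf("share curve: mu = %g, lambda = %g, alpha = %g\n",
              x$mu, x$lambda, x$alpha))
  invisible(x)
}

check_g <- function(g) {
  if (!is.numeric(g) || any(!is.finite(g)))
    stop("'g' (log10 GDP per capita) must be finite numeric")
  g
}

#' Convert GDP per capita to the log10 scale used by the share curves
#'
#' @param gdp_ppp GDP per capita in USD (purchasing power parity); must be > 0.
#' @return log10 of `gdp_ppp`.
#' @export
gdp_log10 <- function(gdp_ppp) {
  if (!is.numeric(gdp_ppp) || any(!is.finite(gdp_ppp)) || any(gdp_ppp <= 0))
    stop("GDP per capita must be finite and > 0")
  log10(gdp_ppp)
}

#' Extensive share curve for chickens
#'
#' Proportion of chickens raised in extensive (backyard, FAO sector 4)
#' systems as a function of log10 GDP per capita:
#' \deqn{P_{ext} = 1 / (1 + e^{4\mu(\lambda - g) + 2})}
#' With `mu < 0` the share declines from 1 towards 0 as GDP rises; the slope
#' at the midpoint (share 1/2, reached at \eqn{g = \lambda + 1/(2\mu)}) equals
#' `mu`, and the share at \eqn{g = \lambda} equals \eqn{1/(1+e^2)}.
#'
#' @param g log10 GDP per capita (PPP); numeric vector, finite.
#' @param params A [share_params()] object; `alpha` must be 1.
#' @return Proportion(s) in (0, 1).
#' @export
p_ext_chicken <- function(g, params) {
  stopifnot(inherits(params, "share_params"))
  if (params$alpha != 1)
    stop("chicken extensive curve has no free bound; 'alpha' must be 1")
  check_g(g)
  1 / (1 + exp(4 * params$mu * (params$lambda - g) + 2))
}

#' Extensive share curve for pigs
#'
#' Proportion of pigs raised in extensive systems (unconfined, typically
#' fewer than 10 animals, scavenging feed), bounded above by `alpha`:
#' \deqn{P_{ext} = \alpha / (1 + e^{4(\mu/\alpha)(\lambda - g) + 2})}
#' The \eqn{\mu/\alpha} scaling keeps `mu` equal to the slope at the
#' half-range point (share \eqn{\alpha/2}, at \eqn{g = \lambda +
#' \alpha/(2\mu)}). With `alpha = 1` the curve reduces exactly to
#' [p_ext_chicken()].
#'
#' @inheritParams p_ext_chicken
#' @param params A [share_params()] object with `alpha` in (0, 1].
#' @return Proportion(s) in (0, alpha).
#' @export
p_ext_pig <- function(g, params) {
  stopifnot(inherits(params, "share_params"))
  check_g(g)
  a <- params$alpha
  a / (1 + exp(4 * (params$mu / a) * (params$lambda - g) + 2))
}

#' Intensive share curve for pigs
#'
#' Proportion of pigs raised in intensive systems (confined, typically more
#' than 100 animals, purchased feed). Two algebraic forms are offered because
#' the roles of the bound differ:
#' \describe{
#'   \item{`as_printed`}{\eqn{P_{int} = 1 - \alpha/(1 + e^{u})} with
#'     \eqn{u = 4(\mu/\alpha)(\lambda - g) + 2}; ranges over
#'     \eqn{(1-\alpha, 1)}, i.e. has a *floor* of \eqn{1-\alpha} at low GDP.}
#'   \item{`bounded`}{\eqn{P_{int} = \alpha/(1 + e^{-u})}; ranges over
#'     \eqn{(0, \alpha)}, i.e. `alpha` is a *ceiling*, rising from 0 at low
#'     GDP.}
#' }
#' Both are monotone increasing in `g` when `mu < 0`, with half-range slope
#' `-mu`. The default is `as_printed`.
#'
#' @inheritParams p_ext_pig
#' @param form Which algebraic form to evaluate; see Details.
#' @return Proportion(s) in \eqn{(1-\alpha, 1)} (`as_printed`) or
#'   \eqn{(0, \alpha)} (`bounded`).
#' @export
p_int_pig <- function(g, params, form = c("as_printed", "bounded")) {
  stopifnot(inherits(params, "share_params"))
  form <- match.arg(form)
  check_g(g)
  a <- params$alpha
  u <- 4 * (params$mu / a) * (params$lambda - g) + 2
  if (form == "as_printed") {
    1 - a / (1 + exp(u))
  } else {
    # algebraically alpha * e^u / (1 + e^u); this form is stable for large u
    a / (1 + exp(-u))
  }
}

#' System shares for chickens at given GDP levels
#'
#' Chickens are split into two systems only: the intensive share is the
#' complement of the extensive share, and the semi-intensive share is
#' identically zero.
#'
#' @inheritParams p_ext_chicken
#' @return A data frame with columns `p_ext`, `p_sint`, `p_int`, one row per
#'   element of `g`; rows sum to 1.
#' @export
shares_chicken <- function(g, params) {
  pe <- p_ext_chicken(g, params)
  data.frame(p_ext = pe, p_sint = 0, p_int = 1 - pe)
}

#' System shares for pigs at given GDP levels
#'
#' The extensive and intensive shares come from their fitted curves; the
#' semi-intensive share is the residual \eqn{1 - (P_{ext} + P_{int})}. Where
#' the two fitted curves overlap enough to drive this residual negative, it
#' is clamped to zero and the extensive and intensive shares are rescaled
#' proportionally so the three sum to 1; a warning reports how many units
#' were clamped.
#'
#' @inheritParams p_int_pig
#' @param ext_params [share_params()] for the extensive curve.
#' @param int_params [share_params()] for the intensive curve.
#' @return A data frame with columns `p_ext`, `p_sint`, `p_int`; rows sum
#'   to 1 exactly.
#' @export
shares_pig <- function(g, ext_params, int_params,
                       form = c("as_printed", "bounded")) {
  form <- match.arg(form)
  pe <- p_ext_pig(g, ext_params)
  pi_ <- p_int_pig(g, int_params, form)
  ps <- 1 - (pe + pi_)
  neg <- ps < 0
  if (any(neg)) {
    warning(sprintf(
      "semi-intensive share negative for %d unit(s); clamped to 0 and renormalized",
      sum(neg)))
    tot <- pe[neg] + pi_[neg]
    pe[neg] <- pe[neg] / tot
    pi_[neg] <- pi_[neg] / tot
    ps[neg] <- 0
  }
  data.frame(p_ext = pe, p_sint = ps, p_int = pi_)
}
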