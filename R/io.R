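#' Read a country/province table from CSV
#'
#' Expected columns: `unit_id`, `gdp_ppp_usd`, `stock`, and optionally
#' `observed_p_ext` and `observed_p_int` (empty cells = unobserved).
#' Validates GDP positivity, non-negative stocks and share ranges, naming
#' the offending column or unit in errors.
#'
#' @param path CSV file path.
#' @return A validated data frame (missing observed columns added as `NA`).
#' @export
read_country_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_country_table(tab)
}

#' @rdname read_country_table
#' @param tab A data frame to validate in place of a file.
#' @export
validate_country_table <- function(tab) {
  for (col in c("unit_id", "gdp_ppp_usd", "stock"))
    if (!col %in% names(tab)) stop("country table missing column '", col, "'")
  for (col in c("observed_p_ext", "observed_p_int"))
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  if (any(!is.finite(tab$gdp_ppp_usd) | tab$gdp_ppp_usd <= 0))
    stop("gdp_ppp_usd must be > 0 (unit ",
         tab$unit_id[which(!is.finite(tab$gdp_ppp_usd) | tab$gdp_ppp_usd <= 0)[1]],
         ")")
  if (any(!is.finite(tab$stock) | tab$stock < 0))
    stop("stock must be >= 0 (unit ",
         tab$unit_id[which(!is.finite(tab$stock) | tab$stock < 0)[1]], ")")
  for (col in c("observed_p_ext", "observed_p_int")) {
    bad <- !is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 1)
    if (any(bad))
      stop(col, " outside [0, 1] (unit ", tab$unit_id[which(bad)[1]], ")")
  }
  tab
}

#' Meat productivity versus GDP per capita
#'
#' Productivity is annual meat output per animal, 1000 x production (metric
#' tons) / stock (head), in kg per head per year. Units with zero stock are
#' excluded. Reports the Pearson correlation between log10 productivity and
#' log10 GDP per capita (`NA` when fewer than 3 usable units).
#'
#' @param units Data frame with `unit_id`, `gdp_ppp_usd`, `stock`,
#'   `production_tonnes`.
#' @return List with `table` (per-unit productivity) and `correlation`.
#' @export
productivity_report <- function(units) {
  for (col in c("gdp_ppp_usd", "stock", "production_tonnes"))
    if (!col %in% names(units)) stop("missing column '", col, "'")
  keep <- units$stock > 0
  tab <- units[keep, , drop = FALSE]
  tab$productivity_kg_per_head <- 1000 * tab$production_tonnes / tab$stock
  r <- if (nrow(tab) >= 3) {
    stats::cor(log10(tab$productivity_kg_per_head), log10(tab$gdp_ppp_usd))
  } else NA_real_
  list(table = tab, correlation = r)
}

#' Write the per-unit conservation ledger as CSV
#'
#' @param result A [disaggregate_species()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(result, path) {
  stopifnot(inherits(result, "disaggregation"))
  utils::write.csv(result$ledger, path, row.names = FALSE)
  invisible(path)
}
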