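#' Dated tax regimes for a mixed cigarette excise structure
#'
#' UK-style cigarette taxation mixes a specific duty (pence per 1000 sticks),
#' an ad valorem duty levied as a fraction of the tax-inclusive retail selling
#' price, and VAT. A regime schedule is a tibble of dated parameter sets; the
#' regime in force at a date is the one with the latest effective date not
#' after it.
#'
#' A regime is valid only if `ad_valorem_rate + vat_rate / (1 + vat_rate) < 1`;
#' otherwise every retail price yields non-positive net-of-tax revenue and the
#' regime is rejected at construction.
#'
#' @param effective_from `Date` vector (coerced via `as.Date()`) of effective
#'   dates, strictly increasing.
#' @param specific_duty Specific duty in pence per 1000 sticks, `>= 0`.
#' @param ad_valorem_rate Ad valorem rate as a fraction of the tax-inclusive
#'   retail price, in `[0, 1)`.
#' @param vat_rate VAT rate (applied on the pre-VAT price), in `[0, 1)`.
#' @return A tibble with class `regime_schedule` and one row per regime.
#' @examples
#' sched <- regime_schedule(
#'   effective_from  = as.Date(c("2008-04-01", "2008-12-01")),
#'   specific_duty   = c(11200, 11200),
#'   ad_valorem_rate = c(0.22, 0.22),
#'   vat_rate        = c(0.175, 0.15)
#' )
#' regime_at(sched, as.Date("2008-06-01"))
#' @export
regime_schedule <- function(effective_from, specific_duty, ad_valorem_rate,
                            vat_rate) {
  sched <- tibble(
    effective_from = as.Date(effective_from),
    specific_duty = as.numeric(specific_duty),
    ad_valorem_rate = as.numeric(ad_valorem_rate),
    vat_rate = as.numeric(vat_rate)
  )
  validate_regime_schedule(sched)
}

validate_regime_schedule <- function(sched) {
  if (nrow(sched) == 0) abort("A regime schedule must contain at least one regime.")
  required <- c("effective_from", "specific_duty", "ad_valorem_rate", "vat_rate")
  missing <- setdiff(required, names(sched))
  if (length(missing) > 0) {
    abort(paste0("Regime schedule is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(sched[required])) abort("Regime schedule contains missing values.")
  if (any(sched$specific_duty < 0)) abort("specific_duty must be >= 0.")
  if (any(sched$ad_valorem_rate < 0 | sched$ad_valorem_rate >= 1)) {
    abort("ad_valorem_rate must lie in [0, 1).")
  }
  if (any(sched$vat_rate < 0 | sched$vat_rate >= 1)) {
    abort("vat_rate must lie in [0, 1).")
  }
  keep <- sched$ad_valorem_rate + sched$vat_rate / (1 + sched$vat_rate)
  if (any(keep >= 1)) {
    abort(paste0(
      "Invalid regime(s) effective ",
      paste(sched$effective_from[keep >= 1], collapse = ", "),
      ": ad_valorem_rate + vat_rate/(1+vat_rate) must be < 1, otherwise ",
      "net-of-tax revenue is non-positive at every price."
    ))
  }
  if (is.unsorted(sched$effective_from, strictly = TRUE)) {
    abort("effective_from dates must be strictly increasing.")
  }
  class(sched) <- unique(c("regime_schedule", class(sched)))
  sched
}

#' Read a regime schedule from CSV
#'
#' Expected columns: `effective_from` (ISO-8601 date),
#' `specific_duty_per_1000`, `ad_valorem_rate`, `vat_rate`. Lines starting
#' with `#` are treated as comments.
#'
#' @param path Path to a CSV file.
#' @return A validated [regime_schedule()] tibble.
#' @export
read_regime_schedule <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  required <- c("effective_from", "specific_duty_per_1000", "ad_valorem_rate",
                "vat_rate")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  regime_schedule(
    effective_from = as.Date(raw$effective_from),
    specific_duty = raw$specific_duty_per_1000,
    ad_valorem_rate = raw$ad_valorem_rate,
    vat_rate = raw$vat_rate
  )
}

#' Write a regime schedule to CSV
#'
#' @param sched A [regime_schedule()] tibble.
#' @param path Output path.
#' @param header Optional character vector of comment lines written (prefixed
#'   with `#`) before the CSV.
#' @return `path`, invisibly.
#' @export
write_regime_schedule <- function(sched, path, header = NULL) {
  out <- tibble(
    effective_from = sched$effective_from,
    specific_duty_per_1000 = sched$specific_duty,
    ad_valorem_rate = sched$ad_valorem_rate,
    vat_rate = sched$vat_rate
  )
  write_csv_with_header(out, path, header)
}

#' Look up the regime in force at a date
#'
#' @param sched A [regime_schedule()] tibble.
#' @param date A single `Date` (or coercible string).
#' @return A one-row tibble: the regime with the latest `effective_from` at
#'   or before `date`.
#' @export
regime_at <- function(sched, date) {
  date <- as.Date(date)
  stopifnot(length(date) == 1)
  idx <- which(sched$effective_from <= date)
  if (length(idx) == 0) {
    abort(paste0(
      "No regime in force at ", format(date), ": the schedule starts at ",
      format(min(sched$effective_from)), "."
    ))
  }
  dplyr::slice(as_tibble(sched), max(idx))
}

#' Per-pack tax breakdown at a retail price
#'
#' Decomposes a tax-inclusive retail price into its specific-duty, ad valorem
#' and VAT components and the net-of-tax revenue retained by manufacturer and
#' retailer. The ad valorem duty is levied on the tax-inclusive retail selling
#' price (the EU convention); VAT is extracted from the tax-inclusive price as
#' `price * v / (1 + v)` because input prices are retail, i.e. already include
#' VAT.
#'
#' @param price Retail price(s) in pence per pack, `> 0`. Vectorised.
#' @param regime A one-row regime (from [regime_at()] or a one-row
#'   [regime_schedule()]).
#' @param pack_size Sticks per pack (default 20; UK packs are 20s, or 19s for
#'   a few brands).
#' @return A tibble with columns `specific`, `ad_valorem`, `vat`, `total` and
#'   `net_revenue`, all in pence per pack; `total = specific + ad_valorem +
#'   vat` and `net_revenue = price - total`.
#' @examples
#' r <- regime_schedule("2009-04-01", 11431, 0.24, 0.175)
#' tax_breakdown(500, r)
#' @export
tax_breakdown <- function(price, regime, pack_size = 20) {
  regime <- as_regime(regime)
  if (any(price <= 0)) abort("price must be positive (pence per pack).")
  if (any(pack_size <= 0)) abort("pack_size must be positive.")
  specific <- regime$specific_duty * pack_size / 1000
  ad_valorem <- regime$ad_valorem_rate * price
  vat <- price * regime$vat_rate / (1 + regime$vat_rate)
  total <- specific + ad_valorem + vat
  tibble(
    specific = specific + numeric(length(price)),
    ad_valorem = ad_valorem,
    vat = vat,
    total = total,
    net_revenue = price - total
  )
}

#' Retail price achieving a target net-of-tax revenue
#'
#' Inverts [tax_breakdown()]: the price whose net-of-tax revenue equals
#' `target_net` under the given regime. Closed form:
#' `P = (target_net + specific_duty * pack_size / 1000) /
#'  (1 - ad_valorem_rate - vat_rate / (1 + vat_rate))`.
#'
#' @inheritParams tax_breakdown
#' @param target_net Target net-of-tax revenue in pence per pack. Vectorised.
#' @return Price(s) in pence per pack.
#' @examples
#' r <- regime_schedule("2009-04-01", 11431, 0.24, 0.175)
#' p <- price_for_net_revenue(76.91, r)
#' tax_breakdown(p, r)$net_revenue # 76.91
#' @export
price_for_net_revenue <- function(target_net, regime, pack_size = 20) {
  regime <- as_regime(regime)
  keep_rate <- 1 - regime$ad_valorem_rate -
    regime$vat_rate / (1 + regime$vat_rate)
  (target_net + regime$specific_duty * pack_size / 1000) / keep_rate
}

#' Specific share of the total tax burden
#'
#' Fraction of the per-pack tax burden (excise plus VAT) accounted for by the
#' specific duty. A higher specific share narrows the absolute price gap
#' between cheap and expensive brands for a given total burden.
#'
#' @param breakdown A tibble from [tax_breakdown()].
#' @return Numeric vector in `[0, 1]`.
#' @export
specific_share <- function(breakdown) {
  if (any(breakdown$total <= 0)) {
    abort("specific_share is undefined where the total tax burden is zero.")
  }
  breakdown$specific / breakdown$total
}

as_regime <- function(regime) {
  if (is.data.frame(regime)) {
    if (nrow(regime) != 1) {
      abort("Expected a single regime (one row); use regime_at() to select one.")
    }
    return(regime)
  }
  abort("regime must be a one-row data frame with regime columns.")
}
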