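#' Brand-level price/share scatter analyses
#'
#' Two diagnostics of pricing strategy at brand level between two periods.
#' `price_change_vs_initial_share()` plots each brand's real price change
#' (per cent, the brand's own prices deflated) against its initial market
#' share (per cent) — probing whether high-share brands take larger price
#' increases. `share_change_vs_price_change()` plots the change in market
#' share (percentage points) against the real price change (per cent) —
#' probing downtrading: whether brands that got relatively cheaper gained
#' share. Each returns the scatter points plus a rank (Spearman) correlation
#' summary; Pearson is available via `method`.
#'
#' Brands missing either endpoint are excluded and counted in
#' `n_excluded`. If either variable is constant across brands the
#' correlation is undefined and reported as `NA` with a `degenerate` flag.
#'
#' @param panel A panel tibble with `segment` assigned.
#' @param cpi An [index_series()] for deflating brand prices.
#' @param t0,t1 Period labels (initial, final).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param oct_2005 Passed to [period_date()].
#' @return An object of class `market_scatter`: a list with `points`
#'   (tibble `brand_id, segment, x, y`), `estimate`, `p.value`, `method`,
#'   `n`, `n_excluded`, `degenerate`, and axis labels. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
price_change_vs_initial_share <- function(panel, cpi, t0, t1,
                                          method = c("spearman", "pearson"),
                                          oct_2005 = FALSE) {
  method <- match.arg(method)
  ends <- brand_endpoints(panel, cpi, t0, t1, oct_2005)
  points <- tibble(
    brand_id = ends$matched$brand_id,
    segment = ends$matched$segment,
    x = 100 * ends$matched$share0,
    y = 100 * (ends$matched$real1 / ends$matched$real0 - 1)
  )
  new_market_scatter(points, method, ends$n_excluded,
                     xlab = paste0("market share at ", t0, " (%)"),
                     ylab = paste0("real price change ", t0, "-", t1, " (%)"))
}

#' @rdname price_change_vs_initial_share
#' @export
share_change_vs_price_change <- function(panel, cpi, t0, t1,
                                         method = c("spearman", "pearson"),
                                         oct_2005 = FALSE) {
  method <- match.arg(method)
  ends <- brand_endpoints(panel, cpi, t0, t1, oct_2005)
  points <- tibble(
    brand_id = ends$matched$brand_id,
    segment = ends$matched$segment,
    x = 100 * (ends$matched$real1 / ends$matched$real0 - 1),
    y = 100 * (ends$matched$share1 - ends$matched$share0)
  )
  new_market_scatter(points, method, ends$n_excluded,
                     xlab = paste0("real price change ", t0, "-", t1, " (%)"),
                     ylab = paste0("market share change ", t0, "-", t1,
                                   " (percentage points)"))
}

brand_endpoints <- function(panel, cpi, t0, t1, oct_2005 = FALSE) {
  if (!"segment" %in% names(panel)) panel$segment <- "unassigned"
  ends <- panel |>
    dplyr::filter(.data$period %in% c(t0, t1)) |>
    dplyr::mutate(real_price = deflate(
      .data$nominal_price, period_date(.data$period, oct_2005 = oct_2005), cpi
    ))
  at0 <- dplyr::filter(ends, .data$period == t0)
  at1 <- dplyr::filter(ends, .data$period == t1)
  matched <- dplyr::inner_join(
    dplyr::select(at0, "brand_id", "segment", share0 = "volume_share",
                  real0 = "real_price"),
    dplyr::select(at1, "brand_id", share1 = "volume_share",
                  real1 = "real_price"),
    by = "brand_id"
  )
  n_excluded <- length(setdiff(
    union(at0$brand_id, at1$brand_id), matched$brand_id
  ))
  if (nrow(matched) == 0) {
    abort(paste0("No brand is observed at both ", t0, " and ", t1, "."))
  }
  list(matched = matched, n_excluded = n_excluded)
}

new_market_scatter <- function(points, method, n_excluded, xlab, ylab) {
  degenerate <- stats::sd(points$x) == 0 || stats::sd(points$y) == 0 ||
    nrow(points) < 3
  if (degenerate) {
    estimate <- NA_real_
    p.value <- NA_real_
  } else {
    ct <- suppressWarnings(
      cor.test(points$x, points$y, method = method, exact = FALSE)
    )
    estimate <- unname(ct$estimate)
    p.value <- ct$p.value
  }
  structure(
    list(points = points, estimate = estimate, p.value = p.value,
         method = method, n = nrow(points), n_excluded = n_excluded,
         degenerate = degenerate, xlab = xlab, ylab = ylab),
    class = "market_scatter"
  )
}

#' @export
print.market_scatter <- function(x, ...) {
  cat("Brand scatter analysis: ", x$ylab, " vs ", x$xlab, "\n", sep = "")
  if (x$degenerate) {
    cat("Correlation undefined (constant variable or n < 3); n =", x$n, "\n")
  } else {
    cat(sprintf("%s correlation = %.3f (p = %.3g), n = %d, excluded = %d\n",
                x$method, x$estimate, x$p.value, x$n, x$n_excluded))
  }
  invisible(x)
}

#' @rdname price_change_vs_initial_share
#' @param x A `market_scatter` object.
#' @param ... Unused.
#' @export
tidy.market_scatter <- function(x, ...) {
  x$points
}

#' @rdname price_change_vs_initial_share
#' @export
glance.market_scatter <- function(x, ...) {
  tibble(
    estimate = x$estimate, p.value = x$p.value, method = x$method,
    n = x$n, n_excluded = x$n_excluded, degenerate = x$degenerate
  )
}

#' @rdname price_change_vs_initial_share
#' @param object A `market_scatter` object.
#' @export
autoplot.market_scatter <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(
    x = .data$x, y = .data$y, colour = .data$segment
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$xlab, y = object$ylab, colour = "segment")
}
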