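#' Plot a fire-regime summary
#'
#' Two stacked panels: annual burned area (bars) with fire counts, and the
#' annual area-weighted mean dNBR with its OLS trend line.
#'
#' @param object a [fire_regime_summary()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fire_regime <- function(object, ...) {
  a <- object$annual %>%
    tidyr::pivot_longer(c("area_km2", "mean_dnbr"),
                        names_to = "panel", values_to = "value") %>%
    mutate(panel = dplyr::recode(.data$panel,
                                 area_km2 = "Burned area (km²)",
                                 mean_dnbr = "Area-weighted mean dNBR"))
  ggplot2::ggplot(a, ggplot2::aes(.data$year, .data$value)) +
    ggplot2::geom_col(data = ~ filter(.x, grepl("area", .data$panel)),
                      fill = "grey55") +
    ggplot2::geom_line(data = ~ filter(.x, grepl("dNBR", .data$panel))) +
    ggplot2::geom_smooth(data = ~ filter(.x, grepl("dNBR", .data$panel)),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL, title = "Fire regime") +
    ggplot2::theme_minimal()
}

#' Plot a severity-class chronosequence
#'
#' One panel per variable, one curve per dNBR class, against years since
#' fire — the standard way to read how fire effects decay with recovery.
#'
#' @param chron a [chronosequence()] table.
#' @param variables subset of variables to show (default all).
#' @return A ggplot object.
#' @export
plot_chronosequence <- function(chron, variables = NULL) {
  if (!is.null(variables)) {
    chron <- filter(chron, .data$variable %in% variables)
  }
  ggplot2::ggplot(chron,
                  ggplot2::aes(.data$years_since_fire, .data$diff,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "Years since fire", y = "Scenario difference",
                  colour = "dNBR class") +
    ggplot2::theme_minimal()
}

#' Plot a regional carbon-balance ledger
#'
#' Cumulative NEP (CB) and cumulative NEP minus direct emissions (CBF)
#' through time.
#'
#' @param object a [aggregate_region()] ledger.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.regional_ledger <- function(object, ...) {
  d <- as_tibble(object) %>%
    select("year", "cb", "cbf") %>%
    tidyr::pivot_longer(-"year", names_to = "series", values_to = "tg_c")
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$tg_c,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Year", y = "Tg C",
                  colour = NULL,
                  title = "Cumulative regional carbon balance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise a regional ledger
#'
#' @param x a [aggregate_region()] ledger.
#' @param ... unused.
#' @return One row: period, final CB, cumulative emissions, final CBF, and
#'   annualized rates.
#' @export
glance.regional_ledger <- function(x, ...) {
  n <- nrow(x)
  tibble(
    years = n,
    cb = x$cb[n], cum_emis = x$cum_emis[n], cbf = x$cbf[n],
    nep_rate = annualize(x$cb[n], n),
    emis_rate = annualize(x$cum_emis[n], n)
  )
}
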