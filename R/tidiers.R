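# Tidyverse-native accessors: tidy / glance / autoplot methods
#
# tidy() returns the observation-level tibble of a result object, glance()
# a one-row summary, autoplot() a ggplot. The generics are re-exported so
# downstream code needs only this package attached.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# ---- angle_series ----------------------------------------------------------

#' @export
tidy.angle_series <- function(x, ...) {
  tidyr::pivot_longer(x$angles, c("bending", "tilting"),
                      names_to = "metric", values_to = "angle")
}

#' @export
glance.angle_series <- function(x, ...) {
  mutate(x$pooled,
         n_interfaces = length(unique(x$angles$interface)),
         n_snapshots = max(x$angles$snapshot),
         n_outliers = sum(x$angles$outlier, na.rm = TRUE))
}

#' @export
autoplot.angle_series <- function(object, metric = c("bending", "tilting"),
                                  ...) {
  metric <- match.arg(metric)
  df <- tidy(object)
  df <- df[df$metric == metric, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps / 1000,
                                   y = .data$angle,
                                   colour = .data$interface)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(data = df[df$outlier, ], shape = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time (ns)",
                  y = paste(metric, "angle (deg)"),
                  colour = "interface") +
    ggplot2::theme_minimal()
}

# ---- pmf_curve -------------------------------------------------------------

#' @export
tidy.pmf_curve <- function(x, ...) x$curve

#' @export
glance.pmf_curve <- function(x, ...) {
  ok <- is.finite(x$curve$G)
  tibble(n_bins = nrow(x$curve), n_occupied = sum(ok),
         xi_min = min(x$curve$xi), xi_max = max(x$curve$xi),
         G_max = max(x$curve$G[ok]),
         temperature = x$temperature)
}

#' @export
autoplot.pmf_curve <- function(object, se = NULL, ...) {
  df <- object$curve[is.finite(object$curve$G), ]
  if (!is.null(se))
    df <- left_join(df, se, by = "xi")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$G))
  if (!is.null(se))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$G - .data$se,
                                               ymax = .data$G + .data$se),
                                  alpha = 0.25)
  if (!is.null(object$annotations))
    p <- p + ggplot2::geom_vline(data = object$annotations,
                                 ggplot2::aes(xintercept = .data$offset),
                                 linetype = 2, colour = "grey50")
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "order parameter (A)", y = "G (kJ/mol)") +
    ggplot2::theme_minimal()
}

# ---- residue_profile -------------------------------------------------------

#' @export
tidy.residue_profile <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.residue_profile <- function(x, ...) {
  tibble(metric = attr(x, "metric") %||% NA_character_,
         n_residues = length(unique(x$resno)),
         n_copies = nrow(x),
         value_min = min(x$value), value_max = max(x$value))
}

#' @export
autoplot.residue_profile <- function(object, mask = NULL, ...) {
  df <- tidy(object)
  if (!is.null(mask))
    df <- left_join(df, select(mask, "chain", "resno", "interface"),
                    by = c("chain", "resno"))
  aes <- if (is.null(mask))
    ggplot2::aes(x = .data$resno, y = .data$value)
  else
    ggplot2::aes(x = .data$resno, y = .data$value,
                 colour = .data$interface)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "residue",
                  y = attr(object, "metric") %||% "value") +
    ggplot2::theme_minimal()
}

# ---- interface_metrics / survey -------------------------------------------

#' @export
tidy.interface_metrics <- function(x, ...) x$pairs

#' @export
glance.interface_metrics <- function(x, ...) {
  tibble(d_lys = x$d_lys, d_lys_max = x$d_lys_max, spacing = x$spacing,
         lateral_offset = x$lateral_offset, arg_inserted = x$arg_inserted,
         saltbridge = x$saltbridge)
}

#' @export
tidy.arrangement_class <- function(x, ...) {
  mutate(glance(x$evidence), class = x$label, .before = 1)
}
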