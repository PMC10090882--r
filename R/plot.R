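#' Plot one comparison cell of a report
#'
#' Scatter of the (log10) measurements coloured by thermoregulatory class,
#' with the fitted group lines, and the fossil placement (point plus
#' soft-tissue corrected range) when available.
#'
#' @param object a `nasallom_report`.
#' @param region `"nasal"` or `"resp"`.
#' @param size_var size proxy column name.
#' @param response `"surface_area"` or `"volume"`.
#' @param method which fitted lines to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nasallom_report
#' @export
autoplot.nasallom_report <- function(object, region = "nasal",
                                     size_var = "skull_vol_mm3",
                                     response = "volume",
                                     method = "PGLS", ...) {
  yv <- response_column(region, response)
  dat <- object$data
  if (region == "resp" &&
      length(object$config$exclude_clades_respiratory)) {
    dat <- dat[!dat$clade %in% object$config$exclude_clades_respiratory, ]
  }
  fits <- object$fits[fits_match(object$fits, region, size_var, response,
                                 toupper(method)), ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[size_var]],
                                         y = .data[[yv]],
                                         colour = .data$thermo_class)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group)) +
    ggplot2::labs(x = paste0("log10 ", size_var),
                  y = paste0("log10 ", yv), colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$fossil) && region == "resp" && response == "volume") {
    fo <- object$fossil[object$fossil$size_var == size_var, ]
    if (nrow(fo)) {
      p <- p +
        ggplot2::geom_point(data = fo,
                            ggplot2::aes(x = .data$x, y = .data$y_bony),
                            inherit.aes = FALSE, shape = 17, size = 3) +
        ggplot2::geom_linerange(
          data = fo,
          ggplot2::aes(x = .data$x, ymin = .data$y_corrected_lo,
                       ymax = .data$y_corrected_hi),
          inherit.aes = FALSE, linetype = 2)
    }
  }
  p
}

fits_match <- function(fits, region, size_var, response, method) {
  fits$region == region & fits$size_var == size_var &
    fits$response == response & fits$method == method
}

#' Plot an allometric group comparison
#'
#' @param object an `allom_comparison`.
#' @param data the data frame the comparison was run on (points).
#' @param group_col grouping column used for colours.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot allom_comparison
#' @export
autoplot.allom_comparison <- function(object, data = NULL,
                                      group_col = "thermo_class", ...) {
  lines <- dplyr::bind_rows(purrr::imap(object$fits, function(f, g) {
    tibble::tibble(group = g, slope = f$slope, intercept = f$intercept)
  }))
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data[[object$size_var]],
                   y = .data[[object$response_var]],
                   colour = .data[[group_col]]))
  }
  p + ggplot2::geom_abline(
    data = lines,
    ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                 colour = .data$group)) +
    ggplot2::labs(title = paste(object$comparison, "-", object$method),
                  x = paste0("log10 ", object$size_var),
                  y = paste0("log10 ", object$response_var), colour = NULL) +
    ggplot2::theme_minimal()
}
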