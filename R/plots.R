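#' Plot a persistence diagram
#'
#' Points above the diagonal are features; essential classes are marked.
#'
#' @param object A `reva_pd` tibble from [compute_persistence()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reva_pd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$birth, .data$death,
                                       shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(title = sprintf("Persistence diagram, dimension %d",
                                  object$dim[1]),
                  x = "birth", y = "death") +
    ggplot2::theme_minimal()
}

#' Plot an accumulative persistence function
#'
#' @param object A `reva_apf` curve from [apf_curve()].
#' @param ... Unused.
#' @return A ggplot of the right-continuous step function.
#' @export
autoplot.reva_apf <- function(object, ...) {
  df <- tibble(m = c(object$m[1], object$m), value = c(0, object$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$value)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(title = sprintf("APF, dimension %s",
                                  attr(object, "homology_dim") %||% "?"),
                  x = "mean age m", y = "cumulative lifetime") +
    ggplot2::theme_minimal()
}

#' Side-by-side left/right APF comparison
#'
#' Overlays the two curves and marks the location of the signed supremum.
#'
#' @param apf_left,apf_right `reva_apf` curves.
#' @return A ggplot.
#' @export
plot_apf_pair <- function(apf_left, apf_right) {
  r <- reva(apf_left, apf_right)
  df <- dplyr::bind_rows(left = as_tibble(apf_left),
                         right = as_tibble(apf_right), .id = "side")
  ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$value, colour = .data$side)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = r$m_max, linetype = 3) +
    ggplot2::labs(title = sprintf("signed supremum %.4g at m = %.4g",
                                  r$value, r$m_max),
                  x = "mean age m", y = "cumulative lifetime") +
    ggplot2::theme_minimal()
}

#' Plot a greyscale image
#'
#' @param object A [greyscale_image()].
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.greyscale_image <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object)), j = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot the multi-asymmetry overlap
#'
#' Bar chart of the non-empty Venn regions of the four top-decile flags —
#' the overlap structure usually drawn as a Venn diagram.
#'
#' @param ov A `reva_overlap` from [overlap()].
#' @return A ggplot.
#' @export
plot_overlap <- function(ov) {
  groups <- setdiff(names(ov$venn), "n")
  df <- ov$venn |>
    dplyr::mutate(region = purrr::pmap_chr(
      dplyr::pick(dplyr::all_of(groups)),
      function(...) {
        on <- groups[c(...)]
        if (!length(on)) "none" else paste(on, collapse = "+")
      })) |>
    dplyr::filter(.data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$region, .data$n),
                                   .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "subjects",
                  title = "Top-decile asymmetry overlap") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
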