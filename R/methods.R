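#' @export
print.rad_map <- function(x, ...) {
  g <- glance(x)
  cat("<rad_map> ", nrow(x), " markers in ", nrow(g), " groups; total ",
      round(sum(g$length_cM), 1), " cM\n", sep = "")
  NextMethod()
}

#' Summarise a genetic map by linkage group
#'
#' @param x A `rad_map`.
#' @param ... Unused.
#' @return Tibble `group`, `n_markers`, `n_bins`, `length_cM`.
#' @method glance rad_map
#' @export
glance.rad_map <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$group) %>%
    summarise(n_markers = n(), n_bins = dplyr::n_distinct(.data$bin),
              length_cM = max(.data$pos_cM), .groups = "drop")
}

#' @method tidy rad_map
#' @export
tidy.rad_map <- function(x, ...) as_tibble(x)

#' Marker positions along each linkage group
#'
#' @param object A `rad_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rad_map
#' @export
autoplot.rad_map <- function(object, ...) {
  d <- as_tibble(object)
  g <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pos_cM)) +
    ggplot2::geom_segment(
      data = g, inherit.aes = FALSE,
      ggplot2::aes(x = .data$group, xend = .data$group, y = 0,
                   yend = .data$length_cM),
      linewidth = 2, colour = "grey80"
    ) +
    ggplot2::geom_point(shape = 95, size = 5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (cM)",
                  title = "Genetic map") +
    ggplot2::theme_minimal()
}

#' @method tidy rad_distortion
#' @export
tidy.rad_distortion <- function(x, ...) as_tibble(x)

#' @method glance rad_distortion
#' @export
glance.rad_distortion <- function(x, ...) {
  tibble(n_markers = nrow(x),
         n_distorted = sum(x$distorted, na.rm = TRUE),
         n_uncallable = sum(x$uncallable),
         alpha = attr(x, "alpha"))
}

#' Signed segregation-distortion profile along the map
#'
#' Plots -log10(p) signed by the direction of distortion (positive favours
#' the parent-A allele) against map position, with dashed significance
#' thresholds at the profile's alpha.
#'
#' @param object A `rad_distortion` with map columns (`group`, `pos_cM`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rad_distortion
#' @export
autoplot.rad_distortion <- function(object, ...) {
  alpha <- attr(object, "alpha")
  d <- as_tibble(object)
  if (!all(c("group", "pos_cM") %in% names(d))) {
    d$group <- "all"
    d$pos_cM <- seq_len(nrow(d))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_cM, y = .data$signed_score)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)",
                  y = expression(-log[10](p) %*% sign(n[A] - n[B])),
                  title = "Segregation distortion") +
    ggplot2::theme_minimal()
}

#' @export
print.rad_qtl_scan <- function(x, ...) {
  cat("<rad_qtl_scan> trait ", x$trait, ": ", nrow(x$scan), " positions, ",
      length(x$cofactors), " cofactors; max LOD ",
      round(max(x$scan$lod, na.rm = TRUE), 2), sep = "")
  if (!is.na(x$threshold)) {
    cat(" (threshold ", round(as.numeric(x$threshold), 2), ", ",
        nrow(x$qtl), " QTL)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @method tidy rad_qtl_scan
#' @export
tidy.rad_qtl_scan <- function(x, ...) {
  mutate(x$scan, trait = x$trait, .before = 1)
}

#' One-row summary of a QTL scan
#'
#' @param x A `rad_qtl_scan`.
#' @param ... Unused.
#' @return Tibble with the trait, peak LOD and position, threshold, number of
#'   declared QTL and cofactors used.
#' @method glance rad_qtl_scan
#' @export
glance.rad_qtl_scan <- function(x, ...) {
  i <- which.max(x$scan$lod)
  tibble(trait = x$trait, max_lod = x$scan$lod[i],
         peak_group = x$scan$group[i], peak_cM = x$scan$pos_cM[i],
         threshold = as.numeric(x$threshold),
         n_qtl = if (is.null(x$qtl)) 0L else nrow(x$qtl),
         n_cofactors = length(x$cofactors))
}

#' LOD curves of a composite interval mapping scan
#'
#' @param object A `rad_qtl_scan`.
#' @param ... Unused.
#' @return A ggplot faceted by linkage group, with the permutation threshold
#'   as a dashed line when available.
#' @method autoplot rad_qtl_scan
#' @export
autoplot.rad_qtl_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  title = paste0("CIM scan: ", object$trait)) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(object$threshold),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
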