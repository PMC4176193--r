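#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a panel set into one row per selected clone
#'
#' @param x A `pericore_panel_set`.
#' @param ... Unused.
#' @return Tibble: `arm_id`, `status`, clone `name`, placement, and arm
#'   coordinates (`d0`/`d1`, bp from the junction), ordered proximal to
#'   distal within each panel.
#' @export
tidy.pericore_panel_set <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    cl <- x$clones[[i]]
    if (is.null(cl) || nrow(cl) == 0L) return(tibble::tibble())
    tibble::tibble(arm_id = x$arm_id[i], status = x$status[i],
                   position = seq_len(nrow(cl)), name = cl$name,
                   chrom = cl$chrom, start = cl$start, end = cl$end,
                   d0 = cl$d0, d1 = cl$d1)
  })
}

#' @rdname tidy.pericore_panel_set
#' @export
glance.pericore_panel_set <- function(x, ...) summarize_panels(x)

#' Tidy a marker characterization
#'
#' @param x A `pericore_characterization`.
#' @param what `"breakpoints"` (default) or `"segments"`.
#' @param ... Unused.
#' @return The requested component with the case id prepended.
#' @export
tidy.pericore_characterization <- function(x, what = c("breakpoints",
                                                       "segments"), ...) {
  what <- match.arg(what)
  tb <- if (what == "breakpoints") x$breakpoints else x$segments
  if (nrow(tb) == 0L) return(tibble::as_tibble(tb))
  dplyr::bind_cols(tibble::tibble(case_id = x$case_id), tb)
}

#' @rdname tidy.pericore_characterization
#' @export
glance.pericore_characterization <- function(x, ...) {
  tibble::tibble(
    case_id = x$case_id, structure = x$structure, class = x$class,
    n_breakpoints = nrow(x$breakpoints),
    content_min_mb = x$content_min_mb, content_max_mb = x$content_max_mb,
    mosaic_fraction = if (is.null(x$mosaic)) NA_real_ else x$mosaic$fraction,
    mosaic_lower = if (is.null(x$mosaic)) NA_real_ else x$mosaic$lower,
    mosaic_upper = if (is.null(x$mosaic)) NA_real_ else x$mosaic$upper,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Plot core-panel coverage per arm
#'
#' Bars of core span by arm, coloured by panel status — the visual analogue
#' of the per-arm coverage table.
#'
#' @param object A `pericore_panel_set` (or compatible tibble with
#'   `arm_id`, `core_span_mb`, `status`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pericore_panel_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$arm_id <- factor(df$arm_id, levels = df$arm_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm_id, y = .data$core_span_mb,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome arm", y = "core span (Mb)",
                  fill = "panel status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the probe-signal pattern behind a characterization
#'
#' Probe placements drawn along the chromosome, coloured by FISH signal,
#' with the inferred breakpoint interval(s) shaded and the junction marked.
#'
#' @param object A `pericore_characterization`.
#' @param calls The call tibble the characterization was built from.
#' @param arms Arm tibble with junctions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pericore_characterization <- function(object, calls, arms, ...) {
  calls$arm_id <- paste0(sub("chr", "", calls$chrom), calls$arm)
  p <- ggplot2::ggplot(calls) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$probe_name,
                                       yend = .data$probe_name,
                                       colour = .data$signal),
                          linewidth = 3) +
    ggplot2::facet_wrap(~arm_id, scales = "free") +
    ggplot2::scale_colour_manual(values = c(absent = "grey70",
                                            diminished = "orange",
                                            single = "forestgreen",
                                            double = "darkblue")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "FISH signal",
                  title = sprintf("%s: %s", object$case_id, object$class)) +
    ggplot2::theme_minimal()
  if (nrow(object$breakpoints)) {
    bp <- object$breakpoints
    bp$arm_id <- paste0(sub("chr", "", bp$chrom), bp$arm)
    p <- p + ggplot2::geom_rect(
      data = bp, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "red")
  }
  ja <- arms[paste0(sub("chr", "", arms$chrom), arms$arm) %in%
               unique(calls$arm_id), ]
  if (nrow(ja) && !all(is.na(ja$junction))) {
    ja$arm_id <- paste0(sub("chr", "", ja$chrom), ja$arm)
    p <- p + ggplot2::geom_vline(
      data = ja[!is.na(ja$junction), ],
      ggplot2::aes(xintercept = .data$junction / 1e6), linetype = 2)
  }
  p
}
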