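#' Stem plots of event streams
#'
#' Events are drawn as vertical stems at their time, by default the
#' any-event indicator over relative time, optionally faceted by a column
#' (up to 500 distinct values), paginated, color-coded (any column) and
#' shape-coded (up to 6 distinct values), with changepoint boundaries
#' and/or cascade intervals overlaid. Every rendered image is accompanied
#' by a serialized plot spec from which the identical image can be
#' regenerated.
#'
#' @name event_plots
NULL

#' Declare a plot specification
#'
#' @param x,y Column names for the axes (defaults: `relative_time`,
#'   `any_event`).
#' @param facet Optional facet column (at most 500 unique values).
#' @param page_size Facet panels per page (`>= 1`).
#' @param color Optional color column (unrestricted cardinality).
#' @param shape Optional shape column (at most 6 unique values).
#' @param overlay Optional overlay: a cascade tibble (shaded bands), a
#'   `changepoint_result` plus its series, or a numeric vector of
#'   changepoint times (vertical lines).
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(x = "relative_time", y = "any_event", facet = NULL,
                      page_size = 6, color = NULL, shape = NULL,
                      overlay = NULL) {
  if (page_size < 1) stop("'page_size' must be >= 1")
  structure(list(x = x, y = y, facet = facet, page_size = page_size,
                 color = color, shape = shape, overlay = overlay),
            class = "plot_spec")
}

#' Validate a plot spec against an event table
#'
#' Checks that the named columns exist and enforces the cardinality rules:
#' at most 500 unique values for a facet column, at most 6 for a shape
#' column; color is unrestricted.
#'
#' @param spec A [plot_spec()].
#' @param events An [event_table].
#' @return `spec`, invisibly, or an error.
#' @export
validate_spec <- function(spec, events) {
  for (col in c(spec$x, spec$y, spec$facet, spec$color, spec$shape)) {
    if (!col %in% names(events)) {
      stop(sprintf("column '%s' not found in event table", col))
    }
  }
  if (!is.null(spec$facet)) {
    k <- length(unique(events[[spec$facet]]))
    if (k > 500) {
      stop(sprintf("facet column '%s' has %d unique values (limit 500)",
                   spec$facet, k))
    }
  }
  if (!is.null(spec$shape)) {
    k <- length(unique(events[[spec$shape]]))
    if (k > 6) {
      stop(sprintf("shape column '%s' has %d unique values (limit 6)",
                   spec$shape, k))
    }
  }
  invisible(spec)
}

#' Assign facets to pages
#'
#' @param n_facets Number of facet values.
#' @param page_size Panels per page (`>= 1`).
#' @return A list with `n_pages` (`ceiling(n_facets / page_size)`) and
#'   `assignment` (integer vector: page of each facet, in facet sort
#'   order).
#' @export
paginate <- function(n_facets, page_size) {
  if (page_size < 1) stop("'page_size' must be >= 1")
  n_pages <- ceiling(n_facets / page_size)
  assignment <- if (n_facets > 0) {
    rep(seq_len(n_pages), each = page_size)[seq_len(n_facets)]
  } else {
    integer(0)
  }
  list(n_pages = as.integer(n_pages), assignment = assignment)
}

overlay_bands <- function(overlay, facet_col) {
  if (is.null(overlay)) {
    return(NULL)
  }
  if (is.data.frame(overlay) && all(c("start", "end") %in% names(overlay))) {
    bands <- tibble::tibble(xmin = overlay$start, xmax = overlay$end)
    if (!is.null(facet_col) && "case" %in% names(overlay)) {
      bands[[facet_col]] <- overlay$case
    }
    return(bands)
  }
  NULL
}

overlay_lines <- function(overlay) {
  if (is.numeric(overlay)) {
    return(tibble::tibble(x = as.numeric(overlay)))
  }
  NULL
}

#' Render one page of an event stem plot
#'
#' Draws a vertical stem per event; facet panels for the requested page
#' only; cascade overlays as shaded bands and changepoint overlays as
#' vertical lines. The returned ggplot object is also written to `out`
#' (format from the file extension), with the plot spec serialized as JSON
#' alongside (`<out>.spec.json`) so the image can be regenerated.
#'
#' @param spec A validated [plot_spec()].
#' @param events An [event_table].
#' @param page 1-based page index (only used with a facet column).
#' @param out Optional output image path; when `NULL` nothing is written.
#' @return The ggplot object, invisibly.
#' @export
render_events <- function(spec, events, page = 1, out = NULL) {
  validate_spec(spec, events)
  dat <- tibble::as_tibble(as.data.frame(events))
  if (!is.null(spec$facet)) {
    values <- sort(unique(dat[[spec$facet]]))
    pg <- paginate(length(values), spec$page_size)
    if (page < 1 || page > max(pg$n_pages, 1)) {
      stop(sprintf("invalid page %s (have %d pages)", page, pg$n_pages))
    }
    keep <- values[pg$assignment == page]
    dat <- dat[dat[[spec$facet]] %in% keep, , drop = FALSE]
  } else if (page != 1) {
    stop("invalid page index: plot has no facet column")
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[spec$x]]))
  bands <- overlay_bands(spec$overlay, spec$facet)
  if (!is.null(bands)) {
    if (!is.null(spec$facet) && spec$facet %in% names(bands)) {
      bands <- bands[bands[[spec$facet]] %in% dat[[spec$facet]], , drop = FALSE]
    }
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "orange", alpha = 0.3,
      inherit.aes = FALSE
    )
  }
  seg_aes <- ggplot2::aes(xend = .data[[spec$x]], y = 0,
                          yend = .data[[spec$y]])
  if (!is.null(spec$color)) {
    seg_aes$colour <- ggplot2::aes(colour = .data[[spec$color]])$colour
  }
  p <- p + ggplot2::geom_segment(seg_aes)
  if (!is.null(spec$shape)) {
    pt_aes <- ggplot2::aes(y = .data[[spec$y]],
                           shape = .data[[spec$shape]])
    if (!is.null(spec$color)) {
      pt_aes$colour <- ggplot2::aes(colour = .data[[spec$color]])$colour
    }
    p <- p + ggplot2::geom_point(pt_aes)
  }
  lines <- overlay_lines(spec$overlay)
  if (!is.null(lines)) {
    p <- p + ggplot2::geom_vline(data = lines,
                                 ggplot2::aes(xintercept = .data$x),
                                 linetype = "dashed")
  }
  if (!is.null(spec$facet)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", spec$facet)))
  }
  p <- p + ggplot2::labs(x = spec$x, y = spec$y) + ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, plot = p, width = 8, height = 6, dpi = 150)
    writeLines(jsonlite::toJSON(spec_to_list(spec, page), auto_unbox = TRUE,
                                pretty = TRUE, null = "null"),
               paste0(out, ".spec.json"))
  }
  invisible(p)
}

spec_to_list <- function(spec, page) {
  ov <- spec$overlay
  list(
    x = spec$x, y = spec$y, facet = spec$facet, page_size = spec$page_size,
    color = spec$color, shape = spec$shape, page = page,
    overlay = if (is.data.frame(ov)) as.data.frame(ov) else ov
  )
}
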