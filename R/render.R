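# Visualisations: data summary plot, (double-plotted) actogram, colored
# actogram. Each function builds an explicit plotted data model first and
# returns it alongside the ggplot object, so structural tests assert on
# data, never on pixels. Overlays: green = detected sleep, brown =
# non-wear, blue = diary sleep.

.col_sleep <- "#7CCD7C"; .col_nonwear <- "#C8A165"; .col_diary <- "#7FA8D9"

save_plot_maybe <- function(p, path, width = 9, height = 6) {
  if (!is.null(path)) ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
  invisible(path)
}

#' Data summary plot of all modalities with sleep/non-wear/diary overlays
#'
#' Stacked panels (movement, x, y, z, temperature, light) at minute
#' resolution, with detected sleep in transparent green, non-wear in
#' transparent brown and, when a diary is given, diary sleep as a blue
#' band.
#'
#' @param bundle \code{\link{process_recording}} output
#' @param rec optional raw recording (for per-minute axis means; without it
#'   the axis panels are omitted)
#' @param diary optional diary data.frame (night_id, onset, offset)
#' @param path optional output image path (png/svg by extension)
#' @return invisible list: \code{plot} (ggplot), \code{data} (panel series
#'   + overlay interval tables)
#' @export
data_summary_plot <- function(bundle, rec = NULL, diary = NULL, path = NULL) {
  if (!length(bundle$movement)) stop("empty recording")
  tt <- minute_times(bundle$movement)
  panels <- list(movement = bundle$movement$values,
                 temp = bundle$temp$values, light = bundle$light$values)
  if (!is.null(rec)) {
    am <- minute_axis_means(rec, bundle$nonwear)
    panels <- c(panels[1], list(x = am[, 1], y = am[, 2], z = am[, 3]),
                panels[2:3])
  }
  long <- do.call(rbind, lapply(names(panels), function(nm) {
    data.frame(timestamp = tt, panel = nm, value = panels[[nm]])
  }))
  long$panel <- factor(long$panel, levels = names(panels))
  main <- bundle$sleep_records
  sleep_iv <- data.frame(start = main$onset, end = main$offset)
  nonwear_iv <- as.data.frame(bundle$nonwear)
  diary_iv <- if (!is.null(diary)) data.frame(start = diary$onset, end = diary$offset) else NULL
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$timestamp, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) + ggplot2::theme_minimal()
  if (nrow(sleep_iv)) p <- p + ggplot2::geom_rect(
    data = sleep_iv, inherit.aes = FALSE, fill = .col_sleep, alpha = 0.3,
    ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf))
  if (nrow(nonwear_iv)) p <- p + ggplot2::geom_rect(
    data = nonwear_iv, inherit.aes = FALSE, fill = .col_nonwear, alpha = 0.4,
    ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf))
  if (!is.null(diary_iv) && nrow(diary_iv)) p <- p + ggplot2::geom_rect(
    data = diary_iv, inherit.aes = FALSE, fill = .col_diary, alpha = 0.25,
    ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf))
  save_plot_maybe(p, path, width = 10, height = 8)
  invisible(list(plot = p, data = list(panels = long, sleep = sleep_iv,
                                       nonwear = nonwear_iv, diary = diary_iv)))
}

actogram_rows <- function(series, mode = c("48h", "24h")) {
  # rows run noon-to-noon so main sleep renders unbroken; in 48h mode each
  # row appends the following 24 h (24-h overlap between consecutive rows)
  mode <- match.arg(mode)
  n_min <- length(series)
  t0 <- as.numeric(series$start)
  # align the series onto a noon grid (rows start at the latest noon <= start)
  full_start <- floor((t0 - 43200) / 86400) * 86400 + 43200
  offset <- as.integer((t0 - full_start) / 60)
  n_days <- ceiling((offset + n_min) / 1440)
  grid <- rep(NA_real_, n_days * 1440)
  grid[offset + seq_len(n_min)] <- series$values
  width <- if (mode == "48h") 2880L else 1440L
  rows <- list()
  for (k in seq_len(n_days)) {
    i0 <- (k - 1L) * 1440L
    seg <- if (mode == "48h") {
      if (i0 + 2880L <= length(grid)) grid[(i0 + 1L):(i0 + 2880L)]
      else c(grid[(i0 + 1L):length(grid)], rep(NA_real_, i0 + 2880L - length(grid)))
    } else grid[(i0 + 1L):(i0 + 1440L)]
    rows[[k]] <- seg
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- format(as.POSIXct(full_start + (seq_len(n_days) - 1L) * 86400,
                                     origin = "1970-01-01", tz = .acti_tz), "%Y-%m-%d")
  mat
}

#' Actogram (stacked per-day activity plot)
#'
#' One row per noon-to-noon day. In 48-h double-plot mode each row shows 48
#' consecutive hours, so the second half of row k is repeated as the first
#' half of row k + 1, giving visual continuity across midnight.
#'
#' @param bundle \code{\link{process_recording}} output
#' @param mode "48h" (double plot, default) or "24h"
#' @param path optional output image path
#' @return invisible list: \code{plot}, \code{data} (rows matrix, sleep and
#'   non-wear interval tables)
#' @export
actogram <- function(bundle, mode = c("48h", "24h"), path = NULL) {
  mode <- match.arg(mode)
  mat <- actogram_rows(bundle$movement, mode)
  df <- data.frame(
    day = rep(rownames(mat), each = ncol(mat)),
    hour = rep((seq_len(ncol(mat)) - 1) / 60, nrow(mat)),
    value = as.vector(t(mat)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour + 12, y = .data$value)) +
    ggplot2::geom_col(width = 1 / 60, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$day)) +
    ggplot2::labs(x = "clock time from noon (h)", y = "movement (g)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
  save_plot_maybe(p, path, width = 9, height = 1.2 * nrow(mat) + 1)
  invisible(list(plot = p,
                 data = list(rows = mat, mode = mode,
                             sleep = data.frame(start = bundle$sleep_records$onset,
                                                end = bundle$sleep_records$offset),
                             nonwear = as.data.frame(bundle$nonwear))))
}

#' Colored actogram (10-min mean activity on a color scale)
#'
#' A day-by-window grid (one row per noon-to-noon day, 144 ten-minute
#' windows per row by default) of mean movement on one shared color scale,
#' with non-wear cells marked distinctly (NA fill).
#'
#' @param bundle \code{\link{process_recording}} output
#' @param window_min cell width in minutes; must divide 1440
#' @param path optional output image path
#' @return invisible list: \code{plot}, \code{data} (grid matrix of cell
#'   means, nonwear cell mask)
#' @export
colored_actogram <- function(bundle, window_min = 10, path = NULL) {
  if (1440 %% window_min != 0) stop("window_min must divide 1440")
  mat <- actogram_rows(bundle$movement, "24h")
  cells_per_row <- 1440L %/% window_min
  grid <- t(apply(mat, 1, function(r) {
    colMeans(matrix(r, nrow = window_min), na.rm = TRUE)
  }))
  grid[is.nan(grid)] <- NA
  nw_mask <- actogram_rows(minute_series(bundle$movement$start,
                                         as.numeric(bundle$movement$missing),
                                         missing = rep(FALSE, length(bundle$movement))),
                           "24h")
  nw_cells <- t(apply(nw_mask, 1, function(r) {
    colMeans(matrix(r, nrow = window_min), na.rm = TRUE) > 0.5
  }))
  df <- data.frame(
    day = rep(rownames(grid), each = cells_per_row),
    cell = rep(seq_len(cells_per_row), nrow(grid)),
    value = as.vector(t(grid)),
    nonwear = as.vector(t(nw_cells)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$day,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = .col_nonwear) +
    ggplot2::labs(x = sprintf("%d-min window from noon", window_min), y = NULL,
                  fill = "movement (g)") +
    ggplot2::theme_minimal()
  save_plot_maybe(p, path, width = 9, height = 0.4 * nrow(grid) + 2)
  invisible(list(plot = p, data = list(grid = grid, nonwear_cells = nw_cells,
                                       window_min = window_min)))
}
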