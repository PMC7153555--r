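#' Fixed categorical colors for the nine admissible strategies
#'
#' One fixed color per code so that every phase diagram uses the same
#' legend: grey for the no-signal strategy, warm colors for permanent
#' signalers, greens for pre-attack switchers, blues for post-attack
#' switchers.
#'
#' @return Named character vector of hex colors keyed by strategy code.
#' @examples
#' strategy_colors()
#' @export
strategy_colors <- function() {
  c(
    NNN = "#BDBDBD", # no signal
    NNL = "#9ECAE1", # post-attack, weak
    NNH = "#2171B5", # post-attack, strong
    NLL = "#A1D99B", # pre-attack, weak
    NHH = "#238B45", # pre-attack, strong
    LLL = "#FDD0A2", # permanent, weak
    LLH = "#9E9AC8", # mixed switcher (approach-stable, attack-boost)
    LHH = "#756BB1", # low-rest pre-attack
    HHH = "#D94801"  # permanent, strong
  )
}

#' Mini-plot: winners along the signal-penalty ladder
#'
#' One tile per run; the vertical axis is the signal penalty (descending,
#' largest on top), the horizontal axis the repeat index, the fill the
#' winning strategy. The reference mini-plot is 51 penalty levels x 3
#' repeats = 153 runs.
#'
#' @param result An `apo_sweep` tibble covering a single
#'   (penalty level, detectability, turnover, learning speed) cell.
#' @return A ggplot object.
#' @export
plot_mini <- function(result) {
  stopifnot(is.data.frame(result))
  df <- dplyr::mutate(result,
    penalty_rank = dplyr::dense_rank(dplyr::desc(.data$signaling_penalty))
  )
  pal <- strategy_colors()
  extra <- setdiff(unique(stats::na.omit(df$winner)), names(pal))
  if (length(extra) > 0) {
    pal <- c(pal, stats::setNames(
      grDevices::hcl.colors(length(extra), "Dark 3"), extra))
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$`repeat`),
    y = .data$penalty_rank,
    fill = .data$winner
  )) +
    ggplot2::geom_tile(color = "white", linewidth = 0.1) +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_fill_manual(values = pal, na.value = "black",
      name = "winner") +
    ggplot2::labs(x = "repeat", y = "signal penalty rank (high → low)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Meta-plot of sweep winners
#'
#' Arranges mini-plots in a facet grid — learning speed across columns,
#' (basal detectability, predator turnover) down rows — for one
#' switchable-penalty level. Non-factorial input simply leaves the missing
#' facets empty.
#'
#' @param object An `apo_sweep` tibble.
#' @param switch_penalty_level Which penalty level to display (defaults to
#'   the first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.apo_sweep <- function(object, switch_penalty_level = NULL, ...) {
  lvl <- switch_penalty_level %||% object$switch_penalty_level[1]
  df <- dplyr::filter(object, .data$switch_penalty_level == lvl)
  p <- plot_mini(df)
  p +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$basal_detectability, .data$predator_turnover),
      cols = ggplot2::vars(.data$learning_speed),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(title = sprintf("switchable-signal penalty: %s", lvl)) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render all phase-diagram files for a sweep
#'
#' Writes one mini-plot per (penalty level, detectability, turnover,
#' learning speed) cell and one composed meta-plot per penalty level, in
#' PNG and/or SVG.
#'
#' @param result An `apo_sweep` tibble.
#' @param out_dir Output directory (created if absent).
#' @param formats Character subset of `c("png", "svg")`.
#' @param width,height Device size in inches for the mini-plots; meta-plots
#'   scale with the facet count.
#' @return Invisibly, the character vector of files written.
#' @export
render_phase_plots <- function(result, out_dir, formats = c("png", "svg"),
                               width = 2.2, height = 4) {
  stopifnot(is.data.frame(result))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  save_all <- function(plot, stem, w, h) {
    for (fmt in formats) {
      path <- file.path(out_dir, paste0(stem, ".", fmt))
      dev <- if (fmt == "svg") grDevices::svg else grDevices::png
      suppressMessages(ggplot2::ggsave(path, plot, device = dev,
        width = w, height = h, units = "in", dpi = 150, bg = "white"))
      written <<- c(written, path)
    }
  }

  cells <- dplyr::distinct(result, .data$switch_penalty_level,
    .data$basal_detectability, .data$predator_turnover, .data$learning_speed)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    df <- dplyr::semi_join(result, cell, by = names(cells))
    stem <- sprintf("mini_%s_bd%g_to%g_ls%g",
      cell$switch_penalty_level, cell$basal_detectability,
      cell$predator_turnover, cell$learning_speed)
    save_all(plot_mini(df), stem, width, height)
  }
  for (lvl in unique(result$switch_penalty_level)) {
    n_cols <- length(unique(result$learning_speed))
    n_rows <- nrow(dplyr::distinct(result, .data$basal_detectability,
      .data$predator_turnover))
    save_all(
      autoplot.apo_sweep(result, switch_penalty_level = lvl),
      sprintf("meta_%s", lvl),
      max(4, 1.1 * n_cols), max(3, 1.1 * n_rows)
    )
  }
  invisible(written)
}
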