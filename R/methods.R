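#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a study report
#'
#' @param x A `study_report` from [run_study()].
#' @param table Which table to return: `"agreement"` (intra and inter rows
#'   bound together, default), `"gold"`, `"quality"` or `"functions"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.study_report <- function(x, table = c("agreement", "gold", "quality",
                                           "functions"), ...) {
  table <- match.arg(table)
  switch(table,
    agreement = dplyr::bind_rows(x$tables$intra, x$tables$inter),
    gold = x$tables$gold,
    quality = x$quality,
    functions = x$functions)
}

#' One-row summary of a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A one-row tibble: subject count, mean raw blood SNR and CNR, the
#'   condition with the smallest inter-observer LVM relative difference, and
#'   the master seed.
#' @export
glance.study_report <- function(x, ...) {
  raw <- dplyr::filter(x$quality, .data$condition == "raw")
  inter_lvm <- dplyr::filter(x$tables$inter, .data$parameter == "LVM")
  best <- inter_lvm$condition[which.min(abs(inter_lvm$mean_rel_pct))]
  tibble::tibble(
    n_subjects = x$config$n_subjects,
    raw_snr_blood = mean(raw$snr_blood),
    raw_cnr = mean(raw$cnr),
    best_inter_lvm_condition = best,
    master_seed = x$provenance$master_seed
  )
}

#' Plot observer-agreement results of a study
#'
#' Bar chart of the relative mean difference (with SD error bars) per
#' filtering condition, faceted by parameter and by study (intra-/
#' inter-observer) — the standard way these variability results are shown.
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  df <- tidy(object, "agreement")
  df$condition <- factor(df$condition, levels = study_conditions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$mean_rel_pct,
                                   fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rel_pct - .data$sd_rel_pct,
      ymax = .data$mean_rel_pct + .data$sd_rel_pct), width = 0.3) +
    ggplot2::facet_grid(.data$study ~ .data$parameter) +
    ggplot2::labs(x = NULL, y = "relative difference (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display one slice of a cine series
#'
#' @param series A [cine_series()].
#' @param slice,phase 1-based slice and phase indices.
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(series, slice, phase = 1L) {
  stopifnot(inherits(series, "cine_series"))
  img <- series$data[, , slice, phase]
  df <- expand.grid(x = seq_len(nrow(img)), y = seq_len(ncol(img)))
  df$value <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "signal") +
    ggplot2::theme_void()
}
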