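#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

row_label <- function(tbl) {
  bit_cols <- grep("^input_", names(tbl), value = TRUE)
  apply(as.data.frame(tbl)[bit_cols], 1, paste, collapse = "")
}

#' Plot a simulated truth table
#'
#' Normalized FAM and NMM intensities per input combination with the
#' decoding threshold overlaid - the in-silico analogue of a normalized
#' dual-channel bar readout.
#'
#' @param object An `mb_truth_table` from [simulate_truth_table()].
#' @param threshold Decoding threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mb_truth_table <- function(object, threshold = 0.4, ...) {
  df <- tibble::tibble(
    inputs = factor(row_label(object), levels = unique(row_label(object))),
    FAM = object$fam_norm,
    NMM = object$nmm_norm
  )
  long <- tidyr::pivot_longer(df, c("FAM", "NMM"),
    names_to = "channel", values_to = "intensity"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$inputs, y = .data$intensity, fill = .data$channel)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(FAM = "#2c7fb8", NMM = "#d95f0e")) +
    ggplot2::labs(
      x = "input combination", y = "normalized intensity",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot verification margins
#'
#' Distance of each channel intensity from the decoding threshold, per
#' input combination; failed rows are highlighted.
#'
#' @param object An `mb_verification` from [verify_circuit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mb_verification <- function(object, ...) {
  rows <- object$rows
  df <- tibble::tibble(
    inputs = factor(row_label(rows), levels = unique(row_label(rows))),
    FAM = rows$fam_margin,
    NMM = rows$nmm_margin,
    pass = rows$pass
  )
  long <- tidyr::pivot_longer(df, c("FAM", "NMM"),
    names_to = "channel", values_to = "margin"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$inputs, y = .data$margin,
      fill = .data$channel, alpha = .data$pass
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35), guide = "none") +
    ggplot2::scale_fill_manual(values = c(FAM = "#2c7fb8", NMM = "#d95f0e")) +
    ggplot2::labs(
      x = "input combination", y = "distance from threshold",
      fill = NULL,
      title = paste0(
        object$kind, ": ", object$n_pass, "/", nrow(rows), " rows match"
      )
    ) +
    ggplot2::theme_minimal()
}
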