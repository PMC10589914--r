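# ggplot2 views of the main result types.

#' Contact-map plot of an interface
#'
#' @param interface A contact tibble from [compute_interface()].
#' @return A ggplot: residues of chain a vs chain b, tiles colored by
#'   contact distance.
#' @export
plot_contact_map <- function(interface) {
  df <- tibble::as_tibble(interface)
  df$res_a <- paste0(df$resno_a, df$ins_a)
  df$res_b <- paste0(df$resno_b, df$ins_b)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$res_a, levels = unique(.data$res_a)),
    y = factor(.data$res_b, levels = unique(.data$res_b)),
    fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "distance (Å)",
                                  direction = -1) +
    ggplot2::labs(
      x = paste("chain", attr(interface, "chain_a")),
      y = paste("chain", attr(interface, "chain_b"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a secondary-structure assignment as a state ribbon
#'
#' @param object An assignment from [assign_secondary()] or [parse_dssp()].
#' @param ... Unused.
#' @return A ggplot of per-residue states along the chain.
#' @export
autoplot.ss_assignment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = 1, fill = .data$ss)) +
    ggplot2::geom_tile(height = 0.6) +
    ggplot2::scale_fill_manual(
      values = c(H = "#D55E00", E = "#0072B2", C = "grey80"),
      name = "state") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "residue position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of a smotif library in the packing/hoist plane
#'
#' @param smotifs A smotif tibble from [extract_smotifs()] (rows from
#'   several chains may be bound together).
#' @return A ggplot of theta vs delta, sized by D, colored by motif type.
#' @export
plot_smotif_geometry <- function(smotifs) {
  df <- tibble::as_tibble(smotifs)
  df <- df[!df$degenerate, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$delta,
                                   size = .data$D,
                                   colour = .data$motif_type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "packing angle θ (°)",
                  y = "hoist angle δ (°)",
                  size = "D (Å)", colour = "type") +
    ggplot2::lims(x = c(0, 180), y = c(0, 180)) +
    ggplot2::theme_minimal()
}
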