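#' Plot sliding-window isoelectric-point profiles
#'
#' One line per peptide over the window centers. When a single peptide and
#' its tripartite annotation are supplied, vertical bars mark the signal
#' peptide / mature / C-terminal extension boundaries, reproducing the
#' characteristic cationic-to-anionic shift at the mature/C-tail junction.
#'
#' @param profile Output of [sliding_pi_profile()].
#' @param annotation Optional one-row annotation (with `sp_end`,
#'   `mature_end`) for boundary bars.
#' @return A ggplot object.
#' @export
plot_pi_profile <- function(profile, annotation = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$center, y = .data$pi, colour = .data$peptide_id
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window center (residue)", y = "average isoelectric point",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(annotation$sp_end, annotation$mature_end) + 0.5,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Plot per-segment net charges of annotated precursors
#'
#' Mature-region versus C-terminal-extension net charge, one point pair per
#' precursor: cationic matures sit above zero, anionic tails below.
#'
#' @param peptides Tibble `id`, `residues`.
#' @param annotations Output of [annotate_precursors()] (or truth columns).
#' @return A ggplot object.
#' @export
plot_segment_charges <- function(peptides, annotations) {
  mature <- extract_segment(peptides, annotations, "mature")
  ctail <- extract_segment(peptides, annotations, "ctail")
  df <- bind_rows(
    tibble(id = mature$id, segment = "mature",
           net_charge = net_charge(mature$residues)),
    tibble(id = ctail$id, segment = "C-terminal extension",
           net_charge = net_charge(ctail$residues))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$segment, y = .data$net_charge, group = .data$id
  )) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "net charge") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of profile-HMM match emissions
#'
#' @param object A `profile_hmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_hmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$state, y = .data$residue, fill = .data$probability
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "match state", y = NULL, fill = "P(residue)") +
    ggplot2::theme_minimal()
}
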