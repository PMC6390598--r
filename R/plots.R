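#' Replicate allele-frequency scatter plot
#'
#' Plots matched calls' allele frequencies of replicate 2 against
#' replicate 1 with the identity line and the OLS R^2 annotated.
#'
#' @param object A `replicate_pair`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.replicate_pair <- function(object, ...) {
  df <- object$matched
  r2 <- if (nrow(df) >= 2) af_correlation(object) else NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$af1, y = .data$af2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "#2166ac") +
    ggplot2::labs(
      x = "Allele frequency, library 1 (%)",
      y = "Allele frequency, library 2 (%)",
      title = paste0("Replicate AF agreement, sample ", object$sample_id),
      subtitle = if (!is.na(r2)) sprintf("R² = %.3f", r2) else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Artifact-census sharing plot
#'
#' Bar chart of potential artifact sites by the number of samples sharing
#' them; singletons are the sites private to one sample.
#'
#' @param object An `artifact_census`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.artifact_census <- function(object, ...) {
  df <- dplyr::count(object$census, .data$n_samples)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_samples),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::labs(x = "Samples sharing the artifact site",
                  y = "Potential artifact sites",
                  title = "Potential sequence artifacts by sharing class") +
    ggplot2::theme_minimal()
}

#' Family-size histogram
#'
#' @param aligned Output of [group_families()] (or [assign_reads()]).
#' @param max_size Sizes above this are pooled into one bin.
#' @return A ggplot.
#' @export
plot_family_sizes <- function(aligned, max_size = 10) {
  if (!"family_id" %in% names(aligned)) aligned <- group_families(aligned)
  fams <- family_table(aligned)
  fams$size_bin <- factor(pmin(fams$size, max_size),
                          levels = seq_len(max_size),
                          labels = c(seq_len(max_size - 1),
                                     paste0(">=", max_size)))
  ggplot2::ggplot(fams, ggplot2::aes(x = .data$size_bin)) +
    ggplot2::geom_bar(fill = "#4393c3") +
    ggplot2::labs(x = "Reads per molecular family", y = "Families",
                  title = "Molecular family sizes") +
    ggplot2::theme_minimal()
}

#' Per-sample call-count comparison plot
#'
#' Paired per-sample call counts with and without barcoding, as in a
#' with/without-MBS cohort comparison.
#'
#' @param counts Tibble with sample_id, mbs_calls, raw_calls (e.g.
#'   [call_count_cohort()]).
#' @return A ggplot.
#' @export
plot_call_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, c("mbs_calls", "raw_calls"),
                              names_to = "arm", values_to = "calls")
  long$arm <- ifelse(long$arm == "mbs_calls", "with MBS", "without MBS")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$calls)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id),
                       colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$arm), size = 2) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "Detected alterations per sample",
                  title = "Calls with and without molecular barcoding") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
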