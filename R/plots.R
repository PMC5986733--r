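#' Plot per-carrier ROHs and the shared haplotype
#'
#' One horizontal track per carrier: the outer ROH (extension to the first
#' heterozygote) as a thin segment, the trimmed ROH (pulled back to shared
#' homozygotes) as a thick one, the shared haplotype as a shaded band and
#' the index variant as a dashed vertical line.
#'
#' @param object A `share_report` from [run_share_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.share_report <- function(object, ...) {
  r <- tidy(object)
  s <- object$shared
  ggplot2::ggplot(r) +
    ggplot2::geom_rect(
      data = s,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "goldenrod", alpha = 0.25) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$outer_start / 1e6, xend = .data$outer_end / 1e6,
                   y = .data$sample_id, yend = .data$sample_id),
      linewidth = 1, colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$trimmed_start / 1e6,
                   xend = .data$trimmed_end / 1e6,
                   y = .data$sample_id, yend = .data$sample_id),
      linewidth = 4, colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = r$index_pos[1] / 1e6,
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s position (Mb)", s$chrom), y = NULL,
      title = sprintf("Shared founder haplotype: %s (%0.4g cM)",
                      object$length_label, object$length_cM),
      subtitle = sprintf("thin: ROH to first het; thick: trimmed to shared homozygotes; band: %d-carrier intersection",
                         s$n_samples)) +
    ggplot2::theme_minimal()
}

#' Plot recessive-filter tallies
#'
#' Bar chart of where input variants ended up: candidate buckets, the
#' unresolved bucket, and each removal reason.
#'
#' @param object A `filter_report` from [run_filter_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.filter_report <- function(object, ...) {
  cs <- object$candidates
  counts <- bind_rows(
    tibble(bucket = "homozygous candidate", n = nrow(cs$homozygous)),
    tibble(bucket = "compound-het member",
           n = length(unique(c(cs$compound_het_pairs$maternal_key,
                               cs$compound_het_pairs$paternal_key)))),
    tibble(bucket = "unresolved", n = nrow(cs$unresolved)),
    cs$removed |> dplyr::count(.data$reason) |>
      rename(bucket = "reason"))
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$bucket, .data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Recessive-model filter outcome") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
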