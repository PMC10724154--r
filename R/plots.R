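# Quick-look figures; ggplot2 is optional (Suggests).

utils::globalVariables(c("start_rank", "retention", "subgenome", "idx", "wml"))

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
}

#' Plot a sliding-window retention profile
#'
#' @param profile a [window_retention()] result.
#' @return a ggplot object (retention per subgenome along gene rank).
#' @export
plot_retention <- function(profile) {
  need_ggplot()
  long <- rbind(
    data.frame(ref_chrom = profile$ref_chrom, start_rank = profile$start_rank,
               subgenome = "subP", retention = profile$retention_P),
    data.frame(ref_chrom = profile$ref_chrom, start_rank = profile$start_rank,
               subgenome = "subM", retention = profile$retention_M))
  ggplot2::ggplot(long, ggplot2::aes(x = start_rank, y = retention,
                                     colour = subgenome)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ref_chrom) +
    ggplot2::scale_colour_manual(values = c(subP = "#d73027", subM = "#4575b4")) +
    ggplot2::labs(x = "window start (gene rank)", y = "retention") +
    ggplot2::theme_minimal()
}

#' Plot a methylation metaplot
#'
#' @param mp a [metaplot()] result.
#' @return a ggplot object of the pooled weighted-methylation track.
#' @export
plot_metaplot <- function(mp) {
  need_ggplot()
  tr <- mp$track
  tr$idx <- seq_len(nrow(tr))
  ggplot2::ggplot(tr, ggplot2::aes(x = idx, y = wml)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(mp$flank_bins + 0.5,
                                       mp$flank_bins + mp$body_bins + 0.5),
                        linetype = "dashed") +
    ggplot2::labs(x = "bin (upstream | body | downstream)",
                  y = "weighted methylation level") +
    ggplot2::theme_minimal()
}
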