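#' Plot donor-similarity trajectories
#'
#' One line per recipient: Sorensen similarity to the (assigned or mean)
#' donor across the visit schedule, coloured by arm.
#'
#' @param data Output of [donor_similarity_trajectory()].
#' @return A ggplot object.
#' @export
plot_similarity_trajectory <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$week, y = .data$sorensen,
    group = .data$subject_id, colour = .data$arm
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "weeks from intervention", y = "Sorensen similarity to donor",
                  colour = "arm") +
    ggplot2::theme_minimal()
}

#' Plot new-OTU abundance over the follow-up
#'
#' Per-subject proportion of abundance carried by OTUs absent at both
#' pre-intervention visits.
#'
#' @param data Output of [track_new_otus()].
#' @return A ggplot object.
#' @export
plot_new_otus <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$week, y = .data$new_otu_proportion,
    group = .data$subject_id, colour = .data$arm
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "weeks from intervention",
                  y = "abundance from OTUs absent pre-intervention",
                  colour = "arm") +
    ggplot2::theme_minimal()
}
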