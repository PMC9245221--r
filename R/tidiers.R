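#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assembly
#'
#' One row per transcript model with scalar columns only (exon chains are
#' flattened to a `chr:start-end|...` string).
#'
#' @param x An `eg_assembly`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.eg_assembly <- function(x, ...) {
  m <- x$models
  chrom_names <- x$header$chroms$name
  tibble::tibble(
    transcript_id = m$transcript_id,
    gene_id = m$gene_id,
    chrom = chrom_names[m$chrom + 1L],
    start = m$start, end = m$end, strand = m$strand,
    n_exons = m$n_exons, length = m$length,
    exon_chain = vapply(m$exons, function(e)
      paste(sprintf("%d-%d", e[, 1], e[, 2]), collapse = "|"), character(1)),
    complete = m$complete, capped = m$capped,
    coverage = m$coverage, share = m$share,
    tss_summit = m$tss_summit, pas_summit = m$pas_summit,
    n_samples_support = m$n_samples_support)
}

#' Summarize an assembly
#'
#' @param x An `eg_assembly`.
#' @param ... Unused.
#' @return A one-row tibble: transcript/locus counts, completeness and
#'   cap statistics, total assigned coverage.
#' @exportS3Method generics::glance
glance.eg_assembly <- function(x, ...) {
  m <- x$models
  tibble::tibble(
    n_transcripts = nrow(m),
    n_loci = x$n_loci,
    n_complete = sum(m$complete),
    n_capped = sum(m$capped),
    n_multiexon = sum(m$n_exons > 1L),
    mean_coverage = if (nrow(m)) mean(m$coverage) else NA_real_,
    total_bases = sum(m$bases))
}

#' Plot assembled transcript models
#'
#' Draws the classic browser-style transcript diagram: exon rectangles
#' joined by intron lines, one row per transcript, faceted by chromosome.
#'
#' @param object An `eg_assembly`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eg_assembly <- function(object, ...) {
  m <- object$models
  if (!nrow(m)) stop("no transcript models to plot")
  chrom_names <- object$header$chroms$name
  ex <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    e <- m$exons[[i]]
    tibble::tibble(transcript_id = m$transcript_id[i],
                   chrom = chrom_names[m$chrom[i] + 1L],
                   strand = m$strand[i], y = i,
                   start = e[, 1], end = e[, 2])
  })
  tx <- tibble::tibble(transcript_id = m$transcript_id,
                       chrom = chrom_names[m$chrom + 1L],
                       y = seq_len(nrow(m)), start = m$start, end = m$end,
                       strand = m$strand)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = tx,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y),
                          linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$y - 0.35,
                                    ymax = .data$y + 0.35,
                                    fill = .data$strand)) +
    ggplot2::scale_y_continuous(breaks = tx$y, labels = tx$transcript_id) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::labs(x = "genomic position (nt)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot end-tag clusters of a locus
#'
#' Shows per-position Start/Cap/End Tag weight with the retained cluster
#' spans and summits overlaid; useful for inspecting why a TSS or PAS was
#' (not) called.
#'
#' @param reads Locus read-model tibble.
#' @param params An [endguide_params()].
#' @return A ggplot.
#' @export
plot_tag_clusters <- function(reads, params = endguide_params()) {
  tags <- extract_tags(reads)
  if (!nrow(tags)) stop("no end tags in these reads")
  clusters <- cluster_tags(tags, distance = params$cluster_distance,
                           threshold_fraction = params$end_cluster_prop,
                           cap_bonus = params$cap_bonus,
                           cap_filter = params$cap_filter)
  agg <- tags |>
    dplyr::mutate(group = ifelse(.data$kind == "E", "PAS", "TSS")) |>
    dplyr::group_by(.data$pos, .data$strand, .data$group) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$pos, y = .data$weight,
                                         colour = .data$group)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::facet_grid(strand ~ .) +
    ggplot2::labs(x = "genomic position (nt)", y = "tag weight") +
    ggplot2::theme_minimal()
  if (nrow(clusters))
    p <- p + ggplot2::geom_vline(data = clusters,
                                 ggplot2::aes(xintercept = .data$summit),
                                 linetype = 2, colour = "grey50")
  p
}
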