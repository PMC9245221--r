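#' Assembly and labeling parameters
#'
#' Collects every tunable parameter of the pipeline with its default value.
#' Defaults follow the short-read assembly settings used throughout the
#' package documentation: a 50 nt chunking/clustering gap, minimum path
#' coverage of 2 reads, minimum transcript length of 60 nt, a 2% signal
#' proportion threshold, 3 nt splice overhang, a 5x Cap Tag bonus and a 2%
#' cap filter.
#'
#' @param max_gap Maximum uncovered gap (nt) within one locus; also the
#'   default Start/End Tag clustering distance.
#' @param min_cov Minimum assigned coverage for an emitted transcript model.
#' @param min_len Minimum emitted transcript length (nt, sum of exons).
#' @param min_proportion Fraction of locus signal below which positions,
#'   junctions and paths are discarded; also the greedy stop threshold.
#' @param min_overhang Minimum aligned nt a read must overlap a frag (or a
#'   splice junction flank) for the overlap to count.
#' @param cap_bonus Multiplicative weight bonus applied to Cap Tags (5'
#'   labels with an upstream untemplated G) during Tag Clustering.
#' @param cap_filter Minimum capped fraction (Cap weight / Start+Cap weight)
#'   for a TSS cluster to count as capped.
#' @param require_cap If `TRUE`, complete models must start at a capped TSS.
#' @param discard_incomplete If `TRUE` (assembly default), only paths that
#'   reached both a Start and an End Tag are emitted. `condense()` sets this
#'   to `FALSE`.
#' @param cluster_distance Tag clustering distance (nt); defaults to
#'   `max_gap`.
#' @param collapse Collapse linear chains in the overlap graph before path
#'   extraction (an optimization; output is invariant).
#' @param end_cluster_prop Signal proportion threshold used for Start/End Tag
#'   position filtering; defaults to `min_proportion`.
#'
#' @return A named list of class `endguide_params`.
#' @export
#' @examples
#' p <- endguide_params(min_len = 200)
#' p$min_len
endguide_params <- function(max_gap = 50L,
                            min_cov = 2,
                            min_len = 60L,
                            min_proportion = 0.02,
                            min_overhang = 3L,
                            cap_bonus = 5,
                            cap_filter = 0.02,
                            require_cap = FALSE,
                            discard_incomplete = TRUE,
                            cluster_distance = max_gap,
                            collapse = TRUE,
                            end_cluster_prop = min_proportion) {
  p <- list(
    max_gap = as.integer(max_gap),
    min_cov = min_cov,
    min_len = as.integer(min_len),
    min_proportion = min_proportion,
    min_overhang = as.integer(min_overhang),
    cap_bonus = cap_bonus,
    cap_filter = cap_filter,
    require_cap = isTRUE(require_cap),
    discard_incomplete = isTRUE(discard_incomplete),
    cluster_distance = as.integer(cluster_distance),
    collapse = isTRUE(collapse),
    end_cluster_prop = end_cluster_prop
  )
  stopifnot(p$max_gap >= 0, p$min_overhang >= 1, p$min_proportion >= 0,
            p$min_proportion <= 1, p$cap_bonus > 0)
  structure(p, class = "endguide_params")
}

#' @export
print.endguide_params <- function(x, ...) {
  cat("<endguide_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
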