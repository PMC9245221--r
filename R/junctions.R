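#' Splice junction tables
#'
#' Junctions are kept as tibbles with one row per (chrom, donor, acceptor,
#' strand): `donor`/`acceptor` are 0-based positions of the first and
#' one-past-last intronic base (`donor < acceptor`), `count` is read
#' support, `samples` the number of supporting samples and `known` whether
#' the junction came from an annotation. On disk they are BED6: the
#' interval is the intron, score holds the read count, name is
#' `known`/`novel`.
#'
#' @param chrom,donor,acceptor,strand,count,samples,known Column vectors.
#' @return A junction tibble.
#' @export
junction_table <- function(chrom = character(), donor = integer(),
                           acceptor = integer(), strand = character(),
                           count = double(), samples = 1L, known = FALSE) {
  n <- length(donor)
  out <- tibble::tibble(
    chrom = recycle_n(as.character(chrom), n),
    donor = as.integer(donor),
    acceptor = as.integer(acceptor),
    strand = recycle_n(as.character(strand), n),
    count = recycle_n(as.double(count), n),
    samples = recycle_n(as.integer(samples), n),
    known = recycle_n(as.logical(known), n)
  )
  if (any(out$donor >= out$acceptor)) stop("junction with donor >= acceptor")
  if (any(out$count < 0)) stop("negative junction count")
  out
}

#' Merge splice junctions across samples
#'
#' Pools per-sample junction sets and filters novel junctions by
#' reproducibility: a junction absent from the known set is retained only
#' when observed in at least `min_reps` samples. Known junctions are always
#' retained (with their pooled support, possibly zero).
#'
#' @param per_sample List of junction tibbles, one per sample.
#' @param min_reps Minimum number of supporting samples for a novel
#'   junction.
#' @param known Optional junction tibble of annotated junctions.
#' @return A merged junction tibble.
#' @export
#' @examples
#' j1 <- junction_table("chr1", 100L, 200L, "+", 5)
#' j2 <- junction_table("chr1", c(100L, 300L), c(200L, 400L), "+", 1)
#' merge_junctions(list(j1, j2), min_reps = 2)
merge_junctions <- function(per_sample, min_reps = 2L, known = NULL) {
  stopifnot(min_reps >= 1L)
  pooled <- dplyr::bind_rows(per_sample) |>
    dplyr::group_by(.data$chrom, .data$donor, .data$acceptor, .data$strand) |>
    dplyr::summarise(count = sum(.data$count), samples = dplyr::n(),
                     .groups = "drop")
  key <- function(d) paste(d$chrom, d$donor, d$acceptor, d$strand)
  if (!is.null(known) && nrow(known)) {
    kk <- key(known)
    pooled$known <- key(pooled) %in% kk
    missing <- known[!(kk %in% key(pooled)), ]
    if (nrow(missing)) {
      missing$count <- 0; missing$samples <- 0L; missing$known <- TRUE
      pooled <- dplyr::bind_rows(pooled, missing)
    }
  } else {
    pooled$known <- FALSE
  }
  out <- pooled[pooled$known | pooled$samples >= min_reps, ]
  dplyr::arrange(out, .data$chrom, .data$donor, .data$acceptor)
}

#' Read / write junction BED6
#'
#' @param path BED6 file: chrom, intron start, intron end, `known`/`novel`,
#'   read count, strand.
#' @return `read_junction_bed()`: a junction tibble.
#' @export
read_junction_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicdc", progress = FALSE)
  junction_table(d$chrom, d$start, d$end, d$strand, d$score,
                 known = d$name == "known")
}

#' @rdname read_junction_bed
#' @param junctions A junction tibble.
#' @export
write_junction_bed <- function(junctions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", junctions$chrom,
                   junctions$donor, junctions$acceptor,
                   ifelse(junctions$known, "known", "novel"),
                   fmt_weight(junctions$count), junctions$strand)
  writeLines(lines, path)
  invisible(length(lines))
}
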