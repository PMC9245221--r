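#' Write transcript models to GTF
#'
#' Emits standard GTF (1-based inclusive coordinates): one `transcript`
#' feature and its `exon` features per model, with attributes carrying
#' coverage, completeness, capped status and per-sample support count.
#' Output is byte-deterministic for identical input.
#'
#' @param x An `eg_assembly` from [assemble()].
#' @param path Output file.
#' @return Number of transcripts written, invisibly.
#' @export
write_gtf <- function(x, path) {
  stopifnot(inherits(x, "eg_assembly"))
  m <- x$models
  chrom_names <- x$header$chroms$name
  lines <- character()
  for (i in seq_len(nrow(m))) {
    chrom <- chrom_names[m$chrom[i] + 1L]
    attrs <- sprintf(
      paste0('gene_id "%s"; transcript_id "%s"; cov "%s"; complete "%s"; ',
             'capped "%s"; samples "%d";'),
      m$gene_id[i], m$transcript_id[i], fmt_weight(round(m$coverage[i], 6)),
      ifelse(m$complete[i], "TRUE", "FALSE"),
      ifelse(m$capped[i], "TRUE", "FALSE"), m$n_samples_support[i])
    lines <- c(lines, sprintf("%s\tendguide\ttranscript\t%d\t%d\t%s\t%s\t.\t%s",
                              chrom, m$start[i] + 1L, m$end[i],
                              fmt_weight(round(m$coverage[i], 6)),
                              m$strand[i], attrs))
    ex <- m$exons[[i]]
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tendguide\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        chrom, ex[k, 1] + 1L, ex[k, 2], m$strand[i], attrs, k))
    }
  }
  writeLines(lines, path)
  invisible(nrow(m))
}

#' Convert a GTF annotation to weighted pseudo-reads
#'
#' Reads a GTF (via rtracklayer) and emits one end-labeled read model per
#' transcript: all junctions spliced, the annotated 5' end labeled as
#' capped evidence (`C`) and the 3' end as an End Tag (`E`), so existing
#' annotations can enter a meta-assembly as high-confidence full-length
#' evidence. Transcripts flagged `complete "FALSE"` keep labels only on
#' the sides their `has_source`/completeness semantics justify (here:
#' no labels). Unstranded transcripts are skipped with a warning.
#'
#' @param path GTF file.
#' @param header Optional [elr_header()]; built from the GTF seqnames when
#'   absent.
#' @param weight_source `"score"` (transcript score / `cov` attribute,
#'   fallback 1) or `"uniform"` (1 per transcript).
#' @param sample Sample index stamped on the pseudo-reads.
#' @return List with `header` and `reads`.
#' @export
gtf_to_read_models <- function(path, header = NULL,
                               weight_source = c("score", "uniform"),
                               sample = 0L) {
  weight_source <- match.arg(weight_source)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF contains no exon features")
  tx_ids <- unique(ex$transcript_id)
  if (is.null(header)) {
    chroms <- tibble::tibble(
      name = unique(as.character(GenomicRanges::seqnames(ex))))
    chroms$length <- vapply(chroms$name, function(cn)
      max(GenomicRanges::end(ex[as.character(GenomicRanges::seqnames(ex)) == cn])) +
        1000L, numeric(1)) |> as.integer()
    header <- elr_header(chroms)
  }
  tx <- gr[gr$type == "transcript"]
  rows <- list()
  for (tid in tx_ids) {
    e <- ex[ex$transcript_id == tid]
    e <- e[order(GenomicRanges::start(e))]
    strand <- as.character(GenomicRanges::strand(e))[1]
    if (!strand %in% c("+", "-")) {
      warning("skipping unstranded transcript ", tid)
      next
    }
    blocks <- cbind(start = GenomicRanges::start(e) - 1L,
                    end = GenomicRanges::end(e))
    trow <- tx[!is.na(tx$transcript_id) & tx$transcript_id == tid]
    complete <- TRUE
    if (length(trow) && !is.null(trow$complete) && !is.na(trow$complete[1]))
      complete <- trow$complete[1] == "TRUE"
    w <- 1
    if (weight_source == "score") {
      if (length(trow) && !is.null(trow$cov) && !is.na(trow$cov[1]))
        w <- as.numeric(trow$cov[1])
      else if (length(trow) && !is.null(trow$score) && !is.na(GenomicRanges::score(trow)[1]))
        w <- as.numeric(GenomicRanges::score(trow)[1])
    }
    ll <- "."; rl <- "."
    if (complete) {
      if (strand == "+") { ll <- "C"; rl <- "E" } else { ll <- "E"; rl <- "C" }
    }
    chrom_idx <- match(as.character(GenomicRanges::seqnames(e))[1],
                       header$chroms$name) - 1L
    rows[[length(rows) + 1L]] <- list(chrom = chrom_idx, blocks = blocks,
                                      strand = strand, ll = ll, rl = rl, w = w)
  }
  if (!length(rows)) return(list(header = header, reads = read_models()))
  reads <- read_models(
    chrom = vapply(rows, `[[`, integer(1), "chrom"),
    blocks = lapply(rows, `[[`, "blocks"),
    junctions = lapply(rows, function(r) rep("SPLICE", nrow(r$blocks) - 1L)),
    strand = vapply(rows, `[[`, character(1), "strand"),
    left_label = vapply(rows, `[[`, character(1), "ll"),
    right_label = vapply(rows, `[[`, character(1), "rl"),
    weight = vapply(rows, `[[`, double(1), "w"),
    sample = sample)
  list(header = header, reads = sort_read_models(reads))
}
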