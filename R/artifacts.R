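#' Flag high-error exons
#'
#' Long-read alignments occasionally contain exons that are mostly
#' alignment error (e.g. around low-quality homopolymers); such exons
#' produce spurious splice boundaries. An exon is flagged when its total
#' error (mismatches + inserted bases + deleted bases) strictly exceeds
#' `max_fraction` of its length: a 100 nt exon with 10 error bases passes,
#' 11 is flagged.
#'
#' @param profile Tibble/data frame with per-exon columns `length`, `mm`,
#'   `ins`, `del`.
#' @param max_fraction Error fraction ceiling (default 0.10).
#' @return Logical vector, one entry per exon.
#' @export
#' @examples
#' flag_high_error_exons(data.frame(length = 100, mm = 10, ins = 0, del = 0))
#' flag_high_error_exons(data.frame(length = 100, mm = 8, ins = 2, del = 1))
flag_high_error_exons <- function(profile, max_fraction = 0.10) {
  (profile$mm + profile$ins + profile$del) > max_fraction * profile$length
}

# apply the high-error-exon filter to an intermediate read structure:
# flagged internal exons are removed (their junctions become a GAP);
# flagged terminal exons are trimmed off with their end label.
drop_high_error_exons <- function(m, max_fraction = 0.10) {
  n <- nrow(m$blocks)
  prof <- data.frame(length = m$blocks[, 2] - m$blocks[, 1],
                     mm = m$exon_mm %||% rep(0L, n),
                     ins = m$exon_ins %||% rep(0L, n),
                     del = m$exon_del %||% rep(0L, n))
  bad <- flag_high_error_exons(prof, max_fraction)
  if (!any(bad)) return(m)
  if (all(bad)) return(NULL)
  keep <- which(!bad)
  if (bad[1L]) m$left_label <- "."
  if (bad[n]) m$right_label <- "."
  junctions <- character()
  for (k in seq_len(length(keep) - 1L)) {
    a <- keep[k]; b <- keep[k + 1L]
    junctions <- c(junctions,
                   if (b == a + 1L) m$junctions[a] else "GAP")
  }
  m$blocks <- m$blocks[keep, , drop = FALSE]
  m$junctions <- junctions
  m$exon_mm <- prof$mm[keep]; m$exon_ins <- prof$ins[keep]
  m$exon_del <- prof$del[keep]
  m
}

#' Flag oligo-dT mispriming
#'
#' Oligo-dT primers anneal not only to poly(A) tails but to genomic A-rich
#' tracts inside transcripts, producing false polyadenylation evidence. A
#' putative cleavage site is flagged when the downstream genomic window (in
#' transcript sense) is A-rich: at least `min_A` A's within `window` nt.
#'
#' @param end_pos 0-based cleavage position (half-open transcript end: the
#'   first genomic base downstream on `+`, one past the last transcribed
#'   base; on `-` the window covers `end_pos - window .. end_pos - 1` as
#'   T's).
#' @param strand `"+"` or `"-"` (transcript sense).
#' @param genome Named character vector / `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param window Window size in nt; 0 disables flagging.
#' @param min_A Minimum count of sense-strand A's in the window.
#' @return `TRUE` if the end looks misprimed.
#' @export
flag_mispriming <- function(end_pos, strand, genome, chrom,
                            window = 20L, min_A = 12L) {
  if (window <= 0L) return(FALSE)
  seqs <- genome_seqs(genome)
  chrseq <- seqs[[chrom]]
  L <- nchar(chrseq)
  if (strand == "+") {
    lo <- end_pos; hi <- min(L, end_pos + window)
    if (lo >= hi) return(FALSE)
    win <- substr(chrseq, lo + 1L, hi)
    sum(strsplit(win, "")[[1]] == "A") >= min_A
  } else {
    lo <- max(0L, end_pos - window); hi <- end_pos
    if (lo >= hi) return(FALSE)
    win <- substr(chrseq, lo + 1L, hi)
    sum(strsplit(win, "")[[1]] == "T") >= min_A
  }
}

#' Strip artifact end labels from a read
#'
#' Applies the mispriming check to a confirmed End Tag and removes the
#' label when it fails; the read body is never altered. Idempotent.
#'
#' @param m A read-model tibble (any number of rows) or an internal
#'   intermediate read structure.
#' @param genome,window,min_A See [flag_mispriming()].
#' @param header An [elr_header()]; required for the tibble form to map
#'   chromosome indices to sequence names.
#' @return The read(s) with artifact labels removed.
#' @export
strip_artifact_labels <- function(m, genome, window = 20L, min_A = 12L,
                                  header = NULL) {
  if (!inherits(m, "data.frame")) {
    if (m$right_label == "E" && m$strand == "+" &&
        flag_mispriming(m$blocks[nrow(m$blocks), 2], "+", genome, m$chrom,
                        window, min_A))
      m$right_label <- "."
    if (m$left_label == "E" && m$strand == "-" &&
        flag_mispriming(m$blocks[1L, 1L], "-", genome, m$chrom, window, min_A))
      m$left_label <- "."
    return(m)
  }
  stopifnot(!is.null(header))
  for (i in seq_len(nrow(m))) {
    chrom <- header$chroms$name[m$chrom[i] + 1L]
    b <- m$blocks[[i]]
    if (m$right_label[i] == "E" && m$strand[i] == "+" &&
        flag_mispriming(b[nrow(b), 2], "+", genome, chrom, window, min_A))
      m$right_label[i] <- "."
    if (m$left_label[i] == "E" && m$strand[i] == "-" &&
        flag_mispriming(b[1L, 1L], "-", genome, chrom, window, min_A))
      m$left_label[i] <- "."
  }
  m
}
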