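#' Read / write FASTQ as a tibble
#'
#' Thin wrappers over Biostrings FASTQ support. Reads come back as a tibble
#' with one row per read and phred+33 quality strings.
#'
#' @param path FASTQ file (gzip transparent).
#' @return `read_fastq()`: tibble with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    name = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fastq
#' @param reads Tibble with columns `name`, `seq`, `qual`.
#' @return `write_fastq()`: number of reads written, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(nrow(reads))
}

#' Default end-label adapters
#'
#' The template-switching oligo whose 3' end marks cDNA 5' termini, and
#' the oligo-dT primer marking 3' termini; the trailing `+` flags the
#' homopolymer run as greedily extendable during trimming.
#' @export
TSO_ADAPTER <- "AAGCAGTGGTATCAACGCAGAGTACGGG"

#' @rdname TSO_ADAPTER
#' @export
OLIGODT_ADAPTER <- "AAGCAGTGGTATCAACGCAGAGTACTTTTTTTTTTTTTTTTTTTT+"

phred <- function(qual) utf8ToInt(qual) - 33L

# longest k >= min_len s.t. the first k read bases match the last k adapter
# bases with mismatch fraction <= rate; bases with quality < qualmask match
# anything. Returns 0 when nothing qualifies.
prefix_overlap <- function(seq, qual, adapter, min_len, rate, qualmask) {
  rs <- strsplit(seq, "")[[1]]
  as <- strsplit(adapter, "")[[1]]
  q <- if (nzchar(qual)) phred(qual) else rep(60L, length(rs))
  kmax <- min(length(rs), length(as))
  if (kmax < min_len) return(0L)
  for (k in kmax:min_len) {
    r <- rs[seq_len(k)]
    a <- as[(length(as) - k + 1L):length(as)]
    mm <- sum(r != a & q[seq_len(k)] >= qualmask)
    if (mm / k <= rate) return(k)
  }
  0L
}

# mirrored: longest k s.t. the last k read bases match the first k bases of
# `lead` (used for the reverse-complemented oligo-dT at the read 3' end).
suffix_overlap <- function(seq, qual, lead, min_len, rate, qualmask) {
  rs <- strsplit(seq, "")[[1]]
  as <- strsplit(lead, "")[[1]]
  q <- if (nzchar(qual)) phred(qual) else rep(60L, length(rs))
  n <- length(rs)
  kmax <- min(n, length(as))
  if (kmax < min_len) return(0L)
  for (k in kmax:min_len) {
    r <- rs[(n - k + 1L):n]
    a <- as[seq_len(k)]
    mm <- sum(r != a & q[(n - k + 1L):n] >= qualmask)
    if (mm / k <= rate) return(k)
  }
  0L
}

#' Detect and trim an end label on one read
#'
#' Scans the read for evidence of the 5' template-switching oligo or the 3'
#' oligo-dT primer. The 5' label is the longest read prefix matching a
#' suffix of `adapter_5`; the 3' label is either a read prefix matching the
#' T-run end of `adapter_3` (extending greedily through additional T) or a
#' read suffix running into the reverse complement of `adapter_3` (an A-run,
#' extended greedily leftward). Bases below `qualmask` are wildcards during
#' matching. Reads with mean quality below `minqual` or post-trim length
#' below `minlen` are discarded.
#'
#' @param seq,qual Read sequence and phred+33 quality string (`qual = ""`
#'   treats all bases as high quality).
#' @param adapter_5,adapter_3 Adapter sequences 5'->3'; a trailing `+` on
#'   `adapter_3` marks the extendable homopolymer.
#' @param min_start,min_end Minimum matched length for a 5' / 3' label.
#' @param mismatch_rate Maximum mismatch fraction in the matched region.
#' @param minlen Minimum post-trim read length.
#' @param minqual Minimum mean base quality.
#' @param qualmask Quality below which a base matches anything.
#' @return List with `seq`, `qual`, `label` (`"5"`, `"3"`, `"none"`),
#'   `label_len` (bases removed), `discard` (logical) and `reason`.
#' @export
#' @examples
#' r <- detect_label(paste0("AAGCAGTGGTATCAACGCAGAGTACGGG",
#'                          "TTCGATCGGAGCTACGATCGATCGTAGCTAGCTAAGGCAT"), "")
#' r$label; r$label_len
detect_label <- function(seq, qual = "",
                         adapter_5 = TSO_ADAPTER, adapter_3 = OLIGODT_ADAPTER,
                         min_start = 7L, min_end = 9L, mismatch_rate = 0.06,
                         minlen = 18L, minqual = 25, qualmask = 16L) {
  out <- list(seq = seq, qual = qual, label = "none", label_len = 0L,
              discard = FALSE, reason = "")
  if (nzchar(qual) && mean(phred(qual)) < minqual) {
    out$discard <- TRUE; out$reason <- "low mean quality"
    return(out)
  }
  extend3 <- endsWith(adapter_3, "+")
  core3 <- sub("\\+$", "", adapter_3)
  homopol <- substr(core3, nchar(core3), nchar(core3))
  rc3 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core3)))

  k5 <- prefix_overlap(seq, qual, adapter_5, min_start, mismatch_rate, qualmask)
  k3p <- prefix_overlap(seq, qual, core3, min_end, mismatch_rate, qualmask)
  if (k3p > 0L && extend3) {
    while (k3p < nchar(seq) && substr(seq, k3p + 1L, k3p + 1L) == homopol)
      k3p <- k3p + 1L
  }
  k3s <- suffix_overlap(seq, qual, rc3, min_end, mismatch_rate, qualmask)
  if (k3s > 0L && extend3) {
    homopol_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(homopol)))
    while (k3s < nchar(seq) &&
           substr(seq, nchar(seq) - k3s, nchar(seq) - k3s) == homopol_rc)
      k3s <- k3s + 1L
  }

  # same-terminus conflict (both 5' and 3' match the read start): keep longer
  if (k5 >= k3p && k5 > 0L) k3p <- 0L else if (k3p > 0L) k5 <- 0L

  if (k5 > 0L) {
    out$label <- "5"; out$label_len <- k5
    out$seq <- substr(seq, k5 + 1L, nchar(seq))
    out$qual <- if (nzchar(qual)) substr(qual, k5 + 1L, nchar(qual)) else ""
  } else if (k3p > 0L || k3s > 0L) {
    out$label <- "3"
    if (k3p >= k3s) {
      out$label_len <- k3p
      out$seq <- substr(seq, k3p + 1L, nchar(seq))
      out$qual <- if (nzchar(qual)) substr(qual, k3p + 1L, nchar(qual)) else ""
    } else {
      out$label_len <- k3s
      out$seq <- substr(seq, 1L, nchar(seq) - k3s)
      out$qual <- if (nzchar(qual)) substr(qual, 1L, nchar(qual) - k3s) else ""
    }
  }
  if (nchar(out$seq) < minlen) {
    out$discard <- TRUE; out$reason <- "shorter than minlen after trimming"
  }
  out
}

#' Label a whole FASTQ table
#'
#' Applies [detect_label()] to every read, drops discarded reads, and
#' records the found label as a `/S` (5') or `/E` (3') read-name suffix so
#' it survives alignment.
#'
#' @param reads Tibble from [read_fastq()].
#' @param ... Parameters passed to [detect_label()].
#' @return Labeled, trimmed read tibble with extra columns `label` and
#'   `label_len`.
#' @export
label_reads <- function(reads, ...) {
  res <- purrr::map2(reads$seq, reads$qual %||% rep("", nrow(reads)),
                     function(s, q) detect_label(s, q, ...))
  out <- tibble::tibble(
    name = reads$name,
    seq = purrr::map_chr(res, "seq"),
    qual = purrr::map_chr(res, "qual"),
    label = purrr::map_chr(res, "label"),
    label_len = purrr::map_int(res, "label_len"),
    discard = purrr::map_lgl(res, "discard")
  )
  out <- out[!out$discard, setdiff(names(out), "discard")]
  suffix <- c("5" = "/S", "3" = "/E", "none" = "")[out$label]
  out$name <- paste0(sub("/[SE]$", "", out$name), suffix)
  out
}

#' Label a read pair
#'
#' Labels each mate independently; orientation metadata (which mate carries
#' the 5' label) is preserved through the read names for downstream ELR
#' conversion. A pair is kept only if both mates survive their filters.
#'
#' @param read1,read2 Single-row tibbles (or lists) with `name`, `seq`,
#'   `qual`.
#' @param ... Parameters passed to [detect_label()].
#' @return List with elements `r1`, `r2` (each as [detect_label()] output)
#'   and `keep`.
#' @export
label_pair <- function(read1, read2, ...) {
  r1 <- detect_label(read1$seq, read1$qual %||% "", ...)
  r2 <- detect_label(read2$seq, read2$qual %||% "", ...)
  list(r1 = r1, r2 = r2, keep = !(r1$discard || r2$discard))
}
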