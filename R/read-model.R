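#' Build a table of read models
#'
#' The central container of the package: one row per aligned read (or
#' weighted pseudo-read), with exon blocks and junction codes held in
#' list-columns. All coordinates are 0-based half-open genomic intervals,
#' written genomic left-to-right regardless of strand.
#'
#' @param chrom Integer chromosome index (0-based, into the header table).
#' @param blocks List of integer matrices with columns `start`, `end`
#'   (half-open), rows strictly increasing and non-overlapping.
#' @param junctions List of character vectors, one code per adjacent block
#'   pair: `"SPLICE"` (spliced intron) or `"GAP"` (unsequenced mate gap).
#' @param strand `"+"`, `"-"` or `"."` (unstranded).
#' @param left_label,right_label Label on the genomic-left / genomic-right
#'   terminus: `"S"` (Start Tag), `"C"` (Cap Tag, 5' label with upstream
#'   untemplated G), `"E"` (End Tag) or `"."` (none).
#' @param weight Non-negative read-count equivalent.
#' @param sample Integer sample index (0-based).
#' @param validate Check invariants (label/strand consistency, block order).
#'
#' @return A tibble of class `eg_reads`.
#' @export
#' @examples
#' read_models(
#'   chrom = 0L,
#'   blocks = list(cbind(start = c(100L, 500L), end = c(200L, 650L))),
#'   junctions = list("SPLICE"),
#'   strand = "+", left_label = "S", right_label = "E"
#' )
read_models <- function(chrom = integer(), blocks = list(),
                        junctions = NULL, strand = character(),
                        left_label = ".", right_label = ".",
                        weight = 1, sample = 0L, validate = TRUE) {
  n <- length(blocks)
  blocks <- lapply(blocks, function(b) {
    b <- matrix(as.integer(b), ncol = 2, dimnames = list(NULL, c("start", "end")))
    b
  })
  if (is.null(junctions)) {
    junctions <- lapply(blocks, function(b) rep("SPLICE", max(0L, nrow(b) - 1L)))
  }
  out <- tibble::tibble(
    chrom = recycle_n(as.integer(chrom), n),
    start = vapply(blocks, function(b) b[1L, 1L], integer(1)),
    end = vapply(blocks, function(b) b[nrow(b), 2L], integer(1)),
    strand = recycle_n(as.character(strand), n),
    blocks = blocks,
    junctions = junctions,
    left_label = recycle_n(as.character(left_label), n),
    right_label = recycle_n(as.character(right_label), n),
    weight = recycle_n(as.double(weight), n),
    sample = recycle_n(as.integer(sample), n)
  )
  class(out) <- c("eg_reads", class(out))
  if (validate) validate_read_models(out)
  out
}

#' Check read-model invariants
#'
#' Errors if any row violates the container contract: ordered non-overlapping
#' blocks, one junction code per adjacent block pair, labels consistent with
#' strand (on `+`, S/C may only sit on the left terminus and E on the right;
#' mirrored on `-`; unstranded reads carry no labels), non-negative weight.
#'
#' @param reads A read-model tibble.
#' @return `reads`, invisibly.
#' @export
validate_read_models <- function(reads) {
  for (i in seq_len(nrow(reads))) {
    b <- reads$blocks[[i]]
    if (nrow(b) == 0L) stop("read ", i, ": empty block list")
    if (any(b[, 2] <= b[, 1])) stop("read ", i, ": empty or inverted block")
    if (nrow(b) > 1L && any(b[-1L, 1] < b[-nrow(b), 2]))
      stop("read ", i, ": blocks overlap or are unsorted")
    j <- reads$junctions[[i]]
    if (length(j) != nrow(b) - 1L)
      stop("read ", i, ": need ", nrow(b) - 1L, " junction codes, got ", length(j))
    if (length(j) && !all(j %in% c("SPLICE", "GAP")))
      stop("read ", i, ": bad junction code")
    s <- reads$strand[i]
    ll <- reads$left_label[i]; rl <- reads$right_label[i]
    if (!s %in% c("+", "-", ".")) stop("read ", i, ": bad strand")
    if (!ll %in% c("S", "C", "E", ".") || !rl %in% c("S", "C", "E", "."))
      stop("read ", i, ": bad label")
    if (s == "." && (ll != "." || rl != "."))
      stop("read ", i, ": unstranded read carries end labels")
    if (s == "+" && (ll == "E" || rl %in% c("S", "C")))
      stop("read ", i, ": label inconsistent with + strand")
    if (s == "-" && (rl == "E" || ll %in% c("S", "C")))
      stop("read ", i, ": label inconsistent with - strand")
    if (reads$weight[i] < 0) stop("read ", i, ": negative weight")
  }
  invisible(reads)
}

#' ELR header: chromosome and sample tables
#'
#' @param chroms Tibble or data frame with columns `name`, `length`; row
#'   order defines the dense 0-based chromosome indices.
#' @param samples Character vector of sample names (0-based indices by
#'   position).
#' @return A list of class `elr_header`.
#' @export
elr_header <- function(chroms, samples = "sample0") {
  chroms <- tibble::as_tibble(chroms)
  stopifnot(all(c("name", "length") %in% names(chroms)))
  if (anyDuplicated(chroms$name)) stop("duplicate chromosome names in header")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample names in header")
  structure(list(chroms = chroms[, c("name", "length")],
                 samples = tibble::tibble(name = samples)),
            class = "elr_header")
}

#' @export
print.elr_header <- function(x, ...) {
  cat("<elr_header> ", nrow(x$chroms), " chromosome(s), ",
      nrow(x$samples), " sample(s)\n", sep = "")
  invisible(x)
}

# Exact-but-readable numeric formatting: shortest decimal form that parses
# back to the same double; integers get a trailing ".0" so weights are
# visibly real-valued.
fmt_weight <- function(w) {
  vapply(w, function(x) {
    if (is.finite(x) && x == round(x) && abs(x) < 1e15) return(sprintf("%.1f", x))
    s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == x) s else sprintf("%.17g", x)
  }, character(1))
}

#' Serialize read models to blockstrings
#'
#' A blockstring is the compact single-token encoding of one read's
#' structure: a left label character (`S`, `C`, `E` or `.`), exon lengths
#' alternating with junction spans, and a right label character. A junction
#' span is the intron/gap length wrapped in a doubled junction character:
#' `>` for a splice, `_` for an unsequenced mate gap. Example:
#' `.50>900>200_100_50.` is a 3-block read (50, 200, 50 nt) with a 900 nt
#' intron then a 100 nt mate gap, no end labels.
#'
#' @param blocks Integer matrix of half-open block intervals.
#' @param junctions Character vector of junction codes.
#' @param left_label,right_label Label characters.
#' @return A single string.
#' @export
format_blockstring <- function(blocks, junctions,
                               left_label = ".", right_label = ".") {
  lens <- blocks[, 2] - blocks[, 1]
  parts <- as.character(lens[1])
  if (nrow(blocks) > 1L) {
    for (k in seq_len(nrow(blocks) - 1L)) {
      jc <- if (junctions[k] == "SPLICE") ">" else "_"
      gap <- blocks[k + 1L, 1] - blocks[k, 2]
      parts <- c(parts, jc, as.character(gap), jc, as.character(lens[k + 1L]))
    }
  }
  paste0(left_label, paste0(parts, collapse = ""), right_label)
}

#' Parse a blockstring
#'
#' Inverse of [format_blockstring()]; needs the genomic start to anchor the
#' block coordinates.
#'
#' @param x Blockstring.
#' @param start 0-based genomic start of the first block.
#' @return List with `blocks`, `junctions`, `left_label`, `right_label`.
#' @export
parse_blockstring <- function(x, start = 0L) {
  n <- nchar(x)
  if (n < 3L) stop("malformed blockstring: ", x)
  ll <- substr(x, 1L, 1L)
  rl <- substr(x, n, n)
  if (!ll %in% c("S", "C", "E", ".") || !rl %in% c("S", "C", "E", "."))
    stop("malformed blockstring labels: ", x)
  body <- substr(x, 2L, n - 1L)
  nums <- suppressWarnings(as.integer(strsplit(body, "[>_]")[[1]]))
  seps <- regmatches(body, gregexpr("[>_]", body))[[1]]
  # grammar: exon ( J intron J exon )*  -> 2J+1 numbers, 2J separator
  # characters that pair up around each intron/gap length
  if (length(nums) == 0L || anyNA(nums) ||
      length(seps) != length(nums) - 1L || length(nums) %% 2L == 0L)
    stop("malformed blockstring body: ", x)
  if (length(seps)) {
    odd <- seps[seq(1L, length(seps), 2L)]
    even <- seps[seq(2L, length(seps), 2L)]
    if (!all(odd == even))
      stop("malformed blockstring junctions: ", x)
    seps <- strrep(odd, 2L)
  }
  n_blocks <- (length(nums) + 1L) %/% 2L
  starts <- integer(n_blocks); ends <- integer(n_blocks)
  pos <- as.integer(start)
  bi <- 1L
  for (k in seq_along(nums)) {
    if (k %% 2 == 1L) { # exon
      starts[bi] <- pos; ends[bi] <- pos + nums[k]
      pos <- pos + nums[k]; bi <- bi + 1L
    } else pos <- pos + nums[k]
  }
  list(blocks = cbind(start = starts, end = ends),
       junctions = if (length(seps)) ifelse(seps == ">>", "SPLICE", "GAP") else character(),
       left_label = ll, right_label = rl)
}

blockstrings <- function(reads) {
  vapply(seq_len(nrow(reads)), function(i) {
    format_blockstring(reads$blocks[[i]], reads$junctions[[i]],
                       reads$left_label[i], reads$right_label[i])
  }, character(1))
}

#' Sort read models into canonical ELR order
#'
#' Orders by (chromosome index, start, blockstring, sample index), the sort
#' key assumed by [write_elr()] and the locus chunker.
#'
#' @param reads A read-model tibble.
#' @return The sorted tibble.
#' @export
sort_read_models <- function(reads) {
  bs <- blockstrings(reads)
  reads[order(reads$chrom, reads$start, bs, reads$sample, method = "radix"), ]
}
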