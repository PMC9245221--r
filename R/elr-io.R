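#' Write read models to an ELR file
#'
#' ELR (end-labeled read) is a sorted, line-oriented text format holding one
#' read per line plus a header declaring chromosome and sample tables:
#' \preformatted{
#' #C <idx> <name> <length>
#' #S <idx> <name>
#' <chrom_idx> <start> <strand> <blockstring> <weight> <sample_idx>
#' }
#' Records must arrive sorted by (chromosome, start, blockstring, sample);
#' identical reads are written as-is (merging weights is the condensation
#' step's job, not serialization's).
#'
#' @param reads Read-model tibble, sorted (see [sort_read_models()]).
#' @param header An [elr_header()].
#' @param path Output file path or connection.
#' @return Number of records written, invisibly.
#' @export
#' @examples
#' h <- elr_header(tibble::tibble(name = "chr1", length = 10000L))
#' r <- read_models(0L, list(cbind(1000L, 1100L)), list(character()), "+",
#'                  "S", "E")
#' f <- tempfile(fileext = ".elr")
#' write_elr(r, h, f)
#' readLines(f)
write_elr <- function(reads, header, path) {
  stopifnot(inherits(header, "elr_header"))
  if (any(reads$chrom < 0L) || any(reads$chrom >= nrow(header$chroms)))
    stop("record references a chromosome index missing from the header")
  if (any(reads$sample < 0L) || any(reads$sample >= nrow(header$samples)))
    stop("record references a sample index missing from the header")
  bs <- blockstrings(reads)
  keys <- paste(reads$chrom, reads$start, bs, reads$sample)
  o <- order(reads$chrom, reads$start, bs, reads$sample, method = "radix")
  if (!identical(keys, keys[o]))
    stop("reads are not sorted by (chrom, start, blockstring, sample)")
  hc <- sprintf("#C %d %s %d", seq_len(nrow(header$chroms)) - 1L,
                header$chroms$name, header$chroms$length)
  hs <- sprintf("#S %d %s", seq_len(nrow(header$samples)) - 1L,
                header$samples$name)
  rec <- sprintf("%d\t%d\t%s\t%s\t%s\t%d", reads$chrom, reads$start,
                 reads$strand, bs, fmt_weight(reads$weight), reads$sample)
  writeLines(c(hc, hs, rec), path)
  invisible(length(rec))
}

#' Read an ELR file
#'
#' @param path ELR file path or connection.
#' @return List with `header` (an [elr_header()]) and `reads` (a read-model
#'   tibble in file order). Invariants are validated; malformed lines raise
#'   an error naming the line number.
#' @export
read_elr <- function(path) {
  lines <- readLines(path)
  is_c <- startsWith(lines, "#C ")
  is_s <- startsWith(lines, "#S ")
  ct <- strsplit(lines[is_c], " ", fixed = TRUE)
  st <- strsplit(lines[is_s], " ", fixed = TRUE)
  if (!length(ct)) stop("ELR header: no chromosome table")
  if (!length(st)) stop("ELR header: no sample table")
  chroms <- tibble::tibble(
    idx = vapply(ct, function(x) as.integer(x[2]), integer(1)),
    name = vapply(ct, `[`, character(1), 3L),
    length = vapply(ct, function(x) as.integer(x[4]), integer(1))
  )
  samples <- tibble::tibble(
    idx = vapply(st, function(x) as.integer(x[2]), integer(1)),
    name = vapply(st, `[`, character(1), 3L)
  )
  if (!identical(chroms$idx, seq_len(nrow(chroms)) - 1L) ||
      !identical(samples$idx, seq_len(nrow(samples)) - 1L))
    stop("ELR header: indices must be dense from 0")
  header <- elr_header(chroms[, c("name", "length")], samples$name)

  body_idx <- which(!is_c & !is_s & nzchar(lines))
  n <- length(body_idx)
  chrom <- integer(n); start <- integer(n); strand <- character(n)
  blocks <- vector("list", n); junctions <- vector("list", n)
  ll <- character(n); rl <- character(n); weight <- double(n); sample <- integer(n)
  for (k in seq_len(n)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L) stop("ELR line ", i, ": expected 6 fields, got ", length(f))
    chrom[k] <- as.integer(f[1]); start[k] <- as.integer(f[2])
    strand[k] <- f[3]
    p <- tryCatch(parse_blockstring(f[4], start[k]),
                  error = function(e) stop("ELR line ", i, ": ", conditionMessage(e)))
    blocks[[k]] <- p$blocks; junctions[[k]] <- p$junctions
    ll[k] <- p$left_label; rl[k] <- p$right_label
    weight[k] <- as.double(f[5]); sample[k] <- as.integer(f[6])
    if (is.na(chrom[k]) || chrom[k] < 0L || chrom[k] >= nrow(header$chroms))
      stop("ELR line ", i, ": chromosome index out of range")
    if (is.na(sample[k]) || sample[k] < 0L || sample[k] >= nrow(header$samples))
      stop("ELR line ", i, ": sample index out of range")
  }
  reads <- read_models(chrom = chrom, blocks = blocks, junctions = junctions,
                       strand = strand, left_label = ll, right_label = rl,
                       weight = weight, sample = sample)
  list(header = header, reads = reads)
}

#' Merge sorted ELR files
#'
#' Merges any number of individually sorted ELR files into one globally
#' sorted read table. Chromosomes are matched by name (conflicting lengths
#' for one name is a header conflict); sample tables are concatenated with
#' made-unique names, and each file's sample indices are remapped into the
#' merged table, so total weight is conserved.
#'
#' @param paths Character vector of ELR file paths.
#' @param distinct_samples If `FALSE`, samples with identical names across
#'   files are pooled under one index instead of kept separate.
#' @return List with merged `header` and sorted `reads`.
#' @export
sort_merge_elr <- function(paths, distinct_samples = TRUE) {
  parts <- lapply(paths, read_elr)
  chroms <- tibble::tibble(name = character(), length = integer())
  all_samples <- character()
  merged <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    h <- parts[[k]]$header
    for (j in seq_len(nrow(h$chroms))) {
      hit <- match(h$chroms$name[j], chroms$name)
      if (is.na(hit)) {
        chroms <- dplyr::bind_rows(chroms, h$chroms[j, ])
      } else if (chroms$length[hit] != h$chroms$length[j]) {
        stop("header conflict: chromosome ", h$chroms$name[j],
             " has lengths ", chroms$length[hit], " and ", h$chroms$length[j])
      }
    }
    snames <- h$samples$name
    if (distinct_samples) snames <- paste0(snames, ".", k)
    new <- setdiff(snames, all_samples)
    all_samples <- c(all_samples, new)
    r <- parts[[k]]$reads
    chrom_map <- match(h$chroms$name, chroms$name) - 1L
    sample_map <- match(snames, all_samples) - 1L
    r$chrom <- chrom_map[r$chrom + 1L]
    r$sample <- sample_map[r$sample + 1L]
    merged[[k]] <- r
  }
  reads <- sort_read_models(dplyr::bind_rows(merged))
  class(reads) <- c("eg_reads", setdiff(class(reads), "eg_reads"))
  list(header = elr_header(chroms, all_samples), reads = reads)
}
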