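#' Read / write minimal SAM text
#'
#' Parses the 11 mandatory SAM columns plus `NM`/`MD` tags into an
#' alignment-record tibble; `@SQ` header lines become the chromosome table.
#' Only what the ELR converter consumes is modeled (no BAM/CRAM).
#'
#' @param path SAM file path.
#' @return List with `chroms` (tibble `name`, `length`) and `alignments`
#'   (tibble with columns `qname`, `flag`, `chrom`, `pos` (1-based),
#'   `mapq`, `cigar`, `seq`, `qual`, `nm`, `md`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  chroms <- tibble::tibble(
    name = sub(".*\tSN:([^\t]+).*", "\\1", sq),
    length = as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  )
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, character(1), i)
  tagval <- function(tag) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", tag, ":"), x[-(1:11)], value = TRUE)
      if (length(hit)) sub("^[A-Za-z]+:[AifZHB]:", "", hit[1]) else NA_character_
    }, character(1))
  }
  aln <- tibble::tibble(
    qname = get(1), flag = as.integer(get(2)), chrom = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    seq = get(10), qual = get(11),
    nm = suppressWarnings(as.integer(tagval("NM"))), md = tagval("MD")
  )
  list(chroms = chroms, alignments = aln)
}

#' @rdname read_sam
#' @param aln Alignment tibble as returned in `$alignments`.
#' @param chroms Chromosome table for `@SQ` lines.
#' @export
write_sam <- function(aln, chroms, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms$name, chroms$length))
  opt <- character(nrow(aln))
  if (!is.null(aln$nm)) opt <- ifelse(is.na(aln$nm), "", sprintf("\tNM:i:%d", aln$nm))
  if (!is.null(aln$md)) opt <- paste0(opt, ifelse(is.na(aln$md), "", sprintf("\tMD:Z:%s", aln$md)))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                 aln$qname, aln$flag, aln$chrom, aln$pos,
                 aln$mapq %||% 60L, aln$cigar, aln$seq,
                 aln$qual %||% "*", opt)
  writeLines(c(hdr, rec), path)
  invisible(nrow(aln))
}

# parse a CIGAR into 0-based blocks, junction codes, soft clip lengths and
# per-exon inserted/deleted base counts (aligned ref segments between N's).
parse_cigar <- function(cigar, pos1) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  ref <- pos1 - 1L # 0-based
  starts <- integer(); ends <- integer(); ins <- integer(); del <- integer()
  cur_start <- NA_integer_; cur_ins <- 0L; cur_del <- 0L
  clip_left <- 0L; clip_right <- 0L
  seen_aln <- FALSE
  flush <- function() {
    if (!is.na(cur_start)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, ref)
      ins <<- c(ins, cur_ins); del <<- c(del, cur_del)
    }
    cur_start <<- NA_integer_; cur_ins <<- 0L; cur_del <<- 0L
  }
  for (k in seq_along(op)) {
    o <- op[k]; l <- len[k]
    if (o %in% c("M", "=", "X")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + l; seen_aln <- TRUE
    } else if (o == "D") {
      if (is.na(cur_start)) cur_start <- ref
      cur_del <- cur_del + l; ref <- ref + l
    } else if (o == "I") {
      cur_ins <- cur_ins + l
    } else if (o == "N") {
      flush(); ref <- ref + l
    } else if (o == "S") {
      if (!seen_aln) clip_left <- l else clip_right <- l
    }
  }
  flush()
  list(blocks = cbind(start = starts, end = ends),
       junctions = rep("SPLICE", max(0L, length(starts) - 1L)),
       clip_left = clip_left, clip_right = clip_right,
       ins = ins, del = del)
}

# per-exon mismatch counts from an MD tag (deletions tracked via CIGAR)
md_mismatch_per_exon <- function(md, blocks) {
  if (is.na(md) || !nzchar(md)) return(rep(0L, nrow(blocks)))
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  # ref offsets are relative to aligned (non-N) reference bases
  exon_len <- blocks[, 2] - blocks[, 1]
  cum <- cumsum(exon_len)
  mm <- rep(0L, nrow(blocks))
  off <- 0L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) off <- off + as.integer(t)
    else if (startsWith(t, "^")) off <- off + nchar(t) - 1L
    else {
      exon <- which(off < cum)[1]
      if (!is.na(exon)) mm[exon] <- mm[exon] + 1L
      off <- off + 1L
    }
  }
  mm
}

rc_chr <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# mismatch fraction of `clip` (given adjacent-to-alignment last) against the
# tail of `pattern`; R in the pattern matches A or G.
clip_matches <- function(clip, pattern, mismatch_rate) {
  k <- min(nchar(clip), nchar(pattern))
  if (k == 0L) return(TRUE) # nothing untemplated left to contradict the label
  cl <- strsplit(substr(clip, nchar(clip) - k + 1L, nchar(clip)), "")[[1]]
  pt <- strsplit(substr(pattern, nchar(pattern) - k + 1L, nchar(pattern)), "")[[1]]
  ok <- ifelse(pt == "R", cl %in% c("A", "G"), cl == pt)
  sum(!ok) / k <= mismatch_rate
}

genome_seqs <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome); names(out) <- names(genome); out
  } else unlist(genome)
}

#' Convert aligned reads to end-labeled read models
#'
#' Turns an alignment-record tibble (see [read_sam()]) plus the reference
#' genome into a read-model tibble, confirming pre-alignment end labels
#' against the soft-clipped (untemplated) terminal sequence and classifying
#' confirmed 5' labels as Cap Tags when at least one untemplated G sits
#' immediately adjacent to the aligned start. Mates of a pair are fused into
#' one read model with a `GAP` junction (overlapping mates are unioned;
#' contradictory splice patterns drop the pair). High-error exons and
#' oligo-dT mispriming artifacts are filtered via [flag_high_error_exons()]
#' and [flag_mispriming()].
#'
#' Label provenance travels in the read name suffix written by
#' [label_reads()]: `/S` = 5' label at the read 5' end, `/E` = 3' label
#' trimmed at the read 5' end (oligo-dT read-through, read is antisense to
#' the transcript), `/EA` = 3' label trimmed at the read 3' end (sense
#' A-run).
#'
#' @param aln Alignment tibble.
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param header An [elr_header()] providing chromosome and sample indices.
#' @param sample Sample index for all converted reads.
#' @param start_seq Untemplated 5' pattern (clip tail) confirming a Start
#'   Tag; default `"ACGGG"`.
#' @param end_seq Untemplated 3' pattern; `R` matches A or G. Default 30 R.
#' @param mismatch_rate Maximum clip/pattern mismatch fraction.
#' @param stranded Assign the alignment strand to unlabeled reads.
#' @param max_error_fraction Per-exon error ceiling for
#'   [flag_high_error_exons()]; `NA` disables the filter.
#' @param mispriming_window,min_A Genomic A-richness window for
#'   [flag_mispriming()]; `mispriming_window = 0` disables the filter.
#' @param max_mapq_zero Drop alignments with `mapq == 0` (multimappers).
#' @return A read-model tibble (dropped alignments are simply absent).
#' @export
alignments_to_read_models <- function(aln, genome, header, sample = 0L,
                                      start_seq = "ACGGG",
                                      end_seq = strrep("R", 30L),
                                      mismatch_rate = 0.2,
                                      stranded = FALSE,
                                      max_error_fraction = NA,
                                      mispriming_window = 20L, min_A = 12L,
                                      max_mapq_zero = TRUE) {
  gseq <- genome_seqs(genome)
  out <- list()
  aln <- aln[bitwAnd(aln$flag, 4L) == 0L, ] # mapped only
  if (max_mapq_zero && !is.null(aln$mapq)) aln <- aln[aln$mapq > 0L, ]
  if (!nrow(aln)) return(read_models())
  groups <- split(seq_len(nrow(aln)), aln$qname)
  for (idx in groups) {
    mates <- lapply(idx, function(i) one_mate(aln[i, ], gseq, start_seq,
                                              end_seq, mismatch_rate))
    mates <- mates[!vapply(mates, is.null, logical(1))]
    if (!length(mates)) next
    m <- if (length(mates) == 2L) fuse_mates(mates[[1]], mates[[2]]) else mates[[1]]
    if (is.null(m)) next
    if (!is.na(max_error_fraction)) m <- drop_high_error_exons(m, max_error_fraction)
    if (is.null(m)) next
    if (mispriming_window > 0L)
      m <- strip_artifact_labels(m, genome = gseq,
                                 window = mispriming_window, min_A = min_A)
    if (m$strand == "." && !stranded) {
      m$left_label <- "."; m$right_label <- "."
    }
    if (m$strand == "." && stranded) m$strand <- m$aln_strand
    out[[length(out) + 1L]] <- m
  }
  if (!length(out)) return(read_models())
  chrom_idx <- match(vapply(out, `[[`, character(1), "chrom"),
                     header$chroms$name) - 1L
  if (anyNA(chrom_idx)) stop("alignment chromosome missing from header")
  read_models(
    chrom = chrom_idx,
    blocks = lapply(out, `[[`, "blocks"),
    junctions = lapply(out, `[[`, "junctions"),
    strand = vapply(out, `[[`, character(1), "strand"),
    left_label = vapply(out, `[[`, character(1), "left_label"),
    right_label = vapply(out, `[[`, character(1), "right_label"),
    weight = 1, sample = sample
  )
}

# one alignment row -> intermediate read structure with label resolution
one_mate <- function(a, gseq, start_seq, end_seq, mismatch_rate) {
  cg <- parse_cigar(a$cigar, a$pos)
  if (!nrow(cg$blocks)) return(NULL)
  rev <- bitwAnd(a$flag, 16L) != 0L
  aln_strand <- if (rev) "-" else "+"
  label <- dplyr::case_when(
    grepl("/S$", a$qname) ~ "S",
    grepl("/EA$", a$qname) ~ "EA",
    grepl("/E$", a$qname) ~ "E",
    .default = "none"
  )
  chrseq <- gseq[[a$chrom]]
  clipL <- if (cg$clip_left > 0L) substr(a$seq, 1L, cg$clip_left) else ""
  clipR <- if (cg$clip_right > 0L)
    substr(a$seq, nchar(a$seq) - cg$clip_right + 1L, nchar(a$seq)) else ""
  left <- cg$blocks[1L, 1L]; right <- cg$blocks[nrow(cg$blocks), 2L]

  m <- list(chrom = a$chrom, blocks = cg$blocks, junctions = cg$junctions,
            strand = ".", aln_strand = aln_strand,
            left_label = ".", right_label = ".",
            exon_ins = cg$ins, exon_del = cg$del,
            exon_mm = md_mismatch_per_exon(a$md %||% NA_character_, cg$blocks),
            mate = if (bitwAnd(a$flag, 128L) != 0L) 2L else 1L)

  if (label == "S") {
    # read 5' end: genomic left if + alignment, right if -
    if (!rev) {
      if (clip_matches(clipL, start_seq, mismatch_rate)) {
        m$strand <- "+"
        m$left_label <- cap_or_start(clipL, chrseq, left, upstream_plus = TRUE)
      }
    } else {
      clip <- rc_chr(clipR) # read orientation, adjacent-to-alignment last
      if (clip_matches(clip, start_seq, mismatch_rate)) {
        m$strand <- "-"
        m$right_label <- cap_or_start(clip, chrseq, right, upstream_plus = FALSE)
      }
    }
  } else if (label %in% c("E", "EA")) {
    # E: oligo-dT trimmed at read 5' -> transcript antisense to alignment
    # EA: A-run trimmed at read 3' -> transcript sense
    e_at_left <- (label == "E" && !rev) || (label == "EA" && rev)
    if (e_at_left) {
      clip <- rc_chr(clipL) # transcript-downstream orientation
      if (clip_matches(clip, end_seq, mismatch_rate)) {
        m$strand <- "-"; m$left_label <- "E"
      }
    } else {
      if (clip_matches(clipR, end_seq, mismatch_rate)) {
        m$strand <- "+"; m$right_label <- "E"
      }
    }
  }
  m
}

# Cap vs Start: count trailing G in the clip (read orientation, adjacent to
# the aligned start; at most 3 examined) against templated upstream G in the
# genome. Any excess G must be untemplated -> Cap.
cap_or_start <- function(clip, chrseq, terminus0, upstream_plus) {
  g_clip <- 0L
  if (nzchar(clip)) {
    cl <- strsplit(clip, "")[[1]]
    for (b in rev(cl)) { if (b == "G" && g_clip < 3L) g_clip <- g_clip + 1L else break }
  }
  if (g_clip == 0L) return("S")
  g_temp <- 0L
  for (k in seq_len(g_clip)) {
    pos0 <- if (upstream_plus) terminus0 - k else terminus0 + k - 1L
    if (pos0 < 0L || pos0 >= nchar(chrseq)) break
    base <- substr(chrseq, pos0 + 1L, pos0 + 1L)
    want <- if (upstream_plus) "G" else "C"
    if (base == want) g_temp <- g_temp + 1L else break
  }
  if (g_clip > g_temp) "C" else "S"
}

# fuse two mates of one pair into a single read model structure
fuse_mates <- function(m1, m2) {
  if (m1$chrom != m2$chrom) return(NULL)
  if (m1$blocks[1L, 1L] > m2$blocks[1L, 1L]) { tmp <- m1; m1 <- m2; m2 <- tmp }
  strands <- setdiff(c(m1$strand, m2$strand), ".")
  if (length(unique(strands)) > 1L) { # conflicting label-derived strands
    m1$left_label <- "."; m1$right_label <- "."
    m2$left_label <- "."; m2$right_label <- "."
    strands <- character()
  }
  strand <- if (length(strands)) strands[1] else "."
  gap <- m2$blocks[1L, 1L] - m1$blocks[nrow(m1$blocks), 2L]
  if (gap >= 0L) {
    blocks <- rbind(m1$blocks, m2$blocks)
    junctions <- c(m1$junctions, "GAP", m2$junctions)
    mm <- c(m1$exon_mm, m2$exon_mm); ins <- c(m1$exon_ins, m2$exon_ins)
    del <- c(m1$exon_del, m2$exon_del)
  } else {
    # overlapping mates: union of blocks; contradictory splices -> drop
    u <- union_blocks(m1$blocks, m1$junctions, m2$blocks, m2$junctions)
    if (is.null(u)) return(NULL)
    blocks <- u$blocks; junctions <- u$junctions
    mm <- rep(0L, nrow(blocks)); ins <- mm; del <- mm # error info not merged
  }
  fwd <- if (m1$mate == 1L) m1$aln_strand else m2$aln_strand
  list(chrom = m1$chrom, blocks = blocks, junctions = junctions,
       strand = strand, aln_strand = fwd,
       left_label = m1$left_label, right_label = m2$right_label,
       exon_mm = mm, exon_ins = ins, exon_del = del, mate = 0L)
}

# union of two block sets; NULL when their splice structures contradict
union_blocks <- function(b1, j1, b2, j2) {
  introns <- function(b, j) {
    if (nrow(b) < 2L) return(cbind(start = integer(), end = integer(), splice = integer()))
    cbind(start = b[-nrow(b), 2], end = b[-1L, 1], splice = as.integer(j == "SPLICE"))
  }
  i1 <- introns(b1, j1); i2 <- introns(b2, j2)
  # a splice intron of one mate whose interior is covered by the other
  # mate's aligned blocks is a contradiction
  check <- function(im, other_b) {
    im <- im[im[, "splice"] == 1L, , drop = FALSE]
    for (r in seq_len(nrow(im))) {
      if (any(other_b[, 1] < im[r, 2] & other_b[, 2] > im[r, 1])) return(FALSE)
    }
    TRUE
  }
  if (!check(i1, b2) || !check(i2, b1)) return(NULL)
  edges <- sort(unique(c(b1[, 1], b1[, 2], b2[, 1], b2[, 2])))
  covered <- function(p) any(b1[, 1] <= p & b1[, 2] > p) || any(b2[, 1] <= p & b2[, 2] > p)
  # walk the union of covered intervals
  pts <- sort(unique(c(as.vector(b1), as.vector(b2))))
  segs <- cbind(pts[-length(pts)], pts[-1L])
  keep <- vapply(seq_len(nrow(segs)), function(k) covered(segs[k, 1]), logical(1))
  segs <- segs[keep, , drop = FALSE]
  starts <- integer(); ends <- integer()
  for (k in seq_len(nrow(segs))) {
    if (length(ends) && segs[k, 1] == ends[length(ends)]) {
      ends[length(ends)] <- segs[k, 2]
    } else {
      starts <- c(starts, segs[k, 1]); ends <- c(ends, segs[k, 2])
    }
  }
  blocks <- cbind(start = starts, end = ends)
  junctions <- rep("SPLICE", max(0L, nrow(blocks) - 1L))
  list(blocks = blocks, junctions = junctions)
}
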