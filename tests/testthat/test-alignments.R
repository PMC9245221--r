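# a tiny genome with a known context around position 100 (0-based):
# upstream of 100 is "TTT" (no templated G), upstream of 200 is "GGG"
make_test_genome <- function() {
  base <- paste(rep("ACGT", 100), collapse = "")
  g <- paste0(substr(base, 1, 97), "TTT", substr(base, 101, 197), "GGG",
              substr(base, 201, 400))
  stats::setNames(g, "chr1")
}

aln_row <- function(qname, pos1, cigar, seq, flag = 0L, mapq = 60L,
                    nm = NA_integer_, md = NA_character_) {
  tibble::tibble(qname = qname, flag = flag, chrom = "chr1", pos = pos1,
                 mapq = mapq, cigar = cigar, seq = seq, qual = "*",
                 nm = nm, md = md)
}

test_that("CIGAR parsing yields blocks, junctions and soft clips", {
  cg <- endguide:::parse_cigar("5S20M100N30M2D10M3S", 101L)
  expect_equal(unname(cg$blocks[, 1]), c(100L, 220L))
  expect_equal(unname(cg$blocks[, 2]), c(120L, 262L))
  expect_equal(cg$junctions, "SPLICE")
  expect_equal(cg$clip_left, 5L)
  expect_equal(cg$clip_right, 3L)
  expect_equal(cg$del, c(0L, 2L))
})

test_that("MD mismatches are assigned to the right exon", {
  blocks <- cbind(start = c(0L, 200L), end = c(50L, 260L))
  mm <- endguide:::md_mismatch_per_exon("30A19A0C58", blocks)
  expect_equal(mm, c(1L, 2L))
  expect_equal(endguide:::md_mismatch_per_exon(NA, blocks), c(0L, 0L))
})

test_that("untemplated G upstream of the aligned start makes a Cap Tag", {
  genome <- make_test_genome()
  header <- elr_header(tibble::tibble(name = "chr1", length = 400L))
  body <- substr(genome[[1]], 101, 140)
  # clip GGG, genome upstream reads TTT -> untemplated -> Cap
  a1 <- aln_row("r1/S", 101L, "3S40M", paste0("GGG", body))
  r1 <- alignments_to_read_models(a1, genome, header, mispriming_window = 0L)
  expect_equal(r1$left_label, "C")
  expect_equal(r1$strand, "+")
  expect_equal(r1$start, 100L)
  # same clip at position 200 where the genome itself reads GGG upstream:
  # fully templated -> Start, not Cap
  body2 <- substr(genome[[1]], 201, 240)
  a2 <- aln_row("r2/S", 201L, "5S40M", paste0("ACGGG", body2))
  r2 <- alignments_to_read_models(a2, genome, header, mispriming_window = 0L)
  expect_equal(r2$left_label, "S")
  # no soft clip at all still confirms a plain Start Tag
  a3 <- aln_row("r3/S", 101L, "40M", body)
  r3 <- alignments_to_read_models(a3, genome, header, mispriming_window = 0L)
  expect_equal(r3$left_label, "S")
})

test_that("clip sequences that contradict the label pattern drop it", {
  genome <- make_test_genome()
  header <- elr_header(tibble::tibble(name = "chr1", length = 400L))
  body <- substr(genome[[1]], 101, 140)
  a <- aln_row("r1/S", 96L, "5S40M", paste0("TTTTT", body))
  r <- alignments_to_read_models(a, genome, header, mismatch_rate = 0.2,
                                 mispriming_window = 0L)
  expect_equal(r$left_label, ".")
  expect_equal(r$strand, ".") # unlabeled single-end stays unstranded
})

test_that("unlabeled unstranded reads carry no labels or strand", {
  genome <- make_test_genome()
  header <- elr_header(tibble::tibble(name = "chr1", length = 400L))
  a <- aln_row("r1", 101L, "40M", substr(genome[[1]], 101, 140))
  r <- alignments_to_read_models(a, genome, header)
  expect_equal(r$strand, ".")
  expect_equal(r$left_label, ".")
  expect_equal(r$right_label, ".")
})

test_that("mates fuse into one read model with a gap junction", {
  genome <- make_test_genome()
  header <- elr_header(tibble::tibble(name = "chr1", length = 400L))
  a <- dplyr::bind_rows(
    aln_row("p1", 11L, "30M", substr(genome[[1]], 11, 40), flag = 64L),
    aln_row("p1", 101L, "30M", substr(genome[[1]], 101, 130), flag = 144L))
  r <- alignments_to_read_models(a, genome, header)
  expect_equal(nrow(r), 1L)
  expect_equal(r$junctions[[1]], "GAP")
  expect_equal(unname(r$blocks[[1]][, 1]), c(10L, 100L))
  # overlapping mates are unioned into one block
  b <- dplyr::bind_rows(
    aln_row("p2", 11L, "30M", substr(genome[[1]], 11, 40), flag = 64L),
    aln_row("p2", 31L, "30M", substr(genome[[1]], 31, 60), flag = 144L))
  r2 <- alignments_to_read_models(b, genome, header)
  expect_equal(nrow(r2$blocks[[1]]), 1L)
  expect_equal(unname(r2$blocks[[1]][1, ]), c(10L, 60L))
})

test_that("mates with contradictory splice patterns are dropped", {
  genome <- make_test_genome()
  header <- elr_header(tibble::tibble(name = "chr1", length = 400L))
  a <- dplyr::bind_rows(
    aln_row("p1", 11L, "20M50N20M", paste0(substr(genome[[1]], 11, 30),
                                           substr(genome[[1]], 81, 100)),
            flag = 64L),
    aln_row("p1", 21L, "40M", substr(genome[[1]], 21, 60), flag = 144L))
  r <- alignments_to_read_models(a, genome, header)
  expect_equal(nrow(r), 0L)
})

test_that("SAM text round trips through the minimal reader", {
  chroms <- tibble::tibble(name = "chr1", length = 400L)
  aln <- dplyr::bind_rows(
    aln_row("x/S", 98L, "3S40M", strrep("A", 43), nm = 2L, md = "40"),
    aln_row("y", 10L, "20M", strrep("C", 20)))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, chroms, f)
  back <- read_sam(f)
  expect_equal(back$chroms, chroms)
  expect_equal(back$alignments$qname, aln$qname)
  expect_equal(back$alignments$cigar, aln$cigar)
  expect_equal(back$alignments$pos, aln$pos)
  expect_equal(back$alignments$nm, aln$nm)
  expect_equal(back$alignments$md, aln$md)
})
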