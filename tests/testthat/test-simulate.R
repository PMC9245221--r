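test_that("simulation is reproducible from its seed", {
  a <- simulate_locus(3L, seed = 7L)
  b <- simulate_locus(3L, seed = 7L)
  expect_identical(a$genome, b$genome)
  expect_identical(a$isoforms$exons, b$isoforms$exons)
  ra <- simulate_reads(a, seed = 8L, emit_fastq = TRUE)
  rb <- simulate_reads(b, seed = 8L, emit_fastq = TRUE)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$fastq, rb$fastq)
})

test_that("label and artifact rates track their parameters", {
  sim <- simulate_locus(2L, seed = 31L)
  rd <- simulate_reads(sim, n = 2000L, seed = 32L,
                       label_rate_5 = 0.1, label_rate_3 = 0.2)
  p5 <- mean(rd$truth$labeled5)
  p3 <- mean(rd$truth$labeled3)
  expect_lt(abs(p5 - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
  expect_lt(abs(p3 - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  # zero rates mean zero labels
  rd0 <- simulate_reads(sim, n = 300L, seed = 33L,
                        label_rate_5 = 0, label_rate_3 = 0)
  expect_true(all(rd0$reads$left_label == "."))
  expect_true(all(rd0$reads$right_label == "."))
  # long-read mispriming rate within binomial bounds
  simA <- simulate_locus(1L, seed = 34L, a_rich_tract = TRUE)
  rdl <- simulate_reads(simA, n = 400L, seed = 35L, protocol = "longread",
                        mispriming_rate = 0.2)
  pm <- mean(rdl$truth$misprimed)
  expect_lt(abs(pm - 0.2), 3 * sqrt(0.2 * 0.8 / 400))
  # impossible configurations are rejected
  expect_error(simulate_reads(sim, n = 10L, label_rate_5 = 1.5))
})

test_that("transcript/genome coordinate mapping functions invert", {
  sim <- simulate_locus(2L, seed = 41L, strand = "-")
  for (i in seq_len(nrow(sim$isoforms))) {
    ex <- sim$isoforms$exons[[i]]
    L <- sim$isoforms$length[i]
    for (t in c(0L, 5L, L - 1L)) {
      b <- endguide:::tx_to_blocks(ex, "-", t, t + 1L)
      g <- b[1, 1]
      expect_equal(endguide:::genomic_to_tx(ex, "-", b[1, 2]), t)
    }
  }
})

test_that("simulated spliced reads respect isoform structure", {
  sim <- simulate_locus(3L, seed = 51L)
  rd <- simulate_reads(sim, n = 400L, seed = 52L)
  iso_introns <- lapply(sim$isoforms$exons, function(e) {
    if (nrow(e) < 2) return(character())
    paste(e[-nrow(e), 2], e[-1, 1])
  })
  for (i in seq_len(nrow(rd$reads))) {
    tt <- rd$truth[i, ]
    if (is.na(tt$iso)) next
    b <- rd$reads$blocks[[i]]
    if (nrow(b) < 2) next
    got <- paste(b[-nrow(b), 2], b[-1, 1])
    expect_true(all(got %in% iso_introns[[tt$iso]]),
                label = paste("read", i))
  }
})

test_that("the fixture suite is deterministic and truth sets are valid GTF", {
  s1 <- make_fixture_suite(1L)
  s2 <- make_fixture_suite(1L)
  expect_identical(names(s1),
                   c("alt_tss", "alt_pas", "tandem", "antisense",
                     "truncated", "dropout_panel"))
  expect_identical(s1$alt_tss$sim$genome, s2$alt_tss$sim$genome)
  for (nm in names(s1)) {
    f <- withr::local_tempfile(fileext = ".gtf")
    n <- truth_to_gtf(s1[[nm]]$sim, f)
    gr <- rtracklayer::import(f, format = "gtf")
    expect_equal(length(unique(gr$transcript_id[gr$type == "transcript"])), n,
                 label = nm)
  }
  # scenario structure: tandem has two genes, antisense two strands
  expect_length(s1$tandem$sim$genes, 2L)
  expect_setequal(vapply(s1$antisense$sim$genes, `[[`, character(1),
                         "strand"), c("+", "-"))
  expect_equal(s1$dropout_panel$sim$n_samples, 16L)
})

test_that("FASTQ emission carries the right adapters for each label", {
  sim <- simulate_locus(1L, seed = 61L)
  rd <- simulate_reads(sim, n = 300L, seed = 62L, label_rate_5 = 0.3,
                       label_rate_3 = 0.3, emit_fastq = TRUE)
  fq <- rd$fastq
  is5 <- fq$true_label == "5"
  is3 <- fq$true_label == "3"
  expect_true(all(startsWith(fq$seq[is5], TSO_ADAPTER)))
  core <- sub("\\+$", "", OLIGODT_ADAPTER)
  expect_true(all(startsWith(fq$seq[is3], core)))
})
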