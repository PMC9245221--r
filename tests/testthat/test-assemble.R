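test_that("a two-isoform alternative-TSS locus is recovered exactly", {
  sim <- simulate_locus(2L, seed = 1L, variations = c("full", "alt_tss"))
  rd <- simulate_reads(sim, seed = 2L, label_rate_5 = 0.15,
                       label_rate_3 = 0.15)
  fit <- assemble(rd$reads, rd$header)
  expect_setequal(model_chains(fit), truth_chains(sim))
  expect_true(all(fit$models$complete))
  # ends sit on the true summits
  m <- fit$models[order(fit$models$start), ]
  tr <- sim$isoforms[order(vapply(sim$isoforms$exons, function(e) e[1, 1],
                                  integer(1))), ]
  expect_equal(m$tss_summit, tr$tss)
  expect_equal(m$pas_summit, tr$pas)
})

test_that("minus-strand loci assemble with mirrored labels", {
  sim <- simulate_locus(2L, seed = 5L, strand = "-")
  rd <- simulate_reads(sim, seed = 6L, label_rate_5 = 0.15,
                       label_rate_3 = 0.15)
  fit <- assemble(rd$reads, rd$header)
  expect_true(all(fit$models$strand == "-"))
  expect_setequal(model_chains(fit), truth_chains(sim))
})

test_that("path filters apply exact boundaries", {
  base <- tibble::tibble(
    chrom = 0L, strand = "+", start = 0L, end = 1000L,
    exons = list(cbind(start = 0L, end = 1000L)), n_exons = 1L,
    length = 1000L, complete = TRUE, has_source = TRUE, has_sink = TRUE,
    capped = FALSE, coverage = 5, bases = 5000, share = 0.5,
    tss_summit = 0L, pas_summit = 1000L, n_samples_support = 1L,
    sample_cov = list(1))
  p <- endguide_params()
  m <- base; m$coverage <- 1.5
  expect_equal(nrow(filter_paths(m, p)), 0L)   # below min_cov 2
  m$coverage <- 2
  expect_equal(nrow(filter_paths(m, p)), 1L)
  m <- base; m$length <- 59L
  expect_equal(nrow(filter_paths(m, p)), 0L)   # below min_len 60
  m$length <- 60L
  expect_equal(nrow(filter_paths(m, p)), 1L)
  m <- base; m$share <- 0.0199
  expect_equal(nrow(filter_paths(m, p)), 0L)   # below min_proportion
  m <- base; m$complete <- FALSE
  expect_equal(nrow(filter_paths(m, p)), 0L)
  expect_equal(nrow(filter_paths(m, endguide_params(
    discard_incomplete = FALSE))), 1L)
  m <- base
  expect_equal(nrow(filter_paths(m, endguide_params(require_cap = TRUE))), 0L)
  m$capped <- TRUE
  expect_equal(nrow(filter_paths(m, endguide_params(require_cap = TRUE))), 1L)
})

test_that("GTF output is 1-based, parseable and round trips exon chains", {
  sim <- simulate_locus(2L, seed = 9L)
  rd <- simulate_reads(sim, seed = 10L, label_rate_5 = 0.15,
                       label_rate_3 = 0.15)
  fit <- assemble(rd$reads, rd$header)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(fit, f)
  # hand check of the first exon line against the model table
  lines <- readLines(f)
  ex1 <- strsplit(grep("\texon\t", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(ex1[4]), fit$models$exons[[1]][1, 1] + 1L)
  expect_equal(as.integer(ex1[5]), fit$models$exons[[1]][1, 2])
  # round trip through the annotation importer
  back <- gtf_to_read_models(f, header = rd$header)
  expect_equal(nrow(back$reads), nrow(fit$models))
  expect_setequal(vapply(back$reads$blocks, chain_str, character(1)),
                  model_chains(fit))
  expect_true(all(back$reads$left_label %in% c("C", "E")))
})

test_that("assembling annotation pseudo-reads reproduces the annotation", {
  sim <- simulate_locus(2L, seed = 13L)
  f <- withr::local_tempfile(fileext = ".gtf")
  truth_to_gtf(sim, f)
  ann <- gtf_to_read_models(f, header = sim$header)
  ann$reads$weight <- 5 # well-supported annotation entries
  fit <- assemble(ann$reads, ann$header)
  expect_setequal(model_chains(fit), truth_chains(sim))
})

test_that("repeated runs are byte identical", {
  sim <- simulate_locus(3L, seed = 17L)
  rd <- simulate_reads(sim, seed = 18L, label_rate_5 = 0.1,
                       label_rate_3 = 0.1)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(assemble(rd$reads, rd$header), f1)
  write_gtf(assemble(rd$reads, rd$header), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("condense keeps incomplete paths and labels only anchored ends", {
  sim <- simulate_locus(1L, seed = 21L)
  # 5'-anchored protocol: no 3' evidence anywhere
  rd <- simulate_reads(sim, seed = 22L, protocol = "fiveprime_only")
  out <- condense(rd$reads, rd$header, sample = 0L)
  expect_gt(nrow(out), 0L)
  expect_true(all(out$left_label %in% c("S", "C")))
  expect_true(all(out$right_label == "."))
  # complete evidence condenses to doubly labeled pseudo-reads
  rd2 <- simulate_reads(sim, seed = 23L, label_rate_5 = 0.2,
                        label_rate_3 = 0.2)
  out2 <- condense(rd2$reads, rd2$header, sample = 0L)
  expect_true(any(out2$left_label %in% c("S", "C") &
                    out2$right_label == "E"))
})
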