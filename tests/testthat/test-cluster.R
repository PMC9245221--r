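test_that("chunking splits on gaps larger than max_gap", {
  mk <- function(starts) read_models(0L, lapply(starts, function(s)
    cbind(s, s + 100L)), strand = ".")
  # reads 40 nt apart (gap <= 50): one chunk
  expect_length(chunk_reads(mk(c(0L, 140L)), 50L), 1L)
  # 60 nt apart: two
  expect_length(chunk_reads(mk(c(0L, 160L)), 50L), 2L)
  # exactly max_gap stays joined
  expect_length(chunk_reads(mk(c(0L, 150L)), 50L), 1L)
  expect_length(chunk_reads(read_models(), 50L), 0L)
  # chromosomes always separate
  r <- read_models(c(0L, 1L), list(cbind(0L, 100L), cbind(100L, 200L)),
                   strand = ".")
  expect_length(chunk_reads(r, 1000L), 2L)
})

test_that("tags are taken from labeled termini only", {
  r <- read_models(0L,
                   list(cbind(100L, 200L), cbind(300L, 400L),
                        cbind(500L, 600L)),
                   strand = c("+", "-", "."),
                   left_label = c("S", "E", "."),
                   right_label = c("E", "C", "."))
  tg <- extract_tags(r)
  expect_equal(nrow(tg), 4L)
  expect_setequal(tg$pos, c(100L, 200L, 300L, 400L))
  expect_equal(tg$kind[tg$pos == 400L], "C")
  expect_equal(tg$strand[tg$pos == 300L], "-")
})

test_that("tag clustering reproduces the worked pooled-signal example", {
  tags <- tibble::tibble(
    pos = c(rep(100L, 5), 102L, 400L),
    strand = "+",
    kind = c(rep("S", 5), "C", "S"),
    weight = 1)
  cl <- cluster_tags(tags, distance = 20L, threshold_fraction = 0.02,
                     cap_bonus = 5, cap_filter = 0.02)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$lo, 100L)
  expect_equal(cl$hi, 102L)
  expect_equal(cl$kind, "TSS")
  # independent per-position recomputation of the signal rule:
  # bonus weights 5 (pos 100), 5 (pos 102), 1 (pos 400); total 11;
  # signal w^2/11 = 2.27, 2.27, 0.091; threshold 0.02 * 4.64 = 0.093
  # drops pos 400; summit tie between 100/102 -> leftmost
  expect_equal(cl$summit, 100L)
  expect_equal(cl$weight, 6)            # unbonused
  expect_equal(cl$capped_fraction, 1 / 6)
  expect_true(cl$capped)
})

test_that("tag clustering is scale invariant and handles degenerate input", {
  set.seed(31)
  tags <- tibble::tibble(pos = sample(100:200, 40, replace = TRUE),
                         strand = "+",
                         kind = sample(c("S", "C", "E"), 40, replace = TRUE),
                         weight = runif(40, 0.5, 3))
  a <- cluster_tags(tags, 25L, 0.02, 5, 0.02)
  tags2 <- tags; tags2$weight <- tags2$weight * 7.3
  b <- cluster_tags(tags2, 25L, 0.02, 5, 0.02)
  expect_equal(a[, c("lo", "hi", "summit", "strand", "kind")],
               b[, c("lo", "hi", "summit", "strand", "kind")])
  expect_equal(b$weight, a$weight * 7.3)
  expect_equal(nrow(cluster_tags(tags[0, ], 25L, 0.02, 5, 0.02)), 0L)
  single <- cluster_tags(tibble::tibble(pos = 50L, strand = "+", kind = "S",
                                        weight = 2), 25L, 0.02, 5, 0.02)
  expect_equal(single$lo, single$hi)
  expect_equal(single$summit, 50L)
})

test_that("cluster weights conserve tag weight within each pool", {
  set.seed(32)
  tags <- tibble::tibble(pos = sample(0:500, 60, replace = TRUE),
                         strand = sample(c("+", "-"), 60, replace = TRUE),
                         kind = sample(c("S", "C", "E"), 60, replace = TRUE),
                         weight = runif(60, 0.5, 2))
  # threshold 0 keeps every position, so pooled cluster weight must equal
  # total tag weight per (strand, pool)
  cl <- cluster_tags(tags, 50L, 0, 5, 0.02)
  for (st in c("+", "-")) {
    expect_equal(sum(cl$weight[cl$strand == st & cl$kind == "TSS"]),
                 sum(tags$weight[tags$strand == st & tags$kind != "E"]))
    expect_equal(sum(cl$weight[cl$strand == st & cl$kind == "PAS"]),
                 sum(tags$weight[tags$strand == st & tags$kind == "E"]))
  }
})

test_that("junction filtering honors overhangs and local coverage share", {
  # a junction seen only with 2 nt flanks does not count at min_overhang 3
  r <- read_models(0L, list(cbind(c(98L, 200L), c(100L, 300L))),
                   list("SPLICE"), "+")
  out <- filter_locus_junctions(r, min_overhang = 3L,
                                threshold_fraction = 0.02)
  expect_equal(nrow(out), 0L)
  # a junction carrying half the local coverage is kept at any
  # threshold <= 0.5
  r2 <- read_models(0L,
                    list(cbind(c(0L, 200L), c(100L, 300L)), cbind(0L, 300L)),
                    list("SPLICE", character()), c("+", "+"))
  out2 <- filter_locus_junctions(r2, 3L, 0.5)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$donor, 100L)
  # whitelisted junctions survive any threshold
  wl <- junction_table("chr1", 100L, 200L, "+", 1)
  out3 <- filter_locus_junctions(r2, 3L, 0.99, whitelist = wl)
  expect_equal(nrow(out3), 1L)
})

test_that("junction filtering matches a naive support/coverage oracle", {
  set.seed(33)
  blocks <- list(); strands <- character()
  for (i in 1:40) {
    d <- sample(c(200L, 400L), 1); a <- d + 100L
    s <- sample(0:150, 1)
    if (runif(1) < 0.6) {
      blocks[[i]] <- cbind(c(d - s - 10L, a), c(d, a + sample(10:80, 1)))
    } else {
      blocks[[i]] <- cbind(s, s + sample(150:400, 1))
    }
    strands[i] <- "+"
  }
  junctions <- lapply(blocks, function(b)
    rep("SPLICE", nrow(b) - 1L))
  r <- read_models(0L, blocks, junctions, strands)
  thr <- 0.1
  got <- filter_locus_junctions(r, 3L, thr)
  # naive recount
  for (d in c(200L, 400L)) {
    a <- d + 100L
    sup <- 0; cov <- 0
    for (i in seq_len(nrow(r))) {
      b <- r$blocks[[i]]
      if (nrow(b) == 2L && b[1, 2] == d && b[2, 1] == a &&
          b[1, 2] - b[1, 1] >= 3L && b[2, 2] - b[2, 1] >= 3L) sup <- sup + 1
      if (r$start[i] < a && r$end[i] > d) cov <- cov + 1
    }
    expect_equal(d %in% got$donor, sup > 0 && sup >= thr * cov,
                 label = paste("junction", d))
  }
})

test_that("frag partitions tile the locus with virtual columns appended", {
  cl <- tibble::tibble(lo = c(100L, 400L), hi = c(100L, 400L),
                       summit = c(100L, 400L), strand = "+",
                       kind = c("TSS", "PAS"), weight = 1,
                       capped_fraction = 0, capped = FALSE)
  jx <- tibble::tibble(donor = 150L, acceptor = 300L, strand = "+",
                       support = 5)
  p <- build_partition(cl, jx, c(50L, 450L))
  expect_equal(p$frags$start, c(50L, 100L, 150L, 300L, 400L))
  expect_equal(p$frags$end, c(100L, 150L, 300L, 400L, 450L))
  expect_equal(p$n_frags, 5L)
  expect_equal(p$vE_minus, 9L)
  # no boundaries: single frag
  p0 <- build_partition(cl[0, ], jx[0, ], c(0L, 500L))
  expect_equal(nrow(p0$frags), 1L)
  # tiling property on random boundary sets
  set.seed(34)
  for (k in 1:20) {
    pos <- sort(sample(10:990, sample(0:12, 1)))
    jr <- tibble::tibble(donor = pos, acceptor = pos + 1000L, strand = "+",
                         support = 1)
    pp <- build_partition(cl[0, ], jr, c(0L, 1000L))
    expect_equal(pp$frags$start[1], 0L)
    expect_equal(pp$frags$end[nrow(pp$frags)], 1000L)
    expect_true(all(pp$frags$start[-1] == pp$frags$end[-nrow(pp$frags)]))
  }
})
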