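# partition with frag edges at 100..600 and clusters usable for labels:
# TSS(+) at 100, PAS(+) at 500
labeled_partition <- function() {
  cl <- tibble::tibble(lo = c(100L, 498L), hi = c(102L, 500L),
                       summit = c(100L, 500L), strand = "+",
                       kind = c("TSS", "PAS"), weight = 10,
                       capped_fraction = c(0.5, 0), capped = c(TRUE, FALSE))
  jx <- tibble::tibble(donor = c(200L, 300L), acceptor = c(250L, 400L),
                       strand = "+", support = 5)
  build_partition(cl, jx, c(0L, 600L))
}

test_that("a spliced, end-labeled read gets the expected membership row", {
  p <- labeled_partition()
  # frags: [0,100) [100,200) [200,250) [250,300) [300,400) [400,500) [500,600)
  expect_equal(p$n_frags, 7L)
  # read: exons [100,300) and [400,500), spanning intron [300,400),
  # 3' End Tag at 500
  r <- read_models(0L, list(cbind(c(100L, 400L), c(300L, 500L))),
                   list("SPLICE"), "+", ".", "E")
  mem <- build_membership(r, p, min_overhang = 3L, n_samples = 1L)
  m <- mem$M[1, ]
  expect_equal(m[2:4], rep(1L, 3))           # covered frags
  expect_equal(m[6], 1L)                     # last exon
  expect_equal(m[5], -1L)                    # spliced-out intron frag
  expect_equal(m[p$vE_plus], 1L)             # End Tag -> E+ virtual
  expect_equal(m[7], -1L)                    # beyond the PAS cluster
  expect_equal(m[1], 0L)                     # upstream, unknown
  expect_equal(m[p$vS_minus], -1L)           # wrong-strand virtuals excluded
  expect_equal(m[p$vE_minus], -1L)
  expect_equal(m[p$vS_plus], 0L)
})

test_that("labels outside any surviving cluster are ignored", {
  p <- labeled_partition()
  r <- read_models(0L, list(cbind(250L, 470L)), list(character()),
                   "+", "S", ".")   # S label at 250: no TSS cluster there
  mem <- build_membership(r, p, 3L, 1L)
  expect_equal(mem$M[1, p$vS_plus], 0L)
})

test_that("identical reads condense into one element with pooled weight", {
  p <- labeled_partition()
  r <- read_models(0L, list(cbind(100L, 200L), cbind(100L, 200L)),
                   list(character(), character()), c("+", "+"))
  mem <- build_membership(r, p, 3L, 1L)
  expect_equal(nrow(mem$M), 1L)
  expect_equal(mem$n_reads, 2L)
  expect_equal(mem$bases, 200)
  expect_equal(mem$weight, 2)   # 200 bases / 100 nt
})

test_that("sum(weight x length) equals total counted aligned bases", {
  set.seed(41)
  for (k in 1:10) {
    sim <- simulate_locus(1 + k %% 3, seed = 4100 + k)
    rd <- simulate_reads(sim, seed = 4200 + k, label_rate_5 = 0.1,
                         label_rate_3 = 0.1)
    reads <- sort_read_models(rd$reads)
    tags <- extract_tags(reads)
    cl <- cluster_tags(tags, 50L, 0.02, 5, 0.02, coverage_lookup(reads))
    jx <- filter_locus_junctions(reads, 3L, 0.02)
    p <- build_partition(cl, jx, c(min(reads$start), max(reads$end)))
    mem <- build_membership(reads, p, 3L, 3L)
    # independent recount of member-frag bases per read
    fs <- p$frags$start; fe <- p$frags$end; fl <- fe - fs
    total <- 0
    for (i in seq_len(nrow(reads))) {
      b <- reads$blocks[[i]]
      ov <- rep(0, p$n_frags)
      for (bk in seq_len(nrow(b)))
        ov <- ov + pmax(0, pmin(fe, b[bk, 2]) - pmax(fs, b[bk, 1]))
      member <- ov > 0 & (ov >= 3 | ov == fl)
      total <- total + sum(ov[member]) * reads$weight[i]
    }
    expect_equal(sum(mem$weight * mem$length), total, tolerance = 1e-10)
  }
})

test_that("overlap codes follow the extension/containment semantics", {
  nf <- 5L
  a <- mrow(nf, 1:2); b <- mrow(nf, 2:3); c_ <- mrow(nf, 1:3)
  d <- mrow(nf, 2L); e <- mrow(nf, 4L, excl = 3L)
  f <- mrow(nf, c(2L, 3L), excl = 4L)
  ord <- function(m) m # already frag-major; virtuals at the end
  # staggered: mutual extension
  expect_equal(overlap_codes(a, b), c(1L, 1L))
  # containment: d inside c
  expect_equal(overlap_codes(d, c_), c(2L, 1L))
  expect_equal(overlap_codes(c_, d), c(1L, 2L))
  # identical support
  expect_equal(overlap_codes(d, d), c(2L, 2L))
  # disagreement on frag 4
  expect_equal(overlap_codes(mrow(nf, 3:5), f), c(-1L, -1L))
  # disjoint support
  expect_equal(overlap_codes(a, e), c(0L, 0L))
  # opposite strands always exclude
  expect_equal(overlap_codes(a, b, "+", "-"), c(-1L, -1L))
})

test_that("overlap matrix invariants hold on random rows and match the
           pairwise scalar recomputation", {
  set.seed(42)
  nf <- 8L
  rows <- lapply(1:20, function(i) {
    sup <- sort(sample(1:nf, sample(1:4, 1)))
    sup <- min(sup):max(sup)
    excl <- sample(setdiff(1:nf, sup), sample(0:2, 1))
    mrow(nf, sup, excl, s_plus = runif(1) < 0.3, e_plus = runif(1) < 0.3)
  })
  mem <- bare_membership(rows, runif(20, 1, 5), nf)
  O <- overlap_matrix(mem)
  ordx <- endguide:::extended_order(mem$partition)
  Mx <- mem$M[, ordx]
  for (i in 1:19) for (j in (i + 1):20) {
    cd <- overlap_codes(Mx[i, ], Mx[j, ], "+", "+")
    expect_equal(c(O[i, j], O[j, i]), cd,
                 label = paste("pair", i, j))
  }
  # symmetry of -1 and 0; containment implies the mate extends or contains
  expect_true(all((O == -1L) == t(O == -1L)))
  expect_true(all((O == 0L) == t(O == 0L)))
  idx <- which(O == 2L, arr.ind = TRUE)
  if (nrow(idx)) expect_true(all(O[idx[, c(2, 1), drop = FALSE]] %in% c(1L, 2L)))
})
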