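test_that("a perfect tiling with identical exclusions collapses to one chain", {
  nf <- 4L
  mem <- bare_membership(
    list(mrow(nf, 1:2), mrow(nf, 2:3), mrow(nf, 3:4)),
    c(2, 2, 2), nf)
  red <- collapse_linear_chains(mem)
  expect_equal(nrow(red$M), 1L)
  expect_equal(red$length, 400)
  expect_equal(red$bases, sum(mem$bases))
  # mutually exclusive reads stay separate
  mem2 <- bare_membership(
    list(mrow(nf, 1:2, excl = 3L), mrow(nf, c(1L, 3L), excl = 2L)),
    c(1, 1), nf)
  expect_equal(nrow(collapse_linear_chains(mem2)$M), 2L)
})

test_that("chain collapse preserves sum(weight x length)", {
  set.seed(51)
  for (k in 1:20) {
    rows <- lapply(1:12, function(i) {
      sup <- sort(sample(1:8, sample(1:3, 1)))
      pool <- setdiff(1:8, min(sup):max(sup))
      excl <- if (length(pool)) pool[sample.int(length(pool), 1)][runif(1) < 0.5]
              else integer()
      mrow(8L, min(sup):max(sup), excl = excl)
    })
    mem <- bare_membership(rows, runif(12, 0.5, 4), 8L)
    red <- collapse_linear_chains(mem)
    expect_equal(sum(red$weight * red$length), sum(mem$weight * mem$length),
                 tolerance = 1e-9)
  }
})

test_that("contained weight is redistributed proportionally to containers", {
  nf <- 6L
  # two containers of weight 10 and 6 and one contained element of
  # weight 4; all supports chosen so container genomic lengths are equal
  rows <- list(mrow(nf, 1:3),            # container A
               mrow(nf, 2:4),            # container B
               mrow(nf, 2:3))            # contained
  mem <- bare_membership(rows, c(10, 6, 4), nf)
  g <- build_overlap_graph(mem)
  g2 <- resolve_containment(g)
  expect_true(g2$removed[3])
  # proportional split 10:6 of the contained weight: since all elements
  # here do not change length, transfers are 2.5 and 1.5 in base units
  # spread over each container's length
  gained_a <- g2$bases[1] - mem$bases[1]
  gained_b <- g2$bases[2] - mem$bases[2]
  expect_equal(gained_a / gained_b, 10 / 6)
  expect_equal(gained_a + gained_b, mem$bases[3])
  expect_equal(gained_a, 2.5 * mem$length[3])
  expect_equal(gained_b, 1.5 * mem$length[3])
  # total conservation
  expect_equal(sum(g2$bases), sum(mem$bases))
})

test_that("a single container receives the full transfer", {
  nf <- 4L
  mem <- bare_membership(list(mrow(nf, 1:4), mrow(nf, 2:3)), c(5, 2), nf)
  g <- resolve_containment(build_overlap_graph(mem))
  expect_true(g$removed[2])
  expect_equal(g$bases[1], sum(mem$bases))
})

test_that("redistribution is blocked when containers jointly exclude
           evidence the element does not", {
  nf <- 6L
  rows <- list(mrow(nf, 1:5, excl = 6L),   # container excluding frag 6
               mrow(nf, 2:3),              # contained, agnostic about 6
               mrow(nf, c(3L, 6L)))        # the node only the contained
                                           # element remains compatible with
  mem <- bare_membership(rows, c(10, 4, 2), nf)
  g <- resolve_containment(build_overlap_graph(mem))
  expect_false(g$removed[2])
})

test_that("conservation holds through the whole reduction pipeline", {
  set.seed(52)
  for (k in 1:15) {
    sim <- simulate_locus(1 + k %% 3, seed = 5200 + k)
    rd <- simulate_reads(sim, seed = 5300 + k, label_rate_5 = 0.1,
                         label_rate_3 = 0.1)
    reads <- sort_read_models(rd$reads)
    tags <- extract_tags(reads)
    cl <- cluster_tags(tags, 50L, 0.02, 5, 0.02, coverage_lookup(reads))
    jx <- filter_locus_junctions(reads, 3L, 0.02)
    jkey <- paste(jx$donor, jx$acceptor)
    ok <- vapply(seq_len(nrow(reads)), function(i) {
      j <- reads$junctions[[i]]
      if (!length(j) || !any(j == "SPLICE")) return(TRUE)
      b <- reads$blocks[[i]]
      all(paste(b[which(j == "SPLICE"), 2],
                b[which(j == "SPLICE") + 1L, 1]) %in% jkey)
    }, logical(1))
    reads <- reads[ok, ]
    p <- build_partition(cl, jx, c(min(reads$start), max(reads$end)))
    mem <- build_membership(reads, p, 3L, 3L)
    t0 <- sum(mem$weight * mem$length)
    red <- collapse_linear_chains(mem)
    g <- resolve_containment(build_overlap_graph(red))
    expect_lt(abs(sum(red$weight * red$length) - t0) / t0, 1e-6)
    expect_lt(abs(sum(g$weight * g$length) - t0) / t0, 1e-6)
  }
})

test_that("the extension graph is acyclic", {
  set.seed(53)
  for (k in 1:20) {
    mem <- make_graph_fixture(5300 + k)
    g <- build_overlap_graph(mem)
    # DFS cycle detection over extension edges
    state <- integer(g$n)
    has_cycle <- FALSE
    visit <- function(i) {
      if (state[i] == 1L) { has_cycle <<- TRUE; return() }
      if (state[i] == 2L) return()
      state[i] <<- 1L
      for (j in g$edges_out[[i]]) visit(j)
      state[i] <<- 2L
    }
    for (i in seq_len(g$n)) visit(i)
    expect_false(has_cycle)
  }
})

test_that("source and sink connect to end-anchored elements only", {
  nf <- 4L
  mem <- bare_membership(
    list(mrow(nf, 1:2, s_plus = TRUE, e_plus = TRUE),
         mrow(nf, 2:3)),
    c(3, 1), nf)
  g <- build_overlap_graph(mem)
  expect_true(g$source_ok[1] && g$sink_ok[1])
  expect_false(g$source_ok[2] || g$sink_ok[2])
})
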