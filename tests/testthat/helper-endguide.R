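# shared helpers: exon-chain signatures, random read generators and the
# abstract overlap-graph fixtures used by the greedy-path oracle tests

chain_str <- function(e) paste(sprintf("%d-%d", e[, 1], e[, 2]), collapse = "|")

model_chains <- function(fit) {
  vapply(fit$models$exons, chain_str, character(1))
}

truth_chains <- function(sim) {
  vapply(sim$isoforms$exons, chain_str, character(1))
}

# random but valid read models for serialization round trips
random_reads <- function(n, seed = 1L, n_chrom = 2L, n_sample = 3L) {
  set.seed(seed)
  blocks <- vector("list", n)
  junctions <- vector("list", n)
  strand <- character(n); ll <- character(n); rl <- character(n)
  for (i in seq_len(n)) {
    k <- sample(1:4, 1)
    starts <- integer(k); ends <- integer(k)
    pos <- sample(0:5000, 1)
    for (b in seq_len(k)) {
      starts[b] <- pos
      ends[b] <- pos + sample(20:300, 1)
      pos <- ends[b] + sample(30:500, 1)
    }
    blocks[[i]] <- cbind(start = starts, end = ends)
    junctions[[i]] <- sample(c("SPLICE", "GAP"), k - 1L, replace = TRUE)
    strand[i] <- sample(c("+", "-", "."), 1)
    ll[i] <- "."; rl[i] <- "."
    if (strand[i] == "+") {
      if (runif(1) < 0.3) ll[i] <- sample(c("S", "C"), 1)
      if (runif(1) < 0.3) rl[i] <- "E"
    } else if (strand[i] == "-") {
      if (runif(1) < 0.3) ll[i] <- "E"
      if (runif(1) < 0.3) rl[i] <- sample(c("S", "C"), 1)
    }
  }
  read_models(chrom = sample(0:(n_chrom - 1L), n, replace = TRUE),
              blocks = blocks, junctions = junctions, strand = strand,
              left_label = ll, right_label = rl,
              weight = round(runif(n, 0.1, 9), 4),
              sample = sample(0:(n_sample - 1L), n, replace = TRUE))
}

test_header <- function(n_chrom = 2L, n_sample = 3L) {
  elr_header(tibble::tibble(name = paste0("chr", seq_len(n_chrom)),
                            length = rep(100000L, n_chrom)),
             samples = paste0("s", seq_len(n_sample) - 1L))
}

# a hand-rolled partition over equal 100 nt frags (no clusters), for
# membership/overlap fixtures built directly from membership rows
bare_partition <- function(nf, clusters = NULL) {
  frags <- tibble::tibble(start = (0:(nf - 1L)) * 100L, end = (1:nf) * 100L)
  if (is.null(clusters))
    clusters <- tibble::tibble(lo = integer(), hi = integer(),
                               summit = integer(), strand = character(),
                               kind = character(), weight = double(),
                               capped_fraction = double(), capped = logical())
  structure(list(span = c(0L, nf * 100L),
                 boundaries = tibble::tibble(pos = (1:(nf - 1L)) * 100L,
                                             type = "DONOR", strand = "+"),
                 clusters = clusters, frags = frags, n_frags = nf,
                 vS_plus = nf + 1L, vE_plus = nf + 2L,
                 vS_minus = nf + 3L, vE_minus = nf + 4L),
            class = "eg_partition")
}

# membership object assembled directly from rows (one sample)
bare_membership <- function(rows, weights, nf, strand = NULL) {
  M <- do.call(rbind, rows)
  if (is.null(strand)) strand <- rep("+", nrow(M))
  len <- as.double((M[, seq_len(nf), drop = FALSE] == 1L) %*%
                     rep(100L, nf))
  structure(list(M = M, weight = weights, bases = weights * len,
                 length = len, n_reads = rep(1L, nrow(M)), strand = strand,
                 sample_bases = matrix(weights * len, ncol = 1),
                 partition = bare_partition(nf)),
            class = "eg_membership")
}

# membership row helper: support frags +1, excluded frags -1, optional
# virtual anchors; minus-strand virtuals excluded for plus elements
mrow <- function(nf, support, excl = integer(), s_plus = FALSE,
                 e_plus = FALSE, upstream_excl = s_plus,
                 downstream_excl = e_plus) {
  m <- integer(nf + 4L)
  m[support] <- 1L
  m[setdiff(excl, support)] <- -1L
  if (s_plus) {
    m[nf + 1L] <- 1L
    if (upstream_excl && min(support) > 1L)
      m[seq_len(min(support) - 1L)] <- -1L
  }
  if (e_plus) {
    m[nf + 2L] <- 1L
    if (downstream_excl && max(support) < nf)
      m[(max(support) + 1L):nf] <- -1L
  }
  m[nf + 3L] <- -1L; m[nf + 4L] <- -1L
  m
}

# abstract overlap-graph generator for the greedy-vs-brute-force oracle:
# a shared uniform-coverage ladder interrupted by 1-2 forks, each fork a
# set of mutually exclusive alternatives (distinct discriminator frags)
# with its own coverage; one sample, so the similarity term is constant,
# and per-frag coverage is uniform along every source-sink route
make_graph_fixture <- function(seed) {
  set.seed(seed)
  n_forks <- sample(1:2, 1)
  alts <- lapply(seq_len(n_forks), function(f)
    round(runif(sample(2:3, 1), 1, 10), 3))
  total <- round(runif(1, 12, 30), 3)
  seg_len <- sample(2:3, n_forks + 1L, replace = TRUE)
  fork_w <- vapply(alts, length, integer(1))
  nf <- sum(seg_len) + sum(fork_w)
  rows <- list(); wts <- double()
  pos <- 1L
  seg_ranges <- list(); fork_ranges <- list()
  for (f in seq_len(n_forks + 1L)) {
    seg_ranges[[f]] <- pos:(pos + seg_len[f] - 1L)
    pos <- pos + seg_len[f]
    if (f <= n_forks) {
      fork_ranges[[f]] <- pos:(pos + fork_w[f] - 1L)
      pos <- pos + fork_w[f]
    }
  }
  add <- function(sup, w, s_plus = FALSE, e_plus = FALSE, excl = integer()) {
    rows[[length(rows) + 1L]] <<- mrow(nf, sup, excl, s_plus, e_plus)
    wts <<- c(wts, w)
  }
  for (f in seq_len(n_forks + 1L)) {
    seg <- seg_ranges[[f]]
    for (p in seq_len(length(seg) - 1L))
      add(seg[p]:(seg[p] + 1L), total,
          s_plus = f == 1L && p == 1L,
          e_plus = f == n_forks + 1L && p == length(seg) - 1L)
  }
  for (f in seq_len(n_forks)) {
    D <- fork_ranges[[f]]
    lflank <- max(seg_ranges[[f]])
    rflank <- min(seg_ranges[[f + 1L]])
    for (a in seq_along(alts[[f]]))
      add(c(lflank, D[a], rflank), alts[[f]][a], excl = D)
  }
  bare_membership(rows, wts, nf)
}

# independent brute-force oracle: enumerate every source-to-sink chain of
# mutually compatible elements (recomputing pair codes with
# overlap_codes) and return the one with the largest bottleneck weight
path_bottleneck <- function(g, path) {
  nf <- g$mem$partition$n_frags
  cov <- double(nf)
  for (p in path) {
    memb <- g$mem$M[p, seq_len(nf)] == 1L
    cov[memb] <- cov[memb] + g$weight[p]
  }
  fr <- which(colSums(g$mem$M[path, seq_len(nf), drop = FALSE] == 1L) > 0)
  if (!length(fr)) return(0)
  min(cov[fr])
}

brute_force_best_path <- function(g) {
  live <- which(!g$removed)
  ord <- endguide:::extended_order(g$mem$partition)
  Mx <- g$mem$M[, ord, drop = FALSE]
  n <- g$n
  codes <- array(0L, c(n, n, 2))
  for (i in live) for (j in live) if (i < j) {
    cd <- overlap_codes(Mx[i, ], Mx[j, ], g$strand[i], g$strand[j])
    codes[i, j, ] <- cd; codes[j, i, ] <- rev(cd)
  }
  lastc <- vapply(live, function(i) max(which(Mx[i, ] == 1L)), integer(1))
  firstc <- vapply(live, function(i) min(which(Mx[i, ] == 1L)), integer(1))
  li <- function(i) match(i, live)
  nbr <- function(i) {
    out <- integer()
    for (j in live) if (j != i) {
      ext <- codes[i, j, 1] == 1L && codes[j, i, 1] == 1L &&
        (lastc[li(j)] > lastc[li(i)] ||
           (lastc[li(j)] == lastc[li(i)] && firstc[li(j)] > firstc[li(i)]))
      cont <- codes[i, j, 1] == 2L && lastc[li(j)] > lastc[li(i)]
      if (ext || cont) out <- c(out, j)
    }
    out
  }
  best_w <- -Inf; best <- NULL
  rec <- function(path) {
    i <- path[length(path)]
    if (g$sink_ok[i]) {
      w <- path_bottleneck(g, path)
      if (w > best_w + 1e-12) { best_w <<- w; best <<- path }
    }
    for (j in nbr(i)) {
      if (j %in% path) next
      if (any(vapply(path, function(p) codes[p, j, 1] == -1L, logical(1)))) next
      rec(c(path, j))
    }
  }
  for (s in live[g$source_ok[live]]) rec(s)
  list(weight = best_w, path = best)
}
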