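# Overlap graph construction, linear-chain collapse, containment
# resolution. All element bookkeeping is in "bases" (sequenced nt), the
# conserved quantity; weight = bases / genomic length is derived.

# merge elements with identical +1 support (mutual containment) so the
# 2<->2 ambiguity never reaches the graph
merge_identical_support <- function(mem, O = NULL) {
  if (is.null(O)) O <- overlap_matrix(mem)
  ne <- nrow(mem$M)
  parent <- seq_len(ne)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(max(ne - 1L, 0L))) for (j in (i + 1L):ne) {
    if (ne < 2L) break
    if (O[i, j] == 2L && O[j, i] == 2L) parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(ne), find, integer(1))
  if (length(unique(roots)) == ne) return(mem)
  groups <- split(seq_len(ne), roots)
  collapse_groups(mem, groups)
}

# pool element groups into merged elements (used by identical-support
# merging and linear-chain collapse)
collapse_groups <- function(mem, groups) {
  nf <- mem$partition$n_frags
  fl <- mem$partition$frags$end - mem$partition$frags$start
  ng <- length(groups)
  M <- matrix(0L, ng, ncol(mem$M))
  bases <- double(ng); n_reads <- integer(ng); strand <- character(ng)
  sample_bases <- matrix(0, ng, ncol(mem$sample_bases))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    sub <- mem$M[rows, , drop = FALSE]
    m <- apply(sub, 2L, function(col) {
      if (any(col == 1L)) 1L else if (any(col == -1L)) -1L else 0L
    })
    M[g, ] <- m
    bases[g] <- sum(mem$bases[rows])
    n_reads[g] <- sum(mem$n_reads[rows])
    s <- setdiff(unique(mem$strand[rows]), ".")
    strand[g] <- if (length(s) == 1L) s else if (length(s) == 0L) "." else
      stop("cannot merge elements of opposite strands")
    sample_bases[g, ] <- colSums(mem$sample_bases[rows, , drop = FALSE])
  }
  len <- as.double((M[, seq_len(nf), drop = FALSE] == 1L) %*% fl)
  structure(list(M = M, weight = ifelse(len > 0, bases / len, 0),
                 bases = bases, length = len, n_reads = n_reads,
                 strand = strand, sample_bases = sample_bases,
                 partition = mem$partition),
            class = "eg_membership")
}

# directed extension edges between elements: i -> j when the pair mutually
# extends (codes 1/1) and j reaches further right in extended column order
extension_edges <- function(mem, O) {
  ord <- extended_order(mem$partition)
  Mx <- mem$M[, ord, drop = FALSE]
  ne <- nrow(Mx)
  lastc <- integer(ne); firstc <- integer(ne)
  for (i in seq_len(ne)) {
    w <- which(Mx[i, ] == 1L)
    firstc[i] <- w[1]; lastc[i] <- w[length(w)]
  }
  from <- integer(); to <- integer()
  if (ne >= 2L) for (i in seq_len(ne - 1L)) for (j in (i + 1L):ne) {
    if (O[i, j] == 1L && O[j, i] == 1L) {
      fwd <- (lastc[j] > lastc[i]) ||
        (lastc[j] == lastc[i] && firstc[j] > firstc[i])
      if (fwd) { from <- c(from, i); to <- c(to, j) }
      else { from <- c(from, j); to <- c(to, i) }
    }
  }
  list(from = from, to = to, firstc = firstc, lastc = lastc)
}

#' Collapse linear chains of elements
#'
#' Merges non-branching corridors of the extension graph before path
#' extraction: consecutive elements `u -> v` where `v` is `u`'s only
#' extension target, `u` is `v`'s only extension source, both share the
#' same exclusion set and neither is involved in a containment with a
#' third element. This is purely an optimization; assembly output is
#' invariant to it.
#'
#' @param mem An `eg_membership`.
#' @return A reduced `eg_membership`.
#' @export
collapse_linear_chains <- function(mem) {
  repeat {
    ne <- nrow(mem$M)
    if (ne < 2L) return(mem)
    O <- overlap_matrix(mem)
    ed <- extension_edges(mem, O)
    out_n <- tabulate(ed$from, ne); in_n <- tabulate(ed$to, ne)
    excl_key <- vapply(seq_len(ne), function(i)
      paste(which(O[i, ] == -1L), collapse = ","), character(1))
    in_containment <- vapply(seq_len(ne), function(i)
      any(O[i, ] == 2L) || any(O[, i] == 2L), logical(1))
    # collect all eligible corridor pairs, then merge a disjoint batch
    used <- rep(FALSE, ne)
    parent <- seq_len(ne)
    merged <- FALSE
    for (k in seq_along(ed$from)) {
      u <- ed$from[k]; v <- ed$to[k]
      if (out_n[u] == 1L && in_n[v] == 1L &&
          excl_key[u] == excl_key[v] &&
          !in_containment[u] && !in_containment[v] &&
          !used[u] && !used[v]) {
        parent[v] <- u
        used[u] <- TRUE; used[v] <- TRUE
        merged <- TRUE
      }
    }
    if (!merged) return(mem)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    roots <- vapply(seq_len(ne), find, integer(1))
    mem <- collapse_groups(mem, split(seq_len(ne), roots))
  }
}

#' Build the overlap graph
#'
#' Wraps a (reduced) membership set into the directed element graph used
#' by path extraction: extension edges oriented genomic left-to-right, a
#' global source feeding every element carrying the source-side virtual
#' frag of its strand (S+ on plus, E- on minus) and a sink draining the
#' mirrored elements, plus per-node exclusion and containment sets.
#'
#' @param mem An `eg_membership` (identical-support elements are merged
#'   first).
#' @return List of class `eg_graph`.
#' @export
build_overlap_graph <- function(mem) {
  mem <- merge_identical_support(mem)
  O <- overlap_matrix(mem)
  ne <- nrow(mem$M)
  ed <- extension_edges(mem, O)
  p <- mem$partition
  edges_out <- lapply(seq_len(ne), function(i) ed$to[ed$from == i])
  edges_in <- lapply(seq_len(ne), function(i) ed$from[ed$to == i])
  excl <- lapply(seq_len(ne), function(i) which(O[i, ] == -1L))
  contained_by <- lapply(seq_len(ne), function(i) which(O[i, ] == 2L))
  source_ok <- mem$M[, p$vS_plus] == 1L | mem$M[, p$vE_minus] == 1L
  sink_ok <- mem$M[, p$vE_plus] == 1L | mem$M[, p$vS_minus] == 1L
  structure(list(mem = mem, O = O, n = ne,
                 edges_out = edges_out, edges_in = edges_in,
                 excl = excl, contained_by = contained_by,
                 firstc = ed$firstc, lastc = ed$lastc,
                 source_ok = source_ok, sink_ok = sink_ok,
                 bases = mem$bases, length = mem$length,
                 weight = mem$weight, sample_bases = mem$sample_bases,
                 strand = mem$strand, removed = rep(FALSE, ne)),
            class = "eg_graph")
}

#' @export
print.eg_graph <- function(x, ...) {
  cat("<eg_graph> ", sum(!x$removed), " live elements, ",
      length(unlist(x$edges_out)), " extension edges\n", sep = "")
  invisible(x)
}

# deterministic processing order: increasing information content (number
# of non-zero memberships), ties by leftmost support then element index
info_order <- function(g, idx = seq_len(g$n)) {
  info <- rowSums(g$mem$M[idx, , drop = FALSE] != 0L)
  idx[order(info, g$firstc[idx], idx)]
}

#' Redistribute contained element weights
#'
#' Every element contained by one or more live longer elements transfers
#' its sequenced bases to those containers, proportionally to the
#' containers' current weights, provided the containers do not jointly
#' exclude any node the element does not already exclude (that would
#' destroy evidence for a path only the contained element supports).
#' Qualifying elements are removed from the graph; processing runs in
#' increasing information content, single pass.
#'
#' @param g An `eg_graph`.
#' @return The updated graph.
#' @export
resolve_containment <- function(g) {
  for (i in info_order(g)) {
    containers <- setdiff(g$contained_by[[i]], which(g$removed))
    if (!length(containers) || g$removed[i]) next
    joint <- Reduce(intersect, g$excl[containers])
    joint <- setdiff(joint, which(g$removed))
    if (length(setdiff(joint, g$excl[[i]]))) next
    w <- g$weight[containers]
    share <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    g$bases[containers] <- g$bases[containers] + g$bases[i] * share
    g$sample_bases[containers, ] <-
      g$sample_bases[containers, , drop = FALSE] +
      outer(share, g$sample_bases[i, ])
    g$weight[containers] <- g$bases[containers] / g$length[containers]
    g$bases[i] <- 0
    g$sample_bases[i, ] <- 0
    g$weight[i] <- 0
    g$removed[i] <- TRUE
  }
  g
}
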