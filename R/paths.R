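# Greedy source-to-sink path extraction from the overlap graph.

# nodes blocked for path P: removed, excluded by any path element, or
# strand-incompatible with the path strand
blocked_nodes <- function(g, path, pstrand) {
  bl <- g$removed
  for (p in path) bl[g$excl[[p]]] <- TRUE
  if (pstrand != ".")
    bl[g$strand != "." & g$strand != pstrand] <- TRUE
  bl
}

# can `node` (or anything leftward of it) reach the source through
# unblocked nodes?
reaches_source <- function(g, node, blocked) {
  seen <- rep(FALSE, g$n)
  stack <- node
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[x] || (blocked[x] && x != node)) next
    seen[x] <- TRUE
    if (g$source_ok[x]) return(TRUE)
    stack <- c(stack, g$edges_in[[x]])
  }
  FALSE
}

reaches_sink <- function(g, node, blocked) {
  seen <- rep(FALSE, g$n)
  stack <- node
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[x] || (blocked[x] && x != node)) next
    seen[x] <- TRUE
    if (g$sink_ok[x]) return(TRUE)
    stack <- c(stack, g$edges_out[[x]])
  }
  FALSE
}

# per-frag coverage of a candidate path (current available weights)
path_frag_cov <- function(g, path, avail) {
  nf <- g$mem$partition$n_frags
  cov <- double(nf)
  for (p in path) {
    memb <- g$mem$M[p, seq_len(nf)] == 1L
    cov[memb] <- cov[memb] + avail[p]
  }
  cov
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1) # no sample information -> neutral
  sum(a * b) / (na * nb)
}

#' Score a candidate path extension
#'
#' The arithmetic mean of three `[0, 1]` terms: the candidate's available
#' weight relative to the heaviest candidate; the cosine similarity of the
#' per-sample coverage distributions of path and candidate; and
#' `1 / (1 + CV)` where CV is the coefficient of variation of per-frag
#' coverage after the hypothetical extension. Source/sink reachability is
#' a hard constraint applied before scoring, not a term.
#'
#' @param g An `eg_graph`.
#' @param path Integer vector of current path elements.
#' @param cand Candidate element index.
#' @param avail Current available weight per element.
#' @param max_cand_w Maximum available weight among all candidates.
#' @param eff_w Effective candidate weight for the weight term (absorbed
#'   candidates count zero; defaults to `avail[cand]`).
#' @param score_weights Named weights of the three terms; the default
#'   combines them equally.
#' @return A scalar score.
#' @export
score_extension <- function(g, path, cand, avail, max_cand_w,
                            eff_w = avail[cand],
                            score_weights = c(weight = 1, similarity = 1,
                                              variance = 1)) {
  w_term <- if (max_cand_w > 0) eff_w / max_cand_w else 1
  len_p <- g$length[path]
  samp_path <- colSums(g$sample_bases[path, , drop = FALSE] /
                         ifelse(len_p > 0, len_p, 1))
  samp_cand <- g$sample_bases[cand, ] / max(g$length[cand], 1)
  sim_term <- cosine_sim(samp_path, samp_cand)
  nf <- g$mem$partition$n_frags
  newp <- c(path, cand)
  memberfrags <- which(colSums(g$mem$M[newp, seq_len(nf), drop = FALSE] == 1L) > 0)
  cov <- path_frag_cov(g, newp, avail)[memberfrags]
  cv <- if (length(cov) > 1L && mean(cov) > 0)
    sqrt(mean((cov - mean(cov))^2)) / mean(cov) else 0
  var_term <- 1 / (1 + cv)
  sum(score_weights * c(w_term, sim_term, var_term)) / sum(score_weights)
}

# candidate extensions on one side of the path: extension-edge neighbours
# plus live containers of the end element that reach further out on that
# side (containment is a directed overlap usable as an edge; a leftover
# fragment's most natural continuation is often the element containing it)
side_candidates <- function(g, path, end_elem, side, pstrand) {
  cand <- if (side == "left") g$edges_in[[end_elem]] else g$edges_out[[end_elem]]
  containers <- g$contained_by[[end_elem]]
  if (length(containers)) {
    reach <- if (side == "left") g$firstc[containers] < g$firstc[end_elem]
             else g$lastc[containers] > g$lastc[end_elem]
    cand <- c(cand, containers[reach & !g$removed[containers]])
  }
  cand <- setdiff(unique(cand), path)
  if (!length(cand)) return(integer())
  bl <- blocked_nodes(g, path, pstrand)
  cand[!bl[cand]]
}

#' Extract greedy source-to-sink paths
#'
#' Iteratively seeds a path at the heaviest unassigned element and extends
#' it in both directions, always taking the extension with the highest
#' [score_extension()] among those that preserve source/sink reachability,
#' until the source-side and sink-side virtual frags are reached or no
#' extension exists. Each finished path is assigned the bottleneck weight
#' (minimum per-frag coverage across its member frags), which is
#' subtracted from its elements so shared elements can support several
#' isoforms; its elements are marked assigned. Iteration stops when the
#' total weight of unassigned elements falls below `end_fraction` of the
#' initial locus weight.
#'
#' @param g An `eg_graph` (after [resolve_containment()]).
#' @param end_fraction Stop threshold as a fraction of initial locus
#'   weight.
#' @param score_weights Passed to [score_extension()]; the default
#'   combines the three terms equally.
#' @return List of paths; each has `elements`, `strand`, `weight`
#'   (assigned coverage), `has_source`, `has_sink`, `complete`, `frags`
#'   (member frag indices) and `sample_cov`.
#' @export
greedy_paths <- function(g, end_fraction = 0.02,
                         score_weights = c(weight = 1, similarity = 1,
                                           variance = 1)) {
  nf <- g$mem$partition$n_frags
  avail <- g$weight
  avail[g$removed] <- 0
  assigned <- g$removed  # element was a constituent of some emitted path
  absorbed <- g$removed  # element fully explained by an emitted path
  total0 <- sum(avail)
  paths <- list()
  if (total0 <= 0) return(paths)
  repeat {
    seedable <- which(!assigned & !absorbed & avail > 1e-12)
    if (!length(seedable)) break
    # continue past the signal threshold only for elements that carry end
    # evidence (a Start/End virtual frag): every surviving boundary
    # cluster deserves an explanation attempt, while unanchored residue
    # below the threshold is left unassigned
    over <- sum(avail[seedable]) > end_fraction * total0
    anchored <- seedable[g$source_ok[seedable] | g$sink_ok[seedable]]
    pool <- if (over) seedable else anchored
    if (!length(pool)) break
    seed <- pool[which.max(avail[pool])]
    path <- grow_path(g, seed, avail, absorbed, score_weights)
    members <- path$elements
    cov <- path_frag_cov(g, members, avail)
    fragset <- which(colSums(g$mem$M[members, seq_len(nf), drop = FALSE] == 1L) > 0)
    w <- if (length(fragset)) min(cov[fragset]) else 0
    avail[members] <- pmax(0, avail[members] - w)
    assigned[members] <- TRUE
    # absorb elements the path fully explains: no membership
    # disagreement, support within the path's (hole-filled) support,
    # compatible strand. They no longer count as unexplained signal and
    # cannot seed recombinations of leftover evidence, but they may
    # still serve as constituents of later paths.
    pm <- path_union_fill(g, members)
    pm_pos <- which(pm == 1L)
    for (e in which(!assigned & !absorbed)) {
      me <- g$mem$M[e, ]
      if (g$strand[e] != "." && path$strand != "." &&
          g$strand[e] != path$strand) next
      if (any(me * pm < 0L)) next
      if (all(which(me == 1L) %in% pm_pos)) absorbed[e] <- TRUE
    }
    if (w <= 0) next # fully drained recombination, nothing to report
    len_m <- ifelse(g$length[members] > 0, g$length[members], 1)
    samp <- colSums(g$sample_bases[members, , drop = FALSE] / len_m)
    paths[[length(paths) + 1L]] <- list(
      elements = members, strand = path$strand, weight = w,
      has_source = path$has_source, has_sink = path$has_sink,
      complete = path$has_source && path$has_sink,
      frags = fragset, sample_cov = samp)
  }
  prune_redundant_paths(paths, g)
}

# membership union of a path with interior unknown frags filled as
# exonic (transcript models fill those holes the same way)
path_union_fill <- function(g, members) {
  nf <- g$mem$partition$n_frags
  pm <- apply(g$mem$M[members, , drop = FALSE], 2L, function(col) {
    if (any(col == 1L)) 1L else if (any(col == -1L)) -1L else 0L
  })
  ones <- which(pm[seq_len(nf)] == 1L)
  if (length(ones) > 1L) {
    interior <- (ones[1]):(ones[length(ones)])
    fill <- interior[pm[interior] == 0L]
    pm[fill] <- 1L
  }
  pm
}

# parsimony: drop a path when every one of its elements is fully
# explained (no membership disagreement, support contained) by some
# other kept path -- such a path only recombines evidence that other
# models already account for. End-labeled elements always conflict with
# paths crossing their excluded flanks, so genuinely distinct isoforms
# are never pruned: dropping requires every element to be redundant.
prune_redundant_paths <- function(paths, g) {
  if (length(paths) < 2L) return(paths)
  pms <- lapply(paths, function(p) path_union_fill(g, p$elements))
  keep <- rep(TRUE, length(paths))
  ord <- order(vapply(paths, `[[`, double(1), "weight"))
  for (i in ord) {
    others <- setdiff(which(keep), i)
    if (!length(others)) next
    explained <- vapply(paths[[i]]$elements, function(e) {
      me <- g$mem$M[e, ]
      any(vapply(others, function(j) {
        pm <- pms[[j]]
        if (g$strand[e] != "." && paths[[j]]$strand != "." &&
            g$strand[e] != paths[[j]]$strand) return(FALSE)
        !any(me * pm < 0L) && all(which(me == 1L) %in% which(pm == 1L))
      }, logical(1)))
    }, logical(1))
    if (all(explained)) keep[i] <- FALSE
  }
  paths[keep]
}

# grow one path from a seed, both directions, greedy best-scoring move.
# Elements already explained by an emitted path (absorbed) count zero in
# the candidate-weight term -- their residual weight is not unexplained
# signal -- so the sample-similarity and coverage-smoothness terms decide
# between explained continuations.
grow_path <- function(g, seed, avail, absorbed = rep(FALSE, g$n),
                      score_weights = c(weight = 1, similarity = 1,
                                        variance = 1)) {
  path <- seed
  pstrand <- g$strand[seed]
  l_elem <- seed; r_elem <- seed
  repeat {
    left_closed <- any(g$source_ok[path])
    right_closed <- any(g$sink_ok[path])
    if (left_closed && right_closed) break
    cands <- list()
    if (!left_closed)
      for (x in side_candidates(g, path, l_elem, "left", pstrand))
        cands[[length(cands) + 1L]] <- list(x = x, side = "left")
    if (!right_closed)
      for (x in side_candidates(g, path, r_elem, "right", pstrand))
        cands[[length(cands) + 1L]] <- list(x = x, side = "right")
    if (!length(cands)) break
    # hard constraint: do not make source or sink newly unreachable
    bl0 <- blocked_nodes(g, path, pstrand)
    src0 <- left_closed || reaches_source(g, l_elem, bl0)
    snk0 <- right_closed || reaches_sink(g, r_elem, bl0)
    ok <- vapply(cands, function(cd) {
      newp <- c(path, cd$x)
      ns <- if (pstrand == ".") g$strand[cd$x] else pstrand
      bl <- blocked_nodes(g, newp, ns)
      nl <- if (cd$side == "left") cd$x else l_elem
      nr <- if (cd$side == "right") cd$x else r_elem
      src <- any(g$source_ok[newp]) || reaches_source(g, nl, bl)
      snk <- any(g$sink_ok[newp]) || reaches_sink(g, nr, bl)
      (!src0 || src) && (!snk0 || snk)
    }, logical(1))
    cands <- cands[ok]
    if (!length(cands)) break
    xs <- vapply(cands, function(cd) cd$x, integer(1))
    effw <- ifelse(absorbed[xs], 0, avail[xs])
    maxw <- max(effw)
    scores <- vapply(seq_along(cands), function(ci)
      score_extension(g, path, cands[[ci]]$x, avail, maxw, effw[ci],
                      score_weights), double(1))
    # ties: leftmost support column, then element index
    o <- order(-scores, g$firstc[xs], xs)
    pick <- cands[[o[1]]]
    path <- c(path, pick$x)
    if (pstrand == "." && g$strand[pick$x] != ".") pstrand <- g$strand[pick$x]
    if (pick$side == "left") l_elem <- pick$x else r_elem <- pick$x
  }
  list(elements = path, strand = pstrand,
       has_source = any(g$source_ok[path]),
       has_sink = any(g$sink_ok[path]))
}
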