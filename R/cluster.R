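#' Split a sorted read stream into loci
#'
#' Walks reads in sorted order and starts a new locus whenever the gap
#' between the rightmost covered base so far and the next read's start
#' exceeds `max_gap`. Chromosomes always separate loci.
#'
#' @param reads Sorted read-model tibble (see [sort_read_models()]).
#' @param max_gap Maximum intra-locus uncovered gap (nt).
#' @return List of read-model tibbles, one per locus, in genomic order.
#' @export
chunk_reads <- function(reads, max_gap = 50L) {
  n <- nrow(reads)
  if (!n) return(list())
  new_chunk <- logical(n); new_chunk[1] <- TRUE
  cur_chrom <- reads$chrom[1]; cur_end <- reads$end[1]
  for (i in seq_len(n)[-1]) {
    if (reads$chrom[i] != cur_chrom || reads$start[i] - cur_end > max_gap) {
      new_chunk[i] <- TRUE
      cur_chrom <- reads$chrom[i]; cur_end <- reads$end[i]
    } else {
      cur_end <- max(cur_end, reads$end[i])
    }
  }
  unname(split(reads, cumsum(new_chunk)))
}

#' Extract Start/Cap/End Tags from labeled reads
#'
#' A Start Tag is the genomic position of a confirmed 5' label (Cap Tag if
#' backed by an upstream untemplated G), an End Tag that of a confirmed 3'
#' label. Left-terminus tags sit at the read `start`, right-terminus tags
#' at the half-open read `end`.
#'
#' @param reads Read-model tibble.
#' @return Tibble with columns `pos`, `strand`, `kind` (`S`, `C`, `E`) and
#'   `weight`.
#' @export
extract_tags <- function(reads) {
  n <- nrow(reads)
  pos <- integer(0); strand <- character(0); kind <- character(0); w <- double(0)
  left <- reads$left_label != "."
  right <- reads$right_label != "."
  if (any(left)) {
    pos <- c(pos, reads$start[left]); strand <- c(strand, reads$strand[left])
    kind <- c(kind, reads$left_label[left]); w <- c(w, reads$weight[left])
  }
  if (any(right)) {
    pos <- c(pos, reads$end[right]); strand <- c(strand, reads$strand[right])
    kind <- c(kind, reads$right_label[right]); w <- c(w, reads$weight[right])
  }
  tibble::tibble(pos = pos, strand = strand, kind = kind, weight = w)
}

#' Cluster Start/Cap/End Tags into boundary clusters
#'
#' Tags are grouped per strand into a TSS pool (Start + Cap Tags, with Cap
#' weight multiplied by `cap_bonus`) and a PAS pool (End Tags). Each
#' position is scored as signal = weight x (weight / coverage): when a
#' read-coverage lookup is supplied, coverage is the total read depth at
#' the tag position, so a position survives when its labeled ends account
#' for at least `threshold_fraction` of the reads crossing it -- a minor
#' TSS inside a well-expressed gene is kept while stray labels are not.
#' Without a coverage lookup, the same-kind tag pool total is used instead
#' and the threshold is `threshold_fraction` of the pool's total signal.
#' Surviving positions within `distance` of each other merge into one
#' cluster whose summit is the position of maximal signal (leftmost on
#' ties); `capped_fraction` is the unbonused Cap share of the cluster
#' weight, and a TSS cluster counts as capped when it reaches
#' `cap_filter`.
#'
#' @param tags Tag tibble from [extract_tags()].
#' @param distance Merge distance (nt).
#' @param threshold_fraction Signal proportion below which positions are
#'   discarded.
#' @param cap_bonus Multiplicative Cap Tag weight bonus.
#' @param cap_filter Minimum capped fraction for a capped TSS cluster.
#' @param coverage_at Optional function mapping a vector of genomic base
#'   positions to read coverage (see [coverage_lookup()]).
#' @return Tibble with one row per cluster: `lo`, `hi` (outermost member
#'   positions), `summit`, `strand`, `kind` (`TSS`/`PAS`), `weight`
#'   (unbonused), `capped_fraction`, `capped`.
#' @export
cluster_tags <- function(tags, distance = 50L, threshold_fraction = 0.02,
                         cap_bonus = 5, cap_filter = 0.02,
                         coverage_at = NULL) {
  empty <- tibble::tibble(lo = integer(), hi = integer(), summit = integer(),
                          strand = character(), kind = character(),
                          weight = double(), capped_fraction = double(),
                          capped = logical())
  if (!nrow(tags)) return(empty)
  tags$group <- ifelse(tags$kind == "E", "PAS", "TSS")
  out <- list()
  for (st in unique(tags$strand)) {
    for (gr in unique(tags$group[tags$strand == st])) {
      tg <- tags[tags$strand == st & tags$group == gr, ]
      agg <- tg |>
        dplyr::group_by(.data$pos) |>
        dplyr::summarise(
          raw = sum(.data$weight),
          cap = sum(.data$weight[.data$kind == "C"]),
          bonus = sum(.data$weight * ifelse(.data$kind == "C", cap_bonus, 1)),
          .groups = "drop") |>
        dplyr::arrange(.data$pos)
      if (is.null(coverage_at)) {
        tot <- sum(agg$bonus)
        agg$signal <- agg$bonus * (agg$bonus / tot)
        agg <- agg[agg$signal >= threshold_fraction * sum(agg$signal), ]
      } else {
        # coverage is taken at the last transcribed base adjacent to the
        # boundary (tag positions are half-open interval edges)
        qpos <- agg$pos
        right_edge <- (gr == "TSS" & st == "-") | (gr == "PAS" & st == "+")
        if (right_edge) qpos <- pmax(qpos - 1L, 0L)
        rc <- pmax(coverage_at(qpos), agg$bonus)
        agg$signal <- agg$bonus * (agg$bonus / rc)
        agg <- agg[agg$bonus >= threshold_fraction * rc, ]
      }
      if (!nrow(agg)) next
      cl_id <- cumsum(c(1L, diff(agg$pos) > distance))
      for (cl in split(agg, cl_id)) {
        summit <- cl$pos[which.max(cl$signal)]
        cw <- sum(cl$raw)
        cf <- if (cw > 0) sum(cl$cap) / cw else 0
        out[[length(out) + 1L]] <- tibble::tibble(
          lo = min(cl$pos), hi = max(cl$pos), summit = summit,
          strand = st, kind = gr, weight = cw, capped_fraction = cf,
          capped = gr == "TSS" & cf >= cap_filter)
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$summit, .data$kind, .data$strand)
}

#' Read-coverage step function of a locus
#'
#' Builds the per-base read coverage (exonic blocks only, weighted) and
#' returns a vectorized lookup function used to normalize tag signal and
#' junction support.
#'
#' @param reads Locus read-model tibble.
#' @return Function mapping base positions to coverage.
#' @export
coverage_lookup <- function(reads) {
  nb <- vapply(reads$blocks, nrow, integer(1))
  allb <- do.call(rbind, reads$blocks)
  w <- rep(reads$weight, nb)
  ev_pos <- c(allb[, 1], allb[, 2])
  ev_w <- c(w, -w)
  o <- order(ev_pos)
  pos <- ev_pos[o]
  cum <- cumsum(ev_w[o])
  # collapse ties to the last cumulative value at each breakpoint
  keep <- c(pos[-1L] != pos[-length(pos)], TRUE)
  pos <- pos[keep]; cum <- cum[keep]
  function(p) {
    idx <- findInterval(p, pos)
    ifelse(idx == 0L, 0, cum[pmax(idx, 1L)])
  }
}

#' Filter locus splice junctions by coverage
#'
#' Collects splice junctions from the locus reads, counting only reads
#' whose aligned blocks flank the junction by at least `min_overhang` nt on
#' both sides, and drops junctions whose support is below
#' `threshold_fraction` of the total read coverage overlapping the intron.
#' Junctions present in `whitelist` are always retained.
#'
#' @param reads Locus read-model tibble.
#' @param min_overhang Minimum flanking aligned nt per side.
#' @param threshold_fraction Minimum support / overlapping-coverage ratio.
#' @param whitelist Optional junction tibble (chrom-agnostic here: matched
#'   on `donor`, `acceptor`).
#' @return Tibble of retained junctions: `donor`, `acceptor`, `strand`,
#'   `support`.
#' @export
filter_locus_junctions <- function(reads, min_overhang = 3L,
                                   threshold_fraction = 0.02,
                                   whitelist = NULL) {
  donors <- integer(); acceptors <- integer(); strands <- character()
  support <- double()
  add <- function(d, a, s, w) {
    d <- as.integer(unname(d)); a <- as.integer(unname(a))
    key <- paste(d, a)
    hit <- match(key, paste(donors, acceptors))
    if (is.na(hit)) {
      donors <<- c(donors, d); acceptors <<- c(acceptors, a)
      strands <<- c(strands, s); support <<- c(support, w)
    } else {
      support[hit] <<- support[hit] + w
      if (strands[hit] == "." && s != ".") strands[hit] <<- s
    }
  }
  for (i in seq_len(nrow(reads))) {
    j <- reads$junctions[[i]]
    if (!length(j) || !any(j == "SPLICE")) next
    b <- reads$blocks[[i]]
    lens <- b[, 2] - b[, 1]
    for (k in which(j == "SPLICE")) {
      if (lens[k] < min_overhang || lens[k + 1L] < min_overhang) next
      add(b[k, 2], b[k + 1L, 1], reads$strand[i], reads$weight[i])
    }
  }
  if (!length(donors))
    return(tibble::tibble(donor = integer(), acceptor = integer(),
                          strand = character(), support = double()))
  keep <- logical(length(donors))
  wl <- if (!is.null(whitelist) && nrow(whitelist))
    paste(whitelist$donor, whitelist$acceptor) else character()
  for (k in seq_along(donors)) {
    cov <- sum(reads$weight[reads$start < acceptors[k] & reads$end > donors[k]])
    keep[k] <- (paste(donors[k], acceptors[k]) %in% wl) ||
      support[k] >= threshold_fraction * cov
  }
  out <- tibble::tibble(donor = donors, acceptor = acceptors,
                        strand = strands, support = support)[keep, ]
  dplyr::arrange(out, .data$donor, .data$acceptor)
}

#' Build the frag partition of a locus
#'
#' Boundary positions (TSS/PAS cluster summits, splice donors and
#' acceptors) partition the locus span into non-overlapping "frags", the
#' atomic columns of the Membership Matrix. Four virtual frags (S+, E+,
#' S-, E-) record the presence of a Start or End Tag on each strand and
#' are appended as columns F+1..F+4.
#'
#' @param clusters Cluster tibble from [cluster_tags()].
#' @param junctions Junction tibble from [filter_locus_junctions()].
#' @param span Length-2 integer vector, half-open locus span.
#' @return List of class `eg_partition` with `span`, `boundaries` (tibble
#'   `pos`, `type`, `strand`), `clusters`, `frags` (tibble `start`, `end`),
#'   `n_frags`, and virtual column indices `vS_plus`, `vE_plus`,
#'   `vS_minus`, `vE_minus`.
#' @export
build_partition <- function(clusters, junctions, span) {
  b <- list()
  if (nrow(clusters)) {
    b[[1]] <- tibble::tibble(pos = clusters$summit, type = clusters$kind,
                             strand = clusters$strand)
  }
  if (nrow(junctions)) {
    b[[length(b) + 1L]] <- tibble::tibble(pos = junctions$donor,
                                          type = "DONOR",
                                          strand = junctions$strand)
    b[[length(b) + 1L]] <- tibble::tibble(pos = junctions$acceptor,
                                          type = "ACCEPTOR",
                                          strand = junctions$strand)
  }
  boundaries <- if (length(b)) dplyr::bind_rows(b) else
    tibble::tibble(pos = integer(), type = character(), strand = character())
  boundaries <- boundaries[boundaries$pos > span[1] & boundaries$pos < span[2], ]
  type_rank <- c(TSS = 1L, ACCEPTOR = 2L, DONOR = 3L, PAS = 4L)
  boundaries <- boundaries[order(boundaries$pos, type_rank[boundaries$type]), ]
  edges <- sort(unique(c(span[1], boundaries$pos, span[2])))
  frags <- tibble::tibble(start = edges[-length(edges)], end = edges[-1L])
  nf <- nrow(frags)
  structure(list(span = span, boundaries = boundaries, clusters = clusters,
                 frags = frags, n_frags = nf,
                 vS_plus = nf + 1L, vE_plus = nf + 2L,
                 vS_minus = nf + 3L, vE_minus = nf + 4L),
            class = "eg_partition")
}

#' @export
print.eg_partition <- function(x, ...) {
  cat("<eg_partition> span [", x$span[1], ",", x$span[2], "), ",
      x$n_frags, " frags + 4 virtual, ", nrow(x$boundaries),
      " boundaries\n", sep = "")
  invisible(x)
}
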