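#' Build the condensed Membership Matrix
#'
#' Re-expresses every locus read over the frag partition: `+1` for each
#' frag the read overlaps by at least `min_overhang` aligned nt (or
#' covers fully), `-1` for each frag the read is incompatible with (a
#' spliced-out intron, a frag upstream of its Start Tag cluster or
#' downstream of its End Tag cluster, or the wrong strand's virtual
#' frags), `0` where the read carries no information (mate gaps, partial
#' terminal slivers, everything beyond an unlabeled terminus). Reads with
#' identical membership rows are condensed into one element whose weight
#' is total sequenced bases over element genomic length, tracked per
#' sample.
#'
#' @param reads Locus read-model tibble. Reads using splice junctions that
#'   are not partition boundaries must be removed beforehand (see
#'   [assemble_locus()]).
#' @param partition An `eg_partition` from [build_partition()].
#' @param min_overhang Minimum aligned overlap (nt) for frag membership.
#' @param n_samples Number of samples in the experiment (sample indices
#'   `0..n_samples-1`).
#' @return List of class `eg_membership`: `M` (elements x columns matrix
#'   of -1/0/+1, columns = frags then S+, E+, S-, E-), `weight`, `bases`,
#'   `length`, `n_reads`, `strand` per element, `sample_bases` (elements x
#'   samples matrix), and the `partition`.
#' @export
build_membership <- function(reads, partition, min_overhang = 3L,
                             n_samples = max(reads$sample, 0L) + 1L) {
  fr <- partition$frags
  nf <- partition$n_frags
  ncol_total <- nf + 4L
  cl <- partition$clusters
  n <- nrow(reads)
  M <- matrix(0L, nrow = n, ncol = ncol_total)
  bases <- double(n)
  fs <- fr$start; fe <- fr$end; fl <- fe - fs
  iSp <- partition$vS_plus; iEp <- partition$vE_plus
  iSm <- partition$vS_minus; iEm <- partition$vE_minus

  find_cluster <- function(pos, strand, kind) {
    hit <- which(cl$strand == strand & cl$kind == kind &
                   cl$lo <= pos & cl$hi >= pos)
    if (length(hit)) hit[1] else NA_integer_
  }

  r_blocks <- reads$blocks; r_junctions <- reads$junctions
  r_strand <- reads$strand; r_ll <- reads$left_label; r_rl <- reads$right_label
  r_start <- reads$start; r_end <- reads$end

  for (i in seq_len(n)) {
    m <- integer(ncol_total)
    b <- r_blocks[[i]]
    j <- r_junctions[[i]]
    ov <- double(nf)
    for (k in seq_len(nrow(b))) {
      ov <- ov + pmax(0L, pmin(fe, b[k, 2]) - pmax(fs, b[k, 1]))
    }
    member <- ov > 0 & (ov >= min_overhang | ov == fl)
    m[seq_len(nf)][member] <- 1L
    # spliced-out introns exclude their interior frags
    if (length(j)) for (k in which(j == "SPLICE")) {
      inside <- fs >= b[k, 2] & fe <= b[k + 1L, 1]
      m[seq_len(nf)][inside & !member] <- -1L
    }
    s <- r_strand[i]
    if (s == "+") { m[iSm] <- -1L; m[iEm] <- -1L }
    if (s == "-") { m[iSp] <- -1L; m[iEp] <- -1L }
    ll <- r_ll[i]; rl <- r_rl[i]
    if (ll %in% c("S", "C")) { # + strand TSS at read start
      ci <- find_cluster(r_start[i], "+", "TSS")
      if (!is.na(ci)) {
        m[iSp] <- 1L
        m[seq_len(nf)][fe <= cl$lo[ci] & !member] <- -1L
      }
    } else if (ll == "E") { # - strand PAS at read start
      ci <- find_cluster(r_start[i], "-", "PAS")
      if (!is.na(ci)) {
        m[iEm] <- 1L
        m[seq_len(nf)][fe <= cl$lo[ci] & !member] <- -1L
      }
    }
    if (rl == "E") { # + strand PAS at read end
      ci <- find_cluster(r_end[i], "+", "PAS")
      if (!is.na(ci)) {
        m[iEp] <- 1L
        m[seq_len(nf)][fs >= cl$hi[ci] & !member] <- -1L
      }
    } else if (rl %in% c("S", "C")) { # - strand TSS at read end
      ci <- find_cluster(r_end[i], "-", "TSS")
      if (!is.na(ci)) {
        m[iSm] <- 1L
        m[seq_len(nf)][fs >= cl$hi[ci] & !member] <- -1L
      }
    }
    M[i, ] <- m
    bases[i] <- sum(ov[member])
  }

  keep <- rowSums(M[, seq_len(nf), drop = FALSE] == 1L) > 0L
  M <- M[keep, , drop = FALSE]
  reads <- reads[keep, ]
  bases <- bases[keep]

  key <- paste(reads$strand, apply(M, 1L, paste, collapse = ""))
  grp <- match(key, unique(key))
  ng <- max(grp, 0L)
  Mg <- matrix(0L, nrow = ng, ncol = ncol_total)
  sample_bases <- matrix(0, nrow = ng, ncol = n_samples)
  g_bases <- double(ng); g_reads <- integer(ng); g_strand <- character(ng)
  g_weight <- double(ng)
  for (g in seq_len(ng)) {
    rows <- which(grp == g)
    Mg[g, ] <- M[rows[1], ]
    g_strand[g] <- reads$strand[rows[1]]
    g_bases[g] <- sum(bases[rows] * reads$weight[rows])
    g_reads[g] <- length(rows)
    for (r in rows) {
      sidx <- reads$sample[r] + 1L
      sample_bases[g, sidx] <- sample_bases[g, sidx] + bases[r] * reads$weight[r]
    }
  }
  g_length <- as.double(
    (Mg[, seq_len(nf), drop = FALSE] == 1L) %*% fl)
  g_weight <- ifelse(g_length > 0, g_bases / g_length, 0)
  structure(list(M = Mg, weight = g_weight, bases = g_bases,
                 length = g_length, n_reads = g_reads, strand = g_strand,
                 sample_bases = sample_bases, partition = partition),
            class = "eg_membership")
}

#' @export
print.eg_membership <- function(x, ...) {
  cat("<eg_membership> ", nrow(x$M), " elements x ", ncol(x$M),
      " columns (", x$partition$n_frags, " frags + 4 virtual)\n", sep = "")
  invisible(x)
}

# extended column order used for run/extension logic: transcripts flow
# genomically left to right on both strands, so the source-side virtuals
# (S+ and E-) sit leftmost and the sink-side virtuals (E+ and S-) rightmost.
extended_order <- function(partition) {
  nf <- partition$n_frags
  c(partition$vS_plus, partition$vE_minus, seq_len(nf),
    partition$vE_plus, partition$vS_minus)
}

#' Pairwise overlap codes between two membership rows
#'
#' Compares two elements column by column (in extended order, with
#' source-side virtual frags leftmost): any `+1` vs `-1` disagreement
#' makes the pair mutually exclusive; sharing no `+1` column means no
#' overlap; otherwise the `+1` support ranges decide extension and
#' containment. Codes: `1` = extends, `-1` = excludes, `2` = is contained
#' by, `0` = does not overlap.
#'
#' @param mi,mj Membership vectors in extended column order.
#' @param strand_i,strand_j Element strands (`+`/`-`/`.`); opposite
#'   stranded elements always exclude each other.
#' @return Integer vector `c(O_ij, O_ji)`.
#' @export
overlap_codes <- function(mi, mj, strand_i = ".", strand_j = ".") {
  if (strand_i != "." && strand_j != "." && strand_i != strand_j)
    return(c(-1L, -1L))
  if (any(mi * mj == -1L)) return(c(-1L, -1L))
  shared <- mi == 1L & mj == 1L
  if (!any(shared)) return(c(0L, 0L))
  wi <- which(mi == 1L); wj <- which(mj == 1L)
  i_sub <- all(wi %in% wj); j_sub <- all(wj %in% wi)
  if (i_sub && j_sub) return(c(2L, 2L)) # identical support
  if (i_sub) return(c(2L, 1L))          # i contained by j, j extends i
  if (j_sub) return(c(1L, 2L))
  c(1L, 1L) # staggered: each extends the other on one side
}

#' Full overlap matrix for a membership set
#'
#' Vectorized equivalent of applying [overlap_codes()] to every element
#' pair.
#'
#' @param mem An `eg_membership`.
#' @return Integer matrix `O` with `O[i, j]` the code of element `i`
#'   relative to `j`.
#' @export
overlap_matrix <- function(mem) {
  ne <- nrow(mem$M)
  O <- matrix(0L, ne, ne)
  if (ne < 2L) return(O)
  P <- mem$M == 1L
  N <- mem$M == -1L
  storage.mode(P) <- "double"; storage.mode(N) <- "double"
  PN <- P %*% t(N)               # i's support hits j's exclusions
  conflict <- PN > 0 | t(PN) > 0
  sconf <- outer(mem$strand, mem$strand,
                 function(a, b) a != "." & b != "." & a != b)
  conflict <- conflict | sconf
  PP <- P %*% t(P)               # shared support counts
  np <- rowSums(P)
  i_sub <- PP == np              # [i, j]: support(i) subset of support(j)
  shared <- PP > 0
  both <- i_sub & t(i_sub)
  code <- matrix(0L, ne, ne)
  code[shared & !conflict] <- 1L              # provisional: extends
  code[shared & !conflict & i_sub] <- 2L      # contained by
  code[shared & !conflict & both] <- 2L       # identical support: mutual
  code[conflict] <- -1L
  diag(code) <- 0L
  code
}
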