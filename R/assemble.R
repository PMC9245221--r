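# Transcript model construction, filtering and end-to-end assembly.

empty_models <- function() {
  tibble::tibble(
    chrom = integer(), strand = character(), start = integer(),
    end = integer(), exons = list(), n_exons = integer(),
    length = integer(), complete = logical(), has_source = logical(),
    has_sink = logical(), capped = logical(), coverage = double(),
    bases = double(), share = double(), tss_summit = integer(),
    pas_summit = integer(), n_samples_support = integer(),
    sample_cov = list())
}

# distinct paths can resolve to the same transcript structure (e.g. after
# element absorption); pool them into one model
dedupe_models <- function(models) {
  if (nrow(models) < 2L) return(models)
  key <- paste(models$strand, vapply(models$exons, function(e)
    paste(as.vector(e), collapse = ","), character(1)))
  grp <- match(key, unique(key))
  out <- list()
  for (gk in seq_len(max(grp))) {
    rows <- models[grp == gk, ]
    r <- rows[which.max(rows$complete * 2 + rows$coverage), ]
    r$coverage <- sum(rows$coverage)
    r$bases <- sum(rows$bases)
    r$share <- sum(rows$share)
    r$sample_cov <- list(Reduce(`+`, rows$sample_cov))
    r$n_samples_support <- sum(r$sample_cov[[1]] > 0)
    out[[gk]] <- r
  }
  dplyr::bind_rows(out)
}

# convert greedy paths to transcript model rows (one locus)
paths_to_models <- function(paths, g, chrom, locus_bases) {
  p <- g$mem$partition
  nf <- p$n_frags
  fs <- p$frags$start; fe <- p$frags$end
  cl <- p$clusters
  out <- list()
  for (path in paths) {
    if (path$strand == ".") next # unstranded leftovers are not reported
    memb <- g$mem$M[path$elements, seq_len(nf), drop = FALSE]
    pm <- apply(memb, 2L, function(col) {
      if (any(col == 1L)) 1L else if (any(col == -1L)) -1L else 0L
    })
    ones <- which(pm == 1L)
    if (!length(ones)) next
    lo <- ones[1]; hi <- ones[length(ones)]
    exonic <- pm[lo:hi] >= 0L # unknown interior gaps are filled as exonic
    idx <- (lo:hi)[exonic]
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    exons <- do.call(rbind, lapply(runs, function(r)
      c(fs[r[1]], fe[r[length(r)]])))
    colnames(exons) <- c("start", "end")
    len <- sum(exons[, 2] - exons[, 1])
    tss <- pas <- NA_integer_
    capped <- FALSE
    if (path$strand == "+") {
      if (path$has_source) {
        tss <- exons[1L, 1L]
        hit <- which(cl$kind == "TSS" & cl$strand == "+" & cl$summit == tss)
        capped <- length(hit) > 0 && any(cl$capped[hit])
      }
      if (path$has_sink) pas <- exons[nrow(exons), 2L]
    } else {
      if (path$has_source) pas <- exons[1L, 1L]
      if (path$has_sink) {
        tss <- exons[nrow(exons), 2L]
        hit <- which(cl$kind == "TSS" & cl$strand == "-" & cl$summit == tss)
        capped <- length(hit) > 0 && any(cl$capped[hit])
      }
    }
    w <- path$weight
    n_ex <- nrow(exons)
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = chrom, strand = path$strand,
      start = exons[1L, 1L], end = exons[n_ex, 2L],
      exons = list(exons), n_exons = n_ex, length = len,
      complete = path$complete, has_source = path$has_source,
      has_sink = path$has_sink, capped = capped,
      coverage = w, bases = w * len,
      share = if (locus_bases > 0) w * len / locus_bases else 0,
      tss_summit = tss, pas_summit = pas,
      n_samples_support = sum(path$sample_cov > 0),
      sample_cov = list(path$sample_cov))
  }
  if (!length(out)) return(empty_models())
  dplyr::bind_rows(out)
}

#' Filter assembled paths into reported transcript models
#'
#' Drops models below the coverage (`min_cov`), length (`min_len`) and
#' locus-share (`min_proportion`) floors; incomplete models (missing a
#' Start- or End-Tag anchor) are dropped when `discard_incomplete`, and
#' `require_cap` additionally restricts complete models to capped TSS
#' clusters.
#'
#' @param models Model tibble from assembly.
#' @param params An [endguide_params()].
#' @return The filtered tibble.
#' @export
filter_paths <- function(models, params = endguide_params()) {
  keep <- models$coverage >= params$min_cov &
    models$length >= params$min_len &
    models$share >= params$min_proportion
  if (params$discard_incomplete) keep <- keep & models$complete
  if (params$require_cap) keep <- keep & (!models$complete | models$capped)
  models[keep, ]
}

#' Assemble one locus
#'
#' The full per-locus pipeline: Start/Cap/End Tag extraction and
#' clustering, coverage filtering of splice junctions, frag partition,
#' Membership Matrix condensation, optional linear-chain collapse, overlap
#' graph with containment resolution, greedy path extraction and path
#' filtering.
#'
#' @param reads Read-model tibble of one locus (single chromosome).
#' @param params An [endguide_params()].
#' @param junction_whitelist Optional junction tibble always retained
#'   (e.g. from [merge_junctions()]).
#' @param n_samples Number of samples (defaults to max index + 1).
#' @return A transcript-model tibble (possibly empty) with the locus
#'   totals in attributes `locus_bases` and `locus_span`.
#' @export
assemble_locus <- function(reads, params = endguide_params(),
                           junction_whitelist = NULL,
                           n_samples = max(reads$sample, 0L) + 1L) {
  if (!nrow(reads)) return(empty_models())
  chrom <- reads$chrom[1]
  span <- c(min(reads$start), max(reads$end))
  tags <- extract_tags(reads)
  clusters <- cluster_tags(tags, distance = params$cluster_distance,
                           threshold_fraction = params$end_cluster_prop,
                           cap_bonus = params$cap_bonus,
                           cap_filter = params$cap_filter,
                           coverage_at = coverage_lookup(reads))
  junctions <- filter_locus_junctions(reads, min_overhang = params$min_overhang,
                                      threshold_fraction = params$min_proportion,
                                      whitelist = junction_whitelist)
  # reads whose splice junctions did not survive filtering are unusable:
  # their introns have no boundary in the partition
  jkey <- paste(junctions$donor, junctions$acceptor)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    j <- reads$junctions[[i]]
    if (!length(j) || !any(j == "SPLICE")) return(TRUE)
    b <- reads$blocks[[i]]
    all(paste(b[which(j == "SPLICE"), 2],
              b[which(j == "SPLICE") + 1L, 1]) %in% jkey)
  }, logical(1))
  reads <- reads[ok, ]
  if (!nrow(reads)) return(empty_models())
  partition <- build_partition(clusters, junctions, span)
  mem <- build_membership(reads, partition, min_overhang = params$min_overhang,
                          n_samples = n_samples)
  if (!nrow(mem$M)) return(empty_models())
  locus_bases <- sum(mem$bases)
  if (params$collapse) mem <- collapse_linear_chains(mem)
  g <- build_overlap_graph(mem)
  g <- resolve_containment(g)
  paths <- greedy_paths(g, end_fraction = params$min_proportion)
  models <- paths_to_models(paths, g, chrom, locus_bases)
  models <- dedupe_models(models)
  models <- filter_paths(models, params)
  attr(models, "locus_bases") <- locus_bases
  attr(models, "locus_span") <- span
  models
}

#' Assemble a whole read set
#'
#' Sorts the reads, splits them into loci (see [chunk_reads()]) and runs
#' [assemble_locus()] on each, assigning deterministic transcript and gene
#' identifiers in genomic order.
#'
#' @param reads Read-model tibble (any order).
#' @param header An [elr_header()].
#' @param params An [endguide_params()].
#' @param junctions Optional junction tibble with a `chrom` column of
#'   chromosome names, used as a per-locus whitelist.
#' @return An object of class `eg_assembly`: list with `models` (tibble,
#'   one row per transcript with `gene_id`/`transcript_id`), `header`,
#'   `params`, `n_loci`.
#' @export
#' @examples
#' sim <- simulate_locus(n_isoforms = 2, seed = 1)
#' rd <- simulate_reads(sim, n = 300, seed = 2)
#' fit <- assemble(rd$reads, rd$header)
#' tidy(fit)
assemble <- function(reads, header, params = endguide_params(),
                     junctions = NULL) {
  reads <- sort_read_models(reads)
  n_samples <- nrow(header$samples)
  loci <- chunk_reads(reads, max_gap = params$max_gap)
  all_models <- list()
  for (li in seq_along(loci)) {
    lr <- loci[[li]]
    chrom_name <- header$chroms$name[lr$chrom[1] + 1L]
    wl <- NULL
    if (!is.null(junctions) && nrow(junctions))
      wl <- junctions[junctions$chrom == chrom_name, ]
    m <- assemble_locus(lr, params, junction_whitelist = wl,
                        n_samples = n_samples)
    if (nrow(m)) {
      m$gene_id <- sprintf("EG.%s.%d", chrom_name, li)
      m <- dplyr::arrange(m, .data$start, .data$end)
      m$transcript_id <- sprintf("%s.%d", m$gene_id, seq_len(nrow(m)))
      all_models[[length(all_models) + 1L]] <- m
    }
  }
  models <- if (length(all_models)) dplyr::bind_rows(all_models) else {
    m <- empty_models(); m$gene_id <- character(); m$transcript_id <- character(); m
  }
  structure(list(models = models, header = header, params = params,
                 n_loci = length(loci)),
            class = "eg_assembly")
}

#' @export
print.eg_assembly <- function(x, ...) {
  cat("<eg_assembly> ", nrow(x$models), " transcript model(s) in ",
      x$n_loci, " locus/loci; ", sum(x$models$complete),
      " complete\n", sep = "")
  invisible(x)
}

#' Condense a read set into weighted pseudo-reads
#'
#' First-pass assembly that keeps incomplete paths and re-encodes every
#' path as a weighted end-labeled read: end labels are attached only where
#' the path actually reached the Start/End virtual frags, so partial
#' evidence stays partial. Pooling condensed outputs from many sparse
#' samples (e.g. single cells) and assembling them again is the
#' meta-assembly strategy.
#'
#' @param reads Read-model tibble of one sample.
#' @param header An [elr_header()].
#' @param params An [endguide_params()]; `discard_incomplete` is forced
#'   off and `min_cov` floors at 1.
#' @param sample Sample index to stamp on the condensed reads.
#' @return A read-model tibble of condensed pseudo-reads.
#' @export
condense <- function(reads, header, params = endguide_params(),
                     sample = 0L) {
  params$discard_incomplete <- FALSE
  params$min_cov <- min(params$min_cov, 1)
  fit <- assemble(reads, header, params)
  m <- fit$models
  if (!nrow(m)) return(read_models())
  ll <- character(nrow(m)); rl <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$strand[i] == "+") {
      ll[i] <- if (m$has_source[i]) (if (m$capped[i]) "C" else "S") else "."
      rl[i] <- if (m$has_sink[i]) "E" else "."
    } else {
      ll[i] <- if (m$has_source[i]) "E" else "."
      rl[i] <- if (m$has_sink[i]) (if (m$capped[i]) "C" else "S") else "."
    }
  }
  sort_read_models(read_models(
    chrom = m$chrom, blocks = m$exons,
    junctions = lapply(m$n_exons, function(k) rep("SPLICE", k - 1L)),
    strand = m$strand, left_label = ll, right_label = rl,
    weight = m$coverage, sample = sample))
}
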