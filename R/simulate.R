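# Ground-truth locus and read simulator. Every stage of the pipeline is
# testable against the truth tables this module emits; no external data
# is required anywhere in the package.

rand_dna <- function(n, p_a = 0.25) {
  probs <- c(A = p_a, C = (1 - p_a) / 3, G = (1 - p_a) / 3, T = (1 - p_a) / 3)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# break genomic motifs that would be indistinguishable from real end
# labels at the read level (adapter 3' ends, long A/T homopolymers), so
# the simulated truth table stays well defined: a read is labeled iff an
# adapter was attached, never because the template imitates one
mask_label_motifs <- function(s) {
  pat <- "GTACGGG|CCCGTAC|TTTTTTTT|AAAAAAAA"
  repeat {
    m <- regexpr(pat, s)
    if (m == -1L) break
    mid <- m + 3L
    cur <- substr(s, mid, mid)
    substr(s, mid, mid) <- c(A = "C", C = "A", G = "C", T = "G")[cur]
  }
  s
}

# one gene scaffold + isoform set, coordinates absolute on the chromosome
simulate_gene <- function(gene_start, n_isoforms, strand = "+",
                          variations = NULL, n_exons = NULL) {
  n_ex <- n_exons %||% sample(4:7, 1)
  exon_len <- sample(110:240, n_ex, replace = TRUE)
  intron_len <- sample(80:250, max(n_ex - 1L, 0L), replace = TRUE)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- gene_start
  for (k in seq_len(n_ex)) {
    starts[k] <- pos; ends[k] <- pos + exon_len[k]
    pos <- ends[k] + if (k < n_ex) intron_len[k] else 0L
  }
  scaffold <- cbind(start = starts, end = ends)

  pool <- c("full", "skip", "alt_tss", "alt_tss_internal", "alt_pas")
  sigs <- character(); isoforms <- list()
  tries <- 0L
  while (length(isoforms) < n_isoforms && tries < 200L) {
    tries <- tries + 1L
    v <- if (!is.null(variations)) variations[length(isoforms) + 1L] else {
      if (length(isoforms) == 0L) "full" else sample(pool[-1], 1)
    }
    first <- 1L; last <- n_ex; skipped <- integer(); tss_off <- 0L
    if (v == "skip" && n_ex >= 3L) skipped <- sample(2:(n_ex - 1L), 1)
    if (v == "alt_tss" && n_ex >= 3L) first <- sample(2:(n_ex - 1L), 1)
    if (v == "alt_tss_internal") tss_off <- exon_len[first] %/% 2L
    if (v == "alt_pas" && n_ex >= 3L) last <- sample(2:(n_ex - 1L), 1)
    keep <- setdiff(first:last, skipped)
    if (length(keep) < 1L) next
    ex <- scaffold[keep, , drop = FALSE]
    ex[1L, 1L] <- ex[1L, 1L] + tss_off
    sig <- paste(v, paste(as.vector(ex), collapse = ","))
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    isoforms[[length(isoforms) + 1L]] <- list(exons = ex, variation = v)
  }
  iso <- tibble::tibble(
    exons = lapply(isoforms, `[[`, "exons"),
    variation = vapply(isoforms, `[[`, character(1), "variation"),
    strand = strand
  )
  # transcript sense ends: on + the TSS is the genomic left edge
  iso$tss <- vapply(seq_len(nrow(iso)), function(i) {
    e <- iso$exons[[i]]
    if (strand == "+") e[1L, 1L] else e[nrow(e), 2L]
  }, integer(1))
  iso$pas <- vapply(seq_len(nrow(iso)), function(i) {
    e <- iso$exons[[i]]
    if (strand == "+") e[nrow(e), 2L] else e[1L, 1L]
  }, integer(1))
  iso$length <- vapply(iso$exons, function(e) sum(e[, 2] - e[, 1]), integer(1))
  list(scaffold = scaffold, isoforms = iso, strand = strand,
       span = c(gene_start, max(ends)))
}

#' Simulate a ground-truth locus
#'
#' Builds one or more genes with a shared splice scaffold and isoform
#' variations (exon skipping, alternative TSS -- at an exon start or
#' internal -- and alternative PAS), assigns per-isoform coverages of
#' 10--60x with per-sample log-normal variation, and generates the genomic
#' sequence with canonical GT..AG splice motifs. Downstream of every true
#' PAS the sequence is kept A-poor so genuine ends never look misprimed;
#' `a_rich_tract` plants an internal A-rich tract (a mispriming magnet)
#' into the first gene.
#'
#' @param n_isoforms Isoforms for the (first) gene.
#' @param seed RNG seed; all structure and sequence derive from it.
#' @param strand Strand of the first gene.
#' @param layout `"single"`, `"tandem"` (two genes, same strand, 300 nt
#'   apart) or `"antisense"` (second gene on the opposite strand
#'   downstream).
#' @param variations Optional character vector forcing the isoform
#'   variation types (`"full"`, `"skip"`, `"alt_tss"`,
#'   `"alt_tss_internal"`, `"alt_pas"`).
#' @param a_rich_tract Plant a 25 nt A-rich tract inside an internal exon.
#' @param n_samples Number of samples the coverage model spans.
#' @param chrom_name Chromosome name.
#' @return List of class `eg_sim`: `genome`, `header`, `genes`,
#'   `isoforms` (flat tibble with `gene`, `iso`, `exons`, `tss`, `pas`,
#'   `cov` matrix column), `span`, `a_tract` (genomic interval or NULL).
#' @export
simulate_locus <- function(n_isoforms = 2L, seed = 1L, strand = "+",
                           layout = c("single", "tandem", "antisense"),
                           variations = NULL, a_rich_tract = FALSE,
                           n_samples = 3L, chrom_name = "chr1") {
  layout <- match.arg(layout)
  set.seed(seed)
  pad <- 600L
  genes <- list(simulate_gene(pad, n_isoforms, strand, variations))
  if (layout %in% c("tandem", "antisense")) {
    s2 <- if (layout == "tandem") strand else (if (strand == "+") "-" else "+")
    g2_start <- genes[[1]]$span[2] + 300L
    genes[[2]] <- simulate_gene(g2_start, max(1L, n_isoforms - 1L), s2)
  }
  span_end <- max(vapply(genes, function(g) g$span[2], integer(1))) + pad
  seq_chr <- mask_label_motifs(rand_dna(span_end))

  put <- function(s, pos0, what) { # overwrite at 0-based pos
    paste0(substr(s, 1L, pos0), what,
           substr(s, pos0 + nchar(what) + 1L, nchar(s)))
  }
  for (g in genes) {
    sc <- g$scaffold
    if (nrow(sc) > 1L) for (k in seq_len(nrow(sc) - 1L)) {
      is0 <- sc[k, 2]; ie0 <- sc[k + 1L, 1]
      if (g$strand == "+") {
        seq_chr <- put(seq_chr, is0, "GT")
        seq_chr <- put(seq_chr, ie0 - 2L, "AG")
      } else {
        seq_chr <- put(seq_chr, is0, "CT")
        seq_chr <- put(seq_chr, ie0 - 2L, "AC")
      }
    }
    # keep 20 nt downstream of each PAS A-poor (transcript sense)
    for (i in seq_len(nrow(g$isoforms))) {
      p <- g$isoforms$pas[i]
      if (g$strand == "+") {
        seq_chr <- put(seq_chr, p, gsub("A", "C", rand_dna(20L)))
      } else {
        seq_chr <- put(seq_chr, max(0L, p - 20L), gsub("T", "G", rand_dna(20L)))
      }
    }
  }
  a_tract <- NULL
  if (a_rich_tract) {
    g <- genes[[1]]
    mid_ex <- g$scaffold[ceiling(nrow(g$scaffold) / 2), ]
    tpos <- mid_ex[1] + (mid_ex[2] - mid_ex[1]) %/% 2L
    tract <- if (g$strand == "+") strrep("A", 25L) else strrep("T", 25L)
    seq_chr <- put(seq_chr, tpos, tract)
    a_tract <- c(tpos, tpos + 25L)
  }

  iso_rows <- list()
  for (gi in seq_along(genes)) {
    it <- genes[[gi]]$isoforms
    it$gene <- gi
    it$iso <- seq_len(nrow(it))
    iso_rows[[gi]] <- it
  }
  isoforms <- dplyr::bind_rows(iso_rows)
  base_cov <- stats::runif(nrow(isoforms), 10, 60)
  fac <- matrix(stats::rlnorm(nrow(isoforms) * n_samples, 0, 0.4),
                nrow(isoforms), n_samples)
  fac <- fac / rowMeans(fac)
  cov <- base_cov * fac
  isoforms$cov <- lapply(seq_len(nrow(isoforms)), function(i) cov[i, ])
  header <- elr_header(tibble::tibble(name = chrom_name,
                                      length = nchar(seq_chr)),
                       samples = paste0("sample", seq_len(n_samples) - 1L))
  genome <- stats::setNames(seq_chr, chrom_name)
  structure(list(genome = genome, header = header, genes = genes,
                 isoforms = isoforms, span = c(0L, span_end),
                 layout = layout, a_tract = a_tract,
                 chrom_name = chrom_name, n_samples = n_samples),
            class = "eg_sim")
}

#' @export
print.eg_sim <- function(x, ...) {
  cat("<eg_sim> ", length(x$genes), " gene(s), ", nrow(x$isoforms),
      " isoform(s), ", nchar(x$genome[[1]]), " nt genome\n", sep = "")
  invisible(x)
}

# map a transcript-coordinate interval [a, b) onto genomic blocks
tx_to_blocks <- function(exons, strand, a, b) {
  lens <- exons[, 2] - exons[, 1]
  if (strand == "-") { exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
                       lens <- rev(lens) }
  offs <- cumsum(c(0L, lens))
  starts <- integer(); ends <- integer()
  for (k in seq_len(nrow(exons))) {
    lo <- max(a, offs[k]); hi <- min(b, offs[k + 1L])
    if (lo < hi) {
      if (strand == "+") {
        gs <- exons[k, 1] + (lo - offs[k]); ge <- gs + (hi - lo)
      } else {
        ge <- exons[k, 2] - (lo - offs[k]); gs <- ge - (hi - lo)
      }
      starts <- c(starts, gs); ends <- c(ends, ge)
    }
  }
  o <- order(starts)
  cbind(start = starts[o], end = ends[o])
}

end_jitter <- function(n) {
  sample(c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 3L), n, replace = TRUE)
}

#' Simulate reads from a ground-truth locus
#'
#' Draws reads isoform by isoform according to the simulated coverages.
#' `smartseq_like` fragments the transcript uniformly (clipped-normal
#' fragment length) and attaches 5'/3' labels at the configured rates,
#' with small downstream jitter at labeled ends (mode at the true
#' position); `fiveprime_only`/`threeprime_only` anchor every read at the
#' respective end; `longread` reads are full length and labeled at both
#' ends. Oligo-dT mispriming relocates a 3' end to the locus A-rich tract;
#' read-through reads (tandem layout) span both genes without labels.
#'
#' @param sim An `eg_sim`.
#' @param n Total read count; defaults to what the per-isoform coverages
#'   imply.
#' @param protocol Read protocol.
#' @param label_rate_5,label_rate_3 Label probabilities per read.
#' @param cap_rate Probability a 5'-labeled read carries an untemplated G
#'   (Cap Tag evidence).
#' @param error_rate Per-base substitution rate (FASTQ emission only).
#' @param mispriming_rate Probability a 3'-labeled read is an internal
#'   mispriming event (requires `a_rich_tract`).
#' @param readthrough_rate Probability a read comes from the read-through
#'   transcript (tandem layout only).
#' @param stranded Emit alignment strand for unlabeled reads.
#' @param seed RNG seed.
#' @param fraglen Fragment length mean, sd and clip range.
#' @param emit_fastq Also build FASTQ records with adapter sequences.
#' @return List with `reads` (read-model tibble), `header`, `truth`
#'   (per-read tibble: `gene`, `iso`, `labeled5`, `labeled3`, `capped`,
#'   `misprimed`, `readthrough`, `sample`), and `fastq` when requested.
#' @export
simulate_reads <- function(sim, n = NULL,
                           protocol = c("smartseq_like", "fiveprime_only",
                                        "threeprime_only", "longread"),
                           label_rate_5 = 0.1, label_rate_3 = 0.1,
                           cap_rate = 0.3, error_rate = 0,
                           mispriming_rate = 0, readthrough_rate = 0,
                           stranded = TRUE, seed = 1L,
                           fraglen = c(mean = 220, sd = 50, min = 90, max = 400),
                           emit_fastq = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(label_rate_5 <= 1, label_rate_3 <= 1, mispriming_rate <= 1)
  set.seed(seed)
  iso <- sim$isoforms
  ns <- sim$n_samples
  covm <- do.call(rbind, iso$cov)
  wt <- as.vector(covm * iso$length) # (iso x sample) flattened by column
  if (is.null(n)) n <- round(sum(wt) / fraglen["mean"])
  pick <- sample(length(wt), n, replace = TRUE, prob = wt)
  iso_i <- ((pick - 1L) %% nrow(iso)) + 1L
  sample_i <- ((pick - 1L) %/% nrow(iso))
  rt_possible <- sim$layout == "tandem" && length(sim$genes) == 2L
  rt <- rt_possible & (stats::runif(n) < readthrough_rate)

  rows <- vector("list", n)
  t_gene <- integer(n); t_iso <- integer(n)
  t_l5 <- logical(n); t_l3 <- logical(n); t_cap <- logical(n)
  t_misp <- logical(n); t_rt <- logical(n)
  fq <- list()
  rt_exons <- NULL
  if (sim$layout == "tandem" && length(sim$genes) == 2L) {
    e1 <- sim$genes[[1]]$isoforms$exons[[1]]
    e2 <- sim$genes[[2]]$isoforms$exons[[1]]
    # read-through pre-mRNA: both full isoforms with the intergenic
    # region retained as exonic sequence
    rt_exons <- rbind(e1[-nrow(e1), , drop = FALSE],
                      c(e1[nrow(e1), 1], e2[1L, 2L]),
                      e2[-1L, , drop = FALSE])
  }
  for (r in seq_len(n)) {
    if (rt[r] && !is.null(rt_exons)) {
      ex <- rt_exons; strand <- sim$genes[[1]]$strand
      L <- sum(ex[, 2] - ex[, 1])
      flen <- min(L, round(stats::rnorm(1, fraglen["mean"], fraglen["sd"])))
      flen <- max(min(flen, fraglen["max"]), fraglen["min"])
      a <- sample.int(max(L - flen, 0L) + 1L, 1) - 1L
      b <- a + flen
      blocks <- tx_to_blocks(ex, strand, a, b)
      rows[[r]] <- list(blocks = blocks, strand = if (stranded) strand else ".",
                        ll = ".", rl = ".", sample = sample_i[r])
      t_gene[r] <- NA_integer_; t_iso[r] <- NA_integer_; t_rt[r] <- TRUE
      next
    }
    i <- iso_i[r]
    ex <- iso$exons[[i]]; strand <- iso$strand[i]; L <- iso$length[i]
    l5 <- switch(protocol, smartseq_like = stats::runif(1) < label_rate_5,
                 fiveprime_only = TRUE, threeprime_only = FALSE,
                 longread = TRUE)
    l3 <- switch(protocol, smartseq_like = stats::runif(1) < label_rate_3,
                 fiveprime_only = FALSE, threeprime_only = TRUE,
                 longread = TRUE)
    flen <- if (protocol == "longread") L else {
      f <- round(stats::rnorm(1, fraglen["mean"], fraglen["sd"]))
      max(min(f, fraglen["max"], L), fraglen["min"])
    }
    if (protocol %in% c("fiveprime_only", "threeprime_only"))
      flen <- min(L, sample(60:140, 1))
    capped <- l5 && stats::runif(1) < cap_rate
    if (l5 && l3) flen <- L
    if (l5) {
      # capped (uuG) reads mark the exact cap site; uncapped 5' labels
      # arise partly from decay/recapping and carry downstream jitter
      a <- if (capped) 0L else min(end_jitter(1L), L - 1L)
      b <- if (l3) max(a + 1L, L - end_jitter(1L)) else min(L, a + flen)
    } else if (l3) {
      b <- max(1L, L - end_jitter(1L))
      a <- max(0L, b - flen)
    } else {
      a <- sample.int(max(L - flen, 0L) + 1L, 1) - 1L
      b <- min(L, a + flen)
    }
    misp <- FALSE
    if (l3 && mispriming_rate > 0 && !is.null(sim$a_tract) &&
        iso$gene[i] == 1L && stats::runif(1) < mispriming_rate) {
      # cleavage right where the A-rich tract begins (transcript sense)
      tb <- genomic_to_tx(ex, strand, sim$a_tract[1])
      if (!is.na(tb) && tb > 30L) { b <- tb; a <- max(0L, min(a, b - 30L)); misp <- TRUE }
    }
    blocks <- tx_to_blocks(ex, strand, a, b)
    ll <- "."; rl <- "."
    if (strand == "+") {
      if (l5) ll <- if (capped) "C" else "S"
      if (l3) rl <- "E"
    } else {
      if (l5) rl <- if (capped) "C" else "S"
      if (l3) ll <- "E"
    }
    rows[[r]] <- list(blocks = blocks,
                      strand = if (stranded || l5 || l3 || nrow(blocks) > 1L)
                        strand else ".",
                      ll = ll, rl = rl, sample = sample_i[r])
    t_gene[r] <- iso$gene[i]; t_iso[r] <- iso$iso[i]
    t_l5[r] <- l5; t_l3[r] <- l3; t_cap[r] <- capped; t_misp[r] <- misp
    if (emit_fastq)
      fq[[length(fq) + 1L]] <- fastq_record(sim, r, blocks, strand, l5, l3,
                                            capped, error_rate)
  }
  reads <- read_models(
    chrom = 0L, blocks = lapply(rows, `[[`, "blocks"),
    junctions = lapply(rows, function(x) rep("SPLICE", nrow(x$blocks) - 1L)),
    strand = vapply(rows, `[[`, character(1), "strand"),
    left_label = vapply(rows, `[[`, character(1), "ll"),
    right_label = vapply(rows, `[[`, character(1), "rl"),
    weight = 1, sample = vapply(rows, `[[`, integer(1), "sample"))
  truth <- tibble::tibble(gene = t_gene, iso = t_iso, labeled5 = t_l5,
                          labeled3 = t_l3, capped = t_cap, misprimed = t_misp,
                          readthrough = t_rt, sample = sample_i)
  # keep truth rows aligned with the sorted read order
  bs <- vapply(seq_len(nrow(reads)), function(i)
    format_blockstring(reads$blocks[[i]], reads$junctions[[i]],
                       reads$left_label[i], reads$right_label[i]),
    character(1))
  o <- order(reads$chrom, reads$start, bs, reads$sample, method = "radix")
  out <- list(reads = reads[o, ], header = sim$header, truth = truth[o, ])
  if (emit_fastq) out$fastq <- dplyr::bind_rows(fq)
  out
}

# transcript coordinate of a genomic position (NA when intronic/outside)
genomic_to_tx <- function(exons, strand, gpos) {
  lens <- exons[, 2] - exons[, 1]
  if (strand == "-") { exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
                       lens <- rev(lens) }
  offs <- cumsum(c(0L, lens))
  for (k in seq_len(nrow(exons))) {
    if (strand == "+" && gpos >= exons[k, 1] && gpos < exons[k, 2])
      return(as.integer(unname(offs[k] + (gpos - exons[k, 1]))))
    if (strand == "-" && gpos > exons[k, 1] && gpos <= exons[k, 2])
      return(as.integer(unname(offs[k] + (exons[k, 2] - gpos))))
  }
  NA_integer_
}

# spliced transcript-sense sequence of a block set
spliced_seq <- function(genome, chrom, blocks, strand) {
  s <- paste0(vapply(seq_len(nrow(blocks)), function(k)
    substr(genome[[chrom]], blocks[k, 1] + 1L, blocks[k, 2]), character(1)),
    collapse = "")
  if (strand == "-") rc_chr(s) else s
}

add_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
  paste(ch, collapse = "")
}

fastq_record <- function(sim, r, blocks, strand, l5, l3, capped, error_rate) {
  body <- spliced_seq(sim$genome, sim$chrom_name, blocks, strand)
  body <- add_errors(body, error_rate)
  name <- sprintf("read%d", r)
  if (l5) {
    uug <- if (capped) strrep("G", sample(1:3, 1)) else ""
    seq <- paste0(TSO_ADAPTER, uug, body)
    lab <- "5"
  } else if (l3) {
    # oligo-dT side: sequencing starts in the primer and reads antisense
    core <- sub("\\+$", "", OLIGODT_ADAPTER)
    seq <- paste0(core, rc_chr(body))
    lab <- "3"
  } else {
    seq <- body
    lab <- "none"
  }
  tibble::tibble(name = name, seq = seq, qual = strrep("I", nchar(seq)),
                 true_label = lab)
}

#' Canonical simulation fixtures
#'
#' A deterministic suite of named scenarios exercising the assembly
#' mechanisms: alternative TSS, alternative PAS, a tandem gene pair with
#' read-through (fusion risk), antisense overlap, a truncated isoform
#' with an internal TSS, and a 16-pseudo-cell dropout panel for
#' condense/meta-assembly.
#'
#' @param seed Root seed; every fixture derives its own seed from it.
#' @return Named list of fixtures; each carries `sim` plus scenario data.
#' @export
make_fixture_suite <- function(seed = 1L) {
  s <- function(k) as.integer((as.double(seed) * 131 + k) %% 2147483647)
  suite <- list()
  suite$alt_tss <- list(sim = simulate_locus(2L, seed = s(1L),
                                             variations = c("full", "alt_tss")))
  suite$alt_pas <- list(sim = simulate_locus(2L, seed = s(2L),
                                             variations = c("full", "alt_pas")))
  suite$tandem <- list(sim = simulate_locus(1L, seed = s(3L), layout = "tandem"))
  suite$antisense <- list(sim = simulate_locus(1L, seed = s(4L),
                                               layout = "antisense"))
  suite$truncated <- list(sim = simulate_locus(
    2L, seed = s(5L), variations = c("full", "alt_tss_internal")))
  # dropout panel: one 3-isoform gene observed across 16 sparse cells
  panel_sim <- simulate_locus(3L, seed = s(6L), n_samples = 16L)
  suite$dropout_panel <- list(sim = panel_sim)
  suite
}

#' Write a simulation's truth set as GTF
#'
#' @param sim An `eg_sim`.
#' @param path Output GTF file.
#' @return Number of transcripts written, invisibly.
#' @export
truth_to_gtf <- function(sim, path) {
  iso <- sim$isoforms
  lines <- character()
  for (i in seq_len(nrow(iso))) {
    gid <- sprintf("TRUE.g%d", iso$gene[i])
    tid <- sprintf("%s.i%d", gid, iso$iso[i])
    ex <- iso$exons[[i]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    lines <- c(lines, sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              sim$chrom_name, ex[1L, 1L] + 1L,
                              ex[nrow(ex), 2L], iso$strand[i], attrs))
    for (k in seq_len(nrow(ex)))
      lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                                sim$chrom_name, ex[k, 1L] + 1L, ex[k, 2L],
                                iso$strand[i], attrs))
  }
  writeLines(lines, path)
  invisible(nrow(iso))
}
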