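# Independent brute-force oracles and fixture builders. These deliberately
# re-derive the counting and statistics rules by literal enumeration, without
# touching the package's interval machinery.

# --- geometry ---------------------------------------------------------------

# CDS positions of a gene in transcription order, enumerated base by base
bf_cds_positions <- function(gene) {
  out <- integer(0)
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons[i, 1]; e <- gene$exons[i, 2]
    p <- if (gene$strand == "+") seq.int(s, e - 1L) else seq.int(e - 1L, s)
    out <- c(out, p)
  }
  out
}

# unmasked counting positions under the end-mask / last-exon rules
bf_region_positions <- function(gene, assay, mask_5p = 10L, mask_3p = 30L) {
  if (assay == "RF" && nrow(gene$introns) > 0L) {
    n <- nrow(gene$exons)
    last <- gene_model(gene$gene_id, gene$strand,
                       gene$exons[n, , drop = FALSE])
    pos <- bf_cds_positions(last)
    m5 <- if (n == 1L) mask_5p else 0L
  } else {
    pos <- bf_cds_positions(gene)
    m5 <- mask_5p
  }
  L <- length(pos)
  if (L - m5 - mask_3p <= 0L) return(integer(0))
  pos[seq.int(m5 + 1L, L - mask_3p)]
}

# random gene geometry, possibly multi-exon, minus strand, or origin-wrapping
random_gene <- function(genome_length = 5000L) {
  strand <- sample(c("+", "-"), 1L)
  wrap <- stats::runif(1) < 0.15
  if (wrap) {
    w1 <- sample(20:300, 1L); w2 <- sample(20:300, 1L)
    exons <- iv(c(genome_length - w1, 0L), c(genome_length, w2))
    if (strand == "-") exons <- exons[2:1, , drop = FALSE]
    return(gene_model("g", strand, exons, genome_length = genome_length,
                      wrap_join = TRUE))
  }
  n_ex <- sample(1:3, 1L)
  widths <- sample(15:400, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1L) sample(30:500, n_ex - 1L, replace = TRUE) else integer(0)
  start0 <- sample(0:1000, 1L)
  starts <- start0 + cumsum(c(0L, widths[-n_ex] + gaps))
  exons <- iv(starts, starts + widths)
  if (strand == "-") exons <- exons[rev(seq_len(n_ex)), , drop = FALSE]
  gene_model("g", strand, exons, genome_length = genome_length)
}

# mirror geometry: position p -> L - 1 - p, strand flipped
mirror_gene <- function(gene, L) {
  ex <- gene$exons
  mex <- iv(L - ex[, 2], L - ex[, 1])
  gene_model(gene$gene_id, if (gene$strand == "+") "-" else "+",
             mex, complex_label = gene$complex_label,
             transcription_unit_id = gene$transcription_unit_id,
             genome_length = L, wrap_join = gene$wrap_join)
}

mirror_blocks <- function(blocks, L) {
  m <- iv(L - blocks[, 2], L - blocks[, 1])
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

# --- counting ---------------------------------------------------------------

bf_block_positions <- function(blocks) {
  unlist(lapply(seq_len(nrow(blocks)), function(i)
    seq.int(blocks[i, 1], blocks[i, 2] - 1L)))
}

# literal per-(read, gene) application of the counting rules
bf_count_genes <- function(alignments, annotation, assay,
                           mask_5p = 10L, mask_3p = 30L,
                           junction_limit = 52L) {
  genes <- annotation$genes
  counts <- stats::setNames(integer(length(genes)), names(genes))
  pos_region <- lapply(genes, bf_region_positions, assay = assay,
                       mask_5p = mask_5p, mask_3p = mask_3p)
  pos_cds <- lapply(genes, bf_cds_positions)
  for (r in seq_len(nrow(alignments))) {
    bp <- bf_block_positions(alignments$blocks[[r]])
    overlapping <- character(0)
    for (gid in names(genes)) {
      if (genes[[gid]]$strand != alignments$strand[r]) next
      if (any(bp %in% pos_region[[gid]])) overlapping <- c(overlapping, gid)
    }
    if (length(overlapping) != 1L) next
    gid <- overlapping
    g <- genes[[gid]]
    masked <- setdiff(if (assay == "RF" && nrow(g$introns) > 0L)
      bf_cds_positions(gene_model(gid, g$strand,
                                  g$exons[nrow(g$exons), , drop = FALSE]))
      else pos_cds[[gid]],
      pos_region[[gid]])
    if (any(bp %in% masked)) next
    if (assay == "RNA" && nrow(g$introns) > 0L) {
      over <- 0L
      for (b in seq_len(nrow(alignments$blocks[[r]]))) {
        blk <- alignments$blocks[[r]][b, , drop = FALSE]
        p <- seq.int(blk[1], blk[2] - 1L)
        in_intron <- sum(p %in% bf_block_positions(g$introns))
        in_exon <- sum(p %in% pos_cds[[gid]])
        if (in_intron > 0L && in_exon > 0L) over <- over + in_intron
      }
      if (over > junction_limit) next
    }
    counts[gid] <- counts[gid] + 1L
  }
  counts
}

# random mini-annotation plus random reads for the counting oracle
random_alignment_set <- function(n_reads = 12L) {
  L <- 3000L
  genes <- list(
    gene_model("gA", "+", iv(100, 600), genome_length = L),
    gene_model("gB", "+", iv(c(700, 1100), c(760, 1500)), genome_length = L),
    gene_model("gC", "-", iv(1600, 2100), genome_length = L),
    gene_model("gD", "+", iv(2050, 2500), genome_length = L)
  )
  ann <- plastome_annotation(L, genes)
  blocks <- vector("list", n_reads)
  strand <- character(n_reads)
  for (i in seq_len(n_reads)) {
    strand[i] <- sample(c("+", "-"), 1L)
    s <- sample(0:(L - 160L), 1L)
    if (stats::runif(1) < 0.2) {  # spliced two-block read
      w1 <- sample(10:60, 1L); gap <- sample(20:400, 1L)
      w2 <- sample(10:60, 1L)
      blocks[[i]] <- iv(c(s, s + w1 + gap), c(s + w1, s + w1 + gap + w2))
    } else {
      w <- sample(20:120, 1L)
      blocks[[i]] <- iv(s, s + w)
    }
  }
  alns <- data.frame(read_id = sprintf("q%03d", seq_len(n_reads)),
                     ref = "plastome", strand = strand,
                     blocks = I(blocks), stringsAsFactors = FALSE)
  list(annotation = ann, alignments = alns)
}

# --- statistics -------------------------------------------------------------

# literal Benjamini-Hochberg step-up with monotonicity, preserving order
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in seq.int(m - 1L, 1L)) adj[i] <- min(adj[i], adj[i + 1L])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# ordinary one-sample t on each row, from first principles
bf_one_sample_t <- function(mat) {
  n <- ncol(mat)
  m <- rowMeans(mat)
  s2 <- rowSums((mat - m)^2) / (n - 1)
  list(t = m / sqrt(s2 / n), df = n - 1)
}

# expected measured-scale log2 fold change of the self-normalized array
# pipeline, from the injected truth alone; genes below the measurement floor
# on either channel (noiseless probe value = gain x expression) come out NA
# since the pipeline censors them
expected_measured_lfc <- function(truth, assay, floor = 100, gain = 1) {
  em <- truth[[paste0(if (assay == "RF") "to" else "rna", "_mutant")]] * gain
  ec <- truth[[paste0(if (assay == "RF") "to" else "rna", "_control")]] * gain
  mm <- em > floor; mc <- ec > floor
  rel_m <- log2(em) - mean(log2(em[mm]))
  rel_c <- log2(ec) - mean(log2(ec[mc]))
  lfc <- ifelse(mm & mc, rel_m - rel_c, NA_real_)
  stats::setNames(lfc, truth$gene_id)
}
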