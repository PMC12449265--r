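#' Gene model on a circular plastome
#'
#' Represents one protein-coding gene: its exons in transcription (5'->3')
#' order, strand, photosynthetic complex membership and transcription unit.
#' Coordinates are 0-based half-open on the plastome. Genes spanning the
#' circular origin are stored unwrapped as two intervals whose junction at the
#' origin is *not* an intron (`wrap_join`).
#'
#' @param gene_id unique gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open genomic intervals, in
#'   transcription order (for minus-strand genes that means descending genomic
#'   coordinates; for origin-wrapping plus-strand genes the interval touching
#'   the origin from the left comes first).
#' @param complex_label one of PSII, PSI, CytB6F, ATPase, NDH, Rubisco,
#'   ExpressionMachinery, Other.
#' @param transcription_unit_id identifier of the (poly)cistron the gene is
#'   transcribed in; genes sharing it are operon-coupled.
#' @param genome_length plastome length in nt; needed to tell the circular
#'   origin junction apart from a genuine intron.
#' @param wrap_join logical; `TRUE` when the gene wraps the origin.
#' @return an object of class `GeneModel` with elements `gene_id`, `strand`,
#'   `exons` (transcription order), `introns` (genomic intervals between
#'   consecutive exons, excluding the origin junction), `cds_length`,
#'   `complex_label`, `transcription_unit_id`, `wrap_join`.
#' @export
gene_model <- function(gene_id, strand, exons,
                       complex_label = "Other",
                       transcription_unit_id = gene_id,
                       genome_length = NULL,
                       wrap_join = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  complex_label <- match.arg(complex_label, COMPLEX_LABELS)
  exons <- iv(exons[, 1], exons[, 2])
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  # pairwise disjoint check (on genomic coordinates)
  red <- iv_reduce(exons)
  if (iv_length(red) != iv_length(exons))
    stop("gene ", gene_id, ": overlapping exons")
  if (iv_length(exons) < 3L)
    stop("gene ", gene_id, ": CDS shorter than 3 nt")

  introns <- intron_intervals(exons, strand, wrap_join, genome_length)
  structure(
    list(gene_id = gene_id, strand = strand, exons = exons,
         introns = introns, cds_length = iv_length(exons),
         complex_label = complex_label,
         transcription_unit_id = transcription_unit_id,
         wrap_join = isTRUE(wrap_join)),
    class = "GeneModel"
  )
}

COMPLEX_LABELS <- c("PSII", "PSI", "CytB6F", "ATPase", "NDH", "Rubisco",
                    "ExpressionMachinery", "Other")

# Genomic gaps between consecutive exons in transcription order; a junction
# that meets the circular origin (one exon ends at genome_length, the next
# starts at 0, in either order) is the unwrapped origin, not an intron.
intron_intervals <- function(exons, strand, wrap_join, genome_length) {
  n <- nrow(exons)
  if (n < 2L) return(iv_empty())
  gaps <- iv_empty()
  for (i in seq_len(n - 1L)) {
    a <- exons[i, ]; b <- exons[i + 1L, ]
    lo <- min(a[2], b[2]); hi <- max(a[1], b[1])
    if (isTRUE(wrap_join) && !is.null(genome_length)) {
      at_origin <- (a[2] == genome_length && b[1] == 0L) ||
        (b[2] == genome_length && a[1] == 0L)
      if (at_origin) next
    }
    if (hi > lo) gaps <- rbind(gaps, iv(lo, hi))
  }
  iv_reduce(gaps)
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %d exon(s), CDS %d nt, %s / TU %s%s\n",
              x$gene_id, x$strand, nrow(x$exons), x$cds_length,
              x$complex_label, x$transcription_unit_id,
              if (x$wrap_join) " [wraps origin]" else ""))
  invisible(x)
}

#' Plastome annotation
#'
#' The container every counting and probe-assignment step references: a
#' circular genome length, the gene models, and the fixed order of reference
#' tiers used by sequential read assignment (rRNA/tRNA contaminants first,
#' then chloroplast, mitochondrial and nuclear references).
#'
#' @param genome_length plastome length (nt).
#' @param genes list of [gene_model()] objects.
#' @param ref_name chloroplast reference (SAM `RNAME`) the genes live on.
#' @return object of class `PlastomeAnnotation`.
#' @export
plastome_annotation <- function(genome_length, genes, ref_name = "plastome") {
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  for (g in genes) {
    if (any(g$exons[, 2] > genome_length))
      stop("gene ", g$gene_id, ": exon beyond genome length")
  }
  structure(
    list(genome_length = as.integer(genome_length), genes = genes,
         ref_name = ref_name,
         tier_references = c("rRNA_tRNA", "chloroplast", "mitochondrial",
                             "nuclear")),
    class = "PlastomeAnnotation"
  )
}

#' @export
print.PlastomeAnnotation <- function(x, ...) {
  cat(sprintf("PlastomeAnnotation: %d genes on circular genome of %d nt (%s)\n",
              length(x$genes), x$genome_length, x$ref_name))
  invisible(x)
}

#' @export
gene_ids <- function(annotation) names(annotation$genes)

#' Load a plastome annotation from GFF3
#'
#' Reads `gene` + `CDS` features (multi-exon CDS allowed), converting 1-based
#' closed GFF coordinates to the package's 0-based half-open convention and
#' reordering minus-strand exon lists into transcription order. Optional
#' attributes `transcription_unit=` and `complex=` on the gene feature are
#' honoured (defaults: the gene's own id / `Other`).
#'
#' Circular-origin genes may be written with `end < start` (the circular
#' dialect of the synthetic generator); such features are unwrapped into two
#' intervals whose total length is preserved and whose junction at the origin
#' is not treated as an intron.
#'
#' @param path GFF3 file (a `##gff-version 3` directive is required; genome
#'   length is taken from `##sequence-region`).
#' @return a [plastome_annotation()].
#' @export
load_annotation <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^##gff-version\\s+3", lines)))
    stop("not a GFF3 file (missing ##gff-version 3 directive): ", path)

  genome_length <- NA_integer_
  ref_name <- "plastome"
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr)) {
    f <- strsplit(sr[1], "\\s+")[[1]]
    ref_name <- f[2]
    genome_length <- as.integer(f[4])
  }

  # Unwrap origin-spanning features (end < start) into two tagged parts so
  # that rtracklayer can parse the result.
  is_feat <- !startsWith(lines, "#") & nzchar(lines)
  out <- character(0)
  for (ln in lines) {
    if (!(!startsWith(ln, "#") && nzchar(ln))) { out <- c(out, ln); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) { out <- c(out, ln); next }
    s <- as.integer(f[4]); e <- as.integer(f[5])
    if (e < s) {
      if (is.na(genome_length))
        stop("origin-wrapping feature but no ##sequence-region directive")
      a <- f; a[4] <- f[4]; a[5] <- as.character(genome_length)
      b <- f; b[4] <- "1"; b[5] <- f[5]
      a[9] <- paste0(f[9], ";wrap_join=true")
      b[9] <- paste0(f[9], ";wrap_join=true")
      out <- c(out, paste(a, collapse = "\t"), paste(b, collapse = "\t"))
    } else out <- c(out, ln)
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(out, tmp)

  gr <- rtracklayer::import(tmp, format = "gff3")
  df <- as.data.frame(gr)
  if (is.na(genome_length)) genome_length <- max(df$end)

  gene_rows <- df[df$type == "gene", , drop = FALSE]
  # an origin-wrapping gene feature arrives as two unwrapped parts; the gene
  # row only carries identity/attributes, so keep one part
  gene_rows <- gene_rows[!duplicated(gene_rows$ID), , drop = FALSE]
  cds_rows <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds_rows)) {
    parent <- vapply(cds_rows$Parent, function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, "")
    cds_rows$parent_id <- parent
    orphans <- setdiff(unique(parent), c(gene_rows$ID, NA))
    if (length(orphans) || anyNA(parent))
      stop("CDS feature without parent gene: ",
           paste(stats::na.omit(c(orphans, if (anyNA(parent)) "<missing Parent>")),
                 collapse = ", "))
  }

  genes <- vector("list", nrow(gene_rows))
  for (i in seq_len(nrow(gene_rows))) {
    grow <- gene_rows[i, ]
    gid <- grow$ID
    parts <- cds_rows[cds_rows$parent_id == gid, , drop = FALSE]
    if (nrow(parts) == 0L) parts <- grow   # gene without CDS children: use span
    strand <- as.character(grow$strand)
    wrap <- "wrap_join" %in% names(df) &&
      any(!is.na(parts$wrap_join) & parts$wrap_join == "true")

    start0 <- parts$start - 1L   # to 0-based half-open
    end0 <- parts$end
    # transcription order via unwrapped coordinate: pieces starting at the
    # origin of a wrapped gene sit downstream of the piece touching the end.
    key <- start0 + ifelse(wrap & start0 == 0L, genome_length, 0L)
    ord <- order(key, decreasing = (strand == "-"))
    exons <- iv(start0[ord], end0[ord])

    tu <- if ("transcription_unit" %in% names(grow) &&
              !is.na(grow$transcription_unit)) grow$transcription_unit else gid
    cx <- if ("complex" %in% names(grow) && !is.na(grow$complex))
      grow$complex else "Other"
    genes[[i]] <- gene_model(gid, strand, exons, complex_label = cx,
                             transcription_unit_id = tu,
                             genome_length = genome_length, wrap_join = wrap)
  }
  plastome_annotation(genome_length, genes, ref_name = ref_name)
}

#' Assay-specific counting region of a gene
#'
#' Derives the CDS interval set over which reads (or probes) are counted.
#' Reads near the CDS ends derive from initiating and terminating ribosomes,
#' so the first `mask_5p` and last `mask_3p` nucleotides of the CDS — in
#' transcription order — are masked. For ribosome footprints (`assay = "RF"`)
#' on intron-containing genes only the last exon is counted (translation of
#' unspliced mRNA can terminate in introns, so upstream exons are not a clean
#' readout); the 3' mask still applies there, and the 5' mask applies only if
#' the last exon is also the first.
#'
#' @param gene a [gene_model()].
#' @param assay `"RF"` (ribosome footprints) or `"RNA"`.
#' @param mask_5p,mask_3p nt masked at the CDS 5'/3' ends (defaults 10 / 30).
#' @return an [interval_set()]; its `masks` attribute carries the masked end
#'   windows as a second `IntervalSet` (used by the counting rules). If the
#'   masks consume the whole region the set is empty and `flagged`.
#' @export
counting_region <- function(gene, assay = c("RF", "RNA"),
                            mask_5p = 10L, mask_3p = 30L) {
  assay <- match.arg(assay)
  exons <- gene$exons
  n <- nrow(exons)
  use_last_only <- assay == "RF" && nrow(gene$introns) > 0L
  if (use_last_only) {
    used <- exons[n, , drop = FALSE]
    m5 <- if (n == 1L) mask_5p else 0L  # last exon is also the first
  } else {
    used <- exons
    m5 <- mask_5p
  }
  widths <- used[, 2] - used[, 1]
  L <- sum(widths)
  lo <- as.integer(m5)
  hi <- as.integer(L - mask_3p)
  if (hi <= lo) {
    res <- interval_set(iv_empty(), flagged = TRUE)
    attr(res, "masks") <- interval_set(transcript_to_genomic(used, gene$strand, 0L, L))
    attr(res, "gene_id") <- gene$gene_id
    return(res)
  }
  region <- transcript_to_genomic(used, gene$strand, lo, hi)
  masks <- rbind(
    if (lo > 0L) transcript_to_genomic(used, gene$strand, 0L, lo) else iv_empty(),
    if (hi < L) transcript_to_genomic(used, gene$strand, hi, L) else iv_empty()
  )
  res <- interval_set(region)
  attr(res, "masks") <- interval_set(masks)
  attr(res, "gene_id") <- gene$gene_id
  res
}

# Map a transcript-coordinate window [lo, hi) back to genomic intervals, given
# exons in transcription order. For minus-strand exons transcription runs from
# the genomic end toward the start.
transcript_to_genomic <- function(exons, strand, lo, hi) {
  widths <- exons[, 2] - exons[, 1]
  cum <- c(0L, cumsum(widths))
  out <- iv_empty()
  for (i in seq_len(nrow(exons))) {
    a <- max(lo, cum[i]); b <- min(hi, cum[i + 1L])
    if (b <= a) next
    o1 <- a - cum[i]; o2 <- b - cum[i]
    if (strand == "+") {
      out <- rbind(out, iv(exons[i, 1] + o1, exons[i, 1] + o2))
    } else {
      out <- rbind(out, iv(exons[i, 2] - o2, exons[i, 2] - o1))
    }
  }
  iv_reduce(out)
}

#' Intronic overhang of an alignment over a gene
#'
#' Number of aligned nucleotides falling inside the gene's introns, summed
#' over contiguous (ungapped) alignment blocks that also cover exonic
#' sequence. Spliced alignments whose gap spans the intron — mature mRNA —
#' contribute 0, as do fully exonic or non-overlapping alignments. RNA-seq
#' reads with an overhang above the junction limit reflect unspliced
#' transcripts and are excluded from counting.
#'
#' @param blocks two-column matrix of 0-based half-open aligned blocks.
#' @param gene a [gene_model()].
#' @return integer overhang in nt.
#' @export
intron_overhang <- function(blocks, gene) {
  ins <- gene$introns; ex <- gene$exons
  if (nrow(ins) == 0L || nrow(blocks) == 0L) return(0L)
  total <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- blocks[i, 1]; e <- blocks[i, 2]
    inx <- sum(pmax(0L, pmin(e, ins[, 2]) - pmax(s, ins[, 1])))
    if (inx > 0L) {
      exx <- sum(pmax(0L, pmin(e, ex[, 2]) - pmax(s, ex[, 1])))
      if (exx > 0L) total <- total + inx
    }
  }
  as.integer(total)
}
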