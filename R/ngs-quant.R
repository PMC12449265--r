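#' Enforce the sequential tier-assignment contract
#'
#' Reads are aligned tier by tier (rRNA/tRNA contaminants, chloroplast,
#' mitochondrial, nuclear) and a read belongs to the *first* tier it aligned
#' in; its alignments in later tiers are discarded. This prevents
#' misassignment of contaminant reads to the chloroplast (and of genuine
#' chloroplast reads to organellar gene copies elsewhere). Only the
#' chloroplast survivors proceed to counting.
#'
#' @param tiers named list of alignment data.frames (or SAM/BAM paths, read
#'   via [read_tier_sam()]) in tier order; names must match
#'   `c("rRNA_tRNA", "chloroplast", "mitochondrial", "nuclear")`.
#' @return list with `assignment` (data.frame `read_id`, `tier`),
#'   `chloroplast` (surviving tier-2 alignments), and `summary` (reads
#'   assigned per tier).
#' @export
enforce_sequential <- function(tiers) {
  tier_order <- c("rRNA_tRNA", "chloroplast", "mitochondrial", "nuclear")
  if (!identical(names(tiers), tier_order))
    stop("tiers must be named, in order: ", paste(tier_order, collapse = ", "))
  tiers <- lapply(tiers, function(t)
    if (is.character(t)) read_tier_sam(t) else t)

  seen <- character(0)
  assignment <- list()
  survivors <- list()
  for (tn in tier_order) {
    al <- tiers[[tn]]
    ids <- unique(al$read_id)
    new <- setdiff(ids, seen)
    assignment[[tn]] <- if (length(new))
      data.frame(read_id = new, tier = tn, stringsAsFactors = FALSE)
    else NULL
    survivors[[tn]] <- al[al$read_id %in% new, , drop = FALSE]
    seen <- c(seen, new)
  }
  assignment <- do.call(rbind, assignment)
  rownames(assignment) <- NULL
  list(assignment = assignment,
       chloroplast = survivors$chloroplast,
       summary = vapply(survivors, function(s) length(unique(s$read_id)), 0L))
}

#' Count chloroplast reads per gene under the CDS rules
#'
#' A read counts for gene `g` iff: the strands match; the alignment overlaps
#' `g`'s counting region; it does *not* overlap the masked end windows
#' (initiating/terminating-ribosome zones — any overlap excludes, the
#' conservative reading); for RNA-seq on intron-containing genes its
#' intronic overhang is at most `junction_limit` (contiguous blocks running
#' deeper into an intron reflect unspliced mRNA); and it overlaps the
#' counting region of no other same-strand gene (ambiguous reads are
#' discarded, mirroring the usual uniquely-assigned counting default).
#'
#' @param alignments alignment data.frame (chloroplast survivors of
#'   [enforce_sequential()]).
#' @param annotation a [plastome_annotation()]; alignments to any other
#'   reference are rejected.
#' @param assay `"RF"` or `"RNA"`.
#' @param mask_5p,mask_3p CDS end masks (defaults 10 / 30 nt).
#' @param junction_limit maximum tolerated intronic overhang for RNA-seq
#'   (default 52 nt).
#' @return data.frame `gene_id`, `assay`, `count`, `counted_length`,
#'   `flagged` (`TRUE` when the end masks consumed the gene's region; such
#'   genes get `NA` counts and a warning).
#' @export
count_genes <- function(alignments, annotation, assay = c("RF", "RNA"),
                        mask_5p = 10L, mask_3p = 30L, junction_limit = 52L) {
  assay <- match.arg(assay)
  if (nrow(alignments) && !all(alignments$ref == annotation$ref_name))
    stop("alignment(s) to unknown reference: ",
         paste(setdiff(unique(alignments$ref), annotation$ref_name),
               collapse = ", "))

  genes <- annotation$genes
  ids <- names(genes)
  regs <- lapply(genes, counting_region, assay = assay,
                 mask_5p = mask_5p, mask_3p = mask_3p)
  flagged <- vapply(regs, `[[`, TRUE, "flagged")
  if (any(flagged))
    warning("counting region empty after masking for: ",
            paste(ids[flagged], collapse = ", "))

  counts <- stats::setNames(integer(length(ids)), ids)

  if (nrow(alignments)) {
    # flatten regions and read blocks into IRanges for one overlap pass
    reg_list <- lapply(regs, `[[`, "intervals")
    reg_n <- vapply(reg_list, nrow, 0L)
    reg_ir <- iv_to_ir(do.call(rbind, reg_list))
    reg_gene <- rep(seq_along(ids), reg_n)

    blk <- alignments$blocks
    blk_n <- vapply(blk, nrow, 0L)
    blk_all <- do.call(rbind, blk)
    blk_ir <- iv_to_ir(blk_all)
    blk_read <- rep(seq_len(nrow(alignments)), blk_n)

    hits <- IRanges::findOverlaps(blk_ir, reg_ir)
    pr <- blk_read[S4Vectors::queryHits(hits)]
    pg <- reg_gene[S4Vectors::subjectHits(hits)]
    same_strand <- alignments$strand[pr] ==
      vapply(genes, `[[`, "", "strand")[pg]
    pairs <- unique(data.frame(read = pr[same_strand],
                               gene = pg[same_strand]))

    if (nrow(pairs)) {
      multi <- unique(pairs$read[duplicated(pairs$read)])
      pairs <- pairs[!(pairs$read %in% multi), , drop = FALSE]
    }
    if (nrow(pairs)) {
      # vectorized exclusion of reads touching their gene's masked windows
      mask_list <- lapply(regs, function(r) attr(r, "masks")$intervals)
      mask_n <- vapply(mask_list, nrow, 0L)
      mask_ir <- iv_to_ir(do.call(rbind, mask_list))
      mask_gene <- rep(seq_along(ids), mask_n)
      mh <- IRanges::findOverlaps(blk_ir, mask_ir)
      masked <- unique(paste(blk_read[S4Vectors::queryHits(mh)],
                             mask_gene[S4Vectors::subjectHits(mh)]))
      pairs <- pairs[!(paste(pairs$read, pairs$gene) %in% masked),
                     , drop = FALSE]
    }
    has_intron <- vapply(genes, function(g) nrow(g$introns) > 0L, TRUE)
    for (k in seq_len(nrow(pairs))) {
      gi <- pairs$gene[k]
      if (assay == "RNA" && has_intron[gi] &&
          intron_overhang(blk[[pairs$read[k]]], genes[[gi]]) > junction_limit)
        next
      counts[gi] <- counts[gi] + 1L
    }
  }

  data.frame(gene_id = ids, assay = assay,
             count = ifelse(flagged, NA_integer_, counts),
             counted_length = vapply(regs, `[[`, 0, "total_length"),
             flagged = unname(flagged),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RPKM over the counted region
#'
#' Reads per kilobase of *counted region* per million *counted chloroplast
#' CDS reads* of the same sample and assay — the analysis is
#' chloroplast-internal, matching the arrays' self-normalization. A
#' pseudocount added to every gene's count keeps knockouts log-safe; the
#' total in the denominator is the raw counted total.
#'
#' @param counts data.frame from [count_genes()].
#' @param pseudocount reads added per gene (default 1).
#' @return `counts` with an `rpkm` column (`NA` for flagged genes).
#' @export
rpkm_table <- function(counts, pseudocount = 1) {
  total <- sum(counts$count, na.rm = TRUE)
  if (total <= 0) stop("no counted reads in sample")
  rpkm <- (counts$count + pseudocount) /
    ((counts$counted_length / 1000) * (total / 1e6))
  rpkm[counts$flagged | counts$counted_length == 0] <- NA_real_
  counts$rpkm <- rpkm
  counts
}

#' NGS branch: per-tier alignments to per-sample RPKM
#'
#' Applies sequential tier assignment and the CDS counting rules to every
#' sample of an alignment set and computes RPKM expression values.
#'
#' @param aln_sets result of [emit_alignment_sets()], or a compatible list of
#'   samples whose `tiers` are SAM/BAM paths.
#' @param annotation the [plastome_annotation()].
#' @param from_files read the SAM files instead of in-memory alignments.
#' @param mask_5p,mask_3p,junction_limit,pseudocount counting/RPKM
#'   parameters.
#' @return data.frame `gene_id`, `assay`, `genotype`, `replicate`, `count`,
#'   `counted_length`, `rpkm`, `flagged`.
#' @export
quantify_ngs <- function(aln_sets, annotation, from_files = FALSE,
                         mask_5p = 10L, mask_3p = 30L, junction_limit = 52L,
                         pseudocount = 1) {
  out <- list()
  for (key in names(aln_sets$samples)) {
    smp <- aln_sets$samples[[key]]
    tiers <- if (from_files) as.list(smp$files) else smp$tiers
    seq_res <- enforce_sequential(tiers)
    ct <- count_genes(seq_res$chloroplast, annotation,
                      assay = smp$meta$assay, mask_5p = mask_5p,
                      mask_3p = mask_3p, junction_limit = junction_limit)
    ct <- rpkm_table(ct, pseudocount = pseudocount)
    ct$genotype <- smp$meta$genotype
    ct$replicate <- smp$meta$replicate
    out[[key]] <- ct
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene_id", "assay", "genotype", "replicate", "count",
          "counted_length", "rpkm", "flagged")]
}
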