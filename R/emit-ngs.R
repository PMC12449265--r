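#' Emit per-tier alignment sets for a scenario
#'
#' Simulates tiered sequencing samples for both genotypes: ribosome-footprint
#' (RF) reads with lengths uniform in 20..39 nt and RNA-seq reads (~100 nt)
#' placed uniformly over each gene's counting-eligible region, with Poisson
#' (optionally Gamma-overdispersed) counts around `expression x depth`.
#' Intron-containing genes additionally receive junction-spanning RNA reads:
#' spliced (gap exactly matching the intron; mature mRNA, countable) and
#' unspliced (contiguous blocks running into the intron with overhangs on
#' both sides of the 52-nt limit, so the junction rule is exercised in both
#' directions). rRNA/tRNA contaminant reads go to the tier-1 file only (the
#' tier files emulate a sequential aligner, which feeds only unmapped reads
#' forward); with `leak_contaminants = TRUE` a fraction of contaminants also
#' carries a chloroplast alignment in the tier-2 file, which sequential
#' assignment must discard — the mode used to exercise
#' [enforce_sequential()]. Decoy mitochondrial and nuclear reads populate
#' tiers 3 and 4. A ground-truth table counting the reads that
#' qualify under the counting rules accompanies the output.
#'
#' @param truth a [simulate_truth()] result.
#' @param annotation the [plastome_annotation()] used to build `truth`.
#' @param scenario the [scenario()].
#' @param read_params list: `rf_len` (range, default c(20, 39)), `rna_len`
#'   (default 100), `depth` (expected reads per unit expression, default
#'   0.25, i.e. ~250 reads for a baseline gene), `poisson` (FALSE rounds the
#'   expectation instead — the noiseless mode), `unspliced_frac`,
#'   `spliced_junction_frac` (fractions of an intron gene's RNA reads,
#'   defaults 0.10 each), `contaminant_frac`, `other_tier_frac` (defaults
#'   0.05 / 0.03).
#' @param dir if non-`NULL`, SAM files (one per tier per sample) are written
#'   there.
#' @param seed RNG seed (default `scenario$seed + 2`).
#' @param mask_5p,mask_3p,junction_limit counting-rule parameters, must match
#'   the ones used at quantification.
#' @return list with `samples` (each: `meta` = assay/genotype/replicate,
#'   `tiers` = named alignment data.frames in tier order, `files`),
#'   `truth_counts` (gene x assay x genotype x replicate), `refs`,
#'   `read_params`.
#' @export
emit_alignment_sets <- function(truth, annotation, scenario,
                                read_params = list(), dir = NULL,
                                seed = scenario$seed + 2L,
                                mask_5p = 10L, mask_3p = 30L,
                                junction_limit = 52L) {
  rp <- utils::modifyList(
    list(rf_len = c(20L, 39L), rna_len = 100L, depth = 0.25, poisson = TRUE,
         unspliced_frac = 0.10, spliced_junction_frac = 0.10,
         contaminant_frac = 0.05, other_tier_frac = 0.03,
         leak_contaminants = FALSE),
    read_params)

  genes <- annotation$genes
  ids <- names(genes)
  refs <- c(stats::setNames(2000L, "rRNA_contam"),
            stats::setNames(annotation$genome_length, annotation$ref_name),
            mito = 5000L, nuclear1 = 8000L)

  # per gene x assay: counting region, masks, and the placement-eligible
  # intervals (region minus other same-strand regions, so no read is ambiguous)
  geo <- list()
  for (assay in c("RF", "RNA")) {
    regs <- lapply(genes, counting_region, assay = assay,
                   mask_5p = mask_5p, mask_3p = mask_3p)
    for (gid in ids) {
      other <- iv_empty()
      for (h in ids) {
        if (h == gid || genes[[h]]$strand != genes[[gid]]$strand) next
        other <- rbind(other, regs[[h]]$intervals)
      }
      geo[[paste(assay, gid)]] <- list(
        region = regs[[gid]], masks = attr(regs[[gid]], "masks"),
        eligible = iv_setdiff(regs[[gid]]$intervals, other))
    }
  }

  qualifies <- function(blocks, gene, assay, region, masks) {
    if (!iv_overlaps(blocks, region$intervals)) return(FALSE)
    if (iv_overlaps(blocks, masks$intervals)) return(FALSE)
    if (assay == "RNA" && intron_overhang(blocks, gene) > junction_limit)
      return(FALSE)
    TRUE
  }

  # vectorized placement of m contiguous reads over eligible pieces
  place_many <- function(pieces, lens) {
    w <- pieces[, 2] - pieces[, 1]
    out_s <- integer(length(lens)); out_e <- integer(length(lens))
    for (len in unique(lens)) {
      sel <- which(lens == len)
      len_use <- len
      slots <- pmax(0L, w - len_use + 1L)
      if (sum(slots) == 0L) {          # fall back to the widest piece
        len_use <- max(w)
        slots <- pmax(0L, w - len_use + 1L)
      }
      cum <- cumsum(as.numeric(slots))
      u <- sample.int(cum[length(cum)], length(sel), replace = TRUE)
      piece <- findInterval(u - 1, c(0, cum))
      off <- u - 1 - c(0, cum)[piece]
      out_s[sel] <- pieces[piece, 1] + as.integer(off)
      out_e[sel] <- out_s[sel] + len_use
    }
    cbind(start = out_s, end = out_e)
  }

  draw_count <- function(lam) {
    d <- scenario$noise$count_dispersion
    if (!rp$poisson) return(as.integer(round(lam)))
    if (d > 0) lam <- lam * stats::rgamma(length(lam), shape = 1 / d, scale = d)
    stats::rpois(length(lam), lam)
  }

  expr_col <- function(assay, genotype)
    paste0(if (assay == "RF") "to" else "rna", "_", genotype)

  build_sample <- function(assay, genotype) {
    read_id <- character(0); strand <- character(0); blocks <- list()
    counted_gene <- character(0)   # gene credited per emitted chloroplast read
    truth_count <- stats::setNames(integer(length(ids)), ids)
    rid <- 0L
    nid <- function(k = 1L) {
      r <- sprintf("r%06d", rid + seq_len(k)); rid <<- rid + k; r
    }

    for (gid in ids) {
      gene <- genes[[gid]]
      gg <- geo[[paste(assay, gid)]]
      if (gg$region$flagged || nrow(gg$eligible) == 0L) next
      expr <- truth[[expr_col(assay, genotype)]][match(gid, truth$gene_id)]
      n <- draw_count(expr * rp$depth)
      if (n <= 0L) next

      n_uns <- n_spl <- 0L
      if (assay == "RNA" && nrow(gene$introns) > 0L) {
        n_uns <- as.integer(round(rp$unspliced_frac * n))
        n_spl <- as.integer(round(rp$spliced_junction_frac * n))
      }
      n_body <- n - n_uns - n_spl

      if (n_body > 0L) {
        lens <- if (assay == "RF")
          sample(seq.int(rp$rf_len[1], rp$rf_len[2]), n_body, replace = TRUE)
        else rep(rp$rna_len, n_body)
        se <- place_many(gg$eligible, lens)
        read_id <- c(read_id, nid(n_body))
        strand <- c(strand, rep(gene$strand, n_body))
        blocks <- c(blocks, lapply(seq_len(n_body), function(i)
          iv(se[i, 1], se[i, 2])))
        truth_count[gid] <- truth_count[gid] + n_body
        counted_gene <- c(counted_gene, rep(gid, n_body))
      }
      for (k in seq_len(n_uns)) {
        intr <- gene$introns[sample.int(nrow(gene$introns), 1L), , drop = FALSE]
        o <- sample(20:80, 1L)           # straddles the 52-nt limit
        anchor <- 20L
        b <- if (stats::runif(1) < 0.5)
          iv(intr[1] - anchor, min(intr[1] + o, intr[2]))
        else
          iv(max(intr[2] - o, intr[1]), intr[2] + anchor)
        q <- qualifies(b, gene, assay, gg$region, gg$masks)
        read_id <- c(read_id, nid()); strand <- c(strand, gene$strand)
        blocks <- c(blocks, list(b))
        if (q) truth_count[gid] <- truth_count[gid] + 1L
        counted_gene <- c(counted_gene, if (q) gid else NA_character_)
      }
      for (k in seq_len(n_spl)) {
        intr <- gene$introns[sample.int(nrow(gene$introns), 1L), , drop = FALSE]
        a <- 50L
        b <- rbind(iv(intr[1] - a, intr[1]), iv(intr[2], intr[2] + a))
        q <- qualifies(b, gene, assay, gg$region, gg$masks)
        read_id <- c(read_id, nid()); strand <- c(strand, gene$strand)
        blocks <- c(blocks, list(b))
        if (q) truth_count[gid] <- truth_count[gid] + 1L
        counted_gene <- c(counted_gene, if (q) gid else NA_character_)
      }
    }

    n_chl <- length(read_id)
    # tier-1 contaminants; ~30% also align to the chloroplast and must be
    # removed by sequential assignment (they are never in the truth table)
    n_cont <- as.integer(round(rp$contaminant_frac * n_chl))
    t1_id <- character(0); t1_blocks <- list()
    for (k in seq_len(n_cont)) {
      id <- nid()
      s <- sample.int(refs[["rRNA_contam"]] - 40L, 1L) - 1L
      t1_id <- c(t1_id, id)
      t1_blocks <- c(t1_blocks, list(iv(s, s + 30L)))
      if (rp$leak_contaminants && stats::runif(1) < 0.3) {
        gid <- sample(ids, 1L)
        gg <- geo[[paste(assay, gid)]]
        if (nrow(gg$eligible) > 0L) {
          se <- place_many(gg$eligible, 30L)
          read_id <- c(read_id, id)
          strand <- c(strand, genes[[gid]]$strand)
          blocks <- c(blocks, list(iv(se[1, 1], se[1, 2])))
        }
      }
    }
    n_other <- as.integer(round(rp$other_tier_frac * n_chl))
    mk_decoy <- function(ref) {
      if (n_other == 0L) return(empty_alignments())
      s <- sample.int(refs[[ref]] - 120L, n_other, replace = TRUE) - 1L
      data.frame(read_id = nid(n_other), ref = ref,
                 strand = sample(c("+", "-"), n_other, replace = TRUE),
                 blocks = I(lapply(s, function(x) iv(x, x + 100L))),
                 stringsAsFactors = FALSE)
    }
    tier3 <- mk_decoy("mito")
    tier4 <- mk_decoy("nuclear1")

    chl <- if (length(read_id))
      data.frame(read_id = read_id, ref = annotation$ref_name,
                 strand = strand, blocks = I(blocks),
                 stringsAsFactors = FALSE)
    else empty_alignments()
    t1 <- if (length(t1_id))
      data.frame(read_id = t1_id, ref = "rRNA_contam", strand = "+",
                 blocks = I(t1_blocks), stringsAsFactors = FALSE)
    else empty_alignments()

    list(tiers = list(rRNA_tRNA = t1, chloroplast = chl,
                      mitochondrial = tier3, nuclear = tier4),
         truth_count = truth_count)
  }

  out <- withr::with_seed(seed, {
    samples <- list()
    truth_rows <- list()
    for (assay in c("RF", "RNA")) {
      for (genotype in c("mutant", "control")) {
        for (r in seq_len(scenario$n_replicates)) {
          bs <- build_sample(assay, genotype)
          key <- sprintf("%s_%s_rep%d", assay, genotype, r)
          samples[[key]] <- list(
            meta = list(assay = assay, genotype = genotype, replicate = r),
            tiers = bs$tiers, files = NULL)
          truth_rows[[key]] <- data.frame(
            gene_id = names(bs$truth_count), assay = assay,
            genotype = genotype, replicate = r,
            count = unname(bs$truth_count), stringsAsFactors = FALSE)
        }
      }
    }
    list(samples = samples, truth_counts = do.call(rbind, truth_rows))
  })
  rownames(out$truth_counts) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tier_refs <- list(rRNA_tRNA = refs["rRNA_contam"],
                      chloroplast = refs[annotation$ref_name],
                      mitochondrial = refs["mito"],
                      nuclear = refs["nuclear1"])
    for (key in names(out$samples)) {
      fl <- character(0)
      for (ti in seq_along(out$samples[[key]]$tiers)) {
        tn <- names(out$samples[[key]]$tiers)[ti]
        f <- file.path(dir, sprintf("%s_tier%d_%s.sam", key, ti, tn))
        write_sam(out$samples[[key]]$tiers[[tn]], tier_refs[[tn]], f)
        fl[tn] <- f
      }
      out$samples[[key]]$files <- fl
    }
  }
  list(samples = out$samples, truth_counts = out$truth_counts,
       refs = refs, read_params = rp)
}

empty_alignments <- function(ref = character(0)) {
  data.frame(read_id = character(0), ref = character(0),
             strand = character(0), blocks = I(list()),
             stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Minimal valid SAM (header with reference lengths, 11 mandatory fields,
#' `SEQ`/`QUAL` omitted as `*`); spliced alignments get `M`/`N` CIGARs.
#'
#' @param alns alignment data.frame (`read_id`, `ref`, `strand`, `blocks`).
#' @param refs named integer vector of reference lengths.
#' @param path output file.
#' @export
write_sam <- function(alns, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  body <- character(nrow(alns))
  for (i in seq_len(nrow(alns))) {
    b <- alns$blocks[[i]]
    cig <- character(0)
    for (j in seq_len(nrow(b))) {
      if (j > 1L) cig <- c(cig, sprintf("%dN", b[j, 1] - b[j - 1L, 2]))
      cig <- c(cig, sprintf("%dM", b[j, 2] - b[j, 1]))
    }
    body[i] <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                       alns$read_id[i],
                       if (alns$strand[i] == "-") 16L else 0L,
                       alns$ref[i], b[1, 1] + 1L, paste(cig, collapse = ""))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read one tier's alignments from SAM/BAM
#'
#' SAM input is converted with Rsamtools and parsed with GenomicAlignments;
#' aligned blocks come from the CIGAR (`N` gaps split blocks).
#'
#' @param path SAM or BAM file.
#' @return alignment data.frame (`read_id`, `ref`, `strand`, `blocks` with
#'   0-based half-open block matrices).
#' @export
read_tier_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "qname"))
  if (!length(gal)) return(empty_alignments())
  bl <- GenomicAlignments::grglist(gal)
  starts <- BiocGenerics::start(bl); ends <- BiocGenerics::end(bl)
  blocks <- lapply(seq_along(gal), function(i)
    iv(starts[[i]] - 1L, ends[[i]]))
  data.frame(read_id = S4Vectors::mcols(gal)$qname,
             ref = as.character(GenomicAlignments::seqnames(gal)),
             strand = as.character(BiocGenerics::strand(gal)),
             blocks = I(blocks), stringsAsFactors = FALSE)
}
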