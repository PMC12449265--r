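#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(x) = y` (monotone decreasing, convex in
#' `1/x`), used by the empirical-Bayes moment equations. Tolerance 1e-8.
#'
#' @param y positive target value.
#' @return `x` with `trigamma(x) = y`; `Inf` for `y <= 0`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, 0)
}

#' Estimate the variance prior across genes
#'
#' Fits the scaled inverse-chi-square prior of the empirical-Bayes moderated
#' t machinery by moment matching on the log sample variances: with
#' `z = log(s^2)`, `E z = log(s0^2) + digamma(df/2) - log(df/2) -
#' (digamma(d0/2) - log(d0/2))` and `Var z = trigamma(df/2) +
#' trigamma(d0/2)`. The excess spread of `z` beyond the residual-df
#' contribution determines `d0` via trigamma inversion; no excess (all
#' variances consistent with one common value) gives an infinite prior.
#'
#' @param s2 per-gene sample variances.
#' @param df residual degrees of freedom (scalar or per gene; equal dfs
#'   assumed for the moment fit).
#' @return object of class `VariancePrior`: list with `d0` (prior degrees of
#'   freedom, possibly `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (all(s2 == 0)) stop("degenerate input: all sample variances are zero")
  if (sum(s2 > 0) < 10)
    stop("need at least 10 genes with positive variance")
  df <- df[1]
  # offset zero variances to the smallest positive one for the log moments
  z <- log(pmax(s2, min(s2[s2 > 0])))
  e <- z - digamma(df / 2) + log(df / 2)
  if (stats::var(z) == 0) {
    # degenerate zero-spread limit: every gene shares this variance exactly
    prior <- list(d0 = Inf, s0_sq = s2[1])
    class(prior) <- "VariancePrior"
    return(prior)
  }
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 1e-8) {
    prior <- list(d0 = Inf, s0_sq = exp(mean(e)))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  class(prior) <- "VariancePrior"
  prior
}

#' @export
print.VariancePrior <- function(x, ...) {
  cat(sprintf("VariancePrior: d0 = %s, s0^2 = %.4g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated t-test per gene
#'
#' Shrinks each gene's variance toward the prior — posterior variance
#' `s_post^2 = (d0 s0^2 + df s^2) / (d0 + df)` — and tests the effect with a
#' t distribution on `d0 + df` degrees of freedom. `d0 = 0` recovers the
#' ordinary t-test; `d0 = Inf` the fixed-variance (z-like) statistic.
#'
#' Designs: `paired_one_sample` tests the mean of per-replicate paired
#' log-ratios against 0 (the co-hybridized arrays); `two_sample` compares
#' group means with a pooled variance (the NGS samples, which are not
#' paired).
#'
#' @param mat numeric matrix, genes x replicates (for `two_sample`, columns
#'   of both groups with `groups` giving the labels).
#' @param design `"paired_one_sample"` or `"two_sample"`.
#' @param prior a [estimate_prior()] result (or `list(d0=, s0_sq=)`).
#' @param groups for `two_sample`: length-ncol factor/character with two
#'   levels; the effect is `mean(level2) - mean(level1)`.
#' @return data.frame `effect`, `s2`, `df_residual`, `t_mod`, `df_total`,
#'   `p`. Genes with fewer than 2 usable replicates (per group) get `NA`.
#' @export
moderated_test <- function(mat, design = c("paired_one_sample", "two_sample"),
                           prior, groups = NULL) {
  design <- match.arg(design)
  mat <- as.matrix(mat)
  if (design == "paired_one_sample") {
    n <- rowSums(is.finite(mat))
    effect <- rowMeans(mat, na.rm = TRUE)
    s2 <- apply(mat, 1, stats::var, na.rm = TRUE)
    df <- n - 1
    se_unit <- 1 / sqrt(n)
  } else {
    if (is.null(groups) || length(unique(groups)) != 2L)
      stop("two_sample design needs a two-level 'groups'")
    lev <- if (is.factor(groups)) levels(groups) else unique(groups)
    groups <- as.character(groups)
    m1 <- mat[, groups == lev[1], drop = FALSE]
    m2 <- mat[, groups == lev[2], drop = FALSE]
    n1 <- rowSums(is.finite(m1)); n2 <- rowSums(is.finite(m2))
    n <- pmin(n1, n2)
    effect <- rowMeans(m2, na.rm = TRUE) - rowMeans(m1, na.rm = TRUE)
    v1 <- apply(m1, 1, stats::var, na.rm = TRUE)
    v2 <- apply(m2, 1, stats::var, na.rm = TRUE)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se_unit <- sqrt(1 / n1 + 1 / n2)
  }
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s_post <- rep(s0, length(effect))
    df_total <- rep(Inf, length(effect))
  } else {
    s_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  t_mod <- effect / (sqrt(s_post) * se_unit)
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  bad <- n < 2
  t_mod[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(effect = effect, s2 = s2, df_residual = df, t_mod = t_mod,
             df_total = df_total, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), input order preserved,
#' monotonicity enforced. Adjusted values never fall below the raw p.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Percentile-derived fold-change cut-off
#'
#' The study justifies its fold-change thresholds by the tail of the
#' observed fold-change distribution: the cut-off is the linear fold change
#' `2^q`, where `q` is the `(1 - tail)` empirical quantile of `|log2 FC|`
#' (linear-interpolation quantile, type 7), i.e. the value exceeded by the
#' `tail` fraction of genes.
#'
#' @param log2fc pool of log2 fold changes (finite).
#' @param tail tail fraction (default 0.05, the 5th percentile rule).
#' @return linear fold-change cut-off (>= 1 for an all-zero pool: 1).
#' @export
tail_cutoff <- function(log2fc, tail = 0.05) {
  log2fc <- log2fc[is.finite(log2fc)]
  if (!length(log2fc)) stop("empty fold-change pool")
  q <- stats::quantile(abs(log2fc), probs = 1 - tail, type = 7, names = FALSE)
  2^q
}

#' Translation-efficiency change
#'
#' TE is the ratio of the changes in translation output and transcript
#' level; on the log2 scale the difference of the two fold changes.
#'
#' @param to_log2fc,rna_log2fc log2 fold changes of translation output and
#'   RNA.
#' @return `to_log2fc - rna_log2fc`.
#' @export
te_change <- function(to_log2fc, rna_log2fc) to_log2fc - rna_log2fc

#' Differential results for the microarray branch
#'
#' Per assay (translation output from the RF arrays, RNA), fits the paired
#' one-sample moderated test on the per-replicate log2 fold changes, adjusts
#' p-values by BH within the assay, and appends the TE change. Variance
#' priors are estimated within assay (different noise regimes).
#'
#' @param fc data.frame from [quantify_array()].
#' @return data.frame `gene_id`, `assay` (`TO`/`RNA`), `mean_log2fc`,
#'   `t_mod`, `df_total`, `p`, `padj`, `log2fc_te`, `censored`.
#' @export
fit_diff_array <- function(fc) {
  res <- list()
  for (assay in c("RF", "RNA")) {
    sub <- fc[fc$assay == assay, ]
    m <- stats::reshape(sub[, c("gene_id", "replicate", "log2fc")],
                        idvar = "gene_id", timevar = "replicate",
                        direction = "wide")
    genes <- m$gene_id
    mm <- as.matrix(m[, -1, drop = FALSE])
    prior <- estimate_prior(apply(mm, 1, stats::var, na.rm = TRUE),
                            df = ncol(mm) - 1)
    mt <- moderated_test(mm, "paired_one_sample", prior)
    cens <- tapply(fc$censored[fc$assay == assay],
                   fc$gene_id[fc$assay == assay], any)
    res[[assay]] <- data.frame(
      gene_id = genes, assay = if (assay == "RF") "TO" else "RNA",
      mean_log2fc = mt$effect, t_mod = mt$t_mod, df_total = mt$df_total,
      p = mt$p, padj = bh_adjust(mt$p),
      censored = as.logical(cens[genes]), stringsAsFactors = FALSE)
  }
  finish_diff(res)
}

#' Differential results for the NGS branch
#'
#' Per assay, fits the two-sample moderated test on log2 RPKM (mutant vs
#' control replicates; NGS samples are not co-hybridized, so there is no
#' pairing) with BH adjustment within assay, and appends the TE change.
#'
#' @param rpkm data.frame from [quantify_ngs()].
#' @return as [fit_diff_array()].
#' @export
fit_diff_ngs <- function(rpkm) {
  res <- list()
  for (assay in c("RF", "RNA")) {
    sub <- rpkm[rpkm$assay == assay & !rpkm$flagged, ]
    sub$col <- paste(sub$genotype, sub$replicate, sep = "_")
    m <- stats::reshape(sub[, c("gene_id", "col", "rpkm")],
                        idvar = "gene_id", timevar = "col",
                        direction = "wide")
    genes <- m$gene_id
    mm <- log2(as.matrix(m[, -1, drop = FALSE]))
    groups <- sub("rpkm\\.(\\w+)_\\d+$", "\\1", colnames(mm))
    v1 <- apply(mm[, groups == "control", drop = FALSE], 1, stats::var)
    v2 <- apply(mm[, groups == "mutant", drop = FALSE], 1, stats::var)
    n1 <- sum(groups == "control"); n2 <- sum(groups == "mutant")
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    prior <- estimate_prior(s2, df = n1 + n2 - 2)
    mt <- moderated_test(mm, "two_sample", prior,
                         groups = factor(groups,
                                         levels = c("control", "mutant")))
    res[[assay]] <- data.frame(
      gene_id = genes, assay = if (assay == "RF") "TO" else "RNA",
      mean_log2fc = mt$effect, t_mod = mt$t_mod, df_total = mt$df_total,
      p = mt$p, padj = bh_adjust(mt$p),
      censored = FALSE, stringsAsFactors = FALSE)
  }
  finish_diff(res)
}

# bind TO and RNA results and attach the exact TE decomposition
finish_diff <- function(res) {
  out <- rbind(res[[1]], res[[2]])
  to <- out[out$assay == "TO", ]
  rna <- out[out$assay == "RNA", ]
  te <- stats::setNames(
    te_change(to$mean_log2fc,
              rna$mean_log2fc[match(to$gene_id, rna$gene_id)]),
    to$gene_id)
  out$log2fc_te <- unname(te[out$gene_id])
  rownames(out) <- NULL
  class(out) <- c("DiffResult", class(out))
  out
}
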