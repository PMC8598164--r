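#' Median-of-ratios count normalization
#'
#' Corrects for variable sequencing depth by the median-of-ratios scheme:
#' each sample is divided by the median, across guides with a positive
#' geometric-mean reference, of its ratio to that per-guide geometric mean.
#' After scaling, the median ratio of every sample to the reference is
#' exactly 1, so depth differences are removed; re-normalizing a normalized
#' matrix can only change it by one global constant (the median/geometric
#' -mean commutator, ~1 for count data), never the relative structure.
#'
#' @param x a [screen_counts()] object, or a bare guide x sample matrix.
#' @return The same type with normalized values; for `screen_counts`, fields
#'   `norm_counts` and `size_factors` are added. Size factors multiply to the
#'   raw scale: `counts = sweep(norm_counts, 2, size_factors, "*")`.
#' @export
median_normalize <- function(x) {
  if (inherits(x, "screen_counts")) {
    sf <- median_size_factors(x$counts)
    x$size_factors <- sf
    x$norm_counts <- sweep(x$counts, 2, sf, "/")
    return(x)
  }
  sweep(x, 2, median_size_factors(x), "/")
}

median_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  zero_sample <- colSums(counts) == 0
  if (any(zero_sample)) {
    stop("all-zero sample: ",
         paste(colnames(counts)[zero_sample], collapse = ", "))
  }
  logref <- rowMeans(log(counts))       # -Inf where any sample has a zero
  use <- is.finite(logref)
  if (!any(use)) stop("no guide is nonzero in every sample")
  ref <- exp(logref[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(col / ref)
  })
  names(sf) <- colnames(counts)
  sf
}

#' Per-guide log2 fold change between sorted bins
#'
#' Computes `log2((high + pseudocount) / (low + pseudocount))` on normalized
#' counts for one marker and replicate, the per-guide enrichment of the
#' marker-high over the marker-low sorted population.
#'
#' @param x a normalized [screen_counts()] (run [median_normalize()] first;
#'   raw counts are used with a warning otherwise).
#' @param marker,replicate which sorted screen to use.
#' @param pseudocount positive value added to both bins after normalization;
#'   bounds the fold change for dropout guides. Default 1.
#' @return A data.frame with columns `guide_id`, `gene`, `is_ntc`, `marker`,
#'   `replicate`, `high`, `low`, `lfc`, and a `pseudocount` attribute.
#' @export
guide_lfc <- function(x, marker, replicate, pseudocount = 1) {
  stopifnot(inherits(x, "screen_counts"), pseudocount > 0)
  mat <- x$norm_counts
  if (is.null(mat)) {
    warning("counts are not normalized; using raw counts")
    mat <- x$counts
  }
  s <- x$samples
  hi <- s$sample_id[!is.na(s$marker) & s$marker == marker &
                      s$replicate == replicate & s$bin == "high"]
  lo <- s$sample_id[!is.na(s$marker) & s$marker == marker &
                      s$replicate == replicate & s$bin == "low"]
  if (length(hi) != 1 || length(lo) != 1) {
    stop("missing high or low bin for ", marker, " replicate ", replicate)
  }
  out <- data.frame(
    guide_id = x$library$guide_id,
    gene = x$library$gene,
    is_ntc = x$library$is_ntc,
    marker = marker,
    replicate = replicate,
    high = mat[, hi],
    low = mat[, lo],
    lfc = log2((mat[, hi] + pseudocount) / (mat[, lo] + pseudocount)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-guide log2 fold changes for all sorted screens
#'
#' Convenience wrapper running [guide_lfc()] over every (marker, replicate)
#' pair present in the sample sheet and stacking the results.
#'
#' @inheritParams guide_lfc
#' @return Stacked data.frame as in [guide_lfc()].
#' @export
all_guide_lfc <- function(x, pseudocount = 1) {
  s <- x$samples
  sorted <- unique(s[s$bin == "high", c("marker", "replicate")])
  if (nrow(sorted) == 0) stop("no sorted samples in sheet")
  do.call(rbind, lapply(seq_len(nrow(sorted)), function(i) {
    guide_lfc(x, sorted$marker[i], sorted$replicate[i], pseudocount)
  }))
}

#' Compare gene-level guide effects to the non-targeting-control null
#'
#' For each gene, the mean guide log2 fold change is standardized against the
#' empirical NTC guide distribution: `z = (mean_gene - mean_ntc) /
#' (sd_ntc / sqrt(n_guides))`, i.e. the NTC spread scaled to the standard
#' error of a mean of `n_guides` null guides, so that z is approximately
#' standard normal for a null gene. Two-sided normal p-values are adjusted by
#' Benjamini-Hochberg across tested genes.
#'
#' @param lfcs a guide-level table from [guide_lfc()] / [all_guide_lfc()]
#'   (columns `gene`, `is_ntc`, `lfc`).
#' @param genes optional character vector restricting which genes are tested;
#'   default all non-NTC genes in `lfcs`.
#' @return Data.frame with one row per tested gene: `gene`, `n_guides`,
#'   `mean_lfc`, `ntc_mean`, `ntc_sd`, `ntc_n`, `z`, `p`, `fdr`.
#' @export
ntc_compare <- function(lfcs, genes = NULL) {
  total <- if (!is.null(lfcs$high)) lfcs$high + lfcs$low else abs(lfcs$lfc) + 1
  ntc_used <- lfcs$is_ntc & total > 0
  n_ntc <- sum(ntc_used)
  if (n_ntc < 30) stop("need >= 30 NTC guides with nonzero counts, have ",
                       n_ntc)
  mu0 <- mean(lfcs$lfc[ntc_used])
  sd0 <- stats::sd(lfcs$lfc[ntc_used])
  tab <- lfcs[!lfcs$is_ntc, , drop = FALSE]
  if (is.null(genes)) genes <- unique(tab$gene)
  absent <- setdiff(genes, tab$gene)
  if (length(absent) > 0) {
    warning(length(absent), " gene(s) without guides skipped")
    genes <- setdiff(genes, absent)
  }
  tab <- tab[tab$gene %in% genes, , drop = FALSE]
  n <- tapply(tab$lfc, tab$gene, length)
  m <- tapply(tab$lfc, tab$gene, mean)
  genes <- names(n)
  z <- (m - mu0) / (sd0 / sqrt(n))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    gene = genes,
    n_guides = as.integer(n),
    mean_lfc = as.numeric(m),
    ntc_mean = mu0, ntc_sd = sd0, ntc_n = n_ntc,
    z = as.numeric(z),
    p = as.numeric(p),
    fdr = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
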