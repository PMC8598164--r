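#' Stouffer combination of z-scores
#'
#' Combines k independent z-scores with equal weights,
#' `z_sum = sum(z) / sqrt(k)`, and recomputes a two-sided normal p-value
#' (`p_sum`). One-sided mode takes the upper tail of `z_sum` directly.
#'
#' @param z numeric vector of z-scores (length >= 1, finite values used).
#' @param two_sided two-sided p (default) or upper-tail one-sided.
#' @return List with `z_sum` and `p_sum`.
#' @export
stouffer <- function(z, two_sided = TRUE) {
  z <- z[is.finite(z)]
  if (length(z) == 0) stop("stouffer needs >= 1 finite z")
  z_sum <- sum(z) / sqrt(length(z))
  p_sum <- if (two_sided) 2 * stats::pnorm(-abs(z_sum)) else
    stats::pnorm(z_sum, lower.tail = FALSE)
  list(z_sum = z_sum, p_sum = min(p_sum, 1))
}

#' Gene score from combined significance and effect
#'
#' `gene_score = log10(p_sum) * beta_sum`. With small p and a negative
#' summed selection coefficient (a positive regulator depleted from the
#' marker-high population), the score is large and positive; ranking in
#' descending order therefore puts positive regulators on top.
#'
#' @param p_sum combined p-value in (0, 1]; values <= 0 are clamped to
#'   1e-300 with a warning.
#' @param beta_sum summed per-condition selection coefficient.
#' @return Numeric score (vectorized).
#' @export
gene_score <- function(p_sum, beta_sum) {
  if (any(p_sum <= 0)) {
    warning("p_sum <= 0 clamped to 1e-300")
    p_sum <- pmax(p_sum, 1e-300)
  }
  if (any(p_sum > 1)) stop("p_sum must be <= 1")
  log10(p_sum) * beta_sum
}

#' Combine per-condition MLE results into a single ranked gene list
#'
#' Sums the per-condition selection coefficients (`beta_sum`), combines the
#' per-condition z-scores by Stouffer's method into `z_sum` and `p_sum`, and
#' scores each gene as `log10(p_sum) * beta_sum`. Genes are ranked in
#' descending score order by [rank_genes()].
#'
#' @param results one `fit_all()` table or a list of them (e.g. the three
#'   marker-aware fits); all conditions across all tables are combined.
#' @param two_sided sidedness of `p_sum` (see [stouffer()]); recorded in the
#'   output attributes together with the combination mode.
#' @return Ranked data.frame: `gene`, `beta_sum`, `z_sum`, `p_sum`,
#'   `gene_score`, `rank`, plus `n_conditions`.
#' @export
combine_screens <- function(results, two_sided = TRUE) {
  if (is.data.frame(results)) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(r) {
    r[!r$is_ntc_pseudo, c("gene", "condition", "beta", "z")]
  }))
  sp <- split(tab, tab$gene)
  out <- data.frame(
    gene = names(sp),
    beta_sum = vapply(sp, function(d) sum(d$beta), 0),
    z_sum = NA_real_, p_sum = NA_real_,
    n_conditions = vapply(sp, nrow, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  st <- lapply(sp, function(d) stouffer(d$z, two_sided = two_sided))
  out$z_sum <- vapply(st, `[[`, 0, "z_sum")
  out$p_sum <- vapply(st, `[[`, 0, "p_sum")
  out$gene_score <- gene_score(out$p_sum, out$beta_sum)
  out <- rank_genes(out)
  attr(out, "combination") <- list(
    mode = "stouffer_across_all_conditions",
    two_sided = two_sided
  )
  out
}

#' Rank genes by descending gene score
#'
#' Ties are broken by larger `|beta_sum|`, then by gene name, so the ranking
#' is a deterministic permutation of the input regardless of row order.
#'
#' @param scores data.frame with `gene`, `gene_score`, `beta_sum`.
#' @return Same data.frame sorted, with a `rank` column `1..G`.
#' @export
rank_genes <- function(scores) {
  stopifnot(all(c("gene", "gene_score", "beta_sum") %in% names(scores)))
  o <- order(-scores$gene_score, -abs(scores$beta_sum), scores$gene)
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cluster the most selected genes across screens
#'
#' Takes the union over screens of each screen's most extreme genes — the
#' top `fraction/2` enriched plus the top `fraction/2` depleted by beta,
#' i.e. the 5 percent most enriched or depleted per screen at the default —
#' and k-means-clusters their per-screen beta vectors (k = 8 by default,
#' >= 25 seeded restarts, best inertia kept).
#'
#' @param beta_mat genes x screens numeric matrix of selection coefficients
#'   (rownames = genes).
#' @param fraction total extreme fraction per screen (default 0.05).
#' @param k number of clusters (default 8).
#' @param seed RNG seed; the same seed reproduces identical assignments.
#' @param nstart k-means restarts (default 25).
#' @return Data.frame `gene`, one beta column per screen, `cluster`;
#'   attribute `degenerate` flags fewer distinct rows than k.
#' @export
top_fraction_cluster <- function(beta_mat, fraction = 0.05, k = 8, seed = 1,
                                 nstart = 25) {
  beta_mat <- as.matrix(beta_mat)
  if (is.null(rownames(beta_mat))) stop("beta_mat needs gene rownames")
  half <- fraction / 2
  G <- nrow(beta_mat)
  n_tail <- max(1L, ceiling(half * G))
  pick <- unique(unlist(lapply(seq_len(ncol(beta_mat)), function(j) {
    o <- order(beta_mat[, j])
    rownames(beta_mat)[c(utils::head(o, n_tail), utils::tail(o, n_tail))]
  })))
  if (length(pick) < k) stop("fewer eligible genes (", length(pick),
                             ") than clusters (", k, ")")
  sub <- beta_mat[pick, , drop = FALSE]
  distinct <- nrow(unique(sub))
  degenerate <- distinct < k
  k_eff <- min(k, distinct)
  cl <- with_seed(seed, stats::kmeans(sub, centers = k_eff, nstart = nstart,
                                      iter.max = 100))
  out <- data.frame(gene = rownames(sub), sub, cluster = cl$cluster,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  attr(out, "k") <- k_eff
  out
}
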