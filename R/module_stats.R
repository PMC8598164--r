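#' Binomial depletion/enrichment test for a set of guides
#'
#' Tests whether a unit's guides fall beyond the library-wide null median
#' more often than chance. With `x` = number of the unit's `n` guides beyond
#' the median in the tested direction and null probability `p0` (0.5 for a
#' median split), the one-sided p-value is the upper binomial tail
#' `P(X >= x | n, p0)`. Guides exactly at the median count as not-beyond.
#'
#' @param values per-guide statistics for the unit (e.g. high/low log2 fold
#'   changes from [guide_lfc()]).
#' @param null_median the library-wide null median (typically of the NTC
#'   guides or all guides).
#' @param p0 null probability that a guide falls beyond the median in the
#'   tested direction (default 0.5).
#' @param direction `"depleted"` counts guides below the median (positive
#'   regulators lost from the marker-high bin), `"enriched"` guides above.
#' @param unit label carried into the result.
#' @return One-row data.frame: `unit`, `n`, `x`, `p0`, `direction`, `p`.
#' @export
binomial_enrichment <- function(values, null_median, p0 = 0.5,
                                direction = c("depleted", "enriched"),
                                unit = NA_character_) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("need >= 1 finite guide value")
  x <- if (direction == "depleted") sum(values < null_median) else
    sum(values > null_median)
  p <- stats::pbinom(x - 1, size = n, prob = p0, lower.tail = FALSE)
  data.frame(unit = unit, n = n, x = x, p0 = p0, direction = direction,
             p = p, stringsAsFactors = FALSE)
}

#' Binomial test per gene and per module over a guide-statistic table
#'
#' Applies [binomial_enrichment()] to each gene's guides, and pools all
#' guides of a module's member genes into one module-level test with the
#' same rule.
#'
#' @param guide_stats data.frame with columns `gene` and a statistic column.
#' @param modules named list of member-gene vectors (see
#'   [read_module_list()]); may be `NULL` for gene-level results only.
#' @param stat name of the statistic column (default `"lfc"`).
#' @param null_median null median; default the median of the statistic over
#'   NTC guides if an `is_ntc` column exists, otherwise over all guides.
#' @param p0,direction see [binomial_enrichment()].
#' @param adjust apply Benjamini-Hochberg across units (default FALSE,
#'   matching per-unit significance-star reporting).
#' @return Data.frame of per-unit tests, genes first then modules, with a
#'   `level` column (`gene` / `module`) and optionally `fdr`.
#' @export
module_binomial <- function(guide_stats, modules = NULL, stat = "lfc",
                            null_median = NULL, p0 = 0.5,
                            direction = c("depleted", "enriched"),
                            adjust = FALSE) {
  direction <- match.arg(direction)
  stopifnot(stat %in% names(guide_stats), "gene" %in% names(guide_stats))
  vals <- guide_stats[[stat]]
  if (is.null(null_median)) {
    null_median <- if ("is_ntc" %in% names(guide_stats) &&
                       any(guide_stats$is_ntc)) {
      stats::median(vals[guide_stats$is_ntc], na.rm = TRUE)
    } else stats::median(vals, na.rm = TRUE)
  }
  tab <- if ("is_ntc" %in% names(guide_stats)) {
    guide_stats[!guide_stats$is_ntc, , drop = FALSE]
  } else guide_stats
  per_gene <- split(tab[[stat]], tab$gene)
  gene_res <- do.call(rbind, Map(function(v, g) {
    binomial_enrichment(v, null_median, p0, direction, unit = g)
  }, per_gene, names(per_gene)))
  gene_res$level <- "gene"
  res <- gene_res
  if (!is.null(modules)) {
    mod_res <- do.call(rbind, Map(function(members, m) {
      v <- tab[[stat]][tab$gene %in% members]
      if (length(v) == 0) stop("module ", m, " has no member guides")
      binomial_enrichment(v, null_median, p0, direction, unit = m)
    }, modules, names(modules)))
    mod_res$level <- "module"
    res <- rbind(res, mod_res)
  }
  rownames(res) <- NULL
  if (adjust) res$fdr <- stats::p.adjust(res$p, method = "BH")
  attr(res, "null_median") <- null_median
  res
}

#' N-module stability score for one subunit knockout
#'
#' Summarizes how strongly a complex I subunit knockout destabilizes the
#' electron-accepting N-module: the sum over module members of the member's
#' median log2 abundance ratio in that KO line, minus the KO subunit's own
#' term (which reflects the deletion itself, not module stability).
#'
#' @param log2_ratios subunit x KO-line numeric matrix of median log2 protein
#'   abundance ratios (rownames = subunits, colnames = KO lines).
#' @param module character vector of module member subunits.
#' @param ko the knocked-out subunit (a column of `log2_ratios`).
#' @return One-row data.frame: `ko`, `score`, `n_members`.
#' @export
n_module_score <- function(log2_ratios, module, ko) {
  log2_ratios <- as.matrix(log2_ratios)
  if (!(ko %in% colnames(log2_ratios))) stop("KO column missing: ", ko)
  missing <- setdiff(unique(c(module, ko)), rownames(log2_ratios))
  if (length(missing) > 0) {
    stop("missing subunit row: ", paste(missing, collapse = ", "))
  }
  module <- unique(module)
  score <- sum(log2_ratios[module, ko]) - log2_ratios[ko, ko]
  data.frame(ko = ko, score = score, n_members = length(module),
             stringsAsFactors = FALSE)
}

#' Stability scores for every knockout column
#'
#' @inheritParams n_module_score
#' @param kos KO lines to score (default: all columns present as rows too).
#' @return Data.frame of [n_module_score()] rows.
#' @export
n_module_scores <- function(log2_ratios, module, kos = NULL) {
  log2_ratios <- as.matrix(log2_ratios)
  if (is.null(kos)) {
    kos <- intersect(colnames(log2_ratios), rownames(log2_ratios))
  }
  do.call(rbind, lapply(kos, function(k) {
    n_module_score(log2_ratios, module, k)
  }))
}

#' Correlate module-stability scores with selection coefficients
#'
#' Pearson correlation between each subunit's stability score and its
#' screen selection coefficient (beta), with a Fisher-z 95 percent
#' confidence interval and a two-sided t test (n - 2 degrees of freedom).
#' Listed genes (e.g. an essential subunit whose surviving guides must have
#' spared function) are excluded before pairing.
#'
#' @param scores data.frame with `ko` and `score` (see [n_module_scores()]).
#' @param betas named numeric vector of per-gene selection coefficients.
#' @param exclude genes to drop before correlating.
#' @param conf_level confidence level for the Fisher-z interval.
#' @return List of class `stability_correlation`: `r`, `conf_int`, `p`, `n`,
#'   `excluded`, `pairs` (the matched table).
#' @export
stability_beta_correlation <- function(scores, betas, exclude = character(),
                                       conf_level = 0.95) {
  keep <- !(scores$ko %in% exclude) & scores$ko %in% names(betas)
  pairs <- data.frame(ko = scores$ko[keep], score = scores$score[keep],
                      beta = unname(betas[scores$ko[keep]]),
                      stringsAsFactors = FALSE)
  n <- nrow(pairs)
  if (n < 3) stop("need >= 3 paired observations after exclusion, have ", n)
  r <- stats::cor(pairs$score, pairs$beta)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  fz <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(fz + c(-1, 1) * zq / sqrt(n - 3))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(r = r, conf_int = ci, p = p, n = n,
                 excluded = intersect(exclude, scores$ko), pairs = pairs),
            class = "stability_correlation")
}

#' @export
print.stability_correlation <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.4f (95%% CI %.4f-%.4f), p = %.3g, n = %d%s\n",
    x$r, x$conf_int[1], x$conf_int[2], x$p, x$n,
    if (length(x$excluded)) paste0("; excluded: ",
                                   paste(x$excluded, collapse = ", ")) else ""
  ))
  invisible(x)
}
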