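#' Run the full screen-analysis chain on one screen object
#'
#' Orchestrates the stages in order: median normalization, dispersion fit,
#' marker-blind MLE (plus optional marker-aware high/low fits), Stouffer
#' integration into the ranked gene score, optional preranked gene-set
#' enrichment, optional binomial gene/module tests, and optional clustering
#' of the most selected genes. Deterministic for a fixed seed; no stage
#' mutates its inputs. A manifest recording parameters, seed and package
#' version is attached to the result.
#'
#' @param screen a [screen_counts()] object (raw counts).
#' @param collection optional gene-set collection for GSEA.
#' @param modules optional named module list for the binomial tests.
#' @param marker_aware also run the marker-aware high and low fits (default
#'   TRUE when the sheet has >= 2 markers).
#' @param pseudocount pseudocount for guide log2 fold changes.
#' @param gsea_min,gsea_max,n_perm gene-set size window and permutations.
#' @param cluster_fraction,cluster_k parameters of
#'   [top_fraction_cluster()]; clustering is skipped when fewer eligible
#'   genes than `cluster_k` exist or fewer than 2 markers were screened.
#' @param seed seed for every stochastic stage.
#' @return List of class `screen_pipeline`: `normalized`, `dispersion`,
#'   `mle_blind`, `mle_aware_high`, `mle_aware_low`, `combined`, `lfc`,
#'   `ntc_test`, `gsea`, `module_test`, `clusters`, `manifest`.
#' @export
run_screen_pipeline <- function(screen, collection = NULL, modules = NULL,
                                marker_aware = NULL, pseudocount = 1,
                                gsea_min = 10, gsea_max = 500, n_perm = 1000,
                                cluster_fraction = 0.05, cluster_k = 8,
                                seed = 1) {
  t0 <- Sys.time()
  stopifnot(inherits(screen, "screen_counts"))
  markers <- unique(screen$samples$marker[!is.na(screen$samples$marker)])
  if (is.null(marker_aware)) marker_aware <- length(markers) >= 2

  norm <- median_normalize(screen)
  disp <- fit_dispersion(norm)
  lfc <- all_guide_lfc(norm, pseudocount = pseudocount)
  ntc_test <- ntc_compare(lfc)

  mle_blind <- fit_all(norm, design_marker_blind(norm$samples),
                       dispersion = disp, seed = seed)
  mle_hi <- mle_lo <- NULL
  if (marker_aware) {
    mle_hi <- fit_all(norm, design_marker_aware(norm$samples, "high"),
                      dispersion = disp, seed = seed)
    mle_lo <- fit_all(norm, design_marker_aware(norm$samples, "low"),
                      dispersion = disp, seed = seed)
  }
  combined <- combine_screens(mle_blind)

  gsea_res <- NULL
  if (!is.null(collection)) {
    stats_vec <- stats::setNames(combined$gene_score, combined$gene)
    gsea_res <- gsea_preranked(stats_vec, collection, min_size = gsea_min,
                               max_size = gsea_max, n_perm = n_perm,
                               seed = seed)
  }
  module_test <- NULL
  if (!is.null(modules)) {
    module_test <- module_binomial(lfc, modules)
  }
  clusters <- NULL
  if (marker_aware && !is.null(mle_lo)) {
    bm <- beta_matrix(mle_lo)
    n_tail <- max(1L, ceiling(cluster_fraction / 2 * nrow(bm)))
    if (length(unique(as.vector(bm))) > 1 &&
        2 * n_tail * ncol(bm) >= cluster_k) {
      clusters <- tryCatch(
        top_fraction_cluster(bm, fraction = cluster_fraction,
                             k = cluster_k, seed = seed),
        error = function(e) NULL
      )
    }
  }
  manifest <- list(
    stages = c("normalize", "dispersion", "lfc", "ntc_test", "mle_blind",
               if (marker_aware) c("mle_aware_high", "mle_aware_low"),
               "integrate", if (!is.null(gsea_res)) "gsea",
               if (!is.null(module_test)) "module_test",
               if (!is.null(clusters)) "cluster"),
    parameters = list(pseudocount = pseudocount, gsea_min = gsea_min,
                      gsea_max = gsea_max, n_perm = n_perm,
                      cluster_fraction = cluster_fraction,
                      cluster_k = cluster_k),
    seed = seed,
    n_guides = nrow(screen$counts), n_samples = ncol(screen$counts),
    package_version = as.character(utils::packageVersion("sortscreen")),
    started = t0, finished = Sys.time()
  )
  structure(list(normalized = norm, dispersion = disp, lfc = lfc,
                 ntc_test = ntc_test, mle_blind = mle_blind,
                 mle_aware_high = mle_hi, mle_aware_low = mle_lo,
                 combined = combined, gsea = gsea_res,
                 module_test = module_test, clusters = clusters,
                 manifest = manifest),
            class = "screen_pipeline")
}

#' Reshape a marker-aware fit into a genes x screens beta matrix
#'
#' @param fit a [fit_all()] table from a marker-aware design.
#' @return Numeric matrix, genes x conditions, NTC pseudo-genes dropped.
#' @export
beta_matrix <- function(fit) {
  fit <- fit[!fit$is_ntc_pseudo, , drop = FALSE]
  conds <- unique(fit$condition)
  genes <- unique(fit$gene)
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  m[cbind(match(fit$gene, genes), match(fit$condition, conds))] <- fit$beta
  m
}

#' @export
print.screen_pipeline <- function(x, ...) {
  cat("screen_pipeline:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat("  top of ranked list:",
      paste(utils::head(x$combined$gene, 5), collapse = ", "), "\n")
  invisible(x)
}
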