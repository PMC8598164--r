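#' Configuration for the synthetic sorting-screen generator
#'
#' Defaults emulate the structure of a genome-scale FACS screen at desk
#' scale: `n_genes` protein-coding genes with four guides each plus 1000
#' non-targeting controls, three markers screened in duplicate, 15 percent
#' high/low sort gates set as population quantiles, log-normal baseline
#' guide abundances, Beta(5, 1.5) guide efficiencies (most guides cut well,
#' some are weak), and ten planted shared positive regulators whose knockout
#' lowers the latent marker by four latent-noise standard deviations.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per gene (default 4).
#' @param n_ntc number of non-targeting control guides (default 1000).
#' @param markers marker names screened (default MHCII, CD40, PDL1).
#' @param replicates replicate selections per marker (default 2).
#' @param cells_per_guide cells per library per guide (coverage; default
#'   250).
#' @param f_high,f_low sorted gate fractions as population quantiles
#'   (default 0.15 each; must sum to <= 1).
#' @param depth_per_guide sequenced reads per guide per sample (default
#'   400).
#' @param efficiency_shape Beta(a, b) parameters of per-guide knockout
#'   efficiency.
#' @param sigma latent marker noise standard deviation (default 1; effect
#'   sizes `delta_*` are expressed in units of `sigma`).
#' @param abundance_sdlog log-normal sd of baseline guide abundance.
#' @param n_positive,delta_positive shared positive regulators (knockout
#'   lowers all markers) and their latent shift in sigma units.
#' @param n_negative,delta_negative shared negative regulators (knockout
#'   raises all markers).
#' @param n_marker_specific,delta_marker_specific marker-specific
#'   regulators, assigned to markers in rotation.
#' @param custom_deltas optional numeric vector of per-gene latent shifts
#'   (sigma units, applied to all markers) planted into the first
#'   `length(custom_deltas)` genes, overriding the role-based effects; genes
#'   with a nonzero custom shift carry role `custom`.
#' @param seed RNG seed recorded in the output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, guides_per_gene = 4, n_ntc = 1000,
                       markers = c("MHCII", "CD40", "PDL1"), replicates = 2,
                       cells_per_guide = 250, f_high = 0.15, f_low = 0.15,
                       depth_per_guide = 400,
                       efficiency_shape = c(5, 1.5), sigma = 1,
                       abundance_sdlog = 0.3,
                       n_positive = 10, delta_positive = -4,
                       n_negative = 0, delta_negative = 4,
                       n_marker_specific = 0, delta_marker_specific = -4,
                       custom_deltas = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (f_high + f_low > 1) stop("f_high + f_low must be <= 1")
  if (f_high <= 0 || f_low <= 0) stop("gate fractions must be positive")
  if (n_positive + n_negative + n_marker_specific > n_genes) {
    stop("more planted regulators than genes")
  }
  if (length(custom_deltas) > n_genes) {
    stop("more custom deltas than genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a FACS-sorted CRISPR screen with known ground truth
#'
#' Fully seeded generative model: (1) baseline guide abundances are drawn
#' log-normal; (2) for each marker x replicate, cells are assigned to guides
#' multinomially and each cell receives a latent marker value `efficiency *
#' delta(gene, marker) * sigma + Normal(0, sigma)`; (3) cells are sorted
#' into high/low bins by population quantile gates, so bin occupancies equal
#' the configured fractions exactly; (4) per-bin guide tallies are
#' multinomially subsampled to the sequencing depth; (5) one input sample
#' per replicate is drawn from the pre-sort cell pool.
#'
#' @param config a [sim_config()].
#' @return List with `screen` (a [screen_counts()] of all samples), `truth`
#'   (list `genes`: gene, role, per-marker delta; `guides`: guide_id, gene,
#'   efficiency; `sort_stats`: pre-sequencing cells per sorted bin), and
#'   `config`.
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_screen_impl(config))
}

simulate_screen_impl <- function(cfg) {
  genes <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  roles <- rep("null", cfg$n_genes)
  idx <- 0
  if (cfg$n_positive > 0) {
    roles[idx + seq_len(cfg$n_positive)] <- "positive_regulator"
    idx <- idx + cfg$n_positive
  }
  if (cfg$n_negative > 0) {
    roles[idx + seq_len(cfg$n_negative)] <- "negative_regulator"
    idx <- idx + cfg$n_negative
  }
  if (cfg$n_marker_specific > 0) {
    roles[idx + seq_len(cfg$n_marker_specific)] <- "marker_specific"
  }
  delta <- matrix(0, cfg$n_genes, length(cfg$markers),
                  dimnames = list(genes, cfg$markers))
  delta[roles == "positive_regulator", ] <- cfg$delta_positive
  delta[roles == "negative_regulator", ] <- cfg$delta_negative
  ms <- which(roles == "marker_specific")
  for (i in seq_along(ms)) {
    delta[ms[i], 1 + (i - 1) %% length(cfg$markers)] <-
      cfg$delta_marker_specific
  }
  if (length(cfg$custom_deltas) > 0) {
    k <- length(cfg$custom_deltas)
    delta[seq_len(k), ] <- cfg$custom_deltas
    roles[seq_len(k)] <- ifelse(cfg$custom_deltas != 0, "custom", "null")
  }

  lib <- guide_library(
    guide_id = c(paste0(rep(genes, each = cfg$guides_per_gene), "_g",
                        seq_len(cfg$guides_per_gene)),
                 sprintf("NTC_%04d", seq_len(cfg$n_ntc))),
    gene = c(rep(genes, each = cfg$guides_per_gene),
             rep("NTC", cfg$n_ntc)),
    ntc_label = "NTC"
  )
  n_guides <- nrow(lib)
  gene_of <- match(lib$gene, genes)            # NA for NTC
  eff <- stats::rbeta(n_guides, cfg$efficiency_shape[1],
                      cfg$efficiency_shape[2])
  eff[lib$is_ntc] <- 0
  w <- stats::rlnorm(n_guides, 0, cfg$abundance_sdlog)
  w <- w / sum(w)

  n_cells <- round(cfg$cells_per_guide * n_guides)
  depth <- round(cfg$depth_per_guide * n_guides)
  k_low <- round(cfg$f_low * n_cells)
  k_high <- round(cfg$f_high * n_cells)
  if (k_low < 1 || k_high < 1 || k_low + k_high > n_cells) {
    stop("infeasible gates for ", n_cells, " cells")
  }

  samples <- list(); counts <- list(); sort_stats <- list()
  for (r in seq_len(cfg$replicates)) {
    pool <- as.integer(stats::rmultinom(1, n_cells, w))
    sid <- paste0("input_r", r)
    samples[[sid]] <- data.frame(sample_id = sid, marker = NA_character_,
                                 replicate = r, bin = "input")
    counts[[sid]] <- as.integer(stats::rmultinom(1, depth, pool))
    for (mi in seq_along(cfg$markers)) {
      mk <- cfg$markers[mi]
      cells <- as.integer(stats::rmultinom(1, n_cells, w))
      gidx <- rep.int(seq_len(n_guides), cells)
      shift <- ifelse(is.na(gene_of), 0, delta[cbind(gene_of, mi)]) *
        eff * cfg$sigma
      latent <- shift[gidx] + stats::rnorm(length(gidx), 0, cfg$sigma)
      t_low <- sort(latent, partial = k_low)[k_low]
      t_high <- sort(latent, partial = length(latent) - k_high + 1)[
        length(latent) - k_high + 1]
      low_tally <- tabulate(gidx[latent <= t_low], nbins = n_guides)
      high_tally <- tabulate(gidx[latent >= t_high], nbins = n_guides)
      for (b in c("high", "low")) {
        sid <- paste0(mk, "_", b, "_r", r)
        samples[[sid]] <- data.frame(sample_id = sid, marker = mk,
                                     replicate = r, bin = b)
        tally <- if (b == "high") high_tally else low_tally
        counts[[sid]] <- as.integer(stats::rmultinom(1, depth, tally))
        sort_stats[[sid]] <- data.frame(
          sample_id = sid, marker = mk, replicate = r, bin = b,
          cells_in_bin = sum(tally), n_cells = length(gidx),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  sheet_df <- do.call(rbind, samples)
  sheet <- sample_sheet(sheet_df$sample_id, sheet_df$marker,
                        sheet_df$replicate, sheet_df$bin)
  mat <- do.call(cbind, counts)
  rownames(mat) <- lib$guide_id
  screen <- screen_counts(mat, lib, sheet)
  truth <- list(
    genes = data.frame(gene = genes, role = roles, delta,
                       row.names = NULL, stringsAsFactors = FALSE,
                       check.names = FALSE),
    guides = data.frame(guide_id = lib$guide_id, gene = lib$gene,
                        efficiency = eff, baseline_weight = w,
                        row.names = NULL, stringsAsFactors = FALSE),
    sort_stats = do.call(rbind, c(sort_stats, make.row.names = FALSE))
  )
  list(screen = screen, truth = truth, config = cfg)
}

#' Generate a synthetic subunit-knockout proteomics matrix
#'
#' A labelled synthetic stand-in for subunit-KO proteomics of a protein
#' complex: for each knockout line, module-member proteins drop by an amount
#' proportional to the KO's latent destabilization strength, the knocked-out
#' protein itself is strongly depleted, and non-members stay near zero.
#' Useful for exercising [n_module_scores()] and
#' [stability_beta_correlation()] without the external dataset.
#'
#' @param subunits character vector of subunit names (rows and KO columns).
#' @param module subset of `subunits` forming the scored module.
#' @param strength named destabilization strength per KO line in \[0, 1\];
#'   default drawn uniformly.
#' @param member_drop maximal median log2 drop of a module member under a
#'   fully destabilizing KO (default -2).
#' @param own_drop median log2 ratio of the knocked-out protein itself
#'   (default -4).
#' @param noise_sd measurement noise on each median log2 ratio.
#' @param seed RNG seed.
#' @return List: `log2_ratios` (subunit x KO matrix), `strength`.
#' @export
simulate_subunit_proteomics <- function(subunits, module,
                                        strength = NULL,
                                        member_drop = -2, own_drop = -4,
                                        noise_sd = 0.25, seed = 1) {
  stopifnot(all(module %in% subunits))
  with_seed(seed, {
    if (is.null(strength)) {
      strength <- stats::setNames(stats::runif(length(subunits)), subunits)
    }
    m <- matrix(stats::rnorm(length(subunits)^2, 0, noise_sd),
                length(subunits), length(subunits),
                dimnames = list(subunits, subunits))
    for (ko in subunits) {
      m[module, ko] <- m[module, ko] + member_drop * strength[ko]
      m[ko, ko] <- own_drop + stats::rnorm(1, 0, noise_sd)
    }
    list(log2_ratios = m, strength = strength)
  })
}

#' Evaluate recovery of planted regulators from a ranked result
#'
#' @param ranked a ranked table with `gene` and `rank` columns (e.g. from
#'   [combine_screens()]), or a [fit_all()] table (ranked ascending by beta
#'   of its first condition).
#' @param truth the `truth` element of [simulate_screen()].
#' @param top_n size of the top list to evaluate (default 20).
#' @return List: `recall` (fraction of planted regulators in the top
#'   `top_n`; `NA` when no regulators were planted), `n_regulators`,
#'   `ntc_pseudo_in_top` and `ntc_pseudo_fdr` (NTC pseudo-genes ranked in
#'   the top list, count and fraction), `top_genes`.
#' @export
truth_eval <- function(ranked, truth, top_n = 20) {
  if (!("rank" %in% names(ranked))) {
    stopifnot(all(c("gene", "beta") %in% names(ranked)))
    first <- ranked$condition == ranked$condition[1]
    ranked <- ranked[first, , drop = FALSE]
    ranked <- ranked[order(ranked$beta), , drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
  }
  top <- ranked$gene[ranked$rank <= top_n]
  regulators <- truth$genes$gene[truth$genes$role != "null"]
  ntc_top <- sum(grepl("^NTC_pseudo", top))
  list(
    recall = if (length(regulators) == 0) NA_real_ else
      mean(regulators %in% top),
    n_regulators = length(regulators),
    ntc_pseudo_in_top = ntc_top,
    ntc_pseudo_fdr = ntc_top / length(top),
    top_genes = top
  )
}
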