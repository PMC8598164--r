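#' Weighted running-sum enrichment score
#'
#' Classic gene-set enrichment statistic on a ranked list: walking down the
#' list, members of the set ("hits") increment the running sum by
#' `|score|^p / sum(|score at hits|^p)` and non-members decrement it by
#' `1 / (N - N_hits)`; the enrichment score (ES) is the signed maximum
#' deviation from zero. `p = 1` is the standard "weighted" statistic.
#'
#' @param stats named numeric vector of gene-level scores; sorted into
#'   descending order internally. Names must be unique.
#' @param set character vector of member genes.
#' @param p weight exponent (default 1).
#' @return Numeric ES in \[-1, 1\], with attributes `n_hits` and
#'   `degenerate` (TRUE when the set covers the whole list, in which case the
#'   miss term is absent and the score is computed from the hit increments
#'   alone).
#' @export
enrichment_score <- function(stats, set, p = 1) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be uniquely named by gene")
  }
  stats <- sort(stats, decreasing = TRUE)
  hit_pos <- which(names(stats) %in% set)
  if (length(hit_pos) == 0) stop("set has no genes in the ranked list")
  es <- es_from_positions(hit_pos, abs(stats)^p, length(stats))
  attr(es, "n_hits") <- length(hit_pos)
  attr(es, "degenerate") <- length(hit_pos) == length(stats)
  es
}

# ES from sorted hit positions; weights = |score|^p over the whole list.
# Running-sum extrema only occur at hits (just after) and just before hits,
# so only those 2*Nh candidate values are evaluated.
es_from_positions <- function(pos, weights, N) {
  nh <- length(pos)
  w <- weights[pos]
  nr <- sum(w)
  hit_cum <- if (nr > 0) cumsum(w) / nr else seq_len(nh) / nh
  if (nh == N) {                         # degenerate: no misses
    return(max(hit_cum))
  }
  miss <- (pos - seq_len(nh)) / (N - nh) # miss mass accrued before hit k
  tops <- hit_cum - miss
  bottoms <- c(0, hit_cum[-nh]) - miss
  hi <- max(tops)
  lo <- min(bottoms)
  if (hi >= -lo - 1e-12) hi else lo     # exact ties resolve positive
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted ES for each set against a ranked score list, then a
#' seeded gene-label permutation null (random sets of matching size drawn
#' from the list). Normalization is sign-matched mean division: NES = ES
#' divided by the mean |null ES| of the same sign. The nominal p comes from
#' the same-sign null tail, and the FDR q from the standard ratio of pooled
#' normalized-null exceedance to observed exceedance, clamped to \[0, 1\].
#'
#' @param stats named numeric vector of gene scores (any order; sorted
#'   descending internally).
#' @param collection a `gene_set_collection` (see [read_gmt()]) or named list
#'   of character vectors.
#' @param min_size,max_size set-size window after intersecting with the
#'   ranked list (defaults 10 and 500).
#' @param n_perm permutations per set (default 1000).
#' @param p weight exponent for the ES (default 1).
#' @param seed RNG seed; identical seeds give identical tables.
#' @return Data.frame sorted by decreasing NES: `set`, `size`, `es`, `nes`,
#'   `p_value`, `fdr_q`. Sets with no genes in the list are skipped with a
#'   warning.
#' @export
gsea_preranked <- function(stats, collection, min_size = 10, max_size = 500,
                           n_perm = 1000, p = 1, seed = 1) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be uniquely named by gene")
  }
  stats <- sort(stats, decreasing = TRUE)
  N <- length(stats)
  absp <- abs(stats)^p
  genes <- names(stats)

  sizes0 <- vapply(collection, function(s) sum(genes %in% s), 0L)
  skip <- sizes0 == 0
  if (any(skip)) {
    warning(sum(skip), " set(s) with no genes in the ranked list skipped")
  }
  keep <- !skip & sizes0 >= min_size & sizes0 <= max_size
  sets <- collection[keep]
  sizes <- sizes0[keep]
  if (length(sets) == 0) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(),
                      fdr_q = numeric()))
  }

  es_obs <- vapply(seq_along(sets), function(i) {
    es_from_positions(which(genes %in% sets[[i]]), absp, N)
  }, 0)

  null_es <- with_seed(seed, {
    lapply(sizes, function(s) {
      vapply(seq_len(n_perm), function(j) {
        es_from_positions(sort.int(sample.int(N, s)), absp, N)
      }, 0)
    })
  })

  norm_one <- function(es, null) {
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    nes <- ifelse(es >= 0, es / pos_mean, es / neg_mean)
    null_nes <- ifelse(null >= 0, null / pos_mean, null / neg_mean)
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    p_val <- if (length(same) == 0) NA_real_ else
      sum(abs(same) >= abs(es)) / length(same)
    list(nes = nes, null_nes = null_nes, p = p_val)
  }
  normed <- Map(norm_one, es_obs, null_es)
  nes <- vapply(normed, `[[`, 0, "nes")
  p_val <- vapply(normed, `[[`, 0, "p")
  pooled <- unlist(lapply(normed, `[[`, "null_nes"))

  fdr_q <- vapply(nes, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num_d <- sum(pooled >= 0); obs_d <- sum(nes >= 0)
      num <- if (num_d > 0) sum(pooled >= v) / num_d else 0
      den <- if (obs_d > 0) sum(nes >= v) / obs_d else 1
    } else {
      num_d <- sum(pooled < 0); obs_d <- sum(nes < 0)
      num <- if (num_d > 0) sum(pooled <= v) / num_d else 0
      den <- if (obs_d > 0) sum(nes <= v) / obs_d else 1
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, 0)

  out <- data.frame(
    set = names(sets), size = as.integer(sizes), es = es_obs, nes = nes,
    p_value = p_val, fdr_q = fdr_q, row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$nes), , drop = FALSE]
}
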