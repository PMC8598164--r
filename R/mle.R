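#' Marker-blind design matrix
#'
#' Builds the design used for the combined analysis: two conditions, one for
#' all low-bin samples and one for all high-bin samples, pooling the three
#' marker screens so that every sorted selection acts as a replicate
#' measurement. Input libraries form the implicit baseline (all-zero rows).
#'
#' @param sheet a [sample_sheet()].
#' @return A samples x conditions 0/1 matrix with rownames = sample ids and
#'   colnames `c("low", "high")`; baseline (input) rows are all zero.
#' @export
design_marker_blind <- function(sheet) {
  if (!any(sheet$bin %in% c("high", "low"))) stop("no sorted samples")
  d <- cbind(
    low = as.numeric(sheet$bin == "low"),
    high = as.numeric(sheet$bin == "high")
  )
  rownames(d) <- sheet$sample_id
  d[, colSums(d) > 0, drop = FALSE]
}

#' Marker-aware, bin-specific design matrix
#'
#' One condition per marker, restricted to the requested bin, to test for
#' marker-specific effects: e.g. the low-bin design contrasts MHCII-low vs
#' CD40-low vs PD-L1-low against the input baseline.
#'
#' @param sheet a [sample_sheet()].
#' @param bin `"high"` or `"low"`.
#' @return A samples x markers 0/1 matrix; samples not in the requested bin
#'   (including inputs) have all-zero rows. Columns are named by marker.
#' @export
design_marker_aware <- function(sheet, bin = c("low", "high")) {
  bin <- match.arg(bin)
  markers <- unique(sheet$marker[!is.na(sheet$marker)])
  if (length(markers) == 0) stop("no sorted samples")
  missing <- markers[!vapply(markers, function(m) {
    any(sheet$marker %in% m & sheet$bin == bin)
  }, TRUE)]
  if (length(missing) > 0) {
    stop("marker without a ", bin, " bin: ", paste(missing, collapse = ", "))
  }
  d <- vapply(markers, function(m) {
    as.numeric(sheet$marker %in% m & sheet$bin == bin)
  }, numeric(nrow(sheet)))
  d <- matrix(d, nrow = nrow(sheet), dimnames = list(sheet$sample_id, markers))
  d
}

#' Estimate per-guide negative-binomial dispersions
#'
#' Method-of-moments dispersion per guide, `alpha = max(floor,
#' (s^2 - m) / m^2)` on normalized counts, shrunk on the log scale toward a
#' trend in log mean fitted by least squares across guides. The trend borrows
#' strength across the library; the floor keeps the NB well-defined for
#' guides with no excess variance.
#'
#' @param x a normalized [screen_counts()] object or a matrix of normalized
#'   counts.
#' @param floor minimal dispersion (default 1e-4).
#' @param shrink weight of the per-guide estimate vs the trend, in \[0,1\];
#'   0.5 by default.
#' @return List of class `dispersion_model`: `alpha` (named per-guide vector),
#'   `trend` (intercept/slope on log alpha ~ log mean), `floor`.
#' @export
fit_dispersion <- function(x, floor = 1e-4, shrink = 0.5) {
  mat <- if (inherits(x, "screen_counts")) {
    if (is.null(x$norm_counts)) stop("run median_normalize() first")
    x$norm_counts
  } else as.matrix(x)
  if (ncol(mat) < 2) stop("need >= 2 samples to estimate dispersion")
  m <- rowMeans(mat)
  v <- apply(mat, 1, stats::var)
  raw <- pmax(floor, (v - m) / pmax(m, 1e-8)^2)
  ok <- m > 0 & raw > floor
  if (sum(ok) >= 10) {
    fit <- stats::lm.fit(cbind(1, log(m[ok])), log(raw[ok]))
    co <- fit$coefficients
  } else {
    co <- c(log(pmax(stats::median(raw), floor)), 0)
  }
  trend <- pmax(floor, exp(co[1] + co[2] * log(pmax(m, 1e-8))))
  alpha <- pmax(floor, exp(shrink * log(raw) + (1 - shrink) * log(trend)))
  alpha[m == 0] <- trend[m == 0]
  names(alpha) <- rownames(mat)
  structure(list(alpha = alpha, trend = c(intercept = unname(co[1]),
                                          slope = unname(co[2])),
                 floor = floor),
            class = "dispersion_model")
}

# Negative-binomial log-likelihood pieces on the log-mean scale.
# mean_ij = sf_j * mu_i * 2^(d_j . beta); eta = log mean.
# dl/deta = y - m (y + r) / (m + r), d2l/deta2 = -m r (y + r) / (m + r)^2,
# with r = 1/alpha.
nb_loglik <- function(y, m, r) {
  sum(stats::dnbinom(y, size = r, mu = m, log = TRUE))
}

#' Fit the selection coefficient (beta) for one gene
#'
#' Maximizes the negative-binomial likelihood of one gene's guide counts with
#' a per-guide baseline abundance `mu_i` and a shared gene-level coefficient
#' vector beta on the log2 scale: the mean of guide i in sample j is
#' `sizefactor_j * mu_i * 2^(sum_k d_jk beta_k)`. Positive beta means the
#' gene's guides are enriched in that condition relative to the input
#' library. Newton iterations with step-halving on the joint
#' `(log mu, beta)` parameter; if the optimizer fails to converge a profiled
#' coordinate grid search over beta supplies the fallback. Wald z per
#' condition comes from the observed information.
#'
#' @param counts guide x sample matrix of raw counts for one gene.
#' @param design samples x conditions design matrix
#'   ([design_marker_blind()] / [design_marker_aware()]), rows matching
#'   `colnames(counts)`.
#' @param size_factors per-sample size factors (see [median_normalize()]).
#' @param alpha per-guide NB dispersion(s); recycled if length 1.
#' @param beta_bounds box constraint on each beta (log2 scale); the fit is
#'   clamped here because the unpenalized MLE diverges when a condition's
#'   counts are all zero.
#' @param max_iter,tol Newton iteration cap and log-likelihood convergence
#'   tolerance.
#' @return List: `beta`, `z`, `se`, `pos_p`/`neg_p` (one-sided Wald pair,
#'   summing to 1), `p` (two-sided), `mu`, `loglik`, `converged`, `n_guides`.
#' @export
fit_gene <- function(counts, design, size_factors, alpha,
                     beta_bounds = c(-8, 8), max_iter = 200, tol = 1e-8) {
  counts <- matrix(as.numeric(counts), nrow = NROW(counts),
                   dimnames = dimnames(counts))
  G <- nrow(counts)
  S <- ncol(counts)
  design <- as.matrix(design)
  stopifnot(nrow(design) == S, length(size_factors) == S)
  K <- ncol(design)
  if (length(alpha) == 1) alpha <- rep(alpha, G)
  r <- 1 / alpha                              # per-guide NB size
  ln2 <- log(2)
  lsf <- log(size_factors)

  y <- counts                                  # G x S
  # start: mu from baseline samples if any, else overall mean
  base <- rowSums(design != 0) == 0
  mu0 <- if (any(base)) {
    rowMeans(sweep(y[, base, drop = FALSE], 2, size_factors[base], "/"))
  } else rowMeans(sweep(y, 2, size_factors, "/"))
  u <- log(pmax(mu0, 0.5))                     # log mu per guide
  beta <- rep(0, K)

  eta_fun <- function(u, beta) {
    outer(u, lsf, "+") + matrix(rep(ln2 * drop(design %*% beta), each = G),
                                nrow = G)
  }
  ll_fun <- function(u, beta) {
    m <- exp(eta_fun(u, beta))
    sum(stats::dnbinom(y, size = r, mu = m, log = TRUE))
  }

  ll <- ll_fun(u, beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- exp(eta_fun(u, beta))
    W1 <- y - m * (y + r) / (m + r)            # dl/deta, G x S
    W2 <- m * r * (y + r) / (m + r)^2          # -d2l/deta2, G x S
    gu <- rowSums(W1)                          # grad wrt u_i
    gb <- ln2 * as.numeric(t(design) %*% colSums(W1))
    # active box constraints: frozen out of the Newton system
    fixed <- (beta <= beta_bounds[1] + 1e-12 & gb < 0) |
      (beta >= beta_bounds[2] - 1e-12 & gb > 0)
    free <- which(!fixed)
    Huu <- rowSums(W2)
    Hub <- ln2 * (W2 %*% design)               # G x K
    Hbb <- ln2^2 * t(design) %*% diag(colSums(W2), S) %*% design
    info <- rbind(cbind(diag(Huu, G), Hub[, free, drop = FALSE]),
                  cbind(t(Hub[, free, drop = FALSE]),
                        Hbb[free, free, drop = FALSE]))
    nf <- length(free)
    step <- tryCatch(solve(info + diag(1e-10, G + nf), c(gu, gb[free])),
                     error = function(e) NULL)
    if (is.null(step)) break
    sz <- 1
    stuck <- FALSE
    repeat {
      u_new <- u + sz * step[seq_len(G)]
      b_new <- beta
      if (nf > 0) {
        b_new[free] <- pmin(beta_bounds[2],
                            pmax(beta_bounds[1],
                                 beta[free] + sz * step[G + seq_len(nf)]))
      }
      ll_new <- ll_fun(u_new, b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) { stuck <- TRUE; break }
    }
    if (stuck) break                     # hand over to the grid fallback
    done <- abs(ll_new - ll) < tol &&
      max(abs(c(u_new - u, b_new - beta))) < 1e-6
    u <- u_new; beta <- b_new; ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    # profiled coordinate grid fallback: coarse then refined per condition
    for (pass in 1:2) {
      stepw <- if (pass == 1) 0.05 else 0.005
      for (k in seq_len(K)) {
        grid <- seq(beta_bounds[1], beta_bounds[2], by = stepw)
        lls <- vapply(grid, function(b) {
          bb <- beta; bb[k] <- b
          ll_fun(u, bb)
        }, 0)
        beta[k] <- grid[which.max(lls)]
      }
      # refresh u by short Newton on u alone
      for (j in 1:25) {
        m <- exp(eta_fun(u, beta))
        W1 <- y - m * (y + r) / (m + r)
        W2 <- m * r * (y + r) / (m + r)^2
        u <- u + rowSums(W1) / pmax(rowSums(W2), 1e-10)
      }
    }
    ll <- ll_fun(u, beta)
  }

  # Wald from observed information at the optimum
  m <- exp(eta_fun(u, beta))
  W2 <- m * r * (y + r) / (m + r)^2
  Huu <- rowSums(W2)
  Hub <- ln2 * (W2 %*% design)
  Hbb <- ln2^2 * t(design) %*% diag(colSums(W2), S) %*% design
  # beta covariance = Schur complement of the u block
  Vbb <- tryCatch({
    schur <- Hbb - t(Hub) %*% (Hub / pmax(Huu, 1e-10))
    solve(schur + diag(1e-10, K))
  }, error = function(e) matrix(NA_real_, K, K))
  se <- sqrt(pmax(diag(Vbb), 0))
  z <- beta / se
  z[!is.finite(z)] <- 0
  pos_p <- stats::pnorm(z, lower.tail = FALSE)   # evidence for enrichment
  neg_p <- stats::pnorm(z, lower.tail = TRUE)    # evidence for depletion
  names(beta) <- names(z) <- names(se) <- colnames(design)
  list(beta = beta, z = z, se = se, pos_p = pos_p, neg_p = neg_p,
       p = 2 * stats::pnorm(-abs(z)), mu = exp(u), loglik = ll,
       converged = converged, n_guides = G)
}

#' Fit selection coefficients for every gene in a screen
#'
#' Runs [fit_gene()] per gene on raw counts with the screen's size factors
#' and dispersion model, Benjamini-Hochberg-adjusts the two-sided Wald
#' p-values per condition across genes, and (by default) assembles NTC
#' pseudo-genes — random, seeded partitions of the non-targeting guides into
#' groups the size of a typical gene — fitted identically to supply an
#' empirical null. The pseudo-gene z distribution yields an NTC-based
#' empirical p (`ntc_p`) and its BH adjustment (`ntc_fdr`) per condition.
#'
#' @param x a normalized [screen_counts()].
#' @param design samples x conditions design matrix.
#' @param dispersion optional [fit_dispersion()] result; fitted if `NULL`.
#' @param ntc_pseudo assemble NTC pseudo-genes? Default `TRUE`.
#' @param ntc_group_size guides per pseudo-gene (default 4, a typical gene).
#' @param seed seed for the NTC partition, recorded in the result's
#'   attributes.
#' @param beta_bounds passed to [fit_gene()].
#' @return Long-format data.frame, one row per gene x condition: `gene`,
#'   `condition`, `beta`, `z`, `pos_p`, `neg_p`, `p`, `fdr`, `ntc_p`,
#'   `ntc_fdr`, `n_guides`, `converged`, `is_ntc_pseudo`. Attributes:
#'   `seed`, `conditions`.
#' @export
fit_all <- function(x, design, dispersion = NULL, ntc_pseudo = TRUE,
                    ntc_group_size = 4, seed = 1, beta_bounds = c(-8, 8)) {
  stopifnot(inherits(x, "screen_counts"))
  if (is.null(x$size_factors)) stop("run median_normalize() first")
  if (is.null(dispersion)) dispersion <- fit_dispersion(x)
  design <- as.matrix(design)[colnames(x$counts), , drop = FALSE]
  lib <- x$library

  genes <- unique(lib$gene[!lib$is_ntc])
  units <- split(lib$guide_id[!lib$is_ntc], lib$gene[!lib$is_ntc])[genes]
  pseudo_flag <- rep(FALSE, length(units))

  if (ntc_pseudo) {
    ntc_ids <- lib$guide_id[lib$is_ntc]
    if (length(ntc_ids) >= ntc_group_size) {
      perm <- with_seed(seed, sample(ntc_ids))
      n_grp <- floor(length(perm) / ntc_group_size)
      grp <- split(perm[seq_len(n_grp * ntc_group_size)],
                   rep(seq_len(n_grp), each = ntc_group_size))
      names(grp) <- sprintf("NTC_pseudo_%03d", seq_len(n_grp))
      units <- c(units, grp)
      pseudo_flag <- c(pseudo_flag, rep(TRUE, n_grp))
    }
  }

  K <- ncol(design)
  res <- vector("list", length(units))
  for (i in seq_along(units)) {
    ids <- units[[i]]
    fit <- fit_gene(x$counts[ids, , drop = FALSE], design,
                    x$size_factors, dispersion$alpha[ids],
                    beta_bounds = beta_bounds)
    res[[i]] <- data.frame(
      gene = names(units)[i], condition = colnames(design),
      beta = unname(fit$beta), z = unname(fit$z),
      pos_p = unname(fit$pos_p), neg_p = unname(fit$neg_p),
      p = unname(fit$p), n_guides = fit$n_guides,
      converged = fit$converged, is_ntc_pseudo = pseudo_flag[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (any(!out$converged)) {
    warning(sum(!out$converged) / K, " gene(s) flagged non-converged; ",
            "beta from best iterate")
  }
  out$fdr <- NA_real_
  out$ntc_p <- NA_real_
  out$ntc_fdr <- NA_real_
  for (cond in colnames(design)) {
    sel <- out$condition == cond & !out$is_ntc_pseudo
    out$fdr[sel] <- stats::p.adjust(out$p[sel], method = "BH")
    null_z <- abs(out$z[out$condition == cond & out$is_ntc_pseudo])
    if (length(null_z) >= 20) {
      zz <- abs(out$z[sel])
      out$ntc_p[sel] <- (1 + vapply(zz, function(v) sum(null_z >= v), 0L)) /
        (1 + length(null_z))
      out$ntc_fdr[sel] <- stats::p.adjust(out$ntc_p[sel], method = "BH")
    }
  }
  attr(out, "seed") <- seed
  attr(out, "conditions") <- colnames(design)
  out
}

# evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
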