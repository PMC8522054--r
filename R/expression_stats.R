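# Core expression statistics: TPM, expressed-gene filtering, the
# negative-binomial differential-expression engine (leave-one-out
# intersection and trio modes), outlier z-scores with latent-factor
# correction, PAGE, and preferential-expression flags.

#' Compute transcripts-per-million from counts
#'
#' `TPM_g = (c_g / l_g) / sum_j (c_j / l_j) * 1e6` per column.
#'
#' @param counts genes x columns non-negative count matrix.
#' @param lengths per-gene lengths in bp (recycled along rows).
#' @return TPM matrix; every column sums to 1e6.
#' @examples
#' compute_tpm(matrix(c(100, 300), 2, 1), c(1000, 3000))
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop_twohit("gene lengths must be positive")
  rate <- counts / lengths
  cs <- colSums(rate)
  if (any(cs == 0)) stop_twohit("all-zero column in count matrix")
  sweep(rate, 2, cs, "/") * 1e6
}

#' Filter for expressed genes
#'
#' A gene is expressed when all replicates of at least one sample exceed
#' the TPM threshold (strictly).
#'
#' @param tpm TPM matrix with `sample.replicate` column names.
#' @param threshold TPM threshold (default 0.2).
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(tpm, threshold = 0.2) {
  samples <- sample_of_column(colnames(tpm))
  keep <- vapply(rownames(tpm), function(g) {
    x <- tpm[g, ]
    any(tapply(x > threshold, samples, all))
  }, logical(1))
  rownames(tpm)[keep]
}

# gene-wise dispersion by moment matching of the Pearson statistic to its
# residual degrees of freedom (after a Poisson pre-fit), shrunk toward a
# lowess mean-dispersion trend.  Solving
#   sum (y - mu)^2 / (mu + phi mu^2) = n - p
# accounts for the df consumed by the mean model, which a naive
# method-of-moments estimate ignores.
estimate_dispersion <- function(y, x, offset, prior_df = 10) {
  G <- nrow(y)
  phi_raw <- numeric(G)
  mu_bar <- rowMeans(y)
  p <- ncol(x)
  n <- ncol(y)
  resid_df <- max(n - p, 1)
  for (g in seq_len(G)) {
    fit <- glm.fit(x, y[g, ], family = poisson(), offset = offset)
    mu <- fit$fitted.values
    r2 <- (y[g, ] - mu)^2
    f <- function(phi) sum(r2 / (mu + phi * mu^2)) - resid_df
    phi_raw[g] <- if (f(1e-8) <= 0) 1e-6
      else if (f(50) >= 0) 50
      else stats::uniroot(f, c(1e-8, 50), tol = 1e-6)$root
  }
  phi_raw <- pmin(pmax(phi_raw, 1e-6), 50)
  lm_ab <- log(mu_bar + 0.5)
  phi_trend <- if (G >= 3 && length(unique(lm_ab)) >= 2) {
    tr <- suppressWarnings(lowess(lm_ab, phi_raw, f = 0.5))
    approx(tr$x, tr$y, xout = lm_ab, rule = 2)$y
  } else rep(median(phi_raw), G)
  phi_trend <- pmin(pmax(phi_trend, 1e-6), 50)
  w <- resid_df / (resid_df + prior_df)
  pmin(pmax(w * phi_raw + (1 - w) * phi_trend, 1e-6), 50)
}

nb_deviance <- function(x, y, offset, theta) {
  fit <- suppressWarnings(
    glm.fit(x, y, family = MASS::negative.binomial(theta = theta),
            offset = offset))
  fit
}

#' Negative-binomial differential expression test
#'
#' Per-gene NB log-linear models fitted by iteratively reweighted least
#' squares with gene-wise method-of-moments dispersions shrunk toward a
#' mean-dispersion trend; the group coefficient is tested by a
#' likelihood-ratio chi-square with 1 df and BH-adjusted across tested
#' genes.  Library-size offsets use log column totals.  Genes failing the
#' low-expression rule (fewer than `min_prop` of the smallest group's
#' replicate count having >= `min_count` reads) are excluded before
#' testing.
#'
#' @param counts integer count matrix (genes x columns).
#' @param groupA,groupB column names of the two groups (>= 2 each);
#'   `logFC` is log2 fold change of group B relative to group A.
#' @param covariates optional factor (or data.frame of factors) over
#'   `c(groupA, groupB)` columns, e.g. family.
#' @param min_count,min_prop low-expression filter.
#' @param prior_df shrinkage strength of the dispersion trend.
#' @return data.frame(gene_id, logFC, p, fdr, mean_expr, tested).
#' @export
de_test <- function(counts, groupA, groupB, covariates = NULL,
                    min_count = 10, min_prop = 0.7, prior_df = 10) {
  cols <- c(groupA, groupB)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop_twohit("each group needs >= 2 columns")
  y <- counts[, cols, drop = FALSE]
  if (any(y != round(y)) || any(y < 0))
    stop_twohit("counts must be non-negative integers")
  group <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))),
                  levels = c("A", "B"))
  dat <- data.frame(.group = group)
  if (!is.null(covariates)) {
    cv <- if (is.data.frame(covariates)) covariates
          else data.frame(.cov = covariates)
    cv[] <- lapply(cv, function(z) droplevels(factor(z)))
    dat <- cbind(dat, cv)
  }
  x_full <- stats::model.matrix(
    stats::reformulate(c(setdiff(names(dat), ".group"), ".group")), dat)
  x_red <- if (ncol(dat) > 1)
    stats::model.matrix(
      stats::reformulate(setdiff(names(dat), ".group")), dat)
  else matrix(1, nrow(dat), 1)
  if (qr(x_full)$rank < ncol(x_full))
    stop_twohit("design matrix is rank deficient")
  offset <- log(colSums(y))
  offset <- offset - mean(offset)

  n_small <- min(length(groupA), length(groupB))
  expressed <- rowSums(y >= min_count) >= min_prop * n_small
  out <- data.frame(gene_id = rownames(counts), logFC = NA_real_,
                    p = NA_real_, fdr = NA_real_,
                    mean_expr = rowMeans(y), tested = FALSE,
                    stringsAsFactors = FALSE)
  ysub <- y[expressed, , drop = FALSE]
  if (!nrow(ysub)) return(out)
  phi <- estimate_dispersion(ysub, x_full, offset, prior_df)
  gidx <- which(expressed)
  bcol <- ncol(x_full)
  for (k in seq_along(gidx)) {
    g <- gidx[k]
    res <- tryCatch({
      theta <- 1 / phi[k]
      full <- nb_deviance(x_full, y[g, ], offset, theta)
      red <- nb_deviance(x_red, y[g, ], offset, theta)
      lrt <- max(red$deviance - full$deviance, 0)
      list(logFC = unname(coef(full)[bcol]) / log(2),
           p = pchisq(lrt, df = 1, lower.tail = FALSE))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$logFC[g] <- res$logFC
      out$p[g] <- res$p
      out$tested[g] <- TRUE
    }
  }
  out$fdr[out$tested] <- bh_fdr(out$p[out$tested])
  out
}

#' Leave-one-out intersection differential expression
#'
#' Repeats the carrier-vs-noncarrier NB test once per sample, each time
#' excluding all replicates of that sample, and intersects the FDR < `fdr`
#' gene sets across iterations; family is included as a covariate.  The
#' full-data fit provides the reported fold changes.
#'
#' @param counts count matrix with `sample.replicate` columns.
#' @param ped pedigree giving carrier status and family per sample.
#' @param fdr significance threshold per iteration.
#' @param exclude_genes optional genes (e.g. sex-specific) removed first.
#' @param ... passed to [de_test()].
#' @return list(intersection, per_iteration, full): intersection gene set,
#'   per-left-out-sample DE sets, and the full-data [de_test()] table.
#' @export
global_de_loo <- function(counts, ped, fdr = 0.05,
                          exclude_genes = character(0), ...) {
  counts <- counts[setdiff(rownames(counts), exclude_genes), ,
                   drop = FALSE]
  cols <- colnames(counts)
  smp <- sample_of_column(cols)
  carrier <- ped$carrier[match(smp, ped$sample)]
  family <- ped$family[match(smp, ped$sample)]
  if (sum(unique(data.frame(smp, carrier))$carrier == 1) < 3 ||
      sum(unique(data.frame(smp, carrier))$carrier == 0) < 3)
    stop_twohit("need >= 3 carriers and >= 3 noncarriers")
  # covariate order must match c(groupA, groupB)
  run_one <- function(drop_sample) {
    keep <- smp != drop_sample
    ca <- carrier[keep]
    if (!any(ca == 1) || !any(ca == 0))
      stop_twohit("leaving out ", drop_sample, " empties a group")
    colsA <- cols[keep][ca == 0]
    colsB <- cols[keep][ca == 1]
    fam <- family[match(sample_of_column(c(colsA, colsB)), ped$sample)]
    de_test(counts, groupA = colsA, groupB = colsB, covariates = fam, ...)
  }
  per <- lapply(unique(smp), function(s) {
    d <- run_one(s)
    d$gene_id[d$tested & d$fdr < fdr]
  })
  names(per) <- unique(smp)
  inter <- Reduce(intersect, per)
  colsA <- cols[carrier == 0]; colsB <- cols[carrier == 1]
  fam <- family[match(sample_of_column(c(colsA, colsB)), ped$sample)]
  full <- de_test(counts, colsA, colsB, covariates = fam, ...)
  list(intersection = inter, per_iteration = per, full = full)
}

#' Trio differential expression between offspring and one parent
#'
#' NB test without covariates on the two samples' replicates; genes
#' expressed (count > 0) in fewer than 25% of the replicates are removed
#' first, and the DE set requires `|logFC| > 0.5` and FDR < 0.05.
#'
#' @param counts count matrix; `offspring`, `parent` sample ids.
#' @param lfc,fdr DE thresholds.
#' @param min_expr_prop replicate expression rule.
#' @param ... passed to [de_test()].
#' @return list(de = character gene set, table = [de_test()] output).
#' @export
trio_de <- function(counts, offspring, parent, lfc = 0.5, fdr = 0.05,
                    min_expr_prop = 0.25, ...) {
  cols <- colnames(counts)
  co <- cols[sample_of_column(cols) == offspring]
  cp <- cols[sample_of_column(cols) == parent]
  if (length(co) < 2 || length(cp) < 2)
    stop_twohit("missing replicates for ", offspring, " or ", parent)
  sel <- counts[, c(cp, co), drop = FALSE]
  keep <- rowMeans(sel > 0) >= min_expr_prop
  tab <- de_test(counts[keep, , drop = FALSE], groupA = cp, groupB = co,
                 ...)
  de <- tab$gene_id[tab$tested & abs(tab$logFC) > lfc & tab$fdr < fdr]
  list(de = de, table = tab)
}

#' Outlier expression z-scores with latent-factor correction
#'
#' Median TPM across replicates per individual, log2(x+1) transform,
#' per-gene z-scores across individuals, removal of the top `n_latent`
#' singular components of the z matrix (a PEER-style latent-factor
#' correction), per-gene re-standardisation, and outlier flags at
#' `|z| > z_thresh` (strict).
#'
#' @param tpm TPM matrix with `sample.replicate` columns.
#' @param n_latent latent factors to remove (default 1).
#' @param z_thresh outlier threshold (default 2).
#' @return list(z, flags, dropped, n_latent): corrected z matrix
#'   (genes x individuals), logical outlier flags, zero-variance genes
#'   dropped.
#' @export
outlier_zscores <- function(tpm, n_latent = 1, z_thresh = 2) {
  samples <- unique(sample_of_column(colnames(tpm)))
  if (length(samples) < 3) stop_twohit("need >= 3 individuals")
  med <- sapply(samples, function(s)
    apply(tpm[, sample_of_column(colnames(tpm)) == s, drop = FALSE], 1,
          median))
  lx <- log2(med + 1)
  sds <- apply(lx, 1, sd)
  dropped <- rownames(lx)[sds == 0]
  if (length(dropped))
    warning(length(dropped), " gene(s) with zero variance dropped")
  lx <- lx[sds > 0, , drop = FALSE]
  z <- t(scale(t(lx)))
  if (n_latent > 0) {
    sv <- svd(z, nu = n_latent, nv = n_latent)
    z <- z - sv$u %*% diag(sv$d[seq_len(n_latent)], n_latent) %*% t(sv$v)
    z <- t(scale(t(z)))
  }
  flags <- abs(z) > z_thresh
  list(z = z, flags = flags, dropped = dropped, n_latent = n_latent)
}

#' Parametric gene-set enrichment on fold changes (PAGE)
#'
#' `Z = (S_m - mu) * sqrt(m) / delta` where `mu` and `delta` are the mean
#' and SD of all log fold changes, `S_m` the set mean and `m` the set
#' size; two-tailed normal p-values with BH correction across sets.
#'
#' @param logfc named numeric vector of log fold changes.
#' @param sets named list of gene-id vectors.
#' @param min_size minimum set size after intersection (default 10).
#' @return data.frame(set, m, Z, p, fdr).
#' @export
page_enrichment <- function(logfc, sets, min_size = 10) {
  mu <- mean(logfc)
  delta <- sd(logfc)
  if (delta == 0) stop_twohit("zero variance in fold changes")
  res <- lapply(names(sets), function(nm) {
    g <- intersect(sets[[nm]], names(logfc))
    m <- length(g)
    if (m < min_size) return(NULL)
    Z <- (mean(logfc[g]) - mu) * sqrt(m) / delta
    data.frame(set = nm, m = m, Z = Z, p = 2 * pnorm(-abs(Z)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(set = character(0), m = integer(0), Z = numeric(0),
                      p = numeric(0), fdr = numeric(0)))
  res$fdr <- bh_fdr(res$p)
  res
}

#' Flag preferentially expressed genes per tissue
#'
#' A (gene, tissue) pair is flagged when the expression exceeds the
#' across-tissue median by more than two across-tissue SDs (strict).
#'
#' @param expr genes x tissues expression matrix (>= 3 tissues).
#' @return logical matrix of flags with the same dimensions.
#' @export
preferential_expression <- function(expr) {
  if (ncol(expr) < 3) stop_twohit("need >= 3 tissues")
  med <- apply(expr, 1, median)
  sds <- apply(expr, 1, sd)
  sweep(expr, 1, med + 2 * sds, ">")
}
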