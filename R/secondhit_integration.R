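# Variant-class x expression-change enrichment, burden tests, synergy
# genes, and change-type correlations.

# 2x2 odds ratio with Haldane-Anscombe correction for the Wald CI only
wald_or_ci <- function(a, b, c, d, level = 0.95) {
  or <- (a * d) / (b * c)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- qnorm(1 - (1 - level) / 2)
  list(or = or, lo = exp(lor - zq * se), hi = exp(lor + zq * se))
}

#' Enrichment of variant classes towards expression changes
#'
#' For each (variant class, change type, stratum): a 2x2 table over
#' gene-individual units in the stratum's background (a = variant and
#' change, b = variant only, c = change only, d = neither), two-sided
#' Fisher exact p, Wald 95% CI on the odds ratio (Haldane-Anscombe 0.5
#' correction when a cell is zero), and BH correction across the variant
#' classes within each (change type, stratum).
#'
#' @param changes data.frame(gene_id, sample, change_type) of called
#'   expression changes.
#' @param classified classified-variant table (gene_id, sample, class,
#'   inheritance).
#' @param background data.frame(gene_id, sample) enumerating the
#'   gene-individual universe (e.g. expressed genes x stratum samples).
#' @param strata named list; each element is a list with `samples`
#'   (character vector) and optionally `inheritance` (restrict the
#'   variants counted to those inherited labels).
#' @param classes variant classes to test (default all 25).
#' @return data.frame(class, change_type, stratum, a, b, c, d, or, ci_lo,
#'   ci_hi, p, fdr).
#' @export
enrichment_matrix <- function(changes, classified, background,
                              strata = list(all = list(samples = NULL)),
                              classes = variant_classes()) {
  out <- list()
  for (snm in names(strata)) {
    st <- strata[[snm]]
    bg <- background
    if (!is.null(st$samples))
      bg <- bg[bg$sample %in% st$samples, , drop = FALSE]
    if (!nrow(bg)) {
      warning("empty stratum ", snm, " skipped")
      next
    }
    vv <- classified
    if (!is.null(st$samples))
      vv <- vv[vv$sample %in% st$samples, , drop = FALSE]
    if (!is.null(st$inheritance))
      vv <- vv[vv$inheritance %in% st$inheritance, , drop = FALSE]
    bg_key <- paste(bg$gene_id, bg$sample)
    for (ct in unique(changes$change_type)) {
      ch <- changes[changes$change_type == ct, , drop = FALSE]
      ch_key <- unique(paste(ch$gene_id, ch$sample))
      has_change <- bg_key %in% ch_key
      res <- lapply(classes, function(cl) {
        vk <- unique(paste(vv$gene_id[vv$class == cl],
                           vv$sample[vv$class == cl]))
        has_var <- bg_key %in% vk
        a <- sum(has_var & has_change)
        b <- sum(has_var & !has_change)
        cc <- sum(!has_var & has_change)
        d <- sum(!has_var & !has_change)
        ci <- wald_or_ci(a, b, cc, d)
        p <- min(1, fisher.test(matrix(c(a, b, cc, d), 2))$p.value)
        data.frame(class = cl, change_type = ct, stratum = snm,
                   a = a, b = b, c = cc, d = d, or = ci$or,
                   ci_lo = ci$lo, ci_hi = ci$hi, p = p,
                   stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      res$fdr <- bh_fdr(res$p)
      out[[length(out) + 1L]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Burden of rare variants in outlier vs non-outlier genes
#'
#' One-tailed (greater) two-sample t-tests of per-unit variant counts,
#' outlier units against non-outlier units, in aggregate and per class,
#' with BH across classes.  Optionally repeated on subsets (e.g. genes
#' intolerant to variation or brain-preferential genes) via
#' `gene_subsets`.
#'
#' @param outlier_units data.frame(gene_id, sample, outlier = logical).
#' @param classified classified-variant table.
#' @param classes classes to test individually.
#' @param gene_subsets optional named list of gene-id vectors.
#' @return data.frame(scope, class, n_outlier, n_other, statistic, p,
#'   fdr).
#' @export
variant_burden_test <- function(outlier_units, classified,
                                classes = variant_classes(),
                                gene_subsets = NULL) {
  key <- paste(outlier_units$gene_id, outlier_units$sample)
  count_for <- function(cls) {
    v <- classified
    if (!is.null(cls)) v <- v[v$class == cls, , drop = FALSE]
    tab <- table(paste(v$gene_id, v$sample))
    n <- as.integer(tab[key])
    n[is.na(n)] <- 0L
    n
  }
  run_scope <- function(scope, units_idx) {
    flag <- outlier_units$outlier[units_idx]
    rows <- lapply(c(list(NULL), as.list(classes)), function(cls) {
      n <- count_for(cls)[units_idx]
      x <- n[flag]; y <- n[!flag]
      if (length(x) < 2 || length(y) < 2 || (var(x) == 0 && var(y) == 0))
        return(data.frame(scope = scope,
                          class = cls %||% "aggregate",
                          n_outlier = length(x), n_other = length(y),
                          statistic = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      tt <- t.test(x, y, alternative = "greater")
      data.frame(scope = scope, class = cls %||% "aggregate",
                 n_outlier = length(x), n_other = length(y),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    cls_rows <- res$class != "aggregate" & !is.na(res$p)
    res$fdr <- NA_real_
    res$fdr[cls_rows] <- bh_fdr(res$p[cls_rows])
    res
  }
  scopes <- list(all = seq_len(nrow(outlier_units)))
  if (!is.null(gene_subsets))
    for (nm in names(gene_subsets))
      scopes[[nm]] <- which(outlier_units$gene_id %in% gene_subsets[[nm]])
  out <- do.call(rbind, lapply(names(scopes), function(nm)
    run_scope(nm, scopes[[nm]])))
  rownames(out) <- NULL
  out
}

#' Detect genes with synergistic deletion x second-hit effects
#'
#' Emits every (gene, carrier individual) where the gene is in the global
#' (leave-one-out intersection) DE set, is an expression outlier in that
#' carrier, and carries a nearby second-hit variant inherited from the
#' noncarrier parent.
#'
#' @param global_de character vector: the global DE gene set.
#' @param zmat [outlier_zscores()] output.
#' @param classified classified-variant table with inheritance.
#' @param carriers character vector of deletion-carrier sample ids.
#' @return data.frame(gene_id, sample, z, variant_id, class).
#' @export
synergy_detect <- function(global_de, zmat, classified, carriers) {
  v <- classified[classified$inheritance == "noncarrier_parent" &
                  classified$sample %in% carriers, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(v))) {
    g <- v$gene_id[i]; s <- v$sample[i]
    if (!g %in% global_de) next
    if (!g %in% rownames(zmat$flags) || !s %in% colnames(zmat$flags))
      next
    if (!zmat$flags[g, s]) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, sample = s, z = zmat$z[g, s],
      variant_id = v$variant_id[i], class = v$class[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), sample = character(0),
                      z = numeric(0), variant_id = character(0),
                      class = character(0))
  unique(res)
}

#' Correlations among per-offspring change counts
#'
#' Pearson correlation for every pair of change-count columns with
#' two-sided t-distribution p-values and BH correction across pairs;
#' zero-variance columns are skipped.
#'
#' @param counts data.frame or matrix: offspring x (change type x
#'   pattern) counts, >= 5 offspring.
#' @return data.frame(col1, col2, r, p, fdr).
#' @export
change_count_correlations <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 5) stop_twohit("need >= 5 offspring")
  keep <- apply(m, 2, var) > 0
  m <- m[, keep, drop = FALSE]
  cn <- colnames(m)
  if (length(cn) < 2)
    return(data.frame(col1 = character(0), col2 = character(0),
                      r = numeric(0), p = numeric(0), fdr = numeric(0)))
  prs <- combn(cn, 2)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    ct <- cor.test(m[, prs[1, k]], m[, prs[2, k]], method = "pearson")
    data.frame(col1 = prs[1, k], col2 = prs[2, k],
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- bh_fdr(res$p)
  res
}
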