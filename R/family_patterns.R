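# Trio extraction and family-specific pattern classification of offspring
# expression changes.

#' Extract trios from a pedigree
#'
#' Every (offspring, carrier parent, noncarrier parent) triple with both
#' parents enrolled and discordant carrier statuses.  Carrier offspring are
#' returned by default (including carrier parents compared against their
#' own parents, i.e. grandparent trios); noncarrier offspring are added
#' with `include_noncarrier_offspring = TRUE`.  Offspring whose parents
#' are both carriers are skipped with a warning.
#'
#' @param ped a `twohit_pedigree`.
#' @param include_noncarrier_offspring also emit noncarrier-offspring
#'   trios.
#' @return data.frame(offspring, carrier_parent, noncarrier_parent,
#'   offspring_carrier).
#' @export
extract_trios <- function(ped, include_noncarrier_offspring = FALSE) {
  out <- list()
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father[i]; mo <- ped$mother[i]
    if (fa == "0" || mo == "0") next
    stf <- ped$carrier[match(fa, ped$sample)]
    stm <- ped$carrier[match(mo, ped$sample)]
    if (is.na(stf) || is.na(stm)) next
    if (stf == stm) {
      if (stf == 1L)
        warning("both parents of ", ped$sample[i],
                " are carriers; trio excluded")
      next
    }
    if (ped$carrier[i] == 0L && !include_noncarrier_offspring) next
    out[[length(out) + 1L]] <- data.frame(
      offspring = ped$sample[i],
      carrier_parent = if (stf == 1L) fa else mo,
      noncarrier_parent = if (stf == 1L) mo else fa,
      offspring_carrier = ped$carrier[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(offspring = character(0),
                      carrier_parent = character(0),
                      noncarrier_parent = character(0),
                      offspring_carrier = integer(0))
  res
}

#' Classify offspring expression changes by family-specific pattern
#'
#' Given the DE sets of one offspring against each parent: `unique` =
#' changed relative to both parents (intersection); `shared_carrier` =
#' changed only relative to the noncarrier parent; `shared_noncarrier` =
#' changed only relative to the carrier parent.
#'
#' @param set_vs_carrier,set_vs_noncarrier gene sets from the two
#'   offspring-parent comparisons.
#' @return data.frame(gene_id, pattern).
#' @export
classify_pattern <- function(set_vs_carrier, set_vs_noncarrier) {
  u <- intersect(set_vs_carrier, set_vs_noncarrier)
  sc <- setdiff(set_vs_noncarrier, set_vs_carrier)
  sn <- setdiff(set_vs_carrier, set_vs_noncarrier)
  data.frame(
    gene_id = c(u, sc, sn),
    pattern = rep(c("unique", "shared_carrier", "shared_noncarrier"),
                  c(length(u), length(sc), length(sn))),
    stringsAsFactors = FALSE)
}

#' Compare shared-with-carrier vs shared-with-noncarrier change counts
#'
#' Paired two-sided Wilcoxon signed-rank test (the paired analogue of the
#' Mann-Whitney test) on per-offspring counts, or proportions of each
#' offspring's total changes (the default).
#'
#' @param shared_carrier,shared_noncarrier numeric vectors, one entry per
#'   offspring (>= 5 offspring).
#' @param totals optional per-offspring totals; when given (default when
#'   `use_proportions`) the test runs on proportions.
#' @param use_proportions test proportions of totals rather than raw
#'   counts.
#' @return list(statistic, p.value, method).
#' @export
compare_pattern_counts <- function(shared_carrier, shared_noncarrier,
                                   totals = NULL,
                                   use_proportions = !is.null(totals)) {
  if (length(shared_carrier) < 5)
    stop_twohit("need >= 5 offspring")
  a <- shared_carrier; b <- shared_noncarrier
  if (use_proportions) {
    tot <- totals %||% (shared_carrier + shared_noncarrier)
    a <- a / tot; b <- b / tot
  }
  signed_rank_test(a, b)
}

#' Paired Wilcoxon signed-rank test with an exact tie-aware null
#'
#' Two-sided signed-rank test on paired differences.  For n <= 20
#' non-zero differences the null distribution of the rank sum is built
#' exactly by convolution over sign flips (midranks for ties), so tied
#' differences still get exact p-values; larger n uses the
#' tie-corrected normal approximation of [stats::wilcox.test()].
#'
#' @param a,b paired numeric vectors.
#' @return list(statistic, p.value, method).
#' @export
signed_rank_test <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero")
    return(list(statistic = NA_real_, p.value = 1,
                method = "Wilcoxon signed rank (degenerate)"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (length(d) <= 20) {
    # exact null by convolution; double the midranks so they are integer
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1)
    dist[1] <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), dist[seq_len(total + 1 - rk)])
      dist <- (dist + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    p_lo <- sum(dist[seq_len(v2 + 1)])
    p_hi <- sum(dist[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = v, p.value = p,
                method = "Exact Wilcoxon signed rank (tie-aware)"))
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}
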