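# Alternative splicing (isoform-level DE in genes lacking gene-level DE)
# and allele-specific expression (binomial haplotype tests).

#' Call alternative splicing in one trio
#'
#' For each offspring-parent pair, both the isoform-level and gene-level
#' NB tests are run; splicing calls are isoforms with FDR < `fdr` whose
#' parent gene is not differentially expressed in the same comparison.
#' Genes with <= `min_total` counts summed over all samples or with a
#' single isoform are excluded.  Calls from the two parental comparisons
#' are combined into family-specific patterns via [classify_pattern()].
#'
#' @param iso_counts isoform count matrix; `iso_map`
#'   data.frame(isoform_id, gene_id).
#' @param gene_counts gene count matrix.
#' @param trio one row of [extract_trios()].
#' @param fdr significance threshold.
#' @param min_total minimum summed gene count.
#' @param ... passed to [de_test()].
#' @return list(calls = data.frame(gene_id = isoform's gene, isoform_id,
#'   pattern), vs_carrier, vs_noncarrier): per-pattern splicing calls and
#'   the per-parent isoform call sets (gene ids).
#' @export
alt_splicing <- function(iso_counts, iso_map, gene_counts, trio,
                         fdr = 0.05, min_total = 2, ...) {
  stopifnot(all(rownames(iso_counts) %in% iso_map$isoform_id))
  multi <- names(which(table(iso_map$gene_id) >= 2))
  keep_iso <- iso_map$isoform_id[iso_map$gene_id %in% multi]
  expressed <- rowSums(gene_counts) > min_total
  keep_iso <- keep_iso[iso_map$gene_id[match(keep_iso, iso_map$isoform_id)]
                       %in% rownames(gene_counts)[expressed]]
  iso <- iso_counts[keep_iso, , drop = FALSE]
  one_parent <- function(parent) {
    it <- trio_de(iso, trio$offspring, parent, lfc = 0, fdr = fdr, ...)
    gt <- trio_de(gene_counts[expressed, , drop = FALSE], trio$offspring,
                  parent, lfc = 0, fdr = fdr, ...)
    iso_sig <- it$de
    gene_of <- iso_map$gene_id[match(iso_sig, iso_map$isoform_id)]
    sig <- iso_sig[!gene_of %in% gt$de]
    list(iso = sig,
         gene = unique(iso_map$gene_id[match(sig, iso_map$isoform_id)]))
  }
  vc <- one_parent(trio$carrier_parent)
  vn <- one_parent(trio$noncarrier_parent)
  pat <- classify_pattern(vc$iso, vn$iso)
  if (nrow(pat)) {
    calls <- data.frame(
      isoform_id = pat$gene_id,
      gene_id = iso_map$gene_id[match(pat$gene_id, iso_map$isoform_id)],
      pattern = pat$pattern, stringsAsFactors = FALSE)
  } else {
    calls <- data.frame(isoform_id = character(0), gene_id = character(0),
                        pattern = character(0))
  }
  list(calls = calls, vs_carrier = vc$gene, vs_noncarrier = vn$gene)
}

#' Test allele-specific expression for one individual
#'
#' Genes with more than `min_reads` total haplotype reads are tested with
#' a two-sided exact binomial test at p = 0.5 (minimum-likelihood
#' two-sided p-value), BH-corrected across tested genes within the
#' individual; ASE is called at FDR < `fdr`.
#'
#' @param hap data.frame(gene_id, hapA_count, hapB_count) for one
#'   individual.
#' @param min_reads minimum total reads (strict >; default 10).
#' @param fdr significance threshold.
#' @return data.frame(gene_id, hapA_count, hapB_count, allelic_logfc, p,
#'   fdr, major_haplotype, ase).
#' @export
ase_test <- function(hap, min_reads = 10, fdr = 0.05) {
  if (any(hap$hapA_count < 0 | hap$hapB_count < 0))
    stop_twohit("haplotype counts must be >= 0")
  tot <- hap$hapA_count + hap$hapB_count
  tested <- tot > min_reads
  d <- hap[tested, , drop = FALSE]
  p <- vapply(seq_len(nrow(d)), function(i)
    binom.test(d$hapA_count[i], d$hapA_count[i] + d$hapB_count[i],
               0.5)$p.value, numeric(1))
  q <- bh_fdr(p)
  data.frame(
    gene_id = d$gene_id, hapA_count = d$hapA_count,
    hapB_count = d$hapB_count,
    allelic_logfc = log2((d$hapA_count + 0.5) / (d$hapB_count + 0.5)),
    p = p, fdr = q,
    major_haplotype = ifelse(d$hapA_count >= d$hapB_count, "hapA",
                             "hapB"),
    ase = q < fdr, stringsAsFactors = FALSE)
}

#' Flag ASE calls whose overexpressed haplotype carries a coding variant
#'
#' A called ASE gene is flagged when a classified variant with a coding
#' class (LOF, missense, splice-site) in the same individual is phased
#' onto the overexpressed haplotype.
#'
#' @param ase [ase_test()] output for one individual.
#' @param classified classified-variant table for that individual (columns
#'   variant_id, gene_id, class).
#' @param phase data.frame(gene_id, hapA_variants, hapB_variants) with
#'   comma-separated variant ids per haplotype.
#' @return `ase` with a logical `coding_hit` column.
#' @export
flag_ase_with_coding_hit <- function(ase, classified, phase) {
  coding <- classified[classified$class %in%
                       c("LOF", "missense", "splice_site"), , drop = FALSE]
  split_ids <- function(x) unlist(strsplit(x, ","))
  ase$coding_hit <- FALSE
  for (i in which(ase$ase)) {
    ph <- phase[phase$gene_id == ase$gene_id[i], , drop = FALSE]
    if (!nrow(ph)) next
    major_col <- if (ase$major_haplotype[i] == "hapA") "hapA_variants"
                 else "hapB_variants"
    ids <- split_ids(ph[[major_col]][1])
    ids <- ids[nzchar(ids)]
    if (!length(ids)) next
    hit <- coding$variant_id %in% ids &
      coding$gene_id == ase$gene_id[i]
    ase$coding_hit[i] <- any(hit)
  }
  ase
}
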