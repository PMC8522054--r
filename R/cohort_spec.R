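# Cohort specification: all tunable parameters of the synthetic generator.

#' Default planted-variant plan
#'
#' One row per planted variant group: variant class, number of (child,
#' gene) plantings, cis log2 fold-change on the target gene's expression in
#' the variant carriers, and the inheritance to stamp.  Defaults plant every
#' one of the 25 classes at least twice with mixed inheritance, plus one
#' strong loss-of-function variant per carrier child inherited from the
#' noncarrier parent (the configuration under which class-level enrichment
#' is expected to be recoverable).  Per-class cis effect sizes are synthetic
#' placeholders for power studies; they are not anchored to any measured
#' human effect sizes.
#'
#' @return data.frame with columns `class`, `n`, `logfc`, `inheritance`.
#' @export
default_variant_plan <- function() {
  cls <- variant_classes()
  base <- data.frame(
    class = rep(cls, each = 2),
    n = 1L,
    logfc = rep(ifelse(grepl("^LOF$|encapsulating", cls), -1,
                ifelse(grepl("^DUP", cls), 0.6, 0.5)), each = 2),
    inheritance = rep(c("carrier_parent", "noncarrier_parent"),
                      length(cls)),
    stringsAsFactors = FALSE)
  # regulatory SNVs get +/-0.5 alternating sign
  reg <- base$class %in% c("promoter_snv", "enhancer_snv", "silencer_snv",
                           "upstream_snv", "downstream_snv", "UTR5_snv",
                           "UTR3_snv", "intronic_snv")
  base$logfc[reg] <- base$logfc[reg] * rep_len(c(1, -1), sum(reg))
  # strong LOF wave: one per carrier child, from the noncarrier parent
  lof <- data.frame(class = "LOF", n = 9L, logfc = -1,
                    inheritance = "noncarrier_parent",
                    stringsAsFactors = FALSE)
  rbind(base, lof)
}

#' Specify a synthetic family cohort
#'
#' Collects every parameter of the synthetic cohort generator.  Defaults
#' emulate a five-family, 32-individual cohort with three lymphoblastoid
#' replicates per person, a hemizygous 7-gene deletion region (0.5x dosage),
#' planted second-hit variants of all 25 classes with Mendelian
#' transmission, negative-binomial expression with family/deletion/cis
#' variant/outlier effects, isoform-usage shifts, allelic imbalance, and a
#' weighted gene network with optional planted proximity structure.
#'
#' @param n_genes total genes simulated (including deletion-region genes).
#' @param family_structures list of pedigree templates; see
#'   [simulate_pedigree()].
#' @param replicates_per_sample biological replicates per individual
#'   (>= 2).
#' @param deletion_region list with `contig` and `n_genes` for the
#'   hemizygous region.
#' @param planted_variant_plan data.frame as [default_variant_plan()].
#' @param mean_range,dispersion_range per-gene baseline negative-binomial
#'   mean (counts/replicate) and dispersion ranges.
#' @param family_effect_sd SD (log2) of the gene loadings of the shared
#'   per-family expression shift (a rank-one batch-like factor).
#' @param bio_sd per-individual biological SD (log2) around the gene mean.
#' @param outlier_effect planted outlier shift in units of the expected
#'   between-individual SD (z-shift).
#' @param n_outliers number of planted (gene, individual) outliers.
#' @param n_synergy planted synergy cases: second-hit variants on
#'   deletion-region genes in carrier children, inherited from the
#'   noncarrier parent, so the deletion and the second-hit jointly push
#'   the gene to outlier expression.
#' @param n_splice number of planted splice-shift (gene, child) events.
#' @param splice_usage target-isoform usage in splice-shifted samples.
#' @param n_ase,n_ase_link planted allele-specific-expression genes, and
#'   how many of them carry a deleterious coding variant phased onto the
#'   overexpressed haplotype.
#' @param ase_shift allelic fraction for planted ASE genes.
#' @param ase_depth mean haplotype-level read depth per gene.
#' @param network_params list: `edge_prob` (background edge density),
#'   `mode` ("planted" or "null"), `attach_prob` (probability of an extra
#'   high-weight edge per labelled pair under planted proximity).
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return list of class `twohit_cohort_spec`.
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$replicates_per_sample
#' @export
cohort_spec <- function(n_genes = 260,
                        family_structures = default_family_structures(),
                        replicates_per_sample = 3,
                        deletion_region = list(contig = "chr16",
                                               n_genes = 7),
                        planted_variant_plan = default_variant_plan(),
                        mean_range = c(100, 2000),
                        dispersion_range = c(0.02, 0.08),
                        family_effect_sd = 0.3,
                        bio_sd = 0.2,
                        outlier_effect = 4,
                        n_outliers = 20,
                        n_synergy = 3,
                        n_splice = 10,
                        splice_usage = 0.9,
                        n_ase = 10,
                        n_ase_link = 5,
                        ase_shift = 0.85,
                        ase_depth = 200,
                        network_params = list(edge_prob = 0.02,
                                              mode = "planted",
                                              attach_prob = 0.35),
                        seed = 1) {
  check_number(replicates_per_sample, "replicates_per_sample", lower = 2)
  check_number(n_genes, "n_genes", lower = 20)
  check_number(family_effect_sd, "family_effect_sd", lower = 0)
  check_number(outlier_effect, "outlier_effect", lower = 0)
  check_number(ase_shift, "ase_shift", lower = 0, upper = 1)
  check_number(seed, "seed")
  if (any(dispersion_range <= 0))
    stop_twohit("dispersion_range must be positive")
  if (!all(c("class", "n", "logfc", "inheritance") %in%
           names(planted_variant_plan)))
    stop_twohit("planted_variant_plan needs class, n, logfc, inheritance")
  unknown <- setdiff(planted_variant_plan$class, variant_classes())
  if (length(unknown))
    stop_twohit("planted classes outside the taxonomy: ",
                paste(unknown, collapse = ", "))
  structure(list(
    n_genes = as.integer(n_genes),
    family_structures = family_structures,
    n_families = length(family_structures),
    replicates_per_sample = as.integer(replicates_per_sample),
    deletion_region = deletion_region,
    planted_variant_plan = planted_variant_plan,
    mean_range = mean_range, dispersion_range = dispersion_range,
    family_effect_sd = family_effect_sd, bio_sd = bio_sd,
    outlier_effect = outlier_effect, n_outliers = as.integer(n_outliers),
    n_synergy = as.integer(n_synergy),
    n_splice = as.integer(n_splice), splice_usage = splice_usage,
    n_ase = as.integer(n_ase), n_ase_link = as.integer(n_ase_link),
    ase_shift = ase_shift, ase_depth = ase_depth,
    network_params = network_params,
    seed = as.integer(seed)), class = "twohit_cohort_spec")
}
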