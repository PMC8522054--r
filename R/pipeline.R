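# End-to-end pipeline driver: executes every analysis stage on a cohort
# in dependency order and writes one TSV per stage plus a JSON manifest.

#' Pipeline configuration
#'
#' Collects every analysis threshold with its default: 0.2 TPM expression
#' filter, |z| > 2 outliers with one latent factor, |logFC| > 0.5 and
#' FDR < 0.05 trio DE, FDR < 0.05 elsewhere, network edge threshold 2.0
#' with 100 permutations, and the variant filter thresholds of
#' [variant_filter_config()].
#'
#' @param tpm_threshold,z_thresh,n_latent,lfc,fdr,edge_threshold,n_perm
#'   stage thresholds.
#' @param filter_config variant filters.
#' @param seed seed for the network permutations.
#' @return list of class `twohit_config`.
#' @export
pipeline_config <- function(tpm_threshold = 0.2, z_thresh = 2,
                            n_latent = 1, lfc = 0.5, fdr = 0.05,
                            edge_threshold = 2.0, n_perm = 100,
                            filter_config = variant_filter_config(),
                            seed = 1) {
  stopifnot(tpm_threshold > 0, z_thresh > 0, lfc >= 0, fdr > 0,
            edge_threshold > 0, n_perm > 0)
  structure(list(tpm_threshold = tpm_threshold, z_thresh = z_thresh,
                 n_latent = n_latent, lfc = lfc, fdr = fdr,
                 edge_threshold = edge_threshold, n_perm = n_perm,
                 filter_config = filter_config, seed = as.integer(seed)),
            class = "twohit_config")
}

#' Run the full two-hit analysis pipeline
#'
#' Stages, in dependency order: variant taxonomy with inheritance; global
#' leave-one-out intersection DE; outlier z-scores; per-trio DE with
#' family-specific patterns; alternative splicing; allele-specific
#' expression with coding-hit flags; variant-class enrichment (stratified
#' by sample type and inheritance); synergy genes; and network proximity
#' per carrier offspring with a cohort-level paired test.  Writes
#' `variants.tsv`, `de_global.tsv`, `outliers.tsv`, `patterns.tsv`,
#' `splicing.tsv`, `ase.tsv`, `enrichment.tsv`, `synergy.tsv`,
#' `network_proximity.tsv` and `manifest.json` into `outdir`.
#'
#' @param cohort a `twohit_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(cohort, outdir, config = pipeline_config()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_twohit("cannot create output directory ", outdir)
  fp <- function(x) file.path(outdir, x)
  ped <- cohort$pedigree
  models <- cohort$models
  manifest <- list(config = unclass(config),
                   n_samples = nrow(ped),
                   n_genes = nrow(models$genes))

  # ---- stage 1: variant taxonomy ---------------------------------------
  classified <- classify_variants(cohort$snv, cohort$sv, cohort$str,
                                  models, cohort$chromatin, ped,
                                  config$filter_config)
  write_tsv(classified, fp("variants.tsv"))
  manifest$n_classified <- nrow(classified)

  # ---- stage 2: expressed genes + global LOO DE ------------------------
  pc <- models$genes$gene_id[models$genes$biotype == "protein_coding"]
  expressed <- filter_expressed(cohort$tpm, config$tpm_threshold)
  expressed_pc <- intersect(expressed, pc)
  counts <- cohort$counts[expressed_pc, , drop = FALSE]
  loo <- global_de_loo(counts, ped, fdr = config$fdr)
  de_tab <- loo$full
  de_tab$in_intersection <- de_tab$gene_id %in% loo$intersection
  write_tsv(de_tab, fp("de_global.tsv"))
  manifest$n_global_de <- length(loo$intersection)

  # ---- stage 3: outlier z-scores ---------------------------------------
  zres <- outlier_zscores(cohort$tpm[expressed_pc, , drop = FALSE],
                          n_latent = config$n_latent,
                          z_thresh = config$z_thresh)
  oidx <- which(zres$flags, arr.ind = TRUE)
  outliers <- data.frame(gene_id = rownames(zres$z)[oidx[, 1]],
                         sample = colnames(zres$z)[oidx[, 2]],
                         z = zres$z[oidx], stringsAsFactors = FALSE)
  write_tsv(outliers, fp("outliers.tsv"))
  manifest$n_outlier_calls <- nrow(outliers)

  # ---- stage 4: trio DE + patterns -------------------------------------
  trios <- extract_trios(ped)
  patterns <- list()
  trio_sets <- list()
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    vc <- trio_de(counts, tr$offspring, tr$carrier_parent,
                  lfc = config$lfc, fdr = config$fdr)
    vn <- trio_de(counts, tr$offspring, tr$noncarrier_parent,
                  lfc = config$lfc, fdr = config$fdr)
    pat <- classify_pattern(vc$de, vn$de)
    trio_sets[[tr$offspring]] <- list(vs_carrier = vc$de,
                                      vs_noncarrier = vn$de)
    if (nrow(pat))
      patterns[[length(patterns) + 1L]] <-
        data.frame(offspring = tr$offspring, gene_id = pat$gene_id,
                   change_type = "DE", pattern = pat$pattern,
                   stringsAsFactors = FALSE)
  }

  # ---- stage 5: alternative splicing -----------------------------------
  iso <- cohort$isoforms
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    sp <- alt_splicing(iso$counts, iso$map, counts, tr,
                       fdr = config$fdr)
    if (nrow(sp$calls))
      patterns[[length(patterns) + 1L]] <-
        data.frame(offspring = tr$offspring, gene_id = sp$calls$gene_id,
                   change_type = "splicing", pattern = sp$calls$pattern,
                   stringsAsFactors = FALSE)
  }
  patterns <- if (length(patterns)) unique(do.call(rbind, patterns)) else
    data.frame(offspring = character(0), gene_id = character(0),
               change_type = character(0), pattern = character(0))
  rownames(patterns) <- NULL
  write_tsv(patterns, fp("patterns.tsv"))
  write_tsv(patterns[patterns$change_type == "splicing", , drop = FALSE],
            fp("splicing.tsv"))
  manifest$n_pattern_calls <- nrow(patterns)

  # ---- stage 6: allele-specific expression -----------------------------
  hap <- cohort$haplotypes
  ase_all <- list()
  for (s in unique(hap$individual)) {
    hs <- hap[hap$individual == s, , drop = FALSE]
    at <- ase_test(hs, fdr = config$fdr)
    cls_s <- classified[classified$sample == s, , drop = FALSE]
    at <- flag_ase_with_coding_hit(at, cls_s, hs)
    if (nrow(at)) {
      at$sample <- s
      ase_all[[length(ase_all) + 1L]] <- at[at$ase, , drop = FALSE]
    }
  }
  ase_all <- if (length(ase_all)) do.call(rbind, ase_all) else
    data.frame()
  write_tsv(ase_all, fp("ase.tsv"))
  manifest$n_ase_calls <- nrow(ase_all)

  # ---- stage 7: enrichment ---------------------------------------------
  samples <- ped$sample
  bg <- expand.grid(gene_id = expressed_pc, sample = samples,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  changes <- rbind(
    data.frame(gene_id = outliers$gene_id, sample = outliers$sample,
               change_type = "outlier", stringsAsFactors = FALSE),
    data.frame(gene_id = patterns$gene_id, sample = patterns$offspring,
               change_type = patterns$change_type,
               stringsAsFactors = FALSE))
  carrier_children <- ped$sample[ped$role == "child" & ped$carrier == 1L]
  carrier_parents <- ped$sample[ped$role == "parent" & ped$carrier == 1L]
  noncar_parents <- ped$sample[ped$role == "parent" & ped$carrier == 0L]
  strata <- list(
    all = list(samples = NULL),
    carrier_child = list(samples = carrier_children),
    carrier_parent = list(samples = carrier_parents),
    noncarrier_parent = list(samples = noncar_parents),
    inherited_from_carrier = list(samples = carrier_children,
                                  inheritance = "carrier_parent"),
    inherited_from_noncarrier = list(samples = carrier_children,
                                     inheritance = "noncarrier_parent"))
  enr <- enrichment_matrix(changes, classified, bg, strata)
  write_tsv(enr, fp("enrichment.tsv"))

  # ---- stage 8: synergy genes ------------------------------------------
  carriers <- ped$sample[ped$carrier == 1L]
  syn <- synergy_detect(loo$intersection, zres, classified, carriers)
  write_tsv(syn, fp("synergy.tsv"))
  manifest$n_synergy <- nrow(syn)

  # ---- stage 9: network proximity --------------------------------------
  g <- build_network(cohort$network, config$edge_threshold)
  prox <- list()
  carrier_trios <- trios[trios$offspring_carrier == 1L, , drop = FALSE]
  for (i in seq_len(nrow(carrier_trios))) {
    off <- carrier_trios$offspring[i]
    setA <- unique(classified$gene_id[classified$sample == off &
                                      classified$class %in%
                                        coding_classes()])
    setB <- unique(c(patterns$gene_id[patterns$offspring == off],
                     outliers$gene_id[outliers$sample == off],
                     ase_all$gene_id[ase_all$sample == off]))
    pr <- tryCatch(
      permutation_test(g, setA, setB, n = config$n_perm,
                       seed = derive_seed(config$seed, paste0("net", off))),
      error = function(e) NULL)
    if (is.null(pr)) next
    prox[[length(prox) + 1L]] <- data.frame(
      offspring = off, observed = pr$observed,
      permuted_mean = pr$permuted_mean, permuted_sd = pr$permuted_sd,
      z = pr$z, p = pr$p, p_empirical = pr$p_empirical,
      n_pairs = pr$n_pairs, stringsAsFactors = FALSE)
  }
  prox <- if (length(prox)) do.call(rbind, prox) else
    data.frame(offspring = character(0), observed = numeric(0),
               permuted_mean = numeric(0), permuted_sd = numeric(0),
               z = numeric(0), p = numeric(0), p_empirical = numeric(0),
               n_pairs = integer(0))
  if (nrow(prox)) prox$fdr <- bh_fdr(prox$p)
  write_tsv(prox, fp("network_proximity.tsv"))
  if (nrow(prox) >= 5) {
    ct <- cohort_proximity_test(prox$observed, prox$permuted_mean)
    manifest$cohort_proximity_p <- ct$p.value
  }

  manifest$n_trios <- nrow(trios)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(classified = classified, loo = loo, outliers = outliers,
                 zres = zres, patterns = patterns, ase = ase_all,
                 enrichment = enr, synergy = syn, proximity = prox,
                 trios = trios, expressed = expressed_pc,
                 manifest = manifest))
}
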