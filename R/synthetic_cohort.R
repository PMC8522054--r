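# Synthetic family-cohort generator: planted variants, expression,
# isoforms, haplotype counts and an interaction network, all with a ground
# truth table for parameter-recovery testing.

sample_of_column <- function(cols) sub("\\.r[0-9]+$", "", cols)

truth_row <- function(gene_id, sample, kind, magnitude = NA_real_,
                      parent = NA_character_, class = NA_character_) {
  data.frame(gene_id = gene_id, sample = sample, kind = kind,
             magnitude = magnitude, parent = parent, class = class,
             stringsAsFactors = FALSE)
}

# children eligible for planting inherited variants: carriers with both
# parents enrolled
trio_children <- function(ped) {
  ped$sample[ped$role == "child" & ped$carrier == 1L &
             ped$father != "0" & ped$mother != "0"]
}

# per-class SNV anchor position (0-based) within/near a gene
snv_position <- function(class, g) {
  plus <- g$strand == "+"
  switch(class,
    LOF = ,
    missense = g$cds_start + 50L,
    splice_site = g$tx_start + 602L,            # 2 bp into intron 1
    intronic_snv = g$tx_start + 1600L,          # mid intron 1
    UTR5_snv = if (plus) g$tx_start + 100L else g$tx_end - 100L,
    UTR3_snv = if (plus) g$tx_end - 100L else g$tx_start + 100L,
    upstream_snv = if (plus) g$tx_start - 500L else g$tx_end - 1L + 500L,
    downstream_snv = if (plus) g$tx_end - 1L + 500L else g$tx_start - 500L,
    promoter_snv = ,
    enhancer_snv = ,
    silencer_snv = if (plus) g$tx_start - 10000L else g$tx_end - 1L + 10000L,
    stop_twohit("no SNV position rule for class ", class))
}

snv_csq <- function(class) {
  switch(class, LOF = "stopgain", missense = "missense",
         missense)
}

#' Simulate second-hit variants for a pedigree
#'
#' Plants every variant class in `spec$planted_variant_plan` in carrier
#' children with Mendelian-consistent parental genotypes, emits chromatin
#' segments supporting the regulatory classes, and adds decoy small
#' variants that fail each quality/rarity filter plus decoy STR loci
#' (zero variance, low call rate).  Also returns the per-sample cis
#' expression effects implied by the planted variants and a ground-truth
#' table.
#'
#' @param ped a `twohit_pedigree`.
#' @param spec a [cohort_spec()].
#' @param models gene models from [simulate_gene_models()].
#' @return list with `snv` (`list(variants, gt)`), `sv`, `str`,
#'   `chromatin`, `cis_effects` (gene, sample, logfc) and `truth`.
#' @export
simulate_variants <- function(ped, spec, models) {
  with_seed(derive_seed(spec$seed, "variants"), {
    plan <- spec$planted_variant_plan
    genes <- models$genes
    pool <- genes$gene_id[genes$biotype == "protein_coding" &
                          !startsWith(genes$gene_id, "DELG")]
    children <- trio_children(ped)
    # expand plan to one row per planted instance
    inst <- plan[rep(seq_len(nrow(plan)), plan$n), , drop = FALSE]
    inst$sample <- sample(children, nrow(inst), replace = TRUE)
    if (nrow(inst) > length(pool))
      stop_twohit("not enough genes for the planted variant plan")
    inst$gene_id <- sample(pool, nrow(inst))
    inst$parent <- NA_character_
    fa <- ped$father[match(inst$sample, ped$sample)]
    mo <- ped$mother[match(inst$sample, ped$sample)]
    fa_carrier <- ped$carrier[match(fa, ped$sample)] == 1L
    want_carrier <- inst$inheritance == "carrier_parent"
    want_noncar <- inst$inheritance == "noncarrier_parent"
    inst$parent[want_carrier] <- ifelse(fa_carrier[want_carrier],
                                        fa[want_carrier], mo[want_carrier])
    inst$parent[want_noncar] <- ifelse(fa_carrier[want_noncar],
                                       mo[want_noncar], fa[want_noncar])
    inst$synergy <- FALSE

    # synergy cases: noncarrier-parent-inherited second-hits on
    # deletion-region genes in distinct carrier children (mostly
    # non-coding, echoing the deletion + second-hit interaction design)
    if (spec$n_synergy > 0) {
      delg <- genes$gene_id[startsWith(genes$gene_id, "DELG")]
      syn_class <- rep_len(c("missense", "intronic_snv", "upstream_snv"),
                           spec$n_synergy)
      syn_child <- sample(children, spec$n_synergy,
                          replace = spec$n_synergy > length(children))
      # the deletion's dosage split inflates the per-gene SD, so the
      # second-hit must shift well past one dosage unit to stand out
      syn <- data.frame(class = syn_class, n = 1L, logfc = -1.5,
                        inheritance = "noncarrier_parent",
                        sample = syn_child,
                        gene_id = sample(delg, spec$n_synergy),
                        stringsAsFactors = FALSE)
      sfa <- ped$father[match(syn$sample, ped$sample)]
      smo <- ped$mother[match(syn$sample, ped$sample)]
      sfa_car <- ped$carrier[match(sfa, ped$sample)] == 1L
      syn$parent <- ifelse(sfa_car, smo, sfa)
      syn$synergy <- TRUE
      inst <- rbind(inst, syn[, names(inst)])
    }

    snv_classes <- c("LOF", "missense", "splice_site", "UTR5_snv",
                     "UTR3_snv", "upstream_snv", "downstream_snv",
                     "intronic_snv", "promoter_snv", "enhancer_snv",
                     "silencer_snv")
    is_snv <- inst$class %in% snv_classes
    is_sv <- grepl("^(DEL|DUP)_", inst$class)
    is_str <- grepl("^STR_", inst$class)

    samples <- ped$sample
    vrows <- list(); gts <- list(); chrom_segs <- list()
    sv_rows <- list(); str_rows <- list(); truth <- list()
    cis <- list()
    vcount <- 0L

    add_cis <- function(gene, carriers, logfc) {
      cis[[length(cis) + 1L]] <<- data.frame(gene_id = gene,
                                             sample = carriers,
                                             logfc = logfc,
                                             stringsAsFactors = FALSE)
    }

    # ---- small variants ------------------------------------------------
    first_lof <- TRUE
    for (i in which(is_snv)) {
      vcount <- vcount + 1L
      gi <- genes[genes$gene_id == inst$gene_id[i], ]
      pos <- snv_position(inst$class[i], gi)
      cadd <- switch(inst$class[i],
                     LOF = if (first_lof) 5 else round(runif(1, 25, 45), 1),
                     missense = round(runif(1, 15, 35), 1),
                     splice_site = round(runif(1, 3, 9), 1),
                     round(runif(1, 12, 30), 1))
      if (inst$class[i] == "LOF") first_lof <- FALSE
      vid <- sprintf("snv%04d", vcount)
      vrows[[vcount]] <- data.frame(
        variant_id = vid, contig = gi$contig, pos = pos,
        ref = "A", alt = "T", qual = round(runif(1, 80, 500), 1),
        depth = sample(20:60, 1),
        allele_balance = round(runif(1, 0.4, 0.6), 3),
        qd = round(runif(1, 2, 30), 2),
        gnomad_af = signif(runif(1, 0, 5e-4), 3),
        inhouse_count = sample(0:3, 1),
        cadd = cadd,
        csq = switch(inst$class[i], LOF = "stopgain",
                     missense = "missense", "other"),
        splice = as.integer(inst$class[i] == "splice_site"),
        stringsAsFactors = FALSE)
      gt <- setNames(rep("0/0", length(samples)), samples)
      gt[inst$sample[i]] <- "0/1"
      if (!is.na(inst$parent[i])) gt[inst$parent[i]] <- "0/1"
      gts[[vcount]] <- gt
      if (inst$class[i] %in% c("promoter_snv", "enhancer_snv",
                               "silencer_snv")) {
        state <- switch(inst$class[i], promoter_snv = 2L,
                        enhancer_snv = 5L, silencer_snv = 12L)
        chrom_segs[[length(chrom_segs) + 1L]] <- data.frame(
          contig = gi$contig, start = pos - 250L, end = pos + 250L,
          state = state, stringsAsFactors = FALSE)
      }
      carriers <- names(gt)[gt != "0/0"]
      add_cis(gi$gene_id, carriers, inst$logfc[i])
      truth[[length(truth) + 1L]] <- cbind(
        truth_row(gi$gene_id, inst$sample[i], "cis_de", inst$logfc[i],
                  inst$parent[i], inst$class[i]),
        variant_id = vid)
      if (inst$synergy[i])
        truth[[length(truth) + 1L]] <- cbind(
          truth_row(gi$gene_id, inst$sample[i], "synergy", inst$logfc[i],
                    inst$parent[i], inst$class[i]),
          variant_id = vid)
    }

    # decoy small variants: each fails exactly one filter
    decoy_fail <- c("cadd", "af", "qual", "depth", "ab", "qd", "inhouse")
    decoy_pool <- setdiff(pool, inst$gene_id)
    for (k in seq_along(decoy_fail)) {
      vcount <- vcount + 1L
      gid <- decoy_pool[k]
      gi <- genes[genes$gene_id == gid, ]
      child <- sample(children, 1)
      vrows[[vcount]] <- data.frame(
        variant_id = sprintf("snv%04d", vcount), contig = gi$contig,
        pos = gi$cds_start + 60L, ref = "G", alt = "C",
        qual = if (decoy_fail[k] == "qual") 30 else 200,
        depth = if (decoy_fail[k] == "depth") 5L else 40L,
        allele_balance = if (decoy_fail[k] == "ab") 0.1 else 0.5,
        qd = if (decoy_fail[k] == "qd") 1.0 else 10,
        gnomad_af = if (decoy_fail[k] == "af") 0.05 else 1e-4,
        inhouse_count = if (decoy_fail[k] == "inhouse") 20L else 1L,
        cadd = if (decoy_fail[k] == "cadd") 9 else 25,
        csq = "missense", splice = 0L, stringsAsFactors = FALSE)
      gt <- setNames(rep("0/0", length(samples)), samples)
      gt[child] <- "0/1"
      gts[[vcount]] <- gt
      truth[[length(truth) + 1L]] <- cbind(
        truth_row(gid, child, "decoy", NA_real_, NA_character_,
                  "missense"),
        variant_id = sprintf("snv%04d", vcount))
    }

    snv <- list(variants = do.call(rbind, vrows),
                gt = do.call(rbind, gts))
    rownames(snv$gt) <- snv$variants$variant_id

    # ---- structural variants -------------------------------------------
    for (i in which(is_sv)) {
      gi <- genes[genes$gene_id == inst$gene_id[i], ]
      type <- sub("_.*$", "", inst$class[i])
      geom <- sub("^(DEL|DUP)_", "", inst$class[i])
      plus <- gi$strand == "+"
      iv <- switch(geom,
        encapsulating = c(gi$tx_start - 1000L, gi$tx_end + 1000L),
        interstitial = c(gi$tx_start + 700L, gi$tx_start + 2000L),
        UTR5_overhang = if (plus) c(gi$tx_start - 2000L, gi$tx_start + 1500L)
                        else c(gi$tx_end - 1500L, gi$tx_end + 2000L),
        UTR3_overhang = if (plus) c(gi$tx_end - 1500L, gi$tx_end + 2000L)
                        else c(gi$tx_start - 2000L, gi$tx_start + 1500L))
      sv_rows[[length(sv_rows) + 1L]] <- data.frame(
        chrom = gi$contig, start = iv[1], end = iv[2], type = type,
        sample = inst$sample[i], genotype = "0/1",
        stringsAsFactors = FALSE)
      carriers <- inst$sample[i]
      if (!is.na(inst$parent[i])) {
        # parental call with slight breakpoint jitter; reciprocal overlap
        # stays far above 50%
        sv_rows[[length(sv_rows) + 1L]] <- data.frame(
          chrom = gi$contig, start = iv[1] + 50L, end = iv[2] + 50L,
          type = type, sample = inst$parent[i], genotype = "0/1",
          stringsAsFactors = FALSE)
        carriers <- c(carriers, inst$parent[i])
      }
      add_cis(gi$gene_id, carriers, inst$logfc[i])
      truth[[length(truth) + 1L]] <- cbind(
        truth_row(gi$gene_id, inst$sample[i], "cis_de", inst$logfc[i],
                  inst$parent[i], inst$class[i]),
        variant_id = sprintf("%s:%d-%d:%s", gi$contig, iv[1], iv[2], type))
    }
    sv <- if (length(sv_rows)) do.call(rbind, sv_rows) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), type = character(0),
                 sample = character(0), genotype = character(0))

    # ---- short tandem repeats ------------------------------------------
    make_locus <- function(gi, class) {
      plus <- gi$strand == "+"
      switch(class,
        STR_exonic = gi$tx_start + 2900L,     # mid exon 2
        STR_intronic = gi$tx_start + 1600L,
        STR_UTR5 = if (plus) gi$tx_start + 100L else gi$tx_end - 100L,
        STR_UTR3 = if (plus) gi$tx_end - 100L else gi$tx_start + 100L,
        STR_upstream = if (plus) gi$tx_start - 500L
                       else gi$tx_end - 1L + 500L,
        STR_downstream = if (plus) gi$tx_end - 1L + 500L
                         else gi$tx_start - 500L)
    }
    emit_locus <- function(gi, pos, expanded_samples, expanded_len = NULL,
                           lengths = NULL, keep = samples) {
      base <- lengths %||% pmax(5L, round(rnorm(length(samples), 10, 0.8)))
      names(base) <- samples
      if (length(expanded_samples)) {
        L <- expanded_len %||%
          as.integer(ceiling(mean(base) + 8 * sd(base)))
        base[expanded_samples] <- L
      }
      data.frame(chrom = gi$contig, start = pos, end = pos + 30L,
                 motif = "CAG", sample = names(base)[names(base) %in% keep],
                 repeat_length = unname(base[names(base) %in% keep]),
                 depth = 40L, qual = 0.99, span = 1L,
                 stringsAsFactors = FALSE)
    }
    for (i in which(is_str)) {
      gi <- genes[genes$gene_id == inst$gene_id[i], ]
      pos <- make_locus(gi, inst$class[i])
      expanded <- c(inst$sample[i],
                    if (!is.na(inst$parent[i])) inst$parent[i])
      str_rows[[length(str_rows) + 1L]] <- emit_locus(gi, pos, expanded)
      add_cis(gi$gene_id, expanded, inst$logfc[i])
      truth[[length(truth) + 1L]] <- cbind(
        truth_row(gi$gene_id, inst$sample[i], "cis_de", inst$logfc[i],
                  inst$parent[i], inst$class[i]),
        variant_id = sprintf("%s:%d:%s", gi$contig, pos, "CAG"))
    }
    # decoy loci: zero variance, and low call rate (no truth rows)
    dg1 <- genes[genes$gene_id == decoy_pool[8], ]
    str_rows[[length(str_rows) + 1L]] <-
      emit_locus(dg1, dg1$tx_start + 1600L, character(0),
                 lengths = rep(12L, length(samples)))
    dg2 <- genes[genes$gene_id == decoy_pool[9], ]
    str_rows[[length(str_rows) + 1L]] <-
      emit_locus(dg2, dg2$tx_start + 1600L, dg2_exp <- sample(children, 1),
                 keep = samples[seq_len(floor(length(samples) * 0.8))])
    str <- do.call(rbind, str_rows)

    # background neutral chromatin far from any gene
    chrom_segs[[length(chrom_segs) + 1L]] <- data.frame(
      contig = "chr1", start = 5e7 + (0:9) * 10000, end = 5e7 +
        (0:9) * 10000 + 5000, state = rep(8:9, 5))
    chromatin <- do.call(rbind, chrom_segs)

    cis_effects <- do.call(rbind, cis)
    # a gene/sample may in principle collect several effects; sum them
    agg <- stats::aggregate(logfc ~ gene_id + sample, cis_effects, sum)
    list(snv = snv, sv = sv, str = str, chromatin = chromatin,
         cis_effects = agg, truth = do.call(rbind, truth))
  })
}

#' Simulate replicate-level expression counts and TPM
#'
#' Counts are negative binomial with log2 mean = baseline + a rank-one
#' family batch effect + per-individual biological noise + deletion dosage
#' (log2 0.5 for deletion-region genes in carriers) + cis variant effects +
#' planted outlier shifts.  The outlier shift is `spec$outlier_effect`
#' times the expected between-individual SD for that gene, so the planted
#' z-shift is calibrated per gene.  TPM is computed from the counts with
#' the gene-model lengths.
#'
#' @param ped pedigree; `variants` output of [simulate_variants()].
#' @param spec a [cohort_spec()]; `models` gene models.
#' @return list(counts, tpm, truth): matrices gene x (sample.replicate)
#'   plus truth rows for dosage and outlier effects.
#' @export
simulate_expression <- function(ped, variants, spec, models) {
  with_seed(derive_seed(spec$seed, "expression"), {
    if (any(spec$dispersion_range <= 0))
      stop_twohit("dispersion must be positive")
    genes <- models$genes
    G <- nrow(genes)
    samples <- ped$sample
    reps <- spec$replicates_per_sample
    cols <- as.vector(t(outer(samples, paste0("r", seq_len(reps)),
                              paste, sep = ".")))
    base <- exp(runif(G, log(spec$mean_range[1]), log(spec$mean_range[2])))
    phi <- runif(G, spec$dispersion_range[1], spec$dispersion_range[2])
    fam_load <- rnorm(G, 0, spec$family_effect_sd)
    fam_score <- rnorm(spec$n_families)
    names(fam_score) <- unique(ped$family)
    bio <- matrix(rnorm(G * length(samples), 0, spec$bio_sd), G)
    colnames(bio) <- samples

    log2mu <- matrix(log2(base), G, length(samples)) +
      outer(fam_load, fam_score[ped$family]) + bio
    # deletion dosage
    delg <- startsWith(genes$gene_id, "DELG")
    carriers <- ped$carrier == 1L
    log2mu[delg, carriers] <- log2mu[delg, carriers] - 1
    # cis effects
    ce <- variants$cis_effects
    for (k in seq_len(nrow(ce))) {
      gi <- match(ce$gene_id[k], genes$gene_id)
      si <- match(ce$sample[k], samples)
      if (!is.na(gi) && !is.na(si))
        log2mu[gi, si] <- log2mu[gi, si] + ce$logfc[k]
    }
    # planted outliers on untouched protein-coding genes
    used <- unique(c(genes$gene_id[delg], ce$gene_id))
    pool <- setdiff(genes$gene_id[genes$biotype == "protein_coding"], used)
    out_gene <- sample(pool, spec$n_outliers)
    out_sample <- sample(samples, spec$n_outliers, replace = TRUE)
    truth <- list()
    # expected between-individual SD of the log2 median-TPM statistic:
    # biological SD plus replicate-median sampling noise for an NB count
    for (k in seq_len(spec$n_outliers)) {
      gi <- match(out_gene[k], genes$gene_id)
      si <- match(out_sample[k], samples)
      rep_var <- 0.449 * (1 / base[gi] + phi[gi]) / log(2)^2
      shift <- spec$outlier_effect * sqrt(spec$bio_sd^2 + rep_var) *
        sample(c(-1, 1), 1)
      log2mu[gi, si] <- log2mu[gi, si] + shift
      truth[[k]] <- truth_row(out_gene[k], out_sample[k], "outlier",
                              spec$outlier_effect)
      truth[[k]]$variant_id <- NA_character_
    }
    for (s in which(carriers)) for (g in which(delg)) {
      truth[[length(truth) + 1L]] <- cbind(
        truth_row(genes$gene_id[g], samples[s], "deletion_dosage", -1),
        variant_id = NA_character_)
    }
    mu <- 2^log2mu
    counts <- matrix(0L, G, length(cols), dimnames = list(genes$gene_id,
                                                          cols))
    for (j in seq_along(cols)) {
      si <- match(sample_of_column(cols[j]), samples)
      counts[, j] <- rnbinom(G, mu = mu[, si], size = 1 / phi)
    }
    tpm <- compute_tpm(counts, genes$length[match(rownames(counts),
                                                  genes$gene_id)])
    list(counts = counts, tpm = tpm, truth = do.call(rbind, truth))
  })
}

#' Simulate isoform-level counts with planted usage shifts
#'
#' Each gene gets 2-3 isoforms with Dirichlet baseline usage; isoform
#' counts are a multinomial split of the gene counts (so per-gene totals
#' are conserved exactly).  Planted splice-shift (gene, child) events move
#' the target isoform's usage to `spec$splice_usage` in all replicates of
#' that child, leaving gene totals untouched.
#'
#' @param counts gene count matrix; `ped` pedigree; `spec`, `models` as
#'   elsewhere; `exclude_genes` genes already carrying planted effects.
#' @return list(counts, map, truth): isoform count matrix, isoform-to-gene
#'   map, splice-shift truth rows.
#' @export
simulate_isoforms <- function(counts, ped, spec, models,
                              exclude_genes = character(0)) {
  with_seed(derive_seed(spec$seed, "isoforms"), {
    gids <- rownames(counts)
    n_iso <- sample(2:3, length(gids), replace = TRUE)
    usage <- lapply(seq_along(gids), function(i) {
      u <- stats::rgamma(n_iso[i], 5)
      u / sum(u)
    })
    pool <- setdiff(gids[models$genes$biotype[
      match(gids, models$genes$gene_id)] == "protein_coding"],
      exclude_genes)
    children <- trio_children(ped)
    sp_gene <- sample(pool, spec$n_splice)
    sp_child <- sample(children, spec$n_splice, replace = TRUE)
    iso_ids <- unlist(lapply(seq_along(gids), function(i)
      paste0(gids[i], ".iso", seq_len(n_iso[i]))))
    map <- data.frame(isoform_id = iso_ids,
                      gene_id = rep(gids, n_iso),
                      stringsAsFactors = FALSE)
    iso_counts <- matrix(0L, length(iso_ids), ncol(counts),
                         dimnames = list(iso_ids, colnames(counts)))
    col_sample <- sample_of_column(colnames(counts))
    for (i in seq_along(gids)) {
      rows <- which(map$gene_id == gids[i])
      sp <- which(sp_gene == gids[i])
      for (j in seq_len(ncol(counts))) {
        p <- usage[[i]]
        if (length(sp) && col_sample[j] %in% sp_child[sp]) {
          p <- p * (1 - spec$splice_usage) / (1 - p[1])
          p[1] <- spec$splice_usage
        }
        iso_counts[rows, j] <- rmultinom(1, counts[i, j], p)[, 1]
      }
    }
    truth <- do.call(rbind, lapply(seq_len(spec$n_splice), function(k)
      cbind(truth_row(sp_gene[k], sp_child[k], "splice_shift",
                      spec$splice_usage),
            variant_id = paste0(sp_gene[k], ".iso1"))))
    list(counts = iso_counts, map = map, truth = truth)
  })
}

#' Simulate per-gene haplotype read counts
#'
#' Non-ASE genes draw hapA counts as Binomial(n, 0.5); planted ASE genes
#' use Binomial(n, `spec$ase_shift`).  A configurable number of planted
#' cases additionally phase a deleterious coding variant onto the major
#' haplotype (hapA), linking a classified variant to the overexpressed
#' allele.
#'
#' @param ped pedigree; `variants` output of [simulate_variants()];
#'   `spec`, `models` as elsewhere.
#' @return list(haplotypes, truth): data.frame(gene_id, individual,
#'   hapA_count, hapB_count, hapA_variants, hapB_variants) plus ASE truth
#'   rows.
#' @export
simulate_haplotype_counts <- function(ped, variants, spec, models) {
  with_seed(derive_seed(spec$seed, "haplotypes"), {
    genes <- models$genes
    gids <- genes$gene_id[genes$biotype == "protein_coding"]
    samples <- ped$sample
    tv <- variants$truth
    coding <- tv[tv$kind == "cis_de" &
                 tv$class %in% c("missense", "LOF"), , drop = FALSE]
    link <- head(coding, spec$n_ase_link)
    pool <- setdiff(gids, c(tv$gene_id,
                            gids[startsWith(gids, "DELG")]))
    ase_gene <- sample(pool, spec$n_ase)
    ase_sample <- sample(samples, spec$n_ase, replace = TRUE)
    df <- expand.grid(gene_id = gids, individual = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- rnbinom(nrow(df), mu = spec$ase_depth, size = 10)
    p <- rep(0.5, nrow(df))
    key <- paste(df$gene_id, df$individual)
    p[key %in% paste(ase_gene, ase_sample)] <- spec$ase_shift
    p[key %in% paste(link$gene_id, link$sample)] <- spec$ase_shift
    hapA <- rbinom(nrow(df), n, p)
    df$hapA_count <- hapA
    df$hapB_count <- n - hapA
    df$hapA_variants <- ""
    df$hapB_variants <- ""
    li <- match(paste(link$gene_id, link$sample), key)
    df$hapA_variants[li] <- link$variant_id
    truth <- rbind(
      if (spec$n_ase) do.call(rbind, lapply(seq_len(spec$n_ase),
        function(k) cbind(truth_row(ase_gene[k], ase_sample[k], "ase",
                                    spec$ase_shift),
                          variant_id = NA_character_))),
      if (nrow(link)) do.call(rbind, lapply(seq_len(nrow(link)),
        function(k) cbind(truth_row(link$gene_id[k], link$sample[k],
                                    "ase_coding_link", spec$ase_shift),
                          variant_id = link$variant_id[k]))))
    list(haplotypes = df, truth = truth)
  })
}

#' Simulate a weighted gene-interaction network
#'
#' Background edges follow an Erdos-Renyi wiring with probability weights
#' straddling the retention threshold 2.0.  In "planted" mode, extra
#' high-weight edges connect second-hit coding-variant genes to
#' expression-changed genes (deletion-region and outlier genes), creating
#' genuine proximity; in "null" mode wiring is independent of labels.
#'
#' @param variants,expression outputs of [simulate_variants()] and
#'   [simulate_expression()]; `spec`, `models` as elsewhere.
#' @return data.frame(geneA, geneB, probability).
#' @export
simulate_network <- function(variants, expression, spec, models) {
  with_seed(derive_seed(spec$seed, "network"), {
    np <- spec$network_params
    nodes <- models$genes$gene_id
    if (length(nodes) < 2) stop_twohit("need >= 2 network nodes")
    pairs <- combn(nodes, 2)
    take <- runif(ncol(pairs)) < np$edge_prob
    above <- runif(sum(take)) < (np$frac_above %||% 0.5)
    w <- ifelse(above, runif(sum(take), 2.05, 4.0),
                runif(sum(take), 0.5, 2.0))
    edges <- data.frame(geneA = pairs[1, take], geneB = pairs[2, take],
                        probability = round(w, 3),
                        stringsAsFactors = FALSE)
    if (identical(np$mode, "planted")) {
      tv <- variants$truth
      setA <- unique(tv$gene_id[tv$kind == "cis_de" &
                                tv$class %in% coding_classes()])
      te <- expression$truth
      setB <- unique(te$gene_id[te$kind %in% c("deletion_dosage",
                                               "outlier")])
      grid <- expand.grid(geneA = setA, geneB = setB,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$geneA != grid$geneB, , drop = FALSE]
      sel <- runif(nrow(grid)) < (np$attach_prob %||% 0.35)
      if (any(sel))
        edges <- rbind(edges, data.frame(
          geneA = grid$geneA[sel], geneB = grid$geneB[sel],
          probability = round(runif(sum(sel), 3, 4), 3)))
    }
    edges
  })
}

#' Simulate a complete labelled synthetic cohort
#'
#' Runs every generator stage in order and assembles the cohort object:
#' pedigree, gene models, variant call sets, chromatin segments,
#' expression/isoform/haplotype matrices, interaction network and the
#' combined ground-truth table.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `twohit_cohort`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' table(cohort$truth$kind)
#' }
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  models <- simulate_gene_models(spec)
  ped <- simulate_pedigree(spec)
  variants <- simulate_variants(ped, spec, models)
  expr <- simulate_expression(ped, variants, spec, models)
  iso <- simulate_isoforms(expr$counts, ped, spec, models,
                           exclude_genes = unique(c(
                             variants$truth$gene_id, expr$truth$gene_id)))
  hap <- simulate_haplotype_counts(ped, variants, spec, models)
  net <- simulate_network(variants, expr, spec, models)
  truth <- rbind(variants$truth, expr$truth, iso$truth, hap$truth)
  rownames(truth) <- NULL
  structure(list(spec = spec, pedigree = ped, models = models,
                 snv = variants$snv, sv = variants$sv, str = variants$str,
                 chromatin = variants$chromatin,
                 cis_effects = variants$cis_effects,
                 counts = expr$counts, tpm = expr$tpm,
                 isoforms = iso[c("counts", "map")],
                 haplotypes = hap$haplotypes, network = net,
                 truth = truth), class = "twohit_cohort")
}
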