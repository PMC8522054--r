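# Rare-variant filtering and the 25-class taxonomy with inheritance.

#' The 25-class second-hit variant taxonomy
#'
#' Eleven SNV/indel classes (coding, UTR, flanking, intronic and
#' chromatin-state regulatory), eight structural-variant classes (deletion
#' and duplication crossed with gene-overlap geometry) and six short tandem
#' repeat classes by genomic location.
#'
#' @return character vector of the 25 class labels.
#' @export
variant_classes <- function() {
  c("LOF", "missense", "splice_site", "UTR5_snv", "UTR3_snv",
    "upstream_snv", "downstream_snv", "intronic_snv", "promoter_snv",
    "enhancer_snv", "silencer_snv",
    paste(rep(c("DEL", "DUP"), each = 4),
          c("encapsulating", "interstitial", "UTR5_overhang",
            "UTR3_overhang"), sep = "_"),
    paste("STR", c("exonic", "intronic", "UTR5", "UTR3", "upstream",
                   "downstream"), sep = "_"))
}

# coding classes used for burden/ASE/network "second-hit coding" sets
coding_classes <- function() {
  c("LOF", "missense", "splice_site", "STR_exonic",
    "DEL_encapsulating", "DUP_encapsulating")
}

#' Variant filter configuration
#'
#' Quality and rarity thresholds for small variants: `QUAL > 50`, read depth
#' `> 8`, allele balance within \[0.25, 0.75\] (or `> 0.9` for homozygous
#' calls), quality-depth (QUAL / alt reads) `>= 1.5` (low-QD calls are
#' removed), gnomAD allele frequency `<= 0.001`, in-house cohort carrier
#' count `< 10`, and CADD `>= 10` for every annotation class except
#' loss-of-function and splice-site variants.
#'
#' @param min_qual,min_depth,ab_range,hom_ab,min_qd,max_af,max_inhouse,min_cadd
#'   thresholds as above.
#' @param missing how to treat records with missing quality fields:
#'   `"drop"` (default) or `"pass"`.
#' @return list of thresholds.
#' @export
variant_filter_config <- function(min_qual = 50, min_depth = 8,
                                  ab_range = c(0.25, 0.75), hom_ab = 0.9,
                                  min_qd = 1.5, max_af = 0.001,
                                  max_inhouse = 10, min_cadd = 10,
                                  missing = c("drop", "pass")) {
  list(min_qual = min_qual, min_depth = min_depth, ab_range = ab_range,
       hom_ab = hom_ab, min_qd = min_qd, max_af = max_af,
       max_inhouse = max_inhouse, min_cadd = min_cadd,
       missing = match.arg(missing))
}

#' Filter small variants on quality, rarity and deleteriousness
#'
#' @param snvs a small-variant set as produced by [simulate_variants()] or
#'   [read_vcf_variants()]: `list(variants = data.frame, gt = matrix)`.
#' @param config a [variant_filter_config()].
#' @return the same structure restricted to passing variants.
#' @export
filter_small_variants <- function(snvs, config = variant_filter_config()) {
  v <- snvs$variants
  if (any(v$depth < 0, na.rm = TRUE) ||
      any(v$gnomad_af < 0 | v$gnomad_af > 1, na.rm = TRUE))
    stop_twohit("negative depth or allele frequency outside [0, 1]")
  qfields <- cbind(v$qual, v$depth, v$allele_balance, v$qd, v$gnomad_af,
                   v$cadd)
  has_na <- rowSums(is.na(qfields)) > 0
  lof_or_splice <- v$csq %in% c("stopgain", "frameshift") | v$splice == 1
  ab_ok <- (v$allele_balance >= config$ab_range[1] &
            v$allele_balance <= config$ab_range[2]) |
           v$allele_balance > config$hom_ab
  keep <- v$qual > config$min_qual &
    v$depth > config$min_depth &
    ab_ok &
    v$qd >= config$min_qd &
    v$gnomad_af <= config$max_af &
    (is.na(v$inhouse_count) | v$inhouse_count < config$max_inhouse) &
    (lof_or_splice | v$cadd >= config$min_cadd)
  keep[is.na(keep)] <- FALSE
  if (config$missing == "pass") keep[has_na] <- TRUE
  list(variants = v[keep, , drop = FALSE],
       gt = snvs$gt[keep, , drop = FALSE])
}

# genic + regulatory labels for one SNV against all genes.  Returns a
# data.frame(gene_id, class); zero rows when nothing applies.
classify_one_snv <- function(contig, pos, csq, splice, genes, exons,
                             chromatin, flank = 1000L, reg_window = 50000L) {
  g <- genes[genes$contig == contig &
             genes$biotype == "protein_coding", , drop = FALSE]
  out <- list()
  if (nrow(g)) {
    tss <- gene_tss(g); tes <- gene_tes(g)
    u5 <- gene_utr5(g); u3 <- gene_utr3(g)
    inside <- pos >= g$tx_start & pos < g$tx_end
    for (i in which(inside)) {
      labs <- character(0)
      if (csq %in% c("stopgain", "frameshift")) labs <- c(labs, "LOF")
      if (csq == "missense") labs <- c(labs, "missense")
      if (isTRUE(splice == 1)) labs <- c(labs, "splice_site")
      if (!length(labs)) {
        gid <- g$gene_id[i]
        if (pos >= u5$start[i] && pos < u5$end[i]) labs <- "UTR5_snv"
        else if (pos >= u3$start[i] && pos < u3$end[i]) labs <- "UTR3_snv"
        else {
          ex <- exons[exons$gene_id == gid, , drop = FALSE]
          in_exon <- any(pos >= ex$start & pos < ex$end)
          if (!in_exon) labs <- "intronic_snv"
          # exonic CDS 'other' consequence (e.g. synonymous): no class
        }
      }
      if (length(labs))
        out[[length(out) + 1L]] <- data.frame(gene_id = g$gene_id[i],
                                              class = labs)
    }
    # flanking labels, strand-aware and outside the transcript
    up <- !inside & ifelse(g$strand == "+",
                           pos < g$tx_start & g$tx_start - pos <= flank,
                           pos >= g$tx_end & pos - (g$tx_end - 1L) <= flank)
    dn <- !inside & ifelse(g$strand == "+",
                           pos >= g$tx_end & pos - (g$tx_end - 1L) <= flank,
                           pos < g$tx_start & g$tx_start - pos <= flank)
    for (i in which(up))
      out[[length(out) + 1L]] <- data.frame(gene_id = g$gene_id[i],
                                            class = "upstream_snv")
    for (i in which(dn))
      out[[length(out) + 1L]] <- data.frame(gene_id = g$gene_id[i],
                                            class = "downstream_snv")
    # regulatory labels: chromatin state at the position, assigned to every
    # gene whose TSS is within the regulatory window
    if (!is.null(chromatin) && nrow(chromatin)) {
      seg <- chromatin[chromatin$contig == contig &
                       chromatin$start <= pos & chromatin$end > pos, ,
                       drop = FALSE]
      if (nrow(seg)) {
        states <- unique(seg$state)
        reg <- character(0)
        if (any(states %in% 1:3)) reg <- c(reg, "promoter_snv")
        if (any(states %in% 4:7)) reg <- c(reg, "enhancer_snv")
        if (any(states == 12)) reg <- c(reg, "silencer_snv")
        if (length(reg)) {
          near <- which(abs(pos - tss) <= reg_window)
          for (i in near)
            out[[length(out) + 1L]] <-
              data.frame(gene_id = g$gene_id[i], class = reg)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), class = character(0)))
  unique(do.call(rbind, out))
}

#' Classify filtered small variants into SNV classes
#'
#' Assigns genic labels from the consequence annotation (stopgain/frameshift
#' to LOF, missense, splice flag to splice-site) or position (5'/3' UTR,
#' intronic, within 1 kbp upstream of the TSS or downstream of the TES,
#' strand-aware), and additional regulatory labels (promoter: chromatin
#' states 1-3; enhancer: 4-7; silencer: 12) when the position falls in a
#' matching chromatin segment within 50 kbp of a gene's TSS.  A variant may
#' yield labels for several genes and several labels per gene.
#'
#' @param snvs filtered small-variant set.
#' @param models gene models.
#' @param chromatin chromatin-state segments: data.frame(contig, start,
#'   end, state), 0-based half-open; or `NULL` to skip regulatory labels.
#' @return data.frame(variant_id, gene_id, class).
#' @export
classify_small_variants <- function(snvs, models, chromatin = NULL) {
  v <- snvs$variants
  known <- unique(models$genes$contig)
  res <- lapply(seq_len(nrow(v)), function(i) {
    if (!v$contig[i] %in% known) {
      warning("variant ", v$variant_id[i],
              " on contig absent from gene models")
      return(NULL)
    }
    cl <- classify_one_snv(v$contig[i], v$pos[i], v$csq[i], v$splice[i],
                           models$genes, models$exons, chromatin)
    if (!nrow(cl)) return(NULL)
    data.frame(variant_id = v$variant_id[i], cl,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(variant_id = character(0), gene_id = character(0),
                      class = character(0))
  res
}

#' Merge adjacent CNV calls
#'
#' Same-type calls from one sample are merged transitively when they overlap
#' or are separated by a gap smaller than 20% of the CNV length and smaller
#' than 50 kbp; the merged interval is the union span.
#'
#' @param calls data.frame(chrom, start, end, type, sample, ...).
#' @param max_gap_frac,max_gap_bp the gap rule.
#' @return merged data.frame with the same key columns.
#' @export
merge_cnv_calls <- function(calls, max_gap_frac = 0.2, max_gap_bp = 50000) {
  if (!nrow(calls)) return(calls)
  keys <- interaction(calls$chrom, calls$sample, calls$type, drop = TRUE)
  out <- lapply(split(calls, keys), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    acc <- list()
    for (i in seq_len(nrow(d))[-1]) {
      gap <- d$start[i] - cur$end
      len <- max(cur$end - cur$start, d$end[i] - d$start[i])
      if (gap <= 0 || (gap < max_gap_frac * len && gap < max_gap_bp)) {
        cur$end <- max(cur$end, d$end[i])
      } else {
        acc[[length(acc) + 1L]] <- cur
        cur <- d[i, , drop = FALSE]
      }
    }
    acc[[length(acc) + 1L]] <- cur
    do.call(rbind, acc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a structural variant against overlapped genes
#'
#' Per overlapped protein-coding gene: encapsulating when the SV spans the
#' whole gene, interstitial when contained within it, and 5'/3' UTR
#' overhang when it covers only the strand-aware 5' or 3' end.
#'
#' @param svs data.frame(chrom, start, end, type, sample) with 0-based
#'   half-open intervals and type DEL or DUP.
#' @param models gene models.
#' @return data.frame(variant_id, gene_id, class, sample); variant ids are
#'   `chrom:start-end:type`.
#' @export
classify_svs <- function(svs, models) {
  g <- models$genes[models$genes$biotype == "protein_coding", ,
                    drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(svs))) {
    if (!svs$type[i] %in% c("DEL", "DUP"))
      stop_twohit("SV type must be DEL or DUP")
    hit <- g[g$contig == svs$chrom[i] &
             g$tx_start < svs$end[i] & g$tx_end > svs$start[i], ,
             drop = FALSE]
    if (!nrow(hit)) next
    five_cov <- ifelse(hit$strand == "+",
                       svs$start[i] <= hit$tx_start,
                       svs$end[i] >= hit$tx_end)
    three_cov <- ifelse(hit$strand == "+",
                        svs$end[i] >= hit$tx_end,
                        svs$start[i] <= hit$tx_start)
    suffix <- ifelse(five_cov & three_cov, "encapsulating",
              ifelse(five_cov, "UTR5_overhang",
              ifelse(three_cov, "UTR3_overhang", "interstitial")))
    out[[length(out) + 1L]] <- data.frame(
      variant_id = sprintf("%s:%d-%d:%s", svs$chrom[i], svs$start[i],
                           svs$end[i], svs$type[i]),
      gene_id = hit$gene_id,
      class = paste(svs$type[i], suffix, sep = "_"),
      sample = svs$sample[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(variant_id = character(0), gene_id = character(0),
                      class = character(0), sample = character(0))
  rownames(res) <- NULL
  res
}

#' Flag short-tandem-repeat expansions across a cohort
#'
#' Loci are first filtered for call quality (read depth in (20, 1000),
#' call QUAL > 0.9, spanning reads), call rate (> 95% of samples) and
#' non-zero variance; an expansion is any call whose repeat length exceeds
#' the cohort mean plus three (sample, n-1) standard deviations at that
#' locus.
#'
#' @param strs data.frame(chrom, start, end, motif, sample, repeat_length,
#'   depth, qual, span).
#' @param n_samples cohort size used for the call-rate filter; defaults to
#'   the number of distinct samples in `strs`.
#' @param call_rate,sd_mult filter and expansion thresholds.
#' @return data.frame of flagged calls with the locus threshold attached.
#' @export
call_str_expansions <- function(strs, n_samples = NULL, call_rate = 0.95,
                                sd_mult = 3) {
  if (any(strs$repeat_length < 0)) stop_twohit("repeat length must be >= 0")
  n_samples <- n_samples %||% length(unique(strs$sample))
  ok <- strs$depth > 20 & strs$depth < 1000 & strs$qual > 0.9 &
    strs$span == 1
  strs <- strs[ok, , drop = FALSE]
  locus <- interaction(strs$chrom, strs$start, strs$end, strs$motif,
                       drop = TRUE)
  out <- lapply(split(strs, locus), function(d) {
    d <- d[!duplicated(d$sample), , drop = FALSE]
    if (nrow(d) <= n_samples * call_rate) return(NULL)
    if (var(d$repeat_length) == 0) return(NULL)
    thr <- mean(d$repeat_length) + sd_mult * sd(d$repeat_length)
    hit <- d[d$repeat_length > thr, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    hit$threshold <- thr
    hit
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(strs[0, , drop = FALSE], threshold = numeric(0))
  rownames(res) <- NULL
  res
}

#' Classify STR expansions by genomic location
#'
#' One label per overlapped or flanking (<= 1 kbp) protein-coding gene:
#' exonic, intronic, 5'/3' UTR, upstream or downstream, strand-aware.
#'
#' @param expansions output of [call_str_expansions()].
#' @param models gene models.
#' @return data.frame(variant_id, gene_id, class, sample).
#' @export
classify_strs <- function(expansions, models, flank = 1000L) {
  g <- models$genes[models$genes$biotype == "protein_coding", ,
                    drop = FALSE]
  ex <- models$exons
  out <- list()
  for (i in seq_len(nrow(expansions))) {
    pos <- expansions$start[i]
    hit <- g[g$contig == expansions$chrom[i], , drop = FALSE]
    if (!nrow(hit)) next
    u5 <- gene_utr5(hit); u3 <- gene_utr3(hit)
    for (j in seq_len(nrow(hit))) {
      lab <- NULL
      if (pos >= hit$tx_start[j] && pos < hit$tx_end[j]) {
        if (pos >= u5$start[j] && pos < u5$end[j]) lab <- "STR_UTR5"
        else if (pos >= u3$start[j] && pos < u3$end[j]) lab <- "STR_UTR3"
        else {
          exj <- ex[ex$gene_id == hit$gene_id[j], , drop = FALSE]
          lab <- if (any(pos >= exj$start & pos < exj$end)) "STR_exonic"
                 else "STR_intronic"
        }
      } else {
        before <- pos < hit$tx_start[j] &&
          hit$tx_start[j] - pos <= flank
        after <- pos >= hit$tx_end[j] &&
          pos - (hit$tx_end[j] - 1L) <= flank
        if (before || after) {
          five_side <- if (hit$strand[j] == "+") before else after
          lab <- if (five_side) "STR_upstream" else "STR_downstream"
        }
      }
      if (!is.null(lab))
        out[[length(out) + 1L]] <- data.frame(
          variant_id = sprintf("%s:%d:%s", expansions$chrom[i],
                               expansions$start[i], expansions$motif[i]),
          gene_id = hit$gene_id[j], class = lab,
          sample = expansions$sample[i], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(variant_id = character(0), gene_id = character(0),
                      class = character(0), sample = character(0))
  rownames(res) <- NULL
  res
}

# parent label helper: carrier_parent / noncarrier_parent for a given
# transmitting parent id
parent_label <- function(parent_id, ped) {
  st <- ped$carrier[match(parent_id, ped$sample)]
  ifelse(st == 1L, "carrier_parent", "noncarrier_parent")
}

#' Assign inheritance to classified variants
#'
#' SNVs are inherited when either parent carries the alternate allele (both
#' parents: unresolved; neither: de novo); SVs when a same-type parental
#' call has > 50% reciprocal overlap; STR expansions when the child repeat
#' length matches a parental length (within `str_tol`).  Individuals
#' without both parents enrolled are labelled `unresolved`.
#'
#' @param classified data.frame(variant_id, gene_id, class, sample) from
#'   the per-type classifiers; SNV rows are expanded per carrier sample
#'   beforehand by [classify_variants()].
#' @param snvs,svs,strs the raw call sets (used to look up parental
#'   genotypes/calls).
#' @param ped a `twohit_pedigree`.
#' @param str_tol absolute repeat-length tolerance for STR matching.
#' @return `classified` with an `inheritance` column.
#' @export
assign_inheritance <- function(classified, snvs, svs, strs, ped,
                               str_tol = 0) {
  if (!all(classified$sample %in% ped$sample))
    stop_twohit("classified samples absent from pedigree")
  inh <- character(nrow(classified))
  fa <- ped$father[match(classified$sample, ped$sample)]
  mo <- ped$mother[match(classified$sample, ped$sample)]
  has_alt <- function(gt) gt %in% c("0/1", "1/1", "0|1", "1|0", "1|1")
  for (i in seq_len(nrow(classified))) {
    if (fa[i] == "0" || mo[i] == "0") { inh[i] <- "unresolved"; next }
    vid <- classified$variant_id[i]
    type <- classified$class[i]
    if (grepl("^(DEL|DUP)_", type)) {
      parts <- regmatches(vid, regexec("^(.+):(\\d+)-(\\d+):(DEL|DUP)$",
                                       vid))[[1]]
      s <- as.numeric(parts[3]); e <- as.numeric(parts[4])
      carriers <- character(0)
      for (p in c(fa[i], mo[i])) {
        pc <- svs[svs$sample == p & svs$type == parts[5] &
                  svs$chrom == parts[2], , drop = FALSE]
        if (nrow(pc) &&
            any(reciprocal_overlap(s, e, pc$start, pc$end) > 0.5))
          carriers <- c(carriers, p)
      }
      inh[i] <- if (length(carriers) == 2L) "unresolved"
                else if (length(carriers) == 1L) parent_label(carriers, ped)
                else "de_novo"
    } else if (grepl("^STR_", type)) {
      parts <- regmatches(vid, regexec("^(.+):(\\d+):(.+)$", vid))[[1]]
      child_len <- strs$repeat_length[strs$sample == classified$sample[i] &
                                      strs$chrom == parts[2] &
                                      strs$start == as.numeric(parts[3])]
      carriers <- character(0)
      for (p in c(fa[i], mo[i])) {
        plen <- strs$repeat_length[strs$sample == p &
                                   strs$chrom == parts[2] &
                                   strs$start == as.numeric(parts[3])]
        if (length(plen) && length(child_len) &&
            any(abs(plen - child_len[1]) <= str_tol))
          carriers <- c(carriers, p)
      }
      inh[i] <- if (length(carriers) == 2L) "unresolved"
                else if (length(carriers) == 1L) parent_label(carriers, ped)
                else "de_novo"
    } else {
      k <- match(vid, snvs$variants$variant_id)
      carriers <- character(0)
      for (p in c(fa[i], mo[i]))
        if (p %in% colnames(snvs$gt) && has_alt(snvs$gt[k, p]))
          carriers <- c(carriers, p)
      inh[i] <- if (length(carriers) == 2L) "unresolved"
                else if (length(carriers) == 1L) parent_label(carriers, ped)
                else "de_novo"
    }
  }
  classified$inheritance <- inh
  classified
}

#' Filter and classify all variant types for a cohort
#'
#' End-to-end taxonomy stage: small-variant quality/rarity/CADD filtering,
#' SNV classification (genic, flanking and regulatory), CNV merging and SV
#' classification, STR expansion calling and classification, and
#' inheritance assignment.
#'
#' @param snvs small-variant set (`list(variants, gt)`).
#' @param svs SV calls data.frame.
#' @param strs STR call table.
#' @param models gene models.
#' @param chromatin chromatin-state segments or `NULL`.
#' @param ped pedigree with carrier statuses.
#' @param filter_config a [variant_filter_config()].
#' @return data.frame(variant_id, gene_id, class, sample, inheritance):
#'   one row per (variant, gene, class, carrier sample).
#' @export
classify_variants <- function(snvs, svs, strs, models, chromatin, ped,
                              filter_config = variant_filter_config()) {
  kept <- filter_small_variants(snvs, filter_config)
  snv_cls <- classify_small_variants(kept, models, chromatin)
  # expand SNV classifications per carrier sample
  if (nrow(snv_cls)) {
    has_alt <- kept$gt %in% c("0/1", "1/1", "0|1", "1|0", "1|1")
    dim(has_alt) <- dim(kept$gt)
    dimnames(has_alt) <- dimnames(kept$gt)
    rows <- lapply(seq_len(nrow(snv_cls)), function(i) {
      k <- match(snv_cls$variant_id[i], kept$variants$variant_id)
      smp <- colnames(has_alt)[has_alt[k, ]]
      if (!length(smp)) return(NULL)
      data.frame(snv_cls[i, , drop = FALSE], sample = smp,
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    snv_cls <- do.call(rbind, rows)
  }
  if (is.null(snv_cls) || !nrow(snv_cls))
    snv_cls <- data.frame(variant_id = character(0),
                          gene_id = character(0), class = character(0),
                          sample = character(0))
  sv_cls <- if (nrow(svs)) classify_svs(merge_cnv_calls(svs), models)
            else data.frame(variant_id = character(0),
                            gene_id = character(0), class = character(0),
                            sample = character(0))
  str_cls <- if (nrow(strs))
    classify_strs(call_str_expansions(strs), models)
  else data.frame(variant_id = character(0), gene_id = character(0),
                  class = character(0), sample = character(0))
  all_cls <- rbind(snv_cls, sv_cls, str_cls)
  all_cls <- unique(all_cls)
  stopifnot(all(all_cls$class %in% variant_classes()))
  assign_inheritance(all_cls, snvs, svs, strs, ped)
}
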