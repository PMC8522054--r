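# Standard-format writers/readers for cohort data: VCF 4.2 small
# variants, BED chromatin segments, TSV call sets and matrices.

#' Write small variants as VCF 4.2
#'
#' INFO keys: DP, AB, QD, GNOMAD_AF, INHOUSE, CADD, CSQ, SPLICE; GT per
#' sample.  Internal 0-based positions are converted to 1-based VCF
#' coordinates.
#'
#' @param snvs `list(variants, gt)` small-variant set.
#' @param path output path.
#' @export
write_vcf <- function(snvs, path) {
  v <- snvs$variants
  samples <- colnames(snvs$gt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=twohit",
    sprintf("##contig=<ID=%s>", unique(v$contig)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AB,Number=1,Type=Float,Description=\"Allele balance\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality depth\">",
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=INHOUSE,Number=1,Type=Integer,Description=\"In-house cohort carrier count\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD Phred score\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=SPLICE,Number=1,Type=Integer,Description=\"Splice-disrupting flag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  info <- sprintf(
    "DP=%d;AB=%s;QD=%s;GNOMAD_AF=%s;INHOUSE=%d;CADD=%s;CSQ=%s;SPLICE=%d",
    v$depth, v$allele_balance, v$qd, v$gnomad_af, v$inhouse_count,
    v$cadd, v$csq, v$splice)
  body <- paste(v$contig, v$pos + 1L, v$variant_id, v$ref, v$alt, v$qual,
                "PASS", info, "GT", sep = "\t")
  gtcol <- apply(snvs$gt, 1, paste, collapse = "\t")
  writeLines(c(hdr, paste(body, gtcol, sep = "\t")), path)
  invisible(path)
}

#' Read small variants from VCF
#'
#' Parses a VCF (via \pkg{vcfR}) with the INFO keys written by
#' [write_vcf()] into the internal small-variant structure (0-based
#' positions).
#'
#' @param path VCF path.
#' @return `list(variants, gt)`.
#' @export
read_vcf_variants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_twohit("reading VCF requires the 'vcfR' package")
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vc)
  num <- function(key) as.numeric(vcfR::extract.info(vc, key))
  v <- data.frame(
    variant_id = fix[, "ID"], contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L, ref = fix[, "REF"],
    alt = fix[, "ALT"], qual = as.numeric(fix[, "QUAL"]),
    depth = as.integer(num("DP")), allele_balance = num("AB"),
    qd = num("QD"), gnomad_af = num("GNOMAD_AF"),
    inhouse_count = as.integer(num("INHOUSE")), cadd = num("CADD"),
    csq = as.character(vcfR::extract.info(vc, "CSQ")),
    splice = as.integer(num("SPLICE")), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vc)
  rownames(gt) <- v$variant_id
  list(variants = v, gt = gt)
}

#' Write a synthetic cohort to a directory
#'
#' Emits: `variants.vcf`, `svs.tsv`, `strs.tsv`, `chromatin.bed`
#' (0-based half-open, state in column 4), `genes.gtf`, `cohort.ped` +
#' `status.tsv`, `counts.tsv`/`tpm.tsv`/`isoforms.tsv` matrices,
#' `haplotypes.tsv`, `network.tsv` and `truth.tsv`.
#'
#' @param cohort a `twohit_cohort` from [simulate_cohort()].
#' @param outdir output directory (created if needed).
#' @return invisibly, `outdir`.
#' @export
write_cohort <- function(cohort, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_twohit("cannot create output directory ", outdir)
  fp <- function(x) file.path(outdir, x)
  write_vcf(cohort$snv, fp("variants.vcf"))
  write_tsv(cohort$sv, fp("svs.tsv"))
  write_tsv(cohort$str, fp("strs.tsv"))
  write.table(cohort$chromatin, fp("chromatin.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gtf(cohort$models, fp("genes.gtf"))
  write_pedigree(cohort$pedigree, fp("cohort.ped"), fp("status.tsv"))
  write_matrix_tsv(cohort$counts, fp("counts.tsv"))
  write_matrix_tsv(cohort$tpm, fp("tpm.tsv"))
  iso <- data.frame(isoform_id = rownames(cohort$isoforms$counts),
                    gene_id = cohort$isoforms$map$gene_id[
                      match(rownames(cohort$isoforms$counts),
                            cohort$isoforms$map$isoform_id)],
                    cohort$isoforms$counts, check.names = FALSE)
  write_tsv(iso, fp("isoforms.tsv"))
  write_tsv(cohort$haplotypes, fp("haplotypes.tsv"))
  write_tsv(cohort$network, fp("network.tsv"))
  write_tsv(cohort$truth, fp("truth.tsv"))
  invisible(outdir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `twohit_cohort`-shaped list (without the generating spec).
#' @export
read_cohort <- function(dir) {
  fp <- function(x) file.path(dir, x)
  for (f in c("variants.vcf", "svs.tsv", "strs.tsv", "chromatin.bed",
              "genes.gtf", "cohort.ped", "status.tsv", "counts.tsv",
              "tpm.tsv", "isoforms.tsv", "haplotypes.tsv", "network.tsv"))
    if (!file.exists(fp(f))) stop_twohit("missing cohort file ", f)
  chromatin <- read.table(fp("chromatin.bed"), sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end",
                                        "state"),
                          stringsAsFactors = FALSE)
  isodf <- read_tsv(fp("isoforms.tsv"))
  iso_counts <- as.matrix(isodf[, -(1:2), drop = FALSE])
  rownames(iso_counts) <- isodf$isoform_id
  truth <- if (file.exists(fp("truth.tsv"))) read_tsv(fp("truth.tsv"))
           else NULL
  structure(list(
    pedigree = parse_pedigree(fp("cohort.ped"), fp("status.tsv")),
    models = read_gtf(fp("genes.gtf")),
    snv = read_vcf_variants(fp("variants.vcf")),
    sv = read_tsv(fp("svs.tsv")),
    str = read_tsv(fp("strs.tsv")),
    chromatin = chromatin,
    counts = read_matrix_tsv(fp("counts.tsv")),
    tpm = read_matrix_tsv(fp("tpm.tsv")),
    isoforms = list(counts = iso_counts,
                    map = isodf[, c("isoform_id", "gene_id")]),
    haplotypes = local({
      h <- read_tsv(fp("haplotypes.tsv"))
      for (cc in c("hapA_variants", "hapB_variants")) {
        h[[cc]] <- as.character(h[[cc]])
        h[[cc]][is.na(h[[cc]])] <- ""
      }
      h$hapA_count <- as.numeric(h$hapA_count)
      h$hapB_count <- as.numeric(h$hapB_count)
      h
    }),
    network = parse_edge_list(fp("network.tsv")),
    truth = truth), class = "twohit_cohort")
}
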