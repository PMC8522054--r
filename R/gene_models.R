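# Synthetic gene models and GTF I/O.
#
# Gene models are a list (class "twohit_gene_models") of two data.frames:
#   genes: gene_id, contig, strand, tx_start, tx_end, cds_start, cds_end,
#          length (sum of exon widths, bp), biotype, pli, rvis
#   exons: gene_id, start, end
# All intervals are internal 0-based half-open; GTF conversion happens at the
# file boundary.

new_gene_models <- function(genes, exons) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  if (any(genes$tx_start >= genes$tx_end))
    stop_twohit("gene transcript intervals must be non-empty")
  structure(list(genes = genes, exons = exons),
            class = "twohit_gene_models")
}

# strand-aware TSS/TES base position (0-based)
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$tx_start,
                                   genes$tx_end - 1L)
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$tx_end - 1L,
                                   genes$tx_start)

# strand-aware UTR intervals as [start, end)
gene_utr5 <- function(genes) {
  data.frame(start = ifelse(genes$strand == "+", genes$tx_start,
                            genes$cds_end),
             end = ifelse(genes$strand == "+", genes$cds_start,
                          genes$tx_end))
}
gene_utr3 <- function(genes) {
  data.frame(start = ifelse(genes$strand == "+", genes$cds_end,
                            genes$tx_start),
             end = ifelse(genes$strand == "+", genes$tx_end,
                          genes$cds_start))
}

#' Simulate gene models for a synthetic cohort
#'
#' Lays out `spec$n_genes` multi-exon protein-coding genes (a handful of
#' non-coding genes included) on two contigs.  The deletion-region genes
#' (default 7) sit contiguously on their own contig.  Exon/intron structure
#' is regular: 3-6 exons of 600 bp separated by 2-kbp introns, with 200-bp
#' UTRs at each transcript end.
#'
#' @param spec a [cohort_spec()].
#' @return a `twohit_gene_models` object.
#' @export
simulate_gene_models <- function(spec = cohort_spec()) {
  with_seed(derive_seed(spec$seed, "genes"), {
    n <- spec$n_genes
    ndel <- spec$deletion_region$n_genes
    if (n <= ndel + 10)
      stop_twohit("n_genes must exceed deletion gene count by > 10")
    ids <- c(sprintf("DELG%02d", seq_len(ndel)),
             sprintf("G%04d", seq_len(n - ndel)))
    contig <- c(rep(spec$deletion_region$contig, ndel),
                rep("chr1", n - ndel))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_ex <- sample(3:6, n, replace = TRUE)
    exw <- 600L; inw <- 2000L
    tx_len <- n_ex * exw + (n_ex - 1L) * inw
    spacing <- 120000L
    # per-contig coordinates
    pos <- integer(n)
    for (ct in unique(contig)) {
      i <- which(contig == ct)
      pos[i] <- 10000L + (seq_along(i) - 1L) * spacing
    }
    genes <- data.frame(
      gene_id = ids, contig = contig, strand = strand,
      tx_start = pos, tx_end = pos + tx_len,
      cds_start = pos + 200L, cds_end = pos + tx_len - 200L,
      length = n_ex * exw,
      biotype = ifelse(seq_len(n) %in% sample((ndel + 1):n, 8L),
                       "lincRNA", "protein_coding"),
      pli = round(stats::rbeta(n, 0.3, 0.7), 3),
      rvis = round(runif(n, 0, 100), 1),
      stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(n), function(i) {
      st <- genes$tx_start[i] + (seq_len(n_ex[i]) - 1L) * (exw + inw)
      data.frame(gene_id = ids[i], start = st, end = st + exw,
                 stringsAsFactors = FALSE)
    }))
    new_gene_models(genes, exons)
  })
}

#' Write gene models as GTF (1-based inclusive)
#'
#' Emits `gene`, `exon` and `CDS` features with `gene_id`, `gene_biotype`,
#' `pli` and `rvis` attributes.
#'
#' @param models a `twohit_gene_models`.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  attr_str <- sprintf(
    'gene_id "%s"; gene_biotype "%s"; pli "%s"; rvis "%s";',
    g$gene_id, g$biotype, g$pli, g$rvis)
  gene_lines <- sprintf("%s\ttwohit\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$contig, g$tx_start + 1L, g$tx_end, g$strand,
                        attr_str)
  ex <- merge(models$exons, g[, c("gene_id", "contig", "strand")],
              by = "gene_id", sort = FALSE)
  exon_lines <- sprintf('%s\ttwohit\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                        ex$contig, ex$start + 1L, ex$end, ex$strand,
                        ex$gene_id)
  cds_lines <- sprintf('%s\ttwohit\tCDS\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                       g$contig, g$cds_start + 1L, g$cds_end, g$strand,
                       g$gene_id)
  writeLines(c(gene_lines, exon_lines, cds_lines), path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Uses \pkg{rtracklayer} to parse the GTF, then converts features back into
#' the package's internal 0-based half-open representation.
#'
#' @param path GTF path (as written by [write_gtf()] or equivalent, with
#'   `gene`, `exon` and `CDS` features keyed by `gene_id`).
#' @return a `twohit_gene_models`.
#' @export
read_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_twohit("reading GTF requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  gn <- df[df$type == "gene", ]
  cds <- df[df$type == "CDS", ]
  ex <- df[df$type == "exon", ]
  i <- match(gn$gene_id, cds$gene_id)
  genes <- data.frame(
    gene_id = gn$gene_id, contig = gn$seqnames, strand = gn$strand,
    tx_start = gn$start - 1L, tx_end = gn$end,
    cds_start = cds$start[i] - 1L, cds_end = cds$end[i],
    biotype = if ("gene_biotype" %in% names(gn)) gn$gene_biotype
              else "protein_coding",
    pli = if ("pli" %in% names(gn)) as.numeric(gn$pli) else NA_real_,
    rvis = if ("rvis" %in% names(gn)) as.numeric(gn$rvis) else NA_real_,
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = ex$gene_id, start = ex$start - 1L,
                      end = ex$end, stringsAsFactors = FALSE)
  exlen <- tapply(exons$end - exons$start, exons$gene_id, sum)
  genes$length <- as.integer(exlen[genes$gene_id])
  genes <- genes[, c("gene_id", "contig", "strand", "tx_start", "tx_end",
                     "cds_start", "cds_end", "length", "biotype", "pli",
                     "rvis")]
  new_gene_models(genes, exons)
}
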