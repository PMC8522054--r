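# Shared fixtures, built in code and memoised across test files.

.twohit_test_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.twohit_test_cache$cohort))
    .twohit_test_cache$cohort <- simulate_cohort(cohort_spec(seed = 1))
  .twohit_test_cache$cohort
}

default_classified <- function() {
  if (is.null(.twohit_test_cache$classified)) {
    co <- default_cohort()
    .twohit_test_cache$classified <- classify_variants(
      co$snv, co$sv, co$str, co$models, co$chromatin, co$pedigree)
  }
  .twohit_test_cache$classified
}

default_pipeline <- function() {
  if (is.null(.twohit_test_cache$pipe)) {
    dir <- file.path(tempdir(), "twohit-default-pipeline")
    .twohit_test_cache$pipe <- suppressWarnings(
      run_pipeline(default_cohort(), dir))
    .twohit_test_cache$pipe_dir <- dir
  }
  .twohit_test_cache$pipe
}

# inheritance label implied by a truth row's transmitting parent
truth_inheritance <- function(truth, ped) {
  ifelse(is.na(truth$parent), "de_novo",
         ifelse(ped$carrier[match(truth$parent, ped$sample)] == 1L,
                "carrier_parent", "noncarrier_parent"))
}

# a tiny single-gene model for classifier unit tests:
# + strand gene on "c1" spanning [1000, 2000), CDS [1200, 1800),
# exons [1000,1300), [1500, 2000)
tiny_models <- function(strand = "+") {
  genes <- data.frame(
    gene_id = "gX", contig = "c1", strand = strand,
    tx_start = 1000L, tx_end = 2000L, cds_start = 1200L,
    cds_end = 1800L, length = 800L, biotype = "protein_coding",
    pli = 0.95, rvis = 10, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "gX", start = c(1000L, 1500L),
                      end = c(1300L, 2000L), stringsAsFactors = FALSE)
  twohit:::new_gene_models(genes, exons)
}

# one-variant small-variant set with all quality fields passing
tiny_snv <- function(pos = 1210, csq = "missense", splice = 0L,
                     cadd = 20, qual = 100, depth = 30, ab = 0.5,
                     qd = 10, af = 1e-4, inhouse = 1L,
                     gt = c(ch = "0/1", fa = "0/1", mo = "0/0")) {
  v <- data.frame(variant_id = "v1", contig = "c1", pos = pos,
                  ref = "A", alt = "T", qual = qual, depth = depth,
                  allele_balance = ab, qd = qd, gnomad_af = af,
                  inhouse_count = inhouse, cadd = cadd, csq = csq,
                  splice = splice, stringsAsFactors = FALSE)
  gtm <- matrix(gt, nrow = 1, dimnames = list("v1", names(gt)))
  list(variants = v, gt = gtm)
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
# (minimum-likelihood rule, as the exact test defines it)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force shortest weighted path by DFS over all simple paths
bf_shortest <- function(edges, from, to) {
  nodes <- unique(c(edges$a, edges$b))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    i <- edges$a == v | edges$b == v
    data.frame(to = ifelse(edges$a[i] == v, edges$b[i], edges$a[i]),
               w = edges$w[i], stringsAsFactors = FALSE)
  })
  best <- Inf
  walk <- function(v, seen, acc) {
    if (acc >= best) return(invisible(NULL))
    if (v == to) { best <<- acc; return(invisible(NULL)) }
    nb <- adj[[v]]
    for (j in seq_len(nrow(nb)))
      if (!nb$to[j] %in% seen)
        walk(nb$to[j], c(seen, nb$to[j]), acc + nb$w[j])
  }
  if (!from %in% nodes || !to %in% nodes) return(Inf)
  walk(from, from, 0)
  best
}
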