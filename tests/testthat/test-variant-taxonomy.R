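# Variant filtering, 25-class taxonomy, CNV merging, STR expansion
# calling, inheritance assignment.

test_that("quality, rarity and CADD filters keep and drop as specified", {
  pass <- tiny_snv()                     # QUAL 100, depth 30, AB .5, CADD 20
  expect_equal(nrow(filter_small_variants(pass)$variants), 1)
  # missense with CADD 9 removed
  expect_equal(nrow(filter_small_variants(tiny_snv(cadd = 9))$variants), 0)
  # stopgain with CADD 5 kept: LOF exempt from the CADD rule
  expect_equal(nrow(filter_small_variants(
    tiny_snv(csq = "stopgain", cadd = 5))$variants), 1)
  # splice-flagged variant with low CADD kept
  expect_equal(nrow(filter_small_variants(
    tiny_snv(splice = 1L, cadd = 4))$variants), 1)
  # each remaining filter
  expect_equal(nrow(filter_small_variants(tiny_snv(qual = 40))$variants), 0)
  expect_equal(nrow(filter_small_variants(tiny_snv(depth = 8))$variants), 0)
  expect_equal(nrow(filter_small_variants(tiny_snv(ab = 0.1))$variants), 0)
  expect_equal(nrow(filter_small_variants(tiny_snv(ab = 0.95))$variants), 1)
  expect_equal(nrow(filter_small_variants(tiny_snv(qd = 1.0))$variants), 0)
  expect_equal(nrow(filter_small_variants(tiny_snv(af = 0.05))$variants), 0)
  expect_equal(nrow(filter_small_variants(
    tiny_snv(inhouse = 10L))$variants), 0)
  expect_error(filter_small_variants(tiny_snv(depth = -1)), "depth")
})

test_that("SNV classification follows position, annotation and chromatin", {
  m <- tiny_models()
  cls <- function(...) classify_small_variants(tiny_snv(...), m, NULL)
  expect_equal(cls(pos = 1210, csq = "stopgain")$class, "LOF")
  expect_equal(cls(pos = 1210, csq = "missense")$class, "missense")
  expect_equal(cls(pos = 1350, csq = "other", splice = 1L)$class,
               "splice_site")
  expect_equal(cls(pos = 1100, csq = "other")$class, "UTR5_snv")
  expect_equal(cls(pos = 1900, csq = "other")$class, "UTR3_snv")
  expect_equal(cls(pos = 1400, csq = "other")$class, "intronic_snv")
  expect_equal(cls(pos = 500, csq = "other")$class, "upstream_snv")
  expect_equal(cls(pos = 2400, csq = "other")$class, "downstream_snv")
  # strand-aware: on the minus strand upstream flips to the right end
  mm <- tiny_models(strand = "-")
  expect_equal(classify_small_variants(
    tiny_snv(pos = 2400, csq = "other"), mm, NULL)$class, "upstream_snv")
})

test_that("regulatory labels need a matching state within 50 kbp of a TSS", {
  m <- tiny_models()
  enh <- data.frame(contig = "c1", start = 400L, end = 600L, state = 5L)
  got <- classify_small_variants(tiny_snv(pos = 500, csq = "other"), m,
                                 enh)
  expect_setequal(got$class, c("upstream_snv", "enhancer_snv"))
  # same segment but a silencer state
  sil <- data.frame(contig = "c1", start = 400L, end = 600L, state = 12L)
  got <- classify_small_variants(tiny_snv(pos = 500, csq = "other"), m,
                                 sil)
  expect_true("silencer_snv" %in% got$class)
  # > 50 kbp from the TSS: no regulatory label
  far <- data.frame(contig = "c1", start = 61000L, end = 62000L,
                    state = 12L)
  got <- classify_small_variants(tiny_snv(pos = 61500, csq = "other"), m,
                                 far)
  expect_equal(nrow(got), 0)
  # variant off every contig: warning + empty
  v <- tiny_snv(); v$variants$contig <- "c9"
  expect_warning(got <- classify_small_variants(v, m, NULL), "contig")
  expect_equal(nrow(got), 0)
})

test_that("CNV merging applies the gap rule transitively", {
  mk <- function(s, e) data.frame(chrom = "c1", start = s, end = e,
                                  type = "DEL", sample = "s1")
  # gap 10k < 20% of 100k and < 50 kbp: merged to the union span
  m <- merge_cnv_calls(rbind(mk(0, 100000), mk(110000, 200000)))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 200000))
  # gap 60 kbp >= 50 kbp: not merged
  m <- merge_cnv_calls(rbind(mk(0, 100000), mk(160000, 260000)))
  expect_equal(nrow(m), 2)
  # overlapping calls always merge
  m <- merge_cnv_calls(rbind(mk(0, 1000), mk(500, 2000)))
  expect_equal(nrow(m), 1)
  # different types never merge
  two <- rbind(mk(0, 1000), mk(500, 2000))
  two$type <- c("DEL", "DUP")
  expect_equal(nrow(merge_cnv_calls(two)), 2)
})

test_that("SV gene-overlap geometry maps to the four classes", {
  m <- tiny_models()          # gene [1000, 2000), + strand
  sv <- function(s, e, type = "DEL")
    data.frame(chrom = "c1", start = s, end = e, type = type,
               sample = "s1")
  expect_equal(classify_svs(sv(900, 2100, "DUP"), m)$class,
               "DUP_encapsulating")
  expect_equal(classify_svs(sv(900, 1500), m)$class, "DEL_UTR5_overhang")
  expect_equal(classify_svs(sv(1100, 1200), m)$class, "DEL_interstitial")
  expect_equal(classify_svs(sv(1500, 2100), m)$class, "DEL_UTR3_overhang")
  # minus strand flips the overhang orientation
  mm <- tiny_models(strand = "-")
  expect_equal(classify_svs(sv(900, 1500), mm)$class, "DEL_UTR3_overhang")
})

test_that("STR expansions use the cohort mean plus three sample SDs", {
  mk <- function(sample, len)
    data.frame(chrom = "c1", start = 100L, end = 130L, motif = "CAG",
               sample = sample, repeat_length = len, depth = 40L,
               qual = 0.99, span = 1L)
  tab <- rbind(do.call(rbind, lapply(1:20, function(i)
    mk(paste0("s", i), 10))), mk("s21", 30))
  got <- call_str_expansions(tab, n_samples = 21)
  expect_equal(got$sample, "s21")
  expect_equal(got$threshold, mean(tab$repeat_length) +
               3 * sd(tab$repeat_length))
  expect_lt(abs(got$threshold - 24.0), 0.1)
  # all-equal lengths: zero variance, locus dropped
  flat <- do.call(rbind, lapply(1:21, function(i) mk(paste0("s", i), 10)))
  expect_equal(nrow(call_str_expansions(flat, n_samples = 21)), 0)
  # called in 90% of samples with a 95% call-rate filter: dropped
  expect_equal(nrow(call_str_expansions(tab[1:19, ], n_samples = 21)), 0)
})

test_that("STR classes follow genomic position", {
  m <- tiny_models()
  exp_at <- function(pos)
    data.frame(chrom = "c1", start = pos, end = pos + 30L, motif = "CAG",
               sample = "s1", repeat_length = 30, depth = 40, qual = .99,
               span = 1, threshold = 20)
  expect_equal(classify_strs(exp_at(1250L), m)$class, "STR_exonic")
  expect_equal(classify_strs(exp_at(1400L), m)$class, "STR_intronic")
  expect_equal(classify_strs(exp_at(1100L), m)$class, "STR_UTR5")
  expect_equal(classify_strs(exp_at(1900L), m)$class, "STR_UTR3")
  expect_equal(classify_strs(exp_at(500L), m)$class, "STR_upstream")
  expect_equal(classify_strs(exp_at(2400L), m)$class, "STR_downstream")
  expect_equal(nrow(classify_strs(exp_at(990000L), m)), 0)
})

test_that("inheritance assignment distinguishes parents and de novo", {
  ped <- twohit:::new_pedigree(data.frame(
    sample = c("fa", "mo", "ch"), family = "F1",
    father = c("0", "0", "fa"), mother = c("0", "0", "mo"),
    sex = c(1L, 2L, 1L), role = c("parent", "parent", "child"),
    carrier = c(1L, 0L, 1L), stringsAsFactors = FALSE))
  cls <- data.frame(variant_id = "v1", gene_id = "gX",
                    class = "missense", sample = "ch",
                    stringsAsFactors = FALSE)
  mk_snv <- function(gt) tiny_snv(gt = gt)
  got <- assign_inheritance(cls, mk_snv(c(fa = "0/1", mo = "0/0",
                                          ch = "0/1")),
                            data.frame(), data.frame(), ped)
  expect_equal(got$inheritance, "carrier_parent")
  got <- assign_inheritance(cls, mk_snv(c(fa = "0/0", mo = "0/1",
                                          ch = "0/1")),
                            data.frame(), data.frame(), ped)
  expect_equal(got$inheritance, "noncarrier_parent")
  got <- assign_inheritance(cls, mk_snv(c(fa = "0/0", mo = "0/0",
                                          ch = "0/1")),
                            data.frame(), data.frame(), ped)
  expect_equal(got$inheritance, "de_novo")
  got <- assign_inheritance(cls, mk_snv(c(fa = "0/1", mo = "0/1",
                                          ch = "0/1")),
                            data.frame(), data.frame(), ped)
  expect_equal(got$inheritance, "unresolved")
  expect_error(assign_inheritance(
    transform(cls, sample = "nobody"),
    mk_snv(c(fa = "0/0", mo = "0/0", ch = "0/1")),
    data.frame(), data.frame(), ped), "pedigree")
})

test_that("SV inheritance needs strictly more than 50% reciprocal overlap", {
  ped <- twohit:::new_pedigree(data.frame(
    sample = c("fa", "mo", "ch"), family = "F1",
    father = c("0", "0", "fa"), mother = c("0", "0", "mo"),
    sex = c(1L, 2L, 1L), role = c("parent", "parent", "child"),
    carrier = c(1L, 0L, 1L), stringsAsFactors = FALSE))
  cls <- data.frame(variant_id = "c1:100-200:DEL", gene_id = "gX",
                    class = "DEL_interstitial", sample = "ch",
                    stringsAsFactors = FALSE)
  sv_parent <- function(s, e)
    data.frame(chrom = "c1", start = s, end = e, type = "DEL",
               sample = "fa", genotype = "0/1")
  # overlap 50 = exactly 50% of both: NOT inherited
  got <- assign_inheritance(cls, tiny_snv(), sv_parent(150, 250),
                            data.frame(), ped)
  expect_equal(got$inheritance, "de_novo")
  # overlap 60%: inherited from the carrier father
  got <- assign_inheritance(cls, tiny_snv(), sv_parent(140, 240),
                            data.frame(), ped)
  expect_equal(got$inheritance, "carrier_parent")
  # reciprocal-overlap predicate is symmetric
  expect_equal(twohit:::reciprocal_overlap(100, 200, 150, 250),
               twohit:::reciprocal_overlap(150, 250, 100, 200))
})

test_that("classification is order-independent and label-closed", {
  co <- default_cohort()
  cls <- default_classified()
  expect_true(all(cls$class %in% variant_classes()))
  # shuffle the SNV rows and reclassify
  perm <- rev(seq_len(nrow(co$snv$variants)))
  snv2 <- list(variants = co$snv$variants[perm, ],
               gt = co$snv$gt[perm, , drop = FALSE])
  cls2 <- classify_variants(snv2, co$sv, co$str, co$models,
                            co$chromatin, co$pedigree)
  key <- function(d) sort(paste(d$variant_id, d$gene_id, d$class,
                                d$sample, d$inheritance))
  expect_identical(key(cls), key(cls2))
})

test_that("every planted (variant, class, inheritance) triple is recovered", {
  co <- default_cohort()
  cls <- default_classified()
  tv <- co$truth[co$truth$kind == "cis_de", ]
  inh <- truth_inheritance(tv, co$pedigree)
  planted <- paste(tv$gene_id, tv$class, tv$sample, inh)
  called <- paste(cls$gene_id, cls$class, cls$sample, cls$inheritance)
  expect_true(all(planted %in% called))
  decoys <- co$truth[co$truth$kind == "decoy", ]
  expect_false(any(decoys$variant_id %in% cls$variant_id))
})
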