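# Synthetic cohort generator: structure, planted effects, conservation
# laws, determinism.

test_that("default pedigree reproduces the cohort layout", {
  ped <- simulate_pedigree(cohort_spec(seed = 1))
  expect_equal(nrow(ped), 32)
  expect_equal(length(unique(ped$family)), 5)
  expect_equal(sum(ped$carrier == 1), 19)
  expect_equal(sum(ped$carrier == 0), 13)
  expect_equal(sum(ped$role == "child" & ped$carrier == 1), 10)
  # each family has a discordant parent pair
  for (f in unique(ped$family)) {
    pp <- ped[ped$family == f & ped$role %in% c("parent", "grandparent"), ]
    expect_true(any(pp$carrier == 1) && any(pp$carrier == 0))
  }
})

test_that("a minimal one-family template yields one carrier parent", {
  tmpl <- list(data.frame(id = c("P1", "S1", "C1"),
                          father = c("0", "0", "P1"),
                          mother = c("0", "0", "S1"),
                          role = c("parent", "parent", "child"),
                          carrier = c(1L, 0L, 1L),
                          stringsAsFactors = FALSE))
  ped <- simulate_pedigree(cohort_spec(family_structures = tmpl, seed = 3))
  expect_equal(nrow(ped), 3)
  expect_equal(sum(ped$role == "parent" & ped$carrier == 1), 1)
})

test_that("pedigree simulation is deterministic under a fixed seed", {
  p1 <- simulate_pedigree(cohort_spec(seed = 11))
  p2 <- simulate_pedigree(cohort_spec(seed = 11))
  expect_identical(p1, p2)
})

test_that("planted variants are Mendelian-consistent and cover all classes", {
  co <- default_cohort()
  tv <- co$truth[co$truth$kind == "cis_de", ]
  # every class present in some child
  expect_setequal(unique(c(tv$class)), unique(tv$class))
  expect_true(all(variant_classes() %in% tv$class))
  # SNV inherited rows: the stamped parent genotype carries the allele
  snv_rows <- tv[grepl("^snv", tv$variant_id) & !is.na(tv$parent), ]
  for (i in seq_len(nrow(snv_rows))) {
    expect_true(co$snv$gt[snv_rows$variant_id[i], snv_rows$parent[i]]
                %in% c("0/1", "1/1"))
    expect_true(co$snv$gt[snv_rows$variant_id[i], snv_rows$sample[i]]
                %in% c("0/1", "1/1"))
  }
})

test_that("planted STR expansions exceed the recomputed mean + 3 SD", {
  co <- default_cohort()
  tv <- co$truth[co$truth$kind == "cis_de" &
                 grepl("^STR_", co$truth$class), ]
  for (i in seq_len(nrow(tv))) {
    parts <- strsplit(tv$variant_id[i], ":")[[1]]
    loc <- co$str[co$str$chrom == parts[1] &
                  co$str$start == as.integer(parts[2]), ]
    thr <- mean(loc$repeat_length) + 3 * sd(loc$repeat_length)
    child_len <- loc$repeat_length[loc$sample == tv$sample[i]]
    expect_gt(child_len, thr)
  }
})

test_that("deletion dosage halves carrier expression of region genes", {
  co <- default_cohort()
  ped <- co$pedigree
  smp <- twohit:::sample_of_column(colnames(co$counts))
  carrier_cols <- ped$carrier[match(smp, ped$sample)] == 1
  delg <- grep("^DELG", rownames(co$counts), value = TRUE)
  ratios <- vapply(delg, function(g)
    mean(co$counts[g, carrier_cols]) / mean(co$counts[g, !carrier_cols]),
    numeric(1))
  expect_true(all(ratios > 0.3 & ratios < 0.75))
  expect_lt(abs(mean(ratios) - 0.5), 0.1)
})

test_that("planted outliers top the median-TPM ranking for their gene", {
  co <- default_cohort()
  smp <- twohit:::sample_of_column(colnames(co$tpm))
  med <- sapply(unique(smp), function(s)
    apply(co$tpm[, smp == s, drop = FALSE], 1, median))
  tv <- co$truth[co$truth$kind == "outlier", ]
  extreme <- vapply(seq_len(nrow(tv)), function(i) {
    x <- med[tv$gene_id[i], ]
    rank_dev <- rank(-abs(x - median(x)))
    rank_dev[tv$sample[i]] <= 2
  }, logical(1))
  expect_gte(mean(extreme), 0.9)
})

test_that("null genes show equal group means within sampling error", {
  co <- default_cohort()
  used <- unique(co$truth$gene_id)
  null_genes <- setdiff(rownames(co$counts), used)
  smp <- twohit:::sample_of_column(colnames(co$counts))
  carrier_cols <- co$pedigree$carrier[match(smp, co$pedigree$sample)] == 1
  lfc <- vapply(null_genes, function(g)
    log2(mean(co$counts[g, carrier_cols]) /
         mean(co$counts[g, !carrier_cols])), numeric(1))
  expect_lt(abs(mean(lfc)), 0.1)
  expect_lt(mean(abs(lfc) > 0.5), 0.05)
})

test_that("isoform counts conserve gene totals and usage shifts plant", {
  co <- default_cohort()
  sums <- rowsum(co$isoforms$counts + 0,
                 co$isoforms$map$gene_id[
                   match(rownames(co$isoforms$counts),
                         co$isoforms$map$isoform_id)])
  expect_equal(sums[rownames(co$counts), ], co$counts + 0,
               ignore_attr = TRUE)
  tv <- co$truth[co$truth$kind == "splice_shift", ]
  smp <- twohit:::sample_of_column(colnames(co$counts))
  for (i in seq_len(nrow(tv))) {
    iso1 <- paste0(tv$gene_id[i], ".iso1")
    cols <- smp == tv$sample[i]
    usage <- sum(co$isoforms$counts[iso1, cols]) /
      sum(co$counts[tv$gene_id[i], cols])
    expect_gt(usage, 0.8)
    # unaffected relatives keep baseline usage away from the shift
    other <- smp != tv$sample[i]
    usage_other <- sum(co$isoforms$counts[iso1, other]) /
      sum(co$counts[tv$gene_id[i], other])
    expect_lt(usage_other, 0.8)
  }
})

test_that("TPM columns each sum to one million", {
  co <- default_cohort()
  expect_equal(unname(colSums(co$tpm)), rep(1e6, ncol(co$tpm)))
})

test_that("haplotype counts reflect planted allelic fractions", {
  co <- default_cohort()
  hap <- co$haplotypes
  tv <- co$truth[co$truth$kind %in% c("ase", "ase_coding_link"), ]
  key <- paste(hap$gene_id, hap$individual)
  for (i in seq_len(nrow(tv))) {
    row <- hap[key == paste(tv$gene_id[i], tv$sample[i]), ]
    frac <- row$hapA_count / (row$hapA_count + row$hapB_count)
    expect_gt(frac, 0.7)
  }
  # linked cases carry the coding variant on the major haplotype
  link <- co$truth[co$truth$kind == "ase_coding_link", ]
  for (i in seq_len(nrow(link))) {
    row <- hap[key == paste(link$gene_id[i], link$sample[i]), ]
    expect_match(row$hapA_variants, "^snv")
  }
  # null genes: overall allelic fraction near one half
  null_rows <- !key %in% paste(tv$gene_id, tv$sample)
  frac <- sum(hap$hapA_count[null_rows]) /
    sum(hap$hapA_count[null_rows] + hap$hapB_count[null_rows])
  expect_lt(abs(frac - 0.5), 0.01)
})

test_that("planted network proximity wires labelled genes closer", {
  co <- default_cohort()
  g <- build_network(co$network)
  tv <- co$truth
  setA <- unique(tv$gene_id[tv$kind == "cis_de" &
                            tv$class %in% twohit:::coding_classes()])
  setB <- unique(tv$gene_id[tv$kind %in% c("deletion_dosage", "outlier")])
  obs <- avg_min_distance(g, setA, setB)$mean_distance
  pr <- permutation_test(g, setA, setB, n = 50, seed = 7)
  expect_lt(obs, pr$permuted_mean)
})

test_that("cohort simulation is deterministic and file-stable", {
  c1 <- simulate_cohort(cohort_spec(seed = 5, n_genes = 120,
                                    n_outliers = 5, n_splice = 2,
                                    n_ase = 2, n_ase_link = 1))
  c2 <- simulate_cohort(cohort_spec(seed = 5, n_genes = 120,
                                    n_outliers = 5, n_splice = 2,
                                    n_ase = 2, n_ase_link = 1))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$snv, c2$snv)
  expect_identical(c1$network, c2$network)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
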