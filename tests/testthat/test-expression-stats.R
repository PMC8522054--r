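# TPM handling, the NB DE engine, outlier z-scores, PAGE, BH-FDR.

test_that("TPM normalisation matches the rate definition", {
  expect_equal(as.vector(compute_tpm(matrix(c(5, 5)), c(100, 100))),
               c(5e5, 5e5))
  expect_equal(as.vector(compute_tpm(matrix(c(100, 300)), c(1000, 3000))),
               c(5e5, 5e5))
  expect_equal(as.vector(compute_tpm(matrix(7), 500)), 1e6)
  expect_error(compute_tpm(matrix(c(0, 0)), c(100, 100)), "all-zero")
  expect_error(compute_tpm(matrix(c(1, 1)), c(0, 100)), "length")
})

test_that("expressed-gene filter needs all replicates of one sample", {
  tpm <- rbind(kept = c(0.3, 0.3, 0.3, 0.1, 0.1, 0.1),
               dropped = c(0.3, 0.1, 0.3, 0.3, 0.1, 0.3),
               boundary = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
  colnames(tpm) <- c("a.r1", "a.r2", "a.r3", "b.r1", "b.r2", "b.r3")
  expect_equal(filter_expressed(tpm), "kept")
})

test_that("constant counts give zero logFC and p near one", {
  y <- matrix(50L, 5, 8,
              dimnames = list(paste0("g", 1:5),
                              paste0("s", 1:8, ".r1")))
  res <- suppressWarnings(de_test(y, colnames(y)[1:4], colnames(y)[5:8]))
  expect_equal(res$logFC, rep(0, 5), tolerance = 1e-6)
  expect_true(all(res$p > 0.9))
  expect_error(de_test(y + 0.5, colnames(y)[1:4], colnames(y)[5:8]),
               "integers")
})

test_that("a planted fold change is detected with high power", {
  set.seed(42)
  G <- 300; hit <- 1:15
  mu <- matrix(100, G, 12); mu[hit, 7:12] <- 400
  y <- matrix(rnbinom(G * 12, mu = as.vector(mu), size = 10), G,
              dimnames = list(paste0("g", 1:G),
                              paste0("s", 1:12, ".r1")))
  res <- suppressWarnings(de_test(y, colnames(y)[1:6], colnames(y)[7:12]))
  expect_gte(mean(res$fdr[hit] < 0.05), 0.9)
  expect_lt(mean(res$fdr[-hit] < 0.05, na.rm = TRUE), 0.05)
  # cross-check fold changes against the edgeR engine on the same data
  skip_if_not_installed("edgeR")
  dge <- edgeR::DGEList(y, group = rep(c("A", "B"), each = 6))
  dge <- edgeR::calcNormFactors(dge)
  design <- model.matrix(~ rep(c("A", "B"), each = 6))
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmQLFit(dge, design)
  qlf <- edgeR::glmQLFTest(fit)
  both <- res$tested
  expect_gt(cor(res$logFC[both], qlf$table$logFC[both]), 0.98)
})

test_that("LOO intersection is contained in every per-iteration set", {
  pipe <- default_pipeline()
  loo <- pipe$loo
  for (s in names(loo$per_iteration))
    expect_true(all(loo$intersection %in% loo$per_iteration[[s]]))
  # a gene significant in all but one iteration is excluded
  fake <- loo$per_iteration
  fake[[1]] <- setdiff(fake[[1]], loo$intersection[1])
  expect_false(loo$intersection[1] %in% Reduce(intersect, fake))
})

test_that("trio DE applies the logFC and expression thresholds", {
  co <- default_cohort()
  tr <- extract_trios(co$pedigree)[1, ]
  pc <- co$models$genes$gene_id[co$models$genes$biotype ==
                                "protein_coding"]
  counts <- co$counts[intersect(rownames(co$counts), pc), ]
  res <- suppressWarnings(
    trio_de(counts, tr$offspring, tr$carrier_parent))
  tab <- res$table[res$table$tested, ]
  expect_true(all(abs(tab$logFC[tab$gene_id %in% res$de]) > 0.5))
  expect_true(all(tab$fdr[tab$gene_id %in% res$de] < 0.05))
  # gene significant but below the fold-change threshold is not DE
  weak <- tab$gene_id[tab$fdr < 0.05 & abs(tab$logFC) <= 0.5]
  expect_false(any(weak %in% res$de))
})

test_that("outlier z rows are standardised and the threshold is strict", {
  co <- default_cohort()
  pc <- co$models$genes$gene_id[co$models$genes$biotype ==
                                "protein_coding"]
  z <- outlier_zscores(co$tpm[intersect(rownames(co$tpm), pc), ])
  expect_equal(unname(rowMeans(z$z)), rep(0, nrow(z$z)),
               tolerance = 1e-6)
  expect_equal(unname(apply(z$z, 1, sd)), rep(1, nrow(z$z)),
               tolerance = 1e-6)
  expect_true(all(abs(z$z[z$flags]) > 2))
  # constant gene is dropped with a warning
  tpm <- co$tpm[intersect(rownames(co$tpm), pc), ]
  tpm[1, ] <- 5
  expect_warning(z2 <- outlier_zscores(tpm), "zero variance")
  expect_false(rownames(tpm)[1] %in% rownames(z2$z))
})

test_that("latent-factor correction reduces family clustering of outliers", {
  co <- default_cohort()
  pc <- co$models$genes$gene_id[co$models$genes$biotype ==
                                "protein_coding"]
  tpm <- co$tpm[intersect(rownames(co$tpm), pc), ]
  raw <- outlier_zscores(tpm, n_latent = 0)
  cor_ <- outlier_zscores(tpm, n_latent = 1)
  fam <- co$pedigree$family[match(colnames(raw$z), co$pedigree$sample)]
  spread <- function(z) {
    per_fam <- tapply(colSums(abs(z) > 2), fam, mean)
    var(per_fam)
  }
  expect_lte(spread(cor_$z), spread(raw$z))
})

test_that("PAGE matches its closed form and is null-calibrated", {
  # hand-computed example: x has 4 set genes at 2 and 12 others at 0, so
  # mu = 0.5, delta = sqrt(0.8), Z = (2 - 0.5) * 2 / sqrt(0.8)
  x <- setNames(c(rep(2, 4), rep(0, 12)), paste0("g", 1:16))
  got <- page_enrichment(x, list(s = paste0("g", 1:4)), min_size = 4)
  expect_equal(got$Z, 1.5 * 2 / sqrt(0.8), tolerance = 1e-10)
  expect_equal(got$p, 2 * pnorm(-1.5 * 2 / sqrt(0.8)))
  # set mean equal to the global mean -> Z = 0, p = 1
  y <- setNames(rep(c(-1, 1), 10), paste0("h", 1:20))
  got <- page_enrichment(y, list(s = paste0("h", 1:10)), min_size = 10)
  expect_equal(got$Z, 0)
  expect_equal(got$p, 1)
  expect_error(page_enrichment(setNames(rep(1, 20), paste0("h", 1:20)),
                               list(s = paste0("h", 1:10))), "variance")
  # random sets under the null: uniform p (KS)
  set.seed(1)
  big <- setNames(rnorm(2000), paste0("n", 1:2000))
  ps <- replicate(200, page_enrichment(
    big, list(s = sample(names(big), 30)))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("preferential expression uses a strict 2-SD rule", {
  e <- rbind(flat = rep(10, 5), spike = c(10, 10, 10, 10, 40))
  flags <- preferential_expression(e)
  expect_false(any(flags["flat", ]))
  # spike: median 10, sd = sd(row); 40 > 10 + 2 sd but 10 is not
  expect_identical(unname(flags["spike", ]),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # exactly median + 2 SD is not flagged (strict >): for c(0,0,0,k) the
  # spike sits exactly at median + 2 sd for any k
  b <- rbind(g = c(0, 0, 0, 8))
  expect_false(any(preferential_expression(b)))
  expect_error(preferential_expression(e[, 1:2]), "tissues")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27)
  manual <- rev(cummin(rev(p * 5 / seq_along(p))))
  expect_equal(bh_fdr(p), pmin(manual, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(bh_fdr(p) >= p))
})
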