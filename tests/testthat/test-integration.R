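# Variant-class enrichment, burden tests, synergy genes, and
# change-count correlations.

test_that("odds ratios follow the cross-product rule", {
  ch <- data.frame(gene_id = c("g1", "g2", "g3"),
                   sample = "s1", change_type = "outlier")
  # build a background realising the table (2, 8, 1, 89)
  bg <- data.frame(gene_id = paste0("g", 1:100), sample = "s1")
  cls <- data.frame(variant_id = paste0("v", 1:10),
                    gene_id = paste0("g", c(1, 2, 4:11)), sample = "s1",
                    class = "LOF", inheritance = "carrier_parent")
  res <- enrichment_matrix(ch, cls, bg, classes = "LOF")
  expect_equal(unlist(res[, c("a", "b", "c", "d")]),
               c(a = 2, b = 8, c = 1, d = 89))
  expect_equal(res$or, (2 * 89) / (8 * 1))
  expect_equal(res$or, 22.25)
  # balanced table: OR 1, p 1
  ch2 <- data.frame(gene_id = paste0("g", c(1:5, 11:15)), sample = "s1",
                    change_type = "outlier")
  cls2 <- data.frame(variant_id = paste0("v", 1:10),
                     gene_id = paste0("g", 1:10), sample = "s1",
                     class = "LOF", inheritance = "carrier_parent")
  bg2 <- data.frame(gene_id = paste0("g", 1:20), sample = "s1")
  res2 <- enrichment_matrix(ch2, cls2, bg2, classes = "LOF")
  expect_equal(res2$or, 1)
  expect_equal(res2$p, 1)
  # cells conserve the background count
  expect_equal(res2$a + res2$b + res2$c + res2$d, nrow(bg2))
})

test_that("Fisher p equals the hypergeometric oracle for small tables", {
  worst <- 0
  for (n in 2:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      p_impl <- min(1, fisher.test(matrix(c(a, b, cc, d), 2))$p.value)
      p_oracle <- min(1, fisher_oracle(a, b, cc, d))
      worst <- max(worst, abs(p_impl - p_oracle))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("empty strata are skipped with a warning", {
  ch <- data.frame(gene_id = "g1", sample = "s1",
                   change_type = "outlier")
  bg <- data.frame(gene_id = paste0("g", 1:5), sample = "s1")
  cls <- data.frame(variant_id = "v1", gene_id = "g1", sample = "s1",
                    class = "LOF", inheritance = "carrier_parent")
  expect_warning(
    res <- enrichment_matrix(ch, cls, bg,
                             strata = list(none = list(samples = "zz"),
                                           all = list(samples = NULL)),
                             classes = "LOF"),
    "empty stratum")
  expect_equal(unique(res$stratum), "all")
})

test_that("burden test behaves under the null and detects a shift", {
  set.seed(4)
  units <- data.frame(gene_id = paste0("g", 1:2200),
                      sample = "s1",
                      outlier = rep(c(TRUE, FALSE), c(200, 2000)))
  cls_null <- data.frame(variant_id = paste0("v", 1:500),
                         gene_id = sample(units$gene_id, 500),
                         sample = "s1", class = "missense",
                         inheritance = "carrier_parent")
  res <- variant_burden_test(units, cls_null, classes = "missense")
  agg <- res[res$class == "aggregate" & res$scope == "all", ]
  expect_gt(agg$p, 0.05)
  # outlier units shifted +1 variant on average
  extra <- data.frame(variant_id = paste0("w", 1:200),
                      gene_id = units$gene_id[units$outlier],
                      sample = "s1", class = "missense",
                      inheritance = "carrier_parent")
  res2 <- variant_burden_test(units, rbind(cls_null, extra),
                              classes = "missense")
  expect_lt(res2$p[res2$class == "aggregate" & res2$scope == "all"],
            0.05)
  # subset scope restricted to a gene list
  res3 <- variant_burden_test(units, rbind(cls_null, extra),
                              classes = "missense",
                              gene_subsets = list(
                                sub = units$gene_id[1:1000]))
  expect_true("sub" %in% res3$scope)
})

test_that("synergy detection enforces the triple condition", {
  z <- list(z = matrix(c(-3, 0.5), 1, 2,
                       dimnames = list("g1", c("kid", "dad"))),
            flags = matrix(c(TRUE, FALSE), 1, 2,
                           dimnames = list("g1", c("kid", "dad"))))
  base <- data.frame(variant_id = "v1", gene_id = "g1", class = "LOF",
                     sample = "kid", inheritance = "noncarrier_parent")
  got <- synergy_detect("g1", z, base, carriers = "kid")
  expect_equal(nrow(got), 1)
  expect_equal(got$z, -3)
  # variant from the carrier parent: not emitted
  cp <- transform(base, inheritance = "carrier_parent")
  expect_equal(nrow(synergy_detect("g1", z, cp, carriers = "kid")), 0)
  # noncarrier individual: not emitted
  expect_equal(nrow(synergy_detect("g1", z, base, carriers = "dad")), 0)
  # gene not globally DE: not emitted
  expect_equal(nrow(synergy_detect("g9", z, base, carriers = "kid")), 0)
  # planted synergy cases in the default cohort are recovered
  pipe <- default_pipeline()
  co <- default_cohort()
  tv <- co$truth[co$truth$kind == "synergy", ]
  key <- paste(pipe$synergy$gene_id, pipe$synergy$sample)
  expect_true(all(paste(tv$gene_id, tv$sample) %in% key))
})

test_that("change-count correlations handle exact and degenerate cases", {
  m <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 4, 6, 8, 10),
                  z = c(5, 3, 8, 1, 9), const = rep(2, 5))
  res <- change_count_correlations(m)
  expect_equal(res$r[res$col1 == "x" & res$col2 == "y"], 1)
  expect_false(any(res$col1 == "const" | res$col2 == "const"))
  expect_error(change_count_correlations(m[1:4, ]), ">= 5")
  # independent columns: roughly 5% nominally significant
  set.seed(9)
  sig <- replicate(200, {
    a <- rnorm(20); b <- rnorm(20)
    cor.test(a, b)$p.value < 0.05
  })
  expect_lt(abs(mean(sig) - 0.05), 0.05)
})
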