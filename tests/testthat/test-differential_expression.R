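test_that("exact Wilcoxon equals exhaustive enumeration, with and without ties", {
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rpois(n1, 2); y <- rpois(n2, 2)  # heavy ties
    expect_equal(rank_sum_test(x, y), wilcox_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
  # tie-free data additionally agrees with R's exact wilcox.test
  for (i in 1:20) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(rank_sum_test(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("a planted 5-vs-5 separation hits the enumeration p-value", {
  # one gene fully separating the groups; exact two-sided p over all
  # choose(10,5) = 252 assignments
  x <- c(6, 7, 8, 9, 10); y <- c(1, 2, 3, 4, 5)
  expect_equal(rank_sum_test(x, y), wilcox_enum_oracle(x, y))
  expect_equal(rank_sum_test(x, y), 2 / 252)
})

test_that("region_de excludes null genes, reports marker statistics", {
  d <- toy_dataset()
  norm <- normalize_log(d)
  de <- region_de(norm, d, "target", "ref", min_pct = 0, lfc_threshold = 0.25)
  # gC identical in both groups -> lfc 0 -> excluded; gD silent -> excluded
  expect_false("gC" %in% de$gene)
  expect_false("gD" %in% de$gene)
  expect_true(all(c("gA", "gE") %in% de$gene))
  a <- de[de$gene == "gA", ]
  expect_gt(a$lfc, 0)
  expect_equal(a$pct_in, 1)
  expect_equal(a$pct_out, 0.25)
  expect_equal(a$specificity, 4)
  # Bonferroni denominator is the number of genes actually tested
  expect_equal(de$p_adj, pmin(1, de$p * nrow(de)))
  prov <- attr(de, "provenance")
  expect_equal(prov$n_tested, nrow(de))
  expect_error(region_de(norm, d, "nosuch", "ref"), "target")
  expect_error(region_de(norm, d, "target", "target"), "disjoint")
})

test_that("swapping target and reference negates lfc and preserves p", {
  gen <- cached("swap_gen",
                generate_dataset(synthetic_spec(n_genes = 400, n_signature = 30,
                                                n_gradient = 20, n_phase = 10,
                                                seed = 5)))
  d <- gen$dataset
  norm <- normalize_log(d)
  de1 <- region_de(norm, d, "blastema", c("digit", "bone", "boundary"),
                   min_pct = 0.05, lfc_threshold = 0.1)
  de2 <- region_de(norm, d, c("digit", "bone", "boundary"), "blastema",
                   min_pct = 0.05, lfc_threshold = 0.1)
  shared <- intersect(de1$gene, de2$gene)
  expect_gt(length(shared), 10)
  i1 <- match(shared, de1$gene); i2 <- match(shared, de2$gene)
  expect_equal(de1$lfc[i1], -de2$lfc[i2], tolerance = 1e-10)
  expect_equal(de1$p[i1], de2$p[i2], tolerance = 1e-10)
  expect_equal(de1$pct_in[i1], de2$pct_out[i2])
})

test_that("expressing_fraction counts detection on raw counts", {
  counts <- matrix(c(0, 0, 1, 3,
                     0, 0, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gX", "gZ"), paste0("s", 1:4)))
  d <- SpotDataset(counts, data.frame(x = 1:4, y = 0), "s", "r")
  expect_equal(expressing_fraction(d, "gX", paste0("s", 1:4)), 0.5)
  expect_equal(expressing_fraction(d, "gZ", paste0("s", 1:4)), 0)
  expect_error(expressing_fraction(d, "nope", paste0("s", 1:4)), "unknown gene")

  # dense recount oracle on a generated dataset
  gen <- default_gen()
  dn <- as.matrix(gen$dataset$counts[1:50, ])
  bl <- region_spots(gen$dataset, "blastema")
  for (g in rownames(dn)[c(1, 25, 50)])
    expect_equal(expressing_fraction(gen$dataset, g, bl),
                 mean(dn[g, bl] > 0))
})

test_that("specificity_ratio follows the declared conventions", {
  expect_equal(specificity_ratio(0.8, 0.2), 4)
  expect_equal(specificity_ratio(0, 0), 0)
  expect_equal(specificity_ratio(0.5, 0), 1e6)
  expect_equal(specificity_ratio(0.5, 0, cap = 42), 42)
  expect_equal(specificity_ratio(c(0.8, 0, 0.5), c(0.2, 0, 0)),
               c(4, 0, 1e6))
  expect_error(specificity_ratio(1.2, 0.5))
})

test_that("deg_set_overlap reports sizes and pairwise intersections", {
  mk <- function(genes, p_adj = 0.001, lfc = 1)
    structure(data.frame(gene = genes, lfc = lfc, p = p_adj, p_adj = p_adj,
                         pct_in = 1, pct_out = 0.1, specificity = 10),
              class = c("DifferentialTable", "data.frame"))
  ov <- deg_set_overlap(list(A = mk(c("a", "b")), B = mk("c")))
  expect_equal(unname(ov$sizes), c(2L, 1L))
  expect_equal(ov$pairs$intersection, 0L)
  ov2 <- deg_set_overlap(list(X = mk(c("a", "b", "c")),
                              Y = mk(c("b", "c", "d")),
                              Z = mk("z", p_adj = 0.9)))  # not significant
  expect_equal(ov2$pairs$intersection[ov2$pairs$set_a == "X" &
                                        ov2$pairs$set_b == "Y"], 2L)
  expect_equal(unname(ov2$sizes["Z"]), 0L)
})

test_that("planted enriched genes are recovered at 300 vs 900 spots", {
  gen <- default_gen()
  d <- gen$dataset
  # fixed-seed 900-spot reference draw from the non-blastema regions
  others <- region_spots(d, c("digit", "bone", "boundary"))
  ref <- sort(others)[seq(1, length(others), length.out = 900)]
  sub <- subset_spots(d, c(region_spots(d, "blastema"), ref))
  de <- region_de(normalize_log(sub), sub, "blastema",
                  c("digit", "bone", "boundary"))
  planted <- gen$gene_truth$gene[gen$gene_truth$set == "signature"]
  hits <- de$gene[de$p_adj < 0.05 & de$lfc > 0]
  expect_gte(mean(planted %in% hits), 0.95)
})
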