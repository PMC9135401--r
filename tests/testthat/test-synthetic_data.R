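test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_genes = 300, n_signature = 20, n_gradient = 10,
                         n_phase = 10, seed = 17)
  g1 <- generate_dataset(spec)
  g2 <- generate_dataset(spec)
  expect_identical(as.matrix(g1$dataset$counts), as.matrix(g2$dataset$counts))
  expect_identical(g1$spot_truth, g2$spot_truth)
  g3 <- generate_dataset(synthetic_spec(n_genes = 300, n_signature = 20,
                                        n_gradient = 10, n_phase = 10,
                                        seed = 18))
  expect_false(identical(as.matrix(g1$dataset$counts),
                         as.matrix(g3$dataset$counts)))
})

test_that("spec validation rejects infeasible worlds", {
  expect_error(synthetic_spec(n_genes = 50), "n_genes")
  expect_error(synthetic_spec(detect_in = 1.4), "detect_in")
  expect_error(synthetic_spec(cycle_mixture = list(
    blastema = c(S = 0.5, G2M = 0.4, G1 = 0.4),
    boundary = c(S = 0.1, G2M = 0.1, G1 = 0.8),
    bone = c(S = 0.1, G2M = 0.1, G1 = 0.8),
    digit = c(S = 0.1, G2M = 0.1, G1 = 0.8))), "sum to 1")
})

test_that("background counts match negative-binomial moments", {
  # two samples with no depth variation: counts of a background gene are iid
  # NB(mean = rate * depth, size), so empirical moments must track theory
  gen <- cached("moment_gen", generate_dataset(synthetic_spec(
    depth_sdlog = 0,
    samples = data.frame(sample_id = c("a", "b"),
                         condition = c("young", "young")),
    seed = 23)))
  stopifnot(ncol(gen$dataset$counts) >= 2000)
  params <- gen$gene_params
  planted <- gen$gene_truth$gene
  bg <- params[params$model == "background" & !(params$gene %in% planted), ]
  bg <- bg[order(-bg$base_rate), ][1:25, ]  # well-expressed genes
  cnt <- as.matrix(gen$dataset$counts[bg$gene, ])
  n <- ncol(cnt)
  for (i in seq_len(nrow(bg))) {
    mu <- bg$base_rate[i] * gen$spec$mean_depth
    v <- mu + mu^2 / bg$nb_size[i]
    # mean within 4 standard errors; variance within 25% (4th-moment noise)
    expect_lt(abs(mean(cnt[i, ]) - mu), 4 * sqrt(v / n))
    expect_lt(abs(var(cnt[i, ]) - v) / v, 0.25)
  }
})

test_that("layout geometry orders blastema before remaining digit", {
  gen <- default_gen()
  d <- gen$dataset
  line <- gen$polylines[[1]]$vertices
  dist_to_line <- function(pts) {
    dd <- rep(Inf, nrow(pts))
    for (i in seq_len(nrow(line) - 1))
      dd <- pmin(dd, point_segment_distance(pts, line[i, ], line[i + 1, ]))
    dd
  }
  bl <- dist_to_line(d$coords[d$region == "blastema", , drop = FALSE])
  dg <- dist_to_line(d$coords[d$region == "digit", , drop = FALSE])
  expect_lt(max(bl), min(dg))
  # stated world: ~300 blastema spots, ~1200 in the other regions
  expect_gt(sum(d$region == "blastema"), 250)
  expect_lt(sum(d$region == "blastema"), 350)
  expect_gt(sum(d$region != "blastema"), 1100)
})

test_that("planted signature genes realize their effect and specificity", {
  gen <- default_gen()
  d <- gen$dataset
  planted <- gen$gene_truth$gene[gen$gene_truth$set == "signature"]
  bl <- d$region == "blastema"
  cnt <- d$counts[planted, ]
  mean_in <- Matrix::rowMeans(cnt[, bl]); mean_out <- Matrix::rowMeans(cnt[, !bl])
  pct_in <- Matrix::rowMeans(cnt[, bl] > 0)
  pct_out <- Matrix::rowMeans(cnt[, !bl] > 0)
  # mean fold change centred on the requested 2.5
  expect_equal(median(mean_in / mean_out), gen$spec$signature_effect,
               tolerance = 0.15)
  # realized expressing-fraction specificity reaches the stated >= 4
  expect_gte(median(specificity_ratio(pct_in, pct_out)), 4)
})

test_that("a null world yields only Bonferroni-level false positives", {
  gen <- null_gen()
  d <- gen$dataset
  de <- region_de(normalize_log(d), d, "blastema")
  expect_lte(sum(de$p_adj < 0.05), 3)
})

test_that("cell dataset separates the planted cluster by module score", {
  cells <- cached("cell_gen", generate_cell_dataset(
    n_genes = 800, n_clusters = 4, cells_per_cluster = 80,
    signature_genes = sprintf("g%04d", 1:60), seed = 13))
  d <- cells$dataset
  norm <- normalize_log(d)
  ms <- module_score(norm, cells$signature_genes, seed = 5)
  means <- tapply(ms$score, d$region, mean)
  expect_equal(names(which.max(means)), cells$planted_cluster)
  expect_gt(min(means[cells$planted_cluster] - means[names(means) !=
                                                       cells$planted_cluster]),
            0.3)
  # clusters without planted genes sit near zero; binned controls absorb
  # most, but not all, of the planted inflation of dataset-wide means, so a
  # modest negative offset (bounded by the planted share times the effect)
  # is expected
  expect_lt(max(abs(means[names(means) != cells$planted_cluster])), 0.25)
  # deterministic under fixed seed
  cells2 <- generate_cell_dataset(n_genes = 800, n_clusters = 4,
                                  cells_per_cluster = 80,
                                  signature_genes = sprintf("g%04d", 1:60),
                                  seed = 13)
  expect_identical(as.matrix(cells2$dataset$counts), as.matrix(d$counts))
})
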