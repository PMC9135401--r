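# small normalized-like matrix with named dims for direct scorer tests
make_norm <- function(values, n_genes, n_spots, genes = NULL) {
  m <- matrix(values, nrow = n_genes, ncol = n_spots)
  dimnames(m) <- list(if (is.null(genes)) sprintf("g%03d", seq_len(n_genes))
                      else genes,
                      sprintf("s%03d", seq_len(n_spots)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("module_score is zero on a constant matrix and seeded-deterministic", {
  norm <- make_norm(0.7, 60, 15)
  ms <- module_score(norm, sprintf("g%03d", 1:10), n_bins = 4, n_ctrl = 5,
                     seed = 3)
  expect_equal(unname(ms$score), rep(0, 15), tolerance = 1e-12)
  ms2 <- module_score(norm, sprintf("g%03d", 1:10), n_bins = 4, n_ctrl = 5,
                      seed = 3)
  expect_identical(ms, ms2)
  ms3 <- module_score(norm, sprintf("g%03d", 1:10), n_bins = 4, n_ctrl = 5,
                      seed = 4)
  expect_false(identical(ms$control_draws, ms3$control_draws))
})

test_that("module_score matches a brute-force recomputation from its draws", {
  set.seed(31)
  base <- matrix(abs(rnorm(200 * 40, 1, 0.3)), 200, 40)
  sig <- sprintf("g%03d", 1:20)
  shift_spots <- 1:15
  base[1:20, shift_spots] <- base[1:20, shift_spots] + 1  # planted program
  norm <- make_norm(base, 200, 40)
  # n_bins = 5 keeps control candidates in the top bin after the planted
  # genes are excluded from candidacy
  ms <- module_score(norm, sig, n_bins = 5, n_ctrl = 8, seed = 7)
  # independent dense recomputation of the formula with the recorded draws
  dn <- as.matrix(norm)
  pool <- unlist(ms$control_draws)
  expected <- colMeans(dn[sig, , drop = FALSE]) -
    colMeans(dn[pool, , drop = FALSE])
  expect_equal(ms$score, expected, tolerance = 1e-12)
  expect_gt(mean(ms$score[shift_spots]), mean(ms$score[-shift_spots]))
  # controls never include signature genes
  expect_length(intersect(pool, sig), 0)
})

test_that("shift equivariance is exact under fixed control draws", {
  set.seed(32)
  base <- matrix(abs(rnorm(150 * 30, 1, 0.3)), 150, 30)
  norm <- make_norm(base, 150, 30)
  sig <- sprintf("g%03d", 5:24)
  ms0 <- module_score(norm, sig, n_bins = 8, n_ctrl = 10, seed = 9)
  shifted <- base
  shifted[5:24, 1:10] <- shifted[5:24, 1:10] + 1
  ms1 <- module_score(make_norm(shifted, 150, 30), sig, n_bins = 8,
                      n_ctrl = 10, seed = 9,
                      control_draws = ms0$control_draws)
  expect_equal(ms1$score[1:10] - ms0$score[1:10], rep(1, 10),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ms1$score[11:30], ms0$score[11:30], tolerance = 1e-12)
})

test_that("module_score validates its gene-set preconditions", {
  norm <- make_norm(0.5, 30, 5)
  expect_error(module_score(norm, c("nope1", "nope2")), "missing")
  expect_error(module_score(norm, rownames(norm)), "universe")
})

test_that("cell-cycle phases follow the argmax rule with G1 fallback", {
  set.seed(33)
  n_genes <- 120; n_spots <- 30
  base <- matrix(abs(rnorm(n_genes * n_spots, 1, 0.2)), n_genes, n_spots)
  s_genes <- sprintf("g%03d", 1:15)
  g2m_genes <- sprintf("g%03d", 16:30)
  s_spots <- 1:10; g2m_spots <- 11:20  # rest G1
  base[1:15, s_spots] <- base[1:15, s_spots] + 1.5
  base[16:30, g2m_spots] <- base[16:30, g2m_spots] + 1.5
  norm <- make_norm(base, n_genes, n_spots)
  cc <- cell_cycle_score(norm, s_genes, g2m_genes, n_bins = 3, n_ctrl = 8,
                         seed = 2)
  expect_s3_class(cc, "CellCycleResult")
  expect_equal(cc$phase[s_spots], rep("S", 10))
  expect_equal(cc$phase[g2m_spots], rep("G2M", 10))
  # G1 iff neither score positive
  expect_equal(cc$phase == "G1", pmax(cc$s_score, cc$g2m_score) <= 0)
  # argmax with S on ties: rule checked directly on the score columns
  pos <- pmax(cc$s_score, cc$g2m_score) > 0
  expect_equal(cc$phase[pos] == "S", cc$s_score[pos] >= cc$g2m_score[pos])
})

test_that("score_contrast matches enumeration on small groups", {
  counts <- matrix(rpois(40, 3), 4, 10,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  d <- SpotDataset(counts, data.frame(x = 1:10, y = 0), "s",
                   rep(c("a", "b"), each = 5))
  scores <- setNames(c(5, 6, 7, 8, 9, 1, 2, 3, 4, 4.5), paste0("s", 1:10))
  ct <- score_contrast(scores, d, "a", "b")
  expect_equal(ct$mean_diff, mean(scores[1:5]) - mean(scores[6:10]))
  expect_equal(ct$p, wilcox_enum_oracle(scores[1:5], scores[6:10]))
  # identical score vectors: zero difference, p = 1
  same <- setNames(rep(1, 10), paste0("s", 1:10))
  ct0 <- score_contrast(same, d, "a", "b")
  expect_equal(ct0$mean_diff, 0)
  expect_equal(ct0$p, 1)
})

test_that("phase_distribution returns per-region fractions summing to one", {
  counts <- matrix(1, 2, 6, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  d <- SpotDataset(counts, data.frame(x = 1:6, y = 0), "s",
                   c(rep("blastema", 4), "digit", "digit"))
  cc <- structure(data.frame(barcode = paste0("s", 1:4),
                             s_score = c(0.4, 0.2, -1, 0.1),
                             g2m_score = c(-0.1, 0.1, -0.5, 0.3),
                             phase = c("S", "S", "G1", "G2M")),
                  class = c("CellCycleResult", "data.frame"))
  expect_warning(pd <- phase_distribution(cc, d), "digit")
  expect_equal(pd$region, "blastema")
  expect_equal(pd[, c("S", "G2M", "G1")],
               data.frame(S = 0.5, G2M = 0.25, G1 = 0.25))
  expect_equal(rowSums(pd[, c("S", "G2M", "G1")]), 1, ignore_attr = TRUE)
})
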