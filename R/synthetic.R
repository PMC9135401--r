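#' Specification of a synthetic Visium-like digit dataset
#'
#' Describes the stated world the generator emulates: a hex lattice over a
#' digit-shaped domain (remaining digit body, residual bone stump, boundary
#' ring, blastema cap distal to the amputation plane), negative-binomial
#' counts with log-normal spot depths, and planted programs with known
#' ground truth:
#' \itemize{
#'   \item a blastema signature set with controlled mean fold change
#'     (`signature_effect`) and expressing-fraction specificity, modelled as
#'     a per-spot detection gate (probability `detect_in` inside the target
#'     region, `detect_in / detect_ratio` outside) over conditional NB
#'     counts whose means are balanced so the realized mean ratio equals the
#'     requested effect;
#'   \item a proximal-high gradient program whose rate multiplier follows
#'     `exp(beta * (1 - d))` where `d` is the spot's min-max scaled distance
#'     to the bone-stump polyline;
#'   \item S-phase and G2M-phase programs upshifted in spots whose latent
#'     phase (drawn from a per-region mixture) matches.
#' }
#'
#' @param n_genes total genes (default 2000).
#' @param pitch lattice pitch in micrometres (default 100, Visium-like).
#' @param mean_depth mean spot library size (default 5500 UMIs).
#' @param depth_sdlog log-normal sd of spot depth (default 0.35).
#' @param dispersion_range range of per-gene NB size parameters, sampled
#'   log-uniformly (default c(1, 10)).
#' @param n_signature,signature_effect planted blastema signature size and
#'   mean fold change (defaults 100 and 2.5).
#' @param detect_in,detect_ratio in-region detection-gate probability and
#'   its target/rest ratio (defaults 0.6 and 5; the ratio is chosen above
#'   the specificity requirement of 4 because conditional detection losses
#'   shrink the realized expressing-fraction ratio).
#' @param signature_cond_mean conditional NB mean (per unit relative depth)
#'   of signature genes outside the target region (default 4).
#' @param signature_size NB size of signature genes (default 5).
#' @param n_gradient,gradient_beta gradient program size and log-amplitude
#'   (defaults 50 genes, `log(2.5)`).
#' @param n_phase genes per cell-cycle phase program (default 50, about the
#'   size of the canonical S and G2M marker lists).
#' @param cycle_effect rate multiplier of phase genes in matching-phase
#'   spots (default 40: canonical phase markers are switch-like --
#'   near-silent outside cycling cells, strongly induced within them -- and
#'   phase assignment by thresholded module scores relies on that contrast).
#' @param cycle_base_quantiles expression-quantile band over which
#'   phase-marker baseline abundances are spread (default c(0.05, 0.30):
#'   lowly expressed when not cycling, with realistic gene-to-gene spread so
#'   the markers do not crowd a single control bin).
#' @param cycle_mixture named list of per-region `c(S, G2M, G1)` phase
#'   proportions.
#' @param samples data frame `sample_id`, `condition`; one lattice
#'   realization per row.
#' @param condition_effects named list per condition: `cycle_factor`
#'   multiplies the planted S/G2M proportions, `gradient_beta_factor`
#'   scales the gradient amplitude (emulates the aged phenotype).
#' @param seed integer seed; identical specs generate byte-identical data.
#' @return an object of class `SyntheticSpec` (a validated list).
#' @export
synthetic_spec <- function(n_genes = 2000L, pitch = 100,
                           mean_depth = 5500, depth_sdlog = 0.35,
                           dispersion_range = c(1, 10),
                           n_signature = 100L, signature_effect = 2.5,
                           detect_in = 0.6, detect_ratio = 5,
                           signature_cond_mean = 4, signature_size = 5,
                           n_gradient = 50L, gradient_beta = log(2.5),
                           n_phase = 50L, cycle_effect = 40,
                           cycle_base_quantiles = c(0.05, 0.30),
                           cycle_mixture = list(
                             blastema = c(S = 0.25, G2M = 0.20, G1 = 0.55),
                             boundary = c(S = 0.15, G2M = 0.10, G1 = 0.75),
                             bone     = c(S = 0.05, G2M = 0.05, G1 = 0.90),
                             digit    = c(S = 0.05, G2M = 0.05, G1 = 0.90)),
                           samples = data.frame(sample_id = "S1",
                                                condition = "young",
                                                stringsAsFactors = FALSE),
                           condition_effects = list(
                             young = list(cycle_factor = 1,
                                          gradient_beta_factor = 1),
                             aged = list(cycle_factor = 1.5,
                                         gradient_beta_factor = 0.6)),
                           seed = 1L) {
  stopifnot(n_genes >= n_signature + n_gradient + 2 * n_phase,
            pitch > 0, mean_depth > 0, depth_sdlog >= 0,
            length(dispersion_range) == 2, all(dispersion_range > 0),
            signature_effect > 0, detect_in > 0, detect_in <= 1,
            detect_ratio >= 1, cycle_effect > 0)
  if (detect_in > 1 || detect_in / detect_ratio > 1)
    stop("infeasible expressing-fraction target > 1")
  for (m in cycle_mixture)
    if (abs(sum(m) - 1) > 1e-8 || any(m < 0))
      stop("cycle_mixture entries must be non-negative and sum to 1")
  structure(list(n_genes = as.integer(n_genes), pitch = pitch,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 dispersion_range = dispersion_range,
                 n_signature = as.integer(n_signature),
                 signature_effect = signature_effect,
                 detect_in = detect_in, detect_ratio = detect_ratio,
                 signature_cond_mean = signature_cond_mean,
                 signature_size = signature_size,
                 n_gradient = as.integer(n_gradient),
                 gradient_beta = gradient_beta,
                 n_phase = as.integer(n_phase), cycle_effect = cycle_effect,
                 cycle_base_quantiles = cycle_base_quantiles,
                 cycle_mixture = cycle_mixture, samples = samples,
                 condition_effects = condition_effects,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Digit-shaped hex lattice with region labels and the stump polyline.
# Fixed default geometry (micrometre frame, amputation plane at x = 7700):
# digit body x in [200, 5400], |y - cy| <= 800; exposed bone stump
# x in (5400, 7700], |y - cy| <= 250; blastema = half-ellipse cap
# (a = 2200, b = 750) distal to the plane; boundary = 160 um shell around
# the blastema interface. The gap between digit body and the plane keeps
# every digit spot farther from the stump line than any blastema spot
# (layout sanity the tests rely on).
.digit_layout <- function(pitch) {
  scale <- pitch / 100
  x_amp <- 7700 * scale; cy <- 11 * pitch * sqrt(3) / 2
  a <- 2200 * scale; b <- 750 * scale
  rows <- 23L; cols <- 101L
  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  x <- (c_ - 1) * pitch + (r %% 2) * pitch / 2
  y <- (r - 1) * pitch * sqrt(3) / 2
  dy <- abs(y - cy)
  in_blastema <- x > x_amp & ((x - x_amp) / a)^2 + (dy / b)^2 <= 1
  in_boundary_out <- x > x_amp & !in_blastema &
    ((x - x_amp) / (a + 160 * scale))^2 + (dy / (b + 160 * scale))^2 <= 1
  in_boundary_in <- x <= x_amp & x > x_amp - 160 * scale & dy <= b + 160 * scale
  in_bone <- x <= x_amp & x > 5400 * scale & dy <= 250 * scale &
    !in_boundary_in
  in_digit <- x >= 200 * scale & x <= 5400 * scale & dy <= 800 * scale
  region <- rep(NA_character_, length(x))
  region[in_digit] <- "digit"
  region[in_bone] <- "bone"
  region[in_boundary_out | in_boundary_in] <- "boundary"
  region[in_blastema] <- "blastema"
  keep <- !is.na(region)
  list(coords = cbind(x = x[keep], y = y[keep]),
       region = region[keep],
       array_row = r[keep], array_col = c_[keep],
       polyline_vertices = cbind(x = rep(x_amp, 3),
                                 y = c(cy - b, cy, cy + b)))
}

#' Generate a synthetic spot dataset with planted ground truth
#'
#' Draws one lattice realization per sample row of the spec, with
#' negative-binomial counts `counts(g, j) ~ NB(mean = rate(g) * depth(j) *
#' effect(g, j), size(g))`; planted sets perturb `effect` as described in
#' [synthetic_spec()]. Ground truth (planted gene assignments, per-spot
#' phases and gradient positions) is returned alongside the data.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `dataset` ([SpotDataset]), `polylines` (named
#'   list of [ReferencePolyline], one per sample), `gene_truth` (data frame
#'   `gene`, `set`, `effect`), `spot_truth` (data frame `barcode`,
#'   `sample_id`, `region`, `phase`, `grad_pos`), `gene_params` (per-gene
#'   `base_rate`, `nb_size`, `model` for moment-level checks), and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .with_seed(spec$seed, .generate_dataset_impl(spec))
}

.generate_dataset_impl <- function(spec) {
  layout <- .digit_layout(spec$pitch)
  n_spots1 <- nrow(layout$coords)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  idx_sig <- seq_len(spec$n_signature)
  idx_grad <- spec$n_signature + seq_len(spec$n_gradient)
  idx_s <- spec$n_signature + spec$n_gradient + seq_len(spec$n_phase)
  idx_g2m <- spec$n_signature + spec$n_gradient + spec$n_phase +
    seq_len(spec$n_phase)

  # per-gene relative abundance and dispersion (shared across samples).
  # Signature genes use the detection-gate model instead and are excluded
  # from the baseline pool, so background rates sum to 1 and the expected
  # library size stays analytically at mean_depth plus the (small, known)
  # gate contribution.
  w <- stats::rlnorm(spec$n_genes, meanlog = 0, sdlog = 1.2)
  w[idx_grad] <- stats::quantile(w, 0.6)   # gradient program: solid baseline
  qs <- seq(spec$cycle_base_quantiles[1], spec$cycle_base_quantiles[2],
            length.out = spec$n_phase)
  w[idx_s] <- stats::quantile(w, qs)
  w[idx_g2m] <- stats::quantile(w, qs)
  w[idx_sig] <- 0
  rate <- w / sum(w)
  size <- exp(stats::runif(spec$n_genes, log(spec$dispersion_range[1]),
                           log(spec$dispersion_range[2])))

  # gradient position: per-spot scaled distance to the stump line over the
  # blastema (0 proximal, 1 distal); NA outside
  seg_d <- rep(Inf, n_spots1)
  v <- layout$polyline_vertices
  for (i in seq_len(nrow(v) - 1L))
    seg_d <- pmin(seg_d, point_segment_distance(layout$coords, v[i, ], v[i + 1L, ]))
  in_bl <- layout$region == "blastema"
  grad_pos <- rep(NA_real_, n_spots1)
  grad_pos[in_bl] <- (seg_d[in_bl] - min(seg_d[in_bl])) /
    (max(seg_d[in_bl]) - min(seg_d[in_bl]))

  p_in <- spec$detect_in
  p_out <- spec$detect_in / spec$detect_ratio
  m_out <- spec$signature_cond_mean
  m_in <- m_out * spec$signature_effect * p_out / p_in

  counts_list <- list(); bc_list <- list(); sample_list <- list()
  phase_list <- list(); poly_list <- list()
  for (si in seq_len(nrow(spec$samples))) {
    sid <- spec$samples$sample_id[si]
    cond <- spec$samples$condition[si]
    ce <- spec$condition_effects[[cond]]
    if (is.null(ce)) ce <- list(cycle_factor = 1, gradient_beta_factor = 1)
    depth <- stats::rlnorm(n_spots1,
                           meanlog = log(spec$mean_depth) -
                             spec$depth_sdlog^2 / 2,
                           sdlog = spec$depth_sdlog)
    d_rel <- depth / spec$mean_depth

    # latent phases from the (condition-adjusted) per-region mixture
    phase <- character(n_spots1)
    for (reg in names(spec$cycle_mixture)) {
      mix <- spec$cycle_mixture[[reg]]
      mix[c("S", "G2M")] <- pmin(mix[c("S", "G2M")] * ce$cycle_factor, 0.45)
      mix["G1"] <- 1 - sum(mix[c("S", "G2M")])
      ii <- which(layout$region == reg)
      if (length(ii))
        phase[ii] <- sample(c("S", "G2M", "G1"), length(ii), replace = TRUE,
                            prob = mix[c("S", "G2M", "G1")])
    }

    # effect multipliers (genes x spots), 1 by default
    beta <- spec$gradient_beta * ce$gradient_beta_factor
    eff_grad <- rep(1, n_spots1)
    eff_grad[in_bl] <- exp(beta * (1 - grad_pos[in_bl]))

    mu <- outer(rate, depth)                      # baseline means
    mu[idx_grad, ] <- mu[idx_grad, , drop = FALSE] *
      rep(eff_grad, each = length(idx_grad))
    mu[idx_s, ] <- mu[idx_s, , drop = FALSE] *
      rep(ifelse(phase == "S", spec$cycle_effect, 1), each = length(idx_s))
    mu[idx_g2m, ] <- mu[idx_g2m, , drop = FALSE] *
      rep(ifelse(phase == "G2M", spec$cycle_effect, 1),
          each = length(idx_g2m))

    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = rep(size, times = n_spots1)),
                  nrow = spec$n_genes)

    # signature genes: detection gate x conditional NB, overriding baseline
    gate_p <- ifelse(layout$region == "blastema", p_in, p_out)
    cond_mu <- ifelse(layout$region == "blastema", m_in, m_out) * d_rel
    for (g in idx_sig) {
      gate <- stats::rbinom(n_spots1, 1L, gate_p)
      cnt[g, ] <- gate * stats::rnbinom(n_spots1, mu = cond_mu,
                                        size = spec$signature_size)
    }

    bc <- sprintf("%s_BC%05d", sid, seq_len(n_spots1))
    counts_list[[si]] <- cnt
    bc_list[[si]] <- bc
    sample_list[[si]] <- rep(sid, n_spots1)
    phase_list[[si]] <- phase
    poly_list[[sid]] <- ReferencePolyline(sid, layout$polyline_vertices)
  }

  counts <- do.call(cbind, counts_list)
  barcodes <- unlist(bc_list)
  dimnames(counts) <- list(genes, barcodes)
  n_samp <- nrow(spec$samples)
  dataset <- SpotDataset(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    coords = do.call(rbind, rep(list(layout$coords), n_samp)),
    sample_id = unlist(sample_list),
    region = rep(layout$region, n_samp),
    meta = data.frame(array_row = rep(layout$array_row, n_samp),
                      array_col = rep(layout$array_col, n_samp),
                      row.names = barcodes))

  gene_truth <- data.frame(
    gene = genes[c(idx_sig, idx_grad, idx_s, idx_g2m)],
    set = rep(c("signature", "gradient", "s_phase", "g2m_phase"),
              c(length(idx_sig), length(idx_grad), length(idx_s),
                length(idx_g2m))),
    effect = rep(c(spec$signature_effect, exp(spec$gradient_beta),
                   spec$cycle_effect, spec$cycle_effect),
                 c(length(idx_sig), length(idx_grad), length(idx_s),
                   length(idx_g2m))),
    stringsAsFactors = FALSE)
  spot_truth <- data.frame(
    barcode = barcodes,
    sample_id = unlist(sample_list),
    region = rep(layout$region, n_samp),
    phase = unlist(phase_list),
    grad_pos = rep(grad_pos, n_samp),
    stringsAsFactors = FALSE)
  gene_params <- data.frame(
    gene = genes, base_rate = rate, nb_size = size,
    model = ifelse(seq_len(spec$n_genes) %in% idx_sig, "gate", "background"),
    stringsAsFactors = FALSE)

  list(dataset = dataset, polylines = poly_list, gene_truth = gene_truth,
       spot_truth = spot_truth, gene_params = gene_params, spec = spec)
}

#' Generate a synthetic single-cell-like dataset with cluster truth
#'
#' Emulates applying a spatially derived signature back to dissociated-cell
#' data: clustered cells with one blastema-fibroblast-like cluster in which
#' the planted signature genes are upshifted by `effect`. Returned as a
#' [SpotDataset] whose `region` labels are the cluster truth (coordinates
#' are a nominal lattice), so the scoring machinery applies unchanged.
#'
#' @param n_genes total genes.
#' @param n_clusters number of clusters; cluster `"cluster1"` carries the
#'   planted program.
#' @param cells_per_cluster cells per cluster.
#' @param signature_genes ids of the planted genes (default the first 100
#'   gene ids, matching [generate_dataset()]).
#' @param effect rate multiplier of signature genes in the planted cluster.
#' @param mean_depth mean cell library size.
#' @param seed integer seed.
#' @return list with `dataset` ([SpotDataset]; `region` = cluster label),
#'   `planted_cluster`, `signature_genes`.
#' @export
generate_cell_dataset <- function(n_genes = 2000L, n_clusters = 5L,
                                  cells_per_cluster = 150L,
                                  signature_genes = sprintf("g%04d", 1:100),
                                  effect = 2.5, mean_depth = 5000,
                                  seed = 1L) {
  stopifnot(n_clusters >= 2, cells_per_cluster >= 2, effect > 0)
  .with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    if (!all(signature_genes %in% genes))
      stop("signature_genes must be drawn from the generated gene universe")
    n_cells <- n_clusters * cells_per_cluster
    cluster <- rep(paste0("cluster", seq_len(n_clusters)),
                   each = cells_per_cluster)
    w <- stats::rlnorm(n_genes, 0, 1.2)
    w[match(signature_genes, genes)] <- stats::quantile(w, 0.6)
    rate <- w / sum(w)
    size <- exp(stats::runif(n_genes, log(1), log(10)))
    depth <- stats::rlnorm(n_cells, log(mean_depth) - 0.35^2 / 2, 0.35)
    mu <- outer(rate, depth)
    planted <- match(signature_genes, genes)
    in_cl <- cluster == "cluster1"
    mu[planted, in_cl] <- mu[planted, in_cl, drop = FALSE] * effect
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = rep(size, times = n_cells)),
                  nrow = n_genes)
    bc <- sprintf("CELL%05d", seq_len(n_cells))
    dimnames(cnt) <- list(genes, bc)
    grid <- cbind(x = as.numeric((seq_len(n_cells) - 1) %% 50),
                  y = as.numeric((seq_len(n_cells) - 1) %/% 50))
    dataset <- SpotDataset(Matrix::Matrix(cnt, sparse = TRUE), grid,
                           sample_id = "cells", region = cluster)
    list(dataset = dataset, planted_cluster = "cluster1",
         signature_genes = signature_genes)
  })
}
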