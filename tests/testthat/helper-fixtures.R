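# Shared fixtures (built in code, cached for the test run) and independent
# oracles. Oracles deliberately use different algorithms than the package.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# default stated-world dataset (one sample, planted programs)
default_gen <- function() cached("default_gen",
                                 generate_dataset(synthetic_spec(seed = 424242L)))

# everything-null spec: all planted effects neutral
null_spec <- function(seed = 99L)
  synthetic_spec(signature_effect = 1, detect_ratio = 1, gradient_beta = 0,
                 cycle_effect = 1, seed = seed)

null_gen <- function() cached("null_gen", generate_dataset(null_spec()))

# tiny hand-built dataset: 5 genes x 8 spots, two regions, one sample
toy_dataset <- function() {
  counts <- matrix(c(
    # spots:  t1 t2 t3 t4 r1 r2 r3 r4      (t = target, r = reference)
    5, 4, 6, 5, 0, 1, 0, 0,   # gA enriched in target
    0, 0, 1, 3, 0, 2, 1, 0,   # gB mixed
    2, 2, 2, 2, 2, 2, 2, 2,   # gC flat
    0, 0, 0, 0, 0, 0, 0, 0,   # gD silent
    1, 0, 0, 0, 4, 5, 6, 4),  # gE enriched in reference
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("g", LETTERS[1:5]), paste0("spot", 1:8)))
  SpotDataset(counts,
              coords = data.frame(x = c(1:4, 1:4) * 10, y = rep(c(0, 10), each = 4)),
              sample_id = "toy", region = rep(c("target", "ref"), each = 4))
}

# ---- independent Wilcoxon oracle: exhaustive subset enumeration ----
# Enumerates every assignment of the pooled values to the first group with
# utils::combn; two-sided p = share of assignments at least as far from the
# enumeration mean of the rank sum as the observed one.
wilcox_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  combos <- utils::combn(n, n1)
  W <- colSums(matrix(r[combos], nrow = n1))
  mu <- mean(W)
  w_obs <- sum(r[seq_len(n1)])
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
}

# ---- independent polyline-distance oracle: dense sampling + golden-section
# refinement around the best sample (never uses the projection formula) ----
polyline_dist_oracle <- function(p, vertices, n_dense = 1000L) {
  seg_best <- Inf
  for (i in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[i, ]; b <- vertices[i + 1L, ]
    f <- function(t) sqrt(sum((p - (a + t * (b - a)))^2))
    ts <- seq(0, 1, length.out = n_dense)
    ds <- vapply(ts, f, 0)
    j <- which.min(ds)
    lo <- ts[max(1L, j - 1L)]; hi <- ts[min(n_dense, j + 1L)]
    ref <- if (hi > lo)
      stats::optimize(f, c(lo, hi), tol = 1e-12)$objective else ds[j]
    seg_best <- min(seg_best, ref, ds[j])
  }
  seg_best
}

# random rigid motion applied to a point matrix
apply_rigid <- function(xy, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(xy %*% t(R), 2, shift, "+")
}
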