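# Shared coarse-resolution orchard fixtures for fast unit tests.
# 2 x 3 trees at 3 m spacing, 5 cm pixels (140 x 200 px scenes).

mini_spec <- function(seed = 1L, overlap = 0, margin = 1.5, noise_sd = 0.005,
                      smooth_sd = 0.025, ...) {
  orchard_spec(
    n_rows = 2L, n_cols = 3L, row_spacing = 3, tree_spacing = 3,
    margin = margin, resolution = 0.05,
    crown_radius = c(0.8, 0.95), crown_height = c(2, 3),
    scaffold_height = c(1.8, 2.8),
    major_arm_length = c(0.45, 0.6), minor_arm_length = c(0.25, 0.4),
    major_arm_width = 0.15, minor_arm_width = 0.1,
    overlap_factor = overlap, noise_sd = noise_sd, smooth_sd = smooth_sd,
    seed = seed, ...
  )
}

# closing radius scaled to the coarse grid: inter-tree scaffold gaps are
# ~30 px, so 8 px closes within-tree gaps without bridging neighbours
mini_config <- function(...) {
  segment_config(closing_radius = 8L, despeckle_min_area = 16L,
                 min_area = 10L, ...)
}

# match measured crowns to planted trees by nearest scaffold-centroid
match_crowns_to_truth <- function(seg, truth, resolution) {
  sc <- seg$scaffolds
  vapply(seq_len(nrow(sc)), function(i) {
    rr <- sc$centroid_row[i] * resolution
    cc <- sc$centroid_col[i] * resolution
    which.min((truth$trees$centre_row_m - rr)^2 +
              (truth$trees$centre_col_m - cc)^2)
  }, integer(1))
}
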