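# Markers, watershed flooding, fragment merging, end-to-end segmentation.

make_scaffolds <- function(nr, nc, blobs) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    lab[b$rows, b$cols] <- i
  }
  convex_scaffolds(lab)
}

test_that("markers are hull-foliage intersections; unseeded trees reported", {
  sc <- make_scaffolds(20, 20, list(
    list(rows = 3:6, cols = 3:6),
    list(rows = 12:15, cols = 12:15)
  ))
  foliage <- matrix(TRUE, 20, 20)
  mk <- build_markers(sc, foliage)
  expect_identical(mk == 1L, scaffold_hull_mask(sc, 1))
  expect_identical(mk == 2L, scaffold_hull_mask(sc, 2))
  expect_length(attr(mk, "unseeded"), 0)
  # tree 2's hull over background: unseeded and absent
  foliage2 <- matrix(TRUE, 20, 20); foliage2[10:20, 10:20] <- FALSE
  mk2 <- build_markers(sc, foliage2)
  expect_equal(attr(mk2, "unseeded"), 2L)
  expect_false(any(mk2 == 2L))
  expect_error(build_markers(sc, matrix(FALSE, 20, 20)), "no markers")
})

test_that("contested marker pixels go to the nearer centroid, ties to lower id", {
  # tree 1 is a square frame whose hull is the full 2:10 x 2:10 square
  # (centroid (6, 6)); tree 2 is a blob tucked into one corner of that hull,
  # so the hulls overlap on the blob and the blob is nearer its own centroid
  lab <- matrix(0L, 20, 20)
  lab[2:10, 2] <- 1L; lab[2, 2:10] <- 1L; lab[10, 2:10] <- 1L; lab[2:10, 10] <- 1L
  lab[3:4, 3:4] <- 2L # carved into the square's interior, off-centre
  sc <- convex_scaffolds(lab)
  foliage <- matrix(TRUE, 20, 20)
  mk <- build_markers(sc, foliage)
  expect_true(all(mk[3:4, 3:4] == 2L)) # nearer tree 2's centroid (3.5, 3.5)
  expect_true(all(mk[2, 2:10] == 1L))  # the frame stays tree 1

  # exact tie: two interlocking triangles (disjoint pixels, overlapping
  # hulls); centroids (5, 9) and (9, 9), so pixel (7, 9) is equidistant
  lab2 <- matrix(0L, 14, 18)
  lab2[2, 2] <- 1L; lab2[2, 16] <- 1L; lab2[11, 9] <- 1L  # points down
  lab2[12, 2] <- 2L; lab2[12, 16] <- 2L; lab2[3, 9] <- 2L # points up
  sc2 <- convex_scaffolds(lab2)
  expect_equal(sc2$centroid_row, c(5, 9))
  expect_equal(sc2$centroid_col, c(9, 9))
  mk2 <- build_markers(sc2, matrix(TRUE, 14, 18))
  expect_equal(mk2[7, 9], 1L) # tie -> lower tree id
  expect_equal(mk2[6, 9], 1L) # nearer tree 1
  expect_equal(mk2[8, 9], 2L) # nearer tree 2
})

test_that("a single marker floods its whole foliage component and keeps 0 elsewhere", {
  set.seed(41)
  h <- matrix(runif(400, 0, 2), 20, 20)
  foliage <- matrix(FALSE, 20, 20)
  foliage[4:10, 4:10] <- TRUE   # component with the marker
  foliage[15:18, 15:18] <- TRUE # component with no marker
  markers <- matrix(0L, 20, 20); markers[6, 6] <- 1L
  lab <- marker_watershed(height_raster(h, 1), markers, foliage)
  expect_true(all(lab[4:10, 4:10] == 1L))
  expect_true(all(lab[15:18, 15:18] == 0L))
  expect_true(all(lab[!foliage] == 0L))
  expect_error(marker_watershed(height_raster(h, 1), matrix(0L, 20, 20), foliage),
               "at least one non-empty marker")
})

test_that("watershed preserves marker labels and splits a saddle between domes", {
  # two Gaussian domes with a saddle along the middle column
  nr <- 19; nc <- 19
  h <- outer(seq_len(nr), seq_len(nc), function(r, c) {
    pmax(2 * exp(-((r - 10)^2 + (c - 5)^2) / 18),
         2 * exp(-((r - 10)^2 + (c - 15)^2) / 18))
  })
  foliage <- h > 0.05
  markers <- matrix(0L, nr, nc)
  markers[10, 5] <- 1L; markers[10, 15] <- 2L
  lab <- marker_watershed(height_raster(h, 1), markers, foliage)
  expect_identical(lab[markers > 0L], markers[markers > 0L])
  expect_true(all(lab[foliage] > 0L))
  expect_true(all(lab[10, 2:8][foliage[10, 2:8]] == 1L))
  expect_true(all(lab[10, 12:18][foliage[10, 12:18]] == 2L))
  # label boundary lies on the saddle: columns left of 10 are 1, right are 2
  expect_true(all(lab[, 1:9][foliage[, 1:9]] == 1L))
  expect_true(all(lab[, 11:19][foliage[, 11:19]] == 2L))
  # and the result matches the independent ordered-flooding oracle
  expect_identical(lab, oracle_watershed(h, markers, foliage))
})

test_that("watershed matches the ordered-flooding oracle on random scenes", {
  set.seed(42)
  for (i in 1:25) {
    sc <- random_watershed_scene(sample(8:20, 1), sample(8:20, 1), sample(1:3, 1))
    got <- marker_watershed(height_raster(sc$height, 1), sc$markers, sc$foliage)
    expect_identical(got, oracle_watershed(sc$height, sc$markers, sc$foliage))
    # marker preservation and one-label-per-pixel are implied pixel-for-pixel
    expect_identical(got[sc$markers > 0L], sc$markers[sc$markers > 0L])
  }
})

test_that("orphan fragments merge to the nearest hull centroid", {
  sc <- make_scaffolds(30, 30, list(
    list(rows = 4:8, cols = 4:8),    # centroid (6, 6)
    list(rows = 20:24, cols = 20:24) # centroid (22, 22)
  ))
  foliage <- matrix(FALSE, 30, 30)
  foliage[4:8, 4:8] <- TRUE; foliage[20:24, 20:24] <- TRUE
  labels <- matrix(0L, 30, 30)
  labels[4:8, 4:8] <- 1L; labels[20:24, 20:24] <- 2L
  # islet of 5 px nearer tree 2
  foliage[17:18, 17] <- TRUE; foliage[17, 18:20] <- TRUE
  merged <- merge_small_parts(labels, foliage, sc)
  expect_true(all(merged[foliage] > 0L))
  expect_true(all(merged[17:18, 17] == 2L))
  # no orphans: identity
  expect_identical(merge_small_parts(merged, foliage, sc), merged)
  # equidistant islet goes to the lower tree id (midpoint of the centroids)
  foliage2 <- foliage; foliage2[14, 14] <- TRUE
  merged2 <- merge_small_parts(labels, foliage2, sc)
  expect_equal(merged2[14, 14], 1L)
  # max_merge_area guard leaves big fragments unlabelled
  guarded <- merge_small_parts(labels, foliage, sc, max_merge_area = 2)
  expect_true(all(guarded[17, 18:20] == 0L))
})

test_that("segment_trees recovers a small orchard deterministically", {
  spec <- mini_spec(seed = 7L)
  bare <- generate_bare_scene(spec)
  fol <- generate_foliated_scene(spec)
  seg <- segment_trees(bare$raster, fol$raster, config = mini_config())
  expect_equal(seg$stats$n_trees, 6)
  expect_equal(sort(unique(seg$labels[seg$labels > 0])), 1:6)
  expect_length(seg$unseeded, 0)
  # conservation: labelled pixels == foliage pixels, exactly
  expect_identical(seg$labels > 0L, seg$foliage)
  # determinism
  seg2 <- segment_trees(bare$raster, fol$raster, config = mini_config())
  expect_identical(seg2$labels, seg$labels)
  # per-crown containment: each marker region sits inside its crown
  mk <- build_markers(seg$scaffolds, seg$foliage)
  sel <- mk > 0L
  expect_identical(seg$labels[sel], mk[sel])
})

test_that("mismatched rasters and degenerate scenes raise stage-named errors", {
  spec <- mini_spec(seed = 8L)
  bare <- generate_bare_scene(spec)
  small <- height_raster(matrix(0, 10, 10), spec$resolution)
  expect_error(segment_trees(bare$raster, small), "not co-registered")
  flat <- height_raster(matrix(0, dim(bare$raster)[1], dim(bare$raster)[2]),
                        spec$resolution)
  expect_error(segment_trees(flat, flat, config = mini_config()),
               "scaffold stage")
  expect_error(foliage_mask(flat), "no crowns detected")
})

test_that("masking a tree out of the field removes it from the foliage mask", {
  spec <- mini_spec(seed = 9L)
  fol <- generate_foliated_scene(spec)
  dims <- dim(fol$raster)
  # exclude the last planting column (tree centres at col 160 of 200)
  poly <- polygon_mask(x = c(0, 130, 130, 0), y = c(0, 0, dims[1] + 1, dims[1] + 1))
  fg <- foliage_mask(fol$raster, poly, threshold_params())
  excluded <- fol$truth$labels %in% c(5L, 6L) # trees in the last column
  expect_false(any(fg[matrix(excluded, dims[1], dims[2]) & col(fg) > 130]))
  # and crowns inside the polygon are still well covered
  kept <- fol$truth$labels == 1L
  expect_gt(sum(fg[kept]) / sum(kept), 0.9)
})

test_that("increasing crown overlap never increases recovered-count accuracy", {
  overlaps <- c(0, 0.4, 0.8)
  correct <- sapply(overlaps, function(ov) {
    hits <- 0
    for (seed in 1:3) {
      spec <- mini_spec(seed = seed, overlap = ov, margin = 2.5)
      # window widened so corner neighbourhoods still reach a tree centre
      # (margin here exceeds half the default window)
      seg <- try(segment_trees(generate_bare_scene(spec)$raster,
                               generate_foliated_scene(spec)$raster,
                               config = mini_config(window = 111L)), silent = TRUE)
      if (inherits(seg, "try-error")) next
      fol <- generate_foliated_scene(spec)
      rec <- crown_metrics(seg, spec$resolution)
      m <- match_crowns_to_truth(seg, fol$truth, spec$resolution)
      ok <- seg$stats$n_trees == 6 &&
        length(unique(seg$labels[seg$labels > 0])) == 6 &&
        length(unique(m)) == 6 &&
        all(abs(rec$CPA_m2 / fol$truth$records$CPA_m2[m] - 1) <= 0.25)
      if (ok) hits <- hits + 1
    }
    hits
  })
  expect_true(all(diff(correct) <= 0))
  expect_equal(correct[1], 3) # clean scenes always recover all six trees
})
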