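test_that("the composite area-by-layer atlas counts and encodes correctly", {
  ph <- make_phantom(phantom_spec(hemi_width = 8L, length = 30L, n_areas = 3L,
                                  seed = 5L))
  dep <- compute_depth(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equidistant")
  atlas <- make_layer_atlas(ph$area_labels, dep, ph$gm_mask, n_layers = 6L)
  labs <- setdiff(unique(as.integer(atlas)), 0L)
  expect_equal(length(labs), 3L * 6L)
  expect_setequal(labs %/% 100L, 1:3)
  expect_setequal(labs %% 100L, 1:6)
  # every labeled GM voxel with defined depth got exactly one composite label
  sel <- ph$area_labels > 0L & !is.na(dep$depth)
  expect_true(all(atlas[sel] > 0L))
  # layer volumes within an area are near-equal on the flat ribbon
  v <- table(atlas[atlas %/% 100L == 2L])
  expect_lt(max(abs(v - mean(v))) / mean(v), 0.10)
  expect_error(make_layer_atlas(ph$area_labels, dep, ph$gm_mask, 100L), "1..99")
})

test_that("cross-tabulation counts voxel overlaps exactly", {
  dims <- c(6, 5, 2)
  a <- array(0L, dims); b <- array(0L, dims)
  a[1:3, , 1] <- 1L; a[4:6, , 1] <- 2L           # 15 / 15
  b[1:3, 1:4, 1] <- 7L; b[1:3, 5, 1] <- 9L       # overlaps with a=1: 12 / 3
  b[4:6, 1:2, 1] <- 7L; b[4:6, 3:5, 1] <- 9L     # overlaps with a=2: 6 / 9
  ct <- cross_tabulate(a, b)
  expect_equal(ct$row_labels, c(1L, 2L))
  expect_equal(ct$col_labels, c(7L, 9L))
  expect_equal(unname(ct$counts), matrix(c(12L, 6L, 3L, 9L), 2))
  expect_equal(sum(ct$counts), sum(a > 0L & b > 0L))
  # identical segmentations give a diagonal matrix
  s <- array(0L, dims)
  s[1:2, , 1] <- 1L; s[3:6, 1:5, 1] <- 2L; s[, , 2] <- 3L
  ct2 <- cross_tabulate(s, s)
  expect_equal(unname(diag(ct2$counts)), c(10L, 20L, 30L))
  expect_equal(sum(ct2$counts) - sum(diag(ct2$counts)), 0L)
  expect_error(cross_tabulate(a, array(0L, c(2, 2, 2))), "grid mismatch")
})

test_that("hemisphere correspondence is the contingency matrix product", {
  cl <- structure(list(counts = matrix(c(5L, 0L, 1L, 4L), 2,
                                       dimnames = list(c(101, 102), c(1, 2))),
                       row_labels = c(101L, 102L), col_labels = c(1L, 2L)),
                  class = "contingency")
  cr <- structure(list(counts = matrix(c(4L, 1L, 0L, 5L), 2,
                                       dimnames = list(c(101, 102), c(3, 4))),
                       row_labels = c(101L, 102L), col_labels = c(3L, 4L)),
                  class = "contingency")
  corr <- hemisphere_correspondence(cl, cr)
  expect_equal(unname(corr$M), unname(t(cl$counts) %*% cr$counts))
  expect_true(all(corr$M >= 0))
  bad <- cr; bad$row_labels <- c(101L, 103L)
  expect_error(hemisphere_correspondence(cl, bad), "differ")
})

test_that("the assignment solver is exact against brute force", {
  # permutation affinity recovers the permutation: row i overlaps only
  # column perm[i]
  P <- diag(5)[c(3, 1, 5, 2, 4), ]
  asg <- kuhn_munkres_match(P)
  expect_equal(asg$pairs$col[order(asg$pairs$row)], c(3, 1, 5, 2, 4))
  # random rectangular integer matrices: optimal total equals exhaustive max
  set.seed(17)
  for (t in 1:100) {
    nr <- sample(2:7, 1)
    nc <- (nr:7)[sample.int(8 - nr, 1)]
    A <- matrix(sample(0:50, nr * nc, TRUE), nr, nc)
    asg <- kuhn_munkres_match(A)
    got <- sum(asg$pairs$overlap[asg$pairs$round == 1L])
    # brute force can also leave zero-overlap rows unmatched
    expect_equal(got, brute_force_assignment(A))
  }
  expect_error(kuhn_munkres_match(matrix(numeric(0), 0, 0)), "empty")
  expect_error(kuhn_munkres_match(matrix(-1, 2, 2)), "non-negative")
})

test_that("surplus rows attach greedily in decreasing size order", {
  set.seed(21)
  A <- matrix(runif(10 * 4, 1, 10), 10, 4)
  asg <- kuhn_munkres_match(A)
  expect_equal(sum(asg$pairs$round == 1L), 4L)
  expect_equal(nrow(asg$pairs), 10L)
  leftovers <- asg$pairs[asg$pairs$round > 1L, ]
  # one leftover per subsequent round, largest (by row sums) first
  expect_equal(sort(leftovers$round), 2:7)
  sizes <- rowSums(A)[leftovers$row[order(leftovers$round)]]
  expect_true(all(diff(sizes) <= 0))
  # each leftover goes to its own best column
  for (i in seq_len(nrow(leftovers)))
    expect_equal(leftovers$col[i], which.max(A[leftovers$row[i], ]))
})

test_that("hemisphere harmonization recovers a known permutation exactly", {
  ph <- tiny_phantom(seed = 41L)
  dep <- compute_depth(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equidistant")
  atlas <- make_layer_atlas(ph$area_labels, dep, ph$gm_mask, 6L)
  left <- ph$layer_class_labels * (ph$hemisphere == 1L)
  right <- ph$layer_class_labels * (ph$hemisphere == 2L)
  harm <- harmonize_hemispheres(left, right, atlas,
                                ph$hemisphere == 1L, ph$hemisphere == 2L)
  # the right hemisphere was generated by permuting mirrored left labels;
  # harmonization must undo the permutation: the mirrored relabeled right
  # equals the left voxelwise (100% agreement)
  flipped <- mirror_x(harm$right_relabeled)
  lm <- ph$hemisphere == 1L & ph$gm_mask
  expect_identical(flipped[lm], left[lm])
  # identity input: relabeling changes nothing
  harm_id <- harmonize_hemispheres(left, left, atlas,
                                   ph$hemisphere == 1L, ph$hemisphere == 1L)
  expect_identical(harm_id$right_relabeled, left + 0L)
  # geometry untouched: per-label voxel sets only renamed
  expect_true(partitions_identical(right[right > 0L],
                                   harm$right_relabeled[right > 0L]))
})

test_that("random right-label permutations are recovered across draws", {
  ph <- tiny_phantom(seed = 43L)
  dep <- compute_depth(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equidistant")
  atlas <- make_layer_atlas(ph$area_labels, dep, ph$gm_mask, 6L)
  left <- ph$layer_class_labels * (ph$hemisphere == 1L)
  base_right <- mirror_x(left)   # identical mirrored labeling
  rmask <- ph$hemisphere == 2L
  for (s in 1:10) {
    set.seed(100 + s)
    perm <- sample(14L)
    right <- base_right
    nz <- right > 0L
    right[nz] <- perm[right[nz]]
    right[!rmask] <- 0L
    harm <- harmonize_hemispheres(left, right, atlas,
                                  ph$hemisphere == 1L, rmask)
    flipped <- mirror_x(harm$right_relabeled)
    lm <- ph$hemisphere == 1L & ph$gm_mask
    expect_identical(flipped[lm], left[lm])
  }
})
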