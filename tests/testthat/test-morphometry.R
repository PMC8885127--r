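test_that("branch orders follow both conventions on a generated tree", {
  tree <- makeVesselTree(treeSimParams(max_branch_order = 2,
                                       diameter_by_order_um = c(15, 9, 7),
                                       isd_by_order_um = c(12, 18, 25),
                                       n_offshoots = 2))
  seg_truth <- treeSegments(tree)

  ex <- treeSegments(assignBranchOrders(tree, "ex_vivo"))
  expect_true(all(ex$branch_order[ex$is_pa] == 0))
  expect_equal(ex$branch_order[!ex$is_pa], seg_truth$order_cap[!ex$is_pa])

  iv <- treeSegments(assignBranchOrders(tree, "in_vivo"))
  expect_equal(iv$branch_order[iv$is_pa], seg_truth$pa_index[iv$is_pa])
  expect_equal(iv$branch_order[!iv$is_pa], seg_truth$order_cap[!iv$is_pa])
  # first offshoots are always capillary order 1
  off <- !iv$is_pa & iv$parent_id %in% iv$id[iv$is_pa]
  expect_true(all(iv$branch_order[off] == 1))
})

test_that("an unbranched root is order 0 under both conventions", {
  seg <- data.frame(id = "PA0", parent_id = NA_character_, is_pa = TRUE,
                    pa_index = 0L, order_cap = NA_integer_,
                    x0 = 0, y0 = 0, x1 = 0, y1 = -50,
                    length_um = 50, diameter_um = 15)
  tree <- manualTree(seg)
  expect_equal(treeSegments(assignBranchOrders(tree, "ex_vivo"))$branch_order, 0L)
  expect_equal(treeSegments(assignBranchOrders(tree, "in_vivo"))$branch_order, 0L)
})

test_that("inter-soma distances are Euclidean to the nearest proximal soma", {
  expect_equal(measureISD(data.frame(x = c(0, 3), y = c(0, 4))), 5)
  d <- measureISD(data.frame(x = c(10, 30, 60), y = c(0, 0, 0)))
  expect_equal(d, c(20, 30))
  expect_equal(length(measureISD(data.frame(x = 1, y = 1))), 0)
  # pixel scaling
  expect_equal(measureISD(data.frame(x = c(0, 3), y = c(0, 4)),
                          pixel_size_um = 0.5), 2.5)
})

test_that("generated trees reproduce the configured per-order ISDs", {
  p <- treeSimParams(max_branch_order = 3,
                     diameter_by_order_um = c(15, 9, 7, 6),
                     isd_by_order_um = c(10, 15, 20, 30))
  tree <- makeVesselTree(p)
  tree <- assignBranchOrders(tree, "ex_vivo")
  seg <- treeSegments(tree)
  for (o in 1:3) {
    ids <- seg$id[!seg$is_pa & seg$branch_order == o]
    isds <- unlist(lapply(ids, vasomorph:::segmentISDs, tree = tree))
    expect_equal(mean(isds), p$isd_by_order_um[o + 1], tolerance = 1e-9)
  }
  # ISD non-increasing in diameter across orders (inverse relation)
  mean_isd <- vapply(0:3, function(o) {
    ids <- seg$id[seg$branch_order == o | (o == 0 & seg$is_pa)]
    mean(unlist(lapply(ids, vasomorph:::segmentISDs, tree = tree)))
  }, numeric(1))
  diam <- p$diameter_by_order_um
  expect_true(all(diff(mean_isd[order(diam)]) <= 0))
})

test_that("diameters interpolate along tapers and specialize at branch points", {
  seg <- data.frame(id = c("PA0", "C001"),
                    parent_id = c(NA_character_, "PA0"),
                    is_pa = c(TRUE, FALSE), pa_index = c(0L, NA),
                    order_cap = c(NA, 1L),
                    x0 = c(0, 0), y0 = c(0, -50), x1 = c(0, 40),
                    y1 = c(-50, -50),
                    length_um = c(50, 40), diameter_um = c(15, 8),
                    diameter0_um = c(NA, 10), diameter1_um = c(NA, 6))
  bp <- data.frame(id = "bp1", x_um = 0, y_um = -50,
                   parent_segment = "PA0", child_segments = "C001",
                   local_diameter_um = 12, local_isd_um = 9)
  tree <- manualTree(seg, branch_points = bp)
  expect_equal(measureDiameter(tree, "PA0", 25), 15)
  expect_equal(measureDiameter(tree, "C001", 20), 8)   # taper midpoint
  expect_equal(measureDiameter(tree, "C001", 10), 9)
  expect_equal(measureDiameter(tree, "PA0", 50), 12)   # distal branch point
  expect_equal(measureDiameter(tree, "C001", 0), 12)   # proximal side
  expect_error(measureDiameter(tree, "C001", 99), "outside")
  expect_error(measureDiameter(tree, "nope", 1), "unknown")
})

test_that("branch-point ratios recover the generator configuration", {
  tree <- makeVesselTree(treeSimParams(branch_diameter_ratio = 1.2,
                                       branch_isd_ratio = 0.6))
  r <- branchPointRatios(tree)
  expect_equal(nrow(r), 24)
  expect_equal(mean(r$diameter_ratio), 1.2, tolerance = 0.05)
  expect_equal(mean(r$isd_ratio), 0.6, tolerance = 0.05)

  unity <- branchPointRatios(makeVesselTree(treeSimParams(
    branch_diameter_ratio = 1, branch_isd_ratio = 1)))
  expect_equal(unity$diameter_ratio, rep(1, nrow(unity)), tolerance = 1e-9)
  expect_equal(unity$isd_ratio, rep(1, nrow(unity)), tolerance = 1e-9)
})

test_that("ratio arithmetic matches the worked example (10 vs 9 and 7)", {
  tree <- makeVesselTree(treeSimParams())
  bp <- treeBranchPoints(tree)
  # replicate the hand computation on stored values of the first branch point
  seg <- treeSegments(tree)
  kids <- strsplit(bp$child_segments[1], ",")[[1]]
  up <- seg$diameter_um[seg$id == bp$parent_segment[1]]
  down <- mean(seg$diameter_um[seg$id %in% kids])
  r <- branchPointRatios(tree)
  expect_equal(r$diameter_ratio[r$branch_point == bp$id[1]],
               bp$local_diameter_um[1] / ((up + down) / 2))
})

test_that("marker termination points recover the configured branch orders", {
  p <- treeSimParams(marker_termination_orders =
                       c(elastin = 0, nestin = 2, aSMA = 3))
  tree <- makeVesselTree(p)
  bo <- vapply(c("elastin", "nestin", "aSMA"), function(m) {
    tp <- terminationProfile(tree, m)
    expect_identical(tp$status, "ok")
    tp$termination$branch_order
  }, numeric(1))
  expect_equal(unname(bo), c(0, 2, 3))
  expect_true(bo["elastin"] < bo["nestin"] && bo["nestin"] < bo["aSMA"])
})

test_that("termination profiles are normalized to 1 at offset 0", {
  tree <- makeVesselTree(treeSimParams())
  tp <- terminationProfile(tree, "nestin")
  expect_equal(tp$offsets$isd_norm[tp$offsets$offset == 0], 1)
  expect_equal(tp$offsets$isd_um / tp$termination$isd_um,
               tp$offsets$isd_norm)
})

test_that("ubiquitous or absent markers are signalled distinctly", {
  p <- treeSimParams(marker_termination_orders = c(ng2 = 4, elastin = 0))
  tree <- makeVesselTree(p)
  expect_identical(terminationProfile(tree, "ng2")$status, "no_termination")
  expect_identical(terminationProfile(tree, "elastin",
                                      threshold = 1e6)$status, "absent")
  expect_error(terminationProfile(tree, "unknown"), "not annotated")
})

test_that("perivascular intensity profiles normalize to the order-0 vessel", {
  img <- matrix(7, 40, 40)
  mask <- matrix(NA_integer_, 40, 40)
  mask[, 19:21] <- 0L
  prof <- perivascularIntensityProfile(img, mask, c(0, 5, 10),
                                       shell_width_um = 2)
  expect_true(all(prof$intensity_norm == 1))

  # 100 within 5 um of the vessel, 50 beyond -> (1.0, 0.5, 0.5)
  xs <- matrix(rep(seq_len(40), each = 40), nrow = 40)
  dist_from_band <- pmax(abs(xs - 20) - 1, 0)
  img2 <- ifelse(dist_from_band <= 5, 100, 50)
  prof2 <- perivascularIntensityProfile(img2, mask, c(0, 10, 20),
                                        shell_width_um = 2)
  expect_equal(prof2$intensity_norm, c(1, 0.5, 0.5))

  # strictly decreasing field -> strictly decreasing profile
  img3 <- 200 - 3 * dist_from_band
  prof3 <- perivascularIntensityProfile(img3, mask, c(0, 4, 8, 12),
                                        shell_width_um = 2)
  expect_true(all(diff(prof3$intensity) < 0))

  expect_error(perivascularIntensityProfile(img, mask, c(5, 10)), "include 0")
  mask2 <- mask; mask2[, 19:21] <- 1L
  expect_error(perivascularIntensityProfile(img, mask2, 0), "order-0")
})
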