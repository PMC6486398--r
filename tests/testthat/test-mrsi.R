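# a 20x20x2 image grid tiled by four 10x10x1 blocks on slice 1
grid4 <- function(lac = c(1, 2, 3, 4), ml9 = lac, qpass = TRUE) {
  mrsi_grid_regular(c(20, 20, 2), block = c(10, 10), slice = 1,
                    lac_cr = lac, ml9_cr = ml9, quality_pass = qpass)
}

test_that("mrsi_grid validates geometry and quality inputs", {
  g <- grid4()
  expect_s3_class(g, "mrsi_grid")
  expect_equal(nrow(g), 4)
  bad <- tibble::as_tibble(g)[, setdiff(names(g), "voxel_id")]
  bad$x0[2] <- 5                       # overlaps block 1
  expect_error(mrsi_grid(bad, c(20, 20, 2)), "overlap")
  bad2 <- tibble::as_tibble(g)[, setdiff(names(g), "voxel_id")]
  bad2$x0[1] <- 15                     # extends outside the grid
  expect_error(mrsi_grid(bad2, c(20, 20, 2)), "outside")
  # rel_sd quality route: 20% threshold
  q <- tibble::as_tibble(g)[, setdiff(names(g), c("voxel_id",
                                                  "quality_pass"))]
  q$rel_sd <- c(5, 19.9, 20.1, 50)
  g2 <- mrsi_grid(q, c(20, 20, 2))
  expect_identical(g2$quality_pass, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("coverage fractions count mask voxels per block", {
  g <- grid4()
  full <- mk_mask(c(20, 20, 2))
  full$data[1:10, 1:10, 1] <- TRUE       # block 1 fully covered
  full$data[1:5, 11:15, 1] <- TRUE       # 25 voxels of block 2
  cov <- coverage_fractions(full, g)
  expect_equal(cov$coverage, c(1, 0.25, 0, 0))
  expect_error(coverage_fractions(mk_mask(c(19, 20, 2)), g), "match")
})

test_that("containment filter requires full tumor coverage and quality", {
  tumor <- mk_mask(c(20, 20, 2), label = "CE")
  tumor$data[, , 1] <- TRUE
  g_all <- grid4()
  expect_true(all(tumor_containment_filter(tumor, g_all)$included))

  hole <- tumor
  hole$data[3, 3, 1] <- FALSE            # one image voxel missing
  f <- tumor_containment_filter(hole, g_all)
  expect_identical(f$included, c(FALSE, TRUE, TRUE, TRUE))

  g_q <- grid4(qpass = c(TRUE, FALSE, TRUE, TRUE))
  f2 <- tumor_containment_filter(tumor, g_q)
  expect_identical(f2$included, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("weighted metabolite value reproduces the hand example", {
  tumor <- mk_mask(c(20, 20, 2), label = "CE")
  tumor$data[, , 1] <- TRUE
  g <- grid4(lac = c(1, 2, 9, 9))
  comp <- mk_mask(c(20, 20, 2))
  comp$data[1:5, 1:4, 1] <- TRUE         # 20/100 of block 1
  comp$data[1:10, 11:16, 1] <- TRUE      # 60/100 of block 2
  r <- weighted_metabolite(comp, g, tumor, "lac_cr")
  expect_equal(r$weights[[1]]$weight, c(0.25, 0.75))
  expect_equal(r$value, 1.75)            # 0.25*1 + 0.75*2
  expect_equal(r$n_voxels, 2L)

  solo <- mk_mask(c(20, 20, 2))
  solo$data[11:13, 2:3, 1] <- TRUE       # only block 3 touched
  r1 <- weighted_metabolite(solo, g, tumor, "lac_cr")
  expect_equal(r1$value, 9)
  expect_equal(r1$weights[[1]]$weight, 1)

  none <- mk_mask(c(20, 20, 2))
  none$data[1, 1, 2] <- TRUE             # outside every block
  r0 <- weighted_metabolite(none, g, tumor, "lac_cr")
  expect_true(is.na(r0$value))
  expect_equal(r0$n_voxels, 0L)
})

test_that("weighted value equals the per-image-voxel oracle on phantoms", {
  for (seed in 1:6) {
    b <- make_phantom(mini_spec(seed = seed))
    comp <- b$truth$core_restricted
    for (met in c("lac_cr", "ml9_cr")) {
      mine <- weighted_metabolite(comp, b$mrsi, b$ce, met)$value
      orc <- oracle_weighted_metabolite(comp, b$mrsi, b$ce, met)
      expect_equal(mine, orc, tolerance = 1e-12)
    }
  }
})

test_that("weighted value stays in the convex hull of contributing ratios", {
  for (seed in 7:10) {
    b <- make_phantom(mini_spec(seed = seed))
    r <- weighted_metabolite(b$truth$core_elevated, b$mrsi, b$ce, "lac_cr")
    if (r$n_voxels > 0) {
      expect_gte(r$value, min(r$weights[[1]]$ratio))
      expect_lte(r$value, max(r$weights[[1]]$ratio))
    }
  }
})

test_that("equal coverage reduces to the plain mean; constants recover exactly", {
  tumor <- mk_mask(c(20, 20, 2), label = "CE")
  tumor$data[, , 1] <- TRUE
  g <- grid4(lac = c(2, 4, 6, 12))
  tiles <- mk_mask(c(20, 20, 2))
  tiles$data[1:20, 1:20, 1] <- TRUE      # all four blocks fully covered
  r <- weighted_metabolite(tiles, g, tumor, "lac_cr")
  expect_equal(r$value, mean(c(2, 4, 6, 12)))

  gc <- grid4(lac = rep(3.5, 4))
  part <- mk_mask(c(20, 20, 2))
  part$data[1:7, 1:20, 1] <- TRUE        # uneven coverage, constant ratio
  expect_identical(weighted_metabolite(part, gc, tumor, "lac_cr")$value,
                   3.5)
})

test_that("coverage weighting is invariant to uniform grid upsampling", {
  tumor <- mk_mask(c(20, 20, 2), label = "CE")
  tumor$data[, , 1] <- TRUE
  g <- grid4(lac = c(1, 2, 3, 4))
  comp <- mk_mask(c(20, 20, 2))
  comp$data[1:5, 1:4, 1] <- TRUE
  comp$data[1:10, 11:16, 1] <- TRUE
  v1 <- weighted_metabolite(comp, g, tumor, "lac_cr")$value

  # upsample the image grid 2x in-plane: same geometry at doubled indices
  up <- function(m) {
    a <- m$data[rep(1:20, each = 2), rep(1:20, each = 2), , drop = FALSE]
    roi_mask(a, m$label, c(0.5, 0.5, 1))
  }
  g2 <- mrsi_grid_regular(c(40, 40, 2), block = c(20, 20), slice = 1,
                          lac_cr = c(1, 2, 3, 4), ml9_cr = 0)
  v2 <- weighted_metabolite(up(comp), g2, up(tumor), "lac_cr")$value
  expect_equal(v2, v1, tolerance = 1e-12)
})

test_that("the MRSI table round-trips through its CSV schema", {
  g <- grid4(lac = c(1.1, 2.2, 3.3, 4.4), ml9 = c(0.1, 0.2, 0.3, 0.4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_mrsi(g, f)
  back <- read_mrsi(f)
  expect_equal(attr(back, "image_dim"), attr(g, "image_dim"))
  expect_equal(back$lac_cr, g$lac_cr)
  expect_equal(back$quality_pass, g$quality_pass)
  expect_error(read_mrsi(file.path(tempdir(), "missing.csv")), "not found")
})
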