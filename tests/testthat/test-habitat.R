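roi8 <- function(values) {
  dims <- c(8, 1, 1)
  list(map = mk_vol(values, dims), roi = mk_mask(dims, 1:8, label = "CE"))
}

test_that("pooled quartiles use the linear-interpolation definition", {
  f <- roi8(1:8)
  th <- pooled_quartiles(f$map, f$roi)
  expect_equal(th$q1, 2.75)        # hand: x2 + 0.75 (x3 - x2)
  expect_equal(th$q3, 6.25)

  g <- roi8(rep(4.2, 8))
  thc <- pooled_quartiles(g$map, g$roi)
  expect_equal(thc$q1, 4.2)
  expect_equal(thc$q3, 4.2)

  one <- mk_mask(c(8, 1, 1), 3, label = "CE")
  th1 <- pooled_quartiles(f$map, one)
  expect_equal(th1$q1, 3)
  expect_equal(th1$q3, 3)

  expect_error(pooled_quartiles(f$map, mk_mask(c(8, 1, 1))), "empty")
})

test_that("quartile masks select the expected voxels", {
  f <- roi8(1:8)
  th <- pooled_quartiles(f$map, f$roi)
  low <- lowest_quartile_mask(f$map, f$roi, th)
  high <- highest_quartile_mask(f$map, f$roi, th)
  expect_identical(which(low$data), 1:2)     # values 1, 2 <= 2.75
  expect_identical(which(high$data), 7:8)    # values 7, 8 >= 6.25
  expect_false(any(low$data & high$data))

  g <- roi8(rep(1, 8))                       # degenerate: all ties
  thc <- pooled_quartiles(g$map, g$roi)
  expect_equal(sum(lowest_quartile_mask(g$map, g$roi, thc)$data), 8)
  expect_equal(sum(highest_quartile_mask(g$map, g$roi, thc)$data), 8)
})

test_that("distinct-valued quartile masks hold 25% of the ROI within a voxel", {
  set.seed(41)
  for (n in c(16, 101, 250, 4000)) {
    dims <- c(n, 1, 1)
    map <- mk_vol(sample(seq_len(5 * n), n), dims)   # distinct values
    roi <- mk_mask(dims, seq_len(n), label = "CE")
    th <- pooled_quartiles(map, roi)
    n_low <- sum(lowest_quartile_mask(map, roi, th)$data)
    n_high <- sum(highest_quartile_mask(map, roi, th)$data)
    expect_lte(abs(n_low - n / 4), 1)
    expect_lte(abs(n_high - n / 4), 1)
  }
})

test_that("quartile masks are invariant to strictly increasing transforms", {
  set.seed(42)
  dims <- c(10, 10, 4)
  roi <- mk_mask(dims, sample(prod(dims), 150), label = "CE")
  map <- mk_vol(runif(prod(dims), 0.1, 3), dims)
  base_low <- lowest_quartile_mask(map, roi, pooled_quartiles(map, roi))
  base_high <- highest_quartile_mask(map, roi, pooled_quartiles(map, roi))
  for (f in list(function(x) 2 * x + 7, exp, function(x) x^3)) {
    tm <- mk_vol(f(map$data), dims)
    th <- pooled_quartiles(tm, roi)
    expect_identical(lowest_quartile_mask(tm, roi, th)$data, base_low$data)
    expect_identical(highest_quartile_mask(tm, roi, th)$data,
                     base_high$data)
  }
})

test_that("compartment intersection matches brute-force set operations", {
  set.seed(7)
  dims <- c(20, 20, 20)
  for (rep in 1:5) {
    ce_idx <- sample(prod(dims), 2000)
    ce <- mk_mask(dims, ce_idx, label = "CE")
    rcbv_l <- mk_mask(dims, sample(ce_idx, 600))
    # ADC quartile masks are disjoint whenever q1 < q3: emulate that
    adc_split <- sample(ce_idx, 1200)
    adc_l <- mk_mask(dims, adc_split[1:500])
    adc_h <- mk_mask(dims, adc_split[501:1200])
    res <- intersect_compartments(rcbv_l, adc_l, adc_h, ce)
    # voxel-by-voxel oracle
    for (v in ce_idx) {
      lo <- adc_l$data[v] && rcbv_l$data[v]
      hi <- adc_h$data[v] && rcbv_l$data[v]
      if (res$`ADC_L-rCBV_L`$data[v] != lo ||
          res$`ADC_H-rCBV_L`$data[v] != hi ||
          res$CEC$data[v] != (!lo && !hi)) {
        fail(sprintf("voxel %d disagrees with set-operation oracle", v))
      }
    }
    succeed()
    expect_false(any(res$`ADC_L-rCBV_L`$data & res$`ADC_H-rCBV_L`$data &
                       FALSE))
    total <- sum(res$`ADC_L-rCBV_L`$data) + sum(res$`ADC_H-rCBV_L`$data) +
      sum(res$CEC$data)
    expect_identical(total, sum(ce$data))
  }
})

test_that("compartment intersection edge and error cases", {
  dims <- c(6, 6, 1)
  ce <- mk_mask(dims, 1:30, label = "CE")
  rcbv_l <- ce
  adc_l <- mk_mask(dims, 1:8)
  adc_h <- mk_mask(dims, 21:30)
  res <- intersect_compartments(rcbv_l, adc_l, adc_h, ce)
  expect_identical(res$`ADC_L-rCBV_L`$data, adc_l$data)
  expect_identical(res$`ADC_H-rCBV_L`$data, adc_h$data)

  empty <- mk_mask(dims)
  res2 <- intersect_compartments(rcbv_l, empty, adc_h, ce)
  expect_equal(sum(res2$`ADC_L-rCBV_L`$data), 0)
  expect_identical(res2$CEC$data | res2$`ADC_H-rCBV_L`$data, ce$data)

  stray <- mk_mask(dims, 31:32)
  expect_error(intersect_compartments(rcbv_l, stray, adc_h, ce),
               "outside")
})

test_that("absolute and proportional volumes follow the voxel arithmetic", {
  dims <- c(10, 10, 10)
  expect_equal(mask_volume(mk_mask(dims, 1:1000)), 1.0)   # 1000 mm^3
  expect_equal(mask_volume(mk_mask(dims)), 0.0)
  m8 <- mk_mask(c(2, 2, 2), 1:8, vd = c(0.5, 0.5, 0.5))
  expect_equal(mask_volume(m8), 0.001)

  ce <- mk_mask(dims, 1:200, label = "CE")
  expect_equal(proportional_volume(mk_mask(dims, 1:25), ce), 12.5)
  expect_equal(proportional_volume(ce, ce), 100)
  expect_equal(proportional_volume(mk_mask(dims), ce), 0)
  expect_error(proportional_volume(ce, mk_mask(dims)), "empty")
})

test_that("segment_habitats partitions CE and recovers a planted core", {
  b <- make_phantom(mini_spec(seed = 5))
  res <- segment_habitats(b$adc, b$rcbv, b$ce, b$nawm)
  n_ce <- sum(b$ce$data)
  parts <- c("ADC_L-rCBV_L", "ADC_H-rCBV_L", "CEC")
  expect_identical(sum(vapply(parts, function(p) sum(res$masks[[p]]$data),
                              integer(1))), n_ce)
  expect_false(any(res$masks$`ADC_L-rCBV_L`$data &
                     res$masks$`ADC_H-rCBV_L`$data))
  expect_gte(dice(res$masks$rCBV_L, b$truth$core), 0.99)
  expect_gte(dice(res$masks$`ADC_L-rCBV_L`, b$truth$core_restricted), 0.99)
  expect_gte(dice(res$masks$`ADC_H-rCBV_L`, b$truth$core_elevated), 0.99)
  expect_true(all(res$volumes$prop_of_ce_pct >= 0 &
                    res$volumes$prop_of_ce_pct <= 100))
})

test_that("tiny CE regions are flagged but still measured", {
  dims <- c(12, 12, 6)
  ce <- mk_mask(dims, 1:20, label = "CE")
  nawm <- mk_mask(dims, 500:560, label = "NAWM")
  set.seed(2)
  adc <- mk_vol(runif(prod(dims), 0.5, 1.5), dims, modality = "ADC")
  rcbv <- mk_vol(runif(prod(dims), 0.5, 2.5), dims, modality = "rCBV")
  res <- segment_habitats(adc, rcbv, ce, nawm)
  expect_match(res$flags, "CE has 20 voxels", all = FALSE)
  expect_equal(res$volumes$abs_volume_cm3[res$volumes$roi == "CE"], 0.02)
})
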