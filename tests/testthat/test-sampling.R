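test_that("partial postcodes map to quintiles by mean rank", {
  imd <- gen_imd_table(N = 100, seed = 1,
                       partial_map = list(AB1 = c(5, 10, 15),
                                          CD2 = 100,
                                          EF3 = c(20, 21),
                                          GH4 = 40))
  expect_equal(quintile_for_partial_postcode("AB1", imd), 1L)
  expect_equal(quintile_for_partial_postcode("CD2", imd), 5L)
  # mean 20.5 falls just beyond the first cut-point
  expect_equal(quintile_for_partial_postcode("EF3", imd), 2L)
  # boundary: mean exactly 2N/5 stays in quintile 2
  expect_equal(quintile_for_partial_postcode("GH4", imd), 2L)
  expect_error(quintile_for_partial_postcode("ZZ99", imd), "unmapped")
})

test_that("a partial postcode spanning two nations is rejected", {
  a <- gen_imd_table("England", N = 50, seed = 1,
                     partial_map = list(AB1 = c(1, 2)))
  b <- gen_imd_table("Wales", N = 50, seed = 2,
                     partial_map = list(AB1 = c(3, 4)))
  both <- imd_table(rbind(as.data.frame(a), as.data.frame(b)),
                    N = c(England = 50L, Wales = 50L))
  expect_error(quintile_for_partial_postcode("AB1", both),
               "more than one nation")
})

test_that("quintile mapping is invariant to rank scale", {
  for (s in 1:20) {
    set.seed(800 + s)
    N <- sample(50:500, 1)
    ranks <- sample(N, sample(1:6, 1))
    imd1 <- imd_table(data.frame(nation = "England", partial = "PP",
                                 postcode = paste("PP", seq_along(ranks)),
                                 rank = ranks),
                      N = c(England = N))
    k <- sample(2:5, 1)
    imd2 <- imd_table(data.frame(nation = "England", partial = "PP",
                                 postcode = paste("PP", seq_along(ranks)),
                                 rank = ranks * k),
                      N = c(England = N * k))
    expect_equal(quintile_for_partial_postcode("PP", imd1),
                 quintile_for_partial_postcode("PP", imd2))
  }
})

test_that("the default frame is 6 bands x 5 quintiles x 2 sexes of 10", {
  f <- build_frame()
  expect_equal(nrow(f), 60)
  expect_equal(sum(f$target), 600)
  expect_true(all(f$target == 10))
  # 20 per band-by-quintile cell, 100 per band
  bq <- aggregate(target ~ band + quintile, data = f, sum)
  expect_true(all(bq$target == 20))
  bt <- aggregate(target ~ band, data = f, sum)
  expect_true(all(bt$target == 100))

  one <- build_frame(bands = age_bands()[1, ])
  expect_equal(sum(one$target), 100)
  expect_error(build_frame(bands = age_bands()[0, ]), "no age bands")
  expect_error(build_frame(expected_total = 599), "totals 600")
})

test_that("flow filters exclude planted counts in order", {
  r <- gen_roster(1000, seed = 2,
                  mix = list(non_gb = 50, not_completed = 200,
                             language_disability = 100, not_audible = 30))
  fl <- apply_flow_filters(r$roster)
  expect_equal(fl$flow$stage, c("country", "completion",
                                "language_disability", "audibility"))
  expect_equal(fl$flow$excluded, c(50, 200, 100, 30))
  expect_equal(fl$flow$remaining, c(950, 750, 650, 620))
  expect_equal(nrow(fl$roster), 620)

  all_pass <- gen_roster(200, seed = 3)
  fl2 <- apply_flow_filters(all_pass$roster)
  expect_true(all(fl2$flow$excluded == 0))
  expect_error(apply_flow_filters(r$roster, filters = "nonsense"),
               "unknown flow filter")
})

test_that("flow conservation holds on random rosters", {
  for (s in 1:10) {
    r <- gen_roster(500, seed = 900 + s,
                    mix = list(non_gb = 0.05, not_completed = 0.3,
                               language_disability = 0.2,
                               not_audible = 0.1))
    fl <- apply_flow_filters(r$roster)
    inflow <- c(500, fl$flow$remaining[-nrow(fl$flow)])
    expect_equal(inflow - fl$flow$excluded, fl$flow$remaining)
    expect_equal(fl$flow$remaining[nrow(fl$flow)], nrow(fl$roster))
    expect_true(all(diff(fl$flow$remaining) <= 0))
  }
})

test_that("participants route to their cell until it fills", {
  imd <- gen_imd_table(N = 100, seed = 4,
                       partial_map = list(MID = c(45, 50, 55)))
  f <- build_frame()
  p <- list(id = "P1", age_months = 54, sex = "F", partial_postcode = "MID")
  res <- assign_participant(f, p, imd)
  expect_equal(res$status, "ASSIGNED")
  expect_equal(res$cell, "4:6-4:11|3|F")

  # the 11th eligible girl finds the cell full
  f2 <- f
  for (i in 1:10)
    f2 <- assign_participant(f2, list(id = paste0("G", i), age_months = 62,
                                      sex = "F", partial_postcode = "MID"),
                             imd)$frame
  res2 <- assign_participant(f2, list(id = "G11", age_months = 62,
                                      sex = "F", partial_postcode = "MID"),
                             imd)
  expect_equal(res2$status, "FULL")

  res3 <- assign_participant(f, list(id = "X", age_months = 100, sex = "M",
                                     partial_postcode = "MID"), imd)
  expect_equal(res3$status, "OUT_OF_FRAME")
})

test_that("no cell ever exceeds its target under random assignment", {
  imd <- gen_imd_table(N = 100, seed = 5)
  r <- gen_roster(2000, seed = 6,
                  partial_postcodes = unique(imd$partial))
  asg <- assign_roster(build_frame(), r$roster, imd)
  expect_true(all(asg$frame$filled <= asg$frame$target))
  expect_lte(sum(asg$frame$filled), 600)
  expect_equal(sum(asg$frame$filled),
               sum(asg$assignments$status == "ASSIGNED"))
})

test_that("frame status reports fill, shortfall and oversampling factor", {
  st <- frame_status(build_frame(), completed = 2340, audible = 889)
  expect_equal(st$oversampling_factor, 2.6)
  expect_equal(st$total_target, 600)
  expect_equal(nrow(st$shortfall), 60)  # untouched frame: every cell short
  expect_true(all(st$cells$shortfall == st$cells$target))
  expect_true(is.na(frame_status(build_frame(), completed = 10,
                                 audible = 0)$oversampling_factor))

  # a full frame has no shortfall
  imd <- gen_imd_table(N = 10, seed = 7,
                       partial_map = list(LOW = 1))
  f <- build_frame(bands = age_bands()[1, ], n_quintiles = 1, per_cell = 1)
  f <- assign_participant(f, list(id = "a", age_months = 50, sex = "M",
                                  partial_postcode = "LOW"), imd)$frame
  f <- assign_participant(f, list(id = "b", age_months = 50, sex = "F",
                                  partial_postcode = "LOW"), imd)$frame
  expect_equal(nrow(frame_status(f)$shortfall), 0)
})

test_that("rosters round-trip through CSV", {
  r <- gen_roster(50, seed = 8, mix = list(bilingual = 5))
  p <- tempfile(fileext = ".csv")
  write_roster_csv(r$roster, p)
  r2 <- read_roster_csv(p)
  expect_equal(r2$monolingual, r$roster$monolingual)
  expect_equal(r2$id, r$roster$id)
  unlink(p)
})
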