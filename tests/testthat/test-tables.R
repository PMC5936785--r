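test_that("packaged tables carry the printed values digit for digit", {
  tb <- study_tables()
  t1 <- tb$table1
  pick <- function(q, h, g) t1$value_text[t1$quantity == q & t1$heart == h &
                                            t1$geometry == g]
  expect_identical(pick("delta_p_kpa", "D", "detailed"), "4.9")
  expect_identical(pick("wss_median_pa", "B", "detailed"), "0.34")
  expect_identical(pick("area_inlet_m2", "D", ""), "9.4e-4")
  expect_identical(pick("reynolds_inlet", "D", ""), "5764")
  expect_identical(nrow(tb$table2[tb$table2$quantity == "delta_p_kpa", ]), 4L)
  expect_identical(sort(unique(tb$table3$geometry)),
                   c("detailed", "smoothed"))
  expect_identical(as.numeric(sort(unique(tb$table4$sigma_kg_m2))), c(7, 20, 40, 70))
})

test_that("table_stats recomputes the quoted derived statistics", {
  st <- table_stats()
  expect_named(st, c("delta_p_diff", "mean_delta_p_diff_abce",
                     "vortex_mean_smoothed", "vortex_sd_smoothed",
                     "vortex_mean_detailed", "vortex_sd_detailed",
                     "wss_reduction_pct", "wss_reduction_range"))
  expect_equal(st$delta_p_diff,
               c(A = 0.2, B = 0.3, C = 0.1, D = 2.7, E = 0.2))
  expect_equal(unname(st$wss_reduction_pct["D"]), 100 * (0.63 - 0.66) / 0.63)
  expect_lt(st$wss_reduction_pct["D"], 0)  # heart D shows no reduction
  expect_length(st$wss_reduction_range, 2)
})
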