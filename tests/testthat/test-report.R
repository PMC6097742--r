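test_that("the bundled ten-case study parses into named scenarios", {
  cfgs <- read_scenario(cases_table1())
  expect_length(cfgs, 10)
  expect_setequal(names(cfgs),
                  c("Baseline", "Length_1", "Length_2", "Shape_1", "Shape_2",
                    "Stenosis", "Material_1", "Material_2", "Material_3",
                    "Pressure"))
  expect_equal(cfgs$Length_2$incision$cut_length_mm, 60)
  expect_equal(cfgs$Stenosis$vessel$stenosis_pct, 80)
  expect_equal(cfgs$Pressure$stages$postop_mmHg, 45)
  expect_equal(cfgs$Material_2$patch_material, "porcine xenopericardium")
  # every case inherits the shared defaults
  expect_true(all(vapply(cfgs, function(cs) cs$flow$rate_lpm, numeric(1)) == 4))
})

test_that("scenario validation rejects bad configs before any solve", {
  cfg <- default_scenario_for_tests()
  cfg$patch_material <- "kevlar"
  expect_error(run_case(cfg), "unknown material")
  cfg2 <- default_scenario_for_tests()
  cfg2$incision$shape <- "zigzag"
  expect_error(run_case(cfg2), "shape")
  expect_error(run_matrix(list()), "empty")
})

test_that("a coarse scenario runs end to end with a sensible report", {
  rep <- fixture("cheap_case", function() run_case(cheap_scenario()))
  expect_s3_class(rep, "scenario_report")
  expect_lt(rep$postop_stenosis_pct, 50)   # surgery always helps
  expect_gt(rep$patch_area_mm2, 0)
  expect_gt(rep$max_arterial_stress_kPa, 0)
  expect_gte(rep$max_patch_stress_kPa, rep$avg_patch_stress_kPa)
  expect_gt(rep$reynolds_max, 0)
  expect_gt(rep$delta_p_mmHg, 0)
  expect_gt(rep$traction_N_per_m, 0)
})

test_that("run_matrix collects rows and survives per-case failure", {
  good <- cheap_scenario()
  bad <- cheap_scenario()
  bad$name <- "Broken"
  bad$incision$cut_length_mm <- 500  # exceeds the vessel
  tab <- run_matrix(list(good = good, bad = bad))
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$error[1]))
  expect_match(tab$error[2], "incision")
  expect_false(is.na(tab$postop_stenosis_pct[1]))
})
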