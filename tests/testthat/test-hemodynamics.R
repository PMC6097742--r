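test_that("Reynolds profile matches the closed form and scales linearly", {
  flow <- flow_spec()
  a0 <- pi * 0.009^2
  prof <- analytic_area_profile(vessel_spec(stenosis_fraction = 0), 11)
  re <- reynolds_profile(prof, flow)
  # rho v D / mu with v = Q/A on the healthy 18 mm vessel
  re_ref <- flow$density * (flow$flow_rate / a0) * 0.018 / flow$viscosity
  expect_equal(re$Re, rep(re_ref, 11), tolerance = 1e-12)
  # doubling Q doubles Re everywhere
  flow2 <- flow_spec(flow_rate = 2 * flow$flow_rate)
  expect_equal(reynolds_profile(prof, flow2)$Re, 2 * re$Re)
  # the maximum sits at the minimum-area sample
  p70 <- analytic_area_profile(vessel_spec(stenosis_fraction = 0.7), 201)
  re70 <- reynolds_profile(p70, flow)
  expect_equal(which.max(re70$Re), which.min(re70$area))
  expect_error(reynolds_profile(list(z = 1:3, area = c(1, 0, 1)), flow),
               "area")
})

test_that("pressure-drop estimate has the Poiseuille limit and is monotone", {
  flow <- flow_spec()
  prof0 <- analytic_area_profile(vessel_spec(stenosis_fraction = 0,
                                             total_length = 0.1,
                                             stenosis_length = 0.05), 101)
  dp <- pressure_drop_estimate(prof0, flow)
  # 32 mu L vbar / D^2 for the straight 100 mm tube
  a0 <- pi * 0.009^2
  dp_ref <- 32 * flow$viscosity * 0.1 * (flow$flow_rate / a0) / 0.018^2
  expect_equal(dp, dp_ref, tolerance = 1e-3)
  # vanishing flow -> vanishing drop (flow_spec requires Q > 0)
  tiny <- flow_spec(flow_rate = 1e-12)
  expect_lt(pressure_drop_estimate(prof0, tiny), 1e-5)
  # strictly decreasing in throat area at fixed flow
  drops <- vapply(c(0.8, 0.7, 0.5, 0.3), function(s)
    pressure_drop_estimate(
      analytic_area_profile(vessel_spec(stenosis_fraction = s), 101), flow),
    numeric(1))
  expect_true(all(diff(drops) < 0))
  # pre-op 70% drops more than a mildly stenosed "post-op" lumen
  dp70 <- pressure_drop_estimate(
    analytic_area_profile(vessel_spec(stenosis_fraction = 0.7), 101), flow)
  dp24 <- pressure_drop_estimate(
    analytic_area_profile(vessel_spec(stenosis_fraction = 0.24), 101), flow)
  expect_gt(dp70, dp24)
})
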