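test_that("dB conversion uses the energy convention", {
  expect_equal(to_db(1), 0)
  expect_equal(to_db(0.5), -3.0103, tolerance = 1e-4)
  expect_equal(to_db(2), 3.0103, tolerance = 1e-4)
  expect_identical(to_db(0), -Inf)
  expect_error(to_db(-0.1), "non-negative")
})

test_that("energy gain over depth reproduces the reference ratios", {
  gain <- energy_gain_curve(radii = c(0, 40, 76))
  expect_equal(gain$db[gain$radius_mm == 0], 0)
  r76 <- gain[gain$radius_mm == 76, ]
  expect_gte(r76$ratio[r76$orientation == "radial"], 2)
  expect_equal(r76$ratio[r76$orientation == "tangential"], 1.7,
               tolerance = 0.06)
  # monotone growth towards the surface
  for (o in c("radial", "tangential")) {
    sub <- gain[gain$orientation %in% c("free", o), ]
    expect_true(all(diff(sub$energy[order(sub$radius_mm)]) > 0))
  }
})

test_that("term spectra concentrate the central source at l = 1 and sum to the gain", {
  ts <- term_spectrum(radii = c(0, 50, 76), l_max = 30)
  ctr <- ts[ts$radius_mm == 0, ]
  expect_equal(ctr$fraction[ctr$l == 1], 1, tolerance = 1e-12)
  expect_equal(ctr$fraction[ctr$l > 1], rep(0, 29))
  # l = 1 contribution identical across depths and orientations
  l1 <- ts$fraction[ts$l == 1]
  expect_equal(l1, rep(1, length(l1)), tolerance = 1e-12)
  # row sums over l reproduce the energy-gain values (tail < 1e-6 at 50 mm)
  gain <- energy_gain_curve(radii = 50)
  s50 <- sum(ts$fraction[ts$radius_mm == 50 & ts$orientation == "radial"])
  expect_equal(s50, gain$ratio[gain$orientation == "radial"],
               tolerance = 1e-6)
})

test_that("coarse layouts systematically underestimate captured energy", {
  model <- fix_model()
  ens <- dipole_ensemble(radii = c(0, 30, 60, 76), per_shell = 8, seed = 2,
                         model = model)
  devs <- sampled_energy_deviation(list(`34` = fix_layout(34)), model, ens)
  expect_true(all(devs$rel_dev < 0))
  expect_equal(nrow(devs), nrow(ens))
  # deviation grows towards the surface on average
  agg <- tapply(devs$rel_dev, devs$radius_mm, mean)
  expect_lt(agg[["76"]], agg[["0"]])
  # dense-limit sanity: 900 points capture energies within a few percent
  dense <- sampled_energy_deviation(list(`900` = fix_layout(900)), model,
                                    ens[ens$radius_mm %in% c(0, 76), ])
  expect_lt(max(abs(dense$rel_dev)), 0.03)
})

test_that("SH and Sphara spectra of forward fields agree with the series", {
  model <- fix_model()
  mesh <- fix_layout(900)
  ens <- dipole_ensemble(radii = c(0, 40, 70), per_shell = 8, seed = 3,
                         model = model)
  shsp <- sh_spectrum(mesh$vertices, model, ens, l_max = 8)
  expect_s3_class(shsp, "energy_spectrum")
  # per-degree energies match the closed-form term energies closely
  ts <- term_spectrum(model, radii = 70, l_max = 8)
  for (ocl in c("radial", "tangential")) {
    got <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(shsp, .data$radius_mm == 70,
                                    .data$orientation_class == ocl,
                                    .data$l >= 1), .data$l),
      fr = mean(.data$fraction), .groups = "drop")
    want <- ts$fraction[ts$orientation == ocl]
    expect_equal(got$fr, want, tolerance = 5e-4)
  }
  # spurious DC stays far below the reference
  expect_lt(max(shsp$db[shsp$l == 0]), -60)

  basis <- sphara_basis(mesh, 81)
  spsp <- sphara_spectrum(basis, model, ens, l_max = 8)
  cmp <- compare_spectra(shsp[shsp$l >= 1, ], spsp[spsp$l >= 1, ])
  expect_lt(cmp$max_abs_diff, 1)       # sub-percent agreement at 900 points
  expect_lt(cmp$median_abs_diff, 0.05)
  # identical inputs give zero difference
  cmp0 <- compare_spectra(spsp, spsp)
  expect_equal(cmp0$max_abs_diff, 0)
  expect_error(compare_spectra(shsp, spsp[spsp$l > 2, ]), "grouping")

  # central sources put ~100% into the first non-DC group
  ctr <- dplyr::filter(spsp, .data$radius_mm == 0, .data$l == 1)
  expect_equal(ctr$fraction, rep(1, nrow(ctr)), tolerance = 0.02)
})

test_that("percentile envelopes are ordered and degenerate correctly", {
  model <- fix_model()
  mesh <- fix_layout(900)
  ens <- dipole_ensemble(radii = c(0, 40, 70), per_shell = 6, seed = 4,
                         model = model)
  spsp <- sh_spectrum(mesh$vertices, model, ens, l_max = 6)
  env <- percentile_envelopes(spsp)
  wide <- tidyr::pivot_wider(env[, c("l", "stat", "fraction")],
                             names_from = "stat", values_from = "fraction")
  expect_true(all(c("p50", "p90", "p99", "p99.9", "max") %in% names(wide)))
  expect_true(all(wide$p50 <= wide$p90 & wide$p90 <= wide$p99 &
                    wide$p99 <= wide$p99.9 & wide$p99.9 <= wide$max))
  # a single source collapses all percentiles onto its spectrum
  one <- spsp[spsp$source == spsp$source[1], ]
  env1 <- percentile_envelopes(one)
  expect_equal(tapply(env1$fraction, env1$l, function(x) diff(range(x))),
               tapply(env1$fraction, env1$l, function(x) 0))
  # envelopes decay with spatial frequency beyond the l = 1 peak
  mx <- wide$max[wide$l >= 1]
  expect_true(all(diff(mx) < 0))
})

test_that("depth grouping partitions sources and orders envelopes", {
  model <- fix_model()
  mesh <- fix_layout(900)
  ens <- dipole_ensemble(radii = c(10, 30, 50, 65, 73, 76), per_shell = 6,
                         seed = 5, model = model)
  spsp <- sh_spectrum(mesh$vertices, model,
                      dplyr::bind_rows(dipole_ensemble(radii = 0, per_shell = 6,
                                                       seed = 5, model = model),
                                       ens) |>
                        dplyr::mutate(source = dplyr::row_number()),
                      l_max = 6)
  denv <- depth_group_envelopes(spsp, n_groups = 3)
  expect_equal(sum(dplyr::distinct(denv, .data$group, .data$n_sources)$n_sources),
               length(unique(spsp$source)))
  # one group equals the overall max curve
  denv1 <- depth_group_envelopes(spsp, edges = c(0, 200))
  env <- percentile_envelopes(spsp)
  expect_equal(denv1$fraction,
               env$fraction[env$stat == "max"][match(denv1$l, sort(unique(env$l)))],
               tolerance = 1e-12)
  # shallow groups dominate at the highest resolved frequency
  hi <- denv[denv$l == max(denv$l), ]
  expect_gt(hi$fraction[which.min(hi$depth_min)],
            hi$fraction[which.max(hi$depth_min)])
  expect_error(depth_group_envelopes(spsp, edges = c(30, 10)), "increasing")
})

test_that("source geometry metrics recover depth and orientation", {
  src <- tibble::tibble(
    x = c(0, 0, 30), y = c(0, 0, 0), z = c(70, 70, 40),
    mx = c(0, 1, 0), my = c(0, 0, 1), mz = c(1, 0, 0)
  )
  got <- source_geometry_metrics(src, outer = 92, inner = 80)
  expect_equal(got$depth_mm[1:2], c(22, 22))
  expect_equal(got$orientation_deg[1], 0, tolerance = 1e-9)
  expect_equal(got$orientation_deg[2], 90, tolerance = 1e-9)
  expect_equal(got$orientation_deg[3], 90, tolerance = 1e-9)
  expect_error(source_geometry_metrics(
    tibble::tibble(x = 85, y = 0, z = 0, mx = 0, my = 0, mz = 1),
    outer = 92, inner = 80), "outside")

  # mesh-based route agrees with the analytic spheres on a dense mesh
  outer_mesh <- fix_layout(900)
  got2 <- source_geometry_metrics(src[3, ], outer = outer_mesh, inner = 80)
  expect_equal(got2$depth_mm, 92 - 50, tolerance = 0.05)
})
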