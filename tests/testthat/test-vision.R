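test_that("receptor templates peak at the nominal wavelength and behave like pigments", {
  for (pk in c(428L, 536L)) {
    s <- receptor_template(pk)
    expect_true(all(s >= 0))
    expect_equal(max(s), 1)
    expect_identical((300:700)[which.max(s)], pk)
  }
  # the UV pigment's beta band overlaps its alpha band and may displace the
  # realized maximum by a few nm
  suv <- receptor_template(328)
  expect_true(all(suv >= 0))
  expect_lt(abs((300:700)[which.max(suv)] - 328), 7)
  # the UV and blue pigment curves cross exactly once between 300 and 500 nm
  d <- receptor_template(328) - receptor_template(428)
  d <- d[300:700 <= 500]
  expect_identical(sum(diff(sign(d[d != 0])) != 0), 1L)
  expect_error(receptor_template(250), "outside")
})

test_that("von Kries adaptation normalizes the background and is scale-invariant", {
  ctx <- test_ctx()
  bg <- spec_set(ctx$grid, ctx$background)
  p <- quantum_catch(bg, ctx)
  expect_equal(unname(p[1, ]), c(1, 1, 1))

  loc <- hexagon_locus(p)
  expect_equal(c(loc$x, loc$y), c(0, 0))
  expect_equal(achromatic_contrast(loc), 0.5)  # lum of the background

  # doubling the background reflectance doubles all catches
  p2 <- quantum_catch(spec_set(ctx$grid, 2 * ctx$background), ctx)
  expect_equal(unname(p2[1, ]), c(2, 2, 2))

  expect_equal(unname(quantum_catch(spec_set(ctx$grid, rep(0.001, 401) * 0), ctx)[1, ]),
               c(0, 0, 0))

  # rescaling the illuminant by any positive constant leaves loci unchanged
  ill <- default_illuminant()
  ill_scaled <- spec_set(ill$wl, 37.5 * ill$values, kind = "irradiance")
  ctx2 <- viewing_context(illuminant = ill_scaled)
  flowers <- random_smooth_spectra(25, seed = 4)
  expect_equal(hexagon_locus(quantum_catch(flowers, ctx2)),
               hexagon_locus(quantum_catch(flowers, ctx)), tolerance = 1e-12)
})

test_that("hexagon geometry: excitations bounded, loci within circumradius 1", {
  # extreme catches approach the hexagon vertices
  loc <- hexagon_locus(rbind(c(0, 0, 1e9), c(0, 1e9, 0)))
  expect_equal(c(loc$x[1], loc$y[1]), c(sqrt(3) / 2, -0.5), tolerance = 1e-6)
  expect_equal(c(loc$x[2], loc$y[2]), c(0, 1), tolerance = 1e-6)

  set.seed(11)
  p <- matrix(rexp(3000, rate = 0.5), ncol = 3)
  loc <- hexagon_locus(p)
  e <- as.matrix(loc[, 1:3])
  expect_true(all(e >= 0 & e < 1))
  expect_true(all(sqrt(loc$x^2 + loc$y^2) <= 1 + 1e-12))
})

test_that("chromatic distance is a symmetric metric; dL is an absolute difference", {
  a <- data.frame(x = 0, y = 0, e_green = 0.8)
  b <- data.frame(x = sqrt(3) / 2, y = -0.5, e_green = 0.3)
  expect_equal(chromatic_contrast(a, a), 0)
  expect_equal(chromatic_contrast(a, b), 1)  # centre to vertex = circumradius
  expect_equal(chromatic_contrast(a, b), chromatic_contrast(b, a))
  expect_equal(achromatic_contrast(a, b), 0.5)
  expect_equal(achromatic_contrast(a, b), achromatic_contrast(b, a))

  set.seed(3)
  tri <- hexagon_locus(matrix(rexp(9), 3, 3))
  expect_lte(chromatic_contrast(tri[1, ], tri[3, ]),
             chromatic_contrast(tri[1, ], tri[2, ]) +
               chromatic_contrast(tri[2, ], tri[3, ]) + 1e-12)
})

test_that("monochromatic locus bounds broadband stimuli and is well ordered", {
  ml <- test_boundary()
  expect_identical(nrow(ml), 401L)
  # UV-peak boundary points sit in the UV sector of the hexagon
  ang <- atan2(ml$y[ml$lambda == 328], ml$x[ml$lambda == 328]) * 180 / pi
  expect_lt(abs(ang - (-150)), 45)

  # broadband flower spectra are less saturated than their boundary reference
  # for the overwhelming share of hues (the UV+red "purple" gap is the
  # exception, where the clamp applies)
  flowers <- random_smooth_spectra(100, seed = 21)
  loc <- hexagon_locus(quantum_catch(flowers, test_ctx()))
  pur <- spectral_purity(loc, ml)
  r <- sqrt(loc$x^2 + loc$y^2)
  rb <- ml$radius[match(pur$boundary_lambda, ml$lambda)]
  expect_gt(mean(r <= rb + 1e-9), 0.9)
  expect_lt(max(r), max(ml$radius))
  expect_true(all(pur$purity >= 0 & pur$purity <= 1))

  # consecutive-wavelength boundary points are nearest neighbours along the rim
  bb <- ml[ml$radius > 0.1, ]
  gaps <- vapply(seq_len(nrow(bb)), function(i) {
    d <- (bb$x - bb$x[i])^2 + (bb$y - bb$y[i])^2
    d[i] <- Inf
    abs(bb$lambda[which.min(d)] - bb$lambda[i])
  }, numeric(1))
  expect_lte(max(gaps), 2)

  expect_error(monochromatic_locus(test_ctx(), bandwidth_nm = 0.5), "grid step")
})

test_that("spectral purity is the radial ratio to the boundary reference", {
  ml <- test_boundary()
  centre <- spectral_purity(data.frame(x = 0, y = 0), ml)
  expect_equal(centre$purity, 0)
  expect_true(is.na(centre$boundary_lambda))

  j <- which(ml$lambda %in% c(350, 450, 540))
  onb <- spectral_purity(data.frame(x = ml$x[j], y = ml$y[j]), ml)
  expect_equal(onb$purity, rep(1, 3))
  expect_equal(onb$boundary_lambda, c(350, 450, 540))

  # half-radius points along the ray to every strong boundary point score 0.5
  k <- which(ml$radius > 0.3)
  half <- spectral_purity(data.frame(x = ml$x[k] / 2, y = ml$y[k] / 2), ml)
  expect_equal(half$purity, rep(0.5, length(k)), tolerance = 1e-8)

  # the nearest-Euclidean mode stays within bounds but can inflate interior
  # ratios on this non-convex locus (why ray is the default)
  near <- spectral_purity(data.frame(x = ml$x[k] / 2, y = ml$y[k] / 2), ml,
                          mode = "nearest")
  expect_true(all(near$purity >= 0.5 - 1e-9 & near$purity <= 1))
})

test_that("contrast table covers the ten pairs and degrades with missing modules", {
  wl <- 300:700
  full <- spec_set(wl, replicate(4, runif(1, 0.1, 0.6) + 0.2 * receptor_template(550)),
                   species = "spA", module = c("sepal", "petal", "lip_tip", "lip_base"))
  ct <- contrast_table(mean_spectra(full), test_ctx())
  expect_identical(nrow(ct), 10L)
  expect_identical(sum(ct$type == "extrafloral"), 4L)
  expect_true(all(ct$dS >= 0))
  expect_true(all(is.na(ct$lum[ct$type == "intrafloral"])))

  sep_only <- spec_set(wl, matrix(0.3, 401), species = "spB", module = "sepal")
  ct2 <- contrast_table(mean_spectra(sep_only), test_ctx())
  expect_identical(nrow(ct2), 1L)
  expect_identical(as.character(ct2$pair), "leaf-sepal")
})
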