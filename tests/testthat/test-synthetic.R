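test_that("synthetic spectra hit their category targets and are seed-deterministic", {
  # UV-Black: every band mean below its threshold, category round-trips
  vb <- make_spectrum("UV-Black")
  bm <- band_means(spec_set(300:700, vb))
  expect_true(all(unlist(bm[, c("uv", "blue", "green", "red")]) <
                    unname(default_thresholds()[1:4]) - 4))
  expect_identical(categorize_color(bm)$category, "UV-Black")

  # UV+Yellow construction targets
  by <- band_means(spec_set(300:700, make_spectrum("UV+Yellow")))
  expect_gte(by$uv, 15); expect_lt(by$blue, 25)
  expect_gte(by$green, 45); expect_gte(by$red, 65)

  expect_identical(make_spectrum("UV+Pink", noise_sd = 2, seed = 5),
                   make_spectrum("UV+Pink", noise_sd = 2, seed = 5))
  expect_error(make_spectrum("UV-Purple"), "unknown colour category")
})

test_that("pure-birth trees are ultrametric with unit height and reproducible", {
  tr <- make_tree(3, seed = 1)
  expect_identical(tr$Nnode, 2L)
  tr2 <- make_tree(25, seed = 9)
  depths <- ape::node.depth.edgelength(tr2)[1:25]
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(ape::write.tree(make_tree(25, seed = 9)), ape::write.tree(tr2))
  expect_false(identical(ape::write.tree(make_tree(25, seed = 10)), ape::write.tree(tr2)))
  expect_error(make_tree(2), "at least 3")
})

test_that("the paper-like community reproduces the study structure deterministically", {
  cm <- make_community(scenario_config(), seed = 7)
  expect_identical(as.integer(table(cm$traits$reward_type)[c("unknown", "deceit", "nectar", "oil", "fragrance")]),
                   c(47L, 19L, 8L, 10L, 11L))
  expect_identical(sum(rowSums(cm$truth$present) == 4L), 74L)
  expect_identical(sum(!is.na(cm$traits$its_mm)), 35L)
  expect_true(all(cm$traits[, size_variables()] > 0))

  subs <- make_subsets(load_traits(cm$traits), cm$spectra$meta)
  expect_identical(length(subs$size), 95L)
  expect_identical(length(subs$color), 74L)
  expect_identical(length(subs$its), 35L)

  cm2 <- make_community(scenario_config(), seed = 7)
  expect_identical(cm$spectra$values, cm2$spectra$values)
  expect_identical(cm$traits, cm2$traits)
  expect_identical(ape::write.tree(cm$tree), ape::write.tree(cm2$tree))
})

test_that("configured couplings are realized in the community's ground truth", {
  cm <- make_community(scenario_config(rho_c = 0.5, rho_a = -0.3), seed = 13)
  expect_equal(cor(cm$truth$chromatic, cm$truth$f_latent), 0.5, tolerance = 1e-8)
  expect_equal(cor(cm$truth$achromatic, cm$truth$d_latent), -0.3, tolerance = 1e-8)

  cm0 <- make_community(scenario_config(rho_c = 0, rho_a = 0), seed = 13)
  expect_equal(cor(cm0$truth$chromatic, cm0$truth$f_latent), 0, tolerance = 1e-8)
})

test_that("reward-specific category modes surface as positive chi-square residuals", {
  cm <- make_community(scenario_config(), seed = 19)
  ct <- category_table(mean_spectra(cm$spectra))
  rw <- cm$traits$reward_type[match(ct$species, cm$traits$species)]
  tip <- ct$module == "lip_tip"
  r <- suppressWarnings(chi_square_sim(table(rw[tip], ct$category[tip]),
                                       B = 5000, seed = 2))
  expect_gt(r$SR["oil", "UV+Yellow"], 0)
  expect_gt(r$SR["fragrance", "UV-Green"], 0)
  pet <- ct$module == "petal"
  r2 <- suppressWarnings(chi_square_sim(table(rw[pet], ct$category[pet]),
                                        B = 5000, seed = 2))
  expect_gt(r2$SR["deceit", "UV+White"], 0)
})

test_that("writing a community emits the pipeline's file formats round-trippably", {
  cm <- make_community(small_config(), seed = 4)
  dir <- file.path(tempdir(), "bundle-test")
  write_community(cm, dir)
  expect_setequal(list.files(dir), c("spectra.csv", "traits.csv", "tree.nwk", "truth.json"))

  spectra <- read_spectra(file.path(dir, "spectra.csv"))
  expect_equal(spectra$values, cm$spectra$values, tolerance = 1e-12)
  traits <- load_traits(file.path(dir, "traits.csv"))
  expect_identical(traits$species, cm$traits$species)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_identical(sort(tree$tip.label), sort(cm$tree$tip.label))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$seed, 4L)
  unlink(dir, recursive = TRUE)
})
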