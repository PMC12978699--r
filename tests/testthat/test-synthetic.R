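test_that("measurement tables inherit the generative structure", {
  tab <- make_measurement_table(6, sizes = c(8, 8, 7, 10, 9, 8), seed = 21)
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), sum(c(8, 8, 7, 10, 9, 8)))
  expect_equal(names(tab),
               c("cyst_id", "cell_id", "stage_label", "n_bridges",
                 "fusome_volume_um3", "pard3_area_um2", "nucleus_diameter_um"))
  expect_true(all(tab$fusome_volume_um3 > 0))
  expect_true(all(tab$pard3_area_um2 > 0))
  expect_true(all(tab$nucleus_diameter_um > 0))
  expect_true(all(tab$n_bridges >= 1))
  # per-cyst bridge counts satisfy the handshake lemma for a tree
  for (ci in unique(tab$cyst_id)) {
    sub <- tab[tab$cyst_id == ci, ]
    expect_equal(sum(sub$n_bridges), 2L * (nrow(sub) - 1L))
  }
})

test_that("a fixed seed reproduces a byte-identical CSV", {
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_cystkit_csv(make_measurement_table(4, seed = 77), t1,
                    meta = list(seed = 77))
  write_cystkit_csv(make_measurement_table(4, seed = 77), t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_true(file.exists(paste0(t1, ".json")))
  expect_equal(jsonlite::read_json(paste0(t1, ".json"))$seed, 77)
})

test_that("sister asymmetry in 2-cell cysts is detectable against f = 0.5", {
  sister_asym <- function(f, seed) {
    tab <- make_measurement_table(16, sizes = 2,
                                  params = fusome_params(f = f, sigma = 0.25),
                                  seed = seed)
    mean(vapply(split(tab$fusome_volume_um3, tab$cyst_id),
                function(v) asymmetry_index(v[1], v[2]), numeric(1)))
  }
  obs <- sister_asym(0.7, seed = 1)
  null_dist <- vapply(1:199, function(i) sister_asym(0.5, seed = 1000 + i),
                      numeric(1))
  p <- (1 + sum(null_dist >= obs)) / 200
  expect_lt(p, 0.05)
  # and with no asymmetry and no noise the index vanishes identically
  flat <- make_measurement_table(5, sizes = 2,
                                 params = fusome_params(f = 0.5, sigma = 0),
                                 seed = 2)
  idx <- vapply(split(flat$fusome_volume_um3, flat$cyst_id),
                function(v) asymmetry_index(v[1], v[2]), numeric(1))
  expect_equal(unname(idx), rep(0, 5))
})

test_that("mt-gap records are internally consistent and truth-dependent", {
  ds <- make_mt_gap_dataset(truth = "programmed", eta = 0, seed = 5)
  expect_length(ds, 15L)
  expect_equal(vapply(ds, `[[`, integer(1), "cyst_size"),
               rep(c(7L, 8L, 9L, 10L), times = c(3L, 8L, 1L, 3L)))
  for (rec in ds) {
    # gap edge is a real bridge and six_predicted is recomputable from it
    expect_silent(i <- cystkit:::bridge_index(rec$graph, rec$gap_edge))
    expect_identical(rec$six_predicted,
                     any(fragment_sizes(rec$graph, rec$gap_edge) == 6L))
  }
  # programmed truth places the gap at a 6-yielding bridge whenever the
  # topology has one: true for the 7- and 8-cell cysts
  s <- as_breakage_sample(ds)
  expect_true(all(s$six_predicted[s$cyst_size %in% c(7L, 8L)]))

  # all-8-cell programmed datasets predict six in every record
  ds8 <- make_mt_gap_dataset(size_mix = c(`8` = 15L), truth = "programmed",
                             eta = 0, seed = 6)
  expect_true(all(as_breakage_sample(ds8)$six_predicted))

  # eta = 1: never a 6-yielding gap when alternatives exist
  ds_eta <- make_mt_gap_dataset(size_mix = c(`8` = 30L), truth = "programmed",
                                eta = 1, seed = 7)
  expect_false(any(as_breakage_sample(ds_eta)$six_predicted))

  # datasets are reproducible from (config, seed)
  a <- make_mt_gap_dataset(truth = "random", seed = 8)
  b <- make_mt_gap_dataset(truth = "random", seed = 8)
  expect_identical(lapply(a, `[[`, "gap_edge"), lapply(b, `[[`, "gap_edge"))
})

test_that("random-truth gap placement reproduces the enumerated 6-cut rate", {
  ds <- make_mt_gap_dataset(size_mix = c(`8` = 10000L), truth = "random",
                            seed = 9)
  freq <- mean(as_breakage_sample(ds)$six_predicted)
  p <- 2 / 7
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(freq - p), 3 * se)
})

test_that("voxel counting recovers analytic sphere volumes", {
  sph <- data.frame(x = 0, y = 0, z = 0, radius = 5)
  vv <- voxelize_granules(sph, voxel_size = 0.2)
  analytic <- 4 / 3 * pi * 125
  expect_lt(abs(measure_volume(vv, 1) - analytic) / analytic, 0.02)

  # monotone refinement on a fixed sphere set
  errs <- vapply(c(0.4, 0.2, 0.1), function(vs)
    abs(measure_volume(voxelize_granules(sph, vs), 1) - analytic), numeric(1))
  expect_true(all(diff(errs) < 0))

  # multiple non-overlapping granules measured independently
  two <- data.frame(x = c(0, 10), y = 0, z = 0, radius = c(2, 1.5))
  vv2 <- voxelize_granules(two, voxel_size = 0.25)
  expect_lt(abs(measure_volume(vv2, 1) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8),
            0.05)
  expect_lt(abs(measure_volume(vv2, 2) - 4 / 3 * pi * 1.5^3) /
              (4 / 3 * pi * 1.5^3), 0.05)
  expect_equal(measure_volume(vv2, 99), 0)

  expect_error(voxelize_granules(data.frame(x = c(0, 1), y = 0, z = 0,
                                            radius = c(1, 1)), 0.2),
               "overlapping")
  empty <- voxelize_granules(data.frame(x = numeric(), y = numeric(),
                                        z = numeric(), radius = numeric()),
                             0.2)
  expect_equal(measure_volume(empty, 1), 0)
})
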