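test_that("fi_trust matches its closed form on a grid and is monotone", {
  fs <- 10^seq(-8, -0.5, length.out = 20)
  ps <- seq(0.05, 0.95, length.out = 20)
  for (f in fs) {
    trust <- fi_trust(f, ps)
    expect_true(all(abs((1 - f)^trust - ps) < 1e-9))
  }
  expect_equal(fi_trust(0.5, 0.5), 1)
  # decreasing in f; a stricter avoidance probability (p closer to 1)
  # tolerates fewer founder infections, so trust decreases in p
  expect_true(all(diff(fi_trust(fs, 0.9)) < 0))
  expect_true(all(diff(fi_trust(1e-4, ps)) < 0))
  expect_error(fi_trust(0, 0.9), "strictly")
  expect_error(fi_trust(0.5, 1), "strictly")
})

test_that("the uCIP worked example holds at the printed numbers", {
  expect_equal(round(fi_trust(3.5e-6, 0.9)), 30103)
  expect_gt(fi_trust(3.5e-6, 0.9), 2484)
  p_multi <- multi_founder_prob(3.5e-6, 2484)
  expect_lt(p_multi, 0.01)
  expect_equal(p_multi, 0.0087, tolerance = 0.01)
})

test_that("effective frequency multiplies members and imputes absentees", {
  lib <- vbc_library(tibble::tibble(
    vbc = sort(random_barcodes(3)),
    umi_count = c(82L, 8199918L, 0L)
  ))
  expect_equal(effective_frequency(lib$vbc[1], lib), 1e-5)

  lib2 <- vbc_library(tibble::tibble(
    vbc = sort(random_barcodes(3)),
    umi_count = c(100L, 1000L, 998900L)
  ))
  v <- lib2$vbc[order(lib2$umi_count)][1:2]
  expect_equal(effective_frequency(v, lib2), 1e-7)

  absent <- setdiff(random_barcodes(5), lib2$vbc)[1]
  expect_equal(effective_frequency(absent, lib2), 1e-6)
  expect_equal(
    effective_frequency(list(lib2$vbc[1], absent), lib2),
    c(lib2$frequency[1], 1e-6)
  )
})

test_that("founder estimation matches small-case draw distributions", {
  empty <- tibble::tibble(
    cell_barcode = character(), vbc = character(), umis = integer()
  )
  lib <- toy_library(10)
  est0 <- estimate_founders(empty, lib, seed = 1)
  expect_identical(est0$estimate, 0)

  # two equal barcodes, target 2: draws ~ 1 + Geometric(1/2)
  lib2 <- vbc_library(tibble::tibble(
    vbc = random_barcodes(2), umi_count = c(500L, 500L)
  ))
  est <- estimate_founders(NULL, lib2, replicates = 2000, seed = 2,
    target = 2
  )
  expect_true(all(est$draws >= 2))
  expect_equal(mean(est$draws == 2), 0.5, tolerance = 0.05)
  expect_equal(mean(est$draws), 3, tolerance = 0.1)

  expect_error(
    estimate_founders(NULL, lib2, target = 5),
    "exceeds"
  )
})

test_that("founder estimation is calibrated in the birthday regime", {
  # uniform library far from saturation: estimate ~= target
  lib <- vbc_library(tibble::tibble(
    vbc = random_barcodes(20000), umi_count = rep(1L, 20000)
  ))
  est <- estimate_founders(NULL, lib, replicates = 5, seed = 3, target = 100)
  expect_lte(abs(est$estimate - 100), 3)
})

test_that("exclusion rules flag the defined barcode categories", {
  lib <- toy_library(50, counts = rep(10L, 50), seed = 200)
  absent <- setdiff(random_barcodes(60), lib$vbc)
  # felony: library-absent in 2 control cells
  felony_vbc <- absent[1]
  # misdemeanor-like: present with tiny frequency in 3 cells needs a huge
  # library; instead feed frequencies through a custom rule threshold
  control <- tibble::tibble(
    cell_barcode = c("c1", "c2", "c1", "c2", "c3", "c4"),
    vbc = c(felony_vbc, felony_vbc, lib$vbc[1], lib$vbc[1], lib$vbc[1],
      absent[2]
    ),
    umis = 10L
  )
  excl <- build_exclusions(
    control, lib,
    misdemeanor_rules = list(
      list(max_frequency = 0.5, min_cells = 2)
    ),
    abundant_quantile = NULL
  )
  expect_identical(excl$felony, felony_vbc)
  expect_identical(excl$misdemeanor, lib$vbc[1])
  expect_identical(excl$cross_experiment, character(0))
  expect_identical(nrow(excl$concatemer_pairs), 0L)

  # cross-experiment: library-absent barcode in two independent experiments
  exps <- list(
    tibble::tibble(cell_barcode = "e1", vbc = absent[3], umis = 8L),
    tibble::tibble(cell_barcode = "e2", vbc = absent[3], umis = 8L),
    tibble::tibble(cell_barcode = "e3", vbc = lib$vbc[2], umis = 8L)
  )
  excl2 <- build_exclusions(control, lib, experiments = exps,
    abundant_quantile = NULL
  )
  expect_identical(excl2$cross_experiment, absent[3])
})

test_that("concatemer pairs exceed the independence binomial tail", {
  # 1000 control cells; two barcodes in 10 cells each (rate 0.01),
  # co-occurring in 5 cells: expected 0.1 co-occurrences
  pair <- sort(random_barcodes(2))
  fill <- random_barcodes(1000)
  rows <- dplyr::bind_rows(
    tibble::tibble(
      cell_barcode = sprintf("c%04d", 1:5),
      vbc = rep(pair[1], 5)
    ),
    tibble::tibble(
      cell_barcode = sprintf("c%04d", 1:5),
      vbc = rep(pair[2], 5)
    ),
    tibble::tibble(
      cell_barcode = sprintf("c%04d", 6:10), vbc = rep(pair[1], 5)
    ),
    tibble::tibble(
      cell_barcode = sprintf("c%04d", 11:15), vbc = rep(pair[2], 5)
    ),
    tibble::tibble(
      cell_barcode = sprintf("c%04d", 16:1000), vbc = fill[16:1000]
    )
  )
  rows$umis <- 10L
  got <- vbctrace:::concatemer_pairs(rows, alpha = 0.05)
  expect_identical(got$vbc1, pair[1])
  expect_identical(got$vbc2, pair[2])
  # binomial-tail oracle at the marginal rates
  p_tail <- stats::pbinom(4, 1000, 0.01 * 0.01, lower.tail = FALSE)
  expect_lt(p_tail, 0.05)
})

test_that("network assembly keeps trusted units and drops abundant ones", {
  vb <- sort(random_barcodes(4))
  lib <- vbc_library(tibble::tibble(
    vbc = vb,
    umi_count = c(1L, 1L, 500000L, 1L)
  ))
  # rare barcode in 7 cells; abundant barcode (f = 0.5) in 3 cells
  tab <- dplyr::bind_rows(
    tibble::tibble(
      cell_barcode = sprintf("p%02d", 1:7), vbc = vb[1], umis = 10L
    ),
    tibble::tibble(
      cell_barcode = sprintf("q%02d", 1:3), vbc = vb[3], umis = 10L
    )
  )
  nets <- infer_networks(tab, lib, founder_estimate = 50, seed = 4)
  expect_identical(nrow(nets), 1L)
  expect_identical(nets$defining_vbcs, vb[1])
  expect_identical(lengths(nets$members), 7L)
  expect_identical(as.character(nets$size_category), "large")
})

test_that("redundant networks resolve to maximal, pair-preferred units", {
  all_vb <- sort(random_barcodes(1000))
  vb <- all_vb[1:3]
  lib <- vbc_library(tibble::tibble(
    vbc = all_vb, umi_count = rep(1L, 1000)
  ))
  # vb1 and vb2 share the same 3 cells (pair unit + two singles);
  # vb3 spans an overlapping but non-nested set of cells
  cells <- sprintf("c%02d", 1:6)
  tab <- dplyr::bind_rows(
    tidyr::expand_grid(cell_barcode = cells[1:3], vbc = vb[1:2]),
    tibble::tibble(cell_barcode = cells[3:6], vbc = vb[3])
  )
  tab$umis <- 10L
  nets <- infer_networks(tab, lib, founder_estimate = 10, seed = 5)
  expect_identical(nrow(nets), 2L)
  # identical member sets collapse to the pair-defined unit
  expect_true(paste(vb[1], vb[2], sep = "+") %in% nets$defining_vbcs)
  expect_true(vb[3] %in% nets$defining_vbcs)

  # a strict-subset member set is absorbed by the maximal network
  tab2 <- dplyr::bind_rows(
    tibble::tibble(cell_barcode = cells[1:3], vbc = vb[1]),
    tibble::tibble(cell_barcode = cells[1:4], vbc = vb[3])
  )
  tab2$umis <- 10L
  nets2 <- infer_networks(tab2, lib, founder_estimate = 10, seed = 7)
  expect_identical(nets2$defining_vbcs, vb[3])
  expect_identical(lengths(nets2$members), 4L)

  # concatemer pairs are not allowed to define networks
  excl <- structure(
    list(
      felony = character(0), misdemeanor = character(0),
      cross_experiment = character(0),
      concatemer_pairs = tibble::tibble(vbc1 = vb[1], vbc2 = vb[2]),
      library_abundant = character(0)
    ),
    class = "vbc_exclusions"
  )
  nets2 <- infer_networks(tab, lib, exclusions = excl,
    founder_estimate = 10, seed = 6
  )
  expect_false(paste(vb[1], vb[2], sep = "+") %in% nets2$defining_vbcs)
})

test_that("a zero-collision simulation is recovered exactly", {
  cfg <- sim_config(
    n_vbcs = 50000, n_starters = 25, n_collision_testable = 200,
    n_jackpots = 0, n_genes = 20,
    ascertain_starter = 1, ascertain_presyn = 1,
    substitution_rate = 0, chimera_rate = 0
  )
  sl <- simulate_library(cfg, seed = 91)
  sim <- simulate_experiment(sl, cfg, seed = 92)
  # no library collision among drawn founders in this fixture
  expect_false(any(duplicated(sim$truth$clones$vbc)))
  tab <- collapse_cell_vbcs(sim$records, chemistry = "v3")
  nets <- infer_networks(tab, sl$library, chemistry = "v3", seed = 93)
  truth_groups <- sim$truth$members |>
    dplyr::filter(detected) |>
    dplyr::group_by(clone_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(cells = list(cell_barcode), .groups = "drop")
  want <- coassigned_pairs(truth_groups$cells)
  got <- coassigned_pairs(nets$members)
  expect_setequal(got, want)
})
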