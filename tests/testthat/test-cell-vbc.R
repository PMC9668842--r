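make_umis <- function(n, seed = NULL) {
  f <- function() random_barcodes(n, L = 12)
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

cell_rec <- function(vbc, umis, reads = 2L, cb = "cell1") {
  tibble::tibble(
    cell_barcode = cb, umi = umis, vbc = vbc,
    reads = rep(reads, length(umis))
  )
}

test_that("UMI inclusion thresholds follow chemistry and stage", {
  tab <- tibble::tibble(
    cell_barcode = "c1", vbc = random_barcodes(3), umis = c(7L, 6L, 3L)
  )
  v3 <- filter_min_umi(tab, "v3", "network")
  expect_identical(v3$umis, 7L)
  v2 <- filter_min_umi(tab, "v2", "network")
  expect_identical(sort(v2$umis), c(3L, 6L, 7L))
  v3c <- filter_min_umi(tab, "v3", "collapse")
  expect_identical(sort(v3c$umis), c(6L, 7L))
  expect_error(filter_min_umi(tab, "v5"), "arg")
})

test_that("within-cell mutational collapse absorbs close siblings only", {
  parent <- strrep("A", 20)
  sib <- paste0(strrep("A", 19), "T")
  rec <- dplyr::bind_rows(
    cell_rec(parent, make_umis(10, 1)),
    cell_rec(sib, make_umis(2, 2))
  )
  out <- collapse_within_cell(rec)
  expect_identical(unique(out$vbc), parent)
  expect_lte(dplyr::n_distinct(out$umi), 12L)

  far <- paste0(strrep("C", 10), strrep("G", 10))
  rec2 <- dplyr::bind_rows(
    cell_rec(parent, make_umis(5, 3)),
    cell_rec(far, make_umis(4, 4))
  )
  out2 <- collapse_within_cell(rec2)
  expect_setequal(unique(out2$vbc), c(parent, far))
})

test_that("bipartite collapse follows the strict >50% UMI-sharing rule", {
  a <- strrep("A", 20)
  b <- paste0(strrep("C", 10), strrep("G", 10))
  ua <- make_umis(10, 5)
  # B shares 5 of its 6 UMIs with A: 5/6 > 0.5 -> absorbed
  ub <- c(ua[1:5], make_umis(1, 6))
  rec <- dplyr::bind_rows(cell_rec(a, ua), cell_rec(b, ub))
  out <- collapse_bipartite(rec)
  expect_identical(unique(out$vbc), a)

  # exactly 50% sharing stays separate (strict inequality)
  ub2 <- c(ua[1:3], make_umis(3, 7))
  rec2 <- dplyr::bind_rows(cell_rec(a, ua), cell_rec(b, ub2))
  out2 <- collapse_bipartite(rec2)
  expect_setequal(unique(out2$vbc), c(a, b))

  # disjoint UMI sets are untouched
  rec3 <- dplyr::bind_rows(
    cell_rec(a, make_umis(6, 8)), cell_rec(b, make_umis(6, 9))
  )
  expect_setequal(unique(collapse_bipartite(rec3)$vbc), c(a, b))
})

test_that("no cell-UMI is counted under two VBCs after bipartite collapse", {
  a <- strrep("A", 20)
  b <- paste0(strrep("C", 10), strrep("G", 10))
  ua <- make_umis(8, 10)
  ub <- c(ua[1:2], make_umis(6, 11)) # shared UMIs but only 2/8 sharing
  out <- collapse_bipartite(
    dplyr::bind_rows(cell_rec(a, ua), cell_rec(b, ub))
  )
  expect_false(any(duplicated(out$umi)))
})

test_that("both collapse passes are idempotent", {
  withr::with_seed(12, {
    parent <- random_barcodes(1)
    sib <- sub("^.", ifelse(substr(parent, 1, 1) == "A", "C", "A"), parent)
    other <- random_barcodes(1)
    ua <- make_umis(9)
    rec <- dplyr::bind_rows(
      cell_rec(parent, ua),
      cell_rec(sib, c(ua[1], make_umis(2))),
      cell_rec(other, make_umis(5))
    )
  })
  once <- collapse_within_cell(rec)
  expect_equal(collapse_within_cell(once), dplyr::arrange(once, vbc, umi),
    ignore_attr = TRUE
  )
  bi <- collapse_bipartite(once)
  expect_equal(collapse_bipartite(bi), bi)
})

test_that("infection classification uses a strict 1% rabies fraction", {
  prof <- tibble::tibble(
    cell_barcode = c("a", "b", "c"),
    total_umis = c(10000L, 5000L, 10000L),
    rabies_umis = c(150L, 0L, 100L)
  )
  out <- classify_infected(prof)
  expect_identical(out$infected, c(TRUE, FALSE, FALSE))
  expect_error(
    classify_infected(dplyr::mutate(prof, total_umis = c(0L, 1L, 1L))),
    "zero"
  )
})

test_that("moi summary reports per-cell and per-group statistics", {
  tab <- tibble::tibble(
    cell_barcode = c("c1", "c1", "c2"),
    vbc = random_barcodes(3),
    umis = c(5L, 9L, 4L)
  )
  prof <- tibble::tibble(
    cell_barcode = c("c1", "c2"),
    total_umis = c(1000L, 1000L), rabies_umis = c(20L, 10L),
    coarse_type = c("neuron", "neuron")
  )
  m <- moi_summary(tab, prof)
  cell1 <- m$cells[m$cells$cell_barcode == "c1", ]
  expect_identical(cell1$unique_vbcs, 2L)
  expect_identical(cell1$vbc_umis, 14L)
  expect_identical(m$groups$n_cells, 2L)
  expect_equal(m$groups$mean_unique_vbcs, 1.5)
  # groups absent from the profiles are absent from the output
  expect_false(any(is.na(m$groups$group)))
})

test_that("post-collapse within-cell VBC distances look like random 20-mers", {
  # surviving VBC pairs in a cell should be unrelated sequences:
  # mean pairwise Hamming distance 15 = 20 * 3/4 for random 20-mers
  cfg <- sim_config(
    n_vbcs = 3000, n_starters = 40, n_collision_testable = 100,
    n_jackpots = 0, n_genes = 20, lambda = 2.5,
    ascertain_starter = 1, ascertain_presyn = 1
  )
  sl <- simulate_library(cfg, seed = 61)
  sim <- simulate_experiment(sl, cfg, seed = 62)
  noisy <- add_read_noise(sim$records, 0.005, 0.01, seed = 63)
  tab <- collapse_cell_vbcs(noisy, chemistry = "v3")
  dists <- tab |>
    dplyr::group_by(cell_barcode) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(d = list({
      cb <- utils::combn(vbc, 2)
      hamming_distance(cb[1, ], cb[2, ])
    }), .groups = "drop") |>
    dplyr::pull(d) |>
    unlist()
  expect_gt(length(dists), 30)
  sd_expect <- sqrt(20 * 0.75 * 0.25)
  expect_lt(abs(mean(dists) - 15), 2 * sd_expect / sqrt(length(dists)) + 0.5)
  expect_true(all(dists > 2))
})

test_that("collapse removes the artifactual UMI-count/MOI correlation", {
  cfg_clean <- sim_config(
    n_vbcs = 3000, n_starters = 60, n_collision_testable = 100,
    n_jackpots = 0, n_genes = 20, lambda = 2,
    ascertain_starter = 1, ascertain_presyn = 1,
    substitution_rate = 0, chimera_rate = 0
  )
  sl <- simulate_library(cfg_clean, seed = 71)
  sim <- simulate_experiment(sl, cfg_clean, seed = 72)
  per_cell_stats <- function(tab) {
    tab |>
      dplyr::group_by(cell_barcode) |>
      dplyr::summarise(
        unique_vbcs = dplyr::n_distinct(vbc), total = sum(umis),
        .groups = "drop"
      )
  }
  clean <- per_cell_stats(collapse_cell_vbcs(sim$records, "v3"))
  noisy_rec <- add_read_noise(sim$records, 0.005, 0.02, seed = 73)
  noisy <- per_cell_stats(collapse_cell_vbcs(noisy_rec, "v3"))
  rho_clean <- stats::cor(clean$total, clean$unique_vbcs,
    method = "spearman"
  )
  rho_noisy <- stats::cor(noisy$total, noisy$unique_vbcs,
    method = "spearman"
  )
  expect_lt(abs(rho_noisy - rho_clean), 0.1)
})

test_that("the collapse report tracks entry bookkeeping", {
  cfg <- sim_config(
    n_vbcs = 2000, n_starters = 15, n_collision_testable = 50,
    n_jackpots = 0, n_genes = 20, ascertain_starter = 1,
    ascertain_presyn = 1
  )
  sl <- simulate_library(cfg, seed = 81)
  sim <- simulate_experiment(sl, cfg, seed = 82)
  noisy <- add_read_noise(sim$records, 0.01, 0.02, seed = 83)
  tab <- collapse_cell_vbcs(noisy, chemistry = "v3")
  rep <- collapse_report(tab)
  expect_gte(rep$entries_removed_fraction, 0)
  expect_lte(rep$entries_removed_fraction, 1)
  expect_identical(rep$final_entries, nrow(tab))
  expect_gte(rep$raw_entries, rep$final_entries)
})
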