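# Small fixture: networks with assigned starters of two types and typed
# presynaptic members.
fixture_networks <- function(starter_types, presyn_types_per_net,
                             prefix = "n") {
  stopifnot(length(starter_types) == length(presyn_types_per_net))
  members <- list()
  profiles <- list()
  nets <- purrr::imap(starter_types, function(st, i) {
    s <- sprintf("%s%02d_s", prefix, i)
    ps <- sprintf("%s%02d_p%d", prefix, i,
      seq_along(presyn_types_per_net[[i]])
    )
    profiles[[i]] <<- tibble::tibble(
      cell_barcode = c(s, ps),
      coarse_type = c(st, presyn_types_per_net[[i]])
    )
    tibble::tibble(
      network_id = sprintf("%s%02d", prefix, i),
      defining_vbcs = random_barcodes(1),
      members = list(c(s, ps)),
      starter = s
    )
  })
  list(
    networks = vbctrace:::new_vbc_networks(dplyr::bind_rows(nets)),
    profiles = dplyr::bind_rows(profiles)
  )
}

test_that("composition test flags divergent and ignores identical mixes", {
  same <- fixture_networks(
    c("A", "A", "B", "B"),
    rep(list(c("x", "x", "y")), 4)
  )
  ct <- composition_test(same$networks, same$profiles)
  expect_gt(glance(ct)$p.value, 0.9)
  expect_true(all(abs(tidy(ct)$std_residual) < 1e-8))

  diff <- fixture_networks(
    c("A", "A", "B", "B"),
    list(
      rep("x", 5), rep("x", 5), rep("y", 5), rep("y", 5)
    )
  )
  ct2 <- composition_test(diff$networks, diff$profiles)
  expect_lt(glance(ct2)$p.value, 0.01)
  expect_true(max(abs(tidy(ct2)$std_residual)) > 3)

  # textbook chi-square on the underlying 2x2 table
  tab <- ct2$table
  expect_equal(unname(tab["A", "x"]), 10)
  manual <- suppressWarnings(stats::chisq.test(tab))
  expect_equal(glance(ct2)$statistic, unname(manual$statistic))
})

test_that("network size tests recover shifted distributions", {
  sizes_small <- list(rep("x", 2), rep("x", 3), rep("x", 4))
  sizes_large <- list(rep("x", 8), rep("x", 9), rep("x", 10))
  fx <- fixture_networks(
    c("A", "A", "A", "B", "B", "B"),
    c(sizes_small, sizes_large)
  )
  st <- network_size_test(fx$networks, fx$profiles)
  expect_identical(
    sort(st$data$presynaptic_size), c(2L, 3L, 4L, 8L, 9L, 10L)
  )
  pw <- tidy(st)
  # exact rank-sum enumeration: all 3 A-values below all 3 B-values
  expect_equal(pw$p.value, 2 / choose(6, 3), tolerance = 1e-9)

  # identical distributions leave p near 1; relabelling is symmetric
  fx2 <- fixture_networks(
    c("A", "A", "B", "B"),
    list(rep("x", 3), rep("x", 6), rep("x", 3), rep("x", 6))
  )
  st2 <- network_size_test(fx2$networks, fx2$profiles)
  expect_gt(glance(st2)$p.value, 0.9)
  fx3 <- fx2
  relabeled <- dplyr::mutate(
    fx3$profiles,
    coarse_type = ifelse(coarse_type == "A", "B",
      ifelse(coarse_type == "B", "A", coarse_type)
    )
  )
  st3 <- network_size_test(fx3$networks, relabeled)
  expect_equal(glance(st3)$p.value, glance(st2)$p.value)
})

test_that("the immune score is a scale-invariant mean over the set", {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 4), j = c(1, 1, 2, 2), x = c(10, 90, 40, 60),
    dims = c(4, 2)
  )
  rownames(m) <- c("Ifit1", "other", "Ifit3", "RV:EGFP")
  colnames(m) <- c("cellA", "cellB")
  sc <- innate_immune_score(m, c("Ifit1", "Ifit3"))
  # cellA expresses only Ifit1: score = cp100k(Ifit1)/2
  expect_equal(sc$score[1], (10 / 100 * 1e5) / 2)
  # cellB expresses only Ifit3 (RV gene excluded from totals)
  expect_equal(sc$score[2], (40 / 40 * 1e5) / 2)
  sc2 <- innate_immune_score(m * 7, c("Ifit1", "Ifit3"))
  expect_equal(sc2$score, sc$score)
  # single-gene set equals that gene's normalised value
  one <- innate_immune_score(m, "Ifit1")
  expect_equal(one$score[1], 10 / 100 * 1e5)
  expect_error(innate_immune_score(m, "absent"), "present")
})

# Expression fixture for the size-category DE procedure.
de_fixture <- function(n_per_cat = 6, n_genes = 60, planted = character(0),
                       fold = 4, seed = 301, n_pool = 30) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    base <- stats::rlnorm(n_genes, 2, 0.8)
    cellnames <- c(
      sprintf("small%02d", seq_len(n_per_cat)),
      sprintf("large%02d", seq_len(n_per_cat)),
      sprintf("pool%02d", seq_len(n_pool))
    )
    cat <- c(
      rep("small", n_per_cat), rep("large", n_per_cat),
      rep(NA, n_pool)
    )
    counts <- vapply(seq_along(cellnames), function(i) {
      w <- base
      if (!is.na(cat[i]) && cat[i] == "large") {
        w[match(planted, genes)] <- w[match(planted, genes)] * fold
      }
      stats::rmultinom(1, 20000, w)[, 1]
    }, numeric(n_genes))
    rownames(counts) <- genes
    colnames(counts) <- cellnames
    m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    list(
      counts = m,
      cells = tibble::tibble(
        cell_barcode = cellnames[seq_len(2 * n_per_cat)],
        subtype = "SPN",
        size_category = cat[seq_len(2 * n_per_cat)]
      ),
      pool = tibble::tibble(
        cell_barcode = cellnames[-seq_len(2 * n_per_cat)],
        subtype = "SPN"
      )
    )
  })
}

test_that("identical aggregates produce no DE candidates", {
  fx <- de_fixture(planted = character(0), seed = 310)
  de <- de_by_network_size(fx$counts, fx$cells, n_perm = 0)
  expect_identical(sum(de$nominated, na.rm = TRUE), 0L)
})

test_that("a planted fold change is detected and survives permutation", {
  fx <- de_fixture(planted = c("g001", "g002"), fold = 4, seed = 311)
  de <- de_by_network_size(fx$counts, fx$cells, presyn_pool = fx$pool,
    n_perm = 20, seed = 312
  )
  nominated <- de$gene[de$nominated]
  expect_true(all(c("g001", "g002") %in% nominated))
  planted_rows <- de[de$gene %in% c("g001", "g002"), ]
  expect_false(any(planted_rows$flagged))
  expect_true(all(planted_rows$log2fc > 1))
  # permuted cohorts rarely nominate the planted genes
  expect_true(all(planted_rows$perm_hits <= 1))
})

test_that("genes under the aggregated UMI floor are never tested", {
  fx <- de_fixture(seed = 313)
  m <- as.matrix(fx$counts)
  m["g010", ] <- 0
  m["g010", c("small01", "large01")] <- c(12, 12) # 24 aggregated UMIs
  de <- de_by_network_size(
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
    fx$cells,
    n_perm = 0
  )
  expect_false("g010" %in% de$gene)
})

test_that("pseudotime bins are equal-occupancy and the screen is exact on
          proportional genes", {
  withr::with_seed(321, {
    n <- 103
    prof <- tibble::tibble(
      cell_barcode = sprintf("c%03d", seq_len(n)),
      pseudotime = stats::runif(n),
      infected = stats::runif(n) < 0.3
    )
    # ensure controls exist everywhere
    prof$infected[order(prof$pseudotime)[seq(1, n, by = 10)]] <- FALSE
    genes <- c("flat", "prop", "anti", "zero")
    m <- matrix(0, nrow = 4, ncol = n, dimnames = list(genes, prof$cell_barcode))
    m["flat", ] <- 50
    m["prop", ] <- round(200 * prof$pseudotime) + 1
    m["anti", ] <- round(200 * (1 - prof$pseudotime)) + 1
    m["zero", ] <- 0
  })
  ms <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  scr <- infectivity_correlation(prof, ms, n_bins = 10, r_threshold = 0.75)
  expect_lte(diff(range(scr$bins$n_cells)), 1)
  expect_false("zero" %in% scr$genes$gene)
  expect_false("flat" %in% scr$genes$gene[scr$genes$correlated])

  # a gene exactly proportional to the infected fraction scores r = 1
  frac <- scr$bins$infected_fraction
  m2 <- rbind(m, exact = 0)
  for (b in seq_len(10)) {
    cb <- scr$bins$bin[b]
  }
  # rebuild with the exact gene using bin-level assignment
  pf <- dplyr::mutate(prof, bin = dplyr::ntile(pseudotime, 10))
  m2["exact", ] <- frac[pf$bin] * 1000 + 1
  ms2 <- methods::as(Matrix::Matrix(m2, sparse = TRUE), "CsparseMatrix")
  scr2 <- infectivity_correlation(prof, ms2, n_bins = 10)
  expect_true(scr2$genes$correlated[scr2$genes$gene == "exact"])
  expect_equal(scr2$genes$r[scr2$genes$gene == "exact"], 1,
    tolerance = 0.05
  )
})

test_that("planted trajectory genes are recovered with high sensitivity", {
  cfg <- sim_config(
    n_vbcs = 2000, n_starters = 60, n_collision_testable = 50,
    n_jackpots = 0, n_genes = 120, n_traj_genes = 20, n_controls = 250,
    ascertain_starter = 1, ascertain_presyn = 1
  )
  sl <- simulate_library(cfg, seed = 331)
  sim <- simulate_experiment(sl, cfg, seed = 332)
  prof <- classify_infected(sim$profiles)
  scr <- infectivity_correlation(prof, sim$counts, n_bins = 10)
  hits <- correlated_genes(scr)
  sens <- mean(sim$truth$traj_genes %in% hits)
  expect_gte(sens, 0.9)
})

test_that("control gene sets honour size, mode and decile structure", {
  withr::with_seed(341, {
    ref <- stats::setNames(
      c(stats::rlnorm(200, 2, 1), rep(0, 20)),
      sprintf("g%03d", 1:220)
    )
  })
  expect_identical(
    nrow(control_gene_sets(ref, character(0), replicates = 3, seed = 1)),
    0L
  )
  rnd <- control_gene_sets(ref, names(ref)[1:40], mode = "random",
    replicates = 5, seed = 2
  )
  expect_identical(dplyr::count(rnd, set_id)$n, rep(40L, 5))
  expect_true(all(rnd$gene %in% names(ref)[ref > 0]))

  # expression-matched: target = all expressed genes -> a permutation
  expressed <- names(ref)[ref > 0]
  matched <- control_gene_sets(ref, expressed, mode = "expression_matched",
    replicates = 2, seed = 3
  )
  for (s in unique(matched$set_id)) {
    expect_setequal(matched$gene[matched$set_id == s], expressed)
  }

  # decile histograms of matched sets track the target's
  target <- names(sort(ref, decreasing = TRUE))[1:40] # top-expression target
  matched2 <- control_gene_sets(ref, target, mode = "expression_matched",
    replicates = 4, seed = 4
  )
  decile <- stats::setNames(
    dplyr::ntile(rank(ref[expressed], ties.method = "first"), 10), expressed
  )
  target_hist <- table(factor(decile[intersect(target, expressed)],
    levels = 1:10
  ))
  for (s in unique(matched2$set_id)) {
    got_hist <- table(factor(decile[matched2$gene[matched2$set_id == s]],
      levels = 1:10
    ))
    expect_equal(as.integer(got_hist), as.integer(target_hist))
  }
  # different seeds give different draws for an unsaturated target
  mid_target <- withr::with_seed(7, sample(expressed, 40))
  a <- control_gene_sets(ref, mid_target, replicates = 1, seed = 5)
  b <- control_gene_sets(ref, mid_target, replicates = 1, seed = 6)
  expect_false(identical(sort(a$gene), sort(b$gene)))
})

test_that("two-way anova wrapper returns a tidy table", {
  withr::with_seed(351, {
    df <- tibble::tibble(
      load = stats::rnorm(40, rep(c(1, 3), each = 20)),
      type = rep(c("A", "B"), each = 20),
      size = rep(c("small", "large"), 20)
    )
  })
  out <- two_way_anova(df, "load", "type", "size")
  expect_identical(
    out$term[1:3], c("type", "size", "type:size")
  )
  expect_lt(out$p.value[1], 0.01)
})
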