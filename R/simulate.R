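# Forward simulation of a complete barcoded-rabies experiment with ground
# truth: a skewed-abundance barcoded library, Poisson-distributed founder
# infections in sparse starter cells, cell-type-dependent clonal spread into
# presynaptic partners, partial single-cell ascertainment with differential
# starter loss, PCR/sequencing substitutions on barcodes and UMIs, and
# strand-displacement chimeras that swap a read's barcode while keeping its
# UMI. Every read traces to a truth entry, so each pipeline stage has a
# recovery test without external data.

random_seqs <- function(n, L) {
  out <- do.call(paste0, lapply(seq_len(L), function(i) {
    sample(DNA_BASES, n, replace = TRUE)
  }))
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_seqs(length(dup), L)
  }
  out
}

#' Simulation settings
#'
#' Defaults describe one culture-well-scale experiment infected from a
#' deeply characterised library: ~1.29 million unique barcodes averaging
#' ~6.4 UMIs each with a small jackpot tail, sparse starter cells at founder
#' MOI ~1.5 (zero-truncated Poisson), negative-binomial presynaptic spread
#' with type-specific means, 25% presynaptic vs 2.5% starter ascertainment
#' (starter cells are preferentially destroyed during dissociation), and
#' low per-base substitution plus chimera rates.
#'
#' @param n_vbcs Library size (unique barcodes).
#' @param abundance_meanlog,abundance_sigma Log-normal UMI-count model.
#' @param n_jackpots Number of planted jackpot (over-amplified) barcodes.
#' @param n_collision_testable Size of the subset guaranteed pairwise
#'   Hamming distance >= 3 (error-correction identifiability); real
#'   libraries offer no such guarantee.
#' @param n_starters Starter cells in the experiment.
#' @param lambda Founder-infection MOI per starter (zero-truncated Poisson).
#' @param cell_types Type catalog: `type`, `class` (neuron/glia),
#'   `starter_prob`, `presyn_mu`, `presyn_disp`.
#' @param composition Starter-type x presynaptic-type composition matrix.
#' @param transmission_prob Probability a presynaptic cell receives each of
#'   its starter's clones (cells receiving none get one at random).
#' @param ascertain_presyn,ascertain_starter Capture probabilities.
#' @param umi_mu,umi_size Negative-binomial VBC UMI counts per cell by class.
#' @param reads_per_umi Mean extra reads per UMI (1 + Poisson).
#' @param substitution_rate Per-base substitution probability on VBCs/UMIs.
#' @param chimera_rate Per-read probability of a VBC swap within the cell.
#' @param ambient_rabies_frac Rabies fraction in uninfected cells.
#' @param chemistry `"v3"` or `"v2"` (sets the detection threshold recorded
#'   in the truth).
#' @param n_genes,n_controls Host gene count and uninfected control cells.
#' @param rabies_frac_neuron,rabies_frac_glia Rabies transcription load of
#'   infected cells by class.
#' @param bg_raav_rate,bg_tva_rate,starter_raav_mu,starter_tva_rate rAAV
#'   transgene model: background rAAV rate per host UMI, background
#'   recombined-TVA rate per rAAV UMI, starter rAAV mean, starter
#'   recombined-TVA rate.
#' @param n_de_genes,de_fold Genes upregulated `de_fold`-fold in starters of
#'   large networks (0 = null simulation).
#' @param n_traj_genes Genes with expression rising along pseudotime.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_vbcs = 1.29e6,
                       abundance_meanlog = 1.4, abundance_sigma = 1,
                       n_jackpots = 88, n_collision_testable = 1000,
                       n_starters = 50, lambda = 1.5,
                       cell_types = default_cell_types(),
                       composition = default_composition(),
                       transmission_prob = 0.9,
                       ascertain_presyn = 0.25, ascertain_starter = 0.025,
                       umi_mu = c(neuron = 100, glia = 15), umi_size = 2,
                       reads_per_umi = 3,
                       substitution_rate = 0.005, chimera_rate = 0.01,
                       ambient_rabies_frac = 0.003,
                       chemistry = "v3",
                       n_genes = 200, n_controls = 0,
                       rabies_frac_neuron = 0.15, rabies_frac_glia = 0.05,
                       bg_raav_rate = 0.005, bg_tva_rate = 0.02,
                       starter_raav_mu = 600, starter_tva_rate = 0.8,
                       n_de_genes = 0, de_fold = 4, n_traj_genes = 0) {
  cfg <- as.list(environment())
  stopifnot(
    lambda > 0,
    all(c(
      transmission_prob, ascertain_presyn, ascertain_starter,
      substitution_rate, chimera_rate, ambient_rabies_frac
    ) >= 0),
    all(c(
      transmission_prob, ascertain_presyn, ascertain_starter,
      substitution_rate, chimera_rate, ambient_rabies_frac
    ) <= 1)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_cell_types <- function() {
  tibble::tibble(
    type = c("glutamatergic", "interneuron", "SPN", "astrocyte"),
    class = c("neuron", "neuron", "neuron", "glia"),
    starter_prob = c(0.35, 0.2, 0.3, 0.15),
    presyn_mu = c(3.6, 3.7, 6.7, 4.6),
    presyn_disp = c(3, 3, 3, 3)
  )
}

#' @rdname sim_config
#' @export
default_composition <- function() {
  m <- rbind(
    glutamatergic = c(0.45, 0.20, 0.25, 0.10),
    interneuron   = c(0.30, 0.35, 0.25, 0.10),
    SPN           = c(0.25, 0.15, 0.45, 0.15),
    astrocyte     = c(0.30, 0.20, 0.20, 0.30)
  )
  colnames(m) <- c("glutamatergic", "interneuron", "SPN", "astrocyte")
  m
}

#' Simulate a barcoded viral library
#'
#' Unique random 20-mers with log-normal UMI counts plus `n_jackpots`
#' planted jackpot barcodes strictly more abundant than every other
#' barcode. A designated subset is regenerated until all of its pairwise
#' Hamming distances are >= 3, making error-correction identifiability
#' testable.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return List of class `sim_library`: `library` (a [vbc_library]) and
#'   `truth` (`jackpots`, `collision_testable` barcode vectors).
#' @export
simulate_library <- function(config = sim_config(), seed = NULL) {
  stopifnot(config$n_vbcs >= 1)
  with_seed_or_not(seed, {
    n <- as.integer(config$n_vbcs)
    vbcs <- random_seqs(n, 20L)
    m <- min(config$n_collision_testable, n)
    if (m > 1) {
      repeat {
        pairs <- neighbor_pairs(vbcs[seq_len(m)], 2L)
        if (!ncol(pairs)) break
        redo <- unique(pairs[2, ])
        repl <- random_seqs(length(redo), 20L)
        while (any(repl %in% vbcs)) {
          clash <- repl %in% vbcs
          repl[clash] <- random_seqs(sum(clash), 20L)
        }
        vbcs[redo] <- repl
      }
    }
    counts <- ceiling(stats::rlnorm(
      n, config$abundance_meanlog, config$abundance_sigma
    ))
    k <- min(config$n_jackpots, n - 1)
    jack <- integer(0)
    if (k > 0) {
      jack <- sample.int(n, k)
      top <- max(counts[-jack])
      counts[jack] <- ceiling(top * stats::runif(k, 1.2, 2))
    }
    lib <- vbc_library(tibble::tibble(vbc = vbcs, umi_count = counts))
    structure(
      list(
        library = lib,
        truth = list(
          jackpots = sort(vbcs[jack]),
          collision_testable = sort(vbcs[seq_len(m)])
        )
      ),
      class = "sim_library"
    )
  })
}

# Zero-truncated Poisson draws.
rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

#' Simulate UMI-level sequencing records of a library
#'
#' Emits, for every barcode of the profile, its UMI count's worth of
#' distinct random 12-bp UMIs with 1 + Poisson read counts — the noiseless
#' substrate of [count_library()]. Pass through [add_read_noise()] to add
#' substitutions.
#'
#' @param library A [vbc_library] (keep it small; one row per UMI results).
#' @param reads_per_umi Mean extra reads per UMI.
#' @param seed Optional RNG seed.
#' @return A UMI records tibble (`cell_barcode` constant `"library"`).
#' @export
simulate_library_records <- function(library, reads_per_umi = 3,
                                     seed = NULL) {
  with_seed_or_not(seed, {
    n_umis <- sum(library$umi_count)
    tibble::tibble(
      cell_barcode = "library",
      umi = random_seqs(n_umis, 12L),
      vbc = rep(library$vbc, library$umi_count),
      reads = 1L + stats::rpois(n_umis, reads_per_umi - 1)
    )
  })
}

#' Simulate a complete spread experiment
#'
#' Starter cells receive zero-truncated-Poisson founder infections drawn
#' with replacement from the library's frequencies (so realistic barcode
#' collisions can occur). All clones of a starter spread into that
#' starter's presynaptic partner set (negative-binomial size, type-specific
#' mean and composition); each presynaptic cell receives each clone
#' independently with `transmission_prob` (at least one). Cells are then
#' ascertained at class-specific rates, VBC UMI counts drawn per
#' (cell, clone) from class-dependent negative binomials, and expression
#' profiles generated with rabies genes, rAAV transgene features, optional
#' planted differential-expression and pseudotime-trajectory genes.
#'
#' @param sim_lib A `sim_library` from [simulate_library()] (or a
#'   [vbc_library], in which case no library truth is attached).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return List of class `sim_experiment`: `records` (noiseless UMI-level
#'   records of captured cells), `profiles` (per-cell metadata incl. types,
#'   pseudotime, rAAV counts, true starter flags), `counts` (features x
#'   cells sparse DGE incl. `RV:` and `AAV:` features), and `truth`
#'   (`clones`, `members` with per-cell true UMI counts and
#'   captured/detected flags, planted gene sets, the detection threshold).
#' @export
simulate_experiment <- function(sim_lib, config = sim_config(),
                                seed = NULL) {
  library <- if (inherits(sim_lib, "sim_library")) sim_lib$library else sim_lib
  ct <- config$cell_types
  comp <- config$composition
  with_seed_or_not(seed, {
    n_s <- config$n_starters
    starter_ids <- sprintf("s%04d", seq_len(n_s))
    starter_type <- sample(ct$type, n_s, replace = TRUE,
      prob = ct$starter_prob
    )
    moi <- rztpois(n_s, config$lambda)
    n_clones <- sum(moi)
    clone_starter <- rep(seq_len(n_s), moi)
    clone_vbc <- library$vbc[
      sample.int(nrow(library), n_clones, replace = TRUE,
        prob = library$frequency
      )
    ]
    clone_id <- sprintf("c%05d", seq_len(n_clones))
    # presynaptic partner sets, one per starter, shared by its clones
    presyn <- purrr::map(seq_len(n_s), function(i) {
      row <- match(starter_type[i], ct$type)
      k <- stats::rnbinom(1, mu = ct$presyn_mu[row],
        size = ct$presyn_disp[row]
      )
      if (k == 0) return(tibble::tibble(
        cell_barcode = character(), type = character()
      ))
      tibble::tibble(
        cell_barcode = sprintf("p%04d_%02d", i, seq_len(k)),
        type = sample(colnames(comp), k, replace = TRUE,
          prob = comp[starter_type[i], ]
        )
      )
    })
    # clone membership: starter always; presynaptic cells get each clone
    # with transmission_prob, at least one clone each
    memb <- purrr::map(seq_len(n_clones), function(j) {
      i <- clone_starter[j]
      cells <- presyn[[i]]$cell_barcode
      got <- cells[stats::runif(length(cells)) < config$transmission_prob]
      tibble::tibble(clone_id = clone_id[j],
        cell_barcode = c(starter_ids[i], got)
      )
    }) |>
      dplyr::bind_rows()
    # presynaptic cells that received no clone get one of their starter's
    for (i in seq_len(n_s)) {
      cells <- presyn[[i]]$cell_barcode
      missing <- setdiff(cells, memb$cell_barcode)
      if (length(missing)) {
        own <- clone_id[clone_starter == i]
        memb <- dplyr::bind_rows(memb, tibble::tibble(
          clone_id = sample(own, length(missing), replace = TRUE),
          cell_barcode = missing
        ))
      }
    }
    cells_tbl <- dplyr::bind_rows(
      tibble::tibble(
        cell_barcode = starter_ids, type = starter_type,
        role = "starter"
      ),
      purrr::imap(presyn, function(df, i) {
        dplyr::mutate(df, role = "presynaptic")
      }) |> dplyr::bind_rows(),
      if (config$n_controls > 0) {
        tibble::tibble(
          cell_barcode = sprintf("u%04d", seq_len(config$n_controls)),
          type = sample(ct$type, config$n_controls, replace = TRUE,
            prob = ct$starter_prob
          ),
          role = "control"
        )
      }
    )
    cells_tbl$class <- ct$class[match(cells_tbl$type, ct$type)]
    cap_rate <- dplyr::case_when(
      cells_tbl$role == "starter" ~ config$ascertain_starter,
      cells_tbl$role == "presynaptic" ~ config$ascertain_presyn,
      TRUE ~ 1
    )
    cells_tbl$captured <- stats::runif(nrow(cells_tbl)) < cap_rate
    # true VBC UMI counts for captured infected cells
    thr <- umi_threshold(config$chemistry, "network")
    memb <- memb |>
      dplyr::left_join(
        cells_tbl |> dplyr::select("cell_barcode", "class", "captured"),
        by = "cell_barcode"
      ) |>
      dplyr::mutate(
        true_umis = pmax(1L, stats::rnbinom(
          dplyr::n(),
          mu = config$umi_mu[.data$class], size = config$umi_size
        )),
        detected = .data$captured & .data$true_umis >= thr,
        vbc = clone_vbc[match(.data$clone_id, .env$clone_id)]
      )
    # UMI-level records for captured cells
    rec_src <- memb |> dplyr::filter(.data$captured)
    records <- if (nrow(rec_src)) {
      purrr::pmap(
        list(rec_src$cell_barcode, rec_src$vbc, rec_src$true_umis),
        function(cb, v, k) {
          tibble::tibble(cell_barcode = cb, vbc = v,
            umi = random_seqs(k, 12L)
          )
        }
      ) |>
        dplyr::bind_rows() |>
        dplyr::mutate(
          reads = 1L + stats::rpois(dplyr::n(), config$reads_per_umi - 1)
        )
    } else {
      tibble::tibble(
        cell_barcode = character(), vbc = character(),
        umi = character(), reads = integer()
      )
    }
    # expression profiles of captured cells
    kept <- cells_tbl |> dplyr::filter(.data$captured)
    counts <- simulate_expression(kept, memb, config)
    profiles <- cell_profiles_from_counts(counts$m) |>
      dplyr::left_join(
        kept |>
          dplyr::select("cell_barcode", "role", "type", "class") |>
          dplyr::rename(coarse_type = "class", granular_type = "type"),
        by = "cell_barcode"
      ) |>
      dplyr::mutate(
        pseudotime = counts$pseudotime[.data$cell_barcode],
        true_starter = .data$role == "starter"
      )
    truth <- list(
      clones = tibble::tibble(
        clone_id = clone_id, vbc = clone_vbc,
        starter_cell = starter_ids[clone_starter]
      ),
      members = memb |>
        dplyr::select(
          "clone_id", "cell_barcode", "vbc", "true_umis", "captured",
          "detected"
        ),
      starters = tibble::tibble(
        cell_barcode = starter_ids,
        captured = cells_tbl$captured[match(starter_ids,
          cells_tbl$cell_barcode
        )]
      ),
      detection_threshold = thr,
      de_genes = counts$de_genes,
      traj_genes = counts$traj_genes,
      library_truth = if (inherits(sim_lib, "sim_library")) sim_lib$truth
    )
    structure(
      list(
        records = records |>
          dplyr::select("cell_barcode", "umi", "vbc", "reads"),
        profiles = profiles, counts = counts$m, truth = truth,
        config = config
      ),
      class = "sim_experiment"
    )
  })
}

# Expression matrix for captured cells: host genes (with optional planted
# DE and trajectory effects), rabies gene rows, rAAV transgene rows.
simulate_expression <- function(kept, memb, config) {
  n_cells <- nrow(kept)
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  base_w <- stats::rlnorm(config$n_genes, 1, 1)
  de_genes <- traj_genes <- character(0)
  free <- seq_len(config$n_genes)
  if (config$n_de_genes > 0) {
    idx <- free[seq_len(config$n_de_genes)]
    de_genes <- genes[idx]
    free <- setdiff(free, idx)
  }
  if (config$n_traj_genes > 0) {
    idx <- free[seq_len(config$n_traj_genes)]
    traj_genes <- genes[idx]
  }
  infected <- kept$role != "control"
  pseudotime <- stats::setNames(numeric(n_cells), kept$cell_barcode)
  pseudotime[infected] <- stats::rbeta(sum(infected), 3, 1.5)
  pseudotime[!infected] <- stats::rbeta(sum(!infected), 1.5, 3)
  # network size category per starter (for planted DE)
  starter_large <- character(0)
  if (length(de_genes)) {
    psize <- memb |>
      dplyr::filter(.data$captured) |>
      dplyr::distinct(.data$clone_id, .data$cell_barcode) |>
      dplyr::count(.data$clone_id)
    large_clones <- psize$clone_id[psize$n >= 8]
    starter_large <- unique(
      memb$cell_barcode[memb$clone_id %in% large_clones &
        memb$cell_barcode %in% kept$cell_barcode[kept$role == "starter"]]
    )
  }
  vbc_umis <- memb |>
    dplyr::filter(.data$captured) |>
    dplyr::group_by(.data$cell_barcode) |>
    dplyr::summarise(vbc_umis = sum(.data$true_umis), .groups = "drop")
  vbc_by_cell <- stats::setNames(
    vbc_umis$vbc_umis, vbc_umis$cell_barcode
  )
  host_total <- round(stats::rlnorm(
    n_cells, log(ifelse(kept$class == "neuron", 9000, 4500)), 0.25
  ))
  host <- vapply(seq_len(n_cells), function(i) {
    w <- base_w
    if (length(de_genes) && kept$cell_barcode[i] %in% starter_large) {
      w[match(de_genes, genes)] <- w[match(de_genes, genes)] * config$de_fold
    }
    if (length(traj_genes)) {
      tmult <- 0.2 + 0.8 * pseudotime[kept$cell_barcode[i]]
      w[match(traj_genes, genes)] <- w[match(traj_genes, genes)] * tmult
    }
    stats::rmultinom(1, host_total[i], w)[, 1]
  }, numeric(config$n_genes))
  rownames(host) <- genes
  # rabies rows: EGFP carries the VBC UMIs; N/P/M/L share the rest
  rfrac <- ifelse(kept$class == "neuron", config$rabies_frac_neuron,
    config$rabies_frac_glia
  )
  egfp <- unname(vbc_by_cell[kept$cell_barcode])
  egfp[is.na(egfp)] <- 0
  rv_total <- ifelse(
    infected,
    pmax(egfp, round(rfrac / (1 - rfrac) * host_total)),
    stats::rbinom(n_cells, host_total, config$ambient_rabies_frac)
  )
  rest <- pmax(rv_total - egfp, 0)
  rv_genes <- c("RV:N", "RV:P", "RV:M", "RV:L")
  rv <- vapply(seq_len(n_cells), function(i) {
    if (rest[i] == 0) return(c(numeric(4), egfp[i]))
    c(stats::rmultinom(1, rest[i], rep(0.25, 4))[, 1], egfp[i])
  }, numeric(5))
  rownames(rv) <- c(rv_genes, "RV:EGFP")
  # rAAV transgene rows
  is_starter <- kept$role == "starter"
  raav <- integer(n_cells)
  raav[is_starter] <- stats::rnbinom(sum(is_starter),
    mu = config$starter_raav_mu, size = 5
  ) + 10L
  raav[!is_starter] <- stats::rbinom(sum(!is_starter),
    host_total[!is_starter], config$bg_raav_rate
  )
  rec <- integer(n_cells)
  rec[is_starter] <- stats::rbinom(sum(is_starter), raav[is_starter],
    config$starter_tva_rate
  )
  rec[!is_starter] <- stats::rbinom(sum(!is_starter), raav[!is_starter],
    config$bg_tva_rate
  )
  aav <- rbind("AAV:TVA-mCherry-rec" = rec, "AAV:cassette" = raav - rec)
  m <- methods::as(
    Matrix::Matrix(rbind(host, rv, aav), sparse = TRUE), "CsparseMatrix"
  )
  colnames(m) <- kept$cell_barcode
  list(
    m = m, pseudotime = pseudotime, de_genes = de_genes,
    traj_genes = traj_genes
  )
}

#' Add substitution and chimera noise to UMI records
#'
#' Expands records to individual reads, applies i.i.d. per-base
#' substitutions to VBC and UMI sequences, and with probability
#' `chimera_rate` swaps a read's VBC for another VBC present in the same
#' cell while keeping its UMI — the strand-displacement chimera signature
#' that the bipartite UMI-sharing collapse is designed to remove. Reads are
#' re-aggregated on output.
#'
#' @param records UMI records tibble (`cell_barcode`, `umi`, `vbc`,
#'   `reads`).
#' @param substitution_rate Per-base substitution probability.
#' @param chimera_rate Per-read VBC swap probability.
#' @param seed Optional RNG seed.
#' @return A noisy records tibble in the same format.
#' @export
add_read_noise <- function(records, substitution_rate = 0.005,
                           chimera_rate = 0.01, seed = NULL) {
  check_cols(records, c("cell_barcode", "umi", "vbc", "reads"), "records")
  if (!nrow(records) || (substitution_rate == 0 && chimera_rate == 0)) {
    return(records)
  }
  with_seed_or_not(seed, {
    idx <- rep(seq_len(nrow(records)), records$reads)
    cell <- records$cell_barcode[idx]
    vbc <- records$vbc[idx]
    umi <- records$umi[idx]
    if (chimera_rate > 0) {
      cell_vbcs <- lapply(
        split(records$vbc, records$cell_barcode), unique
      )
      multi <- names(cell_vbcs)[lengths(cell_vbcs) > 1]
      hit <- which(stats::runif(length(idx)) < chimera_rate &
        cell %in% multi)
      if (length(hit)) {
        vbc[hit] <- vapply(hit, function(r) {
          others <- setdiff(cell_vbcs[[cell[r]]], vbc[r])
          if (!length(others)) vbc[r] else sample(others, 1)
        }, character(1))
      }
    }
    if (substitution_rate > 0) {
      vbc <- mutate_seqs(vbc, substitution_rate)
      umi <- mutate_seqs(umi, substitution_rate)
    }
    tibble::tibble(cell_barcode = cell, umi = umi, vbc = vbc) |>
      dplyr::count(.data$cell_barcode, .data$umi, .data$vbc,
        name = "reads"
      ) |>
      dplyr::mutate(reads = as.integer(.data$reads)) |>
      dplyr::select("cell_barcode", "umi", "vbc", "reads")
  })
}

# Apply i.i.d. substitutions to a vector of equal-length sequences.
mutate_seqs <- function(seqs, rate) {
  if (!length(seqs)) return(seqs)
  L <- nchar(seqs[1])
  n <- length(seqs)
  chars <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = n, byrow = TRUE
  )
  hits <- which(matrix(stats::runif(n * L) < rate, n, L), arr.ind = TRUE)
  if (nrow(hits)) {
    cur <- match(chars[hits], DNA_BASES)
    chars[hits] <- DNA_BASES[
      ((cur - 1 + sample.int(3, nrow(hits), replace = TRUE)) %% 4) + 1
    ]
  }
  do.call(paste0, asplit(chars, 2))
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d captured cells, %d clones, %d UMI records\n",
    nrow(x$profiles), nrow(x$truth$clones), nrow(x$records)
  ))
  invisible(x)
}

#' Write every input format of a simulated experiment
#'
#' Emits the UMI records TSV, the DGE triplet files, cell annotations and a
#' `truth.json`, i.e. everything the pipeline reads plus ground truth.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_umi_records(sim$records, file.path(dir, "cell_records.tsv"))
  write_dge(
    sim$counts, file.path(dir, "matrix.mtx"),
    file.path(dir, "features.tsv"), file.path(dir, "barcodes.tsv")
  )
  write_cell_annotations(
    sim$profiles |>
      dplyr::select(
        "cell_barcode", "coarse_type", "granular_type", "pseudotime"
      ),
    file.path(dir, "annotations.tsv")
  )
  jsonlite::write_json(
    list(
      clones = as.data.frame(sim$truth$clones),
      members = as.data.frame(sim$truth$members),
      starters = as.data.frame(sim$truth$starters),
      detection_threshold = sim$truth$detection_threshold,
      de_genes = sim$truth$de_genes,
      traj_genes = sim$truth$traj_genes
    ),
    file.path(dir, "truth.json"),
    pretty = TRUE
  )
  invisible(dir)
}
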