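# Per-cell, error-corrected viral barcode counts from single-cell reads.
#
# Two collapse passes clean each cell independently: (1) a mutational pass
# assigns low-abundance sibling VBCs to a more numerous parent within a small
# Hamming radius and deduplicates the pooled UMIs; (2) a bipartite pass
# absorbs VBCs that share more than half of their UMI sequences (within
# Hamming distance 2) with a more abundant VBC — the signature of
# strand-displacement chimeras, where a read keeps its UMI but swaps VBC.

# Stage/chemistry UMI inclusion thresholds (distinct UMIs per cell-VBC).
umi_threshold <- function(chemistry = c("v3", "v2"),
                          stage = c("collapse", "network"),
                          config = default_config()) {
  chemistry <- match.arg(chemistry)
  stage <- match.arg(stage)
  config$umi_thresholds[[chemistry]][[stage]]
}

#' Filter cell-VBC entries below the UMI inclusion threshold
#'
#' Thresholds depend on chemistry and pipeline stage: v3 chemistry uses >= 5
#' UMIs before collapse and >= 7 at the network stage; v2 uses >= 3 at both.
#'
#' @param table Tibble with columns `cell_barcode`, `vbc`, `umis`.
#' @param chemistry `"v3"` or `"v2"`.
#' @param stage `"collapse"` or `"network"`.
#' @param config Settings list holding the thresholds.
#' @return The filtered tibble.
#' @export
filter_min_umi <- function(table, chemistry = c("v3", "v2"),
                           stage = c("network", "collapse"),
                           config = default_config()) {
  chemistry <- match.arg(chemistry)
  stage <- match.arg(stage)
  check_cols(table, c("cell_barcode", "vbc", "umis"), "cell-VBC table")
  thr <- config$umi_thresholds[[chemistry]][[stage]]
  dplyr::filter(table, .data$umis >= thr)
}

# Deduplicate one cell-VBC entry's UMI list (Hamming <= umi_dist), keeping
# the family-parent UMI sequences and their pooled read counts.
dedup_umis <- function(umis, reads, umi_dist = 1L) {
  if (length(umis) <= 1L) {
    return(tibble::tibble(umi = umis, reads = reads))
  }
  idx <- umi_family_index(umis, reads, max_dist = umi_dist)
  tibble::tibble(umi = umis[idx], reads = reads) |>
    dplyr::group_by(.data$umi) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
}

#' Mutational collapse of one cell's VBC entries
#'
#' Operates on the UMI-level records of a single cell: VBC families are
#' grown in descending UMI-abundance order within `max_dist` mismatches,
#' sibling entries are assigned the parent VBC, and the pooled UMIs of each
#' family are deduplicated at Hamming distance <= `umi_dist`. With
#' `adaptive_umi_gate` set, a cell whose most abundant VBC reaches the gate
#' is collapsed at radius `max_dist + 1` (abundance-gated radius).
#'
#' @param cell_records Tibble for one cell: `umi`, `vbc`, `reads`.
#' @param max_dist Hamming radius for VBC family growth (default 1).
#' @param umi_dist Hamming radius for UMI deduplication (default 1).
#' @param adaptive_umi_gate UMI count at which the VBC radius is raised by
#'   one (default `Inf`, i.e. off).
#' @return Tibble `vbc`, `umi`, `reads` of collapsed UMI-level entries.
#' @export
collapse_within_cell <- function(cell_records, max_dist = 1L, umi_dist = 1L,
                                 adaptive_umi_gate = Inf) {
  check_cols(cell_records, c("umi", "vbc", "reads"), "cell records")
  per_vbc <- cell_records |>
    dplyr::group_by(.data$vbc, .data$umi) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  vbc_counts <- per_vbc |>
    dplyr::count(.data$vbc, name = "umis")
  if (nrow(vbc_counts) > 1L) {
    dist <- if (max(vbc_counts$umis) >= adaptive_umi_gate) {
      max_dist + 1L
    } else {
      max_dist
    }
    idx <- collapse_index(vbc_counts$vbc, vbc_counts$umis, dist)
    map <- tibble::tibble(
      vbc = vbc_counts$vbc, parent = vbc_counts$vbc[idx]
    )
    per_vbc <- per_vbc |>
      dplyr::left_join(map, by = "vbc") |>
      dplyr::group_by(vbc = .data$parent, .data$umi) |>
      dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  }
  per_vbc |>
    dplyr::group_by(.data$vbc) |>
    dplyr::reframe(dedup_umis(.data$umi, .data$reads, umi_dist)) |>
    dplyr::select("vbc", "umi", "reads")
}

#' Bipartite UMI-sharing collapse of one cell's VBC entries
#'
#' For each VBC pair in a cell, computes the fraction of the less abundant
#' VBC's UMIs that match a UMI of the more abundant VBC within Hamming
#' distance `share_dist`. When the fraction exceeds `share_frac` (strictly),
#' the smaller VBC is absorbed: its UMIs transfer to the parent (then
#' deduplicated) before later comparisons. Parents are processed most
#' abundant first and absorption repeats to a fixed point. Finally any UMI
#' still present under two VBCs is assigned to the VBC where it carries more
#' reads (ties to the more abundant VBC), so no cell-UMI is counted twice.
#'
#' @param cell_records Tibble for one cell: `vbc`, `umi`, `reads` (normally
#'   the output of [collapse_within_cell()]).
#' @param share_dist Hamming radius for UMI matching (default 2).
#' @param share_frac Sharing fraction above which the smaller VBC is
#'   absorbed (default 0.5, strict).
#' @param umi_dist Hamming radius used to deduplicate transferred UMIs.
#' @return Tibble `vbc`, `umi`, `reads`; absorbed VBCs removed.
#' @export
collapse_bipartite <- function(cell_records, share_dist = 2L,
                               share_frac = 0.5, umi_dist = 1L) {
  check_cols(cell_records, c("umi", "vbc", "reads"), "cell records")
  sets <- split(
    cell_records[c("umi", "reads")],
    cell_records$vbc
  )
  repeat {
    if (length(sets) <= 1L) break
    sizes <- vapply(sets, nrow, integer(1))
    ord <- names(sort(sizes, decreasing = TRUE))
    absorbed <- FALSE
    for (parent in ord) {
      if (!parent %in% names(sets)) next
      others <- setdiff(names(sets), parent)
      for (child in others) {
        if (nrow(sets[[child]]) > nrow(sets[[parent]])) next
        child_umis <- sets[[child]]$umi
        parent_umis <- sets[[parent]]$umi
        matched <- vapply(child_umis, function(u) {
          any(hamming_distance(u, parent_umis) <= share_dist)
        }, logical(1))
        if (sum(matched) / length(matched) > share_frac) {
          pooled <- dplyr::bind_rows(sets[[parent]], sets[[child]]) |>
            dplyr::group_by(.data$umi) |>
            dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
          sets[[parent]] <- dedup_umis(pooled$umi, pooled$reads, umi_dist)
          sets[[child]] <- NULL
          absorbed <- TRUE
        }
      }
    }
    if (!absorbed) break
  }
  out <- purrr::imap(sets, function(df, v) {
    tibble::tibble(vbc = v, umi = df$umi, reads = df$reads)
  }) |>
    dplyr::bind_rows()
  if (!nrow(out)) return(out)
  # exact cell-UMI duplicated across VBCs -> keep under one VBC only
  vbc_tot <- out |> dplyr::count(.data$vbc, name = "vbc_umis")
  out |>
    dplyr::left_join(vbc_tot, by = "vbc") |>
    dplyr::group_by(.data$umi) |>
    dplyr::arrange(
      dplyr::desc(.data$reads), dplyr::desc(.data$vbc_umis), .data$vbc
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("vbc", "umi", "reads") |>
    dplyr::arrange(.data$vbc, .data$umi)
}

#' Build the per-cell collapsed VBC table
#'
#' Full per-cell cleaning: apply the pre-collapse UMI inclusion threshold,
#' run the mutational collapse ([collapse_within_cell()]) then the bipartite
#' UMI-sharing collapse ([collapse_bipartite()]) cell by cell, and count the
#' surviving UMIs per (cell, VBC). Network-stage thresholding is applied
#' later by [filter_min_umi()] / [infer_networks()].
#'
#' @param records UMI-level records (`cell_barcode`, `umi`, `vbc`, `reads`).
#' @param chemistry `"v3"` or `"v2"` (sets UMI inclusion thresholds).
#' @param max_dist,umi_dist,share_dist,share_frac,adaptive_umi_gate Collapse
#'   settings, see the per-cell functions.
#' @param config Settings list holding the thresholds.
#' @return A tibble of class `cell_vbc_table` (`cell_barcode`, `vbc`,
#'   `umis`) with a `report` attribute summarising collapse bookkeeping
#'   (entries in/out, removal events per pass), retrievable via
#'   [collapse_report()].
#' @export
collapse_cell_vbcs <- function(records, chemistry = c("v3", "v2"),
                               max_dist = 1L, umi_dist = 1L,
                               share_dist = 2L, share_frac = 0.5,
                               adaptive_umi_gate = Inf,
                               config = default_config()) {
  chemistry <- match.arg(chemistry)
  check_cols(records, c("cell_barcode", "umi", "vbc", "reads"), "records")
  thr <- config$umi_thresholds[[chemistry]]$collapse
  raw <- records |>
    dplyr::group_by(.data$cell_barcode, .data$vbc) |>
    dplyr::summarise(umis = dplyr::n_distinct(.data$umi), .groups = "drop")
  eligible <- raw |> dplyr::filter(.data$umis >= thr)
  kept_records <- records |>
    dplyr::semi_join(eligible, by = c("cell_barcode", "vbc"))
  cells <- split(kept_records, kept_records$cell_barcode)
  n_mut <- 0L
  n_bip <- 0L
  collapsed <- purrr::imap(cells, function(df, cb) {
    a <- collapse_within_cell(df, max_dist, umi_dist, adaptive_umi_gate)
    b <- collapse_bipartite(a, share_dist, share_frac, umi_dist)
    n_mut <<- n_mut + (dplyr::n_distinct(df$vbc) - dplyr::n_distinct(a$vbc))
    n_bip <<- n_bip + (dplyr::n_distinct(a$vbc) - dplyr::n_distinct(b$vbc))
    dplyr::mutate(b, cell_barcode = cb)
  }) |>
    dplyr::bind_rows()
  out <- if (nrow(collapsed)) {
    collapsed |>
      dplyr::count(.data$cell_barcode, .data$vbc, name = "umis") |>
      dplyr::arrange(.data$cell_barcode, .data$vbc)
  } else {
    tibble::tibble(
      cell_barcode = character(), vbc = character(), umis = integer()
    )
  }
  report <- tibble::tibble(
    raw_entries = nrow(raw),
    entries_below_threshold = nrow(raw) - nrow(eligible),
    mutational_collapse_events = n_mut,
    umi_sharing_collapse_events = n_bip,
    final_entries = nrow(out),
    entries_removed_fraction =
      if (nrow(raw)) 1 - nrow(out) / nrow(raw) else 0,
    raw_umis = nrow(dplyr::distinct(records, .data$cell_barcode, .data$vbc,
      .data$umi
    )),
    final_umis = sum(out$umis)
  )
  attr(out, "chemistry") <- chemistry
  attr(out, "report") <- report
  class(out) <- c("cell_vbc_table", class(out))
  out
}

#' Collapse bookkeeping of a cell-VBC table
#'
#' @param table A `cell_vbc_table` from [collapse_cell_vbcs()].
#' @return One-row tibble of collapse statistics (entries and UMIs in/out,
#'   events per pass, fraction of raw entries removed).
#' @export
collapse_report <- function(table) {
  attr(table, "report") %||%
    stop("no collapse report attached", call. = FALSE)
}

#' Classify infected cells by rabies RNA fraction
#'
#' A cell is putatively infected when strictly more than `threshold` of its
#' total UMIs come from rabies genes (default 1%).
#'
#' @param profiles Tibble with `total_umis` and `rabies_umis`.
#' @param threshold Rabies UMI fraction (default 0.01, strict inequality).
#' @return `profiles` with a logical `infected` column added.
#' @export
classify_infected <- function(profiles, threshold = 0.01) {
  check_cols(profiles, c("total_umis", "rabies_umis"), "profiles")
  if (any(profiles$total_umis <= 0)) {
    stop("cells with zero total UMIs cannot be classified", call. = FALSE)
  }
  dplyr::mutate(
    profiles,
    infected = .data$rabies_umis / .data$total_umis > threshold
  )
}

#' Per-cell and per-group multiplicity-of-infection summary
#'
#' Per cell: the number of unique VBCs (the single-cell MOI), total VBC
#' UMIs, and the rabies fraction of the expression profile. Per group
#' (cell type by default): mean and s.e.m. of each, plus the cumulative
#' distribution of unique-VBC counts.
#'
#' @param table A collapsed cell-VBC table (`cell_barcode`, `vbc`, `umis`).
#' @param profiles Tibble with `cell_barcode`, `total_umis`, `rabies_umis`
#'   and the grouping column.
#' @param group Name of the grouping column (default `"coarse_type"`).
#' @return A list of class `moi_summary` with `cells` (per-cell tibble),
#'   `groups` (per-group means and s.e.m.) and `ecdf` (cumulative
#'   distribution of unique VBCs by group). `tidy()` returns the group table.
#' @export
moi_summary <- function(table, profiles, group = "coarse_type") {
  check_cols(table, c("cell_barcode", "vbc", "umis"), "cell-VBC table")
  check_cols(profiles, c("cell_barcode", group), "profiles")
  cells <- table |>
    dplyr::group_by(.data$cell_barcode) |>
    dplyr::summarise(
      unique_vbcs = dplyr::n_distinct(.data$vbc),
      vbc_umis = sum(.data$umis),
      .groups = "drop"
    ) |>
    dplyr::inner_join(profiles, by = "cell_barcode") |>
    dplyr::mutate(
      pct_rabies = if ("rabies_umis" %in% names(profiles)) {
        100 * .data$rabies_umis / .data$total_umis
      } else {
        NA_real_
      }
    )
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  groups <- cells |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_unique_vbcs = mean(.data$unique_vbcs),
      sem_unique_vbcs = sem(.data$unique_vbcs),
      mean_vbc_umis = mean(.data$vbc_umis),
      sem_vbc_umis = sem(.data$vbc_umis),
      mean_pct_rabies = mean(.data$pct_rabies),
      .groups = "drop"
    )
  ecdf_tbl <- cells |>
    dplyr::count(group = .data[[group]], .data$unique_vbcs) |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$unique_vbcs, .by_group = TRUE) |>
    dplyr::mutate(cum_frac = cumsum(.data$n) / sum(.data$n)) |>
    dplyr::ungroup()
  structure(
    list(cells = cells, groups = groups, ecdf = ecdf_tbl),
    class = "moi_summary"
  )
}

#' @export
print.moi_summary <- function(x, ...) {
  cat(sprintf("<moi_summary> %d cells, %d groups\n", nrow(x$cells),
    nrow(x$groups)
  ))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.moi_summary <- function(x, ...) x$groups
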