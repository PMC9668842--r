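# Inference of monosynaptic networks from shared viral barcodes.
#
# A barcode defines a unitary clonal infectivity path (uCIP) only when it is
# rare enough in the infecting library that a single founder infection is the
# credible origin of every cell carrying it. The filter compares each
# candidate barcode's "founder-infection trust" — the number of founder
# infections tolerable before a second occurrence is expected at avoidance
# probability p — with the experiment's estimated founder-infection count,
# obtained by drawing from the library until the observed number of
# recurrent barcodes is matched (a birthday-collision calibration).

#' Founder-infection trust score
#'
#' `fi_trust(f, p) = log10(p) / log10(1 - f)`: the number of founder
#' infections that can occur before a barcode of library frequency `f` is
#' expected to participate in a second founder infection, at avoidance
#' probability `p`. Satisfies `(1 - f)^fi_trust(f, p) = p` exactly.
#'
#' @param f Library frequency (or frequencies), strictly in (0, 1).
#' @param p Avoidance probability, strictly in (0, 1); default 0.9.
#' @return Numeric trust scores.
#' @examples
#' fi_trust(0.5, 0.5) # 1
#' fi_trust(3.5e-6, 0.9) # ~ 30,103
#' @export
fi_trust <- function(f, p = 0.9) {
  if (any(f <= 0 | f >= 1)) stop("`f` must lie strictly in (0, 1)",
    call. = FALSE
  )
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)",
    call. = FALSE
  )
  log10(p) / log10(1 - f)
}

#' Probability of repeated founder infection
#'
#' `1 - (1 - f)^n`: the chance that a barcode of library frequency `f`
#' participates in more than one founder infection when the experiment
#' contains `n` founder infections in total.
#'
#' @param f Library frequency in (0, 1).
#' @param n Number of founder infections.
#' @return Probability (on the 0-1 scale).
#' @export
multi_founder_prob <- function(f, n) {
  stopifnot(all(f > 0 & f < 1), all(n >= 0))
  1 - (1 - f)^n
}

#' Effective library frequency of a VBC set
#'
#' The frequency of a single VBC, or the product of member frequencies for a
#' pair (independent packaging). VBCs absent from the library are presumed
#' rare and assigned the smallest representable frequency, matching a
#' library barcode counted with a single UMI (1 / total UMIs).
#'
#' @param vbcs Character vector of 1 or 2 VBCs, or a list of such vectors.
#' @param library A [vbc_library].
#' @return Numeric frequency (or vector, for a list input).
#' @export
effective_frequency <- function(vbcs, library) {
  if (is.list(vbcs)) {
    return(vapply(vbcs, effective_frequency, numeric(1), library = library))
  }
  stopifnot(length(vbcs) >= 1)
  f_min <- 1 / sum(library$umi_count)
  f <- library$frequency[match(vbcs, library$vbc)]
  f[is.na(f)] <- f_min
  prod(f)
}

#' Estimate an experiment's founder infections by library draws
#'
#' Mimics founder infections by drawing barcodes with replacement from the
#' library's frequencies until the number of unique barcodes drawn matches
#' the number of barcodes observed in two or more cells of the experiment
#' (the spreading founders). The number of draws needed, per replicate, is
#' the founder-count distribution; the median over replicates is the
#' estimate.
#'
#' @param table A cell-VBC table (`cell_barcode`, `vbc`, `umis`), or `NULL`
#'   when `target` is given directly.
#' @param library A [vbc_library].
#' @param replicates Number of draw replicates (default 10).
#' @param seed Optional RNG seed.
#' @param target Override for the number of unique VBCs seen in >= 2 cells.
#' @return An object of class `founder_estimate` with `estimate` (median
#'   draws), `draws` (per-replicate values) and `target`.
#' @export
estimate_founders <- function(table, library, replicates = 10, seed = NULL,
                              target = NULL) {
  if (is.null(target)) {
    check_cols(table, c("cell_barcode", "vbc"), "cell-VBC table")
    target <- table |>
      dplyr::distinct(.data$cell_barcode, .data$vbc) |>
      dplyr::count(.data$vbc) |>
      dplyr::filter(.data$n >= 2) |>
      nrow()
  }
  if (target == 0) {
    return(structure(
      list(estimate = 0, draws = rep(0L, replicates), target = 0L),
      class = "founder_estimate"
    ))
  }
  if (target > nrow(library)) {
    stop(sprintf(
      "target of %d unique VBCs exceeds the library's %d barcodes",
      target, nrow(library)
    ), call. = FALSE)
  }
  n <- nrow(library)
  freq <- library$frequency
  draws <- with_seed_or_not(seed, {
    vapply(seq_len(replicates), function(r) {
      seen <- logical(n)
      uniq <- 0L
      total_draws <- 0L
      chunk <- max(2L * as.integer(target), 100L)
      repeat {
        idx <- sample.int(n, chunk, replace = TRUE, prob = freq)
        first <- !seen[idx] & !duplicated(idx)
        cum_new <- cumsum(first)
        if (uniq + cum_new[chunk] >= target) {
          k <- which(uniq + cum_new >= target)[1]
          total_draws <- total_draws + k
          break
        }
        seen[idx[first]] <- TRUE
        uniq <- uniq + cum_new[chunk]
        total_draws <- total_draws + chunk
      }
      total_draws
    }, integer(1))
  })
  structure(
    list(
      estimate = stats::median(draws), draws = draws,
      target = as.integer(target)
    ),
    class = "founder_estimate"
  )
}

#' @export
print.founder_estimate <- function(x, ...) {
  cat(sprintf(
    "<founder_estimate> %g founder infections (target %d recurrent VBCs; draws %s)\n",
    x$estimate, x$target, paste(x$draws, collapse = ", ")
  ))
  invisible(x)
}

#' Build barcode exclusion lists from no-spread control experiments
#'
#' In a control experiment without viral spread every infected cell is a
#' starter, so a barcode's cell occupancy measures its founder-infection
#' propensity directly. Barcodes (or pairs) that infect more cells than
#' their library abundance predicts are flagged:
#'
#' * felony — absent from the library yet observed in more than
#'   `felony_min_cells` control starters;
#' * misdemeanor — present in the library, but observed in more starters
#'   than its frequency allows (`> 2` cells at frequency below 1e-6, or
#'   `> 8` cells below 10^-5.5);
#' * cross-experiment — absent from the library yet observed in more than
#'   one independent experiment;
#' * concatemer pairs — barcode pairs co-occurring in control starters more
#'   often than independence predicts (Bonferroni-corrected binomial upper
#'   tail on the product of marginal per-cell rates);
#' * library-abundant — barcodes above a configurable frequency quantile of
#'   the library (a coarse pre-filter; the trust filter is the main guard).
#'
#' @param control_table Cell-VBC table from a no-spread control experiment.
#' @param library A [vbc_library].
#' @param experiments Optional list of cell-VBC tables from independent
#'   experiments (for the cross-experiment rule).
#' @param felony_min_cells Occupancy above which a library-absent barcode is
#'   a felony (default 1, i.e. flagged when seen in > 1 cell).
#' @param misdemeanor_rules List of `(max_frequency, min_cells)` rules; a
#'   library-present barcode violating any rule is a misdemeanor.
#' @param concatemer_alpha Familywise level of the pair co-occurrence test.
#' @param abundant_quantile Library frequency quantile above which barcodes
#'   are pre-filtered (default 0.999).
#' @return A list of class `vbc_exclusions` with the five sets.
#' @export
build_exclusions <- function(control_table, library, experiments = list(),
                             felony_min_cells = 1,
                             misdemeanor_rules = list(
                               list(max_frequency = 1e-6, min_cells = 2),
                               list(max_frequency = 10^-5.5, min_cells = 8)
                             ),
                             concatemer_alpha = 0.05,
                             abundant_quantile = 0.999) {
  check_cols(control_table, c("cell_barcode", "vbc"), "control table")
  occ <- control_table |>
    dplyr::distinct(.data$cell_barcode, .data$vbc) |>
    dplyr::count(.data$vbc, name = "n_cells") |>
    dplyr::mutate(
      in_library = .data$vbc %in% library$vbc,
      frequency = library$frequency[match(.data$vbc, library$vbc)]
    )
  felony <- occ |>
    dplyr::filter(!.data$in_library, .data$n_cells > felony_min_cells) |>
    dplyr::pull(.data$vbc)
  viol <- Reduce(`|`, lapply(misdemeanor_rules, function(r) {
    occ$n_cells > r$min_cells &
      !is.na(occ$frequency) & occ$frequency < r$max_frequency
  }))
  misd <- occ$vbc[occ$in_library & viol]
  cross <- character(0)
  if (length(experiments) > 1) {
    seen <- purrr::map(experiments, ~ unique(.x$vbc))
    tab <- table(unlist(purrr::map(seen, unique)))
    cand <- names(tab)[tab > 1]
    cross <- setdiff(cand, library$vbc)
  }
  concat <- concatemer_pairs(control_table, alpha = concatemer_alpha)
  abundant <- character(0)
  if (!is.null(abundant_quantile) && nrow(library)) {
    thr <- stats::quantile(library$frequency, abundant_quantile, names = FALSE)
    abundant <- library$vbc[library$frequency > thr]
  }
  structure(
    list(
      felony = sort(felony), misdemeanor = sort(misd),
      cross_experiment = sort(cross), concatemer_pairs = concat,
      library_abundant = sort(abundant)
    ),
    class = "vbc_exclusions"
  )
}

# Pairs of VBCs co-occurring in control starter cells more often than
# independence of their marginal per-cell rates predicts.
concatemer_pairs <- function(control_table, alpha = 0.05, min_cooc = 2) {
  cells <- control_table |>
    dplyr::distinct(.data$cell_barcode, .data$vbc)
  n_cells <- dplyr::n_distinct(cells$cell_barcode)
  per_cell <- split(cells$vbc, cells$cell_barcode)
  multi <- per_cell[lengths(per_cell) > 1]
  if (!length(multi)) return(tibble::tibble(vbc1 = character(),
    vbc2 = character()
  ))
  pair_rows <- purrr::map(multi, function(v) {
    cb <- utils::combn(sort(v), 2)
    tibble::tibble(vbc1 = cb[1, ], vbc2 = cb[2, ])
  }) |>
    dplyr::bind_rows() |>
    dplyr::count(.data$vbc1, .data$vbc2, name = "cooc") |>
    dplyr::filter(.data$cooc >= min_cooc)
  if (!nrow(pair_rows)) return(tibble::tibble(vbc1 = character(),
    vbc2 = character()
  ))
  marg <- cells |> dplyr::count(.data$vbc, name = "cells")
  pair_rows <- pair_rows |>
    dplyr::mutate(
      p1 = marg$cells[match(.data$vbc1, marg$vbc)] / n_cells,
      p2 = marg$cells[match(.data$vbc2, marg$vbc)] / n_cells,
      p_value = stats::pbinom(.data$cooc - 1, n_cells, .data$p1 * .data$p2,
        lower.tail = FALSE
      )
    )
  n_tests <- nrow(pair_rows)
  pair_rows |>
    dplyr::filter(.data$p_value < alpha / n_tests) |>
    dplyr::select("vbc1", "vbc2")
}

#' @export
print.vbc_exclusions <- function(x, ...) {
  cat(sprintf(
    "<vbc_exclusions> felony %d | misdemeanor %d | cross-experiment %d | concatemer pairs %d | library-abundant %d\n",
    length(x$felony), length(x$misdemeanor), length(x$cross_experiment),
    nrow(x$concatemer_pairs), length(x$library_abundant)
  ))
  invisible(x)
}

#' All single-VBC exclusions
#'
#' @param exclusions A `vbc_exclusions` list.
#' @return Character vector: union of felony, misdemeanor, cross-experiment
#'   and library-abundant barcodes.
#' @export
excluded_vbcs <- function(exclusions) {
  unique(c(
    exclusions$felony, exclusions$misdemeanor,
    exclusions$cross_experiment, exclusions$library_abundant
  ))
}

#' Remove excluded barcodes from a cell-VBC table
#'
#' @param table A cell-VBC table.
#' @param exclusions A `vbc_exclusions` list.
#' @return The filtered table (concatemer pairs are handled as candidate
#'   units inside [infer_networks()], not here).
#' @export
apply_exclusions <- function(table, exclusions) {
  dplyr::filter(table, !.data$vbc %in% excluded_vbcs(exclusions))
}

#' Write / read an exclusion list as JSON
#'
#' @param exclusions A `vbc_exclusions` list.
#' @param path JSON path.
#' @return `write_exclusions()` returns `path` invisibly; `read_exclusions()`
#'   the `vbc_exclusions` object.
#' @export
write_exclusions <- function(exclusions, path) {
  jsonlite::write_json(
    list(
      felony = exclusions$felony,
      misdemeanor = exclusions$misdemeanor,
      cross_experiment = exclusions$cross_experiment,
      concatemer_pairs = as.data.frame(exclusions$concatemer_pairs),
      library_abundant = exclusions$library_abundant
    ),
    path,
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_exclusions
#' @export
read_exclusions <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- x$concatemer_pairs
  if (is.null(pairs) || !length(pairs)) {
    pairs <- tibble::tibble(vbc1 = character(), vbc2 = character())
  } else {
    pairs <- tibble::as_tibble(pairs)
  }
  structure(
    list(
      felony = as.character(x$felony %||% character(0)),
      misdemeanor = as.character(x$misdemeanor %||% character(0)),
      cross_experiment = as.character(x$cross_experiment %||% character(0)),
      concatemer_pairs = pairs,
      library_abundant = as.character(x$library_abundant %||% character(0))
    ),
    class = "vbc_exclusions"
  )
}

# --- network container -----------------------------------------------------

size_category_of <- function(presynaptic_size) {
  cut(presynaptic_size,
    breaks = c(2, 5, 7, Inf), right = FALSE,
    labels = c("small", "medium", "large")
  )
}

recompute_network_sizes <- function(networks) {
  networks$size <- lengths(networks$members)
  has_starter <- !is.na(networks$starter)
  networks$presynaptic_size <- networks$size - as.integer(has_starter)
  networks$size_category <- size_category_of(networks$presynaptic_size)
  networks
}

new_vbc_networks <- function(df, founder_estimate = NA_real_, p = NA_real_) {
  if (!"starter" %in% names(df)) df$starter <- NA_character_
  if (!"ambiguous" %in% names(df)) df$ambiguous <- FALSE
  df <- recompute_network_sizes(tibble::as_tibble(df))
  attr(df, "founder_estimate") <- founder_estimate
  attr(df, "p") <- p
  class(df) <- c("vbc_networks", class(df))
  df
}

#' @export
tidy.vbc_networks <- function(x, ...) {
  x |>
    dplyr::select(
      "network_id", "defining_vbcs", "members", "starter",
      "presynaptic_size", "size_category"
    ) |>
    tidyr::unnest_longer("members", values_to = "cell_barcode") |>
    dplyr::mutate(
      is_starter = !is.na(.data$starter) & .data$cell_barcode == .data$starter
    )
}

#' @export
glance.vbc_networks <- function(x, ...) {
  tibble::tibble(
    n_networks = nrow(x),
    n_cells = length(unique(unlist(x$members))),
    n_with_starter = sum(!is.na(x$starter)),
    n_ambiguous = sum(x$ambiguous),
    mean_size = mean(x$size),
    median_size = stats::median(x$size),
    founder_estimate = attr(x, "founder_estimate"),
    p = attr(x, "p")
  )
}

#' Infer monosynaptic networks from shared barcodes
#'
#' Candidate units are single VBCs observed in two or more cells and
#' unordered VBC pairs co-occurring in two or more cells (concatemer pairs
#' excluded). A unit is retained when its founder-infection trust at the
#' unit's effective library frequency exceeds the experiment's estimated
#' founder-infection count — i.e. when a single founder infection is the
#' credible origin of every carrier. Each retained unit defines a network:
#' the set of cells containing all of its VBCs. Redundant networks are
#' resolved by keeping maximal member sets (a network whose members are a
#' subset of another's is dropped; identical member sets merge, preferring
#' the more specific pair-defined unit). Starters, when supplied, are then
#' attached via [assign_network_starters()].
#'
#' @param table A collapsed cell-VBC table (`cell_barcode`, `vbc`, `umis`).
#' @param library The infecting-library [vbc_library].
#' @param exclusions Optional `vbc_exclusions`; excluded barcodes are
#'   removed and concatemer pairs never form candidate units.
#' @param starters Optional starter barcodes or `starter_call`.
#' @param p Avoidance probability of the trust filter (default 0.9).
#' @param chemistry `"v3"` or `"v2"`; sets the network-stage UMI threshold.
#' @param founder_estimate Optional known founder count; estimated from the
#'   table via [estimate_founders()] when `NULL`.
#' @param replicates,seed Passed to [estimate_founders()].
#' @param apply_umi_filter Apply the network-stage threshold (default TRUE).
#' @param config Settings list holding thresholds.
#' @return A `vbc_networks` tibble: `network_id`, `defining_vbcs` (sorted,
#'   `+`-joined), `n_vbcs`, `members` (list of sorted cell barcodes),
#'   `size`, `starter`, `ambiguous`, `presynaptic_size`, `size_category`,
#'   `trust`, `effective_frequency`; attributes carry the founder estimate
#'   and `p`.
#' @export
infer_networks <- function(table, library, exclusions = NULL, starters = NULL,
                           p = 0.9, chemistry = c("v3", "v2"),
                           founder_estimate = NULL, replicates = 10,
                           seed = NULL, apply_umi_filter = TRUE,
                           config = default_config()) {
  chemistry <- match.arg(chemistry)
  check_cols(table, c("cell_barcode", "vbc", "umis"), "cell-VBC table")
  if (apply_umi_filter) {
    table <- filter_min_umi(table, chemistry, stage = "network",
      config = config
    )
  }
  if (!is.null(exclusions)) table <- apply_exclusions(table, exclusions)
  if (is.null(founder_estimate)) {
    founder_estimate <- estimate_founders(table, library,
      replicates = replicates, seed = seed
    )$estimate
  } else if (inherits(founder_estimate, "founder_estimate")) {
    founder_estimate <- founder_estimate$estimate
  }
  cells <- dplyr::distinct(table, .data$cell_barcode, .data$vbc)
  vbc_cells <- split(cells$cell_barcode, cells$vbc)
  singles <- names(vbc_cells)[lengths(vbc_cells) >= 2]
  per_cell <- split(cells$vbc, cells$cell_barcode)
  multi <- per_cell[lengths(per_cell) > 1]
  pair_tbl <- if (length(multi)) {
    purrr::map(multi, function(v) {
      cb <- utils::combn(sort(v), 2)
      tibble::tibble(vbc1 = cb[1, ], vbc2 = cb[2, ])
    }) |>
      dplyr::bind_rows() |>
      dplyr::count(.data$vbc1, .data$vbc2, name = "cooc") |>
      dplyr::filter(.data$cooc >= 2)
  } else {
    tibble::tibble(vbc1 = character(), vbc2 = character(), cooc = integer())
  }
  if (!is.null(exclusions) && nrow(exclusions$concatemer_pairs)) {
    pair_tbl <- dplyr::anti_join(
      pair_tbl, exclusions$concatemer_pairs,
      by = c("vbc1", "vbc2")
    )
  }
  units <- c(
    purrr::map(singles, identity),
    purrr::map2(pair_tbl$vbc1, pair_tbl$vbc2, c)
  )
  if (!length(units)) {
    return(new_vbc_networks(
      tibble::tibble(
        network_id = character(), defining_vbcs = character(),
        n_vbcs = integer(), members = list(),
        trust = numeric(), effective_frequency = numeric()
      ),
      founder_estimate = founder_estimate, p = p
    ))
  }
  f_eff <- effective_frequency(units, library)
  trust <- fi_trust(f_eff, p)
  keep <- trust > founder_estimate
  units <- units[keep]
  f_eff <- f_eff[keep]
  trust <- trust[keep]
  members <- purrr::map(units, function(u) {
    sort(purrr::reduce(vbc_cells[u], intersect))
  })
  nets <- tibble::tibble(
    defining_vbcs = purrr::map_chr(units, ~ paste(sort(.x), collapse = "+")),
    n_vbcs = lengths(units),
    members = members,
    trust = trust,
    effective_frequency = f_eff,
    msize = lengths(members)
  ) |>
    dplyr::filter(.data$msize >= 2)
  # identical member sets: keep one, preferring the pair-defined unit
  nets <- nets |>
    dplyr::mutate(sig = purrr::map_chr(.data$members, paste, collapse = "|")) |>
    dplyr::arrange(
      .data$sig, dplyr::desc(.data$n_vbcs), .data$defining_vbcs
    ) |>
    dplyr::distinct(.data$sig, .keep_all = TRUE)
  # strict-subset member sets: keep only maximal networks
  nets <- dplyr::arrange(nets, dplyr::desc(.data$msize), .data$defining_vbcs)
  kept <- rep(TRUE, nrow(nets))
  for (i in seq_len(nrow(nets))) {
    if (!kept[i]) next
    mi <- nets$members[[i]]
    for (j in seq_len(i - 1L)) {
      if (kept[j] && all(mi %in% nets$members[[j]])) {
        kept[i] <- FALSE
        break
      }
    }
  }
  nets <- nets[kept, ]
  nets <- nets |>
    dplyr::arrange(dplyr::desc(.data$msize), .data$defining_vbcs) |>
    dplyr::mutate(
      network_id = sprintf("net_%04d", dplyr::row_number())
    ) |>
    dplyr::select(
      "network_id", "defining_vbcs", "n_vbcs", "members", "trust",
      "effective_frequency"
    )
  out <- new_vbc_networks(nets, founder_estimate = founder_estimate, p = p)
  if (!is.null(starters)) out <- assign_network_starters(out, starters)
  out
}
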