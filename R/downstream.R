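# Network-level and expression-level statistics: presynaptic composition
# and size tests, the innate-immune aggregate score, differential expression
# by presynaptic network size with a permutation null, and the pseudotime
# infectivity-correlation screen with matched control gene sets.

# CP100K: counts per 100,000 after removing viral features from the
# normalisation denominator.
host_rows <- function(counts, rabies_prefix = "RV:", raav_prefix = "AAV:") {
  feats <- rownames(counts)
  !startsWith(feats, rabies_prefix) & !startsWith(feats, raav_prefix)
}

cp100k <- function(counts, rabies_prefix = "RV:", raav_prefix = "AAV:") {
  host <- host_rows(counts, rabies_prefix, raav_prefix)
  m <- counts[host, , drop = FALSE]
  totals <- Matrix::colSums(m)
  totals[totals == 0] <- 1
  out <- m %*% Matrix::Diagonal(x = 1e5 / totals)
  dimnames(out) <- dimnames(m)
  out
}

#' Presynaptic composition versus starter type
#'
#' Aggregates presynaptic member cell types over starter-assigned,
#' unambiguous networks and tests whether composition varies with starter
#' cell type (chi-square on the starter-type x presynaptic-type table).
#'
#' @param networks A `vbc_networks` tibble with starters assigned.
#' @param profiles Tibble with `cell_barcode` and the type column.
#' @param type_col Name of the cell-type column (default `"coarse_type"`).
#' @return Object of class `composition_test`: the count table, the
#'   `chisq.test` result and standardised residuals. `tidy()` gives one row
#'   per (starter type, presynaptic type); `glance()` the omnibus test.
#' @export
composition_test <- function(networks, profiles, type_col = "coarse_type") {
  check_cols(profiles, c("cell_barcode", type_col), "profiles")
  types <- stats::setNames(profiles[[type_col]], profiles$cell_barcode)
  nets <- networks |>
    dplyr::filter(!is.na(.data$starter), !.data$ambiguous)
  if (!nrow(nets)) stop("no starter-assigned networks", call. = FALSE)
  rows <- purrr::pmap(
    list(nets$members, nets$starter),
    function(m, s) {
      tibble::tibble(
        starter_type = unname(types[s]),
        presyn_type = unname(types[setdiff(m, s)])
      )
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$starter_type), !is.na(.data$presyn_type))
  tab <- table(rows$starter_type, rows$presyn_type)
  if (!length(tab) || nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need >= 2 starter types and >= 2 presynaptic types", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab))
  structure(
    list(table = tab, test = ht, stdres = ht$stdres,
      n_networks = nrow(nets)
    ),
    class = "composition_test"
  )
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf(
    "<composition_test> X2 = %.3g, df = %d, p = %.3g (%d networks)\n",
    unname(x$test$statistic), unname(x$test$parameter),
    x$test$p.value, x$n_networks
  ))
  invisible(x)
}

#' @export
tidy.composition_test <- function(x, ...) {
  as.data.frame(x$table, stringsAsFactors = FALSE) |>
    stats::setNames(c("starter_type", "presyn_type", "observed")) |>
    tibble::as_tibble() |>
    dplyr::mutate(
      expected = as.vector(x$test$expected),
      std_residual = as.vector(x$stdres)
    )
}

#' @export
glance.composition_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$test$statistic),
    df = unname(x$test$parameter),
    p.value = x$test$p.value,
    n_networks = x$n_networks
  )
}

#' Presynaptic network size versus starter type
#'
#' Kruskal-Wallis omnibus test on presynaptic size distributions across
#' starter types (or subtypes), with pairwise Wilcoxon rank-sum tests.
#'
#' @param networks A `vbc_networks` tibble with starters assigned.
#' @param profiles Tibble mapping `cell_barcode` to the type column.
#' @param type_col Grouping column (default `"coarse_type"`).
#' @return Object of class `network_size_test`; `glance()` gives the
#'   omnibus statistic, `tidy()` the pairwise comparisons.
#' @export
network_size_test <- function(networks, profiles,
                              type_col = "coarse_type") {
  check_cols(profiles, c("cell_barcode", type_col), "profiles")
  types <- stats::setNames(profiles[[type_col]], profiles$cell_barcode)
  df <- networks |>
    dplyr::filter(!is.na(.data$starter), !.data$ambiguous) |>
    dplyr::mutate(group = unname(types[.data$starter])) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::select("network_id", "group", "presynaptic_size")
  sizes <- df |> dplyr::count(.data$group)
  if (nrow(sizes) < 2 || any(sizes$n < 2)) {
    stop("need >= 2 groups with >= 2 networks each", call. = FALSE)
  }
  kw <- stats::kruskal.test(df$presynaptic_size, factor(df$group))
  pairs <- utils::combn(sort(unique(df$group)), 2, simplify = FALSE)
  pw <- purrr::map(pairs, function(pr) {
    a <- df$presynaptic_size[df$group == pr[1]]
    b <- df$presynaptic_size[df$group == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      n1 = length(a), n2 = length(b),
      statistic = unname(wt$statistic), p.value = wt$p.value
    )
  }) |>
    dplyr::bind_rows()
  structure(
    list(omnibus = kw, pairwise = pw, data = df),
    class = "network_size_test"
  )
}

#' @export
print.network_size_test <- function(x, ...) {
  cat(sprintf(
    "<network_size_test> Kruskal-Wallis chi2 = %.3g, p = %.3g; %d pairwise tests\n",
    unname(x$omnibus$statistic), x$omnibus$p.value, nrow(x$pairwise)
  ))
  invisible(x)
}

#' @export
tidy.network_size_test <- function(x, ...) x$pairwise

#' @export
glance.network_size_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$omnibus$statistic),
    df = unname(x$omnibus$parameter),
    p.value = x$omnibus$p.value,
    n_networks = nrow(x$data)
  )
}

#' Aggregate innate-immune expression score
#'
#' Mean CP100K-normalised expression over a curated gene set (viral
#' features excluded from the normalisation denominator). Invariant to
#' uniform scaling of raw counts.
#'
#' @param counts Features x cells sparse count matrix.
#' @param genes Character vector of gene names (any curated set).
#' @param rabies_prefix,raav_prefix Viral feature prefixes.
#' @return Tibble `cell_barcode`, `score`, `n_genes_used`.
#' @export
innate_immune_score <- function(counts, genes, rabies_prefix = "RV:",
                                raav_prefix = "AAV:") {
  present <- intersect(genes, rownames(counts))
  if (!length(present)) {
    stop("none of the gene set is present in the matrix", call. = FALSE)
  }
  norm <- cp100k(counts, rabies_prefix, raav_prefix)
  tibble::tibble(
    cell_barcode = colnames(counts),
    score = as.numeric(
      Matrix::colSums(norm[present, , drop = FALSE]) / length(present)
    ),
    n_genes_used = length(present)
  )
}

#' Two-way ANOVA on a per-cell quantity
#'
#' Convenience wrapper testing a computed per-cell quantity (viral load,
#' immune score, ...) against two crossed factors such as starter type and
#' network size category.
#'
#' @param df Data frame holding the columns.
#' @param response,factor1,factor2 Column names.
#' @return Tidy tibble of the ANOVA table.
#' @export
two_way_anova <- function(df, response, factor1, factor2) {
  check_cols(df, c(response, factor1, factor2), "input")
  fml <- stats::reformulate(
    sprintf("%s * %s", factor1, factor2),
    response = response
  )
  fit <- stats::aov(fml, data = df)
  s <- summary(fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(s)),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    statistic = s$`F value`,
    p.value = s$`Pr(>F)`
  )
}

# One small/large comparison for one subtype: stage-1 aggregated Fisher with
# Bonferroni, stage-2 per-cell Wilcoxon, CP100K log2 fold change.
de_one_comparison <- function(counts, cells_small, cells_large,
                              min_umis = 25, alpha = 0.05,
                              rabies_prefix = "RV:", raav_prefix = "AAV:") {
  host <- host_rows(counts, rabies_prefix, raav_prefix)
  m <- counts[host, , drop = FALSE]
  agg_s <- Matrix::rowSums(m[, cells_small, drop = FALSE])
  agg_l <- Matrix::rowSums(m[, cells_large, drop = FALSE])
  tot_s <- sum(agg_s)
  tot_l <- sum(agg_l)
  tested <- which(agg_s + agg_l >= min_umis)
  if (!length(tested)) {
    return(tibble::tibble(
      gene = character(), agg_small = numeric(), agg_large = numeric(),
      fisher_p = numeric(), fisher_p_adj = numeric(), wilcox_p = numeric(),
      log2fc = numeric(), nominated = logical()
    ))
  }
  fisher_p <- vapply(tested, function(i) {
    stats::fisher.test(matrix(
      c(agg_s[i], tot_s - agg_s[i], agg_l[i], tot_l - agg_l[i]),
      nrow = 2
    ))$p.value
  }, numeric(1))
  p_adj <- pmin(fisher_p * length(tested), 1)
  cand <- which(p_adj < alpha)
  norm <- cp100k(counts, rabies_prefix, raav_prefix)
  wilcox_p <- rep(NA_real_, length(tested))
  if (length(cand)) {
    gene_idx <- tested[cand]
    xs <- as.matrix(norm[gene_idx, cells_small, drop = FALSE])
    xl <- as.matrix(norm[gene_idx, cells_large, drop = FALSE])
    wilcox_p[cand] <- vapply(seq_along(gene_idx), function(k) {
      suppressWarnings(stats::wilcox.test(xs[k, ], xl[k, ]))$p.value
    }, numeric(1))
  }
  cp_s <- agg_s[tested] / tot_s * 1e5
  cp_l <- agg_l[tested] / tot_l * 1e5
  tibble::tibble(
    gene = rownames(m)[tested],
    agg_small = unname(agg_s[tested]),
    agg_large = unname(agg_l[tested]),
    fisher_p = fisher_p,
    fisher_p_adj = p_adj,
    wilcox_p = wilcox_p,
    log2fc = log2((cp_l + 1) / (cp_s + 1)),
    nominated = !is.na(wilcox_p) & wilcox_p < alpha
  )
}

#' Differential expression by presynaptic network size
#'
#' Compares starter-cell RNA profiles between small (2-4 presynaptic cells)
#' and large (7+) network size categories within each cell subtype. Stage 1
#' aggregates UMIs by category and applies Fisher's exact test per gene with
#' at least `min_umis` aggregated UMIs, Bonferroni-corrected within the
#' subtype. Stage 2 requires a per-cell Wilcoxon test on CP100K-normalised
#' expression (rabies UMIs removed before normalisation) at `p < alpha`.
#' Stage 3 repeats the whole procedure for `n_perm` permuted cohorts in
#' which every starter profile is replaced by a random presynaptic profile
#' of the same subtype; genes nominated in two or more permuted replicates
#' of a subtype are flagged as potentially spurious.
#'
#' @param counts Features x cells sparse count matrix (starters and, when
#'   permuting, the presynaptic pool).
#' @param cells Tibble describing the starter cells: `cell_barcode`,
#'   `subtype`, `size_category` (`"small"`/`"medium"`/`"large"`).
#' @param presyn_pool Optional tibble `cell_barcode`, `subtype` of
#'   presynaptic cells available as permutation stand-ins.
#' @param min_umis Aggregated-UMI floor for testing a gene (default 25).
#' @param alpha Significance cutoff for both stages (default 0.05).
#' @param n_perm Number of permuted cohorts (default 100; 0 to skip).
#' @param seed Optional RNG seed for the permutations.
#' @param rabies_prefix,raav_prefix Viral feature prefixes.
#' @return A tibble of class `vbc_de` with one row per (subtype, tested
#'   gene) and columns from the staged tests plus `perm_hits` and `flagged`;
#'   attribute `perm_summary` counts nominations per permuted cohort.
#'   `glance()` compares real and permuted nomination counts.
#' @export
de_by_network_size <- function(counts, cells, presyn_pool = NULL,
                               min_umis = 25, alpha = 0.05, n_perm = 100,
                               seed = NULL, rabies_prefix = "RV:",
                               raav_prefix = "AAV:") {
  check_cols(cells, c("cell_barcode", "subtype", "size_category"), "cells")
  subtypes <- sort(unique(cells$subtype))
  run_subtype <- function(cell_map) {
    purrr::map(subtypes, function(st) {
      sub <- cells[cells$subtype == st, ]
      sm <- cell_map[sub$cell_barcode[sub$size_category == "small"]]
      lg <- cell_map[sub$cell_barcode[sub$size_category == "large"]]
      if (length(sm) < 2 || length(lg) < 2) {
        message(sprintf(
          "skipping subtype '%s': needs >= 2 cells in both small and large",
          st
        ))
        return(NULL)
      }
      de_one_comparison(counts, sm, lg, min_umis, alpha, rabies_prefix,
        raav_prefix
      ) |>
        dplyr::mutate(subtype = st, .before = 1)
    }) |>
      dplyr::bind_rows()
  }
  identity_map <- stats::setNames(cells$cell_barcode, cells$cell_barcode)
  real <- run_subtype(identity_map)
  perm_hits <- tibble::tibble(
    subtype = character(), gene = character(), perm_hits = integer()
  )
  perm_summary <- tibble::tibble(
    perm = integer(), subtype = character(), n_nominated = integer()
  )
  if (n_perm > 0 && !is.null(presyn_pool)) {
    check_cols(presyn_pool, c("cell_barcode", "subtype"), "presyn_pool")
    perm_res <- with_seed_or_not(seed, {
      purrr::map(seq_len(n_perm), function(b) {
        swapped <- vapply(seq_len(nrow(cells)), function(i) {
          pool <- presyn_pool$cell_barcode[
            presyn_pool$subtype == cells$subtype[i]
          ]
          if (!length(pool)) cells$cell_barcode[i] else sample(pool, 1)
        }, character(1))
        run_subtype(stats::setNames(swapped, cells$cell_barcode)) |>
          dplyr::mutate(perm = b)
      })
    }) |>
      dplyr::bind_rows()
    if (nrow(perm_res)) {
      nom <- perm_res |> dplyr::filter(.data$nominated)
      perm_hits <- nom |> dplyr::count(.data$subtype, .data$gene,
        name = "perm_hits"
      )
      perm_summary <- perm_res |>
        dplyr::group_by(.data$perm, .data$subtype) |>
        dplyr::summarise(
          n_nominated = sum(.data$nominated),
          .groups = "drop"
        )
    }
  }
  out <- real |>
    dplyr::left_join(
      perm_hits |> dplyr::rename(ph = "perm_hits"),
      by = c("subtype", "gene")
    ) |>
    dplyr::mutate(
      perm_hits = dplyr::coalesce(.data$ph, 0L),
      flagged = .data$perm_hits >= 2,
      .keep = "unused"
    )
  attr(out, "perm_summary") <- perm_summary
  attr(out, "n_perm") <- n_perm
  class(out) <- c("vbc_de", class(out))
  out
}

#' @export
glance.vbc_de <- function(x, ...) {
  ps <- attr(x, "perm_summary")
  n_perm <- attr(x, "n_perm")
  per_perm <- if (nrow(ps)) {
    ps |>
      dplyr::group_by(.data$perm) |>
      dplyr::summarise(n = sum(.data$n_nominated), .groups = "drop") |>
      dplyr::pull(.data$n)
  } else {
    numeric(0)
  }
  tibble::tibble(
    n_tested = nrow(x),
    n_nominated = sum(x$nominated, na.rm = TRUE),
    n_nominated_unflagged = sum(x$nominated & !x$flagged, na.rm = TRUE),
    n_perm = n_perm,
    perm_mean_nominated = if (length(per_perm)) mean(per_perm) else NA_real_,
    perm_se_nominated = if (length(per_perm) > 1) {
      stats::sd(per_perm) / sqrt(length(per_perm))
    } else {
      NA_real_
    }
  )
}

#' Pseudotime infectivity-correlation screen
#'
#' Orders cells by pseudotime into `n_bins` equal-occupancy bins. Per bin it
#' records the fraction of infected cells and builds a meta-control cell by
#' summing control (uninfected) cell UMIs and normalising to 100,000. Each
#' detected gene is then correlated (Pearson) with the per-bin infected
#' fraction; genes with `r >= r_threshold` are the infectivity-correlated
#' set. Genes with zero variance across bins are excluded (undefined r).
#'
#' @param profiles Tibble with `cell_barcode`, `pseudotime` and logical
#'   `infected` (controls are the uninfected cells).
#' @param counts Features x cells sparse count matrix covering the cells.
#' @param n_bins Number of pseudotime bins (default 10).
#' @param r_threshold Correlation cutoff (default 0.75).
#' @param rabies_prefix,raav_prefix Viral feature prefixes (excluded from
#'   the meta-control).
#' @return Object of class `infectivity_screen`: `genes` (gene, r,
#'   correlated), `bins` (per-bin occupancy and infected fraction) and
#'   `meta` (genes x bins normalised meta-control matrix). `tidy()` gives
#'   the gene table, `glance()` counts.
#' @export
infectivity_correlation <- function(profiles, counts, n_bins = 10,
                                    r_threshold = 0.75,
                                    rabies_prefix = "RV:",
                                    raav_prefix = "AAV:") {
  check_cols(profiles, c("cell_barcode", "pseudotime", "infected"),
    "profiles"
  )
  pf <- profiles |>
    dplyr::filter(!is.na(.data$pseudotime)) |>
    dplyr::mutate(bin = dplyr::ntile(.data$pseudotime, n_bins))
  bins <- pf |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_control = sum(!.data$infected),
      infected_fraction = mean(.data$infected),
      .groups = "drop"
    )
  if (any(bins$n_control == 0)) {
    stop(sprintf(
      "pseudotime bin %d has no control cells; cannot build a meta-control",
      bins$bin[bins$n_control == 0][1]
    ), call. = FALSE)
  }
  host <- host_rows(counts, rabies_prefix, raav_prefix)
  m <- counts[host, , drop = FALSE]
  meta <- vapply(seq_len(n_bins), function(b) {
    cb <- pf$cell_barcode[pf$bin == b & !pf$infected]
    v <- Matrix::rowSums(m[, cb, drop = FALSE])
    v / sum(v) * 1e5
  }, numeric(nrow(m)))
  rownames(meta) <- rownames(m)
  frac <- bins$infected_fraction
  sds <- apply(meta, 1, stats::sd)
  detected <- Matrix::rowSums(meta) > 0
  ok <- detected & sds > 0
  r <- rep(NA_real_, nrow(meta))
  r[ok] <- as.numeric(stats::cor(t(meta[ok, , drop = FALSE]), frac))
  genes <- tibble::tibble(
    gene = rownames(meta),
    r = r,
    detected = detected,
    correlated = !is.na(r) & r >= r_threshold
  ) |>
    dplyr::filter(.data$detected)
  structure(
    list(genes = genes, bins = bins, meta = meta,
      r_threshold = r_threshold
    ),
    class = "infectivity_screen"
  )
}

#' @export
print.infectivity_screen <- function(x, ...) {
  cat(sprintf(
    "<infectivity_screen> %d / %d detected genes correlated (r >= %g) over %d bins\n",
    sum(x$genes$correlated), nrow(x$genes), x$r_threshold, nrow(x$bins)
  ))
  invisible(x)
}

#' @export
tidy.infectivity_screen <- function(x, ...) x$genes

#' @export
glance.infectivity_screen <- function(x, ...) {
  tibble::tibble(
    n_detected = nrow(x$genes),
    n_correlated = sum(x$genes$correlated),
    r_threshold = x$r_threshold,
    n_bins = nrow(x$bins)
  )
}

#' Correlated genes of an infectivity screen
#'
#' @param x An `infectivity_screen`.
#' @return Character vector of correlated gene names.
#' @export
correlated_genes <- function(x) {
  stopifnot(inherits(x, "infectivity_screen"))
  x$genes$gene[x$genes$correlated]
}

#' Control gene sets for enrichment comparisons
#'
#' Builds replicate control gene sets the size of a target set, either
#' expression-matched — per decile of the target genes' expression in a
#' reference profile (e.g. the mature-bin meta-control), an equal number of
#' genes is sampled from that decile of the reference — or at random from
#' all expressed genes. A decile with fewer candidates than needed is
#' sampled with replacement, with a warning.
#'
#' @param reference Named numeric vector: reference expression per gene.
#' @param target_genes Character vector defining the target set.
#' @param mode `"expression_matched"` or `"random"`.
#' @param replicates Number of control sets (default 1000).
#' @param size Genes per set (default `length(target_genes)`).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `set_id`, `gene`.
#' @export
control_gene_sets <- function(reference, target_genes,
                              mode = c("expression_matched", "random"),
                              replicates = 1000, size = NULL, seed = NULL) {
  mode <- match.arg(mode)
  size <- size %||% length(target_genes)
  expressed <- names(reference)[reference > 0]
  if (size == 0) {
    return(tibble::tibble(set_id = integer(), gene = character()))
  }
  with_seed_or_not(seed, {
    if (mode == "random") {
      sets <- purrr::map(seq_len(replicates), function(i) {
        tibble::tibble(set_id = i, gene = sample(expressed, size))
      })
      return(dplyr::bind_rows(sets))
    }
    decile <- stats::setNames(
      dplyr::ntile(rank(reference[expressed], ties.method = "first"), 10),
      expressed
    )
    target_in <- intersect(target_genes, expressed)
    need <- table(factor(decile[target_in], levels = 1:10))
    need <- round(as.numeric(need) / sum(need) * size)
    pools <- split(expressed, decile)
    sets <- purrr::map(seq_len(replicates), function(i) {
      picked <- purrr::map(1:10, function(d) {
        k <- need[d]
        if (k == 0) return(character(0))
        pool <- pools[[as.character(d)]]
        if (length(pool) < k) {
          warning(sprintf(
            "decile %d exhausted (%d candidates for %d); sampling with replacement",
            d, length(pool), k
          ), call. = FALSE)
          sample(pool, k, replace = TRUE)
        } else {
          sample(pool, k)
        }
      })
      tibble::tibble(set_id = i, gene = unlist(picked))
    })
    dplyr::bind_rows(sets)
  })
}
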