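# Library diversity analytics: downsampling, abundance groups, unique-VBC
# draw curves, jackpot filtering and in-silico mixing. These quantify how
# many distinct barcoded genomes a library holds and how likely repeated
# founder infections by the same barcode are at a given infection count.

#' Downsample a library without replacement
#'
#' Draws a multivariate-hypergeometric subsample of `n` UMI counts from the
#' profile, modelling resequencing at lower depth.
#'
#' @param profile A [vbc_library].
#' @param n Number of UMI counts to retain (`n <= total`).
#' @param seed Optional RNG seed.
#' @return A [vbc_library] with total `n` (barcodes drawn to zero dropped).
#' @export
downsample_library <- function(profile, n, seed = NULL) {
  total <- sum(profile$umi_count)
  if (n > total) {
    stop(sprintf("cannot downsample to %d from %d total UMIs", n, total),
      call. = FALSE
    )
  }
  with_seed_or_not(seed, {
    counts <- profile$umi_count
    kept <- integer(length(counts))
    remaining <- total
    left <- n
    for (i in seq_along(counts)) {
      if (left == 0L) break
      ci <- counts[i]
      kept[i] <- stats::rhyper(1, ci, remaining - ci, left)
      left <- left - kept[i]
      remaining <- remaining - ci
    }
    out <- tibble::tibble(vbc = profile$vbc, umi_count = kept) |>
      dplyr::filter(.data$umi_count > 0)
    vbc_library(out, vbc_length = if (nrow(out)) nchar(out$vbc[1]) else 20L)
  })
}

#' Bin library counts by abundance group
#'
#' Abundance group (AG) k holds the UMI counts of all barcodes sampled
#' exactly k times: every count contributed by a barcode counted twice sits
#' in AG 2, and so on.
#'
#' @param profile A [vbc_library].
#' @return A tibble of class `abundance_groups`: `ag`, `n_vbcs`,
#'   `total_counts`, `frac_counts`, `cum_frac` (cumulative fraction of all
#'   counts up to this AG).
#' @export
abundance_groups <- function(profile) {
  out <- as_plain_tibble(profile) |>
    dplyr::count(ag = .data$umi_count, name = "n_vbcs") |>
    dplyr::filter(.data$ag > 0) |>
    dplyr::mutate(
      total_counts = .data$ag * .data$n_vbcs,
      frac_counts = .data$total_counts / sum(.data$total_counts),
      cum_frac = cumsum(.data$frac_counts)
    ) |>
    dplyr::arrange(.data$ag)
  class(out) <- c("abundance_groups", class(out))
  out
}

#' Unique-barcode draw curve
#'
#' Simulates independent draws (with replacement, i.e. founder infections)
#' from the library's barcode frequencies and reports, per draw size, the
#' number of unique barcodes observed and the fraction of draws hitting a
#' barcode seen exactly once. Means are taken over replicates; per-replicate
#' values are retained.
#'
#' @param profile A [vbc_library].
#' @param draw_sizes Integer vector of total draw counts.
#' @param replicates Replicates per draw size (default 10).
#' @param seed Optional RNG seed.
#' @return A tibble of class `diversity_curve` with per-replicate rows
#'   (`draws`, `replicate`, `unique_vbcs`, `frac_unique`); summarise with
#'   [summary.diversity_curve()] or query with [max_draws_at_fraction()].
#' @export
uniqueness_curve <- function(profile, draw_sizes, replicates = 10,
                             seed = NULL) {
  stopifnot(all(draw_sizes >= 1))
  with_seed_or_not(seed, {
    grid <- tidyr::expand_grid(
      draws = as.integer(draw_sizes),
      replicate = seq_len(replicates)
    )
    res <- purrr::pmap(grid, function(draws, replicate) {
      x <- stats::rmultinom(1, draws, profile$frequency)[, 1]
      tibble::tibble(
        unique_vbcs = sum(x > 0),
        frac_unique = sum(x == 1) / draws
      )
    })
    out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
    class(out) <- c("diversity_curve", class(out))
    out
  })
}

#' @export
summary.diversity_curve <- function(object, ...) {
  object |>
    dplyr::group_by(.data$draws) |>
    dplyr::summarise(
      mean_unique = mean(.data$unique_vbcs),
      mean_frac_unique = mean(.data$frac_unique),
      .groups = "drop"
    )
}

#' Largest draw count keeping a given uniqueness fraction
#'
#' @param curve A `diversity_curve` from [uniqueness_curve()].
#' @param fraction Minimum mean fraction of unique draws (default 0.5).
#' @return The largest evaluated draw size whose mean fraction of singleton
#'   draws is at least `fraction` (NA if none qualifies).
#' @export
max_draws_at_fraction <- function(curve, fraction = 0.5) {
  s <- summary(curve)
  ok <- s$draws[s$mean_frac_unique >= fraction]
  if (!length(ok)) NA_integer_ else max(ok)
}

#' Remove the k most abundant barcodes
#'
#' Drops the `k` highest-count barcodes (count ties broken lexicographically)
#' and renormalises frequencies, mirroring removal of "jackpot" barcodes
#' over-amplified during packaging.
#'
#' @param profile A [vbc_library].
#' @param k Number of top barcodes to remove (`k <` library size).
#' @return A [vbc_library] without the top `k` barcodes.
#' @export
filter_top_k <- function(profile, k) {
  if (k >= nrow(profile)) {
    stop("`k` must be smaller than the number of barcodes", call. = FALSE)
  }
  if (k == 0) return(profile)
  keep <- profile |>
    dplyr::arrange(dplyr::desc(.data$umi_count), .data$vbc) |>
    dplyr::slice(-seq_len(k))
  vbc_library(
    keep |> dplyr::select("vbc", "umi_count"),
    vbc_length = nchar(keep$vbc[1])
  )
}

#' Mix libraries in silico
#'
#' Pools independently generated libraries while keeping their barcode
#' spaces distinct: each barcode is namespaced by library index before
#' summing counts, since equivalent libraries carry independent barcode
#' sets and identical sequences across libraries are distinct genomes.
#'
#' @param profiles A list of two or more [vbc_library] objects.
#' @return A tibble of class `vbc_library_mix` with columns `library`,
#'   `vbc`, `umi_count`, `frequency` (frequencies over the pooled total).
#' @export
mix_libraries <- function(profiles) {
  if (length(profiles) < 2) {
    stop("need at least two libraries to mix", call. = FALSE)
  }
  pooled <- purrr::imap(profiles, function(p, i) {
    tibble::tibble(library = i, vbc = p$vbc, umi_count = p$umi_count)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(frequency = .data$umi_count / sum(.data$umi_count)) |>
    dplyr::arrange(.data$library, .data$vbc)
  class(pooled) <- c("vbc_library_mix", class(pooled))
  pooled
}
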