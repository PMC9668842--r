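# The library profile: error-corrected VBC -> UMI count for one viral
# library, with derived frequencies. Stored as a tibble subclass so it
# composes with dplyr verbs; `frequency` is count / total and sums to 1.

#' Build a viral library profile
#'
#' @param counts Data frame with columns `vbc` and `umi_count` (one row per
#'   distinct error-corrected barcode).
#' @param vbc_length Required barcode length (default 20, the standard VBC).
#' @return A tibble of class `vbc_library` with columns `vbc`, `umi_count`,
#'   `frequency`, sorted by barcode.
#' @export
vbc_library <- function(counts, vbc_length = 20L) {
  check_cols(counts, c("vbc", "umi_count"), "library counts")
  seqs <- check_dna(counts$vbc, length = vbc_length, what = "VBC")
  cnt <- counts$umi_count
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("umi_count must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(seqs)) {
    stop(sprintf(
      "duplicate VBC '%s' in library counts", seqs[anyDuplicated(seqs)]
    ), call. = FALSE)
  }
  total <- sum(cnt)
  out <- tibble::tibble(
    vbc = seqs,
    umi_count = as.integer(cnt),
    frequency = if (total > 0) cnt / total else rep(0, length(cnt))
  ) |>
    dplyr::arrange(.data$vbc)
  stopifnot(total == 0 || abs(sum(out$frequency) - 1) < 1e-9)
  class(out) <- c("vbc_library", class(out))
  out
}

#' @export
print.vbc_library <- function(x, ...) {
  cat(sprintf(
    "<vbc_library> %d barcodes, %s UMI counts\n",
    nrow(x), format(sum(x$umi_count), big.mark = ",")
  ))
  NextMethod()
}

#' One-row library summary
#'
#' @param x A [vbc_library] profile.
#' @param ... Unused.
#' @return Tibble with `n_vbcs`, `total_umis`, `mean_umis_per_vbc`,
#'   `max_frequency`.
#' @export
glance.vbc_library <- function(x, ...) {
  tibble::tibble(
    n_vbcs = nrow(x),
    total_umis = sum(x$umi_count),
    mean_umis_per_vbc = sum(x$umi_count) / nrow(x),
    max_frequency = max(x$frequency)
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy
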