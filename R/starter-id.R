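# Transcriptional starter-cell identification.
#
# Starter cells are the postsynaptic cells that received a founder infection:
# they carry Cre-recombined TVA reporter transcripts and high rAAV loads.
# Each cell is tested with two one-sided binomial upper-tail tests against
# experiment-specific background rates — recombined-TVA UMIs out of total
# rAAV UMIs, and rAAV UMIs out of total cell UMIs. Background rates are
# re-estimated on the currently unflagged cells and the flags re-derived,
# iterating to a fixed point (a hard-assignment EM-style update).

#' Call starter cells by dual binomial enrichment
#'
#' @param profiles Tibble with columns `cell_barcode`, `total_umis`,
#'   `raav_umis`, `recombined_tva_umis`.
#' @param alpha Per-family significance level after Bonferroni correction
#'   over the number of cells tested (default 0.01). Both tests must pass.
#' @param max_iter Maximum rate-update iterations (default 20).
#' @param tol Convergence tolerance on the background rates.
#' @return An object of class `starter_call`: `cells` (per-cell p-values and
#'   flags), `rates` (final background rates, add-one smoothed), plus
#'   iteration metadata. `tidy()` returns the per-cell table, `glance()` the
#'   rates and counts.
#' @export
call_starters <- function(profiles, alpha = 0.01, max_iter = 20, tol = 1e-6) {
  check_cols(
    profiles,
    c("cell_barcode", "total_umis", "raav_umis", "recombined_tva_umis"),
    "profiles"
  )
  if (any(profiles$recombined_tva_umis > profiles$raav_umis)) {
    stop("recombined_tva_umis cannot exceed raav_umis", call. = FALSE)
  }
  if (any(profiles$raav_umis > profiles$total_umis)) {
    stop("raav_umis cannot exceed total_umis", call. = FALSE)
  }
  n <- nrow(profiles)
  tva <- profiles$recombined_tva_umis
  raav <- profiles$raav_umis
  total <- profiles$total_umis
  flags <- rep(FALSE, n)
  rates <- c(tva = NA_real_, raav = NA_real_)
  p_tva <- p_raav <- rep(NA_real_, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    bg <- !flags
    new_rates <- c(
      tva = (sum(tva[bg]) + 1) / (sum(raav[bg]) + 2),
      raav = (sum(raav[bg]) + 1) / (sum(total[bg]) + 2)
    )
    p_tva <- stats::pbinom(tva - 1, raav, new_rates["tva"],
      lower.tail = FALSE
    )
    p_raav <- stats::pbinom(raav - 1, total, new_rates["raav"],
      lower.tail = FALSE
    )
    new_flags <- (pmin(p_tva * n, 1) < alpha) & (pmin(p_raav * n, 1) < alpha)
    if (all(new_flags)) {
      stop(
        "every cell was flagged as a starter; the background is degenerate ",
        "- lower `alpha` or check the input profiles",
        call. = FALSE
      )
    }
    done <- identical(new_flags, flags) &&
      all(abs(new_rates - rates) < tol, na.rm = TRUE)
    flags <- new_flags
    rates <- new_rates
    if (done) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      cells = tibble::tibble(
        cell_barcode = profiles$cell_barcode,
        p_tva = p_tva, p_raav = p_raav, starter = flags
      ),
      rates = rates, alpha = alpha, iterations = iter,
      converged = converged, n_cells = n
    ),
    class = "starter_call"
  )
}

#' @export
print.starter_call <- function(x, ...) {
  cat(sprintf(
    "<starter_call> %d / %d cells flagged (alpha = %g, %d iterations%s)\n",
    sum(x$cells$starter), x$n_cells, x$alpha, x$iterations,
    if (x$converged) "" else ", not converged"
  ))
  cat(sprintf(
    "background rates: recombined-TVA|rAAV = %.3g, rAAV|total = %.3g\n",
    x$rates["tva"], x$rates["raav"]
  ))
  invisible(x)
}

#' @export
tidy.starter_call <- function(x, ...) x$cells

#' @export
glance.starter_call <- function(x, ...) {
  tibble::tibble(
    rate_tva = unname(x$rates["tva"]),
    rate_raav = unname(x$rates["raav"]),
    n_cells = x$n_cells,
    n_starters = sum(x$cells$starter),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Starter cell barcodes from a starter call
#'
#' @param x A `starter_call`.
#' @return Character vector of flagged cell barcodes.
#' @export
starter_barcodes <- function(x) {
  stopifnot(inherits(x, "starter_call"))
  x$cells$cell_barcode[x$cells$starter]
}

#' Attach starter cells to networks
#'
#' A network with exactly one flagged member gets that cell as its starter;
#' with none it is starter-orphaned (all members presumed presynaptic); with
#' two or more it is flagged ambiguous and excluded from starter-stratified
#' statistics. Presynaptic size and size category are recomputed.
#'
#' @param networks A `vbc_networks` tibble.
#' @param starters Character vector of starter cell barcodes, or a
#'   `starter_call`.
#' @return The networks tibble with `starter`, `ambiguous`,
#'   `presynaptic_size` and `size_category` updated.
#' @export
assign_network_starters <- function(networks, starters) {
  if (inherits(starters, "starter_call")) starters <- starter_barcodes(starters)
  upd <- purrr::map(networks$members, function(m) {
    hit <- intersect(m, starters)
    list(
      starter = if (length(hit) == 1L) hit else NA_character_,
      ambiguous = length(hit) > 1L
    )
  })
  networks$starter <- purrr::map_chr(upd, "starter")
  networks$ambiguous <- purrr::map_lgl(upd, "ambiguous")
  recompute_network_sizes(networks)
}
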