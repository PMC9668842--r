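# Error correction of viral barcodes (VBCs) and UMIs in sequencing libraries.
#
# Amplification and sequencing substitutions spawn low-abundance "sibling"
# sequences around each true "parent" barcode. Families are reconstructed by
# sweeping barcodes from most to least abundant: each unclaimed barcode seeds
# a family that grows breadth-first through sequences within a small Hamming
# distance of any current member, and the whole family is assigned the
# parent's sequence. UMIs attached to the same parent are then deduplicated
# with the same scheme.

#' Hamming distance between equal-length sequences
#'
#' Counts mismatching positions between pairs of equal-length strings.
#' Vectorised over `a` and `b`; a length-1 argument is recycled.
#'
#' @param a,b Character vectors of sequences. Elements compared pairwise must
#'   have equal length.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_distance("ACGT", "ACGT")
#' hamming_distance("AAAA", c("AAAT", "TTTT"))
#' @export
hamming_distance <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep_len(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep_len(b, length(a))
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length (or length 1)", call. = FALSE)
  }
  if (!length(a)) return(integer(0))
  if (any(nchar(a) != nchar(b))) {
    stop("sequences compared must have equal length", call. = FALSE)
  }
  vapply(
    seq_along(a),
    function(i) sum(utf8ToInt(a[i]) != utf8ToInt(b[i])),
    integer(1)
  )
}

# Candidate pairs at Hamming distance <= max_dist, found by hashing sequences
# with every set of `max_dist` positions masked out. Two sequences that agree
# outside some masked position set differ at <= max_dist positions, so the
# enumeration is exact. Returns a 2 x m integer index matrix.
neighbor_pairs <- function(seqs, max_dist) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), nrow = 2))
  L <- nchar(seqs[1])
  if (max_dist >= L) {
    return(utils::combn(n, 2))
  }
  pos_sets <- utils::combn(L, max_dist, simplify = FALSE)
  chunks <- lapply(pos_sets, function(ps) {
    key <- seqs
    for (p in sort(ps, decreasing = TRUE)) {
      key <- paste0(substr(key, 1, p - 1), substr(key, p + 1, L))
    }
    grp <- split(seq_len(n), key)
    grp <- grp[lengths(grp) > 1L]
    if (!length(grp)) return(NULL)
    do.call(cbind, lapply(grp, utils::combn, m = 2))
  })
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  if (!length(chunks)) return(matrix(integer(0), nrow = 2))
  out <- do.call(cbind, chunks)
  lo <- pmin(out[1, ], out[2, ])
  hi <- pmax(out[1, ], out[2, ])
  keep <- !duplicated(lo * (n + 1) + hi)
  rbind(lo[keep], hi[keep])
}

# Family assignment shared by barcode and UMI collapse. Sequences are swept
# in descending-abundance order (ties broken lexicographically); each
# unclaimed sequence seeds a family grown breadth-first through unclaimed
# neighbors within max_dist. First claim wins. Returns the family-parent
# index for every sequence.
collapse_index <- function(seqs, counts, max_dist = 1L) {
  n <- length(seqs)
  if (!n) return(integer(0))
  if (n == 1L) return(1L)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  pairs <- neighbor_pairs(seqs, max_dist)
  adj <- split(
    c(pairs[2, ], pairs[1, ]),
    factor(c(pairs[1, ], pairs[2, ]), levels = seq_len(n))
  )
  ord <- order(-counts, seqs)
  parent <- integer(n)
  for (i in ord) {
    if (parent[i] != 0L) next
    parent[i] <- i
    frontier <- i
    while (length(frontier)) {
      nb <- unique(unlist(adj[frontier], use.names = FALSE))
      nb <- nb[parent[nb] == 0L]
      parent[nb] <- i
      frontier <- nb
    }
  }
  parent
}

#' Collapse mutational barcode families to their parent sequence
#'
#' Sweeps barcodes from most to least abundant; each unclaimed barcode becomes
#' a family "parent" whose family grows breadth-first through sequences within
#' `max_dist` mismatches of any member, iterating until no new siblings are
#' found. Every family member is assigned the parent's sequence, and family
#' counts are the sum of member counts. Abundance ties are broken
#' lexicographically so the result is run-invariant.
#'
#' @param counts A data frame with one row per distinct barcode.
#' @param seq_col,count_col Names of the sequence and count columns.
#' @param max_dist Maximum Hamming distance joining a sibling to a family.
#' @return A tibble with columns `vbc`, `count`, `parent`, carrying class
#'   `vbc_collapse`. Use [collapsed_counts()] for the per-family totals.
#' @examples
#' x <- tibble::tibble(
#'   vbc = c("AAAA", "AAAT", "AATT", "GGGG"),
#'   count = c(100, 5, 2, 50)
#' )
#' collapsed_counts(collapse_families(x))
#' @export
collapse_families <- function(counts, seq_col = "vbc", count_col = "count",
                              max_dist = 1L) {
  check_cols(counts, c(seq_col, count_col), "counts")
  seqs <- check_dna(counts[[seq_col]], what = "barcode")
  cnt <- counts[[count_col]]
  if (!nrow(counts)) stop("`counts` must be non-empty", call. = FALSE)
  if (anyDuplicated(seqs)) {
    stop("duplicate barcode sequences in `counts`; aggregate first",
      call. = FALSE
    )
  }
  if (any(cnt < 0)) stop("counts must be non-negative", call. = FALSE)
  idx <- collapse_index(seqs, cnt, max_dist)
  out <- tibble::tibble(vbc = seqs, count = cnt, parent = seqs[idx])
  class(out) <- c("vbc_collapse", class(out))
  out
}

#' Per-family totals from a collapse map
#'
#' @param x A `vbc_collapse` tibble from [collapse_families()].
#' @return Tibble with columns `vbc` (the parent sequence), `count` (summed
#'   member counts) and `family_size`, sorted by descending count.
#' @export
collapsed_counts <- function(x) {
  check_cols(x, c("count", "parent"), "collapse map")
  x |>
    dplyr::group_by(vbc = .data$parent) |>
    dplyr::summarise(
      count = sum(.data$count),
      family_size = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$vbc)
}

# Family-parent index for a set of UMIs (internal; also used by the
# within-cell bipartite collapse, which needs the surviving UMI sequences).
umi_family_index <- function(umis, counts = NULL, max_dist = 1L) {
  counts <- counts %||% rep(1, length(umis))
  collapse_index(umis, counts, max_dist)
}

#' Deduplicate UMIs by Hamming-family collapse
#'
#' Counts UMI families among the UMIs attached to one parent barcode, using
#' the same descending-abundance breadth-first scheme as
#' [collapse_families()]. Two UMIs within `max_dist` mismatches are treated as
#' reads of the same molecule.
#'
#' @param umis Character vector of equal-length UMI sequences (one entry per
#'   distinct UMI).
#' @param counts Optional read counts per UMI used for abundance ordering;
#'   defaults to 1 each.
#' @param max_dist Maximum Hamming distance merging two UMIs.
#' @return Integer: the number of UMI families (deduplicated molecule count).
#' @examples
#' collapse_umis(c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), counts = c(10, 1))
#' @export
collapse_umis <- function(umis, counts = NULL, max_dist = 1L) {
  if (!length(umis)) return(0L)
  umis <- check_dna(umis, what = "UMI")
  if (anyDuplicated(umis)) {
    stop("duplicate UMI sequences; aggregate read counts first", call. = FALSE)
  }
  idx <- umi_family_index(umis, counts, max_dist)
  length(unique(idx))
}

#' Count a barcode library from UMI-level sequencing records
#'
#' The library quantification pipeline: sum reads per raw barcode, collapse
#' mutational barcode families ([collapse_families()]), pool each family's
#' UMIs onto the parent, then deduplicate UMIs within `umi_dist` mismatches.
#' The resulting profile counts UMI families per parent barcode.
#'
#' @param records A data frame of UMI records with columns `cell_barcode`
#'   (ignored here; present for format symmetry), `umi`, `vbc`, `reads`, as
#'   returned by [read_umi_records()].
#' @param max_dist Hamming radius for barcode family collapse.
#' @param umi_dist Hamming radius for UMI deduplication.
#' @return A [vbc_library] profile (tibble: `vbc`, `umi_count`, `frequency`).
#' @export
count_library <- function(records, max_dist = 1L, umi_dist = 1L) {
  check_cols(records, c("umi", "vbc", "reads"), "records")
  raw <- records |>
    dplyr::group_by(.data$vbc) |>
    dplyr::summarise(count = sum(.data$reads), .groups = "drop")
  fam <- collapse_families(raw, max_dist = max_dist)
  joined <- records |>
    dplyr::left_join(
      tibble::tibble(vbc = fam$vbc, parent = fam$parent),
      by = "vbc"
    ) |>
    dplyr::group_by(.data$parent, .data$umi) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop_last")
  counted <- joined |>
    dplyr::summarise(
      umi_count = collapse_umis(.data$umi, .data$reads, max_dist = umi_dist),
      .groups = "drop"
    ) |>
    dplyr::rename(vbc = "parent")
  vbc_library(counted, vbc_length = nchar(counted$vbc[1]))
}
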