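# Shared fixtures and independent oracles.

random_barcodes <- function(n, L = 20) {
  out <- unique(replicate(
    n, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  ))
  while (length(out) < n) {
    out <- unique(c(out, paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE),
      collapse = ""
    )))
  }
  out
}

# Independent brute-force family collapse: build the full pairwise distance
# matrix and grow components greedily in descending-abundance order.
brute_force_collapse <- function(seqs, counts, max_dist = 1) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(chars[[i]] != chars[[j]])
    }
  }
  ord <- order(-counts, seqs)
  parent <- rep(NA_integer_, n)
  for (i in ord) {
    if (!is.na(parent[i])) next
    fam <- i
    repeat {
      grow <- which(
        is.na(parent) &
          apply(d[, c(fam), drop = FALSE] <= max_dist, 1, any)
      )
      grow <- setdiff(grow, fam)
      parent[c(fam, grow)] <- i
      if (!length(grow)) break
      fam <- c(fam, grow)
    }
  }
  tibble::tibble(vbc = seqs, count = counts, parent = seqs[parent])
}

# All unordered cell pairs co-assigned by some grouping (a list of cell
# character vectors). Returns a character vector of "a|b" keys, a < b.
coassigned_pairs <- function(groups) {
  out <- lapply(groups, function(m) {
    m <- sort(unique(m))
    if (length(m) < 2) return(character(0))
    cb <- utils::combn(m, 2)
    paste(cb[1, ], cb[2, ], sep = "|")
  })
  unique(unlist(out))
}

# A tiny deterministic library profile for reuse in tests.
toy_library <- function(n = 50, counts = NULL, seed = 99) {
  withr::with_seed(seed, {
    vbcs <- random_barcodes(n)
    counts <- counts %||% (stats::rpois(n, 5) + 1)
    vbc_library(tibble::tibble(vbc = vbcs, umi_count = counts))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
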