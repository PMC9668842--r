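# Readers and writers for every table the pipeline touches. All tables are
# TSV with a header; the digital gene expression (DGE) matrix is 1-based
# Matrix Market coordinate format with feature/barcode sidecar files.
# Writers emit content-sorted rows so files are byte-stable across runs.

#' Read a library barcode count table
#'
#' Expects a TSV with header columns `vbc` and `umi_count`. Sequences are
#' uppercased; non-ACGT characters, non-integer counts and duplicate barcodes
#' are errors that name the offending row.
#'
#' @param path Path to the TSV file.
#' @param vbc_length Required barcode length (default 20).
#' @return A [vbc_library] profile.
#' @export
read_library_counts <- function(path, vbc_length = 20L) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      vbc = readr::col_character(),
      umi_count = readr::col_double()
    )
  )
  check_cols(df, c("vbc", "umi_count"), basename(path))
  df$vbc <- toupper(df$vbc)
  bad <- which(grepl("[^ACGT]", df$vbc) | nchar(df$vbc) != vbc_length)
  if (length(bad)) {
    stop(sprintf(
      "%s row %d: malformed VBC '%s'", basename(path), bad[1], df$vbc[bad[1]]
    ), call. = FALSE)
  }
  bad <- which(is.na(df$umi_count) | df$umi_count < 0 |
    df$umi_count != round(df$umi_count))
  if (length(bad)) {
    stop(sprintf(
      "%s row %d: umi_count is not a non-negative integer", basename(path),
      bad[1]
    ), call. = FALSE)
  }
  dup <- which(duplicated(df$vbc))
  if (length(dup)) {
    stop(sprintf(
      "%s row %d: duplicate VBC '%s'", basename(path), dup[1], df$vbc[dup[1]]
    ), call. = FALSE)
  }
  vbc_library(df, vbc_length = vbc_length)
}

#' Write a library profile
#'
#' @param profile A [vbc_library].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_counts <- function(profile, path) {
  profile |>
    dplyr::arrange(.data$vbc) |>
    dplyr::select("vbc", "umi_count") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read UMI-level barcode records
#'
#' One row per (cell barcode, UMI, VBC) observation with a read count, the
#' pre-collapse substrate for both library counting and per-cell cleaning.
#'
#' @param path TSV with header columns `cell_barcode`, `umi`, `vbc`, `reads`.
#' @param vbc_length Required VBC length (default 20).
#' @return Tibble of validated records.
#' @export
read_umi_records <- function(path, vbc_length = 20L) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      cell_barcode = readr::col_character(),
      umi = readr::col_character(),
      vbc = readr::col_character(),
      reads = readr::col_double()
    )
  )
  check_cols(df, c("cell_barcode", "umi", "vbc", "reads"), basename(path))
  df$vbc <- toupper(df$vbc)
  df$umi <- toupper(df$umi)
  bad <- which(grepl("[^ACGT]", df$vbc) | nchar(df$vbc) != vbc_length)
  if (length(bad)) {
    stop(sprintf(
      "%s row %d: malformed VBC '%s'", basename(path), bad[1], df$vbc[bad[1]]
    ), call. = FALSE)
  }
  bad <- which(grepl("[^ACGT]", df$umi))
  if (length(bad)) {
    stop(sprintf(
      "%s row %d: malformed UMI '%s'", basename(path), bad[1], df$umi[bad[1]]
    ), call. = FALSE)
  }
  bad <- which(is.na(df$reads) | df$reads < 1 | df$reads != round(df$reads))
  if (length(bad)) {
    stop(sprintf(
      "%s row %d: reads must be a positive integer", basename(path), bad[1]
    ), call. = FALSE)
  }
  df$reads <- as.integer(df$reads)
  tibble::as_tibble(df)
}

#' Write UMI-level barcode records
#'
#' @param records Tibble with columns `cell_barcode`, `umi`, `vbc`, `reads`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_umi_records <- function(records, path) {
  check_cols(records, c("cell_barcode", "umi", "vbc", "reads"), "records")
  records |>
    dplyr::arrange(.data$cell_barcode, .data$vbc, .data$umi) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read a sparse digital gene expression matrix
#'
#' Reads a Matrix Market triplet matrix (features x cells) with one-column
#' sidecar files naming features and cell barcodes, and derives per-cell
#' summaries. Viral features are recognised by configurable name prefixes:
#' rabies genes by `rabies_prefix`, rAAV transgene features by `raav_prefix`,
#' with the Cre-recombined TVA reporter identified by `recombined_feature`.
#'
#' @param matrix_path Path to the `.mtx` coordinate file.
#' @param features_path,barcodes_path One-name-per-line sidecars.
#' @param rabies_prefix,raav_prefix Feature-name prefixes tagging viral
#'   features (defaults `"RV:"` and `"AAV:"`).
#' @param recombined_feature Feature name holding recombined TVA UMIs.
#' @return A list of class `dge` with elements `counts` (dgCMatrix, features
#'   in rows), `features`, `barcodes`, and `profiles` — a tibble of per-cell
#'   totals (`total_umis`, `rabies_umis`, `raav_umis`, `recombined_tva_umis`).
#' @export
read_dge <- function(matrix_path, features_path, barcodes_path,
                     rabies_prefix = "RV:", raav_prefix = "AAV:",
                     recombined_feature = "AAV:TVA-mCherry-rec") {
  m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
  features <- readr::read_tsv(
    features_path,
    col_names = "feature", col_types = readr::cols("c")
  )$feature
  barcodes <- readr::read_tsv(
    barcodes_path,
    col_names = "cell_barcode", col_types = readr::cols("c")
  )$cell_barcode
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "DGE dimension mismatch: matrix is %d x %d but sidecars name %d features and %d barcodes",
      nrow(m), ncol(m), length(features), length(barcodes)
    ), call. = FALSE)
  }
  rownames(m) <- features
  colnames(m) <- barcodes
  structure(
    list(
      counts = m, features = features, barcodes = barcodes,
      rabies_prefix = rabies_prefix, raav_prefix = raav_prefix,
      recombined_feature = recombined_feature,
      profiles = cell_profiles_from_counts(
        m, rabies_prefix, raav_prefix, recombined_feature
      )
    ),
    class = "dge"
  )
}

# Per-cell summaries from a features-x-cells count matrix.
cell_profiles_from_counts <- function(m, rabies_prefix = "RV:",
                                      raav_prefix = "AAV:",
                                      recombined_feature = "AAV:TVA-mCherry-rec") {
  feats <- rownames(m)
  rv <- startsWith(feats, rabies_prefix)
  aav <- startsWith(feats, raav_prefix)
  rec <- feats == recombined_feature
  tibble::tibble(
    cell_barcode = colnames(m) %||% character(0),
    total_umis = as.integer(Matrix::colSums(m)),
    rabies_umis = as.integer(Matrix::colSums(m[rv, , drop = FALSE])),
    raav_umis = as.integer(Matrix::colSums(m[aav, , drop = FALSE])),
    recombined_tva_umis = as.integer(Matrix::colSums(m[rec, , drop = FALSE]))
  )
}

#' @export
print.dge <- function(x, ...) {
  cat(sprintf(
    "<dge> %d features x %d cells, %s UMIs\n",
    nrow(x$counts), ncol(x$counts),
    format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' Per-cell profiles of a DGE
#'
#' @param x A `dge` object from [read_dge()].
#' @return The per-cell summary tibble.
#' @export
cell_profiles <- function(x) {
  stopifnot(inherits(x, "dge"))
  x$profiles
}

#' Write a DGE matrix with sidecar files
#'
#' @param counts A features x cells sparse matrix with dimnames.
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_dge <- function(counts, matrix_path, features_path, barcodes_path) {
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), matrix_path)
  readr::write_tsv(
    tibble::tibble(x = rownames(counts)), features_path,
    col_names = FALSE
  )
  readr::write_tsv(
    tibble::tibble(x = colnames(counts)), barcodes_path,
    col_names = FALSE
  )
  invisible(matrix_path)
}

#' Read cell annotations
#'
#' @param path TSV with columns `cell_barcode`, `coarse_type`,
#'   `granular_type` and optionally `pseudotime`.
#' @return Tibble of annotations.
#' @export
read_cell_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  check_cols(df, c("cell_barcode", "coarse_type", "granular_type"),
    basename(path)
  )
  if ("pseudotime" %in% names(df)) {
    df$pseudotime <- as.numeric(df$pseudotime)
  }
  tibble::as_tibble(df)
}

#' Write cell annotations
#'
#' @param annotations Tibble with at least `cell_barcode`, `coarse_type`,
#'   `granular_type`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_annotations <- function(annotations, path) {
  check_cols(
    annotations, c("cell_barcode", "coarse_type", "granular_type"),
    "annotations"
  )
  annotations |>
    dplyr::arrange(.data$cell_barcode) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Write inferred networks
#'
#' Emits one row per (network, member cell). Defining VBCs are joined with
#' `+` in lexicographic order and rows are sorted by (defining VBCs, member),
#' so output is byte-stable across runs.
#'
#' @param networks A `vbc_networks` tibble from [infer_networks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_networks <- function(networks, path) {
  check_cols(networks, c("network_id", "defining_vbcs", "members"), "networks")
  rows <- networks |>
    dplyr::select("network_id", "defining_vbcs", "members", "starter") |>
    tidyr::unnest_longer("members", values_to = "cell_barcode") |>
    dplyr::mutate(
      is_starter = !is.na(.data$starter) & .data$cell_barcode == .data$starter
    ) |>
    dplyr::select("network_id", "defining_vbcs", "cell_barcode", "is_starter") |>
    dplyr::arrange(.data$defining_vbcs, .data$cell_barcode)
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read networks written by [write_networks()]
#'
#' @param path Path to the networks TSV.
#' @return A `vbc_networks` tibble (size categories recomputed).
#' @export
read_networks <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      network_id = "c", defining_vbcs = "c", cell_barcode = "c",
      is_starter = "l"
    )
  )
  if (!nrow(df)) {
    return(new_vbc_networks(tibble::tibble(
      network_id = character(), defining_vbcs = character(),
      members = list(), starter = character()
    )))
  }
  nets <- df |>
    dplyr::group_by(.data$network_id, .data$defining_vbcs) |>
    dplyr::summarise(
      members = list(sort(.data$cell_barcode)),
      starter = if (any(.data$is_starter)) {
        .data$cell_barcode[.data$is_starter][1]
      } else {
        NA_character_
      },
      .groups = "drop"
    )
  new_vbc_networks(nets)
}

#' Default pipeline configuration
#'
#' All named thresholds of the pipeline in one list: collapse radii, UMI
#' inclusion thresholds per chemistry and stage, the infected-cell rabies
#' fraction, starter-test alpha, the avoidance probability used by the
#' founder-trust filter, founder-estimation replicates, and the exclusion
#' rule constants.
#'
#' @return A nested list of settings.
#' @export
default_config <- function() {
  list(
    collapse = list(max_dist = 1, umi_dist = 1),
    umi_thresholds = list(
      v2 = list(collapse = 3, network = 3),
      v3 = list(collapse = 5, network = 7)
    ),
    bipartite = list(share_dist = 2, share_frac = 0.5),
    infected_fraction = 0.01,
    starter = list(alpha = 0.01, max_iter = 20, tol = 1e-6),
    inference = list(p = 0.9, founder_replicates = 10),
    exclusions = list(
      felony_min_cells = 1, misdemeanor_rules = list(
        list(max_frequency = 1e-6, min_cells = 2),
        list(max_frequency = 10^-5.5, min_cells = 8)
      ),
      cross_experiment_min = 1, concatemer_alpha = 0.05,
      abundant_quantile = 0.999
    ),
    de = list(min_umis = 25, alpha = 0.05, n_perm = 100),
    infectivity = list(n_bins = 10, r_threshold = 0.75)
  )
}

#' Read / write a pipeline configuration
#'
#' @param path JSON file path.
#' @return `read_config()` returns the settings list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @rdname read_config
#' @param config A settings list such as [default_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
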