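# Peptide-observation filtering, replicate merging, and per-cell
# proteoform / protein-group inference.

#' Read a peptide observation table
#'
#' TSV columns: `peptide`, `mods` (`;`-joined modification names, may be
#' empty), `cell`, `replicate`, `q_value`.
#'
#' @param path TSV path.
#' @return Observation tibble.
#' @export
read_observations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                  col_types = readr::cols(mods = readr::col_character(),
                                          .default = readr::col_guess())) |>
    dplyr::mutate(mods = dplyr::coalesce(.data$mods, ""))
}

#' Filter peptide observations
#'
#' Retains observations with `q_value <= max_q` and peptide length within
#' bounds. When an index is supplied, peptides mapping only to contaminant
#' entries are flagged and excluded from inference.
#'
#' @param obs Observation tibble.
#' @param max_q q-value cut-off (default 0.01, i.e. FDR < 1 percent).
#' @param min_len,max_len Peptide length bounds (defaults 9 and 25).
#' @param index Optional `peptide_index` for contaminant flagging.
#' @return Filtered observation tibble; the number of contaminant-only
#'   observations removed is stored in the `n_contaminant` attribute.
#' @export
filter_observations <- function(obs, max_q = 0.01, min_len = 9, max_len = 25,
                                index = NULL) {
  out <- obs |>
    dplyr::filter(.data$q_value <= max_q,
                  nchar(.data$peptide) >= min_len,
                  nchar(.data$peptide) <= max_len)
  n_cont <- 0L
  if (!is.null(index) && nrow(out) > 0) {
    keys <- il_key(out$peptide)
    cont <- index$contaminant_only[match(keys, index$il_key)]
    cont[is.na(cont)] <- FALSE
    n_cont <- sum(cont)
    out <- out[!cont, ]
  }
  attr(out, "n_contaminant") <- n_cont
  out
}

#' Merge technical replicates
#'
#' Takes the union of distinct peptides (by I/L key) per gel cell across
#' replicates and reports the replicate overlap. The overlap statistic is the
#' Jaccard index `|intersection| / |union|` by default; `"min"` selects
#' `|intersection| / min(|A|, |B|)` instead (the definition is not universal,
#' so both are available).
#'
#' @param obs Filtered observation tibble with a `replicate` column.
#' @param method `"jaccard"` or `"min"`.
#' @return List with `observations` (replicate-merged tibble), `overlap`
#'   (per-cell tibble: `cell`, `n_rep1`, `n_rep2`, `overlap`), and
#'   `overall_overlap` across all (cell, peptide) pairs.
#' @export
merge_replicates <- function(obs, method = c("jaccard", "min")) {
  method <- match.arg(method)
  obs <- dplyr::mutate(obs, il_key = il_key(.data$peptide))
  reps <- sort(unique(obs$replicate))
  stat <- function(a, b) {
    i <- length(intersect(a, b)); u <- length(union(a, b))
    denom <- if (method == "jaccard") u else min(length(a), length(b))
    if (denom == 0) NA_real_ else i / denom
  }
  per_cell <- obs |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      n_rep1 = dplyr::n_distinct(.data$il_key[.data$replicate == reps[1]]),
      n_rep2 = if (length(reps) > 1) dplyr::n_distinct(.data$il_key[.data$replicate == reps[2]]) else 0L,
      overlap = if (length(reps) > 1) {
        stat(unique(.data$il_key[.data$replicate == reps[1]]),
             unique(.data$il_key[.data$replicate == reps[2]]))
      } else NA_real_,
      .groups = "drop"
    )
  overall <- if (length(reps) > 1) {
    a <- unique(paste(obs$cell, obs$il_key)[obs$replicate == reps[1]])
    b <- unique(paste(obs$cell, obs$il_key)[obs$replicate == reps[2]])
    stat(a, b)
  } else NA_real_

  merged <- obs |>
    dplyr::group_by(.data$cell, .data$il_key) |>
    dplyr::summarise(
      peptide = .data$peptide[1],
      mods = paste(unique(unlist(strsplit(.data$mods[.data$mods != ""], ";"))), collapse = ";"),
      q_value = min(.data$q_value),
      n_replicates = dplyr::n_distinct(.data$replicate),
      .groups = "drop"
    )
  list(observations = merged, overlap = per_cell, overall_overlap = overall)
}

#' Infer proteoforms and protein groups for one gel cell
#'
#' A proteoform is identified when at least one of its peptides is proteotypic
#' and at least two distinct peptides map to it (the singleton rule: one
#' unique plus one or more shared peptides suffices). Evidence that does not
#' identify a proteoform is aggregated into protein groups: connected
#' components of the proteoform-peptide bipartite graph after removing
#' peptides that map only to identified proteoforms. A group is `single_gene`
#' when all member proteoforms share one gene, else `multi_gene`. Proteoforms
#' supported only by shared peptides are never promoted to identifications.
#'
#' @param obs Replicate-merged observations for one cell (must have `il_key`).
#' @param index A `peptide_index`.
#' @return A `cell_inference` list: `cell`, `proteoforms` tibble, `groups`
#'   tibble, `n_peptides`, `n_unmatched`.
#' @export
infer_cell <- function(obs, index) {
  cell <- if (nrow(obs) > 0) obs$cell[1] else NA_character_
  if (!"il_key" %in% names(obs)) obs <- dplyr::mutate(obs, il_key = il_key(.data$peptide))
  keys <- unique(obs$il_key)
  hit <- match(keys, index$il_key)
  unmatched <- sum(is.na(hit))
  keys <- keys[!is.na(hit)]; hit <- hit[!is.na(hit)]

  if (length(keys) == 0) {
    return(structure(list(cell = cell, proteoforms = empty_proteoforms(),
                          groups = empty_groups(), n_peptides = 0L,
                          n_unmatched = unmatched), class = "cell_inference"))
  }

  map_tbl <- tibble(il_key = keys,
                    parents = index$parents[hit],
                    proteotypic = index$proteotypic[hit]) |>
    tidyr::unnest_longer(col = "parents", values_to = "proteoform_id") |>
    dplyr::arrange(.data$proteoform_id, .data$il_key)

  per_pf <- map_tbl |>
    dplyr::group_by(.data$proteoform_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$il_key),
      n_proteotypic = dplyr::n_distinct(.data$il_key[.data$proteotypic]),
      peptides = list(sort(unique(.data$il_key))),
      .groups = "drop"
    ) |>
    dplyr::mutate(identified = .data$n_peptides >= 2 & .data$n_proteotypic >= 1)

  identified <- per_pf[per_pf$identified, ]

  # Peptides explained exclusively by identified proteoforms drop out;
  # the remainder groups the unidentified proteoforms.
  key_parents <- split(map_tbl$proteoform_id, map_tbl$il_key)
  leftover_keys <- names(key_parents)[!purrr::map_lgl(key_parents, function(p) {
    all(p %in% identified$proteoform_id)
  })]
  rest <- map_tbl[map_tbl$il_key %in% leftover_keys &
                    !map_tbl$proteoform_id %in% identified$proteoform_id, ]

  groups <- empty_groups()
  if (nrow(rest) > 0) {
    g <- igraph::graph_from_data_frame(
      rest[, c("proteoform_id", "il_key")], directed = FALSE
    )
    comp <- igraph::components(g)
    membership <- comp$membership
    pf_nodes <- names(membership)[names(membership) %in% rest$proteoform_id]
    groups <- tibble(proteoform_id = pf_nodes,
                     comp = membership[pf_nodes]) |>
      dplyr::group_by(.data$comp) |>
      dplyr::summarise(
        members = list(sort(unique(.data$proteoform_id))), .groups = "drop"
      ) |>
      dplyr::mutate(
        peptides = purrr::map(.data$members, function(m) {
          sort(unique(rest$il_key[rest$proteoform_id %in% m]))
        }),
        genes = purrr::map(.data$members, function(m) {
          sort(unique(gene_of(m, index)))
        }),
        type = purrr::map_chr(.data$genes, function(g) {
          if (length(g) <= 1) "single_gene" else "multi_gene"
        }),
        group_id = purrr::map_chr(.data$members, function(m) {
          paste0("grp:", substr(rlang::hash(paste(m, collapse = "|")), 1, 8))
        })
      ) |>
      dplyr::select("group_id", "type", "members", "genes", "peptides") |>
      dplyr::arrange(purrr::map_chr(.data$members, 1))
  }

  structure(list(cell = cell, proteoforms = identified[, c(
    "proteoform_id", "n_peptides", "n_proteotypic", "peptides"
  )], groups = groups, n_peptides = length(keys), n_unmatched = unmatched),
  class = "cell_inference")
}

empty_proteoforms <- function() {
  tibble(proteoform_id = character(), n_peptides = integer(),
         n_proteotypic = integer(), peptides = list())
}
empty_groups <- function() {
  tibble(group_id = character(), type = character(), members = list(),
         genes = list(), peptides = list())
}

# Gene of each proteoform id. Library ids follow the gene|backbone|events
# convention; contaminants carry the reserved CONT_ prefix.
gene_of <- function(proteoform_ids, index = NULL) {
  vapply(proteoform_ids, function(id) {
    if (startsWith(id, "CONT_")) "contaminant" else strsplit(id, "|", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Infer proteoforms and groups across all gel cells
#'
#' Filters (optionally), merges replicates, and runs [infer_cell()] per cell.
#' The result is deterministic and independent of observation order.
#'
#' @param obs Observation tibble (all cells, both replicates).
#' @param index A `peptide_index`.
#' @param max_q,min_len,max_len Passed to [filter_observations()].
#' @param overlap_method Passed to [merge_replicates()].
#' @return A `proteoform_inference` object: per-cell results plus combined
#'   `proteoforms` and `groups` tibbles with a `cell` column, the replicate
#'   `overlap` table, and `peptide_counts` per cell.
#' @export
infer_experiment <- function(obs, index, max_q = 0.01, min_len = 9,
                             max_len = 25, overlap_method = "jaccard") {
  filtered <- filter_observations(obs, max_q, min_len, max_len, index)
  merged <- merge_replicates(filtered, overlap_method)
  m <- merged$observations
  cells <- sort(unique(m$cell))
  per_cell <- purrr::map(cells, function(cl) infer_cell(m[m$cell == cl, ], index))
  names(per_cell) <- cells

  proteoforms <- purrr::map_dfr(per_cell, function(r) {
    if (nrow(r$proteoforms) == 0) return(NULL)
    dplyr::mutate(r$proteoforms, cell = r$cell)
  })
  if (nrow(proteoforms) == 0) {
    proteoforms <- dplyr::mutate(empty_proteoforms(), cell = character())
  }
  groups <- purrr::map_dfr(per_cell, function(r) {
    if (nrow(r$groups) == 0) return(NULL)
    dplyr::mutate(r$groups, cell = r$cell)
  })
  if (nrow(groups) == 0) {
    groups <- dplyr::mutate(empty_groups(), cell = character())
  }
  structure(list(
    cells = per_cell,
    proteoforms = proteoforms,
    groups = groups,
    observations = m,
    overlap = merged$overlap,
    overall_overlap = merged$overall_overlap,
    n_unmatched = sum(purrr::map_int(per_cell, "n_unmatched"))
  ), class = "proteoform_inference")
}

#' @export
print.proteoform_inference <- function(x, ...) {
  cat("proteoform inference across", length(x$cells), "gel cells\n")
  cat("  identified proteoform calls:", nrow(x$proteoforms),
      " (", dplyr::n_distinct(x$proteoforms$proteoform_id), "distinct )\n")
  cat("  protein groups:", nrow(x$groups), "\n")
  cat("  replicate overlap (pooled):", round(x$overall_overlap, 3), "\n")
  invisible(x)
}

#' Tidy an inference result
#'
#' @param x A `proteoform_inference`.
#' @param ... Unused.
#' @return Tibble of per-cell proteoform identifications.
#' @export
tidy.proteoform_inference <- function(x, ...) {
  if (nrow(x$proteoforms) == 0) return(x$proteoforms)
  dplyr::select(x$proteoforms, "cell", "proteoform_id", "n_peptides", "n_proteotypic")
}

#' One-row summary of an inference result
#'
#' @param x A `proteoform_inference`.
#' @param ... Unused.
#' @return One-row tibble of totals.
#' @export
glance.proteoform_inference <- function(x, ...) {
  tibble(
    n_cells = length(x$cells),
    n_proteoform_calls = nrow(x$proteoforms),
    n_distinct_proteoforms = dplyr::n_distinct(x$proteoforms$proteoform_id),
    n_groups = nrow(x$groups),
    n_single_gene_groups = sum(x$groups$type == "single_gene"),
    n_multi_gene_groups = sum(x$groups$type == "multi_gene"),
    overall_overlap = x$overall_overlap,
    n_unmatched = x$n_unmatched
  )
}
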