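# In-silico tryptic digestion and the peptide-to-proteoform index.

#' Collapse isoleucine/leucine to a joint symbol
#'
#' I and L are isobaric and effectively indistinguishable by shotgun MS, so
#' peptide identity throughout the package is defined on this key.
#'
#' @param peptide Character vector of peptide sequences.
#' @return Character vector with I and L both mapped to `J`.
#' @export
il_key <- function(peptide) chartr("IL", "JJ", peptide)

#' In-silico tryptic digest
#'
#' Cleaves after K or R, by default not before proline (classic trypsin
#' specificity), emits all products with up to `max_missed` internal missed
#' cleavage sites, and applies the peptide length filter. Set `min_len = 1`
#' and `max_len = Inf` to disable the filter.
#'
#' @param seq Single protein sequence.
#' @param max_missed Maximum internal missed cleavages (default 1).
#' @param min_len,max_len Peptide length bounds (defaults 9 and 25).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @return Tibble: `peptide`, `start`, `end` (1-based), `missed`, `il_key`.
#' @export
digest <- function(seq, max_missed = 1, min_len = 9, max_len = 25,
                   proline_rule = TRUE) {
  seq <- validate_sequence(seq)
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  if (proline_rule) {
    cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1, n)] != "P"]
  }
  cut_after <- setdiff(cut_after, n)       # terminal residue ends the chain anyway
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)

  out <- list()
  n_seg <- length(starts)
  for (i in seq_len(n_seg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_seg) break
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1
      if (len < min_len || len > max_len) next
      out[[length(out) + 1]] <- tibble(
        peptide = str_sub(seq, s, e), start = s, end = e, missed = m
      )
    }
  }
  res_tbl <- dplyr::bind_rows(out)
  if (nrow(res_tbl) == 0) {
    return(tibble(peptide = character(), start = integer(), end = integer(),
                  missed = integer(), il_key = character()))
  }
  res_tbl$il_key <- il_key(res_tbl$peptide)
  res_tbl
}

#' Build the peptide-to-proteoform index
#'
#' Digests every library record and indexes all products by their I/L key.
#' Contaminant parents are tracked so that contaminant-only peptides can be
#' excluded from inference.
#'
#' @param library Proteoform record tibble (see [enumerate_proteoforms()] or
#'   [read_library()]).
#' @param ... Passed to [digest()].
#' @return A `peptide_index` tibble: `il_key`, `parents` and `genes`
#'   (list-columns), `n_parents`, `n_genes`, `proteotypic`,
#'   `contaminant_only`.
#' @export
build_peptide_index <- function(library, ...) {
  pep <- purrr::map(seq_len(nrow(library)), function(i) {
    d <- digest(library$sequence[i], ...)
    if (nrow(d) == 0) return(NULL)
    tibble(il_key = unique(d$il_key),
           parent = library$proteoform_id[i],
           gene = library$gene_id[i],
           contaminant = library$is_contaminant[i])
  }) |> dplyr::bind_rows()

  idx <- pep |>
    dplyr::group_by(.data$il_key) |>
    dplyr::summarise(
      parents = list(unique(.data$parent)),
      genes = list(unique(.data$gene[!.data$contaminant])),
      contaminant_only = all(.data$contaminant),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_parents = lengths(.data$parents),
      n_genes = lengths(.data$genes),
      proteotypic = .data$n_parents == 1
    )
  class(idx) <- c("peptide_index", class(idx))
  idx
}

#' Classify a peptide's specificity
#'
#' A peptide is `proteotypic` when its I/L key maps to exactly one proteoform
#' in the library, `gene_specific` when it maps to several proteoforms of one
#' gene, and `multi_gene_shared` otherwise. I/L variants of the same key never
#' distinguish proteoforms.
#'
#' @param peptide Peptide sequence (plain or already I/L-collapsed).
#' @param index A `peptide_index` from [build_peptide_index()].
#' @return One-row tibble: `il_key`, `class`, `parents`, `genes`.
#' @export
classify_peptide <- function(peptide, index) {
  key <- il_key(peptide)
  hit <- index[index$il_key == key, ]
  if (nrow(hit) == 0) {
    abort(sprintf("peptide '%s' is absent from the index", peptide),
          class = "proteogel_lookup_error")
  }
  cls <- if (hit$n_parents == 1) "proteotypic"
         else if (hit$n_genes <= 1) "gene_specific"
         else "multi_gene_shared"
  tibble(il_key = key, class = cls, parents = hit$parents, genes = hit$genes)
}

#' Serialize / restore a peptide index
#'
#' @param index A `peptide_index`.
#' @param path TSV path.
#' @return `write_index`: invisible `path`; `read_index`: the index tibble.
#' @export
write_index <- function(index, path) {
  flat <- tibble(
    il_key = index$il_key,
    parents = purrr::map_chr(index$parents, paste, collapse = ";"),
    genes = purrr::map_chr(index$genes, paste, collapse = ";"),
    contaminant_only = index$contaminant_only
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE)
  idx <- tibble(
    il_key = flat$il_key,
    parents = strsplit(flat$parents, ";"),
    genes = purrr::map(strsplit(flat$genes, ";"), function(g) g[nzchar(g)]),
    contaminant_only = flat$contaminant_only
  ) |>
    dplyr::mutate(n_parents = lengths(.data$parents),
                  n_genes = lengths(.data$genes),
                  proteotypic = .data$n_parents == 1)
  class(idx) <- c("peptide_index", class(idx))
  idx
}
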