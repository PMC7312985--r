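# Sample-customized combinatorial proteoform library construction.

#' Read a transcript table
#'
#' Expects a TSV with columns `gene_id`, `transcript_id`, `kind`
#' (`canonical` or `splice`), `sequence`, `reviewed` (logical) and one or more
#' `fpkm_run*` columns holding per-run expression values.
#'
#' @param path TSV path.
#' @return Tibble with an `fpkm` list-column of per-run values.
#' @export
read_transcripts <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  fpkm_cols <- grep("^fpkm_run", names(raw), value = TRUE)
  if (length(fpkm_cols) == 0) abort("transcript table has no fpkm_run* columns")
  raw$fpkm <- lapply(seq_len(nrow(raw)), function(i) as.numeric(raw[i, fpkm_cols]))
  raw[setdiff(names(raw), fpkm_cols)]
}

#' Read a variant-event table
#'
#' TSV columns: `gene_id`, `event_id`, `kind` (`SAP`, `INS`, `DEL`), `pos`
#' (1-based position on the named backbone's protein coordinates), `ref`,
#' `alt`, `backbones` (`;`-separated transcript ids the event applies to).
#'
#' @param path TSV path.
#' @return Tibble of events.
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        col_types = readr::cols(ref = readr::col_character(),
                                                alt = readr::col_character(),
                                                .default = readr::col_guess()))
  ev$ref[is.na(ev$ref)] <- ""
  ev$alt[is.na(ev$alt)] <- ""
  validate_events(ev)
  ev
}

validate_events <- function(events) {
  if (nrow(events) == 0) return(invisible(events))
  with(events, {
    bad_sap <- kind == "SAP" & (nchar(ref) != 1 | nchar(alt) != 1)
    bad_del <- kind == "DEL" & (nchar(ref) < 1 | nchar(alt) != 0)
    bad_ins <- kind == "INS" & (nchar(ref) != 0 | nchar(alt) < 1)
    if (any(bad_sap)) abort("SAP events must have single-residue ref and alt")
    if (any(bad_del)) abort("DEL events must have non-empty ref and empty alt")
    if (any(bad_ins)) abort("INS events must have empty ref and non-empty alt")
  })
  invisible(events)
}

#' Filter transcripts by expression evidence
#'
#' Retains records that are UniProt-reviewed, exceed the FPKM threshold in at
#' least `min_runs` runs, and whose coefficient of variation (sample sd /
#' mean over all runs) does not exceed `max_cv`. Input order is preserved.
#'
#' @param transcripts Tibble from [read_transcripts()].
#' @param min_fpkm FPKM threshold (default 0.1; values must exceed it).
#' @param max_cv Maximum coefficient of variation (default 0.30).
#' @param min_runs Minimum number of runs above threshold (default 2).
#' @return The retained transcript tibble.
#' @export
filter_transcripts <- function(transcripts, min_fpkm = 0.1, max_cv = 0.30,
                               min_runs = 2) {
  if (!"fpkm" %in% names(transcripts)) abort("transcripts need an fpkm list-column")
  n_runs <- lengths(transcripts$fpkm)
  if (any(n_runs == 0)) abort("transcript record with zero expression runs")
  if (any(n_runs < min_runs)) {
    abort(sprintf("each record needs at least %d expression runs", min_runs))
  }
  keep <- purrr::map_lgl(transcripts$fpkm, function(v) {
    cv <- stats::sd(v) / mean(v)
    sum(v > min_fpkm) >= min_runs && !is.na(cv) && cv <= max_cv
  })
  transcripts[keep & transcripts$reviewed, ]
}

# Applies one event to a sequence in backbone coordinates; checks ref residues.
apply_event <- function(seq, kind, pos, ref, alt, gene_id = "?") {
  n <- nchar(seq)
  if (pos < 1 || pos > n) {
    abort(sprintf("event position %d outside backbone length %d (gene %s)", pos, n, gene_id))
  }
  check_ref <- function(len) {
    found <- str_sub(seq, pos, pos + len - 1)
    if (found != ref) {
      abort(sprintf("event ref mismatch at gene %s position %d: expected '%s', backbone has '%s'",
                    gene_id, pos, ref, found))
    }
  }
  switch(kind,
    SAP = { check_ref(1); paste0(str_sub(seq, 1, pos - 1), alt, str_sub(seq, pos + 1)) },
    DEL = { check_ref(nchar(ref));
            paste0(str_sub(seq, 1, pos - 1), str_sub(seq, pos + nchar(ref))) },
    INS = paste0(str_sub(seq, 1, pos - 1), alt, str_sub(seq, pos)),
    abort(sprintf("unknown event kind '%s'", kind))
  )
}

event_span <- function(kind, pos, ref) {
  len <- if (kind == "INS") 0L else nchar(ref)
  c(pos, pos + max(len - 1L, 0L))
}

events_overlap <- function(e1, e2) {
  s1 <- event_span(e1$kind, e1$pos, e1$ref)
  s2 <- event_span(e2$kind, e2$pos, e2$ref)
  s1[1] <= s2[2] && s2[1] <= s1[2]
}

# Applies a set of events to one backbone. Events are expressed in backbone
# coordinates; applying them in decreasing position order keeps every
# downstream coordinate valid after upstream indels.
apply_events <- function(seq, events, gene_id = "?") {
  events <- events[order(-events$pos), ]
  for (i in seq_len(nrow(events))) {
    seq <- apply_event(seq, events$kind[i], events$pos[i],
                       events$ref[i], events$alt[i], gene_id)
  }
  seq
}

proteoform_category <- function(backbone_kind, event_kinds) {
  base <- if (backbone_kind == "canonical") "canonical" else "splice"
  if (length(event_kinds) == 0) return(base)
  ev <- if (any(event_kinds == "SAP") && any(event_kinds %in% c("INS", "DEL"))) {
    "SAP+indel"
  } else if (any(event_kinds == "SAP")) "SAP" else "indel"
  if (base == "canonical") ev else paste0("splice+", ev)
}

#' Enumerate combinatorial proteoforms
#'
#' For every retained backbone, emits the backbone itself plus, per policy,
#' each compatible event applied alone (`"single"`, the default) or
#' additionally every compatible pair of one SAP with one insertion/deletion
#' (`"paired"`). Event coordinates are 1-based on the backbone's protein
#' sequence; within a combination, overlapping events are skipped with a
#' warning. Records with identical sequences are collapsed into one, keeping
#' every provenance id in `all_ids`.
#'
#' @param transcripts Retained transcript tibble (see [filter_transcripts()]).
#' @param events Event tibble (see [read_events()]).
#' @param policy `"single"` or `"paired"`.
#' @return Tibble of proteoform records: `proteoform_id`, `gene_id`,
#'   `backbone_id`, `backbone_kind`, `category`, `events`, `sequence`,
#'   `all_ids`, `is_contaminant`.
#' @export
enumerate_proteoforms <- function(transcripts, events = NULL,
                                  policy = c("single", "paired")) {
  policy <- match.arg(policy)
  if (is.null(events)) {
    events <- tibble(gene_id = character(), event_id = character(),
                     kind = character(), pos = integer(),
                     ref = character(), alt = character(), backbones = character())
  }
  validate_events(events)

  recs <- list()
  emit <- function(gene, bb_id, bb_kind, ev_ids, ev_kinds, seq) {
    ev_lab <- if (length(ev_ids) == 0) "-" else paste(sort(ev_ids), collapse = "+")
    recs[[length(recs) + 1]] <<- list(
      proteoform_id = paste(gene, bb_id, ev_lab, sep = "|"),
      gene_id = gene, backbone_id = bb_id, backbone_kind = bb_kind,
      category = proteoform_category(bb_kind, ev_kinds),
      events = ev_lab, sequence = seq
    )
  }

  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    validate_sequence(tr$sequence)
    emit(tr$gene_id, tr$transcript_id, tr$kind, character(), character(), tr$sequence)

    ev <- events[events$gene_id == tr$gene_id, ]
    if (nrow(ev) > 0) {
      compat <- purrr::map_lgl(ev$backbones, function(b) {
        tr$transcript_id %in% strsplit(b, ";")[[1]]
      })
      ev <- ev[compat, ]
    }
    if (nrow(ev) == 0) next

    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      emit(tr$gene_id, tr$transcript_id, tr$kind, e$event_id, e$kind,
           apply_events(tr$sequence, e, tr$gene_id))
    }
    if (policy == "paired") {
      saps <- ev[ev$kind == "SAP", ]
      indels <- ev[ev$kind %in% c("INS", "DEL"), ]
      for (a in seq_len(nrow(saps))) for (b in seq_len(nrow(indels))) {
        if (events_overlap(saps[a, ], indels[b, ])) {
          warn(sprintf("skipping overlapping events %s + %s on %s",
                       saps$event_id[a], indels$event_id[b], tr$transcript_id))
          next
        }
        pair <- dplyr::bind_rows(saps[a, ], indels[b, ])
        emit(tr$gene_id, tr$transcript_id, tr$kind, pair$event_id, pair$kind,
             apply_events(tr$sequence, pair, tr$gene_id))
      }
    }
  }

  pull <- function(f) vapply(recs, `[[`, character(1), f)
  if (length(recs) == 0) {
    return(tibble(proteoform_id = character(), gene_id = character(),
                  backbone_id = character(), backbone_kind = character(),
                  category = character(), events = character(),
                  sequence = character(), all_ids = character(),
                  is_contaminant = logical()))
  }
  out <- tibble(
    proteoform_id = pull("proteoform_id"), gene_id = pull("gene_id"),
    backbone_id = pull("backbone_id"), backbone_kind = pull("backbone_kind"),
    category = pull("category"), events = pull("events"),
    sequence = pull("sequence")
  )
  emission_order <- out$proteoform_id
  # Collapse duplicate sequences, keeping all provenance ids.
  out <- out |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(all_ids = paste(.data$proteoform_id, collapse = ";")) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$proteoform_id, emission_order))
  out$is_contaminant <- FALSE
  out
}

#' Write a proteoform library to FASTA
#'
#' Headers encode the proteoform id, gene, category, backbone and event list
#' so that a round-trip through [read_library()] restores all fields.
#' Contaminant entries (appended from `contaminants_fasta`) are flagged with
#' the reserved `CONT_` prefix.
#'
#' @param records Proteoform tibble from [enumerate_proteoforms()].
#' @param path Output FASTA path.
#' @param contaminants_fasta Optional FASTA of contaminant sequences.
#' @return Invisibly, the combined record tibble as written.
#' @export
write_library <- function(records, path, contaminants_fasta = NULL) {
  if (anyDuplicated(records$proteoform_id)) {
    abort("duplicate proteoform_id in library")
  }
  all <- records
  if (!is.null(contaminants_fasta)) {
    cont <- Biostrings::readAAStringSet(contaminants_fasta)
    cont_tbl <- tibble(
      proteoform_id = paste0("CONT_", vapply(strsplit(names(cont), " "), `[`, "", 1)),
      gene_id = "contaminant", backbone_id = "-", backbone_kind = "contaminant",
      category = "contaminant", events = "-",
      sequence = as.character(cont), all_ids = NA_character_, is_contaminant = TRUE
    )
    cont_tbl$all_ids <- cont_tbl$proteoform_id
    all <- dplyr::bind_rows(records, cont_tbl)
  }
  if (anyDuplicated(all$proteoform_id)) abort("duplicate proteoform_id in library")
  headers <- sprintf("%s gene=%s backbone=%s kind=%s category=%s events=%s",
                     all$proteoform_id, all$gene_id, all$backbone_id,
                     all$backbone_kind, all$category, all$events)
  x <- Biostrings::AAStringSet(all$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(all)
}

#' Read a proteoform library FASTA written by [write_library()]
#'
#' @param path FASTA path.
#' @return Proteoform record tibble.
#' @export
read_library <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- names(x)
  field <- function(key) {
    m <- stringr::str_match(hdr, paste0(key, "=([^ ]+)"))[, 2]
    m
  }
  tibble(
    proteoform_id = vapply(strsplit(hdr, " "), `[`, "", 1),
    gene_id = field("gene"), backbone_id = field("backbone"),
    backbone_kind = field("kind"), category = field("category"),
    events = field("events"), sequence = unname(as.character(x)),
    all_ids = NA_character_,
    is_contaminant = startsWith(vapply(strsplit(hdr, " "), `[`, "", 1), "CONT_")
  )
}

#' Library composition statistics
#'
#' @param records Proteoform record tibble.
#' @return List with `by_category` (counts partitioning the library),
#'   `per_gene` (sequences per gene), and scalar `n_records`, `n_genes`,
#'   `mean_per_gene` (contaminants excluded).
#' @export
library_stats <- function(records) {
  recs <- records[!records$is_contaminant, ]
  by_cat <- recs |> dplyr::count(.data$category, name = "n") |> dplyr::arrange(-.data$n)
  per_gene <- recs |> dplyr::count(.data$gene_id, name = "n") |> dplyr::arrange(-.data$n)
  list(
    by_category = by_cat,
    per_gene = per_gene,
    n_records = nrow(recs),
    n_genes = nrow(per_gene),
    mean_per_gene = nrow(recs) / max(nrow(per_gene), 1)
  )
}
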