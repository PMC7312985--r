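# Concordance testing, shift classification, and protein-group resolution
# on the 2DE gel coordinate system.

#' Annotation configuration
#'
#' Tolerances and caps used throughout annotation. Directions of the shift
#' taxonomy are fixed; these magnitudes are tunable because the gel gives
#' directions much more reliably than distances.
#'
#' @param tol_pi pI tolerance around a cell, pH units (default 0.15;
#'   wide enough for calibration scatter, narrow enough that a proteoform one
#'   column away still registers as shifted).
#' @param tol_mw Relative MW tolerance around a cell (default 0.15).
#' @param complex_tol Relative MW tolerance for complex/oligomer mass sums
#'   (default 0.20).
#' @param frag_tol Relative MW tolerance for proteolytic-fragment
#'   compatibility (default 0.25).
#' @param k_max Maximum number of phosphates hypothesized for an acidic shift
#'   (default 5).
#' @param max_oligomer Largest homo-oligomer multiple considered (default 6).
#' @param proline_threshold Proline fraction above which gel retardation is
#'   invoked (default 0.10).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(tol_pi = 0.15, tol_mw = 0.15, complex_tol = 0.20,
                              frag_tol = 0.25, k_max = 5, max_oligomer = 6,
                              proline_threshold = 0.10) {
  structure(list(tol_pi = tol_pi, tol_mw = tol_mw, complex_tol = complex_tol,
                 frag_tol = frag_tol, k_max = k_max, max_oligomer = max_oligomer,
                 proline_threshold = proline_threshold),
            class = "annotation_config")
}

#' Theoretical gel coordinates of a proteoform
#'
#' Average molecular mass (kDa) and Bjellqvist isoelectric point, optionally
#' under a modification hypothesis.
#'
#' @param seq Protein sequence.
#' @param mods Optional [modification_set()].
#' @param pka A [pka_table()].
#' @return One-row tibble: `pi`, `mw_kda`.
#' @export
theoretical_coords <- function(seq, mods = NULL, pka = pka_table()) {
  tibble(pi = isoelectric_point(seq, pka, mods),
         mw_kda = molecular_mass(seq, "average", mods) / 1000)
}

# pI with k position-free phosphate groups (charge is position-independent).
pi_with_phospho <- function(seq, k, pka) {
  sty <- gregexpr("[STY]", seq)[[1]]
  if (sty[1] == -1 || length(sty) < k) return(NA_real_)
  isoelectric_point(seq, pka, modification_set(rep("phospho", k), sty[seq_len(k)]))
}

pi_with_amidation <- function(seq, pka) {
  isoelectric_point(seq, pka, modification_set("amidation_cterm", NA_integer_))
}

#' Read a protein-partner interaction table
#'
#' TSV with columns `a` and `b` (gene or proteoform identifiers). The
#' symmetric closure is applied on load.
#'
#' @param path TSV path.
#' @return Tibble with columns `a`, `b`, symmetric.
#' @export
read_partner_table <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("a", "b") %in% names(p)))
  dplyr::distinct(dplyr::bind_rows(p[, c("a", "b")],
                                   tibble(a = p$b, b = p$a)))
}

partners_of <- function(id, gene, partner_table) {
  if (is.null(partner_table)) return(character())
  unique(partner_table$b[partner_table$a %in% c(id, gene)])
}

#' Per-cell concordance of a proteoform with its observed locations
#'
#' A cell is `concordant` when the unmodified theoretical point falls inside
#' the cell expanded by the tolerances; when the point properly locates to an
#' adjacent cell and only the tolerance expansion reaches the observed cell,
#' the hit is flagged `boundary_artifact`. Otherwise the cell is `discordant`
#' and is passed on to [classify_shift()].
#'
#' @param pi,mw_kda Theoretical coordinates of the proteoform.
#' @param cells Character vector of observed cell labels.
#' @param grid A `gel_grid`.
#' @param config An [annotation_config()].
#' @return Tibble: `cell`, `status` (`concordant`/`discordant`),
#'   `boundary_artifact` (logical).
#' @export
concordance <- function(pi, mw_kda, cells, grid, config = annotation_config()) {
  home <- locate_cell(pi, mw_kda, grid)
  purrr::map_dfr(cells, function(cl) {
    b <- cell_bounds(grid, cl)
    proper <- !is.na(home) && home == cl
    within_tol <- point_in_cell(pi, mw_kda, b, config$tol_pi, config$tol_mw)
    boundary <- within_tol && !proper && !is.na(home) && cells_adjacent(grid, home, cl)
    tibble(cell = cl,
           status = if (within_tol) "concordant" else "discordant",
           boundary_artifact = boundary)
  })
}

#' Classify a discordant gel-cell localization
#'
#' Applies the shift taxonomy as a rule cascade and returns every matching
#' explanation ranked by evidence strength (observed modifications and
#' co-identified partners rank above purely hypothesized causes):
#'
#' * lighter shift: `proteolysis` when the record's peptides in this cell are
#'   confinable to one contiguous fragment whose mass is compatible with the
#'   cell's MW window (within `frag_tol`); a note marks terminal clustering.
#' * heavier shift: `complex_or_oligomer` when a partner is co-identified in
#'   the same cell and the monomer-mass sum (or an integer multiple of the
#'   monomer mass) falls in the cell's MW window (within `complex_tol`).
#' * acidic shift: `acidic_PTM` when phospho/deamidation modifications were
#'   observed in the cell, or when `k <= k_max` phosphates reproduce the
#'   cell's pI window (`k` reported).
#' * basic shift: `basic_PTM` when amidation/methylation was observed, or
#'   when C-terminal amidation reproduces the cell's pI window.
#' * heavier shift with no partner evidence: `proline_retardation` when the
#'   proline fraction exceeds `proline_threshold`; otherwise non-complete
#'   denaturation is noted as an unranked possibility.
#'
#' An empty result means the shift is unexplained. No explanation whose axis
#' contradicts the shift's sign is ever produced.
#'
#' @param seq The record's sequence.
#' @param shift One-row tibble from [shift_vector()].
#' @param grid A `gel_grid`.
#' @param cell_peptides Tibble of the record's peptides observed in this cell
#'   with columns `start`, `end` (positions on `seq`); may be empty.
#' @param observed_mods Character vector of modification names observed on
#'   this record's peptides in this cell.
#' @param partners Character vector of interaction partners (ids or genes) of
#'   the record, from [read_partner_table()].
#' @param co_identified Tibble of other subjects identified in the same cell:
#'   columns `id`, `gene`, `mw_kda`.
#' @param self_interacting TRUE when the record is its own interaction partner
#'   (a self-pair in the partner table); required for the homo-oligomer
#'   integer-multiple branch — a bare mass multiple is too weak on its own.
#' @param pka A [pka_table()].
#' @param config An [annotation_config()].
#' @return Tibble ranked by decreasing `score`: `explanation`, `score`,
#'   `note`.
#' @export
classify_shift <- function(seq, shift, grid, cell_peptides = NULL,
                           observed_mods = character(), partners = character(),
                           co_identified = NULL, self_interacting = FALSE,
                           pka = pka_table(), config = annotation_config()) {
  b <- cell_bounds(grid, shift$cell)
  mw_self <- molecular_mass(seq, "average") / 1000
  out <- list()
  add <- function(explanation, score, note = "") {
    out[[length(out) + 1]] <<- tibble(explanation = explanation,
                                      score = score, note = note)
  }

  # (a) lighter: proteolytic fragment
  if (shift$mw_category == "lighter" &&
      !is.null(cell_peptides) && nrow(cell_peptides) > 0) {
    span <- c(min(cell_peptides$start), max(cell_peptides$end))
    span_mass <- molecular_mass(str_sub(seq, span[1], span[2]), "average") / 1000
    if (span_mass <= b$mw_hi * (1 + config$frag_tol)) {
      n <- nchar(seq)
      note <- if (span[2] <= ceiling(0.5 * n)) "peptides cluster at the N-terminus"
              else if (span[1] >= floor(0.5 * n)) "peptides cluster at the C-terminus"
              else ""
      add("proteolysis", 2 + (note != ""),
          sprintf("fragment spanning %d-%d (%.1f kDa) fits the cell%s%s",
                  span[1], span[2], span_mass,
                  if (note != "") "; " else "", note))
    }
  }

  # (b) heavier: complex with a co-identified partner, or homo-oligomer
  if (shift$mw_category == "heavier") {
    lo <- b$mw_lo * (1 - config$complex_tol)
    hi <- b$mw_hi * (1 + config$complex_tol)
    if (!is.null(co_identified) && nrow(co_identified) > 0 && length(partners) > 0) {
      hits <- co_identified[co_identified$id %in% partners |
                              co_identified$gene %in% partners, ]
      for (i in seq_len(nrow(hits))) {
        total <- mw_self + hits$mw_kda[i]
        if (total >= lo && total <= hi) {
          add("complex_or_oligomer", 3,
              sprintf("co-identified partner %s; monomer sum %.1f kDa fits the cell",
                      hits$id[i], total))
        }
      }
    }
    if (self_interacting) {
      mult <- 2:config$max_oligomer
      fit <- mult[mult * mw_self >= lo & mult * mw_self <= hi]
      if (length(fit) > 0) {
        add("complex_or_oligomer", 2,
            sprintf("homo-oligomer x%d (%.1f kDa) fits the cell", fit[1], fit[1] * mw_self))
      }
    }
  }

  # (c) acidic: observed or hypothesized acidic PTMs
  if (shift$pi_category == "acidic") {
    acidic_obs <- intersect(observed_mods, c("phospho", "deamidation"))
    if (length(acidic_obs) > 0) {
      add("acidic_PTM", 3, paste("observed:", paste(acidic_obs, collapse = ", ")))
    } else {
      for (k in seq_len(config$k_max)) {
        p_k <- pi_with_phospho(seq, k, pka)
        if (is.na(p_k)) break
        if (p_k >= b$pi_lo - config$tol_pi && p_k <= b$pi_hi + config$tol_pi) {
          add("acidic_PTM", 2, sprintf("%d phosphates reproduce the cell pI (%.2f)", k, p_k))
          break
        }
        if (p_k < b$pi_lo - config$tol_pi) break  # overshot; more would go further
      }
    }
  }

  # (d) basic: observed or hypothesized basic PTMs
  if (shift$pi_category == "basic") {
    basic_obs <- intersect(observed_mods, c("amidation_cterm", "methyl"))
    if (length(basic_obs) > 0) {
      add("basic_PTM", 3, paste("observed:", paste(basic_obs, collapse = ", ")))
    } else {
      p_a <- pi_with_amidation(seq, pka)
      if (p_a >= b$pi_lo - config$tol_pi && p_a <= b$pi_hi + config$tol_pi) {
        add("basic_PTM", 2, sprintf("C-terminal amidation reproduces the cell pI (%.2f)", p_a))
      }
    }
  }

  # (e) heavier with no partner evidence: structure-driven retardation
  if (shift$mw_category == "heavier") {
    have_partner <- length(out) > 0 &&
      any(purrr::map_chr(out, function(x) x$explanation) == "complex_or_oligomer" &
            purrr::map_dbl(out, function(x) x$score) == 3)
    if (!have_partner) {
      if (residue_fraction(seq, "P") > config$proline_threshold) {
        add("proline_retardation", 1,
            sprintf("proline fraction %.2f exceeds %.2f",
                    residue_fraction(seq, "P"), config$proline_threshold))
      } else {
        attr_note <- "non-complete denaturation possible (unranked)"
        if (length(out) == 0) {
          res <- tibble(explanation = character(), score = numeric(), note = character())
          attr(res, "unranked_note") <- attr_note
          return(res)
        }
      }
    }
  }

  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(explanation = character(), score = numeric(), note = character())
  } else {
    res <- dplyr::arrange(res, -.data$score)
  }
  res
}

#' Resolve a protein group by gel coordinates
#'
#' Members whose unmodified theoretical coordinates are concordant with the
#' observed cell are candidates; exactly one candidate resolves the group.
#' Groups whose members differ only by single-residue substitutions have
#' near-identical coordinates and are declared unresolvable by coordinates.
#'
#' @param members Tibble with columns `proteoform_id`, `sequence`, `category`.
#' @param cell Observed cell label.
#' @param grid A `gel_grid`.
#' @param pka A [pka_table()].
#' @param config An [annotation_config()].
#' @return List: `status` (`resolved` / `unresolved` /
#'   `unresolvable_by_coordinates`), `resolved_id` (or NA), `concordant_ids`,
#'   `coords` (per-member tibble), `reason`.
#' @export
resolve_group <- function(members, cell, grid, pka = pka_table(),
                          config = annotation_config()) {
  stopifnot(nrow(members) >= 1)
  coords <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
    dplyr::bind_cols(tibble(proteoform_id = members$proteoform_id[i]),
                     theoretical_coords(members$sequence[i], pka = pka))
  })

  # SAP-only groups: equal-length sequences differing by point substitutions.
  if (nrow(members) > 1) {
    lens <- nchar(members$sequence)
    sap_only <- length(unique(lens)) == 1 &&
      max(coords$mw_kda) - min(coords$mw_kda) < 0.5 &&
      max(coords$pi) - min(coords$pi) < 0.1
    if (sap_only) {
      return(list(status = "unresolvable_by_coordinates", resolved_id = NA_character_,
                  concordant_ids = character(), coords = coords,
                  reason = "members differ only by point substitutions; coordinates cannot separate them"))
    }
  }

  b <- cell_bounds(grid, cell)
  conc <- coords$proteoform_id[point_in_cell(coords$pi, coords$mw_kda, b,
                                             config$tol_pi, config$tol_mw)]
  if (length(conc) == 1) {
    list(status = "resolved", resolved_id = conc, concordant_ids = conc,
         coords = coords, reason = "exactly one member fits the cell")
  } else if (length(conc) > 1) {
    list(status = "unresolved", resolved_id = NA_character_, concordant_ids = conc,
         coords = coords,
         reason = sprintf("%d members fit the cell", length(conc)))
  } else {
    list(status = "unresolved", resolved_id = NA_character_, concordant_ids = character(),
         coords = coords, reason = "no member fits the cell")
  }
}

#' Annotate a full experiment
#'
#' For every identified proteoform: gathers its observed cells (any cell
#' holding at least one of its peptides), tests concordance of the unmodified
#' coordinates per cell, classifies every discordant cell with the shift
#' taxonomy, and assigns the subject status: `concordant` when some observed
#' cell is concordant, otherwise `explained_shift` when every discordant cell
#' has at least one explanation, else `unexplained`. Fragment (lighter-shift)
#' cells never create new proteoform calls. Protein groups are resolved per
#' observed cell by coordinate match.
#'
#' @param inference A `proteoform_inference` from [infer_experiment()].
#' @param library Proteoform record tibble (sequences for all subjects).
#' @param grid A `gel_grid`.
#' @param partner_table Optional partner tibble from [read_partner_table()];
#'   when absent the complex rule is skipped with a notice.
#' @param pka A [pka_table()].
#' @param config An [annotation_config()].
#' @return A `proteoform_annotation` object with `subjects` (per-proteoform
#'   tibble), `cells` (per proteoform-cell tibble with explanations),
#'   `groups` (per-group resolution tibble), and `summary`.
#' @export
annotate_experiment <- function(inference, library, grid, partner_table = NULL,
                                pka = pka_table(), config = annotation_config()) {
  if (is.null(partner_table)) {
    rlang::inform("no partner table supplied; the complex/oligomer rule will lack partner evidence")
  }
  lib <- library[!library$is_contaminant, ]
  obs <- inference$observations

  ids <- unique(inference$proteoforms$proteoform_id)
  ids <- ids[!startsWith(ids, "CONT_")]

  # Pre-compute digests and coordinates of all subjects.
  digests <- purrr::map(ids, function(id) {
    digest(lib$sequence[lib$proteoform_id == id][1])
  })
  names(digests) <- ids
  coords <- purrr::map_dfr(ids, function(id) {
    s <- lib$sequence[lib$proteoform_id == id][1]
    dplyr::bind_cols(tibble(proteoform_id = id), theoretical_coords(s, pka = pka))
  })

  # Observed cells per subject: any cell containing >=1 of its peptides.
  key_cells <- obs[, c("cell", "il_key", "mods")]
  subject_cells <- purrr::map(ids, function(id) {
    keys <- digests[[id]]$il_key
    sort(unique(key_cells$cell[key_cells$il_key %in% keys]))
  })
  names(subject_cells) <- ids

  # Identified subjects per cell with monomer masses (for partner evidence).
  ident_by_cell <- inference$proteoforms |>
    dplyr::left_join(coords, by = "proteoform_id") |>
    dplyr::mutate(gene = gene_of(.data$proteoform_id))

  cell_rows <- list()
  subj_rows <- list()
  for (id in ids) {
    s <- lib$sequence[lib$proteoform_id == id][1]
    gene <- gene_of(id)
    th <- coords[coords$proteoform_id == id, ]
    cls <- subject_cells[[id]]
    conc <- concordance(th$pi, th$mw_kda, cls, grid, config)

    expl_per_cell <- purrr::map(seq_len(nrow(conc)), function(i) {
      if (conc$status[i] == "concordant") {
        return(tibble(explanation = if (conc$boundary_artifact[i]) "boundary_artifact" else character(),
                      score = if (conc$boundary_artifact[i]) 1 else numeric(),
                      note = if (conc$boundary_artifact[i]) "adjacent-cell boundary hit" else character()))
      }
      cl <- conc$cell[i]
      sh <- shift_vector(th$pi, th$mw_kda, cl, grid, config$tol_pi, config$tol_mw)
      keys_here <- key_cells[key_cells$cell == cl, ]
      pept <- digests[[id]][digests[[id]]$il_key %in% keys_here$il_key, ]
      mods_here <- unique(unlist(strsplit(
        keys_here$mods[keys_here$il_key %in% digests[[id]]$il_key & keys_here$mods != ""], ";")))
      co <- ident_by_cell[ident_by_cell$cell == cl &
                            ident_by_cell$proteoform_id != id, ]
      prt <- partners_of(id, gene, partner_table)
      classify_shift(
        seq = s, shift = sh, grid = grid, cell_peptides = pept,
        observed_mods = mods_here %||% character(),
        partners = prt,
        co_identified = tibble(id = co$proteoform_id, gene = co$gene,
                               mw_kda = co$mw_kda),
        self_interacting = gene %in% prt || id %in% prt,
        pka = pka, config = config
      )
    })

    for (i in seq_len(nrow(conc))) {
      e <- expl_per_cell[[i]]
      cell_rows[[length(cell_rows) + 1]] <- tibble(
        proteoform_id = id, cell = conc$cell[i], status = conc$status[i],
        boundary_artifact = conc$boundary_artifact[i],
        explanation = if (nrow(e) > 0) e$explanation[1] else
          if (conc$status[i] == "concordant") NA_character_ else "unexplained",
        note = if (nrow(e) > 0) e$note[1] else attr(e, "unranked_note") %||% NA_character_,
        all_explanations = paste(e$explanation, collapse = ";")
      )
    }

    any_conc <- any(conc$status == "concordant")
    disc <- conc$status == "discordant"
    all_explained <- all(purrr::map_int(expl_per_cell[disc], nrow) > 0)
    status <- if (any_conc) "concordant"
              else if (any(disc) && all_explained) "explained_shift"
              else "unexplained"
    subj_rows[[length(subj_rows) + 1]] <- tibble(
      proteoform_id = id, gene_id = gene, pi = th$pi, mw_kda = th$mw_kda,
      n_cells = length(cls), status = status,
      explanations = paste(unique(stats::na.omit(
        purrr::map_chr(expl_per_cell, function(e) {
          if (nrow(e) > 0) e$explanation[1] else NA_character_
        })
      )), collapse = ";")
    )
  }

  subjects <- dplyr::bind_rows(subj_rows)
  cells <- dplyr::bind_rows(cell_rows)

  # Group resolution per observed cell.
  grp_rows <- list()
  if (nrow(inference$groups) > 0) {
    for (i in seq_len(nrow(inference$groups))) {
      g <- inference$groups[i, ]
      memb <- lib[lib$proteoform_id %in% g$members[[1]], c("proteoform_id", "sequence", "category")]
      if (nrow(memb) == 0) next
      res <- resolve_group(memb, g$cell, grid, pka, config)
      grp_rows[[length(grp_rows) + 1]] <- tibble(
        group_id = g$group_id, cell = g$cell, type = g$type,
        n_members = nrow(memb), status = res$status,
        resolved_id = res$resolved_id, reason = res$reason
      )
    }
  }
  groups <- dplyr::bind_rows(grp_rows)

  summary <- list(
    by_status = subjects |> dplyr::count(.data$status, name = "n"),
    by_explanation = cells |>
      dplyr::filter(!is.na(.data$explanation)) |>
      dplyr::count(.data$explanation, name = "n"),
    cell_multiplicity = subjects |>
      dplyr::mutate(multi = ifelse(.data$n_cells > 1, "multi_cell", "single_cell")) |>
      dplyr::count(.data$multi, name = "n"),
    groups_by_status = if (nrow(groups) > 0) groups |> dplyr::count(.data$status, name = "n")
                       else tibble(status = character(), n = integer())
  )

  structure(list(subjects = subjects, cells = cells, groups = groups,
                 summary = summary, config = config),
            class = "proteoform_annotation")
}

#' @export
print.proteoform_annotation <- function(x, ...) {
  cat("proteoform annotation:", nrow(x$subjects), "subjects,",
      nrow(x$groups), "group-cell resolutions\n")
  print(x$summary$by_status)
  invisible(x)
}

#' Tidy an annotation result
#' @param x A `proteoform_annotation`.
#' @param ... Unused.
#' @return The per-subject tibble.
#' @export
tidy.proteoform_annotation <- function(x, ...) x$subjects

#' One-row summary of an annotation result
#' @param x A `proteoform_annotation`.
#' @param ... Unused.
#' @return One-row tibble of status counts.
#' @export
glance.proteoform_annotation <- function(x, ...) {
  s <- x$summary$by_status
  tibble(
    n_subjects = nrow(x$subjects),
    n_concordant = sum(s$n[s$status == "concordant"]),
    n_explained_shift = sum(s$n[s$status == "explained_shift"]),
    n_unexplained = sum(s$n[s$status == "unexplained"]),
    n_groups = nrow(x$groups),
    n_groups_resolved = sum(x$groups$status == "resolved")
  )
}

#' Plot annotation results on the gel plane
#'
#' Theoretical coordinates of every subject over the grid, coloured by status.
#'
#' @param object A `proteoform_annotation`.
#' @param grid The `gel_grid` used for annotation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proteoform_annotation <- function(object, grid, ...) {
  autoplot(grid) +
    ggplot2::geom_point(
      data = object$subjects,
      ggplot2::aes(x = .data$pi, y = .data$mw_kda, colour = .data$status),
      size = 1.5
    ) +
    ggplot2::labs(colour = "status")
}
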