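# Pipeline orchestration, configuration handling, and report tables.

.pipeline_keys <- c("transcripts", "events", "observations", "grid",
                    "partners", "contaminants", "out_dir", "policy",
                    "min_fpkm", "max_cv", "min_runs", "max_q", "min_len",
                    "max_len", "max_missed", "overlap_method", "tol_pi",
                    "tol_mw", "complex_tol", "frag_tol", "k_max",
                    "proline_threshold", "seed")

#' Read and validate a pipeline configuration
#'
#' YAML with file paths (`transcripts`, `events`, `observations`, `grid`,
#' optional `partners`, `contaminants`), an `out_dir`, and optional threshold
#' overrides. Unknown keys are rejected; the configuration round-trips
#' through the file unchanged.
#'
#' @param path YAML path, or a named list already in memory.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), .pipeline_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  need <- c("transcripts", "events", "observations", "grid", "out_dir")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("configuration is missing key(s): ", paste(missing, collapse = ", ")))
  }
  cfg
}

#' Run the full annotation pipeline
#'
#' Executes library construction, digestion/indexing, per-cell inference, and
#' gel-coordinate annotation, writing all artifacts plus a manifest (package
#' version, thresholds, input paths) into the output directory. Fails fast
#' with an actionable message when an input file is missing, before any
#' computation. Reruns on identical inputs produce identical outputs.
#'
#' @param config Configuration list or YAML path (see
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the in-memory results (`library`, `index`,
#'   `inference`, `annotation`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  for (key in c("transcripts", "events", "observations", "grid")) {
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("input file for '%s' not found: %s (nothing was run)", key, cfg[[key]]))
    }
  }
  if (!is.null(cfg$partners) && !file.exists(cfg$partners)) {
    abort(sprintf("partner table not found: %s (nothing was run)", cfg$partners))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- function(key, default) cfg[[key]] %||% default

  grid <- load_grid(cfg$grid)
  transcripts <- read_transcripts(cfg$transcripts)
  events <- read_events(cfg$events)
  kept <- filter_transcripts(transcripts, g("min_fpkm", 0.1),
                             g("max_cv", 0.30), g("min_runs", 2))
  lib <- enumerate_proteoforms(kept, events, g("policy", "single"))
  lib_path <- file.path(cfg$out_dir, "library.fasta")
  lib_all <- write_library(lib, lib_path, cfg$contaminants)

  stats <- library_stats(lib_all)
  readr::write_tsv(stats$by_category, file.path(cfg$out_dir, "library_stats.tsv"))
  readr::write_tsv(stats$per_gene, file.path(cfg$out_dir, "library_per_gene.tsv"))

  index <- build_peptide_index(lib_all, max_missed = g("max_missed", 1),
                               min_len = g("min_len", 9), max_len = g("max_len", 25))
  write_index(index, file.path(cfg$out_dir, "index.tsv"))

  obs <- read_observations(cfg$observations)
  inference <- infer_experiment(obs, index, g("max_q", 0.01),
                                g("min_len", 9), g("max_len", 25),
                                g("overlap_method", "jaccard"))
  readr::write_tsv(tidy(inference), file.path(cfg$out_dir, "proteoforms.tsv"))
  readr::write_tsv(inference$overlap, file.path(cfg$out_dir, "replicate_overlap.tsv"))
  if (nrow(inference$groups) > 0) {
    readr::write_tsv(
      inference$groups |>
        dplyr::mutate(members = purrr::map_chr(.data$members, paste, collapse = ";"),
                      genes = purrr::map_chr(.data$genes, paste, collapse = ";"),
                      peptides = purrr::map_chr(.data$peptides, paste, collapse = ";")),
      file.path(cfg$out_dir, "groups.tsv")
    )
  }

  partners <- if (!is.null(cfg$partners)) read_partner_table(cfg$partners) else NULL
  acfg <- annotation_config(g("tol_pi", 0.2), g("tol_mw", 0.15),
                            g("complex_tol", 0.20), g("frag_tol", 0.25),
                            g("k_max", 5), proline_threshold = g("proline_threshold", 0.10))
  annotation <- annotate_experiment(inference, lib_all, grid, partners,
                                    config = acfg)
  readr::write_tsv(annotation$subjects, file.path(cfg$out_dir, "annotations.tsv"))
  readr::write_tsv(annotation$cells, file.path(cfg$out_dir, "annotation_cells.tsv"))
  jsonlite::write_json(list(
    subjects = annotation$subjects, cells = annotation$cells,
    groups = annotation$groups,
    summary = annotation$summary
  ), file.path(cfg$out_dir, "annotations.json"), dataframe = "rows", auto_unbox = TRUE)

  hm <- cell_heatmap(inference)
  readr::write_tsv(hm$peptides, file.path(cfg$out_dir, "heatmap_peptides.tsv"))
  readr::write_tsv(hm$proteins, file.path(cfg$out_dir, "heatmap_proteins.tsv"))

  summary_tbl <- dplyr::bind_rows(
    dplyr::mutate(annotation$summary$by_status, table = "status"),
    dplyr::mutate(annotation$summary$by_explanation, table = "explanation",
                  status = .data$explanation) |>
      dplyr::select("status", "n", "table"),
    dplyr::mutate(annotation$summary$cell_multiplicity, table = "multiplicity",
                  status = .data$multi) |> dplyr::select("status", "n", "table")
  )
  readr::write_tsv(summary_tbl, file.path(cfg$out_dir, "summary.tsv"))

  manifest <- list(
    package = "proteogel",
    version = as.character(utils::packageVersion("proteogel")),
    inputs = cfg[intersect(names(cfg), c("transcripts", "events", "observations",
                                         "grid", "partners", "contaminants"))],
    thresholds = list(
      min_fpkm = g("min_fpkm", 0.1), max_cv = g("max_cv", 0.30),
      min_runs = g("min_runs", 2), max_q = g("max_q", 0.01),
      min_len = g("min_len", 9), max_len = g("max_len", 25),
      max_missed = g("max_missed", 1), policy = g("policy", "single"),
      overlap_method = g("overlap_method", "jaccard"),
      tol_pi = acfg$tol_pi, tol_mw = acfg$tol_mw,
      complex_tol = acfg$complex_tol, frag_tol = acfg$frag_tol,
      k_max = acfg$k_max, proline_threshold = acfg$proline_threshold
    ),
    seed = cfg$seed %||% NA
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(library = lib_all, index = index, inference = inference,
                 annotation = annotation, out_dir = cfg$out_dir))
}

#' Per-cell identification heatmap tables
#'
#' Counts distinct peptides and identified proteoforms per gel cell as
#' row-A-to-H by column-1-to-12 matrices with a totals row and column,
#' consumable by any plotting tool.
#'
#' @param inference A `proteoform_inference`.
#' @return List of two tibbles, `peptides` and `proteins` (first column
#'   `row`, then columns `1`-`12` and `Total`, final row `Total`).
#' @export
cell_heatmap <- function(inference) {
  counts <- function(df, what) {
    base <- tidyr::expand_grid(row = LETTERS[1:8], col = 1:12) |>
      dplyr::mutate(cell = paste0(.data$row, .data$col))
    per <- df |> dplyr::count(.data$cell, name = "n")
    base |>
      dplyr::left_join(per, by = "cell") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
      dplyr::select(-"cell") |>
      tidyr::pivot_wider(names_from = "col", values_from = "n")
  }
  add_totals <- function(wide) {
    wide$Total <- rowSums(wide[, -1])
    totals <- c(row = "Total", as.list(colSums(wide[, -1])))
    dplyr::bind_rows(wide, tibble::as_tibble(totals[names(wide)]))
  }
  pep <- inference$observations |> dplyr::distinct(.data$cell, .data$il_key)
  prot <- inference$proteoforms |> dplyr::distinct(.data$cell, .data$proteoform_id)
  list(peptides = add_totals(counts(pep)), proteins = add_totals(counts(prot)))
}

#' Plot a per-cell heatmap
#'
#' @param inference A `proteoform_inference`.
#' @param what `"peptides"` or `"proteins"`.
#' @return A ggplot object.
#' @export
plot_cell_heatmap <- function(inference, what = c("peptides", "proteins")) {
  what <- match.arg(what)
  df <- if (what == "peptides") {
    inference$observations |> dplyr::count(.data$cell, name = "n")
  } else {
    inference$proteoforms |> dplyr::distinct(.data$cell, .data$proteoform_id) |>
      dplyr::count(.data$cell, name = "n")
  }
  full <- tidyr::expand_grid(row = LETTERS[1:8], col = 1:12) |>
    dplyr::mutate(cell = paste0(.data$row, .data$col)) |>
    dplyr::left_join(df, by = "cell") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  ggplot2::ggplot(full, ggplot2::aes(x = factor(.data$col), y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(LETTERS[1:8])) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "column (pI)", y = "row (MW)", fill = what)
}
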