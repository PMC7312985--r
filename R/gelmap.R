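# Calibrated 96-cell 2DE gel coordinate system.

#' Load and validate a gel-grid calibration
#'
#' Reads a calibration TSV with columns `row_letter`, `col_number`, `pi_lo`,
#' `pi_hi`, `mw_lo_kda`, `mw_hi_kda` and validates the grid: exactly 96 cells
#' (rows A-H x columns 1-12), rows sharing MW bands and columns sharing pI
#' bands, and bands tiling each axis without overlap. Intervals are half-open,
#' lower-inclusive.
#'
#' @param path Path to a calibration TSV. The packaged example grid (a
#'   self-consistent reconstruction around published cell bounds, see the file
#'   header) is available via [example_grid_path()].
#' @return A `gel_grid` tibble with columns `cell`, `row`, `col`, `pi_lo`,
#'   `pi_hi`, `mw_lo`, `mw_hi`.
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("calibration file not found: %s", path))
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("row_letter", "col_number", "pi_lo", "pi_hi", "mw_lo_kda", "mw_hi_kda")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("calibration is missing column(s): ", paste(missing, collapse = ", ")))
  }
  grid <- tibble(
    cell = paste0(raw$row_letter, raw$col_number),
    row = raw$row_letter, col = as.integer(raw$col_number),
    pi_lo = raw$pi_lo, pi_hi = raw$pi_hi,
    mw_lo = raw$mw_lo_kda, mw_hi = raw$mw_hi_kda
  )

  problems <- character()
  if (nrow(grid) != 96) {
    problems <- c(problems, sprintf("expected 96 cells, found %d", nrow(grid)))
  }
  if (anyDuplicated(grid$cell)) problems <- c(problems, "duplicate cell labels")
  if (!setequal(unique(grid$row), LETTERS[1:8]) || !setequal(unique(grid$col), 1:12)) {
    problems <- c(problems, "labels must cover rows A-H and columns 1-12")
  }
  if (any(grid$pi_lo >= grid$pi_hi)) problems <- c(problems, "pI ranges must have lo < hi")
  if (any(grid$mw_lo >= grid$mw_hi)) problems <- c(problems, "MW ranges must have lo < hi")

  shared <- function(df, key, lo, hi) {
    all(tapply(df[[lo]], df[[key]], function(x) length(unique(x)) == 1)) &&
      all(tapply(df[[hi]], df[[key]], function(x) length(unique(x)) == 1))
  }
  if (length(problems) == 0) {
    if (!shared(grid, "col", "pi_lo", "pi_hi")) {
      problems <- c(problems, "cells in one column must share the pI range")
    }
    if (!shared(grid, "row", "mw_lo", "mw_hi")) {
      problems <- c(problems, "cells in one row must share the MW range")
    }
    tiles <- function(lo, hi) {
      o <- order(lo)
      all(abs(hi[o][-length(hi)] - lo[o][-1]) < 1e-9)
    }
    cols <- dplyr::distinct(grid, .data$col, .data$pi_lo, .data$pi_hi)
    rows <- dplyr::distinct(grid, .data$row, .data$mw_lo, .data$mw_hi)
    if (!tiles(cols$pi_lo, cols$pi_hi)) {
      problems <- c(problems, "pI bands must tile the axis without overlap or gaps")
    }
    if (!tiles(rows$mw_lo, rows$mw_hi)) {
      problems <- c(problems, "MW bands must tile the axis without overlap or gaps")
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid gel calibration:\n", paste0("- ", problems, collapse = "\n")))
  }
  class(grid) <- c("gel_grid", class(grid))
  grid
}

#' Path to the packaged example gel calibration
#' @return File path of the example 96-cell calibration TSV.
#' @export
example_grid_path <- function() {
  system.file("extdata", "example_grid.tsv", package = "proteogel")
}

#' Locate a (pI, MW) point on the gel grid
#'
#' Returns the label of the unique cell whose half-open, lower-inclusive
#' ranges contain the point, or `NA` when the point is out of range.
#' Vectorized over points.
#'
#' @param pI Numeric vector of isoelectric points.
#' @param mw_kda Numeric vector of molecular weights in kDa.
#' @param grid A `gel_grid` from [load_grid()].
#' @return Character vector of cell labels (NA = out of range).
#' @export
locate_cell <- function(pI, mw_kda, grid) {
  stopifnot(inherits(grid, "gel_grid"))
  mapply(function(p, m) {
    hit <- grid$cell[p >= grid$pi_lo & p < grid$pi_hi & m >= grid$mw_lo & m < grid$mw_hi]
    if (length(hit) == 1) hit else NA_character_
  }, pI, mw_kda, USE.NAMES = FALSE)
}

cell_bounds <- function(grid, cell) {
  hit <- grid[grid$cell == cell, ]
  if (nrow(hit) != 1) abort(sprintf("unknown gel cell '%s'", cell))
  hit
}

# Geometric MW midpoint: migration is ~log-linear in mass.
cell_midpoint <- function(grid, cell) {
  b <- cell_bounds(grid, cell)
  c(pI = (b$pi_lo + b$pi_hi) / 2, mw = sqrt(b$mw_lo * b$mw_hi))
}

#' Shift vector between theoretical coordinates and an observed cell
#'
#' Computes the displacement from a theoretical (pI, MW) point to the midpoint
#' of an observed gel cell, and categorizes each axis. A category is `"none"`
#' when the theoretical point falls inside the cell expanded by the tolerance
#' (`tol_pi` pH units on pI; `tol_mw` as a fraction of the MW bounds);
#' otherwise the pI axis is `"acidic"`/`"basic"` and the MW axis
#' `"lighter"`/`"heavier"` according to the direction of the observed cell.
#'
#' @param pI,mw_kda Theoretical coordinates.
#' @param cell Observed cell label.
#' @param grid A `gel_grid`.
#' @param tol_pi pI tolerance in pH units (default 0.15).
#' @param tol_mw Relative MW tolerance (default 0.15).
#' @return One-row tibble: `d_pi`, `d_log_mw` (log2 observed/theoretical),
#'   `pi_category`, `mw_category`.
#' @export
shift_vector <- function(pI, mw_kda, cell, grid, tol_pi = 0.15, tol_mw = 0.15) {
  b <- cell_bounds(grid, cell)
  mid <- cell_midpoint(grid, cell)
  d_pi <- unname(mid["pI"] - pI)
  d_log_mw <- unname(log2(mid["mw"] / mw_kda))

  pi_cat <- if (pI >= b$pi_lo - tol_pi && pI <= b$pi_hi + tol_pi) "none"
            else if (d_pi < 0) "acidic" else "basic"
  mw_cat <- if (mw_kda >= b$mw_lo * (1 - tol_mw) && mw_kda <= b$mw_hi * (1 + tol_mw)) "none"
            else if (d_log_mw < 0) "lighter" else "heavier"

  tibble(cell = cell, d_pi = d_pi, d_log_mw = d_log_mw,
         pi_category = pi_cat, mw_category = mw_cat)
}

# TRUE when theoretical point is inside the cell expanded by tolerance.
point_in_cell <- function(pI, mw_kda, bounds, tol_pi = 0.15, tol_mw = 0.15) {
  pI >= bounds$pi_lo - tol_pi & pI <= bounds$pi_hi + tol_pi &
    mw_kda >= bounds$mw_lo * (1 - tol_mw) & mw_kda <= bounds$mw_hi * (1 + tol_mw)
}

# TRUE when two cells are grid neighbours (share an edge or corner).
cells_adjacent <- function(grid, a, b) {
  ba <- cell_bounds(grid, a); bb <- cell_bounds(grid, b)
  abs(match(ba$row, LETTERS) - match(bb$row, LETTERS)) <= 1 &&
    abs(ba$col - bb$col) <= 1 && a != b
}

#' Plot a gel grid
#'
#' Draws the calibrated cell boundaries with pI on the x axis (decreasing
#' column number left to right follows the calibration) and MW on a log y axis.
#'
#' @param object A `gel_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gel_grid <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$pi_lo, xmax = .data$pi_hi,
                   ymin = .data$mw_lo, ymax = .data$mw_hi),
      fill = NA, colour = "grey40", linewidth = 0.2
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$pi_lo + .data$pi_hi) / 2,
                   y = sqrt(.data$mw_lo * .data$mw_hi), label = .data$cell),
      size = 2.5, colour = "grey30"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pI", y = "MW (kDa)")
}
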