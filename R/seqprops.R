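#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap keep
#' @importFrom stringr str_split str_detect str_sub str_count str_replace_all
NULL

# Residue masses (Da). Monoisotopic and average, canonical 20 letters.
.residue_mass <- local({
  mono <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
  avg <- c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
  )
  list(monoisotopic = mono, average = avg,
       water = c(monoisotopic = 18.010565, average = 18.01528))
})

# Modification mass deltas (Da) and the residues each modification may sit on.
.mod_info <- tibble::tribble(
  ~mod,                ~delta_mono, ~delta_avg, ~residues,   ~terminus,
  "phospho",             79.96633,    79.9799,  "STY",       NA,
  "acetyl",              42.01057,    42.0367,  "K",         "N",
  "methyl",              14.01565,    14.0266,  "KR",        NA,
  "amidation_cterm",     -0.98402,    -0.9847,  "",          "C",
  "deamidation",          0.98402,     0.9848,  "NQ",        NA,
  "carbamidomethyl",     57.02146,    57.0513,  "C",         NA,
  "oxidation",           15.99491,    15.9994,  "M",         NA
)

.canonical_aa <- names(.residue_mass$monoisotopic)

#' Validate a protein sequence
#'
#' Checks that a sequence is non-empty and uses only the 20 canonical one-letter
#' amino-acid codes. Ambiguity codes (B, J, O, U, X, Z) and anything else are
#' rejected with an error naming the first offending position.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return Invisibly, `seq` (upper-cased).
#' @export
validate_sequence <- function(seq) {
  if (length(seq) == 0) abort("no sequence supplied")
  seq <- toupper(seq)
  for (i in seq_along(seq)) {
    s <- seq[[i]]
    if (is.na(s) || !nzchar(s)) abort("sequence must be non-empty")
    letters_i <- strsplit(s, "")[[1]]
    bad <- which(!letters_i %in% .canonical_aa)
    if (length(bad) > 0) {
      abort(sprintf(
        "invalid residue '%s' at position %d of sequence %d (only the 20 canonical letters are allowed)",
        letters_i[bad[1]], bad[1], i
      ))
    }
  }
  invisible(seq)
}

#' Construct a modification set
#'
#' A modification set is a tibble with columns `mod` and `pos`. Positions are
#' 1-based residue positions; `amidation_cterm` takes `pos = NA` (it sits on
#' the C-terminal carboxyl), and `acetyl` at `pos = 1` is interpreted as
#' N-terminal acetylation when residue 1 is not lysine.
#'
#' @param mod Character vector of modification names (one of
#'   `r paste(.mod_info$mod, collapse = ", ")`).
#' @param pos Integer vector of residue positions (NA for C-terminal amidation).
#' @return A `modification_set` tibble.
#' @export
modification_set <- function(mod = character(), pos = integer()) {
  if (length(pos) != length(mod)) abort("mod and pos must have equal length")
  out <- tibble(mod = as.character(mod), pos = as.integer(pos))
  unknown <- setdiff(out$mod, .mod_info$mod)
  if (length(unknown) > 0) {
    abort(paste0("unknown modification(s): ", paste(unknown, collapse = ", ")))
  }
  class(out) <- c("modification_set", class(out))
  out
}

# Checks mod/residue compatibility against one sequence; errors on violation.
validate_mods <- function(seq, mods) {
  if (is.null(mods) || nrow(mods) == 0) return(invisible(NULL))
  seq <- validate_sequence(seq)
  n <- nchar(seq)
  res <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(mods))) {
    m <- mods$mod[i]; p <- mods$pos[i]
    info <- .mod_info[.mod_info$mod == m, ]
    if (m == "amidation_cterm") {
      if (!is.na(p) && p != n) abort("amidation_cterm applies to the C-terminus (pos NA or sequence length)")
      next
    }
    if (is.na(p) || p < 1 || p > n) {
      abort(sprintf("modification %s position %s outside sequence length %d", m, p, n))
    }
    allowed <- strsplit(info$residues, "")[[1]]
    ok <- res[p] %in% allowed || (m == "acetyl" && p == 1)  # N-terminal acetyl
    if (!ok) {
      abort(sprintf("modification %s not compatible with residue %s at position %d", m, res[p], p))
    }
  }
  invisible(NULL)
}

#' Molecular mass of a protein sequence
#'
#' Sum of residue masses plus one water, plus modification deltas. Vectorized
#' over sequences when `mods` is NULL.
#'
#' @param seq Character vector of sequences.
#' @param kind `"average"` or `"monoisotopic"`.
#' @param mods Optional [modification_set()] (single sequence only).
#' @return Numeric vector of masses in Da.
#' @examples
#' molecular_mass("G", "monoisotopic")  # 75.032
#' @export
molecular_mass <- function(seq, kind = c("average", "monoisotopic"), mods = NULL) {
  kind <- match.arg(kind)
  seq <- validate_sequence(seq)
  tab <- .residue_mass[[kind]]
  base <- vapply(seq, function(s) {
    sum(tab[strsplit(s, "")[[1]]]) + .residue_mass$water[[kind]]
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(mods) && nrow(mods) > 0) {
    if (length(seq) != 1) abort("mods are supported for a single sequence at a time")
    validate_mods(seq, mods)
    dcol <- if (kind == "monoisotopic") "delta_mono" else "delta_avg"
    deltas <- .mod_info[[dcol]][match(mods$mod, .mod_info$mod)]
    base <- base + sum(deltas)
  }
  base
}

#' Fraction of a given residue in a sequence
#'
#' @param seq Character vector of sequences.
#' @param letter Single one-letter residue code.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
residue_fraction <- function(seq, letter) {
  seq <- validate_sequence(seq)
  letter <- toupper(letter)
  if (!letter %in% .canonical_aa) abort("letter must be a canonical residue code")
  str_count(seq, stringr::fixed(letter)) / nchar(seq)
}

# ---- pKa tables -------------------------------------------------------------

#' Load a pKa table
#'
#' The default table is the Bjellqvist set: residue-specific N-terminal pKa
#' values, a common C-terminal carboxyl pKa (with side-chain adjustments for
#' C-terminal Asp/Glu), and side-chain pKa values for D, E, C, Y (acidic) and
#' H, K, R (basic). A custom table may be supplied as a TSV with columns
#' `group`, `key`, `pka`, `charge` where `group` is one of `nterm`, `cterm`,
#' `sidechain`, `cterm_sidechain`.
#'
#' @param name Built-in table name (currently `"bjellqvist"`) or a file path.
#' @return A `pka_table` list.
#' @export
pka_table <- function(name = "bjellqvist") {
  path <- if (file.exists(name)) name else {
    system.file("extdata", paste0("pka_", name, ".tsv"), package = "proteogel")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("no pKa table named or located at '%s'", name))
  }
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("group", "key", "pka", "charge") %in% names(raw)))
  if (any(raw$pka <= 0 | raw$pka >= 14)) abort("pKa values must lie in (0, 14)")
  bad <- raw$group == "sidechain" &
    ((raw$charge > 0 & raw$key %in% c("D", "E", "C", "Y")) |
     (raw$charge < 0 & raw$key %in% c("K", "R", "H")))
  if (any(bad)) abort("acidic and basic side-chain groups must be disjoint")
  out <- list(name = basename(path), table = as_tibble(raw))
  class(out) <- "pka_table"
  out
}

# Ionizable-group inventory for one sequence + mods: tibble(pka, charge, n).
# This is the single source of truth for both net_charge and isoelectric_point.
charge_groups <- function(seq, pka = pka_table(), mods = NULL) {
  seq <- validate_sequence(seq)
  validate_mods(seq, mods)
  tab <- pka$table
  res <- strsplit(seq, "")[[1]]
  n <- length(res)

  get1 <- function(group, key) {
    hit <- tab[tab$group == group & tab$key == key, ]
    if (nrow(hit) == 0 && group == "nterm") hit <- tab[tab$group == "nterm" & tab$key == "default", ]
    hit
  }

  rows <- list()
  add <- function(pka_v, charge_v, count = 1L) {
    if (count > 0) rows[[length(rows) + 1]] <<- tibble(pka = pka_v, charge = charge_v, n = count)
  }

  modded_pos <- function(name) {
    if (is.null(mods) || nrow(mods) == 0) integer() else mods$pos[mods$mod == name]
  }
  has_mod <- function(name) {
    !is.null(mods) && nrow(mods) > 0 && name %in% mods$mod
  }

  # N-terminal amine: removed by N-terminal acetylation.
  nterm_acetylated <- 1L %in% modded_pos("acetyl") && res[1] != "K"
  if (!nterm_acetylated) {
    hit <- get1("nterm", res[1])
    add(hit$pka[1], +1)
  }

  # C-terminal carboxyl: removed by amidation.
  if (!has_mod("amidation_cterm")) {
    add(get1("cterm", "default")$pka[1], -1)
  }

  # Side chains. C-terminal D/E get their own pKa when present in the table.
  acet_k <- modded_pos("acetyl")          # acetylated lysines lose the amine
  cam_c  <- modded_pos("carbamidomethyl") # blocked cysteines lose the thiol
  for (letter in c("D", "E", "C", "Y", "H", "K", "R")) {
    pos <- which(res == letter)
    if (letter == "K") pos <- setdiff(pos, acet_k)
    if (letter == "C") pos <- setdiff(pos, cam_c)
    if (length(pos) == 0) next
    if (letter %in% c("D", "E")) {
      ct <- get1("cterm_sidechain", letter)
      if (nrow(ct) > 0 && n %in% pos) {
        add(ct$pka[1], -1)
        pos <- setdiff(pos, n)
      }
    }
    hit <- tab[tab$group == "sidechain" & tab$key == letter, ]
    if (nrow(hit) > 0) add(hit$pka[1], hit$charge[1], length(pos))
  }

  # Modification-introduced groups.
  add(6.5, -1, length(modded_pos("phospho")))       # second phosphate ionization
  add(4.05, -1, length(modded_pos("deamidation")))  # new carboxyl

  dplyr::bind_rows(rows)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: cationic groups contribute
#' `1 / (1 + 10^(pH - pKa))`, anionic groups `-1 / (1 + 10^(pKa - pH))`.
#' Modifications alter the group inventory: phosphorylation adds an acidic
#' group (pKa 6.5), acetylation removes the modified amine, C-terminal
#' amidation removes the terminal carboxyl, deamidation adds a side-chain
#' carboxyl (pKa 4.05), methylation leaves the inventory unchanged, and
#' carbamidomethylation removes the cysteine thiol.
#'
#' @param seq Single protein sequence.
#' @param pH Numeric vector of pH values in `[0, 14]`.
#' @param pka A [pka_table()].
#' @param mods Optional [modification_set()].
#' @return Numeric vector of net charges, one per pH.
#' @export
net_charge <- function(seq, pH, pka = pka_table(), mods = NULL) {
  if (any(pH < 0 | pH > 14)) abort("pH must lie within [0, 14]")
  groups <- charge_groups(seq, pka, mods)
  vapply(pH, function(p) {
    pos <- groups$charge > 0
    sum(groups$n[pos] / (1 + 10^(p - groups$pka[pos]))) -
      sum(groups$n[!pos] / (1 + 10^(groups$pka[!pos] - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` at which the net charge vanishes. The charge is
#' monotone non-increasing in pH, so the zero is unique; bisection stops when
#' `|charge| < tol`.
#'
#' @inheritParams net_charge
#' @param tol Charge tolerance for convergence (default 1e-4).
#' @return The isoelectric point (pH units).
#' @examples
#' isoelectric_point("AAAA")  # (N-terminal pKa of A + C-terminal pKa) / 2
#' @export
isoelectric_point <- function(seq, pka = pka_table(), mods = NULL, tol = 1e-4) {
  groups <- charge_groups(seq, pka, mods)
  chg <- function(p) {
    pos <- groups$charge > 0
    sum(groups$n[pos] / (1 + 10^(p - groups$pka[pos]))) -
      sum(groups$n[!pos] / (1 + 10^(groups$pka[!pos] - p)))
  }
  lo <- 0; hi <- 14
  c_lo <- chg(lo); c_hi <- chg(hi)
  if (c_lo < 0) return(lo)   # all-acidic edge case
  if (c_hi > 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    c_mid <- chg(mid)
    if (abs(c_mid) < tol) return(mid)
    if (c_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
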