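# Concordance, the shift taxonomy, group resolution, and whole-experiment
# annotation.

test_that("theoretical coordinates reproduce the HSPB1 worked example", {
  prot <- load_reference_proteins()
  th <- theoretical_coords(prot[["P04792"]])
  expect_equal(th$pi, 5.98, tolerance = 0.05)
  expect_equal(round(th$mw_kda), 23)

  sty <- gregexpr("[STY]", prot[["P04792"]])[[1]]
  th3 <- theoretical_coords(prot[["P04792"]],
                            modification_set(rep("phospho", 3), sty[1:3]))
  expect_lt(th3$pi, th$pi)

  # empty hypothesis equals the plain calculators
  expect_equal(th$mw_kda, molecular_mass(prot[["P04792"]], "average") / 1000)
  expect_equal(th$pi, isoelectric_point(prot[["P04792"]]))
})

test_that("concordance separates own-cell, boundary, and discordant hits", {
  grid <- example_grid()
  # point well inside E5
  conc <- concordance(6.5, 45, c("E5"), grid)
  expect_equal(conc$status, "concordant")
  expect_false(conc$boundary_artifact)

  # point just across the E5/E4 boundary, observed in E5: boundary artifact
  conc_b <- concordance(6.93, 45, c("E5"), grid)
  expect_equal(conc_b$status, "concordant")
  expect_true(conc_b$boundary_artifact)

  # two rows lighter: discordant
  conc_d <- concordance(6.5, 45, c("G5"), grid)
  expect_equal(conc_d$status, "discordant")
})

test_that("an acidic shift with an observed phosphopeptide is an acidic PTM", {
  grid <- example_grid()
  prot <- load_reference_proteins()
  hspb1 <- prot[["P04792"]]
  th <- theoretical_coords(hspb1)
  sh <- shift_vector(th$pi, th$mw_kda, "C8", grid)   # wrong MW row but acidic column
  expect_equal(sh$pi_category, "acidic")

  res <- classify_shift(hspb1, sh, grid, observed_mods = "phospho")
  expect_equal(res$explanation[1], "acidic_PTM")
  expect_match(res$note[1], "observed")

  # hypothesized path: no observed modification, k phosphates reproduce the pI
  res2 <- classify_shift(hspb1, sh, grid)
  expect_true("acidic_PTM" %in% res2$explanation)
  expect_match(res2$note[res2$explanation == "acidic_PTM"][1], "phosphates")
})

test_that("a lighter shift with terminal peptides is proteolysis", {
  withr::with_seed(501, {
    s <- rand_seq(545)                       # ~60 kDa
    grid <- example_grid()
    th <- theoretical_coords(s)
    d <- digest(s)
    nterm <- d[d$end <= 180, ]               # ~20 kDa N-terminal region
    cell <- locate_cell(th$pi, 20, grid)
    sh <- shift_vector(th$pi, th$mw_kda, cell, grid)
    expect_equal(sh$mw_category, "lighter")
    res <- classify_shift(s, sh, grid, cell_peptides = nterm)
    expect_equal(res$explanation[1], "proteolysis")
    expect_match(res$note[1], "N-terminus")

    # peptides densely covering the whole chain cannot come from one fragment
    res_full <- classify_shift(s, sh, grid, cell_peptides = d)
    expect_false("proteolysis" %in% res_full$explanation)
  })
})

test_that("a heavier shift with a co-identified partner is a complex", {
  withr::with_seed(502, {
    a <- rand_seq(320)                       # ~35 kDa
    b_mass <- 61
    grid <- example_grid()
    th <- theoretical_coords(a)
    total <- th$mw_kda + b_mass              # ~96 kDa -> row B
    cell <- locate_cell(th$pi, total, grid)
    sh <- shift_vector(th$pi, th$mw_kda, cell, grid)
    expect_equal(sh$mw_category, "heavier")

    res <- classify_shift(
      a, sh, grid, partners = "GPB",
      co_identified = tibble::tibble(id = "GPB|T0|-", gene = "GPB", mw_kda = b_mass)
    )
    expect_equal(res$explanation[1], "complex_or_oligomer")
    expect_match(res$note[1], "partner")

    # no partner table evidence: the complex rule stays silent
    res_np <- classify_shift(a, sh, grid)
    expect_false("complex_or_oligomer" %in% res_np$explanation)

    # self-interacting proteins may explain the shift as a homo-oligomer
    cell2 <- locate_cell(th$pi, 2 * th$mw_kda, grid)
    sh2 <- shift_vector(th$pi, th$mw_kda, cell2, grid)
    res_homo <- classify_shift(a, sh2, grid, self_interacting = TRUE)
    expect_equal(res_homo$explanation[1], "complex_or_oligomer")
    expect_match(res_homo$note[1], "homo-oligomer")
  })
})

test_that("basic shifts invoke amidation/methylation; proline explains heavier runs", {
  grid <- example_grid()
  withr::with_seed(503, {
    s <- rand_seq(150)
    th <- theoretical_coords(s)
    basic_cell <- grid$cell[grid$pi_lo > th$pi + 1 & grid$mw_lo <= th$mw_kda &
                              grid$mw_hi > th$mw_kda][1]
    sh <- shift_vector(th$pi, th$mw_kda, basic_cell, grid)
    expect_equal(sh$pi_category, "basic")
    res <- classify_shift(s, sh, grid, observed_mods = c("amidation_cterm", "methyl"))
    expect_equal(res$explanation[1], "basic_PTM")

    # proline-rich protein observed one row heavier, no partner evidence
    p_rich <- paste0(rand_seq(200), paste(rep("P", 40), collapse = ""))
    thp <- theoretical_coords(p_rich)
    heavy_cell <- grid$cell[grid$mw_lo > thp$mw_kda * 1.3 &
                              grid$mw_lo < thp$mw_kda * 2 &
                              grid$pi_lo <= thp$pi & grid$pi_hi > thp$pi][1]
    shp <- shift_vector(thp$pi, thp$mw_kda, heavy_cell, grid)
    expect_equal(shp$mw_category, "heavier")
    resp <- classify_shift(p_rich, shp, grid)
    expect_equal(resp$explanation[1], "proline_retardation")

    # the same shift on a proline-poor protein stays unexplained
    lean <- rand_seq(240)
    if (residue_fraction(lean, "P") > 0.10) lean <- gsub("P", "A", lean)
    thl <- theoretical_coords(lean)
    heavy_cell2 <- grid$cell[grid$mw_lo > thl$mw_kda * 1.3 &
                               grid$mw_lo < thl$mw_kda * 2 &
                               grid$pi_lo <= thl$pi & grid$pi_hi > thl$pi][1]
    shl <- shift_vector(thl$pi, thl$mw_kda, heavy_cell2, grid)
    resl <- classify_shift(lean, shl, grid)
    expect_false("proline_retardation" %in% resl$explanation)
  })
})

test_that("no explanation ever contradicts the shift's axis categories", {
  grid <- example_grid()
  axis_of <- c(proteolysis = "mw", complex_or_oligomer = "mw",
               proline_retardation = "mw", acidic_PTM = "pi", basic_PTM = "pi")
  withr::with_seed(504, {
    for (i in 1:30) {
      s <- rand_seq(sample(100:600, 1))
      th <- theoretical_coords(s)
      cell <- sample(grid$cell, 1)
      sh <- shift_vector(th$pi, th$mw_kda, cell, grid)
      res <- classify_shift(s, sh, grid,
                            observed_mods = sample(c("phospho", "methyl", ""), 1),
                            self_interacting = sample(c(TRUE, FALSE), 1))
      for (ex in res$explanation) {
        if (axis_of[[ex]] == "mw") {
          want <- if (ex == "proteolysis") "lighter" else "heavier"
          expect_equal(sh$mw_category, want)
        } else {
          want <- if (ex == "acidic_PTM") "acidic" else "basic"
          expect_equal(sh$pi_category, want)
        }
      }
    }
  })
})

test_that("groups resolve to the single member matching the cell coordinates", {
  grid <- example_grid()
  withr::with_seed(505, {
    lens <- c(120, 240, 480, 840, 960)
    members <- tibble::tibble(
      proteoform_id = sprintf("GX|T%d|-", seq_along(lens)),
      sequence = vapply(lens, rand_seq, character(1)),
      category = c("canonical", rep("splice", 4))
    )
    th3 <- theoretical_coords(members$sequence[3])
    cell <- locate_cell(th3$pi, th3$mw_kda, grid)
    res <- resolve_group(members, cell, grid)
    expect_equal(res$status, "resolved")
    expect_equal(res$resolved_id, "GX|T3|-")

    # canonical + SAP: same length, near-identical coordinates
    s <- rand_seq(300)
    sap <- sub("G", "A", s)
    pair <- tibble::tibble(
      proteoform_id = c("GY|T0|-", "GY|T0|E1"),
      sequence = c(s, sap), category = c("canonical", "SAP")
    )
    res2 <- resolve_group(pair, locate_cell(theoretical_coords(s)$pi,
                                            theoretical_coords(s)$mw_kda, grid), grid)
    expect_equal(res2$status, "unresolvable_by_coordinates")

    # no member fits: unresolved with a reason
    res3 <- resolve_group(members, "H12", grid)
    expect_equal(res3$status, "unresolved")
    expect_match(res3$reason, "no member")
  })
})

test_that("an event-free simulated experiment annotates 100% concordant", {
  fx <- small_sim(seed = 61, n_genes = 10,
                  inject = c(phospho = 0, proteolysis = 0, complex = 0, basic_PTM = 0))
  inf <- infer_experiment(fx$sim$observations, fx$index)
  ann <- suppressMessages(annotate_experiment(inf, fx$lib, fx$grid))
  in_grid <- !ann$subjects$proteoform_id %in%
    fx$sim$truth$proteoforms$proteoform_id[fx$sim$truth$proteoforms$edge_flag]
  expect_true(all(ann$subjects$status[in_grid] == "concordant"))
  # every subject receives exactly one row; counts partition subjects
  expect_equal(anyDuplicated(ann$subjects$proteoform_id), 0)
  expect_equal(sum(ann$summary$by_status$n), nrow(ann$subjects))
})

test_that("a native-plus-fragment proteoform yields one concordant cell and one proteolysis call", {
  fx <- small_sim(seed = 62, n_genes = 16,
                  inject = c(phospho = 0, proteolysis = 0.3, complex = 0, basic_PTM = 0))
  ev <- fx$sim$truth$events
  expect_gt(nrow(ev), 0)
  inf <- infer_experiment(fx$sim$observations, fx$index)
  ann <- suppressMessages(annotate_experiment(inf, fx$lib, fx$grid,
                                              fx$sim$partner_table))
  for (i in seq_len(nrow(ev))) {
    rows <- ann$cells[ann$cells$proteoform_id == ev$proteoform_id[i], ]
    expect_true(any(rows$status == "concordant"))
    frag <- rows[rows$cell == ev$cell[i], ]
    expect_equal(frag$explanation, "proteolysis")
    # the subject is still counted once
    expect_equal(sum(ann$subjects$proteoform_id == ev$proteoform_id[i]), 1)
  }
})
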