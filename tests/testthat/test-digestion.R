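# Tryptic digestion, the I/L-collapsed peptide index, and specificity classes.

# Independent brute-force oracle: enumerate boundary pairs directly.
brute_digest <- function(seq, max_missed = 1, min_len = 1, max_len = Inf,
                         proline_rule = TRUE) {
  res <- strsplit(seq, "")[[1]]; n <- length(res)
  is_site <- vapply(seq_len(n - 1), function(i) {
    res[i] %in% c("K", "R") && !(proline_rule && res[i + 1] == "P")
  }, logical(1))
  bounds <- c(0, which(is_site), n)
  out <- character()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in (i + 1):length(bounds)) {
      if (j - i - 1 > max_missed) break
      s <- bounds[i] + 1; e <- bounds[j]
      len <- e - s + 1
      if (len >= min_len && len <= max_len) {
        out <- c(out, substr(seq, s, e))
      }
    }
  }
  sort(out)
}

test_that("digest handles chains without cleavage sites and the proline rule", {
  d <- digest("AAAAAAAAAA")
  expect_equal(nrow(d), 1)
  expect_equal(d$peptide, "AAAAAAAAAA")

  d0 <- digest("AKRPGK", min_len = 1, max_len = Inf)
  expect_setequal(d0$peptide[d0$missed == 0], c("AK", "RPGK"))   # no cleavage before P
  expect_equal(nrow(digest("AKRPGK")), 0)                        # all < 9 aa

  d_np <- digest("AKRPGK", min_len = 1, max_len = Inf, proline_rule = FALSE)
  expect_setequal(d_np$peptide[d_np$missed == 0], c("AK", "R", "PGK"))
})

test_that("digest products match the brute-force cleavage oracle", {
  withr::with_seed(201, {
    for (i in 1:40) {
      s <- rand_seq(sample(15:250, 1))
      got <- sort(digest(s, min_len = 1, max_len = Inf)$peptide)
      expect_equal(got, brute_digest(s))
      gotf <- sort(digest(s)$peptide)
      expect_equal(gotf, brute_digest(s, min_len = 9, max_len = 25))
    }
  })
})

test_that("digest positions are 1-based and consistent with the sequence", {
  withr::with_seed(202, {
    s <- rand_seq(120)
    d <- digest(s, min_len = 1, max_len = Inf)
    expect_true(all(substring(s, d$start, d$end) == d$peptide))
  })
})

test_that("digesting across a K junction preserves the parts' products", {
  withr::with_seed(203, {
    a <- paste0(rand_seq(40), "K")
    b <- rand_seq(40)
    if (substr(b, 1, 1) == "P") b <- paste0("A", substr(b, 2, 40))
    concat <- paste0(a, b)
    pa <- digest(a, min_len = 1, max_len = Inf)$peptide
    pb <- digest(b, min_len = 1, max_len = Inf)$peptide
    pc <- digest(concat, min_len = 1, max_len = Inf)$peptide
    expect_true(all(pa %in% pc))
    expect_true(all(pb %in% pc))
  })
})

test_that("identical sequences under two ids share every peptide parent", {
  lib <- tibble::tibble(
    proteoform_id = c("G1|T1|-", "G1|T2|-"), gene_id = "G1",
    backbone_id = c("T1", "T2"), backbone_kind = "canonical",
    category = "canonical", events = "-",
    sequence = "MKTAYRAAGGKLLPWIDEKSAVTRMNPQHERFFKGGATLYK",
    all_ids = NA, is_contaminant = FALSE
  )
  idx <- build_peptide_index(lib)
  expect_true(all(lengths(idx$parents) == 2))
  expect_false(any(idx$proteotypic))

  idx1 <- build_peptide_index(lib[1, ])
  expect_true(all(idx1$proteotypic))
})

test_that("index parent sets equal a quadratic digest-membership scan", {
  withr::with_seed(204, {
    lib <- tibble::tibble(
      proteoform_id = sprintf("G%d|T|-", 1:10), gene_id = sprintf("G%d", 1:10),
      backbone_id = "T", backbone_kind = "canonical", category = "canonical",
      events = "-", sequence = replicate(10, rand_seq(sample(60:150, 1))),
      all_ids = NA, is_contaminant = FALSE
    )
    # share a block between records 1 and 2 so some peptides are shared
    lib$sequence[2] <- paste0(substr(lib$sequence[1], 1, 60), rand_seq(50))
    idx <- build_peptide_index(lib)
    digs <- lapply(lib$sequence, function(s) unique(il_key(digest(s)$peptide)))
    for (row in sample(nrow(idx), 25)) {
      key <- idx$il_key[row]
      oracle_parents <- lib$proteoform_id[vapply(digs, function(d) key %in% d, logical(1))]
      expect_setequal(idx$parents[[row]], oracle_parents)
    }
  })
})

test_that("specificity classes follow parent-set cardinality with I/L equivalence", {
  lib <- tibble::tibble(
    proteoform_id = c("G1|T0|-", "G1|T1|-", "G2|T0|-"),
    gene_id = c("G1", "G1", "G2"),
    backbone_id = c("T0", "T1", "T0"), backbone_kind = "canonical",
    category = c("canonical", "splice", "canonical"), events = "-",
    sequence = c("MPEPTIDEIKAAAGGGWWWR" ,
                 "MPEPTIDELKAAAGGGWWWR",            # I/L variant of the same peptide
                 "MNNNNDDDDEEEEQQQWWwR"),
    all_ids = NA, is_contaminant = FALSE
  )
  lib$sequence <- toupper(lib$sequence)
  idx <- build_peptide_index(lib)

  expect_equal(il_key("PEPTIDEIK"), il_key("PEPTIDELK"))
  c1 <- classify_peptide("MPEPTIDEIK", idx)
  c2 <- classify_peptide("MPEPTIDELK", idx)
  expect_equal(c1$class, "gene_specific")   # maps to both G1 backbones, one gene
  expect_equal(c1$class, c2$class)

  c3 <- classify_peptide("MNNNNDDDDEEEEQQQWWWR", idx)
  expect_equal(c3$class, "proteotypic")

  expect_error(classify_peptide("NOTINTHELIBRARYK", idx), "absent from the index")
})

test_that("adding a SAP variant never makes a shared peptide proteotypic", {
  withr::with_seed(205, {
    base <- tibble::tibble(
      proteoform_id = c("G1|T0|-", "G2|T0|-"), gene_id = c("G1", "G2"),
      backbone_id = "T0", backbone_kind = "canonical", category = "canonical",
      events = "-", sequence = c(rand_seq(150), rand_seq(150)),
      all_ids = NA, is_contaminant = FALSE
    )
    sap_seq <- base$sequence[1]
    substr(sap_seq, 75, 75) <- if (substr(sap_seq, 75, 75) == "G") "A" else "G"
    extended <- dplyr::bind_rows(base, tibble::tibble(
      proteoform_id = "G1|T0|E1", gene_id = "G1", backbone_id = "T0",
      backbone_kind = "canonical", category = "SAP", events = "E1",
      sequence = sap_seq, all_ids = NA, is_contaminant = FALSE
    ))
    idx1 <- build_peptide_index(base)
    idx2 <- build_peptide_index(extended)
    joined <- match(idx1$il_key, idx2$il_key)
    expect_false(anyNA(joined))
    expect_true(all(idx2$n_parents[joined] >= idx1$n_parents))
  })
})

test_that("the index round-trips through TSV", {
  lib <- enumerate_proteoforms(toy_transcripts(), toy_events())
  idx <- build_peptide_index(lib, min_len = 5, max_len = 30)
  path <- tempfile(fileext = ".tsv")
  write_index(idx, path)
  back <- read_index(path)
  expect_equal(back$il_key, idx$il_key)
  expect_equal(back$parents, idx$parents)
  expect_equal(back$proteotypic, idx$proteotypic)
})
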