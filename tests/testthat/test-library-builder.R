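# Expression filtering, combinatorial enumeration, FASTA round-trips, stats.

test_that("expression filter applies threshold, CV and review status", {
  tr <- tibble::tibble(
    gene_id = paste0("G", 1:5), transcript_id = paste0("T", 1:5),
    kind = "canonical", sequence = "MKTAYR", reviewed = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    fpkm = list(c(0.05, 0.05, 0.05),   # below threshold everywhere
                c(1, 1, 1),            # CV = 0, kept
                c(1, 3, 5),            # high CV
                c(2, 2, 2),            # unreviewed
                c(0.05, 2, 2))         # above threshold in 2 of 3 runs, low CV? no: CV high
  )
  # independent CV oracle on the printed triplet
  expect_equal(sd(c(1, 3, 5)) / mean(c(1, 3, 5)), 0.6666, tolerance = 1e-3)
  kept <- filter_transcripts(tr)
  expect_equal(kept$transcript_id, "T2")

  # order preserved for multiple passing records
  tr2 <- tr[c(2, 2, 2), ]
  tr2$transcript_id <- c("a", "b", "c")
  expect_equal(filter_transcripts(tr2)$transcript_id, c("a", "b", "c"))

  tr$fpkm[[1]] <- numeric()
  expect_error(filter_transcripts(tr), "zero expression runs")
})

test_that("single-event enumeration applies each compatible event alone", {
  tr <- toy_transcripts()[3, ]       # one backbone, no events
  lib0 <- enumerate_proteoforms(tr, NULL)
  expect_equal(nrow(lib0), 1)
  expect_equal(lib0$category, "canonical")

  tr <- tibble::tibble(gene_id = "G9", transcript_id = "G9_T0", kind = "canonical",
                       sequence = "MKTAYR", reviewed = TRUE, fpkm = list(c(1, 1, 1)))
  ev <- tibble::tibble(gene_id = "G9", event_id = "E1", kind = "SAP", pos = 3L,
                       ref = "T", alt = "S", backbones = "G9_T0")
  lib <- enumerate_proteoforms(tr, ev)
  expect_equal(nrow(lib), 2)
  expect_equal(lib$sequence[lib$category == "SAP"], "MKSAYR")

  ev_bad <- ev; ev_bad$ref <- "A"
  expect_error(enumerate_proteoforms(tr, ev_bad), "ref mismatch.*G9.*position 3")
})

test_that("indel coordinates re-map: downstream events keep backbone coordinates", {
  # DEL at 3-4 then SAP at 8 must hit the residue that sat at 8 originally
  seq <- "ABCDEFGH"
  seq <- "MKTAYRGW"
  tr <- tibble::tibble(gene_id = "G", transcript_id = "T", kind = "canonical",
                       sequence = seq, reviewed = TRUE, fpkm = list(c(1, 1, 1)))
  ev <- tibble::tibble(
    gene_id = "G", event_id = c("E_del", "E_sap"),
    kind = c("DEL", "SAP"), pos = c(3L, 8L),
    ref = c("TA", "W"), alt = c("", "C"), backbones = "T"
  )
  lib <- enumerate_proteoforms(tr, ev, policy = "paired")
  paired <- lib[grepl("\\+", lib$events), ]
  # explicit string-edit oracle: substitute at 8 first, then cut 3-4
  oracle <- paste0(substr("MKTAYRGC", 1, 2), substr("MKTAYRGC", 5, 8))
  expect_equal(paired$sequence, oracle)
})

test_that("overlapping events in one combination are skipped with a warning", {
  tr <- tibble::tibble(gene_id = "G", transcript_id = "T", kind = "canonical",
                       sequence = "MKTAYRGW", reviewed = TRUE, fpkm = list(c(1, 1, 1)))
  ev <- tibble::tibble(
    gene_id = "G", event_id = c("E_sap", "E_del"),
    kind = c("SAP", "DEL"), pos = c(3L, 2L),
    ref = c("T", "KT"), alt = c("S", ""), backbones = "T"
  )
  expect_warning(lib <- enumerate_proteoforms(tr, ev, policy = "paired"),
                 "overlapping")
  expect_false(any(grepl("\\+", lib$events)))
})

test_that("a SAP and its inverse restore the backbone sequence", {
  tr <- tibble::tibble(gene_id = "G", transcript_id = "T", kind = "canonical",
                       sequence = "MKTAYR", reviewed = TRUE, fpkm = list(c(1, 1, 1)))
  ev <- tibble::tibble(gene_id = "G", event_id = "E1", kind = "SAP", pos = 3L,
                       ref = "T", alt = "S", backbones = "T")
  v1 <- enumerate_proteoforms(tr, ev)
  variant <- v1[v1$category == "SAP", ]
  tr2 <- tibble::tibble(gene_id = "G", transcript_id = "T", kind = "canonical",
                        sequence = variant$sequence, reviewed = TRUE,
                        fpkm = list(c(1, 1, 1)))
  ev2 <- tibble::tibble(gene_id = "G", event_id = "E1r", kind = "SAP", pos = 3L,
                        ref = "S", alt = "T", backbones = "T")
  v2 <- enumerate_proteoforms(tr2, ev2)
  expect_equal(v2$sequence[v2$category == "SAP"], tr$sequence)
})

test_that("a giant gene with 9 backbones, 8 SAPs and 9 indels yields >= 150 records", {
  gg <- make_giant_gene()
  lib <- enumerate_proteoforms(gg$transcripts, gg$events)
  expect_gte(nrow(lib), 150)
  expect_gte(library_stats(lib)$per_gene$n[1], 150)
  # every record traces to exactly one backbone
  expect_true(all(lib$backbone_id %in% gg$transcripts$transcript_id))
})

test_that("duplicate sequences collapse keeping all provenance ids", {
  tr <- tibble::tibble(
    gene_id = "G", transcript_id = c("T1", "T2"), kind = "canonical",
    sequence = "MKTAYRPGW", reviewed = TRUE,
    fpkm = list(c(1, 1, 1), c(1, 1, 1))
  )
  lib <- enumerate_proteoforms(tr, NULL)
  expect_equal(nrow(lib), 1)
  expect_match(lib$all_ids, "T1")
  expect_match(lib$all_ids, "T2")
})

test_that("library FASTA round-trips headers and categories", {
  gg <- make_giant_gene()
  lib <- enumerate_proteoforms(gg$transcripts, gg$events)
  path <- tempfile(fileext = ".fasta")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(nrow(back), nrow(lib))
  expect_equal(dplyr::count(back, category), dplyr::count(lib, category))
  expect_equal(back$sequence, lib$sequence)
  expect_equal(back$proteoform_id, lib$proteoform_id)

  dup <- dplyr::bind_rows(lib[1, ], lib[1, ])
  expect_error(write_library(dup, tempfile()), "duplicate proteoform_id")
})

test_that("contaminants are appended with the reserved prefix", {
  cont <- tempfile(fileext = ".fasta")
  writeLines(c(">TRYP_PIG trypsin", "MKTAYIAKQRQISFVK",
               ">K1C10_HUMAN keratin", "MSVRYSSSKHYSSSRSGGGGGGGC"), cont)
  empty <- enumerate_proteoforms(toy_transcripts()[0, ], NULL)
  path <- tempfile(fileext = ".fasta")
  write_library(empty, path, contaminants_fasta = cont)
  back <- read_library(path)
  expect_equal(nrow(back), 2)
  expect_true(all(back$is_contaminant))
  expect_true(all(startsWith(back$proteoform_id, "CONT_")))
})

test_that("library stats partition records and report per-gene means", {
  one <- enumerate_proteoforms(toy_transcripts()[3, ], NULL)
  st <- library_stats(one)
  expect_equal(st$by_category$n, 1)
  expect_equal(st$by_category$category, "canonical")
  expect_equal(st$mean_per_gene, 1)

  gg <- make_giant_gene()
  lib <- enumerate_proteoforms(gg$transcripts, gg$events)
  st <- library_stats(lib)
  expect_equal(sum(st$by_category$n), st$n_records)       # counts partition
  expect_equal(st$mean_per_gene, st$n_records / st$n_genes)
})
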