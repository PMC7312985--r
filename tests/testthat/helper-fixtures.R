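# Shared fixtures built in code.

aa20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

rand_seq <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# Bundled canonical sequences used by the worked examples.
load_reference_proteins <- function() {
  fa <- Biostrings::readAAStringSet(
    system.file("extdata", "uniprot_sequences.fasta", package = "proteogel")
  )
  s <- as.character(fa)
  names(s) <- sub("sp\\|([^|]+)\\|.*", "\\1", names(fa))
  s
}

toy_transcripts <- function() {
  tibble::tibble(
    gene_id = c("G1", "G1", "G2"),
    transcript_id = c("G1_T0", "G1_T1", "G2_T0"),
    kind = c("canonical", "splice", "canonical"),
    sequence = c(
      "MKTAYRAAGGKLLPWIDEKSAVTRMNPQHERFFKGGATLYKPESDVRWK",
      "MKTAYRAAGGKLLPWIDEKSAVTRK",
      "MNPEWQKHSTVILRAGGADKYYQCRLMFEPTKWDDNSAK"
    ),
    reviewed = TRUE,
    fpkm = list(c(1, 1.1, 0.9), c(2, 2.2, 1.8), c(5, 5.5, 4.5))
  )
}

toy_events <- function() {
  tibble::tibble(
    gene_id = c("G1", "G1"),
    event_id = c("G1_E1", "G1_E2"),
    kind = c("SAP", "DEL"),
    pos = c(3L, 8L),
    ref = c("T", "AG"),
    alt = c("S", ""),
    backbones = c("G1_T0;G1_T1", "G1_T0")
  )
}

# A giant-gene fixture: nine splice backbones, eight SAPs, nine indels, all
# mutually compatible and non-overlapping.
make_giant_gene <- function(seed = 7, len = 600) {
  withr::with_seed(seed, {
    canon <- rand_seq(len)
    tids <- sprintf("PLEC_T%d", 1:9)
    seqs <- vapply(1:9, function(i) {
      blk <- 300 + (i - 1) * 20
      paste0(substr(canon, 1, blk - 1), substr(canon, blk + 15, len))
    }, character(1))
    transcripts <- tibble::tibble(
      gene_id = "PLEC", transcript_id = tids, kind = "splice",
      sequence = seqs, reviewed = TRUE,
      fpkm = replicate(9, c(2, 2.1, 1.9), simplify = FALSE)
    )
    pos <- seq(10, by = 16, length.out = 17)
    kinds <- c(rep("SAP", 8), rep(c("DEL", "INS"), length.out = 9))
    events <- tibble::tibble(
      gene_id = "PLEC", event_id = sprintf("PLEC_E%02d", 1:17),
      kind = kinds, pos = pos,
      ref = ifelse(kinds == "SAP", substring(canon, pos, pos),
                   ifelse(kinds == "DEL", substring(canon, pos, pos + 1), "")),
      alt = ifelse(kinds == "SAP",
                   vapply(pos, function(p) {
                     setdiff(aa20, c(substring(canon, p, p), "I", "L"))[1]
                   }, character(1)),
                   ifelse(kinds == "INS", "W", "")),
      backbones = paste(tids, collapse = ";")
    )
    list(transcripts = transcripts, events = events)
  })
}

example_grid <- function() load_grid(example_grid_path())

# Small simulated experiment shared by inference/annotation tests.
small_sim <- function(seed = 11, n_genes = 14, ...) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes, ...)
  vt <- make_variant_tables(cfg)
  kept <- filter_transcripts(vt$transcripts)
  lib <- enumerate_proteoforms(kept, vt$events)
  grid <- example_grid()
  sim <- suppressMessages(simulate_gel_experiment(lib, grid, cfg))
  list(cfg = cfg, lib = lib, grid = grid, sim = sim,
       index = build_peptide_index(lib))
}
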