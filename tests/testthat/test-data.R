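write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

test_that("FASTA reading handles empty files and single records", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_identical(read_fasta(empty), list())
  path <- write_tmp_fasta(c(">p1 some description", "MKWVTFISLL"))
  recs <- read_fasta(path)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$residues, "MKWVTFISLL")
})

test_that("FASTA round-trips many random records with 60-column wrapping", {
  set.seed(20)
  n <- 200
  seqs <- vapply(sample(2:180, n, replace = TRUE), random_sequence, character(1))
  recs <- lapply(seq_len(n), function(i) {
    protein_sequence(seqs[i], id = sprintf("rec%03d", i))
  })
  path <- tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(path)
  expect_equal(vapply(back, `[[`, character(1), "id"),
               vapply(recs, `[[`, character(1), "id"))
  expect_equal(vapply(back, `[[`, character(1), "residues"), seqs)
  unlink(path)
})

test_that("duplicate FASTA ids are suffixed with a warning", {
  path <- write_tmp_fasta(c(">dup", "MKWV", ">dup", "AAAA"))
  expect_warning(recs <- read_fasta(path), "duplicate")
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("dup", "dup_1"))
})

test_that("non-standard residues follow the configured policy", {
  path <- write_tmp_fasta(c(">odd", "MKXWV"))
  expect_error(read_fasta(path), "non-standard")
  recs <- read_fasta(path, nonstandard = "map", map_to = "G")
  expect_equal(recs[[1]]$residues, "MKGWV")
})

annotation_fixture <- function() {
  tab <- data.frame(
    id = c("sec1", "sec_frag", "sec_long", "sec_dup", "nonsec_nuc",
           "nonsec_memb", "gpos_cyt"),
    oc = c(rep("Eukaryota; Metazoa", 6), "Bacteria; Gram-positive"),
    location = c("Secreted", "Secreted", "Secreted", "Secreted",
                 "Nucleus", "Membrane", "Cytoplasm"),
    signal_start = c(1, 1, 1, 1, NA, NA, NA),
    signal_end = c(18, 18, 20, 18, NA, NA, NA),
    keywords = c("signal", "signal; Fragment", "signal", "signal",
                 "", "", ""),
    sequence = NA_character_,
    stringsAsFactors = FALSE
  )
  set.seed(31)
  base <- random_sequence(90)
  tab$sequence <- c(base,
                    random_sequence(80),
                    random_sequence(150),
                    base, # exact duplicate of sec1
                    random_sequence(70),
                    random_sequence(70),
                    random_sequence(70))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("curation filters keywords, truncates, deduplicates and is idempotent", {
  recs <- read_annotations(annotation_fixture())
  expect_s3_class(recs, "annotated_records")

  sec <- suppressMessages(curate(recs, "secretory", "eukaryote"))
  ids <- sec$id
  expect_false("sec_frag" %in% ids)   # ambiguous keyword excluded
  expect_false("sec_dup" %in% ids)    # exact duplicate removed
  expect_false("gpos_cyt" %in% ids)   # wrong organism class
  expect_true(all(c("sec1", "sec_long") %in% ids))
  expect_equal(nchar(sec$sequence[sec$id == "sec_long"]), 100L) # 150 -> 100
  # idempotence: running the same curation again changes nothing
  again <- suppressMessages(curate(sec, "secretory", "eukaryote"))
  expect_equal(again, sec)

  nonsec <- suppressMessages(curate(recs, "non_secretory", "eukaryote"))
  expect_equal(nonsec$id, "nonsec_nuc") # nucleus kept, membrane dropped
  expect_equal(nchar(nonsec$sequence), 70L) # negatives are not truncated

  gpos <- suppressMessages(curate(recs, "non_secretory", "gram_positive"))
  expect_equal(gpos$id, "gpos_cyt")
})

test_that("curated records convert to validated protein sequences", {
  recs <- read_annotations(annotation_fixture())
  sec <- suppressMessages(curate(recs, "secretory", "eukaryote"))
  seqs <- as_protein_sequences(sec)
  expect_true(all(vapply(seqs, inherits, logical(1), "protein_sequence")))
  expect_equal(vapply(seqs, `[[`, character(1), "id"), sec$id)
})

test_that("the synthetic generator is reproducible and labels its sites", {
  spec <- synthetic_spec(n_pos = 20, n_neg = 20, seed = 13)
  d1 <- generate_synthetic(spec)
  d2 <- generate_synthetic(spec)
  expect_identical(
    vapply(d1$positives, `[[`, character(1), "residues"),
    vapply(d2$positives, `[[`, character(1), "residues"))
  expect_identical(d1$sites, d2$sites)
  expect_equal(nrow(d1$sites), 20L)
  # signal lengths stay inside the 3-60 window
  expect_true(all(d1$sites$site - 1 >= 3 & d1$sites$site - 1 <= 60))
})

test_that("every generated positive passes the rule at its planted site", {
  for (org in c("eukaryote", "prokaryote")) {
    d <- generate_synthetic(synthetic_spec(n_pos = 40, n_neg = 0,
                                           organism = org, seed = 3))
    rules <- rule_set(org)
    ok <- vapply(seq_len(40), function(i) {
      rule_check(d$positives[[i]], d$sites$site[i], rules)
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("generated positives are more hydrophobic than negatives in the signal region", {
  d <- generate_synthetic(synthetic_spec(n_pos = 50, n_neg = 50, seed = 9))
  hyd <- setNames(aa_properties()$hydrophobicity, AA_ALPHABET)
  mean_h <- function(p, upto) {
    chars <- strsplit(substr(p$residues, 1, upto), "")[[1]]
    mean(hyd[chars])
  }
  pos_h <- mapply(mean_h, d$positives, d$sites$site - 1)
  neg_h <- vapply(d$negatives, mean_h, numeric(1), upto = 20)
  expect_gt(mean(pos_h), mean(neg_h))
  expect_lt(t.test(pos_h, neg_h, alternative = "greater")$p.value, 1e-6)
})

test_that("infeasible generator specifications are rejected", {
  expect_error(synthetic_spec(c_region_len = c(2L, 2L)), "at least 3")
  expect_error(synthetic_spec(h_region_len = c(7L, 55L)), "3..60")
})
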