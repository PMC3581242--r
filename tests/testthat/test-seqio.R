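test_that("read_fasta parses records in order, upper-cases, strips stops", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a first protein", "nyrwrcknqn", ">b", "NYQRR", "CKNQN*"), fa)
  fam <- read_fasta(fa)
  expect_s3_class(fam, "seq_family")
  expect_identical(fam$id, c("a", "b"))
  expect_identical(fam$desc, c("first protein", ""))
  expect_identical(fam$residues, c("NYRWRCKNQN", "NYQRRCKNQN"))
  expect_identical(nchar(fam$residues), c(10L, 10L))
})

test_that("read_fasta rejects invalid input, naming the offending record", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "NYRW-CKNQN"), fa)
  expect_error(read_fasta(fa), "record 'a'.*invalid residue")
  writeLines(c(">a", "NYRWR", ">a", "CKNQN"), fa)
  expect_error(read_fasta(fa), "duplicate sequence id")
  writeLines(c(">a", "NYRWRZKNQN"), fa)
  expect_error(read_fasta(fa), "'Z'")
  writeLines(character(), fa)
  expect_error(read_fasta(fa), "no sequence records|parse")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
  # X is tolerated
  writeLines(c(">a", "NYRWXCKNQN", ">b", "AAAA"), fa)
  expect_identical(read_fasta(fa)$residues[1], "NYRWXCKNQN")
})

test_that("FASTA round trip is lossless for id, description and residues", {
  set.seed(11)
  fam <- random_family(5, c(10L, 80L))
  fam$desc <- c("", "some description", "x y z", "", "d")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(fam, fa, width = 17L)  # odd wrap width on purpose
  back <- read_fasta(fa)
  expect_identical(back$id, fam$id)
  expect_identical(back$desc, fam$desc)
  expect_identical(back$residues, fam$residues)
})

test_that("segment report TSV has the contracted shape and ordering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments_tsv(segment_report(character(), integer(), integer(),
                                    character()), path)
  expect_identical(readLines(path),
                   "member\tstart\tend\tlength\tsegment\tlevel\ttag")

  rep1 <- segment_report("m1", 32L, 37L, "NYRWRC", level = 1L)
  write_segments_tsv(rep1, path)
  expect_identical(readLines(path)[2],
                   "m1\t32\t37\t6\tNYRWRC\t1\tunique-segment")

  # out-of-order rows come back sorted by member then start
  rep2 <- segment_report(c("m1", "m1"), c(50L, 10L), c(54L, 12L),
                         c("AAAAA", "CCC"), level = c(1L, 1L))
  write_segments_tsv(rep2, path, provenance = "params: L=3")
  lines <- readLines(path)
  expect_identical(lines[1], "# params: L=3")
  expect_match(lines[3], "^m1\t10\t")
  expect_match(lines[4], "^m1\t50\t")

  back <- read_segments_tsv(path)
  expect_identical(back$start, c(10L, 50L))
  expect_identical(back$segment, c("CCC", "AAAAA"))
})

test_that("segment report JSON variant carries the same fields", {
  path <- withr::local_tempfile(fileext = ".json")
  rep <- segment_report("m1", 3L, 7L, "RWRCK", level = 3L,
                        tag = "hbr-candidate")
  write_segments_json(rep, path, provenance = "v1")
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(parsed$segments$member, "m1")
  expect_identical(parsed$segments$start, 3L)
  expect_identical(parsed$segments$tag, "hbr-candidate")
})

test_that("segment_report enforces coordinate/text invariants", {
  expect_error(segment_report("m", 5L, 3L, "AAA"))
  expect_error(segment_report("m", 1L, 3L, "AAAA"))
  expect_silent(segment_report("m", 1L, 3L, "AAA"))
})

test_that("aligned FASTA and CLUSTAL alignments are read", {
  fa <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">a", "NYRWRC-NQN", ">b", "NYQRRCKNQ-"), fa)
  aln <- read_alignment(fa, "fasta")
  expect_identical(aln$aligned, c("NYRWRC-NQN", "NYQRRCKNQ-"))

  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.0) multiple sequence alignment", "", "",
               "a               NYRWRC-NQN",
               "b               NYQRRCKNQ-", "", ""), cl)
  aln2 <- read_alignment(cl, "clustal")
  expect_identical(sort(aln2$id), c("a", "b"))
  expect_identical(unique(nchar(aln2$aligned)), 10L)
})

test_that("packaged motif tables match the printed cells", {
  fx <- load_published_fixtures()
  t5 <- fx$motif_table5
  expect_identical(nrow(t5), 13L)
  expect_identical(t5$motif[t5$protein == "RNase3"], "NYRWRCKNQN")
  expect_identical(t5$accession[t5$protein == "RNase3"], "P12724")
  expect_identical(t5$motif[t5$protein == "RNase5"], "LTSP-CKDIN")
  expect_identical(t5$motif[t5$protein == "RNase2"], "NYQRRCKNQN")
  expect_identical(t5$motif_identity_pct[t5$protein == "RNase8"], 50)
  expect_identical(t5$protein_identity_pct[t5$protein == "RNase2"], 67)

  t4 <- fx$motif_table4
  expect_identical(nrow(t4), 12L)
  mf <- t4$protein == "RNase3" & t4$organism == "Macaca fascicularis"
  expect_identical(t4$motif[mf], "NYQRRCKNQN")
  expect_identical(t4$motif_identity_pct[mf], 80)
  pp <- t4$protein == "RNase3" & t4$organism == "Pongo pygmaeus"
  expect_identical(t4$motif[pp], "NYQRRCKDQN")
  # the repeated RNase2 motif typo is kept verbatim and curated side by side
  hs2 <- t4$protein == "RNase2" & t4$organism == "Homo sapiens"
  expect_identical(t4$motif_printed[hs2], "NYQRQCKNQN")
  expect_identical(t4$motif[hs2], "NYQRRCKNQN")
  expect_match(t4$note[hs2], "curated")

  expect_length(fx$unique_motifs, 11L)
  expect_true("HISLNPPR" %in% fx$unique_motifs)
  expect_identical(fx$hbr_windows$window, c("RWRCK", "RSRFR", "RPGRR"))
  expect_identical(fx$hbr_windows$start, c(34L, 73L, 101L))
  expect_identical(fx$hbr_windows$end, c(38L, 77L, 105L))
  # all motifs are 10-mers over amino acids plus the gap character
  expect_true(all(nchar(c(t4$motif, t5$motif)) == 10L))
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY-]",
                         c(t4$motif, t5$motif))))
})
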