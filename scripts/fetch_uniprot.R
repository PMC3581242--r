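#!/usr/bin/env Rscript
# Optional helper (requires network access): downloads the 13 human RNaseA
# superfamily accessions from UniProt, trims the annotated signal peptide to
# obtain mature chains, and writes a FASTA ready for the pipeline:
#
#   Rscript scripts/fetch_uniprot.R mature_hrnasea.fa
#   hbr-scout screen-hbr --fasta mature_hrnasea.fa --out hbr.tsv
#
# The core package deliberately has no network code; offline runs use the
# synthetic stand-in family (hrnasea_standin_family()) instead.

accessions <- c(RNase1 = "P07998", RNase2 = "P10153", RNase3 = "P12724",
                RNase4 = "P34096", RNase5 = "P03950", RNase6 = "Q93061",
                RNase7 = "Q9H1E1", RNase8 = "Q8TDE3", RNase9 = "P60153",
                RNase10 = "Q5GAN6", RNase11 = "Q5GAN5", RNase12 = "Q5GAN4",
                RNase13 = "Q5GAN3")

out <- commandArgs(trailingOnly = TRUE)
if (length(out) != 1L) stop("usage: fetch_uniprot.R <out.fasta>")

fetch_entry <- function(acc) {
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.txt", acc)
  lines <- readLines(url, warn = FALSE)
  sig_end <- 0L
  ft <- grep("^FT   SIGNAL", lines, value = TRUE)
  if (length(ft) == 1L) {
    rng <- regmatches(ft, regexpr("[0-9]+\\.\\.[0-9]+", ft))
    if (length(rng) == 1L) sig_end <- as.integer(sub(".*\\.\\.", "", rng))
  }
  sq <- grep("^SQ ", lines)
  seq_lines <- lines[(sq + 1L):(grep("^//", lines)[1L] - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  substring(residues, sig_end + 1L)
}

message("fetching ", length(accessions), " entries from UniProt ...")
seqs <- vapply(accessions, fetch_entry, character(1L))
fam <- hbrscout::seq_family(names(accessions), seqs,
                            desc = paste0("UniProt ", accessions,
                                          " mature chain"))
hbrscout::write_fasta(fam, out)
message("wrote ", out)
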