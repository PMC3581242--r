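# Amino-acid alphabet accepted in family sequences. 'X' (unknown residue) is
# tolerated and matches only a literal 'X'.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_X <- c(AA_ALPHABET, "X")

#' Construct a sequence family
#'
#' A sequence family is the query dataset of the analysis: an ordered set of
#' protein sequences over the 20-letter amino-acid alphabet ('X' tolerated),
#' with pairwise-distinct member ids and no gap characters.
#'
#' @param id Character vector of unique member identifiers.
#' @param residues Character vector of upper-case amino-acid sequences.
#' @param desc Optional character vector of free-text descriptions.
#' @return A data frame of class `seq_family` with columns `id`, `desc`,
#'   `residues`.
#' @examples
#' fam <- seq_family(c("a", "b"), c("NYRWRCKNQN", "NYQRRCKNQN"))
#' nchar(fam$residues)
#' @export
seq_family <- function(id, residues, desc = rep("", length(id))) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  desc <- as.character(desc)
  stopifnot(length(id) == length(residues), length(id) == length(desc))
  fam <- data.frame(id = id, desc = desc, residues = residues,
                    stringsAsFactors = FALSE)
  class(fam) <- c("seq_family", "data.frame")
  validate_family(fam)
  fam
}

#' Validate sequence-family invariants
#'
#' Checks that ids are pairwise distinct, residues are non-empty and contain
#' only amino-acid letters (plus 'X'), and no gap characters are present.
#' Errors name the offending record.
#'
#' @param fam A `seq_family`.
#' @return `fam`, invisibly.
#' @export
validate_family <- function(fam) {
  if (nrow(fam) == 0L) {
    stop("family is empty: no sequence records", call. = FALSE)
  }
  dup <- fam$id[duplicated(fam$id)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(fam))) {
    res <- fam$residues[i]
    if (is.na(res) || nchar(res) == 0L) {
      stop("record '", fam$id[i], "': residues are empty", call. = FALSE)
    }
    chars <- unique(strsplit(res, "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, AA_ALPHABET_X)
    if (length(bad) > 0L) {
      stop("record '", fam$id[i], "': invalid residue character(s) ",
           paste(sQuote(bad), collapse = ", "),
           " (allowed: 20 amino acids plus X; gaps are not allowed)",
           call. = FALSE)
    }
  }
  invisible(fam)
}

#' @export
print.seq_family <- function(x, ...) {
  cat("seq_family with", nrow(x), "member(s)\n")
  for (i in seq_len(min(nrow(x), 20L))) {
    cat(sprintf("  %-14s %5d aa  %s\n", x$id[i], nchar(x$residues[i]),
                substr(x$residues[i], 1, 40)))
  }
  if (nrow(x) > 20L) cat("  ...\n")
  invisible(x)
}

#' Named residue vector of a family
#' @param fam A `seq_family`.
#' @return Named character vector (names are member ids).
#' @keywords internal
family_residues <- function(fam) {
  stats::setNames(fam$residues, fam$id)
}

#' Read a protein FASTA file
#'
#' One record per FASTA entry, order preserved. Residues are upper-cased and
#' trailing `*` stop characters stripped. The record id is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A `seq_family`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("cannot parse FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no sequence records",
         call. = FALSE)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  residues <- sub("\\*+$", "", residues)
  seq_family(id, residues, desc)
}

#' Write a family to FASTA
#'
#' Inverse of [read_fasta()]: the round trip is lossless for ids, descriptions
#' and residues.
#'
#' @param fam A `seq_family`.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(fam, path, width = 60L) {
  validate_family(fam)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(fam))) {
    header <- if (nzchar(fam$desc[i])) paste(fam$id[i], fam$desc[i]) else fam$id[i]
    writeLines(paste0(">", header), con)
    res <- fam$residues[i]
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))), con)
  }
  invisible(path)
}

#' Read a protein multiple alignment (read-only)
#'
#' Supports aligned FASTA and CLUSTAL formats. Alignments are accepted as
#' external inputs only; this package never builds them.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A data frame with columns `id` and `aligned` (gapped rows, equal
#'   widths).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  rows <- as.character(aln)
  widths <- unique(nchar(rows))
  if (length(widths) != 1L) {
    stop("alignment rows have unequal widths in '", path, "'", call. = FALSE)
  }
  data.frame(id = names(rows), aligned = unname(rows), stringsAsFactors = FALSE)
}

#' Assemble a segment report table
#'
#' Normalizes unique-segment or HBR-candidate tables into the common report
#' shape used by [write_segments_tsv()]: one row per segment with 1-based
#' inclusive coordinates and an annotation tag.
#'
#' @param member,start,end,segment,level Report fields; `level` is the
#'   uniqueness level (carrier count) for unique segments, `NA` for HBR rows.
#' @param tag `"unique-segment"` or `"hbr-candidate"`.
#' @return A data frame of class `segment_report`.
#' @export
segment_report <- function(member, start, end, segment,
                           level = rep(NA_integer_, length(member)),
                           tag = "unique-segment") {
  n <- length(member)
  stopifnot(length(start) == n, length(end) == n, length(segment) == n)
  if (n > 0L) {
    stopifnot(all(start >= 1L), all(start <= end),
              all(nchar(segment) == end - start + 1L))
  }
  rep <- data.frame(member = as.character(member),
                    start = as.integer(start), end = as.integer(end),
                    length = as.integer(end - start + 1L),
                    segment = as.character(segment),
                    level = as.integer(level),
                    tag = rep_len(as.character(tag), n),
                    stringsAsFactors = FALSE)
  class(rep) <- c("segment_report", "data.frame")
  rep
}

#' Write a segment report as TSV
#'
#' Tab-separated with header `member start end length segment level tag`,
#' 1-based inclusive coordinates, rows sorted by member id then start.
#' Optional `provenance` lines are written first, prefixed with `#`.
#'
#' @param reports A data frame as returned by [segment_report()],
#'   [unique_segments()] (after tagging) or [screen_family()].
#' @param path Output path.
#' @param provenance Optional character vector of comment lines (without the
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(reports, path, provenance = character()) {
  cols <- c("member", "start", "end", "length", "segment", "level", "tag")
  missing_cols <- setdiff(cols, names(reports))
  if (length(missing_cols) > 0L) {
    stop("report is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  reports <- reports[order(reports$member, reports$start), cols, drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance) > 0L) {
    writeLines(paste0("# ", provenance), con)
  }
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(reports) > 0L) {
    lines <- apply(reports, 1L, function(r) paste(trimws(r), collapse = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a segment report as JSON
#'
#' Same fields as the TSV variant, one object per row.
#'
#' @inheritParams write_segments_tsv
#' @return `path`, invisibly.
#' @export
write_segments_json <- function(reports, path, provenance = character()) {
  cols <- c("member", "start", "end", "length", "segment", "level", "tag")
  reports <- reports[order(reports$member, reports$start), cols, drop = FALSE]
  out <- list(provenance = as.list(provenance),
              segments = reports)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a segment report TSV
#'
#' @param path Path written by [write_segments_tsv()]. `#` comment lines are
#'   skipped.
#' @return A `segment_report` data frame.
#' @export
read_segments_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE)
  segment_report(tab$member, tab$start, tab$end, tab$segment,
                 level = tab$level, tag = tab$tag)
}
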