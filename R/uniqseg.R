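# Unique-segment extraction: fixed-length "primary patterns" (k-mers) are
# indexed across the family, each start position of a member is flagged by how
# many members carry its pattern, and maximal runs of flagged positions are
# merged bottom-up into unique segments.

#' Build a primary-pattern (k-mer) carrier index
#'
#' For every length-`L` substring occurring anywhere in the family, records
#' the *carrier set*: the set of member ids whose sequence contains that
#' pattern at least once. Occurrence multiplicity within one member does not
#' change membership. Any exact-matching backend satisfies the contract; a
#' hash index is used here.
#'
#' @param family A [seq_family()].
#' @param L Primary pattern length in residues. The default of 3 suits
#'   families of closely related proteins; longer patterns suit divergent
#'   families.
#' @return An object of class `pp_index` with elements `L`, `carriers`
#'   (named list: pattern -> character vector of member ids), `residues`
#'   (named character vector), and `members`.
#' @examples
#' fam <- seq_family(c("a", "b"), c("NYRWRCKNQN", "NYQRRCKNQN"))
#' idx <- build_index(fam, L = 3)
#' idx$carriers[["RCK"]]  # both members
#' idx$carriers[["NYR"]]  # only "a"
#' @export
build_index <- function(family, L = 3L) {
  validate_family(family)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  lens <- nchar(family$residues)
  short <- family$id[lens < L]
  if (length(short) > 0L) {
    stop("member(s) shorter than primary pattern length L=", L, ": ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  kmer_df <- do.call(rbind, lapply(seq_len(nrow(family)), function(i) {
    res <- family$residues[i]
    n <- nchar(res)
    starts <- seq_len(n - L + 1L)
    data.frame(kmer = unique(substring(res, starts, starts + L - 1L)),
               id = family$id[i], stringsAsFactors = FALSE)
  }))
  carriers <- split(kmer_df$id, kmer_df$kmer)
  structure(list(L = L, carriers = carriers,
                 residues = family_residues(family),
                 members = family$id),
            class = "pp_index")
}

#' @export
print.pp_index <- function(x, ...) {
  cat("pp_index: L =", x$L, "|", length(x$members), "members |",
      length(x$carriers), "distinct patterns\n")
  invisible(x)
}

#' Carrier counts for every pattern start of one member
#' @keywords internal
carrier_counts <- function(index, member) {
  if (!member %in% index$members) {
    stop("member '", member, "' is not in the index", call. = FALSE)
  }
  res <- index$residues[[member]]
  n <- nchar(res)
  starts <- seq_len(n - index$L + 1L)
  kmers <- substring(res, starts, starts + index$L - 1L)
  lengths(index$carriers[kmers])
}

#' Uniqueness mask of one member
#'
#' Flags each start position `i` of the member (1-based, `1 <= i <=
#' len - L + 1`) as unique when the length-`L` pattern starting there occurs
#' in at most `m` family members. `m = 1` means "present in no other member";
#' the member's own (possibly repeated) occurrences never disqualify a
#' pattern.
#'
#' @param index A `pp_index` from [build_index()].
#' @param member Member id (must be indexed).
#' @param m Uniqueness level threshold (maximum carrier count), `>= 1`.
#' @return An object of class `uniq_mask`: list with `member`, `L`, `m`,
#'   `flags` (logical vector over start positions) and `counts` (carrier
#'   count per start).
#' @examples
#' fam <- seq_family(c("a", "b"), c("NYRWRCKNQN", "NYQRRCKNQN"))
#' uniqueness_mask(build_index(fam, 3), "a")$flags
#' @export
uniqueness_mask <- function(index, member, m = 1L) {
  m <- as.integer(m)
  if (m < 1L) stop("uniqueness level m must be >= 1", call. = FALSE)
  counts <- carrier_counts(index, member)
  structure(list(member = member, L = index$L, m = m,
                 flags = unname(counts <= m), counts = unname(counts)),
            class = "uniq_mask")
}

#' Merge flagged patterns into maximal unique segments
#'
#' Bottom-up merging: each maximal run of *consecutive* flagged start
#' positions `[i..j]` yields one segment spanning residues `[i, j + L - 1]`.
#' Two flagged patterns merge only when their start positions are
#' consecutive, i.e. the patterns overlap by `L - 1` residues; runs separated
#' by a single unflagged start produce distinct segments that may share up to
#' `L - 2` boundary residues (for `L = 3`, one residue), mirroring the
#' printed RNase3 motif list where e.g. HISLNPPR (15-22) and RCTIAMRA (22-29)
#' share Arg22.
#'
#' @param mask A `uniq_mask` from [uniqueness_mask()].
#' @param index The `pp_index` the mask was computed from (provides residues
#'   and carrier counts for the `level` field).
#' @return Data frame with columns `member`, `start`, `end`, `length`,
#'   `segment`, `level` (maximum carrier count among constituent patterns),
#'   sorted by start. Empty mask gives zero rows.
#' @export
merge_segments <- function(mask, index) {
  stopifnot(inherits(mask, "uniq_mask"), inherits(index, "pp_index"))
  if (mask$L != index$L) {
    stop("mask and index were built with different pattern lengths",
         call. = FALSE)
  }
  res <- index$residues[[mask$member]]
  flags <- mask$flags
  empty <- data.frame(member = character(), start = integer(),
                      end = integer(), length = integer(),
                      segment = character(), level = integer(),
                      stringsAsFactors = FALSE)
  if (length(flags) == 0L || !any(flags)) return(empty)
  runs <- rle(flags)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- which(runs$values)
  starts <- run_start[keep]
  ends <- run_end[keep] + mask$L - 1L
  data.frame(member = mask$member,
             start = as.integer(starts), end = as.integer(ends),
             length = as.integer(ends - starts + 1L),
             segment = substring(res, starts, ends),
             level = vapply(keep, function(k) {
               as.integer(max(mask$counts[run_start[k]:run_end[k]]))
             }, integer(1L)),
             stringsAsFactors = FALSE)
}

#' Extract unique segments for every family member
#'
#' Composition of [build_index()], [uniqueness_mask()] and
#' [merge_segments()] over the whole family: for each member, the maximal
#' segments all of whose length-`L` windows occur in at most `m` members.
#'
#' @param family A [seq_family()] with at least two members.
#' @param L Primary pattern length (default 3).
#' @param m Uniqueness level threshold (default 1: member-unique).
#' @return Data frame with columns `member`, `start`, `end`, `length`,
#'   `segment`, `level`, ordered by family member order then start.
#' @examples
#' fam <- seq_family(c("a", "b"), c("NYRWRCKNQN", "NYQRRCKNQN"))
#' unique_segments(fam)  # "NYRWRC" at 1-6 for a, "NYQRRC" at 1-6 for b
#' @export
unique_segments <- function(family, L = 3L, m = 1L) {
  validate_family(family)
  if (nrow(family) < 2L) {
    stop("uniqueness analysis needs a family of >= 2 members", call. = FALSE)
  }
  index <- build_index(family, L)
  out <- do.call(rbind, lapply(family$id, function(id) {
    merge_segments(uniqueness_mask(index, id, m), index)
  }))
  out$member <- factor(out$member, levels = family$id)
  out <- out[order(out$member, out$start), , drop = FALSE]
  out$member <- as.character(out$member)
  rownames(out) <- NULL
  out
}

#' Tag unique segments as a segment report
#'
#' @param segments Output of [unique_segments()].
#' @return A [segment_report()] with tag `unique-segment`.
#' @export
segments_as_report <- function(segments) {
  segment_report(segments$member, segments$start, segments$end,
                 segments$segment, level = segments$level,
                 tag = "unique-segment")
}
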