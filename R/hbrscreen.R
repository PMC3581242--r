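# Heparin-binding-region screening: fixed-width windows rich in basic
# residues (Arg/Lys by default) that overlap a unique segment. The default
# rule (w = 5 windows with >= 3 basics, segments extended by a 2-residue
# flank, >= 3 residues of overlap with the unextended segment) is the minimal
# rule that nominates exactly RWRCK/RSRFR/RPGRR on the RNase3 motif set and
# rejects the other eight unique motifs. The flank is needed because Lys38
# of HBR1 lies one residue outside the unique segment NYRWRC (32-37).

#' Screening configuration
#'
#' @param window Window width `w` in residues (default 5).
#' @param min_basic Minimum number of basic residues per window `b`
#'   (default 3).
#' @param basic Residues counted as basic. Default `c("R", "K")`; histidine
#'   is excluded by default (adding it does not change the RNase3 outcome but
#'   is biologically debatable).
#' @param flank Residues by which a unique segment is extended on each side
#'   before window scanning (default 2).
#' @param min_overlap Minimum residues a qualifying window must share with
#'   the unextended segment (default 3).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(window = 5L, min_basic = 3L, basic = c("R", "K"),
                          flank = 2L, min_overlap = 3L) {
  window <- as.integer(window)
  min_basic <- as.integer(min_basic)
  flank <- as.integer(flank)
  min_overlap <- as.integer(min_overlap)
  basic <- toupper(as.character(basic))
  if (window < 1L) stop("window width must be >= 1", call. = FALSE)
  if (min_basic < 1L || min_basic > window) {
    stop("min_basic must satisfy 1 <= min_basic <= window", call. = FALSE)
  }
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  if (min_overlap < 1L || min_overlap > window) {
    stop("min_overlap must satisfy 1 <= min_overlap <= window", call. = FALSE)
  }
  if (!all(basic %in% AA_ALPHABET)) {
    stop("basic set must be amino-acid letters", call. = FALSE)
  }
  structure(list(window = window, min_basic = min_basic, basic = basic,
                 flank = flank, min_overlap = min_overlap),
            class = "screen_config")
}

#' Count basic residues in a window
#'
#' @param window Residue text (vectorized).
#' @param basic Residues counted as basic.
#' @return Integer count(s) of positions whose residue is in `basic`.
#' @examples
#' basic_count("RWRCK")  # 3
#' basic_count("AAAAA")  # 0
#' @export
basic_count <- function(window, basic = c("R", "K")) {
  stopifnot(all(nchar(window) > 0L))
  vapply(strsplit(toupper(window), "", fixed = TRUE),
         function(ch) sum(ch %in% basic), integer(1L))
}

empty_candidates <- function() {
  data.frame(member = character(), start = integer(), end = integer(),
             window = character(), basic_count = integer(),
             seg_start = integer(), seg_end = integer(),
             stringsAsFactors = FALSE)
}

#' Screen one member's unique segments for cationic windows
#'
#' For each unique segment, all `w`-windows within the segment extended by
#' `flank` residues on each side (clipped to sequence bounds) are scanned.
#' Windows with at least `min_basic` basic residues and at least
#' `min_overlap` residues of overlap with the unextended segment qualify.
#' Per segment, the single representative window with maximal basic count is
#' reported (ties broken leftmost); set `all_windows = TRUE` to keep every
#' qualifying window.
#'
#' @param residues The member's sequence text.
#' @param member Member id.
#' @param segments Data frame of this member's unique segments
#'   (columns `start`, `end`, as from [unique_segments()]).
#' @param cfg A [screen_config()].
#' @param all_windows Report all qualifying windows instead of one
#'   representative per segment.
#' @return Data frame with columns `member`, `start`, `end`, `window`,
#'   `basic_count`, `seg_start`, `seg_end`, sorted by start.
#' @export
screen_member <- function(residues, member, segments, cfg = screen_config(),
                          all_windows = FALSE) {
  stopifnot(inherits(cfg, "screen_config"))
  n <- nchar(residues)
  if (nrow(segments) > 0L && any(segments$end > n)) {
    stop("segment coordinates exceed length of member '", member, "'",
         call. = FALSE)
  }
  w <- cfg$window
  out <- lapply(seq_len(nrow(segments)), function(k) {
    s <- segments$start[k]; e <- segments$end[k]
    lo <- max(1L, s - cfg$flank)
    hi <- min(n, e + cfg$flank)
    if (hi - lo + 1L < w) return(empty_candidates())
    ws <- seq.int(lo, hi - w + 1L)
    win <- substring(residues, ws, ws + w - 1L)
    bc <- basic_count(win, cfg$basic)
    ov <- pmin(e, ws + w - 1L) - pmax(s, ws) + 1L
    ok <- bc >= cfg$min_basic & ov >= cfg$min_overlap
    if (!any(ok)) return(empty_candidates())
    keep <- if (all_windows) which(ok) else which(ok)[which.max(bc[ok])]
    data.frame(member = member, start = as.integer(ws[keep]),
               end = as.integer(ws[keep] + w - 1L), window = win[keep],
               basic_count = as.integer(bc[keep]),
               seg_start = as.integer(s), seg_end = as.integer(e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty_candidates()), out))
  out <- out[order(out$start, out$seg_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a whole family for HBR candidates
#'
#' Per-member application of [screen_member()] over a table of unique
#' segments.
#'
#' @param family A [seq_family()].
#' @param segments Data frame of unique segments with a `member` column, as
#'   returned by [unique_segments()].
#' @param cfg A [screen_config()].
#' @param all_windows Passed to [screen_member()].
#' @return Data frame of candidates across members (family member order,
#'   then start).
#' @export
screen_family <- function(family, segments, cfg = screen_config(),
                          all_windows = FALSE) {
  validate_family(family)
  unknown <- setdiff(unique(segments$member), family$id)
  if (length(unknown) > 0L) {
    stop("segments refer to unknown member(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  res <- family_residues(family)
  out <- do.call(rbind, c(list(empty_candidates()), lapply(family$id, function(id) {
    screen_member(res[[id]], id, segments[segments$member == id, , drop = FALSE],
                  cfg, all_windows = all_windows)
  })))
  rownames(out) <- NULL
  out
}

#' Tag HBR candidates as a segment report
#'
#' @param candidates Output of [screen_family()].
#' @return A [segment_report()] with tag `hbr-candidate`; the `level` column
#'   carries the basic-residue count.
#' @export
candidates_as_report <- function(candidates) {
  segment_report(candidates$member, candidates$start, candidates$end,
                 candidates$window, level = candidates$basic_count,
                 tag = "hbr-candidate")
}
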