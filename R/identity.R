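# Identity computations: positional (Hamming) identity over pre-aligned
# 10-mers (reproduces the printed motif tables), subwindow identity (the
# corresponding-region HBR comparison), and whole-protein global identity via
# Needleman-Wunsch/Gotoh alignment with affine gaps under BLOSUM62.
#
# Motif identity is deliberately *not* a re-run of an alignment service: the
# printed 10-mers are already positionally aligned, and plain column identity
# with gaps scored as mismatches reproduces the printed percentages.

identity_result <- function(query, subject, identical, compared) {
  data.frame(query = query, subject = subject,
             identical = as.integer(identical),
             compared = as.integer(compared),
             percent = 100 * identical / compared,
             stringsAsFactors = FALSE)
}

#' Positional identity between two equal-length motifs
#'
#' Column-by-column comparison; a position counts as identical only when both
#' residues are equal and neither is the gap character `-`. The denominator
#' is always the full motif length (a gap is a mismatch, it is not excluded).
#'
#' @param a,b Motif texts of equal length (amino acids plus `-`).
#' @param query,subject Labels for the result row.
#' @return One-row data frame: `query`, `subject`, `identical`, `compared`,
#'   `percent`.
#' @examples
#' motif_identity_percent("NYQRRCKNQN", "NYRWRCKNQN")$percent  # 80
#' motif_identity_percent("LTSP-CKDIN", "NYRWRCKNQN")$percent  # 30
#' @export
motif_identity_percent <- function(a, b, query = a, subject = b) {
  a <- gsub("[[:space:]]", "", a)
  b <- gsub("[[:space:]]", "", b)
  if (nchar(a) != nchar(b)) {
    stop("motif lengths differ (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  hits <- sum(ca == cb & ca != "-")
  identity_result(query, subject, hits, nchar(a))
}

#' Contiguous subwindow of a motif
#'
#' Maps a region of interest onto a printed motif, e.g. the HBR1 span 34-38
#' onto positions 3-7 of the 32-41 motif.
#'
#' @param motif Motif text.
#' @param offset 1-based start within the motif.
#' @param width Slice width.
#' @return The slice.
#' @examples
#' subwindow("NYRWRCKNQN", 3, 5)  # "RWRCK"
#' @export
subwindow <- function(motif, offset, width) {
  offset <- as.integer(offset); width <- as.integer(width)
  if (offset < 1L || width < 1L || offset + width - 1L > nchar(motif)) {
    stop("subwindow [", offset, ", ", offset + width - 1L,
         "] out of range for motif of length ", nchar(motif), call. = FALSE)
  }
  substr(motif, offset, offset + width - 1L)
}

#' Corresponding-region identity against a reference motif window
#'
#' Slices the same subwindow out of every motif in a table and out of the
#' reference, then computes positional identity per row. With the defaults
#' (positions 3-7 of the 10-mer) this compares the corresponding segments of
#' the family to the HBR1 window RWRCK.
#'
#' @param table Data frame with columns `protein` (or `name`) and `motif`.
#' @param reference Reference motif text (length >= `offset + width - 1`).
#' @param offset,width Subwindow coordinates within the motifs (defaults 3
#'   and 5).
#' @return Data frame of identity results, one row per table row.
#' @export
corresponding_hbr_identity <- function(table, reference, offset = 3L,
                                       width = 5L) {
  label <- if ("protein" %in% names(table)) table$protein else table$name
  ref_win <- subwindow(reference, offset, width)
  out <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    win <- subwindow(table$motif[i], offset, width)
    motif_identity_percent(win, ref_win, query = label[i],
                           subject = "reference")
  }))
  rownames(out) <- NULL
  out
}

#' Alignment parameters
#'
#' Affine gap model: a gap of length `k` costs
#' `gap_open + k * gap_extend`. The defaults (10 and 0.2, BLOSUM62) are the
#' ClustalW protein defaults used for the family alignment.
#'
#' @param gap_open Gap opening penalty (> 0).
#' @param gap_extend Gap extension penalty per residue (> 0).
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings,
#'   e.g. `"BLOSUM62"`), or a numeric matrix.
#' @return A list of class `align_params`.
#' @export
align_params <- function(gap_open = 10, gap_extend = 0.2,
                         matrix = "BLOSUM62") {
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be > 0", call. = FALSE)
  }
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
  }
  stopifnot(is.matrix(matrix))
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix), class = "align_params")
}

#' Needleman-Wunsch global alignment with affine gaps (Gotoh)
#'
#' Full global alignment (terminal gaps penalized). Traceback ties are broken
#' deterministically: diagonal, then up (gap in `b`), then left (gap in `a`).
#'
#' @param a,b Sequence texts.
#' @param params An [align_params()].
#' @return List with `score`, `aligned_a`, `aligned_b`.
#' @export
nw_align <- function(a, b, params = align_params()) {
  stopifnot(inherits(params, "align_params"), nchar(a) > 0L, nchar(b) > 0L)
  sub <- params$matrix
  go <- params$gap_open; ge <- params$gap_extend
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(ca); m <- length(cb)
  if (!all(ca %in% rownames(sub)) || !all(cb %in% colnames(sub))) {
    stop("sequence contains residues absent from the substitution matrix",
         call. = FALSE)
  }
  NEG <- -1e18
  # M: last column is a match/mismatch; X: gap in b (vertical, consumes a);
  # Y: gap in a (horizontal, consumes b). Opening a gap costs go + ge.
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0L) X[2L:(n + 1L), 1L] <- -(go + ge * seq_len(n))
  if (m > 0L) Y[1L, 2L:(m + 1L)] <- -(go + ge * seq_len(m))
  S <- sub[ca, cb, drop = FALSE]
  for (i in 2L:(n + 1L)) {
    Mi1 <- M[i - 1L, ]; Xi1 <- X[i - 1L, ]; Yi1 <- Y[i - 1L, ]
    # vertical moves depend only on the previous row: vectorize over j
    X[i, ] <- pmax(pmax(Mi1, Yi1) - go - ge, Xi1 - ge)
    X[i, 1L] <- -(go + ge * (i - 1L))
    best_prev <- pmax(Mi1, Xi1, Yi1)
    Mrow <- M[i, ]; Yrow <- Y[i, ]; Xrow <- X[i, ]
    for (j in 2L:(m + 1L)) {
      Mrow[j] <- S[i - 1L, j - 1L] + best_prev[j - 1L]
      Yrow[j] <- max(max(Mrow[j - 1L], Xrow[j - 1L]) - go - ge,
                     Yrow[j - 1L] - ge)
    }
    M[i, ] <- Mrow; Y[i, ] <- Yrow
  }
  # traceback, preferring diagonal (M), then up (X), then left (Y)
  state_at <- function(i, j) {
    sc <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
    names(sc)[which.max(sc)]  # which.max keeps the first max: M > X > Y
  }
  i <- n + 1L; j <- m + 1L
  state <- state_at(i, j)
  score <- max(M[i, j], X[i, j], Y[i, j])
  ra <- character(0L); rb <- character(0L)
  eps <- 1e-9
  while (i > 1L || j > 1L) {
    if (state == "M") {
      ra <- c(ca[i - 1L], ra); rb <- c(cb[j - 1L], rb)
      prev <- c(M = M[i - 1L, j - 1L], X = X[i - 1L, j - 1L],
                Y = Y[i - 1L, j - 1L])
      target <- M[i, j] - S[i - 1L, j - 1L]
      state <- names(prev)[which(abs(prev - target) < eps)][1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ra <- c(ca[i - 1L], ra); rb <- c("-", rb)
      from_open <- max(M[i - 1L, j], Y[i - 1L, j]) - go - ge
      if (i == 2L && j == 1L) {
        state <- "M"
      } else if (abs(X[i, j] - from_open) < eps) {
        state <- if (abs(M[i - 1L, j] - (from_open + go + ge)) < eps) "M" else "Y"
      } else {
        state <- "X"
      }
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(cb[j - 1L], rb)
      from_open <- max(M[i, j - 1L], X[i, j - 1L]) - go - ge
      if (j == 2L && i == 1L) {
        state <- "M"
      } else if (abs(Y[i, j] - from_open) < eps) {
        state <- if (abs(M[i, j - 1L] - (from_open + go + ge)) < eps) "M" else "X"
      } else {
        state <- "Y"
      }
      j <- j - 1L
    }
  }
  list(score = score, aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

#' Whole-protein global identity
#'
#' Aligns two sequences globally under [align_params()] and reports percent
#' identity as identical residue pairs over alignment columns, excluding
#' columns that fall in a *terminal* gap run of either aligned sequence
#' (leading/trailing overhangs are not compared); internal gap columns count
#' as mismatches.
#'
#' @param a,b Sequence texts.
#' @param params An [align_params()].
#' @param query,subject Labels for the result row.
#' @return One-row identity data frame (plus attribute `"alignment"`).
#' @export
global_identity_percent <- function(a, b, params = align_params(),
                                    query = "query", subject = "subject") {
  aln <- nw_align(a, b, params)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  keep <- !(terminal_gap_mask(ca) | terminal_gap_mask(cb))
  hits <- sum(ca[keep] == cb[keep] & ca[keep] != "-")
  out <- identity_result(query, subject, hits, sum(keep))
  attr(out, "alignment") <- aln
  out
}

terminal_gap_mask <- function(chars) {
  n <- length(chars)
  mask <- logical(n)
  i <- 1L
  while (i <= n && chars[i] == "-") { mask[i] <- TRUE; i <- i + 1L }
  i <- n
  while (i >= 1L && chars[i] == "-") { mask[i] <- TRUE; i <- i - 1L }
  mask
}

#' Family-wide protein identity against a reference member
#'
#' [global_identity_percent()] of the reference versus every member, in
#' family order; the reference-vs-itself row is flagged in the `self` column.
#'
#' @param family A [seq_family()].
#' @param reference Reference member id.
#' @param params An [align_params()].
#' @return Data frame of identity rows with an added logical `self` column.
#' @export
family_identity_table <- function(family, reference,
                                  params = align_params()) {
  validate_family(family)
  if (!reference %in% family$id) {
    stop("unknown reference id '", reference, "'", call. = FALSE)
  }
  ref_res <- family$residues[family$id == reference]
  out <- do.call(rbind, lapply(seq_len(nrow(family)), function(i) {
    r <- global_identity_percent(ref_res, family$residues[i], params,
                                 query = reference, subject = family$id[i])
    attr(r, "alignment") <- NULL
    r
  }))
  out$self <- out$subject == reference
  rownames(out) <- NULL
  out
}
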