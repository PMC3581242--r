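# Independent oracles used by property and acceptance tests. These must stay
# independent of the implementation paths they check: the segment oracle does
# per-position substring lookups with grepl, the alignment oracle enumerates
# alignments recursively.

# Brute-force unique segments: for every start of every member, test the
# L-window for presence in each member by direct substring search, then take
# maximal runs of consecutive qualifying starts.
oracle_unique_segments <- function(fam, L = 3L, m = 1L) {
  out <- list()
  for (i in seq_len(nrow(fam))) {
    res <- fam$residues[i]
    n <- nchar(res)
    starts <- seq_len(n - L + 1L)
    flags <- vapply(starts, function(s) {
      kmer <- substr(res, s, s + L - 1L)
      carriers <- sum(vapply(fam$residues,
                             function(r) grepl(kmer, r, fixed = TRUE),
                             logical(1L)))
      carriers <= m
    }, logical(1L))
    if (!any(flags)) next
    r <- rle(flags)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    for (k in which(r$values)) {
      st <- starts_r[k]; en <- ends_r[k] + L - 1L
      out[[length(out) + 1L]] <- data.frame(
        member = fam$id[i], start = st, end = en,
        segment = substr(res, st, en), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(member = character(), start = integer(),
                      end = integer(), segment = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Brute-force optimal global alignment score by recursive enumeration of all
# alignments with affine gap costs (state = last move). Exponential; keep
# sequences short (<= 7).
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.2,
                               sub = NULL) {
  if (is.null(sub)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    sub <- env$BLOSUM62
  }
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(ca)) {
      cost <- if (state == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1L, j, "X"))
    }
    if (j <= length(cb)) {
      cost <- if (state == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Random family over a restricted alphabet (smaller alphabets create more
# shared k-mers, exercising the non-unique paths).
random_family <- function(n_members, len_range = c(20L, 60L),
                          alphabet_size = 20L) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  alpha <- alpha[seq_len(alphabet_size)]
  lens <- sample(seq.int(len_range[1L], len_range[2L]), n_members,
                 replace = TRUE)
  seq_family(sprintf("m%02d", seq_len(n_members)),
             vapply(lens, function(l) {
               paste(sample(alpha, l, replace = TRUE), collapse = "")
             }, character(1L)))
}

# Sorted, rowname-free view for data frame comparisons.
canon_segments <- function(df, cols = c("member", "start", "end", "segment")) {
  df <- df[order(df$member, df$start), cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

toy_family <- function() {
  seq_family(c("a", "b"), c("NYRWRCKNQN", "NYQRRCKNQN"))
}
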