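# Synthetic family generator: a conserved scaffold shared by all members,
# per-member substitution noise, planted member-unique segments (every
# analysis-length window inside a planted segment is absent from every other
# member, enforced by rejection sampling iterated to a fixpoint), and
# optional planted cationic windows inside planted segments. Ground truth is
# returned for span-level precision/recall scoring.

#' Synthetic family configuration
#'
#' Defaults emulate the statistical structure of the study family: 13
#' members of ~130 residues sharing a conserved scaffold, each carrying 2-4
#' member-unique segments of 5-14 residues (the length range of the eleven
#' published motifs), up to 2 cationic windows (width 5, >= 3 basics,
#' mirroring the default screen), and 5% per-residue substitution noise on
#' the scaffold. The background residue distribution is uniform over the 20
#' amino acids, which keeps uniqueness probabilities tractable.
#'
#' @param n_members Family size.
#' @param scaffold_length Scaffold length in residues.
#' @param n_segments Integer range (length 2) of planted unique segments per
#'   member.
#' @param segment_length Integer range of planted segment lengths.
#' @param n_cationic Integer range of planted cationic windows per member
#'   (each in a distinct planted segment of sufficient length).
#' @param cationic_window,cationic_min_basic Width and minimum basic count of
#'   planted cationic windows (mirror [screen_config()]).
#' @param noise Per-residue substitution probability on the scaffold copy.
#' @param L Primary pattern length of the downstream analysis (uniqueness of
#'   planted segments is enforced at this length).
#' @param flank Flank used by the downstream screen; basics are cleared in a
#'   margin of this many residues around planted segments so the planted
#'   window is the strict within-segment maximum.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_members = 13L, scaffold_length = 130L,
                         n_segments = c(2L, 4L), segment_length = c(5L, 14L),
                         n_cationic = c(0L, 2L), cationic_window = 5L,
                         cationic_min_basic = 3L, noise = 0.05, L = 3L,
                         flank = 2L) {
  stopifnot(n_members >= 2L, scaffold_length >= 20L,
            length(n_segments) == 2L, n_segments[1L] >= 0L,
            n_segments[1L] <= n_segments[2L],
            length(segment_length) == 2L, segment_length[1L] >= L,
            segment_length[1L] <= segment_length[2L],
            length(n_cationic) == 2L, n_cationic[1L] >= 0L,
            n_cationic[1L] <= n_cationic[2L],
            cationic_window >= 1L, cationic_min_basic >= 1L,
            cationic_min_basic <= cationic_window,
            noise >= 0, noise <= 1, L >= 1L, flank >= 0L)
  structure(list(n_members = as.integer(n_members),
                 scaffold_length = as.integer(scaffold_length),
                 n_segments = as.integer(n_segments),
                 segment_length = as.integer(segment_length),
                 n_cationic = as.integer(n_cationic),
                 cationic_window = as.integer(cationic_window),
                 cationic_min_basic = as.integer(cationic_min_basic),
                 noise = noise, L = as.integer(L), flank = as.integer(flank)),
            class = "synth_config")
}

# sample() treats a scalar first argument as 1:x; these helpers avoid that
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep.int(as.integer(lo), n)
  else resample(seq.int(lo, hi), n, replace = TRUE)
}

rand_aa <- function(k, exclude = character()) {
  pool <- setdiff(AA_ALPHABET, exclude)
  paste(sample(pool, k, replace = TRUE), collapse = "")
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# all length-L windows fully inside text
windows_of <- function(text, L) {
  n <- nchar(text)
  if (n < L) return(character(0L))
  s <- seq_len(n - L + 1L)
  substring(text, s, s + L - 1L)
}

#' Generate a synthetic family with planted ground truth
#'
#' Fully reproducible from `seed`: the same configuration and seed give a
#' byte-identical family. Generation can fail (with an error) if the
#' configuration leaves no room for non-overlapping planted segments.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed for all randomness (required for
#'   reproducibility; `NULL` uses the current RNG state).
#' @return List with `family` (a [seq_family()]) and `truth` (list of data
#'   frames `segments` and `cationic`, spans 1-based inclusive per member).
#' @examples
#' gen <- generate_family(synth_config(n_members = 4), seed = 1)
#' gen$truth$segments
#' @export
generate_family <- function(cfg = synth_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  L <- cfg$L
  ids <- sprintf("member%02d", seq_len(cfg$n_members))
  scaffold <- rand_aa(cfg$scaffold_length)

  # noisy scaffold copies
  seqs <- vapply(ids, function(id) {
    ch <- split1(scaffold)
    hit <- stats::runif(length(ch)) < cfg$noise
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(r) sample(setdiff(AA_ALPHABET, r), 1L),
                        character(1L))
    }
    paste(ch, collapse = "")
  }, character(1L))

  # choose non-overlapping planted spans per member, separated by more than
  # the screening flank so no scan window of one segment can reach into a
  # neighboring planted segment (keeps planted cationic windows the strict
  # maximum of their scan)
  span_gap <- cfg$flank + 1L
  pick_spans <- function(k, len_range, total) {
    spans <- matrix(integer(0L), ncol = 2L)
    for (s in seq_len(k)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        w <- sample_range(len_range[1L], len_range[2L], 1L)
        st <- sample.int(total - w + 1L, 1L)
        en <- st + w - 1L
        if (nrow(spans) == 0L ||
            all(en < spans[, 1L] - span_gap | st > spans[, 2L] + span_gap)) {
          spans <- rbind(spans, c(st, en))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("generation error: cannot place ", k,
             " non-overlapping segments in ", total, " residues",
             call. = FALSE)
      }
    }
    spans[order(spans[, 1L]), , drop = FALSE]
  }

  n_seg <- sample_range(cfg$n_segments[1L], cfg$n_segments[2L],
                        cfg$n_members)
  spans <- lapply(n_seg, pick_spans, len_range = cfg$segment_length,
                  total = cfg$scaffold_length)

  # assign cationic windows to distinct, wide-enough segments
  w <- cfg$cationic_window
  b <- cfg$cationic_min_basic
  cationic_plan <- lapply(seq_len(cfg$n_members), function(i) {
    eligible <- which(spans[[i]][, 2L] - spans[[i]][, 1L] + 1L >= w)
    k <- sample_range(cfg$n_cationic[1L], cfg$n_cationic[2L], 1L)
    k <- min(k, length(eligible))
    if (k == 0L) return(integer(0L))
    sort(resample(eligible, k))
  })

  # build a planted segment text; cationic segments get a window of b basic
  # residues at a fresh random offset, with basics pinned to both window ends
  # (any shifted window drops an end basic, so the planted window is the
  # strict in-segment maximum; needs b >= 2) and no basics elsewhere in the
  # segment. Returns the text and the window offset so rejection can redraw
  # both: with only two basic letters the cationic 3-mer space is small, and
  # redrawing the offset/positions is what lets cross-member collisions
  # resolve.
  build_segment <- function(len, cationic, nobasic = FALSE) {
    if (!cationic) {
      return(list(text = rand_aa(len, exclude = if (nobasic) c("R", "K")
                                   else character()),
                  cat_off = NA_integer_))
    }
    cat_off <- sample.int(len - w + 1L, 1L)
    body <- split1(rand_aa(len, exclude = c("R", "K")))
    basics_at <- c(cat_off, cat_off + w - 1L)
    if (b > 2L) {
      basics_at <- c(basics_at,
                     resample((cat_off + 1L):(cat_off + w - 2L), b - 2L))
    }
    basics_at <- unique(basics_at)[seq_len(min(b, w))]
    body[basics_at] <- sample(c("R", "K"), length(basics_at), replace = TRUE)
    list(text = paste(body, collapse = ""), cat_off = cat_off)
  }

  seg_text <- vector("list", cfg$n_members)
  seg_cat_off <- vector("list", cfg$n_members)
  seg_nobasic <- vector("list", cfg$n_members)
  for (i in seq_len(cfg$n_members)) {
    sp <- spans[[i]]
    seg_text[[i]] <- character(nrow(sp))
    seg_cat_off[[i]] <- rep(NA_integer_, nrow(sp))
    seg_nobasic[[i]] <- rep(FALSE, nrow(sp))
    for (k in seq_len(nrow(sp))) {
      built <- build_segment(sp[k, 2L] - sp[k, 1L] + 1L,
                             k %in% cationic_plan[[i]])
      seg_text[[i]][k] <- built$text
      seg_cat_off[[i]][k] <- built$cat_off
    }
  }

  # clear basic residues once in a fixed margin around cationic-designated
  # segments, so the planted window is the strict maximum of the downstream
  # scan; done before splicing and never re-randomized (keeps the fixpoint
  # loop below convergent)
  margin_width <- cfg$flank + w - 1L
  for (i in seq_len(cfg$n_members)) {
    sp <- spans[[i]]
    if (length(cationic_plan[[i]]) == 0L) next
    ch <- split1(seqs[i])
    in_any_span <- unlist(lapply(seq_len(nrow(sp)),
                                 function(k) sp[k, 1L]:sp[k, 2L]))
    for (k in cationic_plan[[i]]) {
      lo <- max(1L, sp[k, 1L] - margin_width)
      hi <- min(length(ch), sp[k, 2L] + margin_width)
      margin <- setdiff(lo:hi, in_any_span)
      basic <- margin[ch[margin] %in% c("R", "K")]
      if (length(basic) > 0L) {
        ch[basic] <- sample(setdiff(AA_ALPHABET, c("R", "K")),
                            length(basic), replace = TRUE)
      }
    }
    seqs[i] <- paste(ch, collapse = "")
  }

  splice <- function(text, spans, pieces) {
    ch <- split1(text)
    for (k in seq_len(nrow(spans))) {
      ch[spans[k, 1L]:spans[k, 2L]] <- split1(pieces[k])
    }
    paste(ch, collapse = "")
  }

  apply_splice <- function() {
    for (i in seq_len(cfg$n_members)) {
      seqs[i] <<- splice(seqs[i], spans[[i]], seg_text[[i]])
    }
  }
  apply_splice()

  # fixpoint 1: every L-window inside every planted segment must be absent
  # from all other members; resample offending segments (splicing each
  # replacement in immediately, so later checks in the same sweep see it)
  # and repeat until a full sweep is clean
  enforce_uniqueness <- function() {
    max_iter <- 300L
    for (iter in seq_len(max_iter)) {
      clean <- TRUE
      for (i in seq_len(cfg$n_members)) {
        sp <- spans[[i]]
        for (k in seq_len(nrow(sp))) {
          wins <- windows_of(substring(seqs[i], sp[k, 1L], sp[k, 2L]), L)
          others <- seqs[-i]
          bad <- any(vapply(wins, function(p) any(grepl(p, others, fixed = TRUE)),
                            logical(1L)))
          if (bad) {
            clean <- FALSE
            built <- build_segment(sp[k, 2L] - sp[k, 1L] + 1L,
                                   k %in% cationic_plan[[i]],
                                   nobasic = seg_nobasic[[i]][k])
            seg_text[[i]][k] <<- built$text
            seg_cat_off[[i]][k] <<- built$cat_off
            seqs[i] <<- splice(seqs[i], sp[k, , drop = FALSE],
                               seg_text[[i]][k])
          }
        }
      }
      if (clean) return(invisible(NULL))
    }
    stop("generation error: could not reach a uniqueness fixpoint; ",
         "reduce family size or noise, or enlarge the alphabet",
         call. = FALSE)
  }
  enforce_uniqueness()

  # fixpoint 2: each planted cationic window must be the strict winner of the
  # basic-count scan over the maximal unique run it ends up in (substitution
  # noise can fuse a planted segment with adjacent noise-unique stretches,
  # letting a basic-rich background window tie and win the leftmost
  # tie-break). Any window that ties or beats a planted one loses a basic
  # residue outside planted windows; uniqueness is then re-enforced.
  cationic_members <- which(vapply(seg_cat_off, function(x) any(!is.na(x)),
                                   logical(1L)))
  if (length(cationic_members) > 0L) {
    for (iter2 in seq_len(50L)) {
      contested <- FALSE
      fam_now <- seq_family(ids, unname(seqs))
      idx <- build_index(fam_now, L)
      for (i in cationic_members) {
        runs <- merge_segments(uniqueness_mask(idx, ids[i], 1L), idx)
        ks <- which(!is.na(seg_cat_off[[i]]))
        # two planted windows fused into one maximal unique run (noise can
        # bridge the gap between their segments with member-novel 3-mers):
        # restore the scaffold in the inter-segment gap so the run splits,
        # since only one representative window is reported per run
        cs_all <- spans[[i]][ks, 1L] + seg_cat_off[[i]][ks] - 1L
        run_of <- vapply(cs_all, function(p0) {
          hit <- which(runs$start <= p0 & runs$end >= p0 + w - 1L)
          if (length(hit) == 0L) NA_integer_ else hit[1L]
        }, integer(1L))
        if (anyDuplicated(stats::na.omit(run_of)) > 0L) {
          ch <- split1(seqs[i])
          sch <- split1(scaffold)
          in_span <- unlist(lapply(seq_len(nrow(spans[[i]])), function(kk) {
            spans[[i]][kk, 1L]:spans[[i]][kk, 2L]
          }))
          for (rid in unique(run_of[duplicated(run_of) & !is.na(run_of)])) {
            kk <- ks[which(run_of == rid)]
            gap <- setdiff(min(spans[[i]][kk, 1L]):max(spans[[i]][kk, 2L]),
                           in_span)
            ch[gap] <- sch[gap]
          }
          seqs[i] <- paste(ch, collapse = "")
          contested <- TRUE
          next  # runs are stale for this member now; recheck next sweep
        }
        for (k in ks) {
          cs <- spans[[i]][k, 1L] + seg_cat_off[[i]][k] - 1L
          ce <- cs + w - 1L
          run <- runs[runs$start <= cs & runs$end >= ce, , drop = FALSE]
          if (nrow(run) == 0L) next  # uniqueness fixpoint guarantees a run
          lo <- max(1L, run$start[1L] - cfg$flank)
          hi <- min(nchar(seqs[i]), run$end[1L] + cfg$flank)
          ws <- seq.int(lo, hi - w + 1L)
          bc <- basic_count(substring(seqs[i], ws, ws + w - 1L))
          planted_bc <- bc[ws == cs]
          beat <- ws[bc > planted_bc | (bc == planted_bc & ws < cs)]
          beat <- setdiff(beat, cs)
          if (length(beat) == 0L) next
          contested <- TRUE
          ch <- split1(seqs[i])
          protected <- unlist(lapply(ks, function(kk) {
            p0 <- spans[[i]][kk, 1L] + seg_cat_off[[i]][kk] - 1L
            p0:(p0 + w - 1L)
          }))
          for (bwin in beat) {
            cand <- setdiff(bwin:(bwin + w - 1L), protected)
            cand <- cand[ch[cand] %in% c("R", "K")]
            if (length(cand) > 0L) {
              ch[cand[1L]] <- resample(setdiff(AA_ALPHABET, c("R", "K")), 1L)
              # if the repair touched a planted segment, keep that segment
              # basic-free under any future uniqueness resample
              inseg <- which(spans[[i]][, 1L] <= cand[1L] &
                               spans[[i]][, 2L] >= cand[1L])
              if (length(inseg) > 0L) seg_nobasic[[i]][inseg] <- TRUE
            }
          }
          seqs[i] <- paste(ch, collapse = "")
          # keep seg_text in sync where the repair touched planted segments
          for (kk in seq_len(nrow(spans[[i]]))) {
            seg_text[[i]][kk] <- substring(seqs[i], spans[[i]][kk, 1L],
                                           spans[[i]][kk, 2L])
          }
        }
      }
      if (!contested) break
      enforce_uniqueness()
      if (iter2 == 50L) {
        stop("generation error: could not make planted cationic windows ",
             "dominant; lower noise or the number of cationic windows",
             call. = FALSE)
      }
    }
  }

  truth <- list(
    segments = do.call(rbind, lapply(seq_len(cfg$n_members), function(i) {
      sp <- spans[[i]]
      if (nrow(sp) == 0L) return(NULL)
      data.frame(member = ids[i], start = sp[, 1L], end = sp[, 2L],
                 stringsAsFactors = FALSE)
    })),
    cationic = do.call(rbind, lapply(seq_len(cfg$n_members), function(i) {
      keep <- which(!is.na(seg_cat_off[[i]]))
      if (length(keep) == 0L) return(NULL)
      st <- spans[[i]][keep, 1L] + seg_cat_off[[i]][keep] - 1L
      data.frame(member = ids[i], start = st, end = st + w - 1L,
                 stringsAsFactors = FALSE)
    })))
  if (is.null(truth$segments)) {
    truth$segments <- data.frame(member = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE)
  }
  if (is.null(truth$cationic)) {
    truth$cationic <- data.frame(member = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE)
  }
  list(family = seq_family(ids, unname(seqs),
                           desc = rep("synthetic member", cfg$n_members)),
       truth = truth)
}

#' Span-level precision and recall against planted truth
#'
#' A planted span counts as recovered when some detected span in the same
#' member *contains* it (`mode = "segment"`; detected unique segments may
#' legitimately extend past the planted splice) or *equals* it
#' (`mode = "hbr"`). Precision is the fraction of detections supported by a
#' planted span under the same rule; with zero detections and non-empty
#' truth, precision is reported as 1.0 by convention, with a warning.
#'
#' @param detected Data frame with `member`, `start`, `end` (e.g. from
#'   [unique_segments()] or [screen_family()]).
#' @param truth Data frame of planted spans (`member`, `start`, `end`).
#' @param mode `"segment"` (containment) or `"hbr"` (equality).
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
evaluate_recovery <- function(detected, truth, mode = c("segment", "hbr")) {
  mode <- match.arg(mode)
  matches <- function(d_s, d_e, t_s, t_e) {
    if (mode == "segment") d_s <= t_s & d_e >= t_e else d_s == t_s & d_e == t_e
  }
  hit_truth <- vapply(seq_len(nrow(truth)), function(t) {
    d <- detected[detected$member == truth$member[t], , drop = FALSE]
    nrow(d) > 0L && any(matches(d$start, d$end, truth$start[t], truth$end[t]))
  }, logical(1L))
  hit_det <- vapply(seq_len(nrow(detected)), function(d) {
    t <- truth[truth$member == detected$member[d], , drop = FALSE]
    nrow(t) > 0L && any(matches(detected$start[d], detected$end[d],
                                t$start, t$end))
  }, logical(1L))
  recall <- if (nrow(truth) == 0L) 1.0 else mean(hit_truth)
  if (nrow(detected) == 0L) {
    if (nrow(truth) > 0L) {
      warning("no detections against non-empty truth; precision reported ",
              "as 1.0 by convention", call. = FALSE)
    }
    precision <- 1.0
  } else {
    precision <- mean(hit_det)
  }
  c(precision = precision, recall = recall)
}
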