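#' Randomly sample fixed-length training segments at an expected coverage
#'
#' Training segments are drawn with replacement: a contig of length `L`
#' contributes `ceiling(coverage * L / segment_len)` segments whose start
#' positions are uniform on `[0, L - segment_len]`, giving an expected
#' per-base coverage equal to `coverage`. Contigs shorter than `segment_len`
#' contribute the whole sequence `ceiling(coverage)` times. Coordinates are
#' 0-based, half-open.
#'
#' @param contigs a [contig_set()].
#' @param segment_len segment length in bases (default 512).
#' @param coverage expected per-base coverage (default 10).
#' @param both_strands if `TRUE`, every sampled segment is also emitted as its
#'   reverse complement on strand `-`. Strand augmentation can equivalently be
#'   applied at the dataset level with [augment_reverse_complement()].
#' @param seed optional integer seed; when supplied, sampling is reproducible.
#' @return A `data.frame` with columns `contig_id`, `start`, `end`, `strand`,
#'   `seq`, `label`.
#' @export
sample_training_segments <- function(contigs, segment_len = 512L,
                                     coverage = 10, both_strands = FALSE,
                                     seed = NULL) {
  if (segment_len < 1L) stop("`segment_len` must be >= 1")
  if (coverage <= 0) stop("`coverage` must be positive")
  if (!is.null(seed)) set.seed(seed)
  segment_len <- as.integer(segment_len)

  pieces <- lapply(seq_len(nrow(contigs)), function(i) {
    s <- contigs$seq[i]
    L <- nchar(s)
    if (L >= segment_len) {
      n <- ceiling(coverage * L / segment_len)
      start <- sample.int(L - segment_len + 1L, n, replace = TRUE) - 1L
      end <- start + segment_len
    } else {
      n <- ceiling(coverage)
      start <- rep(0L, n)
      end <- rep(L, n)
    }
    data.frame(contig_id = contigs$id[i], start = start, end = end,
               strand = "+",
               seq = substring(s, start + 1L, end),
               label = contigs$label[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (both_strands) {
    minus <- out
    minus$strand <- "-"
    minus$seq <- reverse_complement(minus$seq)
    out <- rbind(out, minus)
    rownames(out) <- NULL
  }
  out
}

#' Tile a contig into contiguous, non-overlapping segments
#'
#' Windows are `[0, segment_len)`, `[segment_len, 2*segment_len)`, ... in
#' genomic order. A final partial window is kept only when its length is at
#' least `min_tail`; a contig shorter than `segment_len` is emitted whole.
#'
#' @inheritParams sample_training_segments
#' @param min_tail minimum length of the trailing partial window (default 50).
#' @return A `data.frame` of segments as in [sample_training_segments()].
#' @export
contiguous_segments <- function(contigs, segment_len = 512L, min_tail = 50L) {
  if (segment_len < 1L) stop("`segment_len` must be >= 1")
  segment_len <- as.integer(segment_len)
  pieces <- lapply(seq_len(nrow(contigs)), function(i) {
    s <- contigs$seq[i]
    L <- nchar(s)
    if (L < segment_len) {
      start <- 0L
      end <- L
    } else {
      start <- seq.int(0L, L - segment_len, by = segment_len)
      end <- start + segment_len
      tail_len <- L - end[length(end)]
      if (tail_len >= min_tail) {
        start <- c(start, end[length(end)])
        end <- c(end, L)
      }
    }
    data.frame(contig_id = contigs$id[i], start = start, end = end,
               strand = "+",
               seq = substring(s, start + 1L, end),
               label = contigs$label[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate fixed-length benchmark fragments from labeled contigs
#'
#' For each requested length `L`, an equal number of virulent-derived and
#' temperate-derived fragments is drawn; each fragment is a uniform random
#' slice of exactly `L` bases from a uniformly chosen source contig of that
#' class with length at least `L`. Fragments inherit the class label, and
#' their `source` field records the originating contig and coordinates for
#' leakage accounting.
#'
#' @param contigs a labeled [contig_set()] with both classes present.
#' @param lengths fragment lengths in bases (default `c(500, 2000, 10000)`).
#' @param n_per_class_per_length fragments per class per length.
#' @param seed optional integer seed.
#' @return A named list, one [contig_set()] of fragments per length.
#' @export
simulate_fragments <- function(contigs, lengths = c(500L, 2000L, 10000L),
                               n_per_class_per_length = 50L, seed = NULL) {
  if (any(is.na(contigs$label))) stop("all source contigs must be labeled")
  classes <- c("virulent", "temperate")
  if (!all(classes %in% contigs$label)) {
    stop("both classes must be present among source contigs")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_per_class_per_length)

  out <- lapply(lengths, function(L) {
    L <- as.integer(L)
    frag_rows <- lapply(classes, function(cl) {
      pool <- contigs[contigs$label == cl & nchar(contigs$seq) >= L, ,
                      drop = FALSE]
      if (nrow(pool) == 0L) {
        stop(sprintf("no %s contig of length >= %d available", cl, L))
      }
      pick <- sample.int(nrow(pool), n, replace = TRUE)
      len <- nchar(pool$seq[pick])
      start <- vapply(len - L + 1L, function(m) sample.int(m, 1L),
                      integer(1)) - 1L
      data.frame(
        id = sprintf("frag_L%d_%s_%03d", L, substr(cl, 1, 4), seq_len(n)),
        seq = substring(pool$seq[pick], start + 1L, start + L),
        label = cl,
        source = sprintf("%s:%d-%d", pool$id[pick], start, start + L),
        stringsAsFactors = FALSE
      )
    })
    fr <- do.call(rbind, frag_rows)
    rownames(fr) <- NULL
    class(fr) <- c("contig_set", "data.frame")
    fr
  })
  names(out) <- as.character(lengths)
  out
}

#' Add reverse-complement records to a contig set
#'
#' Strand orientation of assembled contigs is generally unknown, so datasets
#' are augmented so that every record contributes both strands. Reverse
#' complement records keep the label and get an `_rc` id suffix.
#'
#' @param contigs a [contig_set()].
#' @return A [contig_set()] with twice as many rows.
#' @export
augment_reverse_complement <- function(contigs) {
  rc <- contigs
  rc$id <- paste0(rc$id, "_rc")
  rc$seq <- reverse_complement(rc$seq)
  out <- rbind(contigs, rc)
  rownames(out) <- NULL
  class(out) <- c("contig_set", "data.frame")
  out
}

#' Per-base coverage profile implied by a set of segments
#'
#' @param segments a segment `data.frame` for a single contig.
#' @param contig_len length of the parent contig.
#' @return Integer vector of length `contig_len`: number of segments covering
#'   each base (strand-duplicated segments each count once).
#' @export
per_base_coverage <- function(segments, contig_len) {
  delta <- integer(contig_len + 1L)
  for (i in seq_len(nrow(segments))) {
    s <- segments$start[i]
    e <- segments$end[i]
    delta[s + 1L] <- delta[s + 1L] + 1L
    delta[e + 1L] <- delta[e + 1L] - 1L
  }
  cumsum(delta)[seq_len(contig_len)]
}
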