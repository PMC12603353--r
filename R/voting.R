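#' Combine segment predictions into one contig-level call by weighted voting
#'
#' The contig probability is the weighted mean of segment probabilities with
#' weights equal to segment length in bases, so a short trailing window
#' counts proportionally. Neutral, flagged predictions (p = 0.5 from
#' untokenizable segments) are excluded whenever at least one unflagged
#' prediction exists. A tie at exactly the threshold is called virulent.
#'
#' @param predictions `data.frame` from [predict_segments()] for ONE contig:
#'   columns `contig_id`, `start`, `end`, `p_virulent`, optionally `flagged`.
#' @param threshold decision threshold on p(virulent) (default 0.5).
#' @return A one-row `data.frame`: `contig_id`, `p_virulent`, `label`,
#'   `n_segments`, `total_bases_classified`.
#' @examples
#' pr <- data.frame(contig_id = "c", start = c(0, 300), end = c(300, 400),
#'                  p_virulent = c(1, 0))
#' vote_contig(pr)$p_virulent  # 0.75
#' @export
vote_contig <- function(predictions, threshold = 0.5) {
  if (nrow(predictions) == 0L) stop("no predictions to vote on")
  if (length(unique(predictions$contig_id)) != 1L) {
    stop("vote_contig expects predictions for a single contig")
  }
  if (!is.null(predictions$flagged) && any(!predictions$flagged)) {
    predictions <- predictions[!predictions$flagged, , drop = FALSE]
  }
  w <- predictions$end - predictions$start
  if (any(w <= 0)) stop("segment weights (lengths) must be positive")
  p <- sum(w * predictions$p_virulent) / sum(w)
  data.frame(
    contig_id = predictions$contig_id[1L],
    p_virulent = p,
    label = ifelse(p >= threshold, "virulent", "temperate"),
    n_segments = nrow(predictions),
    total_bases_classified = sum(w),
    stringsAsFactors = FALSE
  )
}

#' Classify whole contigs
#'
#' Each contig is tiled into contiguous segments, optionally duplicated onto
#' the reverse strand (both strand copies are pooled into one length-weighted
#' vote, so the call is strand-symmetric by construction), passed through the
#' segment classifier, and aggregated with [vote_contig()]. Deterministic for
#' a fixed model.
#'
#' @param model a trained `lysotyper_model`.
#' @param contigs a [contig_set()].
#' @param segment_len tiling window (default 512).
#' @param both_strands also predict the reverse complement of every segment.
#' @param threshold decision threshold on p(virulent).
#' @param batch_size forward-pass batch size.
#' @return A `data.frame` with one row per contig: `contig_id`,
#'   `p_virulent`, `label`, `n_segments`, `total_bases_classified`.
#' @export
predict_contigs <- function(model, contigs, segment_len = 512L,
                            both_strands = TRUE, threshold = 0.5,
                            batch_size = 32L) {
  segs <- contiguous_segments(contigs, segment_len = segment_len)
  if (both_strands) {
    minus <- segs
    minus$strand <- "-"
    minus$seq <- reverse_complement(minus$seq)
    segs <- rbind(segs, minus)
  }
  preds <- predict_segments(model, segs, batch_size = batch_size)
  out <- do.call(rbind, lapply(split(preds, preds$contig_id), vote_contig,
                               threshold = threshold))
  # restore input order
  out <- out[match(contigs$id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the contig-vote decision threshold on validation data
#'
#' The segment classifier's probabilities are separable but not necessarily
#' centred on 0.5 (background segments carry no lifestyle signal yet acquire
#' a small class drift during training). Fragments are drawn from held-out
#' validation contigs, voted on, and the threshold maximizing validation
#' balanced accuracy is returned (midpoint of the optimal split; ties break
#' towards 0.5). The calibrated value is then used for test-time calls.
#'
#' @param model a trained `lysotyper_model`.
#' @param contigs labeled validation [contig_set()] (both classes present).
#' @param fragment_len fragment length used for calibration (default 10 kb).
#' @param n_per_class fragments per class (default 25).
#' @param seed seed for fragment sampling.
#' @return Decision threshold in (0, 1).
#' @export
calibrate_vote_threshold <- function(model, contigs, fragment_len = 10000L,
                                     n_per_class = 25L, seed = 7L) {
  frags <- simulate_fragments(contigs, lengths = fragment_len,
                              n_per_class_per_length = n_per_class,
                              seed = seed)[[1L]]
  votes <- predict_contigs(model, frags, threshold = 0.5)
  p <- votes$p_virulent
  y <- frags$label[match(votes$contig_id, frags$id)] == "virulent"
  cand <- sort(unique(c(0.5, (utils::head(sort(p), -1) +
                                utils::tail(sort(p), -1)) / 2)))
  balacc <- vapply(cand, function(th) {
    (mean(p[y] >= th) + mean(p[!y] < th)) / 2
  }, numeric(1))
  best <- cand[balacc == max(balacc)]
  best[which.min(abs(best - 0.5))]
}
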