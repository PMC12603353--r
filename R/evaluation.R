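#' Confusion counts for lifestyle calls
#'
#' Virulent is the positive class throughout; temperate is negative.
#'
#' @param truth,pred character vectors of `"virulent"`/`"temperate"` calls.
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  check_labels(truth)
  check_labels(pred)
  list(tp = sum(truth == "virulent" & pred == "virulent"),
       fp = sum(truth == "temperate" & pred == "virulent"),
       tn = sum(truth == "temperate" & pred == "temperate"),
       fn = sum(truth == "virulent" & pred == "temperate"))
}

#' Binary classification metrics from confusion counts
#'
#' Computes accuracy, balanced accuracy, sensitivity, specificity, F1 and
#' the Matthews correlation coefficient, with virulent as the positive
#' class. Ratios with zero denominators are reported as `NA` and named in
#' the `undefined` attribute rather than silently coerced to 0.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see [confusion_counts()]).
#' @return One-row `data.frame` with the six metrics; attribute `undefined`
#'   lists metrics whose denominator was zero.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total < 1L) stop("confusion counts are all zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    ratio(2 * tp, 2 * tp + fp + fn)   # equivalent closed form, 0/0 -> NA
  } else {
    2 * prec * sens / (prec + sens)
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  balacc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  out <- data.frame(accuracy = (tp + tn) / total,
                    balanced_accuracy = balacc,
                    sensitivity = sens,
                    specificity = spec,
                    f1 = f1,
                    mcc = mcc)
  und <- names(out)[vapply(out, is.na, logical(1))]
  attr(out, "undefined") <- und
  out
}

#' Benchmark a contig-level predictor over simulated fragment sets
#'
#' Applies a predictor to each fragment set from [simulate_fragments()] and
#' assembles the per-fragment-length metric grid (one row per length), the
#' shape used to compare holdout schemes.
#'
#' @param predictor function taking a [contig_set()] and returning lifestyle
#'   labels (character vector, or a `data.frame` with a `label` column in
#'   input order).
#' @param fragment_sets named list of labeled fragment sets keyed by length.
#' @param holdout_mode label recorded in the output rows (e.g. `"strict"`,
#'   `"standard"`).
#' @return `data.frame`: one metric row per fragment length, with columns
#'   `fragment_length`, `holdout_mode` and the six metrics.
#' @export
benchmark_fragments <- function(predictor, fragment_sets,
                                holdout_mode = "standard") {
  rows <- lapply(names(fragment_sets), function(nm) {
    frags <- fragment_sets[[nm]]
    if (length(unique(frags$label)) < 2L) {
      stop(sprintf("fragment set '%s' contains a single class", nm))
    }
    pred <- predictor(frags)
    if (is.data.frame(pred)) pred <- pred$label
    m <- classification_metrics(confusion_counts(frags$label, pred))
    cbind(data.frame(fragment_length = as.integer(nm),
                     holdout_mode = holdout_mode), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end inference speed in classified nucleotides per second
#'
#' Wall time spans the entire predictor call on the raw records --
#' segmentation, tokenization, inference and aggregation included; nothing
#' is excluded. Speed is total input bases (each contig counted once)
#' divided by elapsed seconds, averaged over repeats.
#'
#' @param predictor function taking a [contig_set()] and returning anything;
#'   only its wall time is measured.
#' @param contigs a [contig_set()].
#' @param repeats number of repeated runs (default 1).
#' @return List: `nt_per_sec` (mean over runs), `elapsed_sec` (mean), and
#'   `runs` (`data.frame` of per-run values).
#' @export
inference_speed <- function(predictor, contigs, repeats = 1L) {
  if (nrow(contigs) == 0L) stop("no records to classify")
  total_nt <- sum(nchar(contigs$seq))
  runs <- data.frame(elapsed_sec = numeric(0), nt_per_sec = numeric(0))
  for (r in seq_len(repeats)) {
    t0 <- proc.time()[["elapsed"]]
    predictor(contigs)
    el <- proc.time()[["elapsed"]] - t0
    if (el <= 0) stop("elapsed time below clock resolution")
    runs <- rbind(runs, data.frame(elapsed_sec = el,
                                   nt_per_sec = total_nt / el))
  }
  list(nt_per_sec = mean(runs$nt_per_sec),
       elapsed_sec = mean(runs$elapsed_sec),
       runs = runs)
}
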