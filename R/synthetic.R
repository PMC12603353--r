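# Synthetic phage genome generator. Lifestyle is encoded as planted,
# mutation-noised motif cassettes on a random background: the synthetic
# analogue of the distinct gene repertoires of temperate phages (integrase /
# excisionase like signals) versus virulent phages (lysis / nucleotide
# metabolism like signals). Families of related genomes at controlled
# divergence exercise the leakage filter.

BASES <- c("A", "C", "G", "T")

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fixed default motif panels (12 disjoint 30-mers per class), generated from
# a constant internal seed and checked for 21-mer disjointness so the two
# classes share no canonical 21-mer signal.
default_motif_sets <- function(n_motifs = 12L, motif_len = 30L) {
  with_local_seed(20260301L, {
    repeat {
      vir <- replicate(n_motifs,
                       paste(sample(BASES, motif_len, replace = TRUE),
                             collapse = ""))
      tem <- replicate(n_motifs,
                       paste(sample(BASES, motif_len, replace = TRUE),
                             collapse = ""))
      if (motif_sets_disjoint(vir, tem)) break
    }
    list(virulent = vir, temperate = tem)
  })
}

motif_sets_disjoint <- function(vir, tem, k = 21L) {
  kv <- unique(unlist(lapply(vir, canonical_kmers, k = k)))
  kt <- unique(unlist(lapply(tem, canonical_kmers, k = k)))
  length(intersect(kv, kt)) == 0L
}

#' Configuration of the synthetic phage-genome generator
#'
#' @param genome_len_range genome length range in bp (default 20-100 kb,
#'   the typical span of phage genomes and virome contigs).
#' @param gc_content background GC fraction.
#' @param motif_set_virulent,motif_set_temperate fixed signature 30-mers per
#'   class; the default panels (12 per class) share no canonical 21-mer.
#' @param cassettes_per_genome motif copies planted per genome (default 100,
#'   chosen so 500 bp fragments are genuinely hard -- many carry no motif --
#'   while 10 kb fragments almost surely carry several).
#' @param motif_mutation_rate per-site substitution rate applied
#'   independently to each planted copy (must be in `[0, 0.3]`).
#' @param background_order Markov order of the background (0 or 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(genome_len_range = c(20000L, 100000L),
                             gc_content = 0.5,
                             motif_set_virulent = NULL,
                             motif_set_temperate = NULL,
                             cassettes_per_genome = 100L,
                             motif_mutation_rate = 0.05,
                             background_order = 0L) {
  if (motif_mutation_rate < 0 || motif_mutation_rate > 0.3) {
    stop("`motif_mutation_rate` must lie in [0, 0.3]")
  }
  if (!background_order %in% c(0L, 1L)) {
    stop("`background_order` must be 0 or 1")
  }
  if (is.null(motif_set_virulent) || is.null(motif_set_temperate)) {
    m <- default_motif_sets()
    if (is.null(motif_set_virulent)) motif_set_virulent <- m$virulent
    if (is.null(motif_set_temperate)) motif_set_temperate <- m$temperate
  }
  if (!motif_sets_disjoint(motif_set_virulent, motif_set_temperate)) {
    stop("class motif sets share canonical 21-mers")
  }
  structure(list(genome_len_range = as.integer(genome_len_range),
                 gc_content = gc_content,
                 motif_set_virulent = motif_set_virulent,
                 motif_set_temperate = motif_set_temperate,
                 cassettes_per_genome = as.integer(cassettes_per_genome),
                 motif_mutation_rate = motif_mutation_rate,
                 background_order = as.integer(background_order)),
            class = "generator_config")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_background <- function(L, gc, order) {
  p <- base_probs(gc)
  if (order == 0L) {
    return(sample(BASES, L, replace = TRUE, prob = p))
  }
  # order 1: mild self-transition enrichment with stationary GC preserved
  trans <- t(vapply(1:4, function(i) {
    w <- p * (1 + 0.5 * (seq_len(4) == i))
    w / sum(w)
  }, numeric(4)))
  cum <- t(apply(trans, 1L, cumsum))
  out <- integer(L)
  out[1L] <- sample.int(4L, 1L, prob = p)
  u <- stats::runif(L)
  for (i in 2:L) {
    out[i] <- findInterval(u[i], cum[out[i - 1L], ]) + 1L
  }
  BASES[out]
}

mutate_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  chars
}

#' Generate one labeled synthetic phage genome
#'
#' A random background sequence receives `cassettes_per_genome` copies of
#' motifs drawn from the class's panel, inserted at uniformly random,
#' non-overlapping positions; each copy is independently point-mutated at
#' `motif_mutation_rate`.
#'
#' @param lifestyle `"virulent"` or `"temperate"`.
#' @param cfg a [generator_config()].
#' @param id contig id for the record.
#' @param seed optional integer seed.
#' @return A one-row [contig_set()].
#' @export
generate_genome <- function(lifestyle = c("virulent", "temperate"),
                            cfg = generator_config(), id = "synth_1",
                            seed = NULL) {
  lifestyle <- match.arg(lifestyle)
  if (!is.null(seed)) set.seed(seed)
  span <- cfg$genome_len_range[2L] - cfg$genome_len_range[1L]
  L <- cfg$genome_len_range[1L] + sample.int(span + 1L, 1L) - 1L
  motifs <- if (lifestyle == "virulent") cfg$motif_set_virulent else
    cfg$motif_set_temperate
  w <- nchar(motifs[1L])
  m <- cfg$cassettes_per_genome
  if (L < m * w) {
    stop(sprintf("genome of length %d cannot host %d cassettes of %d bp",
                 L, m, w))
  }
  chars <- random_background(L, cfg$gc_content, cfg$background_order)
  # sorted gaps + fixed offsets give uniform non-overlapping cassette starts
  g <- sort(sample.int(L - m * w + 1L, m, replace = TRUE))
  starts <- g + (seq_len(m) - 1L) * w
  picks <- sample(motifs, m, replace = TRUE)
  for (i in seq_len(m)) {
    copy <- mutate_bases(strsplit(picks[i], "")[[1L]],
                         cfg$motif_mutation_rate)
    chars[starts[i]:(starts[i] + w - 1L)] <- copy
  }
  contig_set(id, paste(chars, collapse = ""), label = lifestyle,
             source = "synthetic")
}

#' Generate a class-balanced labeled dataset with disjoint splits
#'
#' @param n_per_class genomes per lifestyle class (over all splits).
#' @param cfg a [generator_config()].
#' @param seed integer seed; identical seeds reproduce the dataset
#'   bit-for-bit.
#' @param split fractions for the train/val/test partition (summing to 1).
#' @return List of three [contig_set()]s: `train`, `val`, `test`, each
#'   class-balanced, with pairwise-disjoint ids.
#' @export
generate_dataset <- function(n_per_class = 50L, cfg = generator_config(),
                             seed = 1L,
                             split = c(train = 0.6, val = 0.2, test = 0.2)) {
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1")
  if (abs(sum(split) - 1) > 1e-8) stop("`split` must sum to 1")
  set.seed(seed)
  records <- list()
  for (cl in c("virulent", "temperate")) {
    for (i in seq_len(n_per_class)) {
      id <- sprintf("%s_%03d", substr(cl, 1L, 3L), i)
      records[[id]] <- generate_genome(cl, cfg, id = id)
    }
  }
  all <- do.call(rbind, records)
  rownames(all) <- NULL
  class(all) <- c("contig_set", "data.frame")

  n_tr <- max(1L, round(split[["train"]] * n_per_class))
  n_va <- max(1L, round(split[["val"]] * n_per_class))
  n_te <- n_per_class - n_tr - n_va
  if (n_te < 1L) stop("`n_per_class` too small for three non-empty splits")
  assign_split <- rep(c(rep("train", n_tr), rep("val", n_va),
                        rep("test", n_te)), 2L)
  out <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    x <- all[assign_split == sp, , drop = FALSE]
    rownames(x) <- NULL
    class(x) <- c("contig_set", "data.frame")
    x
  })
  out
}

#' Generate a family of genomes at controlled divergence from an ancestor
#'
#' Each descendant is an independent per-site point mutant of the ancestor
#' (substitutions only, no indels), so true ANI to the ancestor is
#' analytically `1 - divergence`.
#'
#' @param ancestor a one-row [contig_set()] (or any row with `id`, `seq`,
#'   `label`).
#' @param divergence per-site substitution rate in `[0, 0.3]`.
#' @param n number of descendants.
#' @param seed optional integer seed.
#' @return A [contig_set()] of `n` descendants (`<ancestor id>_dN`).
#' @export
generate_family <- function(ancestor, divergence, n = 3L, seed = NULL) {
  if (divergence < 0 || divergence > 0.3) {
    stop("`divergence` must lie in [0, 0.3]")
  }
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(ancestor$seq[1L], "")[[1L]]
  desc <- vapply(seq_len(n), function(i) {
    paste(mutate_bases(chars, divergence), collapse = "")
  }, character(1))
  contig_set(sprintf("%s_d%d", ancestor$id[1L], seq_len(n)), desc,
             label = ancestor$label[1L], source = "synthetic_family")
}
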