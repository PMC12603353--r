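test_that("MurmurHash3 x64 matches an independent reference implementation", {
  # values frozen from a big-integer reference implementation of
  # MurmurHash3 x64 128-bit (first word)
  expect_equal(mm3_hash64("ACGTACGTACGTACGTACGTA", 3), "18b1fdabbfcb2f46")
  expect_equal(mm3_hash64("hello", 3), "084ad4bb6b86b133")
  expect_equal(mm3_hash64("aaaaaaaaaaaaaaaa", 3), "019bdca18ff966b8")
  expect_equal(mm3_hash64("The quick brown fox", 7), "85985b5142f02cc8")
  expect_equal(mm3_hash64("", 0), "0000000000000000")
})

test_that("sketches are deterministic, bounded at 300, and strand-invariant", {
  s <- random_dna(5000, seed = 31)
  a <- minhash_sketch(s, id = "a")
  b <- minhash_sketch(s, id = "b")
  expect_identical(a$mins, b$mins)
  expect_length(a$mins, 300)
  expect_identical(a$mins, sort(a$mins))
  expect_false(anyDuplicated(a$mins) > 0)
  rc <- minhash_sketch(reverse_complement(s), id = "rc")
  expect_identical(a$mins, rc$mins)
})

test_that("short sequences give short or empty sketches with a warning", {
  tiny <- minhash_sketch(random_dna(100, seed = 32), id = "t")
  expect_lt(length(tiny$mins), 300)
  expect_warning(minhash_sketch("ACGT", id = "x"), "empty sketch")
})

test_that("Jaccard estimator is exact at the extremes", {
  a <- minhash_sketch(random_dna(4000, seed = 33), id = "a")
  expect_equal(jaccard_estimate(a, a), 1.0)
  b <- minhash_sketch(random_dna(4000, seed = 34), id = "b")
  # two random 4 kb sequences share essentially no canonical 21-mer
  expect_lt(jaccard_estimate(a, b), 0.01)
  amod <- a
  amod$k <- 20L
  expect_error(jaccard_estimate(amod, b), "different")
})

test_that("Jaccard estimates track brute-force exact Jaccard", {
  set.seed(35)
  for (target in c(0.2, 0.5, 0.8)) {
    n <- 10000
    shared <- round((n - 20) * 2 * target / (1 + target))
    sa <- random_dna(n)
    sb <- paste0(substr(sa, 1, shared + 20), random_dna(n - shared - 20))
    ka <- canonical_kmers(sa, 21)
    kb <- canonical_kmers(sb, 21)
    exact <- length(intersect(ka, kb)) / length(union(ka, kb))
    est <- jaccard_estimate(minhash_sketch(sa, "a"), minhash_sketch(sb, "b"))
    expect_lt(abs(est - exact), 3 * sqrt(exact * (1 - exact) / 300) + 1e-9)
  }
})

test_that("unsaturated sketches recover the exact Jaccard", {
  # sequences with < 300 distinct 21-mers carry their complete hash sets
  sa <- random_dna(200, seed = 36)
  sb <- paste0(substr(sa, 1, 120), random_dna(80))
  ka <- canonical_kmers(sa, 21)
  kb <- canonical_kmers(sb, 21)
  exact <- length(intersect(ka, kb)) / length(union(ka, kb))
  est <- jaccard_estimate(minhash_sketch(sa, "a"), minhash_sketch(sb, "b"))
  expect_equal(est, exact)
})

test_that("ANI conversion follows the Mash formula and is monotone", {
  expect_equal(ani_from_jaccard(1, 21), 1)
  j <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  ani <- vapply(j, ani_from_jaccard, numeric(1), k = 21)
  expect_true(all(diff(ani) > 0))
  expect_equal(ani[2], 1 + log(0.2 / 1.1) / 21)
  z <- ani_from_jaccard(0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
  expect_error(ani_from_jaccard(1.2), "0, 1")
})

test_that("sketch ANI of mutated genomes matches the simulated divergence", {
  anc <- contig_set("anc", random_dna(50000, seed = 37), label = "virulent")
  fam <- generate_family(anc, divergence = 0.05, n = 2, seed = 38)
  for (i in 1:2) {
    jac <- jaccard_estimate(minhash_sketch(anc$seq, "anc"),
                            minhash_sketch(fam$seq[i], "d"))
    ani <- as.numeric(ani_from_jaccard(jac, 21))
    expect_lt(abs(ani - 0.95), 0.02)
  }
})

test_that("FastANI output parses with fraction conversion and validation", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "fastani.tsv")
  writeLines(c("a\tb\t97.5\t80\t100", "c\td\t81.25\t40\t160"), p)
  tab <- parse_fastani(p)
  expect_equal(tab$ani_est, c(0.975, 0.8125))
  expect_equal(tab$aligned_frac, c(0.80, 0.25))
  expect_equal(tab$source, c("fastani", "fastani"))

  writeLines(character(0), p)
  expect_equal(nrow(parse_fastani(p)), 0)

  writeLines(c("a\tb\t97.5\t80\t100", "a\tb\t97.5\t80"), p)
  expect_error(parse_fastani(p), "line 2")
})

test_that("standard holdout never removes; strict removes identical records", {
  train <- contig_set(c("t1", "t2"),
                      c(random_dna(20000, seed = 39),
                        random_dna(20000, seed = 40)),
                      label = "virulent")
  test <- contig_set("q1", train$seq[1], label = "virulent")
  std <- build_holdout(train, test, mode = "standard")
  expect_equal(nrow(std$train), 2)
  expect_equal(nrow(std$removed), 0)

  strict <- build_holdout(train, test, mode = "strict")
  expect_equal(strict$train$id, "t2")
  expect_equal(strict$removed$train_id, "t1")
  expect_equal(strict$removed$ani_est, 1)
  expect_equal(strict$removed$source, "sketch")
})

test_that("strict holdout with FastANI applies the two-part 80/80 rule", {
  train <- contig_set(c("t1", "t2", "t3"),
                      vapply(41:43, function(s) random_dna(1000, seed = s), ""),
                      label = "temperate")
  test <- contig_set("q", random_dna(1000, seed = 44), label = "temperate")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "fa.tsv")
  writeLines(c("t1\tq\t85\t90\t100",    # both criteria met -> removed
               "t2\tq\t85\t50\t100",    # aligned fraction too low -> kept
               "t3\tq\t75\t95\t100"),   # ANI too low -> kept
             p)
  res <- build_holdout(train, test, mode = "strict",
                       fastani = parse_fastani(p))
  expect_equal(res$train$id, c("t2", "t3"))
  expect_equal(res$removed$train_id, "t1")
})

test_that("strict holdout is re-verifiably leak-free on synthetic families", {
  cfg <- generator_config(genome_len_range = c(20000L, 25000L))
  anc <- generate_genome("virulent", cfg, id = "anc", seed = 45)
  near <- generate_family(anc, divergence = 0.05, n = 3, seed = 46)
  far <- generate_family(anc, divergence = 0.30, n = 3, seed = 47)
  near$id <- paste0("near_", near$id)
  far$id <- paste0("far_", far$id)
  other <- contig_set("bg", random_dna(20000, seed = 48),
                      label = "temperate")
  train <- rbind(near[1:2, ], far[1:2, ], other)
  class(train) <- c("contig_set", "data.frame")
  test <- rbind(near[3, ], far[3, ])
  test$id <- c("test_near", "test_far")
  class(test) <- c("contig_set", "data.frame")

  res <- build_holdout(train, test, mode = "strict")
  # 5% divergence relatives (ANI ~ 0.95) removed; 30% (ANI ~ 0.64) retained
  expect_true(all(near$id[1:2] %in% res$removed$train_id))
  expect_true(all(far$id[1:2] %in% res$train$id))
  expect_true("bg" %in% res$train$id)
  # re-verify: no surviving pair meets the criterion
  for (i in seq_len(nrow(res$train))) {
    for (j in seq_len(nrow(test))) {
      jac <- jaccard_estimate(minhash_sketch(res$train$seq[i], "x"),
                              minhash_sketch(test$seq[j], "y"))
      expect_lt(as.numeric(ani_from_jaccard(max(jac, 1e-12), 21)), 0.80)
    }
  }
})
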