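# Shared fixtures, all generated in code.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(records,
                            dir = withr::local_tempdir(
                              .local_envir = parent.frame())) {
  path <- file.path(dir, "x.fasta")
  writeLines(unlist(lapply(seq_along(records), function(i) {
    c(paste0(">", names(records)[i]), records[[i]])
  })), path)
  path
}

# brute-force canonical k-mer enumerator, independent of canonical_kmers():
# character-level complementation and explicit string reversal
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w)) next
    chars <- strsplit(w, "")[[1]]
    rc <- paste(rev(unname(comp[chars])), collapse = "")
    out <- c(out, min(w, rc))
  }
  unique(out)
}

# tiny trained-model cache so several tests can share one short training run
get_cached_tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(genome_len_range = c(20000L, 30000L),
                              cassettes_per_genome = 60L)
      set.seed(4242)
      tr <- do.call(rbind, lapply(1:4, function(i) rbind(
        generate_genome("virulent", cfg, id = sprintf("cv%d", i)),
        generate_genome("temperate", cfg, id = sprintf("ct%d", i)))))
      class(tr) <- c("contig_set", "data.frame")
      cache <<- train_lifestyle_model(tr, NULL, max_segments = 600L,
                                      epochs = 1L, learning_rate = 2e-3,
                                      batch_size = 16L, seed = 99L,
                                      quiet = TRUE)
    }
    cache
  }
})
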