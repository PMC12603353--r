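#' Construct a set of contig records
#'
#' A contig set is the package's basic container: a `data.frame` with one row
#' per contig and columns `id`, `seq`, `label`, `source`. Sequences are
#' normalized to uppercase over the closed alphabet `{A,C,G,T,N}`; any other
#' character (including ambiguous IUPAC codes) is collapsed to `N`.
#'
#' @param id character vector of unique contig identifiers.
#' @param seq character vector of nucleotide sequences (same length as `id`).
#' @param label optional lifestyle labels, `"virulent"` or `"temperate"`
#'   (`NA` allowed for unlabeled contigs).
#' @param source optional free-text provenance strings.
#' @return A `data.frame` of class `contig_set` with columns
#'   `id`, `seq`, `label`, `source`.
#' @examples
#' contig_set("p1", "acgtacgt", label = "virulent")
#' @export
contig_set <- function(id, seq, label = NA_character_, source = NA_character_) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length")
  }
  if (length(id) == 0L) {
    stop("a contig set must contain at least one record")
  }
  if (anyNA(id) || any(!nzchar(id))) {
    stop("contig ids must be non-missing and non-empty")
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate contig ids: ", paste(dup, collapse = ", "))
  }
  norm <- normalize_sequence(seq)
  if (any(!nzchar(norm$seq))) {
    stop("empty sequence for contig(s): ",
         paste(id[!nzchar(norm$seq)], collapse = ", "))
  }
  label <- check_labels(rep_len(as.character(label), length(id)))
  out <- data.frame(
    id = id,
    seq = norm$seq,
    label = label,
    source = rep_len(as.character(source), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contig_set", "data.frame")
  out
}

check_labels <- function(label) {
  bad <- !is.na(label) & !label %in% c("virulent", "temperate")
  if (any(bad)) {
    stop("labels must be 'virulent' or 'temperate'; got: ",
         paste(unique(label[bad]), collapse = ", "))
  }
  label
}

#' @keywords internal
normalize_sequence <- function(seq) {
  seq <- toupper(as.character(seq))
  n_total <- nchar(seq)
  clean <- gsub("[^ACGTN]", "N", seq)
  # ambiguity count = characters that were outside the closed alphabet
  n_amb <- n_total - nchar(gsub("[^ACGTN]", "", seq))
  list(seq = clean, n_ambiguous = sum(n_amb))
}

#' Read phage contigs from a FASTA file
#'
#' Reads a (optionally gzip-compressed) multi-record FASTA file into a
#' [contig_set()]. Lowercase bases are uppercased and characters outside
#' `{A,C,G,T,N}` are mapped to `N`; when that happens a warning reports how
#' many characters were replaced. The contig id is the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file (suffix `.gz` is auto-detected by the
#'   underlying reader).
#' @param labels optional named character vector or path to a two-column TSV
#'   (`contig_id<TAB>label`) assigning lifestyle labels.
#' @return A [contig_set()] with one row per FASTA record.
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- as.character(x)
  norm <- normalize_sequence(seqs)
  if (norm$n_ambiguous > 0L) {
    warning(sprintf("%d non-ACGTN character(s) replaced by N in %s",
                    norm$n_ambiguous, path))
  }
  cs <- contig_set(ids, norm$seq, source = path)
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      labels <- read_label_table(labels)
    }
    cs$label <- check_labels(unname(labels[cs$id]))
  }
  cs
}

#' Read a contig label table
#'
#' @param path two-column tab-separated file, `contig_id<TAB>label`, no header.
#' @return Named character vector mapping contig id to label.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("contig_id", "label"),
                           colClasses = "character")
  check_labels(tab$label)
  if (anyDuplicated(tab$contig_id)) {
    stop("duplicate contig ids in label table: ", path)
  }
  stats::setNames(tab$label, tab$contig_id)
}

#' Write contigs to a FASTA file
#'
#' Records are wrapped at 70 characters per line; a `.gz` suffix triggers
#' gzip compression.
#'
#' @param contigs a [contig_set()] (or any data.frame with `id` and `seq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  x <- Biostrings::BStringSet(stats::setNames(contigs$seq, contigs$id))
  compress <- grepl("\\.gz$", path)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L,
                              compress = compress)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' Watson-Crick complement, reversed; `N` is its own complement. Vectorized
#' over its input.
#'
#' @param seq character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- as.character(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))
  )
  unname(out)
}

#' Canonical k-mer set of a sequence
#'
#' Every length-`k` window free of `N` contributes the lexicographic minimum
#' of the window and its reverse complement; windows containing `N` are
#' skipped. The distinct set is returned, so the result is invariant under
#' reverse complementation of the input.
#'
#' @param seq a single nucleotide sequence over `{A,C,G,T,N}`.
#' @param k k-mer size (positive integer).
#' @return Character vector of distinct canonical k-mers (possibly empty).
#' @examples
#' canonical_kmers("AAAA", 2)  # "AA" (TT canonicalizes to AA)
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L, k >= 1L)
  k <- as.integer(k)
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- substring(seq, 1:(n - k + 1L), k:n)
  rc <- reverse_complement(seq)
  # window i of seq corresponds to window (n-k+2-i) of the reverse complement
  rcw <- rev(substring(rc, 1:(n - k + 1L), k:n))
  keep <- !grepl("N", fwd, fixed = TRUE)
  unique(pmin(fwd[keep], rcw[keep]))
}
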