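#' Minimum-length read filter
#'
#' Splits reads into those at least `min_length` nt long and those below
#' it (the downstream pipeline ignores the short ones).
#'
#' @param reads Read table (see [read_sequences()]).
#' @param min_length Minimum kept read length in nt.
#' @return List with `kept` and `removed_short` read tables.
#' @export
length_filter <- function(reads, min_length = 15L) {
  keep <- nchar(reads$sequence) >= min_length
  list(kept = reads[keep, , drop = FALSE],
       removed_short = reads[!keep, , drop = FALSE])
}

#' Build the environmental-contamination index
#'
#' Deduplicates the sequences of environmental (no-template control) reads
#' and drops those shorter than `min_length`, so that trivially short
#' patterns cannot wipe out the samples.
#'
#' @param env_reads Read table of reads from samples labelled
#'   `group = "environment"`.
#' @param min_length Minimum indexed pattern length in nt.
#' @return Object of class `environment_index`: list with `sequences`
#'   (unique patterns, sorted), `min_length`, `n_too_short`.
#' @export
build_environment_index <- function(env_reads, min_length = 15L) {
  seqs <- unique(env_reads$sequence)
  too_short <- nchar(seqs) < min_length
  if (nrow(env_reads) == 0L) {
    warning("no environment reads supplied; environment filtering is a no-op")
  }
  structure(list(sequences = sort(seqs[!too_short]),
                 min_length = min_length,
                 n_too_short = sum(too_short)),
            class = "environment_index")
}

#' Filter sample reads against the environment index
#'
#' A read is removed iff its sequence is identical to an indexed
#' environmental sequence, or contains one as a contiguous forward-strand
#' substring. With `contain_both = TRUE`, reads that are themselves
#' substrings of an indexed sequence are removed as well.
#'
#' @param sample_reads Read table to filter.
#' @param index An [build_environment_index()] result.
#' @param contain_both Also remove sample reads contained in an indexed
#'   sequence.
#' @return List with `kept`, `removed`, and `stats` (per-sample removed
#'   counts and fractions).
#' @export
filter_environment <- function(sample_reads, index, contain_both = FALSE) {
  stopifnot(inherits(index, "environment_index"))
  seqs <- sample_reads$sequence
  uniq <- unique(seqs)
  removed_u <- logical(length(uniq))
  if (length(index$sequences) && length(uniq)) {
    # exact identity first (fast path), then substring containment
    removed_u <- uniq %in% index$sequences
    todo <- which(!removed_u)
    # shortest patterns first: they match the most reads, shrinking `todo`
    pats <- index$sequences[order(nchar(index$sequences))]
    for (p in pats) {
      if (!length(todo)) break
      hit <- stringi::stri_detect_fixed(uniq[todo], p)
      if (any(hit)) {
        removed_u[todo[hit]] <- TRUE
        todo <- todo[!hit]
      }
    }
    if (contain_both && length(todo)) {
      for (i in todo) {
        if (any(stringi::stri_detect_fixed(index$sequences, uniq[i]))) {
          removed_u[i] <- TRUE
        }
      }
    }
  }
  removed <- removed_u[match(seqs, uniq)]
  stats <- NULL
  if (nrow(sample_reads)) {
    dt <- data.table(sample_id = sample_reads$sample_id, removed = removed)
    stats <- as.data.frame(dt[, .(n_reads = .N, n_removed = sum(removed),
                                  fraction_removed = mean(removed)),
                              by = sample_id])
  } else {
    stats <- data.frame(sample_id = character(0), n_reads = integer(0),
                        n_removed = integer(0), fraction_removed = numeric(0))
  }
  list(kept = sample_reads[!removed, , drop = FALSE],
       removed = sample_reads[removed, , drop = FALSE],
       stats = stats)
}
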