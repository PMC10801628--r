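# Shared fixtures, generated once per test run.

# Small simulated study: toy references + 4 samples x 800 reads + an
# environment library. Memoised so test files can share it.
.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- simulation_config(seed = 42L, reads_per_sample = 800L,
                             n_test = 2L, n_control = 2L,
                             environment_reads = 300L)
    refs <- make_toy_references(cfg)
    sim <- simulate_reads(refs, cfg)
    env <- simulate_environment_sample(refs, sim$reads, cfg)
    .fixture_env$study <- list(cfg = cfg, refs = refs, sim = sim, env = env)
  }
  .fixture_env$study
}

# Random feature table on one contig (uniform starts, geometric-ish
# lengths), for merge/counting property tests.
random_feature_set <- function(n, genome_len = 10000L, seqid = "chr1",
                               source_db = "src", max_len = 120L,
                               stranded = TRUE) {
  start <- sample.int(genome_len - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  df <- data.frame(
    seqid = seqid, start = start, end = start + len - 1L,
    strand = if (stranded) sample(c("+", "-"), n, replace = TRUE) else "+",
    source_db = source_db, rna_type = "other_RNA",
    name = paste0("f", seq_len(n)), stringsAsFactors = FALSE)
  df$attributes <- rep(list(list()), n)
  df
}

# Independent O(n^2) oracle for interval-union merging: build the overlap
# adjacency per (seqid, strand), take connected components (igraph), and
# return the component spans sorted by coordinates.
brute_force_merge_spans <- function(features) {
  key <- paste(features$seqid, features$strand)
  spans <- lapply(split(seq_len(nrow(features)), key), function(ix) {
    s <- features$start[ix]; e <- features$end[ix]
    adj <- outer(s, e, "<=") & outer(e, s, ">=")
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    data.frame(seqid = features$seqid[ix[1]],
               strand = features$strand[ix[1]],
               start = as.integer(tapply(s, comp$membership, min)),
               end = as.integer(tapply(e, comp$membership, max)),
               n_members = as.integer(tapply(s, comp$membership, length)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  out <- out[order(out$seqid, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Base-coverage per (seqid, strand) as a set of covered positions.
covered_positions <- function(features) {
  key <- paste(features$seqid, features$strand)
  lapply(split(seq_len(nrow(features)), key), function(ix) {
    sort(unique(unlist(mapply(seq, features$start[ix], features$end[ix],
                              SIMPLIFY = FALSE))))
  })
}

# Quadratic substring oracle for the environment filter: every pattern is
# tested against every read (no dedup, no early exit); a read is removed
# iff some pattern is a substring of it.
naive_env_decisions <- function(read_seqs, patterns) {
  removed <- logical(length(read_seqs))
  for (p in patterns) {
    removed <- removed | grepl(p, read_seqs, fixed = TRUE)
  }
  removed
}

# Tiny taxonomy used by taxa unit tests (subset of the simulator's).
tiny_taxonomy <- function() {
  data.frame(
    taxon_id  = c(1L, 131567L, 2759L, 9606L, 2L, 561L, 562L, 1280L),
    parent_id = c(1L, 1L, 131567L, 2759L, 131567L, 2L, 561L, 2L),
    rank = c("no rank", "no rank", "superkingdom", "species",
             "superkingdom", "genus", "species", "species"),
    name = c("root", "cellular organisms", "Eukaryota", "Homo sapiens",
             "Bacteria", "Escherichia", "Escherichia coli",
             "Staphylococcus aureus"),
    stringsAsFactors = FALSE)
}

# Hit-table builder for two-pass tests.
hit_row <- function(read, taxid, bitscore, group = NA_character_) {
  data.frame(query_id = read, subject_id = "s", percent_identity = 100,
             aln_length = 20, evalue = 0, bitscore = bitscore,
             taxon_id = taxid,
             group = group, stringsAsFactors = FALSE)
}
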