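#' Simulation configuration
#'
#' Defaults mirror the study design used to benchmark the pipeline:
#' 10 samples (5 test + 5 control) of 10,000 reads each, read lengths
#' uniform over 10-44 nt, error-free by default, drawn from a toy host
#' genome with deliberately overlapping multi-source annotations plus a
#' small set of microbial genomes.
#'
#' @param seed Master seed; every generator derives from it.
#' @param host_genome_length Host genome length (nt).
#' @param microbial_genomes Named integer vector: species taxid (as name)
#'   -> genome length. Names must exist in the toy taxonomy.
#' @param features_per_type Features generated per host RNA type and
#'   source.
#' @param reads_per_sample Reads per sample.
#' @param read_length_range Inclusive read-length range (nt).
#' @param error_rate Per-base substitution probability.
#' @param microbial_read_fraction Fraction of reads drawn from microbial
#'   genomes instead of host features.
#' @param background_read_fraction Fraction of reads drawn uniformly from
#'   the host genome rather than from a feature (degradation background:
#'   these land in intergenic or intronic space unless they happen to hit
#'   a feature).
#' @param canonical_read_fraction For host feature reads, probability of
#'   emitting the feature's canonical mature sequence (its 5' end, up to
#'   22 nt) instead of a random fragment; models the fact that mature
#'   small RNAs recur as identical sequences.
#' @param n_de_features Number of miRNA features upweighted in the test
#'   group (a planted differential-expression signal).
#' @param de_fold Sampling-weight fold change of those features in test
#'   samples.
#' @param n_test,n_control Group design.
#' @param environment_reads Reads in the environmental control library.
#' @param contaminant_genome_length Length of the reagent-contaminant
#'   genome behind the environment sample.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              host_genome_length = 100000L,
                              microbial_genomes = c("562" = 20000L,
                                                    "1280" = 15000L),
                              features_per_type = 25L,
                              reads_per_sample = 10000L,
                              read_length_range = c(10L, 44L),
                              error_rate = 0,
                              microbial_read_fraction = 0.15,
                              background_read_fraction = 0.1,
                              canonical_read_fraction = 0.5,
                              n_de_features = 5L, de_fold = 4,
                              n_test = 5L, n_control = 5L,
                              environment_reads = 500L,
                              contaminant_genome_length = 5000L) {
  stopifnot(host_genome_length > 0, all(microbial_genomes > 0),
            error_rate >= 0, error_rate < 1,
            read_length_range[1] >= 1,
            read_length_range[2] <= host_genome_length)
  structure(as.list(environment()), class = "sim_config")
}

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Toy taxonomy covering the default group roots actually exercised by the
# fixtures: host (Homo sapiens), two bacteria, a fungus, a virus, and a
# synthetic reagent-contaminant species.
toy_taxonomy <- function() {
  data.frame(
    taxon_id = c(1L, 131567L, 2759L, 33208L, 9606L,
                 2L, 1224L, 561L, 562L, 1279L, 1280L,
                 4751L, 4932L, 10239L, 2731342L, 10847L,
                 28384L, 32630L),
    parent_id = c(1L, 1L, 131567L, 2759L, 33208L,
                  131567L, 2L, 1224L, 561L, 2L, 1279L,
                  2759L, 4751L, 1L, 10239L, 2731342L,
                  1L, 28384L),
    rank = c("no rank", "no rank", "superkingdom", "kingdom", "species",
             "superkingdom", "phylum", "genus", "species", "genus",
             "species", "kingdom", "species", "superkingdom", "class",
             "species", "no rank", "species"),
    name = c("root", "cellular organisms", "Eukaryota", "Metazoa",
             "Homo sapiens", "Bacteria", "Pseudomonadota", "Escherichia",
             "Escherichia coli", "Staphylococcus", "Staphylococcus aureus",
             "Fungi", "Saccharomyces cerevisiae", "Viruses",
             "Caudoviricetes", "Escherichia phage phiX174",
             "other sequences", "synthetic construct"),
    stringsAsFactors = FALSE)
}

# Internal: lay n non-overlapping-ish features of a given type on the host
# genome. `jitter_overlap` re-places a fraction on top of earlier features
# to create deliberate within-source overlaps.
random_features <- function(n, len_range, type, source_db, prefix,
                            genome_len, seqid, overlap_fraction = 0) {
  start <- sample.int(genome_len - len_range[2], n, replace = TRUE)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  if (overlap_fraction > 0 && n >= 2L) {
    k <- max(1L, round(overlap_fraction * n))
    src <- sample.int(n - k, k, replace = TRUE)
    tgt <- (n - k + 1L):n
    start[tgt] <- pmax(1L, start[src] + sample(-5L:5L, k, replace = TRUE))
    len[tgt] <- pmin(len[tgt], genome_len - start[tgt])
  }
  df <- data.frame(seqid = seqid, start = start, end = start + len - 1L,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   source_db = source_db, rna_type = type,
                   name = paste0(prefix, seq_len(n)),
                   stringsAsFactors = FALSE)
  df$attributes <- rep(list(list()), n)
  df
}

#' Generate toy reference genomes, annotations and taxonomy
#'
#' Produces a random host genome with multi-source annotations that
#' contain deliberate within-source overlaps and cross-source overlaps
#' (piRNA features placed inside tRNA loci, the classic conflict the
#' priority schema resolves), microbial genomes for the configured
#' species, a reagent-contaminant genome, and the toy taxonomy.
#'
#' @param config A [simulation_config()].
#' @return List: `genomes` (named list of `DNAStringSet`, one per taxid,
#'   plus `contaminant`), `host_seqid`, `sources` (named list of feature
#'   tables), `taxonomy`, `config`.
#' @export
make_toy_references <- function(config) {
  with_seed(config$seed, {
    host_seqid <- "host_chr1"
    host <- random_genome(config$host_genome_length)
    genomes <- list("9606" = Biostrings::DNAStringSet(setNames(host,
                                                               host_seqid)))
    for (tid in names(config$microbial_genomes)) {
      nm <- paste0("mg", tid, "_chr1")
      genomes[[tid]] <- Biostrings::DNAStringSet(
        setNames(random_genome(config$microbial_genomes[[tid]]), nm))
    }
    genomes$contaminant <- Biostrings::DNAStringSet(
      setNames(random_genome(config$contaminant_genome_length),
               "contam_chr1"))
    npt <- config$features_per_type
    gl <- config$host_genome_length
    mirna <- random_features(npt, c(20L, 24L), "miRNA", "mirbase_like",
                             "mir", gl, host_seqid)
    trna <- random_features(npt, c(70L, 90L), "tRNA", "gtrnadb_like",
                            "trna", gl, host_seqid)
    # cross-source conflict: piRNAs nested inside tRNA loci
    pirna <- random_features(npt, c(26L, 30L), "piRNA", "pirbase_like",
                             "pir", gl, host_seqid,
                             overlap_fraction = 0)
    nested <- seq_len(max(2L, npt %/% 3L))
    pirna$start[nested] <- trna$start[nested] + 5L
    pirna$end[nested] <- pmin(pirna$start[nested] + 27L, trna$end[nested])
    pirna$strand[nested] <- trna$strand[nested]
    # gencode-like source with within-source overlapping mRNA exons,
    # grouped into genes so introns exist
    genes <- vector("list", npt)
    gene_start <- sample.int(gl - 1200L, npt, replace = TRUE)
    for (i in seq_len(npt)) {
      s1 <- gene_start[i]
      strand <- sample(c("+", "-"), 1)
      ex <- data.frame(
        seqid = host_seqid,
        start = c(s1, s1 + 60L, s1 + 400L),
        end = c(s1 + 120L, s1 + 180L, s1 + 520L),
        strand = strand, source_db = "gencode_like", rna_type = "mRNA",
        name = paste0("gene", i, ".ex", 1:3),
        stringsAsFactors = FALSE)
      ex$attributes <- rep(list(list(gene_id = paste0("gene", i))), 3L)
      genes[[i]] <- ex
    }
    gencode <- do.call(rbind, genes)
    extra <- rbind(
      random_features(npt, c(100L, 150L), "rRNA", "gencode_like", "rrna",
                      gl, host_seqid),
      random_features(npt, c(60L, 110L), "snoRNA", "gencode_like", "sno",
                      gl, host_seqid),
      random_features(npt, c(120L, 200L), "lncRNA", "gencode_like", "lnc",
                      gl, host_seqid, overlap_fraction = 0.2))
    gencode <- rbind(gencode, extra)
    sources <- list(mirbase_like = mirna, gtrnadb_like = trna,
                    pirbase_like = pirna, gencode_like = gencode)
    list(genomes = genomes, host_seqid = host_seqid, sources = sources,
         taxonomy = toy_taxonomy(), config = config)
  })
}

# Internal: vectorised substitution errors.
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  chars <- strsplit(seqs, "")
  unlist(lapply(chars, function(v) {
    hit <- runif(length(v)) < rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    paste(v, collapse = "")
  }))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate small-RNA samples with per-read truth labels
#'
#' Reads are genomic substrings starting inside an annotated host feature
#' (strand-aware) or inside a microbial genome, with uniform length in the
#' configured 10-44 nt range and optional substitution errors. Truth is
#' carried in the read id as `species|feature|type|pos|serial`, so
#' evaluation needs no side table (a tidy truth table is returned too).
#'
#' @param references A [make_toy_references()] result.
#' @param config Defaults to `references$config`.
#' @return List: `reads` (read table over all samples), `truth`
#'   (`data.frame`), `samples` (sample sheet with group labels).
#' @export
simulate_reads <- function(references, config = references$config) {
  host_tid <- 9606L
  sources <- do.call(rbind, lapply(references$sources, function(x)
    x[, c("seqid", "start", "end", "strand", "rna_type", "name")]))
  host_seq <- as.character(references$genomes[["9606"]][[1]])
  gl <- nchar(host_seq)
  micro_ids <- names(config$microbial_genomes)
  micro_seqs <- lapply(micro_ids, function(t)
    as.character(references$genomes[[t]][[1]]))
  names(micro_seqs) <- micro_ids
  samples <- data.frame(
    sample_id = c(sprintf("test%02d", seq_len(config$n_test)),
                  sprintf("ctrl%02d", seq_len(config$n_control))),
    group = c(rep("test", config$n_test),
              rep("control", config$n_control)),
    stringsAsFactors = FALSE)
  lr <- config$read_length_range
  with_seed(config$seed + 1L, {
    all_reads <- vector("list", nrow(samples))
    for (si in seq_len(nrow(samples))) {
      n <- config$reads_per_sample
      n_micro <- rbinom(1L, n, config$microbial_read_fraction)
      n_bg <- rbinom(1L, n - n_micro, config$background_read_fraction)
      n_host <- n - n_micro - n_bg
      # host reads: start uniformly inside a random feature, with a
      # planted group effect on the first miRNA features
      w <- rep(1, nrow(sources))
      de_idx <- which(sources$rna_type == "miRNA")
      de_idx <- de_idx[seq_len(min(config$n_de_features, length(de_idx)))]
      if (samples$group[si] == "test") w[de_idx] <- config$de_fold
      fi <- sample.int(nrow(sources), n_host, replace = TRUE, prob = w)
      fs <- sources$start[fi]
      fe <- sources$end[fi]
      pos <- fs + floor(runif(n_host) * (fe - fs + 1L))
      len <- sample(lr[1]:lr[2], n_host, replace = TRUE)
      # canonical mature reads: the feature's 5' end, up to 22 nt,
      # identical every time it is drawn
      canon <- runif(n_host) < config$canonical_read_fraction
      fi_len <- fe - fs + 1L
      clen <- pmin(fi_len, 22L)
      minus_f <- sources$strand[fi] == "-"
      pos[canon & !minus_f] <- fs[canon & !minus_f]
      pos[canon & minus_f] <- fe[canon & minus_f] - clen[canon & minus_f] + 1L
      len[canon] <- clen[canon]
      pos <- pmin(pos, gl - len + 1L)
      seqs <- stringi::stri_sub(host_seq, pos, length = len)
      minus <- minus_f
      seqs[minus] <- revcomp_chr(seqs[minus])
      host_df <- data.frame(
        species = host_tid, feature = sources$name[fi],
        rna_type = sources$rna_type[fi], pos = pos, sequence = seqs,
        stringsAsFactors = FALSE)
      # background reads: uniform over the host genome
      bg_df <- NULL
      if (n_bg > 0L) {
        blen <- sample(lr[1]:lr[2], n_bg, replace = TRUE)
        bpos <- 1L + floor(runif(n_bg) * (gl - blen + 1L))
        bseq <- stringi::stri_sub(host_seq, bpos, length = blen)
        bminus <- sample(c(FALSE, TRUE), n_bg, replace = TRUE)
        bseq[bminus] <- revcomp_chr(bseq[bminus])
        bg_df <- data.frame(
          species = host_tid, feature = "background",
          rna_type = "background", pos = bpos, sequence = bseq,
          stringsAsFactors = FALSE)
      }
      # microbial reads: uniform over the microbial genomes
      micro_df <- NULL
      if (n_micro > 0L) {
        mt <- sample(micro_ids, n_micro, replace = TRUE)
        mlen <- sample(lr[1]:lr[2], n_micro, replace = TRUE)
        mpos <- vapply(seq_len(n_micro), function(i) {
          L <- nchar(micro_seqs[[mt[i]]])
          1L + floor(runif(1) * (L - mlen[i] + 1L))
        }, numeric(1))
        mseq <- vapply(seq_len(n_micro), function(i)
          stringi::stri_sub(micro_seqs[[mt[i]]], mpos[i],
                            length = mlen[i]), character(1))
        mstrand <- sample(c(FALSE, TRUE), n_micro, replace = TRUE)
        mseq[mstrand] <- revcomp_chr(mseq[mstrand])
        micro_df <- data.frame(
          species = as.integer(mt), feature = "genome",
          rna_type = "genomic", pos = mpos, sequence = mseq,
          stringsAsFactors = FALSE)
      }
      df <- rbind(host_df, bg_df, micro_df)
      df$sequence <- apply_errors(df$sequence, config$error_rate)
      df$read_id <- sprintf("%d|%s|%s|%d|%s_%05d", df$species, df$feature,
                            df$rna_type, df$pos,
                            samples$sample_id[si], seq_len(nrow(df)))
      df$sample_id <- samples$sample_id[si]
      df$group <- samples$group[si]
      all_reads[[si]] <- df
    }
    truth <- do.call(rbind, all_reads)
    reads <- data.frame(read_id = truth$read_id,
                        sequence = truth$sequence,
                        quality = NA_character_,
                        sample_id = truth$sample_id, group = truth$group,
                        stringsAsFactors = FALSE)
    list(reads = reads,
         truth = truth[, c("read_id", "sample_id", "species", "feature",
                           "rna_type", "pos")],
         samples = samples)
  })
}

#' Simulate an environmental (no-template) control sample
#'
#' The environment library mixes reads from the reagent-contaminant
#' genome with planted copies of sample reads: exact duplicates and
#' prefixes (>= 15 nt) of longer sample reads, so that the environment
#' filter has known true positives of both removal kinds (identity and
#' substring containment).
#'
#' @param references A [make_toy_references()] result.
#' @param sample_reads Read table the contaminants are planted from.
#' @param config Defaults to `references$config`.
#' @param planted_fraction Fraction of environment reads copied from
#'   sample reads.
#' @return List: `env_reads` (read table, group `environment`),
#'   `planted_read_ids` (sample read ids that are true contaminants).
#' @export
simulate_environment_sample <- function(references, sample_reads,
                                        config = references$config,
                                        planted_fraction = 0.3) {
  contam <- as.character(references$genomes$contaminant[[1]])
  L <- nchar(contam)
  lr <- config$read_length_range
  with_seed(config$seed + 2L, {
    n <- config$environment_reads
    n_plant <- round(planted_fraction * n)
    n_bg <- n - n_plant
    len <- sample(lr[1]:lr[2], n_bg, replace = TRUE)
    pos <- 1L + floor(runif(n_bg) * (L - len + 1L))
    bg <- stringi::stri_sub(contam, pos, length = len)
    eligible <- which(nchar(sample_reads$sequence) >= 15L)
    pick <- sample(eligible, min(n_plant, length(eligible)))
    half <- length(pick) %/% 2L
    exact <- sample_reads$sequence[pick[seq_len(half)]]
    # prefixes of at least 15 nt: the sample read then CONTAINS the
    # environment sequence
    rest <- pick[-seq_len(half)]
    pref <- vapply(sample_reads$sequence[rest], function(s) {
      substr(s, 1L, max(15L, nchar(s) - sample(0:5, 1L)))
    }, character(1), USE.NAMES = FALSE)
    env_seq <- c(bg, exact, pref)
    env <- data.frame(read_id = sprintf("env_%05d", seq_along(env_seq)),
                      sequence = env_seq, quality = NA_character_,
                      sample_id = "environment01", group = "environment",
                      stringsAsFactors = FALSE)
    planted <- sample_reads$read_id[pick]
    # any other sample read sharing a planted sequence (or containing a
    # planted prefix) is a true contaminant too
    list(env_reads = env, planted_read_ids = planted)
  })
}

#' Exhaustive mismatch-tolerant toy aligner
#'
#' Reports every placement of every read with at most `max_mismatches`
#' substitutions (no indels) on either strand of the given references,
#' together with a BLAST-style hit table whose bitscore proxy is
#' `2*matches - 3*mismatches` (monotone in matches; not a real BLAST
#' bitscore). Exact search (`max_mismatches = 0`) runs through a
#' dictionary match over length-grouped reads and is fast at the
#' 10^5-read scale; mismatch-tolerant search scans pattern by pattern and
#' is intended for small fixtures.
#'
#' @param reads Read table.
#' @param references Named list of `DNAStringSet`s keyed by species taxid
#'   (the `genomes` element of [make_toy_references()] works, ignoring
#'   non-numeric keys), or a single `DNAStringSet` plus `seqid_taxid`.
#' @param max_mismatches Maximum substitutions per placement.
#' @param seqid_taxid Optional named vector contig -> taxid (required if
#'   `references` is a bare `DNAStringSet`).
#' @return List: `placements` (`read_id`, `seqid`, `pos`, `end`, `strand`,
#'   `nm`, `taxon_id`, `sample_id`), `hits` (BLAST-style table with
#'   `taxon_id`), `unmapped` (read ids).
#' @export
naive_align <- function(reads, references, max_mismatches = 0L,
                        seqid_taxid = NULL) {
  if (methods::is(references, "DNAStringSet")) {
    stopifnot(!is.null(seqid_taxid))
    contigs <- references
    tax_of <- seqid_taxid
  } else {
    keys <- names(references)[grepl("^[0-9]+$", names(references))]
    contigs <- Biostrings::DNAStringSet()
    tax_of <- integer(0)
    for (k in keys) {
      g <- references[[k]]
      contigs <- c(contigs, g)
      tax_of <- c(tax_of, setNames(rep(as.integer(k), length(g)),
                                   names(g)))
    }
  }
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  useq <- unique(reads$sequence)
  placements <- exact_or_fuzzy_search(useq, contigs, max_mismatches)
  if (nrow(placements)) {
    placements$taxon_id <- unname(tax_of[placements$seqid])
  } else {
    placements$taxon_id <- integer(0)
  }
  # expand unique-sequence placements back to reads
  idx <- match(reads$sequence, useq)
  hit_list <- split(seq_len(nrow(placements)), placements$query)
  per_read <- hit_list[as.character(idx)]
  n_per <- lengths(per_read)
  rr <- rep(seq_len(nrow(reads)), n_per)
  pr <- unlist(per_read, use.names = FALSE)
  out <- data.frame(read_id = reads$read_id[rr],
                    seqid = placements$seqid[pr],
                    pos = placements$pos[pr],
                    end = placements$end[pr],
                    strand = placements$strand[pr],
                    nm = placements$nm[pr],
                    taxon_id = placements$taxon_id[pr],
                    sample_id = reads$sample_id[rr],
                    stringsAsFactors = FALSE)
  len <- nchar(reads$sequence[rr])
  hits <- data.frame(query_id = out$read_id,
                     subject_id = out$seqid,
                     percent_identity = 100 * (len - out$nm) / len,
                     aln_length = len,
                     evalue = 0,
                     bitscore = 2 * (len - out$nm) - 3 * out$nm,
                     taxon_id = out$taxon_id,
                     stringsAsFactors = FALSE)
  list(placements = out,
       hits = hits,
       unmapped = reads$read_id[n_per == 0L])
}

# Internal search over unique sequences. Returns data.frame(query (index
# into useq), seqid, pos, end, strand, nm).
exact_or_fuzzy_search <- function(useq, contigs, max_mismatches) {
  res <- list()
  widths <- BiocGenerics::width(contigs)
  if (max_mismatches == 0L) {
    # one variable-width dictionary with a trusted band of the minimum
    # read length; heads/tails outside the band are verified exactly
    ss <- Biostrings::DNAStringSet(useq)
    tb <- min(nchar(useq))
    pd <- Biostrings::PDict(ss, tb.start = 1, tb.width = tb)
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(ss),
                               tb.start = 1, tb.width = tb)
    for (ci in seq_along(contigs)) {
      subj <- contigs[[ci]]
      for (sense in c("+", "-")) {
        m <- Biostrings::matchPDict(if (sense == "+") pd else pd_rc, subj)
        n_each <- S4Vectors::elementNROWS(m)
        if (!sum(n_each)) next
        u <- unlist(m)
        res[[length(res) + 1L]] <- data.frame(
          query = rep(seq_along(useq), n_each),
          seqid = names(contigs)[ci],
          pos = BiocGenerics::start(u), end = BiocGenerics::end(u),
          strand = sense, nm = 0L, stringsAsFactors = FALSE)
      }
    }
  } else {
    for (qi in seq_along(useq)) {
      pat <- Biostrings::DNAString(useq[qi])
      rc <- Biostrings::reverseComplement(pat)
      for (ci in seq_along(contigs)) {
        subj <- contigs[[ci]]
        for (sense in c("+", "-")) {
          m <- Biostrings::matchPattern(if (sense == "+") pat else rc,
                                        subj,
                                        max.mismatch = max_mismatches,
                                        with.indels = FALSE)
          if (!length(m)) next
          nm <- vapply(seq_along(m), function(k) {
            sum(strsplit(as.character(m[[k]]), "")[[1]] !=
                  strsplit(as.character(if (sense == "+") pat else rc),
                           "")[[1]])
          }, integer(1))
          res[[length(res) + 1L]] <- data.frame(
            query = qi, seqid = names(contigs)[ci],
            pos = BiocGenerics::start(m), end = BiocGenerics::end(m),
            strand = sense, nm = nm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(query = integer(0), seqid = character(0),
                      pos = integer(0), end = integer(0),
                      strand = character(0), nm = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$query, out$seqid, out$pos, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
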