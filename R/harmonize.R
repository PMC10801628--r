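# Default RNA-type priority order, highest first. When one read overlaps
# features of several types, the type earliest in this list wins.
DEFAULT_PRIORITY <- c("miRNA", "tRNA", "rRNA", "mRNA", "processed_pseudogene",
                      "snRNA", "snoRNA", "mtRNA", "piRNA", "lncRNA",
                      "vaultRNA", "YRNA", "other_RNA", "repeat_tRNA",
                      "repeat_rRNA", "repeat_other")

# Synonyms seen in common annotation sources, mapped onto the priority
# vocabulary. Anything unmapped falls into other_RNA.
DEFAULT_TYPE_MAP <- c(
  mirna = "miRNA", trna = "tRNA", rrna = "rRNA", mrna = "mRNA",
  exon = "mRNA", protein_coding = "mRNA",
  processed_pseudogene = "processed_pseudogene",
  snrna = "snRNA", snorna = "snoRNA",
  mtrna = "mtRNA", mt_trna = "mtRNA", mt_rrna = "mtRNA",
  pirna = "piRNA", lncrna = "lncRNA", lincrna = "lncRNA",
  vaultrna = "vaultRNA", vault_rna = "vaultRNA",
  yrna = "YRNA", y_rna = "YRNA",
  repeat_trna = "repeat_tRNA", repeat_rrna = "repeat_rRNA",
  repeat_other = "repeat_other", repeats = "repeat_other")

#' Build an RNA-type priority schema
#'
#' The schema is an ordered vector of RNA-type class labels, highest
#' priority first, plus a mapping from raw annotation type strings onto
#' those labels. Types with no mapping are classified `other_RNA`.
#'
#' @param ordered_types Character vector of class labels, best first.
#' @param type_map Named character vector mapping lower-cased raw types to
#'   class labels.
#' @return An object of class `priority_schema`.
#' @export
priority_schema <- function(ordered_types = DEFAULT_PRIORITY,
                            type_map = DEFAULT_TYPE_MAP) {
  stopifnot(length(ordered_types) > 0, !anyDuplicated(ordered_types))
  if (!all(type_map %in% ordered_types)) {
    stop("type_map targets must be schema labels")
  }
  structure(list(ordered_types = ordered_types, type_map = type_map),
            class = "priority_schema")
}

#' Classify raw RNA-type strings under a schema
#'
#' @param types Character vector of raw `rna_type` strings.
#' @param schema A [priority_schema()].
#' @return Character vector of class labels (unknown types -> `other_RNA`).
#' @export
classify_rna_type <- function(types, schema = priority_schema()) {
  key <- tolower(types)
  out <- ifelse(types %in% schema$ordered_types, types,
                unname(schema$type_map[key]))
  out[is.na(out)] <- "other_RNA"
  out
}

#' Priority rank of class labels (1 = best)
#'
#' @inheritParams classify_rna_type
#' @return Integer ranks into the schema order.
#' @export
priority_rank <- function(types, schema = priority_schema()) {
  match(classify_rna_type(types, schema), schema$ordered_types)
}

features_to_granges <- function(features) {
  strand <- features$strand
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = strand)
}

#' Merge overlapping features within one annotation source
#'
#' Features from a single source database that overlap by at least one
#' base on the same strand of the same sequence are fused into a union
#' feature spanning the members. The union keeps member names joined with
#' `|` (in coordinate order) and records them under a `members` attribute.
#' Book-ended features (no shared base) are not merged; features on
#' opposite strands never merge.
#'
#' @param features Feature `data.frame` from one `source_db`.
#' @return A list with `merged` (the non-overlapping feature set) and
#'   `report` (source_db, features_in, features_merged, percent_merged).
#' @export
merge_overlapping_features <- function(features) {
  if (nrow(features) == 0L) {
    return(list(merged = features,
                report = data.frame(source_db = character(0),
                                    features_in = integer(0),
                                    features_merged = integer(0),
                                    percent_merged = numeric(0))))
  }
  src <- unique(features$source_db)
  if (length(src) != 1L) {
    stop("merge_overlapping_features() expects features from one source_db; ",
         "got: ", paste(src, collapse = ", "))
  }
  gr <- features_to_granges(features)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  n_members <- lengths(revmap)
  ord_members <- lapply(revmap, function(ix) {
    ix[order(features$start[ix], features$end[ix], features$name[ix])]
  })
  strand <- as.character(BiocGenerics::strand(red))
  strand[strand == "*"] <- "."
  merged <- data.frame(
    seqid = as.character(GenomeInfoDb::seqnames(red)),
    start = BiocGenerics::start(red),
    end = BiocGenerics::end(red),
    strand = strand,
    source_db = src,
    rna_type = vapply(ord_members, function(ix) features$rna_type[ix[1]],
                      character(1)),
    name = vapply(ord_members, function(ix)
      paste(features$name[ix], collapse = "|"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  merged$attributes <- lapply(seq_along(ord_members), function(i) {
    ix <- ord_members[[i]]
    a <- list(members = features$name[ix])
    if (is.null(features$attributes)) return(a)
    if (length(ix) == 1L) {
      return(utils::modifyList(as.list(features$attributes[[ix]]), a))
    }
    # keep attributes whose value every member agrees on (e.g. the
    # gene_id of exons of one gene), so downstream grouping survives
    first <- features$attributes[[ix[1]]]
    for (key in names(first)) {
      vals <- lapply(ix, function(j) features$attributes[[j]][[key]])
      if (all(vapply(vals, identical, logical(1), y = first[[key]]))) {
        a[[key]] <- first[[key]]
      }
    }
    a
  })
  ord <- order(merged$seqid, merged$start, merged$end, merged$strand)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  n_in <- nrow(features)
  n_merged <- sum(n_members[n_members >= 2L])
  list(merged = merged,
       report = data.frame(source_db = src, features_in = n_in,
                           features_merged = n_merged,
                           percent_merged = round(100 * n_merged / n_in),
                           stringsAsFactors = FALSE))
}

#' Place sequences on a genome by exact ungapped full-length matching
#'
#' Each query is searched on both strands of every contig; every exact,
#' full-length, ungapped occurrence becomes a feature (reverse-complement
#' occurrences get strand `-`). Queries with no occurrence are listed as
#' skipped; queries with more than `max_hits` occurrences are truncated to
#' the first `max_hits` placements in genome order and flagged.
#'
#' @param sequences Named character vector (name -> sequence), or a
#'   `data.frame` with columns `name`, `sequence`.
#' @param genome A named `DNAStringSet` or path to a FASTA file.
#' @param rna_type RNA type attached to the produced features.
#' @param source_db Source database label for the produced features.
#' @param max_hits Placement cap per query.
#' @return A list with `features` (placements, with a logical `truncated`
#'   attribute on capped queries) and `skipped` (query names).
#' @export
place_fasta_on_genome <- function(sequences, genome, rna_type = "other_RNA",
                                  source_db = "placed", max_hits = 100L) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$name)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(nchar(sequences) == 0L)) stop("empty query sequence")
  seqs <- normalize_dna(unname(sequences))
  qnames <- names(sequences)
  rows <- vector("list", length(seqs))
  skipped <- character(0)
  contigs <- names(genome)
  for (i in seq_along(seqs)) {
    pat <- Biostrings::DNAString(seqs[i])
    rc <- Biostrings::reverseComplement(pat)
    hits <- list()
    for (ct in contigs) {
      subj <- genome[[ct]]
      fwd <- Biostrings::matchPattern(pat, subj)
      if (length(fwd)) {
        hits[[length(hits) + 1L]] <- data.frame(
          seqid = ct, start = BiocGenerics::start(fwd),
          end = BiocGenerics::end(fwd), strand = "+",
          stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPattern(rc, subj)
      if (length(rev)) {
        hits[[length(hits) + 1L]] <- data.frame(
          seqid = ct, start = BiocGenerics::start(rev),
          end = BiocGenerics::end(rev), strand = "-",
          stringsAsFactors = FALSE)
      }
    }
    if (!length(hits)) {
      skipped <- c(skipped, qnames[i])
      next
    }
    h <- do.call(rbind, hits)
    h <- h[order(match(h$seqid, contigs), h$start, h$strand), , drop = FALSE]
    trunc <- nrow(h) > max_hits
    if (trunc) h <- h[seq_len(max_hits), , drop = FALSE]
    h$source_db <- source_db
    h$rna_type <- rna_type
    h$name <- qnames[i]
    h$attributes <- lapply(seq_len(nrow(h)), function(j) {
      list(members = qnames[i], truncated = as.character(trunc))
    })
    rows[[i]] <- h
  }
  features <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(features)) {
    features <- data.frame(seqid = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           source_db = character(0), rna_type = character(0),
                           name = character(0), stringsAsFactors = FALSE)
    features$attributes <- list()
  }
  rownames(features) <- NULL
  list(features = features, skipped = skipped)
}

#' Derive tRNA-fragment (tRF) annotation from tRNA loci
#'
#' Each tRNA locus is split into a 5' half and a 3' half at
#' `floor(length/2)` bases from the 5' end (strand-aware: on the minus
#' strand the 5' fragment occupies the higher-coordinate half). Fragment
#' names carry `-5p`/`-3p` suffixes; the parent locus name is kept in the
#' attributes.
#'
#' @param trna_features Feature `data.frame` of tRNA loci with known strand.
#' @return Feature `data.frame` of tRF halves (type `tRNA`).
#' @export
derive_trf_annotation <- function(trna_features) {
  keep <- (trna_features$end - trna_features$start + 1L) >= 2L &
    trna_features$strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " tRNA locus/loci shorter than 2 nt or unstranded; skipped")
  }
  tf <- trna_features[keep, , drop = FALSE]
  if (!nrow(tf)) return(tf)
  w <- tf$end - tf$start + 1L
  half <- w %/% 2L
  plus <- tf$strand == "+"
  s5 <- ifelse(plus, tf$start, tf$end - half + 1L)
  e5 <- ifelse(plus, tf$start + half - 1L, tf$end)
  s3 <- ifelse(plus, tf$start + half, tf$start)
  e3 <- ifelse(plus, tf$end, tf$end - half)
  frag <- function(s, e, suffix) {
    out <- data.frame(seqid = tf$seqid, start = s, end = e,
                      strand = tf$strand, source_db = tf$source_db,
                      rna_type = "tRNA",
                      name = paste0(tf$name, suffix),
                      stringsAsFactors = FALSE)
    out$attributes <- lapply(tf$name, function(p) list(parent = p))
    out
  }
  out <- rbind(frag(s5, e5, "-5p"), frag(s3, e3, "-3p"))
  out <- out[order(out$seqid, out$start, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the harmonized annotation catalogue
#'
#' Each source is merged internally with [merge_overlapping_features()];
#' cross-source overlaps are kept (they are resolved per read at counting
#' time by the priority schema). Every feature is tagged with its priority
#' class, and gene spans are derived from mRNA-class features (grouped by
#' their `gene_id` attribute, falling back to the feature name) for the
#' intronic call at counting time.
#'
#' @param sources Named list of feature `data.frame`s (name = source_db).
#' @param schema A [priority_schema()].
#' @return An object of class `harmonized_catalogue`: list with `features`
#'   (including `priority_class` and `feature_id`), `gene_spans`,
#'   `reports` (Table-1-style: one row per source) and `schema`.
#' @export
build_catalogue <- function(sources, schema = priority_schema()) {
  stopifnot(length(sources) > 0, !is.null(names(sources)))
  merged <- vector("list", length(sources))
  reports <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    f <- sources[[i]]
    f$source_db <- names(sources)[i]
    res <- merge_overlapping_features(f)
    merged[[i]] <- res$merged
    reports[[i]] <- res$report
  }
  features <- do.call(rbind, merged)
  features$priority_class <- classify_rna_type(features$rna_type, schema)
  unknown <- !(features$rna_type %in% schema$ordered_types) &
    !(tolower(features$rna_type) %in% names(schema$type_map))
  if (any(unknown)) {
    message(sum(unknown), " feature(s) with unmapped rna_type assigned other_RNA")
  }
  features$feature_id <- paste0(features$source_db, ":", features$name, ":",
                                features$seqid, ":", features$start, "-",
                                features$end, ":", features$strand)
  rownames(features) <- NULL
  mr <- features$priority_class == "mRNA"
  gene_spans <- NULL
  if (any(mr)) {
    mf <- features[mr, , drop = FALSE]
    gid <- vapply(seq_len(nrow(mf)), function(i) {
      a <- mf$attributes[[i]]
      if (!is.null(a$gene_id)) a$gene_id[1] else mf$name[i]
    }, character(1))
    dt <- data.table(seqid = mf$seqid, strand = mf$strand, gene = gid,
                     start = mf$start, end = mf$end)
    gene_spans <- as.data.frame(dt[, .(start = min(start), end = max(end)),
                                   by = .(seqid, strand, gene)])
  } else {
    gene_spans <- data.frame(seqid = character(0), strand = character(0),
                             gene = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(features = features, gene_spans = gene_spans,
                 reports = do.call(rbind, reports), schema = schema),
            class = "harmonized_catalogue")
}

#' @export
print.harmonized_catalogue <- function(x, ...) {
  cat("Harmonized annotation catalogue\n")
  cat("  features:", nrow(x$features), "from",
      length(unique(x$features$source_db)), "source(s)\n")
  cat("  priority classes:",
      paste(head(x$schema$ordered_types, 4), collapse = " > "), "> ...\n")
  print(x$reports)
  invisible(x)
}
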