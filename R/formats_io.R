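#' @importFrom data.table data.table as.data.table setDT setorder rbindlist :=
#' @importFrom stats cor p.adjust rbinom rnbinom runif setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

# Internal: normalise a raw sequence vector to the DNA alphabet used
# throughout the package (uppercase, U -> T).
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N,U}: record ",
         which(bad)[1], call. = FALSE)
  }
  x
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Reads a plain or gzip-compressed FASTA/FASTQ file into the package's
#' read table. Sequences are uppercased and RNA bases (U) are converted to
#' T so that RNA-space databases can be matched against DNA genomes.
#'
#' @param path Path to the input file (may end in `.gz`).
#' @param format `"auto"` (guess from extension), `"fasta"` or `"fastq"`.
#' @param sample_id Sample identifier attached to every read.
#' @param group Group label: one of `"test"`, `"control"`, `"environment"`,
#'   `"ignore"`.
#' @return A `data.frame` with columns `read_id`, `sequence`, `quality`
#'   (`NA` for FASTA), `sample_id`, `group`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = basename(path), group = "test") {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  group <- match.arg(group, c("test", "control", "environment", "ignore"))
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    ss <- Biostrings::readBStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(ss))
  }
  seqs <- normalize_dna(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(nchar(seqs) < 1L)) stop("empty sequence in ", path)
  data.frame(read_id = ids, sequence = seqs, quality = qual,
             sample_id = sample_id, group = group,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads Read table as returned by [read_sequences()].
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`. For FASTQ, reads without stored
#'   qualities get a constant maximum-quality string.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- paste0(">", reads$read_id, "\n", reads$sequence)
  } else {
    qual <- reads$quality
    miss <- is.na(qual)
    if (any(miss)) qual[miss] <- strrep("I", nchar(reads$sequence[miss]))
    out <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual)
  }
  writeLines(out, path)
  invisible(path)
}

# Internal: coerce a single rtracklayer-imported GRanges into the package's
# feature data.frame.
granges_to_features <- function(gr, source_db = NULL) {
  mc <- S4Vectors::mcols(gr)
  std <- c("source", "type", "score", "phase")
  extra <- setdiff(colnames(mc), std)
  name <- rep(NA_character_, length(gr))
  for (key in c("Name", "gene_name", "transcript_id", "gene_id", "ID")) {
    if (key %in% extra) {
      v <- as.character(mc[[key]])
      name[is.na(name) & !is.na(v)] <- v[is.na(name) & !is.na(v)]
    }
  }
  attrs <- lapply(seq_along(gr), function(i) {
    a <- lapply(extra, function(k) {
      v <- mc[[k]][i]
      if (methods::is(v, "List")) v <- unlist(v)
      as.character(v)
    })
    names(a) <- extra
    a[!vapply(a, function(v) length(v) == 0L || all(is.na(v)), logical(1))]
  })
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    seqid = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    source_db = if (is.null(source_db)) as.character(mc$source) else source_db,
    rna_type = as.character(mc$type),
    name = ifelse(is.na(name), paste0("feat", seq_along(gr)), name),
    stringsAsFactors = FALSE, row.names = NULL)
  df$attributes <- attrs
  df
}

#' Read a GTF or GFF3 annotation file
#'
#' Coordinates are 1-based inclusive. GFF3 `ID`/`Name` attributes are lifted
#' into the common attribute map so both dialects land in the same table.
#'
#' @param path Path to a `.gtf`, `.gff`/`.gff3` file.
#' @param source_db Optional override for the source database name; by
#'   default the GTF `source` column is used.
#' @return A feature `data.frame` with columns `seqid`, `start`, `end`,
#'   `strand`, `source_db`, `rna_type`, `name` and a list-column
#'   `attributes`.
#' @export
read_gtf <- function(path, source_db = NULL) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  fmt <- if (ext %in% c("gff", "gff3")) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)
  df <- granges_to_features(gr, source_db = source_db)
  if (any(df$start > df$end) || any(df$start < 1L)) {
    stop("invalid coordinates in ", path)
  }
  df
}

#' Write features as GTF
#'
#' Writes the canonical nine-column GTF dialect used by the package:
#' column 2 carries the source database, column 3 the RNA type, and the
#' attribute column holds `gene_id "<name>"` plus any stored attributes
#' (multi-valued attributes joined with `|`).
#'
#' @param features Feature `data.frame` (see [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  n <- nrow(features)
  attr_str <- vapply(seq_len(n), function(i) {
    a <- if (!is.null(features$attributes)) features$attributes[[i]] else NULL
    a <- a[setdiff(names(a), c("gene_id"))]
    kv <- paste0("gene_id \"", features$name[i], "\";")
    if (length(a)) {
      more <- vapply(names(a), function(k) {
        paste0(" ", k, " \"", paste(a[[k]], collapse = "|"), "\";")
      }, character(1))
      kv <- paste0(kv, paste(more, collapse = ""))
    }
    kv
  }, character(1))
  lines <- paste(features$seqid, features$source_db, features$rna_type,
                 features$start, features$end, ".", features$strand, ".",
                 attr_str, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Default BLAST outfmt 6 column layout with subject taxids.
BLAST_OUTFMT6_STAXIDS <- c("query_id", "subject_id", "percent_identity",
                           "aln_length", "mismatch", "gapopen", "qstart",
                           "qend", "sstart", "send", "evalue", "bitscore",
                           "staxids")

#' Read a tabular BLAST hit file
#'
#' Parses an outfmt-6-style tab-separated file. Rows whose `staxids` field
#' carries several semicolon-separated taxids are expanded into one hit per
#' taxid, sharing all other fields.
#'
#' @param path Path to the tab-separated hit file (no header).
#' @param col_names Column names, in file order. Must contain `staxids`
#'   and `bitscore`.
#' @return A `data.frame` of hits with an integer `taxon_id` column.
#' @export
read_blast_tab <- function(path, col_names = BLAST_OUTFMT6_STAXIDS) {
  if (!"staxids" %in% col_names) {
    stop("column specification lacks the taxid column 'staxids'")
  }
  if (!"bitscore" %in% col_names) {
    stop("column specification lacks the 'bitscore' column")
  }
  if (file.size(path) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(col_names)))
    names(out) <- col_names
    out$taxon_id <- integer(0)
    return(out[setdiff(names(out), "staxids")])
  }
  df <- read.delim(path, header = FALSE, col.names = col_names,
                   stringsAsFactors = FALSE, colClasses = "character")
  taxids <- strsplit(df$staxids, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(df)), lengths(taxids))
  out <- df[idx, setdiff(col_names, "staxids"), drop = FALSE]
  out$taxon_id <- as.integer(unlist(taxids))
  for (num in intersect(c("percent_identity", "aln_length", "mismatch",
                          "gapopen", "qstart", "qend", "sstart", "send",
                          "evalue", "bitscore"), names(out))) {
    out[[num]] <- as.numeric(out[[num]])
  }
  if (any(is.na(out$taxon_id))) stop("non-integer taxid in ", path)
  if (any(out$bitscore < 0)) stop("negative bitscore in ", path)
  rownames(out) <- NULL
  out
}

#' Read alignments from a SAM file
#'
#' All placements of a read (primary plus secondary) are grouped and
#' annotated with the number of candidate placements; unmapped reads are
#' reported separately.
#'
#' @param path Path to a SAM file.
#' @return A list with `placements` (data.frame: `read_id`, `seqid`, `pos`,
#'   `end`, `strand`, `n_candidates`) and `unmapped` (character vector of
#'   read ids).
#' @export
read_sam_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "qwidth"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(x$flag, 4L) != 0L
  pl <- data.frame(read_id = x$qname[!unmapped],
                   seqid = as.character(x$rname[!unmapped]),
                   pos = x$pos[!unmapped],
                   end = x$pos[!unmapped] + x$qwidth[!unmapped] - 1L,
                   strand = as.character(x$strand[!unmapped]),
                   stringsAsFactors = FALSE)
  if (nrow(pl)) {
    cnt <- table(pl$read_id)
    pl$n_candidates <- as.integer(cnt[pl$read_id])
    pl <- pl[order(pl$read_id, pl$seqid, pl$pos), , drop = FALSE]
    rownames(pl) <- NULL
  } else {
    pl$n_candidates <- integer(0)
  }
  list(placements = pl, unmapped = unique(x$qname[unmapped]))
}

#' Read a reduced taxonomy table
#'
#' The package uses a single-file taxonomy dialect: a tab-separated table
#' with header `taxon_id`, `parent_id`, `rank`, `name` (a reduction of the
#' NCBI nodes/names dump). The root is the one node that is its own parent.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` of taxonomy nodes.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(df)))
  validate_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy `data.frame` to validate.
#' @export
validate_taxonomy <- function(taxonomy) {
  root <- taxonomy$taxon_id[taxonomy$taxon_id == taxonomy$parent_id]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (a node that is its own parent)")
  }
  parent <- setNames(taxonomy$parent_id, taxonomy$taxon_id)
  for (id in taxonomy$taxon_id) {
    seen <- integer(0)
    cur <- id
    while (cur != root) {
      if (cur %in% seen || !as.character(cur) %in% names(parent)) {
        stop("taxon ", id, " is not reachable from the root")
      }
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }
  attr(taxonomy, "root") <- root
  taxonomy
}

# Internal: named parent lookup vector for fast ancestor walks.
taxonomy_parents <- function(taxonomy) {
  setNames(taxonomy$parent_id, as.character(taxonomy$taxon_id))
}

# Internal: ancestors of a taxid, self first, root last.
taxon_lineage_ids <- function(taxid, parents) {
  out <- integer(0)
  cur <- taxid
  repeat {
    out <- c(out, cur)
    p <- parents[[as.character(cur)]]
    if (is.null(p) || is.na(p) || p == cur) break
    cur <- p
  }
  out
}
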