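# Reserved rows of the feature count matrix.
RESERVED_ROWS <- c("__unannotated__", "__intronic__")

#' Coverage-guided placement of multi-mapping reads
#'
#' Small-RNA reads commonly map to several loci. Each multi-placement read
#' keeps exactly one candidate: the one whose start lies in the densest
#' local neighbourhood of already-placed reads (weight = number of placed
#' read starts within `window` nt of the candidate start, same seqid and
#' strand). Pass 1 weights by uniquely mapped reads only; later passes
#' recompute weights including the previous pass's placements. Ties break
#' by lowest (seqid, coordinate); uniquely mapped reads never move.
#'
#' @param placements `data.frame` with columns `read_id`, `seqid`, `pos`,
#'   `end`, `strand` (one row per candidate placement).
#' @param window Half-width of the coverage window in nt.
#' @param passes Number of reassignment passes.
#' @return One-row-per-read `data.frame` of chosen placements.
#' @export
reassign_multimappers <- function(placements, window = 50L, passes = 2L) {
  if (nrow(placements) == 0L) return(placements)
  dt <- as.data.table(placements)
  dt[, n_cand := .N, by = read_id]
  uniq <- dt[n_cand == 1L]
  multi <- dt[n_cand > 1L]
  if (nrow(multi) == 0L) {
    out <- as.data.frame(uniq[, !"n_cand"])
    return(out[order(out$read_id), , drop = FALSE])
  }
  setorder(multi, read_id, seqid, pos, strand)
  chosen <- NULL
  for (pass in seq_len(passes)) {
    placed <- if (is.null(chosen)) uniq else rbind(uniq, chosen)
    # sorted start vectors per (seqid, strand) for window counting
    key <- paste(placed$seqid, placed$strand)
    starts <- split(placed$pos, key)
    starts <- lapply(starts, sort)
    mkey <- paste(multi$seqid, multi$strand)
    w <- integer(nrow(multi))
    for (k in unique(mkey)) {
      s <- starts[[k]]
      idx <- which(mkey == k)
      if (is.null(s) || !length(s)) next
      p <- multi$pos[idx]
      w[idx] <- findInterval(p + window, s) -
        findInterval(p - window - 1L, s)
    }
    multi[, weight := w]
    setorder(multi, read_id, -weight, seqid, pos)
    chosen <- multi[, head(.SD, 1L), by = read_id]
    chosen[, weight := NULL]
  }
  out <- rbind(uniq, chosen)[, !"n_cand"]
  out <- as.data.frame(out)
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: resolve each placed read to a single feature (or reserved
# category) under the priority schema. Returns a character vector of
# feature ids / "__intronic__" / "__unannotated__" aligned with
# `placements` rows, plus the number of features each read overlapped.
resolve_priority <- function(placements, catalogue, schema,
                             ignore_strand = FALSE) {
  feats <- catalogue$features
  out <- rep("__unannotated__", nrow(placements))
  n_over <- integer(nrow(placements))
  if (nrow(feats) && nrow(placements)) {
    rgr <- GenomicRanges::GRanges(
      placements$seqid,
      IRanges::IRanges(placements$pos, placements$end),
      strand = ifelse(placements$strand == ".", "*", placements$strand))
    fgr <- features_to_granges(feats)
    ov <- GenomicRanges::findOverlaps(rgr, fgr,
                                      ignore.strand = ignore_strand)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      prio <- priority_rank(feats$rna_type, schema)[sh]
      width <- pmin(placements$end[qh], feats$end[sh]) -
        pmax(placements$pos[qh], feats$start[sh]) + 1L
      dt <- data.table(read = qh, feat = sh, prio = prio, width = width,
                       fstart = feats$start[sh])
      # best class first; within class the largest overlap, then lowest
      # feature start, then feature order for full determinism
      setorder(dt, read, prio, -width, fstart, feat)
      best <- dt[, .(feat = feat[1], n = .N), by = read]
      out[best$read] <- feats$feature_id[best$feat]
      n_over[best$read] <- best$n
    }
  }
  # intronic: inside an mRNA gene span but touching no feature
  un <- which(out == "__unannotated__")
  if (length(un) && nrow(catalogue$gene_spans)) {
    gs <- catalogue$gene_spans
    ggr <- GenomicRanges::GRanges(
      gs$seqid, IRanges::IRanges(gs$start, gs$end),
      strand = ifelse(gs$strand == ".", "*", gs$strand))
    ugr <- GenomicRanges::GRanges(
      placements$seqid[un],
      IRanges::IRanges(placements$pos[un], placements$end[un]),
      strand = ifelse(placements$strand[un] == ".", "*",
                      placements$strand[un]))
    hit <- IRanges::overlapsAny(ugr, ggr, type = "within",
                                ignore.strand = ignore_strand)
    out[un[hit]] <- "__intronic__"
  }
  list(assigned = out, n_overlapping = n_over)
}

#' Priority-aware feature counting
#'
#' Each placed read increments exactly one row: among the features it
#' overlaps (>= 1 shared base, strand-aware by default) the one whose
#' priority class is best; within a class the feature with the largest
#' overlap, ties by lowest start. Reads overlapping no feature but lying
#' within an mRNA gene span count as `__intronic__`; all other unmatched
#' reads count as `__unannotated__`. No ambiguous category exists: the
#' resolution is total by construction.
#'
#' @param placements One placement per read (`read_id`, `seqid`, `pos`,
#'   `end`, `strand`, `sample_id`).
#' @param catalogue A [build_catalogue()] result.
#' @param schema Priority schema; defaults to the catalogue's.
#' @param ignore_strand Count overlaps regardless of strand.
#' @return Object of class `feature_count_matrix`: integer matrix
#'   (features + reserved rows) x samples, with a `feature_table`
#'   attribute and a `per_read` attribute (read -> row, for auditing).
#' @export
count_with_priority <- function(placements, catalogue,
                                schema = catalogue$schema,
                                ignore_strand = FALSE) {
  if (is.null(placements$sample_id)) placements$sample_id <- "sample"
  res <- resolve_priority(placements, catalogue, schema, ignore_strand)
  samples <- sort(unique(placements$sample_id))
  rows <- c(catalogue$features$feature_id, RESERVED_ROWS)
  m <- matrix(0L, nrow = length(rows), ncol = length(samples),
              dimnames = list(rows, samples))
  tab <- table(factor(res$assigned, levels = rows),
               factor(placements$sample_id, levels = samples))
  m[] <- as.integer(tab)
  structure(m, class = c("feature_count_matrix", class(m)),
            feature_table = catalogue$features,
            per_read = data.frame(read_id = placements$read_id,
                                  sample_id = placements$sample_id,
                                  assigned = res$assigned,
                                  n_overlapping = res$n_overlapping,
                                  stringsAsFactors = FALSE))
}

#' Orchestrate the metagenome or successive alignment strategy
#'
#' Under the successive strategy, host placements consume reads first and
#' only reads without any host placement are assigned from metagenome
#' placements. Under the metagenome strategy, host and metagenome
#' placements compete in one combined set: per read only the candidates
#' with the fewest mismatches survive, and the coverage-guided
#' reassignment picks among them. Categories partition the input reads.
#'
#' @param reads Read table for the sample(s) under analysis.
#' @param host_alignments Candidate placements on the host genome
#'   (`read_id`, `seqid`, `pos`, `end`, `strand`, optionally `nm`,
#'   `sample_id`).
#' @param metagenome_alignments Candidate placements on the combined
#'   metagenome; `seqid` follows the `taxid|species|contig` convention of
#'   [build_metagenome()], with the host's own records carrying the host
#'   taxid.
#' @param strategy `"metagenome"` or `"successive"`.
#' @param catalogue Harmonized catalogue for the host annotation.
#' @param host_taxid Host species taxid.
#' @param window,passes Passed to [reassign_multimappers()].
#' @param n_filtered Number of reads already removed upstream (length +
#'   environment filters); only used for the summary percentages.
#' @return List with `provenance` (per read: category, taxon_id),
#'   `counts` (host [count_with_priority()] matrix) and `summary`
#'   (Table-2-style percentage row).
#' @export
orchestrate_strategy <- function(reads, host_alignments,
                                 metagenome_alignments,
                                 strategy = c("metagenome", "successive"),
                                 catalogue, host_taxid = 9606L,
                                 window = 50L, passes = 2L,
                                 n_filtered = 0L) {
  strategy <- match.arg(strategy)
  for (nm_col in list(host_alignments, metagenome_alignments)) {
    stopifnot(is.data.frame(nm_col))
  }
  if (is.null(host_alignments$nm)) host_alignments$nm <- 0L
  if (is.null(metagenome_alignments$nm)) metagenome_alignments$nm <- 0L
  host_alignments$taxon_id <- host_taxid
  if (is.null(metagenome_alignments$taxon_id)) {
    metagenome_alignments$taxon_id <-
      metagenome_seqid_taxid(metagenome_alignments$seqid)
  }

  if (strategy == "successive") {
    host_reads <- unique(host_alignments$read_id)
    meta <- metagenome_alignments[
      !(metagenome_alignments$read_id %in% host_reads) &
        metagenome_alignments$taxon_id != host_taxid, , drop = FALSE]
    pool <- rbind(host_alignments[, c("read_id", "seqid", "pos", "end",
                                      "strand", "nm", "taxon_id")],
                  meta[, c("read_id", "seqid", "pos", "end", "strand",
                           "nm", "taxon_id")])
  } else {
    pool <- metagenome_alignments[, c("read_id", "seqid", "pos", "end",
                                      "strand", "nm", "taxon_id")]
    if (!nrow(pool)) {
      pool <- host_alignments[, c("read_id", "seqid", "pos", "end",
                                  "strand", "nm", "taxon_id")]
    }
  }
  # per read keep only minimal-mismatch candidates, then place by coverage
  if (nrow(pool)) {
    dt <- as.data.table(pool)
    dt[, keep := nm == min(nm), by = read_id]
    pool <- as.data.frame(dt[keep == TRUE][, !"keep"])
  }
  placed <- reassign_multimappers(pool, window = window, passes = passes)

  # host placements must use host-genome coordinates for annotation:
  # strip the metagenome prefix from host records
  is_host <- !is.na(placed$taxon_id) & placed$taxon_id == host_taxid
  placed$seqid[is_host] <- sub("^[0-9]+\\|[^|]*\\|", "",
                               placed$seqid[is_host])
  smap <- setNames(reads$sample_id, reads$read_id)
  placed$sample_id <- unname(smap[placed$read_id])
  placed$sample_id[is.na(placed$sample_id)] <- "sample"

  host_placed <- placed[is_host, , drop = FALSE]
  counts <- count_with_priority(host_placed, catalogue)
  per_read <- attr(counts, "per_read")

  category <- setNames(rep("unidentified", nrow(reads)), reads$read_id)
  taxid <- setNames(rep(NA_integer_, nrow(reads)), reads$read_id)
  other <- placed[!is_host, , drop = FALSE]
  category[other$read_id] <- "other_species"
  taxid[other$read_id] <- other$taxon_id
  annotated <- per_read$read_id[!(per_read$assigned %in% RESERVED_ROWS)]
  intronic <- per_read$read_id[per_read$assigned == "__intronic__"]
  unann <- per_read$read_id[per_read$assigned == "__unannotated__"]
  category[annotated] <- "host_annotated"
  category[intronic] <- "host_intronic"
  category[unann] <- "host_unannotated"
  taxid[c(annotated, intronic, unann)] <- host_taxid

  provenance <- data.frame(read_id = reads$read_id,
                           sample_id = reads$sample_id,
                           category = unname(category[reads$read_id]),
                           taxon_id = unname(taxid[reads$read_id]),
                           stringsAsFactors = FALSE)
  n_total <- nrow(reads) + n_filtered
  pct <- function(n) if (n_total > 0) 100 * n / n_total else NA_real_
  summary <- data.frame(
    strategy = strategy,
    pct_filtered = pct(n_filtered),
    pct_annotated = pct(sum(provenance$category == "host_annotated")),
    pct_intronic = pct(sum(provenance$category == "host_intronic")),
    pct_unannotated = pct(sum(provenance$category == "host_unannotated")),
    pct_other_species = pct(sum(provenance$category == "other_species")),
    pct_unidentified = pct(sum(provenance$category == "unidentified")),
    # reads counted toward more than one row would inflate the matrix
    # total above the read count; the resolution is total, so this is a
    # measured zero, not an assumed one
    pct_ambiguous = pct(sum(unclass(counts)) - nrow(per_read)),
    stringsAsFactors = FALSE)
  list(provenance = provenance, counts = counts, summary = summary)
}

#' Catalogue of expressed sRNA types
#'
#' Per sample, the percentage of each RNA-type class among annotated,
#' non-intronic reads. Intronic and unannotated reads are reported
#' separately (as percentages of all counted reads).
#'
#' @param counts A [count_with_priority()] matrix.
#' @param schema Priority schema used to class the features.
#' @return `data.frame`: rows = type classes (+ `intronic`,
#'   `unannotated` memo rows), columns = samples, values = percentages
#'   (`NA` when a sample has no annotated reads).
#' @export
catalogue_rna_types <- function(counts, schema = priority_schema()) {
  feats <- attr(counts, "feature_table")
  m <- unclass(counts)
  fid <- rownames(m)
  is_res <- fid %in% RESERVED_ROWS
  cls <- feats$priority_class[match(fid[!is_res], feats$feature_id)]
  types <- schema$ordered_types
  out <- matrix(NA_real_, nrow = length(types) + 2L, ncol = ncol(m),
                dimnames = list(c(types, "intronic", "unannotated"),
                                colnames(m)))
  for (j in seq_len(ncol(m))) {
    bytype <- tapply(m[!is_res, j], factor(cls, levels = types), sum)
    bytype[is.na(bytype)] <- 0
    tot <- sum(bytype)
    out[seq_along(types), j] <- if (tot > 0) 100 * bytype / tot else NA_real_
    all_counted <- sum(m[, j])
    out["intronic", j] <- if (all_counted > 0)
      100 * m["__intronic__", j] / all_counted else NA_real_
    out["unannotated", j] <- if (all_counted > 0)
      100 * m["__unannotated__", j] / all_counted else NA_real_
  }
  as.data.frame(out)
}

#' Catalogue of identified species
#'
#' Assigned read counts per detected species and sample, from the
#' strategy-orchestration provenance.
#'
#' @param provenance `provenance` element of [orchestrate_strategy()].
#' @param taxonomy Taxonomy table (for species names).
#' @return `data.frame`: taxon_id, species_name, one count column per
#'   sample.
#' @export
catalogue_species <- function(provenance, taxonomy) {
  pr <- provenance[!is.na(provenance$taxon_id), , drop = FALSE]
  tab <- table(pr$taxon_id, pr$sample_id)
  names_map <- setNames(taxonomy$name, as.character(taxonomy$taxon_id))
  out <- data.frame(taxon_id = as.integer(rownames(tab)),
                    species_name = unname(names_map[rownames(tab)]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame.matrix(tab))
  out <- out[order(-rowSums(tab), out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
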