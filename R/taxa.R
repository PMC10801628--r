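#' Default taxon group set
#'
#' The ordered list of taxonomic groups (name, root taxid) used to bin
#' BLAST hits: the host plus the major clades of potential parasites and
#' microbiome members. A hit is attributed to the first listed group whose
#' subtree contains its taxid.
#'
#' @return `data.frame` with columns `name`, `root`.
#' @export
default_taxon_groups <- function() {
  data.frame(
    name = c("Homo", "Bacteria", "Fungi", "Viruses", "Archaea", "Amoebozoa",
             "Discoba", "CRuMs", "Metamonada", "Sar",
             "Eukaryota incertae sedis", "Aphelida", "Ichthyosporea",
             "Rotosphaerida", "other sequences"),
    root = c(9606L, 2L, 4751L, 10239L, 2157L, 554915L, 2611352L, 2608240L,
             2611341L, 2698737L, 2683617L, 2316435L, 127916L, 2686024L,
             28384L),
    stringsAsFactors = FALSE)
}

# Internal: run `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Draw the representative read subset for species identification
#'
#' Uniform sampling without replacement, reproducible under `seed`. The
#' subset (default 200 reads) is what gets BLASTed in the original
#' workflow; larger subsets trade run time for sensitivity to rare species.
#'
#' @param reads Read table.
#' @param n Subset size; if the input has `n` reads or fewer, all are
#'   returned.
#' @param seed Integer seed.
#' @return Read table subset, in original row order.
#' @export
subsample_reads <- function(reads, n = 200L, seed = 1L) {
  stopifnot(n >= 1L)
  if (nrow(reads) <= n) return(reads)
  idx <- with_seed(seed, sample.int(nrow(reads), n))
  out <- reads[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag BLAST hits with their taxon group
#'
#' Each hit is mapped to the first listed group whose subtree (in the
#' supplied taxonomy) contains the hit's taxid; hits matching no group, or
#' with a taxid absent from the taxonomy, are dropped and counted.
#'
#' @param hits Hit table from [read_blast_tab()].
#' @param groups Group table (see [default_taxon_groups()]).
#' @param taxonomy Taxonomy table from [read_taxonomy()].
#' @return Hit table with a `group` column; attributes `n_dropped_no_group`
#'   and `n_dropped_unknown_taxid` carry the drop counts.
#' @export
filter_hits_by_taxa <- function(hits, groups, taxonomy) {
  parents <- taxonomy_parents(taxonomy)
  uids <- unique(hits$taxon_id)
  known <- uids %in% taxonomy$taxon_id
  grp <- rep(NA_character_, length(uids))
  for (i in which(known)) {
    anc <- taxon_lineage_ids(uids[i], parents)
    m <- which(groups$root %in% anc)
    if (length(m)) grp[i] <- groups$name[min(m)]
  }
  if (any(!known)) {
    message(sum(!known), " taxid(s) absent from taxonomy; their hits dropped")
  }
  map <- setNames(grp, as.character(uids))
  hit_grp <- unname(map[as.character(hits$taxon_id)])
  keep <- !is.na(hit_grp)
  out <- hits[keep, , drop = FALSE]
  out$group <- hit_grp[keep]
  rownames(out) <- NULL
  attr(out, "n_dropped_no_group") <-
    sum(!is.na(match(hits$taxon_id, uids[known])) & !keep)
  attr(out, "n_dropped_unknown_taxid") <- sum(hits$taxon_id %in% uids[!known])
  out
}

# Internal: lift each taxid to its nearest species-or-below node.
# Returns a data.frame(taxon_id, species_id, species_level).
lift_to_species <- function(taxids, taxonomy) {
  parents <- taxonomy_parents(taxonomy)
  ranks <- setNames(taxonomy$rank, as.character(taxonomy$taxon_id))
  uids <- unique(taxids)
  sp <- integer(length(uids))
  lvl <- logical(length(uids))
  for (i in seq_along(uids)) {
    anc <- taxon_lineage_ids(uids[i], parents)
    r <- ranks[as.character(anc)]
    hit <- which(r == "species")
    if (length(hit)) {
      sp[i] <- anc[hit[1]]  # self or nearest ancestor at species rank
      lvl[i] <- TRUE
    } else {
      sp[i] <- uids[i]      # above species: counted at its own rank
      lvl[i] <- FALSE
    }
  }
  data.frame(taxon_id = uids, species_id = sp, species_level = lvl)
}

#' First pass: rank species by their frequency of presence
#'
#' For each read, the qualifying species are those of hits whose bitscore
#' is within `tolerance` of the read's best bitscore. A species'
#' frequency of presence is the number of reads (not hits) in which it
#' qualifies. Species are ranked by that count, descending; ties break by
#' ascending taxid.
#'
#' @param hits Group-tagged hit table (one row per query-taxid pair).
#' @param taxonomy Taxonomy table (used to lift hits to species level).
#' @param tolerance Additive bitscore tolerance defining "similar score".
#' @return `data.frame` (`taxon_id`, `name`, `n_reads_present`, `rank`,
#'   `species_level`), rank 1 = most frequent.
#' @export
first_pass_rank <- function(hits, taxonomy, tolerance = 2) {
  if (nrow(hits) == 0L) {
    return(data.frame(taxon_id = integer(0), name = character(0),
                      n_reads_present = integer(0), rank = integer(0),
                      species_level = logical(0)))
  }
  lift <- lift_to_species(hits$taxon_id, taxonomy)
  dt <- data.table(read = hits$query_id,
                   species = lift$species_id[match(hits$taxon_id,
                                                   lift$taxon_id)],
                   bitscore = hits$bitscore)
  dt[, best := max(bitscore), by = read]
  qual <- unique(dt[bitscore >= best - tolerance, .(read, species)])
  tab <- qual[, .(n_reads_present = .N), by = species]
  setorder(tab, -n_reads_present, species)
  names_map <- setNames(taxonomy$name, as.character(taxonomy$taxon_id))
  out <- data.frame(taxon_id = tab$species,
                    name = unname(names_map[as.character(tab$species)]),
                    n_reads_present = tab$n_reads_present,
                    rank = seq_len(nrow(tab)),
                    stringsAsFactors = FALSE)
  out$species_level <- lift$species_level[match(out$taxon_id, lift$species_id)]
  out
}

#' Second pass: assign each read to the highest-ranked near-best species
#'
#' Per read, the candidate species are those within `tolerance` of the
#' read's best bitscore; the read is assigned to the candidate with the
#' best (smallest) first-pass rank. Species absent from the rank table are
#' treated as worst rank; remaining ties break by ascending taxid. The
#' result is independent of the order of the hit records.
#'
#' @param hits Group-tagged hit table.
#' @param rank_table Result of [first_pass_rank()] on the same hit set.
#' @param taxonomy Taxonomy table.
#' @param tolerance Additive bitscore tolerance.
#' @return `data.frame` (`read_id`, `taxon_id`, `species_name`, `group`,
#'   `bitscore`, `n_candidates`), one row per read with at least one hit.
#' @export
second_pass_assign <- function(hits, rank_table, taxonomy, tolerance = 2) {
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(0), taxon_id = integer(0),
                      species_name = character(0), group = character(0),
                      bitscore = numeric(0), n_candidates = integer(0)))
  }
  lift <- lift_to_species(hits$taxon_id, taxonomy)
  rk <- setNames(rank_table$rank, as.character(rank_table$taxon_id))
  worst <- if (nrow(rank_table)) max(rank_table$rank) + 1L else 1L
  dt <- data.table(read = hits$query_id,
                   species = lift$species_id[match(hits$taxon_id,
                                                   lift$taxon_id)],
                   bitscore = hits$bitscore,
                   group = hits$group)
  dt[, best := max(bitscore), by = read]
  cand <- dt[bitscore >= best - tolerance]
  # best bitscore per candidate species within a read
  cand <- cand[, .(bitscore = max(bitscore), group = group[1]),
               by = .(read, species)]
  cand[, rank := {
    r <- rk[as.character(species)]
    ifelse(is.na(r), worst, r)
  }]
  setorder(cand, read, rank, species)
  win <- cand[, .(taxon_id = species[1], bitscore = bitscore[1],
                  group = group[1], n_candidates = .N), by = read]
  names_map <- setNames(taxonomy$name, as.character(taxonomy$taxon_id))
  out <- data.frame(read_id = win$read, taxon_id = win$taxon_id,
                    species_name = unname(names_map[as.character(win$taxon_id)]),
                    group = win$group, bitscore = win$bitscore,
                    n_candidates = win$n_candidates,
                    stringsAsFactors = FALSE)
  out[order(out$read_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Select species for the metagenome reference
#'
#' Species whose share of assigned reads is strictly greater than
#' `threshold_fraction` (default 1%) are kept for the metagenome, sorted
#' by share descending (ties by ascending taxid).
#'
#' @param assignments Result of [second_pass_assign()].
#' @param threshold_fraction Strict lower bound on the assigned-read share.
#' @return `data.frame` (`taxon_id`, `species_name`, `n_reads`, `fraction`).
#' @export
select_metagenome_species <- function(assignments, threshold_fraction = 0.01) {
  if (nrow(assignments) == 0L) {
    return(data.frame(taxon_id = integer(0), species_name = character(0),
                      n_reads = integer(0), fraction = numeric(0)))
  }
  dt <- data.table(taxon_id = assignments$taxon_id,
                   name = assignments$species_name)
  tab <- dt[, .(n_reads = .N, species_name = name[1]), by = taxon_id]
  tab[, fraction := n_reads / nrow(assignments)]
  tab <- tab[fraction > threshold_fraction]
  setorder(tab, -fraction, taxon_id)
  as.data.frame(tab[, .(taxon_id, species_name, n_reads, fraction)])
}

#' Build the combined metagenome FASTA
#'
#' Concatenates the genomes of the selected species into one multi-FASTA.
#' Record descriptions are rewritten to `taxid|species_name|original_id`,
#' which also disambiguates record-id collisions across species. The host
#' genome (when among the selected species) is placed first.
#'
#' @param species `data.frame` from [select_metagenome_species()].
#' @param genome_files Named character vector: taxid (as name) -> FASTA path.
#' @param host_taxid Taxid treated as host (placed first). Default 9606.
#' @param out_fasta Optional path: write the combined FASTA there.
#' @return List with `sequences` (`DNAStringSet`) and `manifest`
#'   (`data.frame`: taxon_id, species_name, source, n_records, status).
#' @export
build_metagenome <- function(species, genome_files, host_taxid = 9606L,
                             out_fasta = NULL) {
  ord <- order(species$taxon_id != host_taxid,
               seq_len(nrow(species)))  # host first, then selection order
  species <- species[ord, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet()
  man <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    tid <- species$taxon_id[i]
    path <- if (as.character(tid) %in% names(genome_files)) {
      genome_files[[as.character(tid)]]
    } else NA_character_
    if (is.na(path) || !file.exists(path)) {
      man[[i]] <- data.frame(taxon_id = tid,
                             species_name = species$species_name[i],
                             source = path,
                             n_records = 0L, status = "missing",
                             stringsAsFactors = FALSE)
      next
    }
    g <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(g))
    names(g) <- paste(tid, gsub("[|[:space:]]+", "_",
                                species$species_name[i]), ids, sep = "|")
    seqs <- c(seqs, g)
    man[[i]] <- data.frame(taxon_id = tid,
                           species_name = species$species_name[i],
                           source = path, n_records = length(g),
                           status = "ok", stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_fasta)) Biostrings::writeXStringSet(seqs, out_fasta)
  list(sequences = seqs, manifest = manifest)
}

# Internal: seqid of a metagenome record -> species taxid.
metagenome_seqid_taxid <- function(seqids) {
  as.integer(sub("\\|.*$", "", seqids))
}

#' Export species assignments as Krona-importable text
#'
#' One line per species: the read count followed by the tab-separated
#' lineage from just below the root down to the species. Counts sum to the
#' number of assigned reads.
#'
#' @param assignments Result of [second_pass_assign()].
#' @param taxonomy Taxonomy table.
#' @param path Optional output file.
#' @return Character vector of text lines, invisibly if `path` is given.
#' @export
krona_text_export <- function(assignments, taxonomy, path = NULL) {
  parents <- taxonomy_parents(taxonomy)
  root <- attr(validate_taxonomy(taxonomy), "root")
  names_map <- setNames(taxonomy$name, as.character(taxonomy$taxon_id))
  dt <- data.table(taxon_id = assignments$taxon_id)
  tab <- dt[, .(n = .N), by = taxon_id]
  setorder(tab, -n, taxon_id)
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    ids <- rev(taxon_lineage_ids(tab$taxon_id[i], parents))
    ids <- setdiff(ids, root)
    paste(c(tab$n[i], unname(names_map[as.character(ids)])), collapse = "\t")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
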