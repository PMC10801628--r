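#' Spearman sample-correlation matrix
#'
#' Rank-based correlation (average ranks on ties) between the sample
#' columns of a count matrix. The diagonal is 1 by definition; pairs
#' involving a constant column are `NA`.
#'
#' @param counts Numeric matrix, columns = samples.
#' @return Symmetric sample x sample matrix with unit diagonal.
#' @export
spearman_correlation_table <- function(counts) {
  stopifnot(ncol(counts) >= 2L)
  C <- suppressWarnings(cor(counts, method = "spearman"))
  diag(C) <- 1
  C
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        rownames_as),
               as.data.frame(x, stringsAsFactors = FALSE))
    rownames(x) <- NULL
  }
  df <- as.data.frame(x)
  if (!is.null(df$attributes)) df$attributes <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the consolidated report file set
#'
#' One TSV per report section; sections absent from `tables` are written
#' as header-only files where a canonical header is known.
#'
#' @param tables Named list of section tables (`settings`,
#'   `sample_stats`, `species_catalogue`, `rna_type_catalogue`,
#'   `feature_counts`, `spearman`, `de_features`, `summary`, plus any
#'   `alignment_free_*` tables).
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths.
#' @export
emit_report <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    x <- tables[[nm]]
    if (is.matrix(x)) {
      write_tsv(x, path, rownames_as = "row_id")
    } else {
      write_tsv(x, path)
    }
    written <- c(written, path)
  }
  written
}

#' Run the full analysis pipeline on in-memory inputs
#'
#' Executes the stages in order: length filter, environment filter,
#' representative-subset species identification (two-pass), metagenome
#' selection and construction, alignment (exhaustive toy aligner),
#' strategy orchestration with priority counting, RNA-type and species
#' catalogues, differential expression on feature counts, and the
#' alignment-free analysis. Every section is written under `out_dir`; a
#' manifest records the package version, seed and parameters. Identical
#' inputs and parameters give byte-identical outputs.
#'
#' @param reads Read table for all biological samples (groups `test` /
#'   `control`; reads with group `ignore` are dropped).
#' @param env_reads Read table of the environmental control (may have
#'   zero rows).
#' @param references A [make_toy_references()]-shaped reference bundle
#'   (genomes keyed by taxid, annotation `sources`, `taxonomy`).
#' @param out_dir Report directory.
#' @param strategy `"metagenome"` or `"successive"`.
#' @param min_length Minimum read length (nt).
#' @param subset_n,seed Representative subset size and seed.
#' @param tolerance Bitscore tolerance for the two-pass assignment.
#' @param threshold_fraction Metagenome species threshold.
#' @param lfc_threshold,padj_threshold DE significance thresholds.
#' @param keep_count,keep_samples Keep-hits filter parameters.
#' @param cap_up,cap_down Alignment-free selection caps.
#' @param identity_threshold Clustering identity threshold.
#' @param max_mismatches Mismatch allowance of the toy aligner.
#' @return Invisibly, a list with the main in-memory results
#'   (`provenance`, `counts`, `summary`, `rna_types`, `species`,
#'   `de_features`, `alignment_free`).
#' @export
run_pipeline <- function(reads, env_reads, references, out_dir,
                         strategy = c("metagenome", "successive"),
                         min_length = 15L, subset_n = 200L, seed = 1L,
                         tolerance = 2, threshold_fraction = 0.01,
                         lfc_threshold = 1, padj_threshold = 0.05,
                         keep_count = 2L, keep_samples = 2L,
                         cap_up = 1000L, cap_down = 1000L,
                         identity_threshold = 0.8,
                         max_mismatches = 0L) {
  strategy <- match.arg(strategy)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!all(reads$group %in% c("test", "control", "environment", "ignore"))) {
    stop("unknown group label in sample table")
  }
  reads <- reads[reads$group %in% c("test", "control"), , drop = FALSE]
  if (!nrow(reads)) stop("no test/control reads supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n_input <- nrow(reads)
  lf <- stage("length_filter", length_filter(reads, min_length))
  idx <- stage("environment_index", {
    env_kept <- length_filter(env_reads, min_length)$kept
    suppressWarnings(build_environment_index(env_kept, min_length))
  })
  ef <- stage("environment_filter", filter_environment(lf$kept, idx))
  kept <- ef$kept
  n_filtered <- n_input - nrow(kept)

  sub <- stage("subsample", subsample_reads(kept, subset_n, seed))
  aln_all <- stage("subset_alignment",
                   naive_align(sub, references$genomes, max_mismatches))
  tagged <- stage("taxa_filter",
                  filter_hits_by_taxa(aln_all$hits, default_taxon_groups(),
                                      references$taxonomy))
  ranks <- stage("first_pass",
                 first_pass_rank(tagged, references$taxonomy, tolerance))
  assign <- stage("second_pass",
                  second_pass_assign(tagged, ranks, references$taxonomy,
                                     tolerance))
  meta_species <- stage("metagenome_selection",
                        select_metagenome_species(assign,
                                                  threshold_fraction))
  host_tid <- 9606L
  if (!host_tid %in% meta_species$taxon_id) {
    host_row <- data.frame(taxon_id = host_tid,
                           species_name = "Homo sapiens",
                           n_reads = sum(assign$taxon_id == host_tid),
                           fraction = mean(assign$taxon_id == host_tid))
    meta_species <- rbind(host_row, meta_species)
  }
  genome_dir <- file.path(out_dir, "genomes")
  dir.create(genome_dir, showWarnings = FALSE)
  gf <- character(0)
  for (tid in names(references$genomes)) {
    if (!grepl("^[0-9]+$", tid)) next
    p <- file.path(genome_dir, paste0(tid, ".fa"))
    Biostrings::writeXStringSet(references$genomes[[tid]], p)
    gf[tid] <- p
  }
  meta <- stage("metagenome_build",
                build_metagenome(meta_species, gf, host_taxid = host_tid,
                                 out_fasta = file.path(out_dir,
                                                       "metagenome.fa")))
  meta_tax <- setNames(metagenome_seqid_taxid(names(meta$sequences)),
                       names(meta$sequences))
  host_aln <- stage("host_alignment",
                    naive_align(kept, references$genomes["9606"],
                                max_mismatches))
  meta_aln <- stage("metagenome_alignment",
                    naive_align(kept, meta$sequences, max_mismatches,
                                seqid_taxid = meta_tax))
  catalogue <- stage("catalogue", build_catalogue(references$sources))
  orch <- stage("orchestration",
                orchestrate_strategy(kept, host_aln$placements,
                                     meta_aln$placements, strategy,
                                     catalogue, host_taxid = host_tid,
                                     n_filtered = n_filtered))
  rna_types <- stage("rna_type_catalogue",
                     catalogue_rna_types(orch$counts, catalogue$schema))
  species_cat <- stage("species_catalogue",
                       catalogue_species(orch$provenance,
                                         references$taxonomy))
  groups <- setNames(kept$group, kept$sample_id)
  groups <- groups[!duplicated(names(groups))]
  counts_m <- unclass(orch$counts)
  de_feat <- NULL
  if (all(table(groups) >= 2L) &&
      all(c("test", "control") %in% groups)) {
    de_feat <- stage("differential_expression", {
      keep_rows <- rowSums(counts_m) > 0
      differential_expression(counts_m[keep_rows, , drop = FALSE],
                              groups, lfc_threshold, padj_threshold)
    })
  }
  af <- stage("alignment_free", {
    sm <- collapse_sequences(kept)
    sm <- suppressWarnings(filter_keep_hits(sm, keep_count, keep_samples))
    de <- if (nrow(sm)) {
      differential_expression(sm, groups, lfc_threshold, padj_threshold)
    } else {
      data.frame(baseMean = numeric(0), log2FoldChange = numeric(0),
                 pvalue = numeric(0), padj = numeric(0),
                 significant = logical(0))
    }
    sel <- select_top_sequences(de, cap_up, cap_down)
    cl <- cluster_and_consensus(rownames(sel), identity_threshold,
                                counts = rowSums(sm)[rownames(sel)])
    lab <- if (nrow(sel)) {
      sel_reads <- data.frame(read_id = rownames(sel),
                              sequence = rownames(sel),
                              sample_id = "selected", group = "test",
                              stringsAsFactors = FALSE)
      sel_hits <- naive_align(sel_reads, references$genomes,
                              max_mismatches)$hits
      annotate_selected(rownames(sel), sel_hits, references$taxonomy)
    } else character(0)
    list(matrix = sm, de = de, selected = sel, clusters = cl,
         source_labels = lab)
  })
  spear <- stage("spearman", spearman_correlation_table(counts_m))

  settings <- data.frame(
    parameter = c("package_version", "strategy", "min_length", "subset_n",
                  "seed", "tolerance", "threshold_fraction",
                  "lfc_threshold", "padj_threshold", "keep_count",
                  "keep_samples", "cap_up", "cap_down",
                  "identity_threshold", "max_mismatches"),
    value = c(as.character(packageVersion("srnacore")), strategy,
              min_length, subset_n, seed, tolerance, threshold_fraction,
              lfc_threshold, padj_threshold, keep_count, keep_samples,
              cap_up, cap_down, identity_threshold, max_mismatches),
    stringsAsFactors = FALSE)
  sample_stats <- merge(
    as.data.frame(table(sample_id = reads$sample_id),
                  stringsAsFactors = FALSE),
    ef$stats, by = "sample_id", all = TRUE)
  names(sample_stats)[names(sample_stats) == "Freq"] <- "n_input"
  cluster_tab <- if (length(af$clusters)) {
    data.frame(
      cluster = seq_along(af$clusters),
      consensus = vapply(af$clusters, `[[`, character(1), "consensus"),
      n_members = vapply(af$clusters, function(cl) length(cl$members),
                         integer(1)),
      mean_identity = vapply(af$clusters, `[[`, numeric(1),
                             "mean_identity"),
      source = vapply(af$clusters, function(cl) {
        lab <- af$source_labels[cl$members[1]]
        if (is.na(lab)) "unknown" else lab
      }, character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(cluster = integer(0), consensus = character(0),
               n_members = integer(0), mean_identity = numeric(0),
               source = character(0))
  }
  tables <- list(
    settings = settings,
    sample_stats = sample_stats,
    merge_report = catalogue$reports,
    species_catalogue = species_cat,
    rna_type_catalogue = as.matrix(rna_types),
    feature_counts = counts_m,
    spearman = round(spear, 6),
    summary = orch$summary,
    alignment_free_selected = if (nrow(af$selected)) {
      cbind(sequence = rownames(af$selected),
            round(af$selected[, c("baseMean", "log2FoldChange", "pvalue",
                                  "padj")], 6),
            source = unname(af$source_labels[rownames(af$selected)]))
    } else {
      data.frame(sequence = character(0), baseMean = numeric(0),
                 log2FoldChange = numeric(0), pvalue = numeric(0),
                 padj = numeric(0), source = character(0))
    },
    alignment_free_clusters = cluster_tab)
  if (!is.null(de_feat)) {
    tables$de_features <- cbind(feature_id = rownames(de_feat),
                                round(de_feat[, c("baseMean",
                                                  "log2FoldChange",
                                                  "pvalue", "padj")], 6),
                                significant = de_feat$significant)
  } else {
    tables$de_features <- data.frame(feature_id = character(0),
                                     baseMean = numeric(0),
                                     log2FoldChange = numeric(0),
                                     pvalue = numeric(0),
                                     padj = numeric(0),
                                     significant = logical(0))
  }
  krona <- stage("krona", {
    pr <- orch$provenance[!is.na(orch$provenance$taxon_id), , drop = FALSE]
    if (nrow(pr)) {
      krona_text_export(data.frame(taxon_id = pr$taxon_id),
                        references$taxonomy,
                        path = file.path(out_dir, "krona.txt"))
    } else {
      writeLines(character(0), file.path(out_dir, "krona.txt"))
    }
  })
  manifest <- meta$manifest
  # paths relative to the report directory: identical runs must produce
  # byte-identical reports wherever they are written
  manifest$source <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])",
                                          "\\\\\\1", out_dir), "/?"),
                         "", manifest$source)
  write_tsv(manifest, file.path(out_dir, "metagenome_manifest.tsv"))
  write_tsv(ranks, file.path(out_dir, "species_ranks.tsv"))
  emit_report(tables, out_dir)
  invisible(list(provenance = orch$provenance, counts = orch$counts,
                 summary = orch$summary, rna_types = rna_types,
                 species = species_cat, de_features = de_feat,
                 alignment_free = af, spearman = spear,
                 ranks = ranks, metagenome = meta))
}
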