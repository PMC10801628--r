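#' Collapse reads into a unique-sequence count matrix
#'
#' Expression is measured directly on exact read sequences, bypassing any
#' reference: cell (s, j) is the number of reads in sample j whose
#' sequence equals s. Column sums equal the per-sample read counts.
#'
#' @param reads Read table covering all samples (after filtering).
#' @return Integer matrix, rownames = sequences, colnames = sample ids.
#' @export
collapse_sequences <- function(reads) {
  samples <- sort(unique(reads$sample_id))
  seqs <- sort(unique(reads$sequence))
  tab <- table(factor(reads$sequence, levels = seqs),
               factor(reads$sample_id, levels = samples))
  m <- matrix(as.integer(tab), nrow = length(seqs),
              dimnames = list(seqs, samples))
  m
}

#' Keep-hits filter on a sequence count matrix
#'
#' Keeps rows observed with at least `min_count` reads in at least
#' `min_samples` samples; the rest of the (typically huge) unique-sequence
#' matrix is dropped before testing.
#'
#' @param matrix Count matrix from [collapse_sequences()] (or any
#'   feature x sample count matrix).
#' @param min_count Minimum per-sample count.
#' @param min_samples Minimum number of samples reaching `min_count`.
#' @return The filtered matrix.
#' @export
filter_keep_hits <- function(matrix, min_count = 2L, min_samples = 2L) {
  keep <- rowSums(matrix >= min_count) >= min_samples
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("keep-hits filter removed every row")
  out
}

#' Differential expression of a count matrix (test vs control)
#'
#' Fits the standard negative-binomial count model per row with
#' median-of-ratios-style (relative log expression) size-factor
#' normalization, tests the group effect with edgeR's exact NB test, and
#' applies Benjamini-Hochberg adjustment. Works identically for feature
#' count matrices and unique-sequence matrices; the fit is deterministic
#' given the matrix.
#'
#' @param matrix Integer count matrix (rows = features or sequences).
#' @param groups Named vector mapping each column name to `"test"` or
#'   `"control"`.
#' @param lfc_threshold Significance requires `|log2FoldChange| >=` this.
#' @param padj_threshold Significance requires BH-adjusted p below this.
#' @return `data.frame` in input row order: `baseMean` (mean of
#'   size-factor-normalized counts), `log2FoldChange` (test vs control),
#'   `pvalue`, `padj`, `significant`.
#' @export
differential_expression <- function(matrix, groups, lfc_threshold = 1,
                                    padj_threshold = 0.05) {
  groups <- groups[colnames(matrix)]
  if (any(is.na(groups)) || !all(groups %in% c("test", "control"))) {
    stop("every sample column needs a 'test' or 'control' group label")
  }
  if (!all(c("test", "control") %in% groups)) {
    stop("both a test and a control group are required")
  }
  condition <- factor(groups, levels = c("control", "test"))
  storage.mode(matrix) <- "integer"
  y <- edgeR::DGEList(counts = matrix, group = condition)
  y <- edgeR::calcNormFactors(y, method = "RLE")
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y, pair = c("control", "test"))
  eff_lib <- y$samples$lib.size * y$samples$norm.factors
  sf <- eff_lib / exp(mean(log(eff_lib)))
  out <- data.frame(baseMean = rowMeans(sweep(matrix, 2, sf, "/")),
                    log2FoldChange = et$table$logFC,
                    pvalue = et$table$PValue,
                    padj = p.adjust(et$table$PValue, method = "BH"),
                    row.names = rownames(matrix),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$padj) & out$padj < padj_threshold &
    !is.na(out$log2FoldChange) & abs(out$log2FoldChange) >= lfc_threshold
  out
}

#' Cap the selection of differentially expressed sequences
#'
#' Significant rows are split by fold-change sign; each side is sorted by
#' adjusted p ascending (ties: smaller absolute log2 fold change first,
#' then row name lexicographically) and truncated to its cap.
#'
#' @param de_table Result of [differential_expression()] (rownames =
#'   sequences).
#' @param cap_up,cap_down Maximum rows kept per direction.
#' @return The selected subset of `de_table`, up-regulated rows first.
#' @export
select_top_sequences <- function(de_table, cap_up = 1000L,
                                 cap_down = 1000L) {
  sig <- de_table[de_table$significant, , drop = FALSE]
  take <- function(side, cap) {
    s <- sig[side, , drop = FALSE]
    ord <- order(s$padj, abs(s$log2FoldChange), rownames(s))
    s[ord[seq_len(min(cap, nrow(s)))], , drop = FALSE]
  }
  rbind(take(sig$log2FoldChange > 0, cap_up),
        take(sig$log2FoldChange < 0, cap_down))
}

# Internal: global-alignment identities (matches / alignment columns) of
# several patterns against one subject, in one vectorised call.
alignment_identity <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy centroid clustering with consensus calling
#'
#' Sequences are visited in order of decreasing total count (ties:
#' lexicographic); each joins the first existing cluster whose centroid it
#' matches with global-alignment identity >= `identity_threshold`,
#' otherwise it founds a new cluster. The consensus is the per-column
#' majority over the centroid-anchored alignment of all members (ties by
#' alphabetical base; insertions relative to the centroid are ignored, so
#' the consensus has the centroid's length). Members whose identity to
#' the final consensus falls below the threshold are flagged borderline.
#'
#' @param sequences Character vector of sequences.
#' @param identity_threshold Minimum identity to join a cluster.
#' @param counts Optional numeric vector of total counts (same order as
#'   `sequences`) used for the visiting order.
#' @return List of clusters: each has `members`, `consensus`,
#'   `mean_identity`, `borderline` (member sequences below threshold).
#' @export
cluster_and_consensus <- function(sequences, identity_threshold = 0.8,
                                  counts = NULL) {
  if (!length(sequences)) return(list())
  ord <- if (is.null(counts)) order(sequences) else
    order(-counts, sequences)
  seqs <- sequences[ord]
  centroids <- character(0)
  membership <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    k <- if (length(centroids)) {
      eq <- match(seqs[i], centroids)
      if (!is.na(eq)) eq else {
        ident <- alignment_identity(centroids, seqs[i])
        which(ident >= identity_threshold)[1]
      }
    } else NA_integer_
    if (is.na(k)) {
      centroids <- c(centroids, seqs[i])
      k <- length(centroids)
    }
    membership[i] <- k
  }
  lapply(seq_along(centroids), function(k) {
    members <- seqs[membership == k]
    centroid <- centroids[k]
    L <- nchar(centroid)
    votes <- matrix(0L, nrow = 5L, ncol = L,
                    dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    exact <- members == centroid
    if (any(exact)) {
      cols <- strsplit(centroid, "")[[1]]
      for (j in seq_len(L)) votes[cols[j], j] <- votes[cols[j], j] +
          sum(exact)
    }
    rest <- members[!exact]
    if (length(rest)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(rest), Biostrings::DNAString(centroid),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 2, gapExtension = 1)
      pa_all <- as.character(Biostrings::alignedPattern(aln))
      sa_all <- as.character(Biostrings::alignedSubject(aln))
      for (mi in seq_along(rest)) {
        pa <- strsplit(pa_all[mi], "")[[1]]
        sa <- strsplit(sa_all[mi], "")[[1]]
        j <- 0L
        for (col in seq_along(sa)) {
          if (sa[col] != "-") {
            j <- j + 1L
            if (pa[col] != "-") votes[pa[col], j] <- votes[pa[col], j] + 1L
          }
        }
      }
    }
    consensus <- paste(rownames(votes)[apply(votes, 2, which.max)],
                       collapse = "")
    ident <- rep(1, length(members))
    chk <- members != consensus
    if (any(chk)) ident[chk] <- alignment_identity(members[chk], consensus)
    list(members = members, consensus = consensus,
         mean_identity = mean(ident),
         borderline = members[ident < identity_threshold])
  })
}

#' Preliminary source labelling of selected sequences
#'
#' Labels each sequence by the taxon group of its best-bitscore hit
#' (ties: lowest taxid): `human` for the host group, `bacterial` for
#' Bacteria, `other` for any other group, `unknown` without hits.
#'
#' @param sequences Character vector of sequence identifiers matching
#'   `query_id` in `hits` (for collapsed sequences the sequence itself).
#' @param hits Hit table (see [read_blast_tab()]).
#' @param taxonomy Taxonomy table.
#' @param groups Taxon group table.
#' @return Named character vector of labels.
#' @export
annotate_selected <- function(sequences, hits, taxonomy,
                              groups = default_taxon_groups()) {
  labels <- setNames(rep("unknown", length(sequences)), sequences)
  if (nrow(hits)) {
    tagged <- filter_hits_by_taxa(hits, groups, taxonomy)
    tagged <- tagged[tagged$query_id %in% sequences, , drop = FALSE]
    if (nrow(tagged)) {
      dt <- as.data.table(tagged[, c("query_id", "bitscore", "taxon_id",
                                     "group")])
      setorder(dt, query_id, -bitscore, taxon_id)
      best <- dt[, head(.SD, 1L), by = query_id]
      lab <- ifelse(best$group == "Homo", "human",
                    ifelse(best$group == "Bacteria", "bacterial", "other"))
      labels[best$query_id] <- lab
    }
  }
  labels
}
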