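placement_df <- function(read_id, seqid, pos, end, strand = "+",
                         sample_id = "s1") {
  data.frame(read_id = read_id, seqid = seqid, pos = pos, end = end,
             strand = strand, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

simple_catalogue <- function(features) {
  sources <- split(features, features$source_db)
  build_catalogue(sources)
}

test_that("multimapper reassignment follows local coverage and never moves unique reads", {
  # ten unique reads clustered near position 1000; one isolated locus
  uniq <- placement_df(paste0("u", 1:10), "c1", seq(995, 1022, 3),
                       seq(1015, 1042, 3))
  multi <- rbind(
    placement_df("m1", "c1", 1005, 1025),   # inside the cluster
    placement_df("m1", "c1", 5000, 5020))   # isolated
  res <- reassign_multimappers(rbind(uniq, multi))
  expect_equal(nrow(res), 11L)
  expect_equal(res$pos[res$read_id == "m1"], 1005)
  expect_equal(res$pos[res$read_id == "u1"], 995)  # unique unchanged

  # all candidates weight zero -> lowest (seqid, coordinate)
  lonely <- rbind(placement_df("m2", "c2", 300, 320),
                  placement_df("m2", "c1", 700, 720),
                  placement_df("m2", "c2", 100, 120))
  res2 <- reassign_multimappers(lonely)
  expect_equal(res2[res2$read_id == "m2", c("seqid", "pos")],
               data.frame(seqid = "c1", pos = 700), ignore_attr = TRUE)
})

test_that("second pass of reassignment can recruit multimappers into a multimapper cluster", {
  # no unique reads; 5 multimappers share locus A candidates, so pass 2
  # concentrates them after pass 1 breaks the tie toward the lowest
  # coordinate consistently
  multi <- do.call(rbind, lapply(1:5, function(i) rbind(
    placement_df(paste0("m", i), "c1", 1000 + i, 1020 + i),
    placement_df(paste0("m", i), "c1", 8000 + i * 300, 8020 + i * 300))))
  res <- reassign_multimappers(multi, passes = 2L)
  expect_true(all(res$pos < 2000))  # all converge on the shared locus
})

test_that("priority resolution picks miRNA over piRNA and fills reserved rows", {
  feats <- rbind(
    data.frame(seqid = "c1", start = 100L, end = 121L, strand = "+",
               source_db = "mirbase", rna_type = "miRNA", name = "mir1",
               stringsAsFactors = FALSE),
    data.frame(seqid = "c1", start = 95L, end = 124L, strand = "+",
               source_db = "pirbase", rna_type = "piRNA", name = "pir1",
               stringsAsFactors = FALSE))
  feats$attributes <- rep(list(list()), 2)
  cat_h <- simple_catalogue(feats)
  pl <- rbind(placement_df("r1", "c1", 105L, 120L),
              placement_df("r2", "c1", 5000L, 5020L))
  m <- count_with_priority(pl, cat_h)
  mir_row <- cat_h$features$feature_id[cat_h$features$name == "mir1"]
  pir_row <- cat_h$features$feature_id[cat_h$features$name == "pir1"]
  expect_equal(unname(m[mir_row, "s1"]), 1L)
  expect_equal(unname(m[pir_row, "s1"]), 0L)
  expect_equal(unname(m["__unannotated__", "s1"]), 1L)
  expect_equal(sum(m), nrow(pl))  # every read counted exactly once
})

test_that("reads inside an mRNA gene span but off-exon count as intronic", {
  ex <- data.frame(seqid = "c1", start = c(1000L, 2000L),
                   end = c(1100L, 2100L), strand = "+",
                   source_db = "gencode", rna_type = "mRNA",
                   name = c("g1.ex1", "g1.ex2"), stringsAsFactors = FALSE)
  ex$attributes <- rep(list(list(gene_id = "g1")), 2)
  cat_h <- simple_catalogue(ex)
  pl <- rbind(placement_df("exonic", "c1", 1010L, 1030L),
              placement_df("intronic", "c1", 1500L, 1520L),
              placement_df("outside", "c1", 9000L, 9020L),
              placement_df("wrong_strand", "c1", 1500L, 1520L, "-"))
  m <- count_with_priority(pl, cat_h)
  pr <- attr(m, "per_read")
  expect_equal(pr$assigned[pr$read_id == "intronic"], "__intronic__")
  expect_equal(pr$assigned[pr$read_id == "outside"], "__unannotated__")
  expect_equal(pr$assigned[pr$read_id == "wrong_strand"],
               "__unannotated__")
  expect_match(pr$assigned[pr$read_id == "exonic"], "g1\\.ex1")
})

test_that("priority counting matches a brute-force per-read resolver on random instances", {
  set.seed(55)
  n_feat <- 300L; n_reads <- 2000L
  feats <- random_feature_set(n_feat, genome_len = 20000L,
                              source_db = "dbA")
  feats$rna_type <- sample(c("miRNA", "tRNA", "rRNA", "piRNA", "lncRNA"),
                           n_feat, TRUE)
  featsB <- random_feature_set(n_feat %/% 2L, genome_len = 20000L,
                               source_db = "dbB")
  featsB$rna_type <- sample(c("miRNA", "snoRNA"), n_feat %/% 2L, TRUE)
  featsB$name <- paste0("b", seq_len(nrow(featsB)))
  cat_h <- build_catalogue(list(dbA = feats, dbB = featsB))
  pos <- sample.int(19000L, n_reads, replace = TRUE)
  len <- sample(10:44, n_reads, TRUE)
  pl <- placement_df(sprintf("r%04d", seq_len(n_reads)), "chr1", pos,
                     pos + len - 1L,
                     strand = sample(c("+", "-"), n_reads, TRUE))
  m <- count_with_priority(pl, cat_h)
  pr <- attr(m, "per_read")
  # brute-force oracle: scan all catalogue features per read
  cf <- cat_h$features
  sch <- cat_h$schema
  cls_rank <- match(cf$priority_class, sch$ordered_types)
  for (i in sample.int(n_reads, 300L)) {
    ov <- which(cf$seqid == pl$seqid[i] & cf$strand == pl$strand[i] &
                  cf$start <= pl$end[i] & cf$end >= pl$pos[i])
    if (!length(ov)) {
      expect_true(pr$assigned[i] %in% c("__unannotated__", "__intronic__"))
      next
    }
    best_cls <- min(cls_rank[ov])
    cand <- ov[cls_rank[ov] == best_cls]
    width <- pmin(pl$end[i], cf$end[cand]) - pmax(pl$pos[i], cf$start[cand]) + 1L
    cand <- cand[width == max(width)]
    cand <- cand[cf$start[cand] == min(cf$start[cand])]
    expect_equal(pr$assigned[i], cf$feature_id[min(cand)])
  }
  # conservation and zero ambiguity
  expect_equal(sum(m), n_reads)
  expect_false("ambiguous" %in% rownames(m))
})

test_that("promoting a type in the schema never decreases its count", {
  set.seed(66)
  feats <- random_feature_set(100L, genome_len = 5000L, source_db = "db")
  feats$rna_type <- sample(c("miRNA", "piRNA"), 100L, TRUE)
  pos <- sample.int(4900L, 500L, TRUE)
  pl <- placement_df(sprintf("r%03d", 1:500), "chr1", pos, pos + 20L,
                     strand = sample(c("+", "-"), 500L, TRUE))
  count_of <- function(schema) {
    cat_h <- build_catalogue(list(db = feats), schema)
    m <- count_with_priority(pl, cat_h)
    pr <- attr(m, "per_read")
    cls <- cat_h$features$priority_class[
      match(pr$assigned, cat_h$features$feature_id)]
    sum(cls == "piRNA", na.rm = TRUE)
  }
  default_count <- count_of(priority_schema())
  promoted <- priority_schema(c("piRNA", setdiff(DEFAULT_PRIORITY,
                                                 "piRNA")))
  expect_gte(count_of(promoted), default_count)
})

test_that("RNA-type catalogue percentages are scale-invariant and sum to 100", {
  feats <- rbind(
    data.frame(seqid = "c1", start = 100L, end = 130L, strand = "+",
               source_db = "db", rna_type = "miRNA", name = "m1",
               stringsAsFactors = FALSE),
    data.frame(seqid = "c1", start = 500L, end = 580L, strand = "+",
               source_db = "db", rna_type = "tRNA", name = "t1",
               stringsAsFactors = FALSE))
  feats$attributes <- rep(list(list()), 2)
  cat_h <- simple_catalogue(feats)
  pl <- rbind(
    placement_df(paste0("a", 1:6), "c1", 105L, 125L),
    placement_df(paste0("b", 1:4), "c1", 510L, 540L))
  ct <- catalogue_rna_types(count_with_priority(pl, cat_h))
  expect_equal(ct["miRNA", "s1"], 60)
  expect_equal(ct["tRNA", "s1"], 40)
  type_rows <- setdiff(rownames(ct), c("intronic", "unannotated"))
  expect_equal(sum(ct[type_rows, "s1"], na.rm = TRUE), 100, tolerance = 1e-3)
  # duplicating every read leaves percentages unchanged
  pl2 <- rbind(pl, transform(pl, read_id = paste0(read_id, "_dup")))
  ct2 <- catalogue_rna_types(count_with_priority(pl2, cat_h))
  expect_equal(ct2, ct)
  # no annotated reads -> NA percentages
  far <- placement_df("z", "c1", 9000L, 9020L)
  ct3 <- catalogue_rna_types(count_with_priority(far, cat_h))
  expect_true(all(is.na(ct3[type_rows, "s1"])))
})

test_that("strategies agree on clean reads but split host-vs-microbe conflicts", {
  # toy genomes: host and one microbe
  host <- data.frame(seqid = "h1", start = 1L, end = 50L, strand = "+",
                     source_db = "db", rna_type = "miRNA", name = "m1",
                     stringsAsFactors = FALSE)
  host$attributes <- list(list())
  cat_h <- simple_catalogue(host)
  reads <- data.frame(read_id = c("clean_host", "conflict"),
                      sequence = c(strrep("A", 20), strrep("C", 20)),
                      quality = NA, sample_id = "s1", group = "test",
                      stringsAsFactors = FALSE)
  host_aln <- rbind(
    cbind(placement_df("clean_host", "h1", 10L, 29L), nm = 0L),
    cbind(placement_df("conflict", "h1", 100L, 119L), nm = 2L))
  meta_aln <- rbind(
    cbind(placement_df("clean_host", "9606|Homo_sapiens|h1", 10L, 29L),
          nm = 0L),
    cbind(placement_df("conflict", "9606|Homo_sapiens|h1", 100L, 119L),
          nm = 2L),
    cbind(placement_df("conflict", "562|Escherichia_coli|e1", 40L, 59L),
          nm = 0L))
  succ <- orchestrate_strategy(reads, host_aln, meta_aln, "successive",
                               cat_h)
  meta <- orchestrate_strategy(reads, host_aln, meta_aln, "metagenome",
                               cat_h)
  cat_of <- function(res, id)
    res$provenance$category[res$provenance$read_id == id]
  expect_match(cat_of(succ, "clean_host"), "^host_")
  expect_match(cat_of(meta, "clean_host"), "^host_")
  # the 2-mismatch host / perfect microbe read flips between strategies
  expect_match(cat_of(succ, "conflict"), "^host_")
  expect_equal(cat_of(meta, "conflict"), "other_species")
  # category percentages partition 100%
  for (res in list(succ, meta)) {
    s <- res$summary
    expect_equal(s$pct_filtered + s$pct_annotated + s$pct_intronic +
                   s$pct_unannotated + s$pct_other_species +
                   s$pct_unidentified, 100, tolerance = 1e-9)
  }
  expect_error(orchestrate_strategy(reads, host_aln, meta_aln, "bogus",
                                    cat_h), "arg")
})

test_that("species catalogue tabulates provenance per sample", {
  prov <- data.frame(read_id = paste0("r", 1:6),
                     sample_id = rep(c("s1", "s2"), each = 3),
                     category = c("host_annotated", "other_species",
                                  "unidentified", "host_annotated",
                                  "host_annotated", "other_species"),
                     taxon_id = c(9606L, 562L, NA, 9606L, 9606L, 562L),
                     stringsAsFactors = FALSE)
  sc <- catalogue_species(prov, tiny_taxonomy())
  expect_equal(sc$species_name[sc$taxon_id == 9606L], "Homo sapiens")
  expect_equal(sc$s1[sc$taxon_id == 9606L], 1L)
  expect_equal(sc$s2[sc$taxon_id == 9606L], 2L)
  expect_equal(sc$s1[sc$taxon_id == 562L], 1L)
})
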