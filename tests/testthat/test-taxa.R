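test_that("subsampling is reproducible, uniform-ish, and total below n", {
  reads <- data.frame(read_id = paste0("r", 1:100),
                      sequence = strrep("A", 20), quality = NA,
                      sample_id = "s", group = "test",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(subsample_reads(reads, 200L, 1L)), 100L)
  big <- reads[rep(1:100, 10), ]
  big$read_id <- paste0("r", 1:1000)
  s1 <- subsample_reads(big, 50L, 9L)
  s2 <- subsample_reads(big, 50L, 9L)
  expect_identical(s1, s2)
  s3 <- subsample_reads(big, 50L, 10L)
  expect_false(identical(s1$read_id, s3$read_id))
  # empirical inclusion probability over repeated seeds
  hits <- 0L
  for (seed in 1:300) {
    sub <- subsample_reads(big, 100L, seed)
    hits <- hits + ("r1" %in% sub$read_id)
  }
  expect_gt(hits / 300, 0.1 - 0.05)
  expect_lt(hits / 300, 0.1 + 0.05)
})

test_that("hits map to the first taxon group containing their taxid", {
  tax <- tiny_taxonomy()
  hits <- rbind(hit_row("a", 9606L, 40), hit_row("b", 562L, 38),
                hit_row("c", 1280L, 35), hit_row("d", 2759L, 30),
                hit_row("e", 4444L, 30))
  expect_message(tagged <- filter_hits_by_taxa(hits,
                                               default_taxon_groups(),
                                               tax),
                 "absent")
  expect_equal(tagged$group[tagged$query_id == "a"], "Homo")
  expect_equal(tagged$group[tagged$query_id == "b"], "Bacteria")  # via genus
  expect_equal(tagged$group[tagged$query_id == "c"], "Bacteria")
  # Eukaryota node sits in no listed subtree -> dropped
  expect_false("d" %in% tagged$query_id)
  expect_false("e" %in% tagged$query_id)  # unknown taxid dropped
})

test_that("first pass ranks species by reads present, with the documented tie rule", {
  tax <- tiny_taxonomy()
  hits <- rbind(
    hit_row("r1", 9606L, 40, "Homo"), hit_row("r2", 9606L, 42, "Homo"),
    hit_row("r3", 9606L, 44, "Homo"), hit_row("r4", 562L, 41, "Bacteria"))
  rk <- first_pass_rank(hits, tax, tolerance = 2)
  expect_equal(rk$taxon_id[rk$rank == 1L], 9606L)
  expect_equal(rk$n_reads_present, c(3L, 1L))

  # tie on reads-present: lower taxid wins the better rank
  tie <- rbind(hit_row(paste0("x", 1:5), 1280L, 40, "Bacteria"),
               hit_row(paste0("x", 1:5), 562L, 40, "Bacteria"))
  rt <- first_pass_rank(tie, tax, tolerance = 0)
  expect_equal(rt$n_reads_present, c(5L, 5L))
  expect_equal(rt$taxon_id, c(562L, 1280L))

  expect_equal(nrow(first_pass_rank(hits[0, ], tax)), 0L)
})

test_that("tolerance 0 reduces qualification to argmax bitscore (max oracle)", {
  tax <- tiny_taxonomy()
  set.seed(31)
  hits <- do.call(rbind, lapply(1:40, function(i) {
    n <- sample(1:4, 1)
    do.call(rbind, lapply(seq_len(n), function(j)
      hit_row(paste0("q", i), sample(c(9606L, 562L, 1280L), 1),
              round(runif(1, 20, 50), 1), "x")))
  }))
  rk <- first_pass_rank(hits, tax, tolerance = 0)
  # oracle: per read, species attaining the exact max bitscore
  oracle <- table(unlist(lapply(split(hits, hits$query_id), function(h)
    unique(h$taxon_id[h$bitscore == max(h$bitscore)]))))
  for (i in seq_len(nrow(rk))) {
    expect_equal(rk$n_reads_present[i],
                 as.integer(oracle[[as.character(rk$taxon_id[i])]]))
  }
})

test_that("second pass prefers the higher-ranked species within tolerance", {
  tax <- tiny_taxonomy()
  # rank table: B (562) rank 1, A (1280) rank 2
  base <- rbind(hit_row(paste0("bg", 1:3), 562L, 40, "Bacteria"),
                hit_row("bg4", 1280L, 40, "Bacteria"))
  rk <- first_pass_rank(base, tax, 2)
  expect_equal(rk$taxon_id, c(562L, 1280L))
  # read hits A with 40, B with 39.5; tolerance 1 -> B wins on rank
  read <- rbind(hit_row("q", 1280L, 40, "Bacteria"),
                hit_row("q", 562L, 39.5, "Bacteria"))
  asg <- second_pass_assign(read, rk, tax, tolerance = 1)
  expect_equal(asg$taxon_id, 562L)
  expect_equal(asg$n_candidates, 2L)
  # tolerance 0: unique best hit wins regardless of rank
  asg0 <- second_pass_assign(read, rk, tax, tolerance = 0)
  expect_equal(asg0$taxon_id, 1280L)
  # species missing from the rank table is treated as worst rank
  novel <- rbind(hit_row("z", 9606L, 40, "Homo"),
                 hit_row("z", 562L, 39.9, "Bacteria"))
  asgz <- second_pass_assign(novel, rk, tax, tolerance = 1)
  expect_equal(asgz$taxon_id, 562L)
})

test_that("assignments are invariant under permutation of hit records", {
  tax <- tiny_taxonomy()
  set.seed(13)
  hits <- do.call(rbind, lapply(1:100, function(i) {
    n <- sample(1:5, 1)
    do.call(rbind, lapply(seq_len(n), function(j)
      hit_row(sprintf("p%03d", i), sample(c(9606L, 562L, 1280L), 1),
              round(runif(1, 20, 50), 1), "x")))
  }))
  rk <- first_pass_rank(hits, tax, 2)
  a1 <- second_pass_assign(hits, rk, tax, 2)
  perm <- hits[sample.int(nrow(hits)), ]
  rk2 <- first_pass_rank(perm, tax, 2)
  a2 <- second_pass_assign(perm, rk2, tax, 2)
  expect_identical(a1, a2)
})

test_that("hits above species rank lift to species or count at their own rank", {
  tax <- tiny_taxonomy()
  hits <- rbind(hit_row("r1", 561L, 40, "Bacteria"),  # genus -> no species below
                hit_row("r2", 562L, 40, "Bacteria"))
  rk <- first_pass_rank(hits, tax, 0)
  expect_true(561L %in% rk$taxon_id)
  expect_false(rk$species_level[rk$taxon_id == 561L])
  expect_true(rk$species_level[rk$taxon_id == 562L])
})

test_that("metagenome selection applies the strict >1% rule over randomized tables", {
  mk <- function(fracs, total = 1000L) {
    counts <- round(fracs * total)
    taxids <- seq(100L, by = 10L, length.out = length(fracs))
    data.frame(read_id = paste0("r", seq_len(sum(counts))),
               taxon_id = rep(taxids, counts),
               species_name = rep(paste0("sp", seq_along(fracs)), counts),
               group = "x", bitscore = 40,
               n_candidates = 1L, stringsAsFactors = FALSE)
  }
  sel <- select_metagenome_species(mk(c(0.6, 0.3, 0.09, 0.005, 0.005)))
  expect_equal(nrow(sel), 3L)       # 0.5% excluded
  exact <- select_metagenome_species(mk(c(0.99, 0.01)))
  expect_equal(nrow(exact), 1L)     # exactly 1.0% excluded (strict >)
  four <- select_metagenome_species(mk(c(0.595, 0.30, 0.09, 0.015)))
  expect_equal(nrow(four), 4L)
  expect_equal(four$fraction, sort(four$fraction, decreasing = TRUE))
  set.seed(3)
  for (i in 1:20) {
    fr <- runif(6); fr <- fr / sum(fr)
    s <- select_metagenome_species(mk(fr))
    expect_true(all(s$fraction > 0.01))
    got <- mk(fr)
    tab <- table(got$taxon_id) / nrow(got)
    expect_setequal(s$taxon_id, as.integer(names(tab)[tab > 0.01]))
  }
})

test_that("metagenome construction rewrites descriptions and reports missing genomes", {
  d <- withr::local_tempdir()
  g1 <- file.path(d, "a.fa"); g2 <- file.path(d, "b.fa")
  writeLines(c(">contig1 desc", "ACGTACGTAC", ">contig2", "GGGGCCCC"), g1)
  writeLines(c(">contig1", "TTTTAAAA"), g2)  # id collision with g1
  sp <- data.frame(taxon_id = c(9606L, 562L, 1280L),
                   species_name = c("Homo sapiens", "Escherichia coli",
                                    "Staphylococcus aureus"),
                   n_reads = c(5L, 3L, 2L),
                   fraction = c(0.5, 0.3, 0.2))
  res <- build_metagenome(sp, c("562" = g1, "9606" = g2))
  expect_equal(res$manifest$status, c("ok", "ok", "missing"))
  expect_equal(res$manifest$taxon_id[1], 9606L)  # host first
  expect_equal(length(res$sequences), 3L)
  expect_match(names(res$sequences)[1], "^9606\\|Homo_sapiens\\|contig1$")
  # collision disambiguated by taxid prefix
  expect_equal(anyDuplicated(names(res$sequences)), 0L)
})

test_that("Krona text lines carry root-to-species lineages and conserve counts", {
  tax <- tiny_taxonomy()
  asg <- data.frame(taxon_id = c(rep(9606L, 10), rep(562L, 4)))
  lines <- krona_text_export(asg, tax)
  expect_equal(length(lines), 2L)
  parts <- strsplit(lines, "\t")
  counts <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  expect_equal(sum(counts), nrow(asg))
  # lineage oracle: walk the parent table from species to root
  human <- parts[[which(counts == 10)]]
  expect_equal(human[-1], c("cellular organisms", "Eukaryota",
                            "Homo sapiens"))
  ecoli <- parts[[which(counts == 4)]]
  expect_equal(ecoli[-1], c("cellular organisms", "Bacteria",
                            "Escherichia", "Escherichia coli"))
})

test_that("two-species control recovers species with high sensitivity and specificity", {
  st <- small_study()
  reads <- st$sim$reads[nchar(st$sim$reads$sequence) >= 18L, ]
  truth <- setNames(st$sim$truth$species, st$sim$truth$read_id)
  aln <- naive_align(reads, st$refs$genomes, 0)
  tagged <- filter_hits_by_taxa(aln$hits, default_taxon_groups(),
                                st$refs$taxonomy)
  rk <- first_pass_rank(tagged, st$refs$taxonomy, 2)
  asg <- second_pass_assign(tagged, rk, st$refs$taxonomy, 2)
  called <- setNames(asg$taxon_id, asg$read_id)
  for (sp in c(9606L, 562L, 1280L)) {
    is_sp <- truth[reads$read_id] == sp
    called_sp <- reads$read_id %in% names(called)[called == sp]
    sens <- sum(called_sp & is_sp) / sum(is_sp)
    spec <- sum(!called_sp & !is_sp) / sum(!is_sp)
    expect_gte(sens, 0.95)
    expect_gte(spec, 0.95)
  }
})
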