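tax <- fixture_taxonomy()

hit <- function(otu, taxon, ident, bits) {
  data.frame(otu_id = otu, subject_taxon = taxon, pct_identity = ident,
             bitscore = bits, stringsAsFactors = FALSE)
}

test_that("hit filtering applies the identity, bitscore and top-percent gates", {
  h <- rbind(hit("o1", "Sebastes_auriculatus", 98, 500),
             hit("o1", "Sebastes_mystinus", 98, 495),
             hit("o1", "Oxyjulis_californica", 98, 300))
  kept <- filter_hits(h)
  expect_equal(kept$bitscore, c(500, 495))  # 300 < 0.98 * 500
  # identity floor
  expect_equal(nrow(filter_hits(hit("o2", "Sebastes_mystinus", 84, 400))), 0)
  # single clean hit passes all gates
  expect_equal(nrow(filter_hits(hit("o3", "Sebastes_mystinus", 97, 400))), 1)
  # bitscore floor
  expect_equal(nrow(filter_hits(hit("o4", "Sebastes_mystinus", 99, 90))), 0)
})

test_that("majority LCA returns the deepest covering node", {
  u <- function(n, t) do.call(rbind, replicate(n, hit("o", t, 98, 400),
                                               simplify = FALSE))
  expect_equal(weighted_lca(u(10, "Sebastes_auriculatus"), tax),
               "Sebastes_auriculatus")
  # 9 of 10 hits on one species still clears the 85% majority
  h <- rbind(u(9, "Sebastes_auriculatus"), u(1, "Sebastes_mystinus"))
  expect_equal(weighted_lca(h, tax), "Sebastes_auriculatus")
  # 8 of 10 falls below: the shared genus covers all hits
  h <- rbind(u(8, "Sebastes_auriculatus"), u(2, "Sebastes_mystinus"))
  expect_equal(weighted_lca(h, tax), "Sebastes")
  # hits across families resolve at their common ancestor
  h <- rbind(u(5, "Sebastes_auriculatus"), u(5, "Oxyjulis_californica"))
  expect_equal(weighted_lca(h, tax), "Actinopteri")
})

test_that("rank thresholds elevate annotations that fail their gates", {
  a <- apply_rank_thresholds("Sebastes_auriculatus", 98, 400, tax)
  expect_equal(a$rank, "species")
  a <- apply_rank_thresholds("Sebastes_auriculatus", 96.5, 400, tax)
  expect_equal(a$taxon, "Sebastes")
  expect_equal(a$rank, "genus")
  a <- apply_rank_thresholds("Sebastes_auriculatus", 94, 400, tax)
  expect_equal(a$taxon, "Sebastidae")
  expect_equal(a$rank, "family")
  a <- apply_rank_thresholds("Sebastidae", 90, 250, tax)
  expect_equal(a$rank, "family")
  # never finer than the LCA rank
  a <- apply_rank_thresholds("Sebastes", 99, 500, tax)
  expect_equal(a$rank, "genus")
})

test_that("contaminant removal honours the blacklist and NTC threshold", {
  m <- matrix(c(10L, 20L, 30L,
                5L,  8L, 40L,
                0L,  0L, 143L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "NTC1"),
                              c("oA", "oB", "oC")))
  # oC has 143 NTC reads in one scenario, 22 in another
  annot <- data.frame(otu_id = c("oA", "oB", "oC"),
                      taxon_id = c("Sebastes_auriculatus",
                                   "Oxyjulis_californica",
                                   "Semicossyphus_pulcher"),
                      rank = "species", provenance = "lca",
                      stringsAsFactors = FALSE)
  x <- community_matrix(m, "reads")
  res <- remove_contaminants(x, "NTC1", annot, tax)
  expect_false("oC" %in% colnames(res$counts))       # 143 > 100
  expect_true(all(c("oA", "oB") %in% colnames(res$counts)))
  expect_false("NTC1" %in% rownames(res$counts))
  expect_equal(res$log$otu_id, "oC")

  m2 <- m; m2["NTC1", "oC"] <- 22L
  res2 <- remove_contaminants(community_matrix(m2, "reads"), "NTC1", annot, tax)
  expect_true("oC" %in% colnames(res2$counts))       # minor carry-over kept

  # family-level blacklist removes descendants wherever detected
  res3 <- remove_contaminants(x, "NTC1", annot, tax, blacklist = "Labridae")
  expect_false("oB" %in% colnames(res3$counts))
  expect_true(any(res3$log$reason == "blacklisted taxon"))
})

test_that("regional pool filters run in the stated order", {
  m <- matrix(c(10L, 3L, 50L, 7L, 2L,
                 0L, 1L, 30L, 10L, 2L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"),
                              c("o_sp1", "o_sp1b", "o_class", "o_sp2",
                                "o_low")))
  annot <- data.frame(
    otu_id = c("o_sp1", "o_sp1b", "o_class", "o_sp2", "o_low"),
    taxon_id = c("Sebastes_auriculatus", "Sebastes_auriculatus",
                 "Actinopteri", "Oxyjulis_californica",
                 "Semicossyphus_pulcher"),
    rank = c("species", "species", "class", "species", "species"),
    provenance = "lca", stringsAsFactors = FALSE)
  res <- define_regional_pool(community_matrix(m, "reads"), annot, tax)
  # class-rank OTU dropped
  expect_true(any(res$log$reason == "rank above family" &
                    res$log$otu_id == "o_class"))
  # two OTUs sharing the species merged with summed counts (10+0) + (3+1)
  expect_true("Sebastes_auriculatus" %in% colnames(res$counts))
  expect_equal(sum(res$counts[, "Sebastes_auriculatus"]), 14)
  # the 4-read OTU dropped by the < 5 reads rule
  expect_true(any(res$log$otu_id == "o_low" &
                    grepl("fewer than 5", res$log$reason)))
  expect_false("Semicossyphus_pulcher" %in% colnames(res$counts))
})

test_that("hierarchical merging reproduces the four enumerated cases", {
  annot4 <- function(otus, taxa, ranks)
    data.frame(otu_id = otus, taxon_id = taxa, rank = ranks,
               provenance = "lca", stringsAsFactors = FALSE)
  # G-i: genus-rank OTU dominates -> single genus OTU with summed reads
  m <- matrix(c(120L, 40L), 1, 2,
              dimnames = list("s1", c("oG", "oS")))
  res <- hierarchical_merge(community_matrix(m, "reads"),
                            annot4(c("oG", "oS"),
                                   c("Sebastes", "Sebastes_auriculatus"),
                                   c("genus", "species")), tax)
  expect_equal(ncol(res$counts), 1)
  expect_equal(sum(res$counts), 160)
  expect_equal(res$annot$rank, "genus")

  # G-ii: species-rank OTU dominates -> genus OTU absorbed into the species
  m <- matrix(c(10L, 90L), 1, 2, dimnames = list("s1", c("oG", "oS")))
  res <- hierarchical_merge(community_matrix(m, "reads"),
                            annot4(c("oG", "oS"),
                                   c("Sebastes", "Sebastes_auriculatus"),
                                   c("genus", "species")), tax)
  expect_equal(colnames(res$counts), "oS")
  expect_equal(sum(res$counts), 100)
  expect_equal(res$annot$taxon_id, "Sebastes_auriculatus")

  # F-i: family-rank OTU dominates -> all merged to family
  m <- matrix(c(100L, 20L, 10L), 1, 3,
              dimnames = list("s1", c("oF", "oG", "oS")))
  res <- hierarchical_merge(community_matrix(m, "reads"),
                            annot4(c("oF", "oG", "oS"),
                                   c("Labridae", "Oxyjulis",
                                     "Semicossyphus_pulcher"),
                                   c("family", "genus", "species")), tax)
  expect_equal(ncol(res$counts), 1)
  expect_equal(sum(res$counts), 130)
  expect_equal(res$annot$taxon_id, "Labridae")

  # F-ii: a finer OTU dominates -> family OTU merged into it
  m <- matrix(c(5L, 50L), 1, 2, dimnames = list("s1", c("oF", "oG")))
  res <- hierarchical_merge(community_matrix(m, "reads"),
                            annot4(c("oF", "oG"),
                                   c("Sebastidae", "Sebastes"),
                                   c("family", "genus")), tax)
  expect_equal(colnames(res$counts), "oG")
  expect_equal(sum(res$counts), 55)
  expect_equal(res$annot$taxon_id, "Sebastes")
})

test_that("hierarchical merging conserves reads and is idempotent", {
  set.seed(21)
  otus <- c("o1", "o2", "o3", "o4", "o5", "o6")
  m <- matrix(rpois(12, 20), 2, 6, dimnames = list(c("s1", "s2"), otus))
  annot <- data.frame(
    otu_id = otus,
    taxon_id = c("Sebastes", "Sebastes_auriculatus", "Sebastes_mystinus",
                 "Labridae", "Oxyjulis_californica", "Semicossyphus"),
    rank = c("genus", "species", "species", "family", "species", "genus"),
    provenance = "lca", stringsAsFactors = FALSE)
  x <- community_matrix(m, "reads")
  res <- hierarchical_merge(x, annot, tax)
  expect_equal(sum(res$counts), sum(m))  # merging never creates/destroys reads
  # idempotence
  res2 <- hierarchical_merge(res$counts, res$annot, tax)
  expect_identical(unclass(res2$counts)[, ], unclass(res$counts)[, ])
  expect_equal(res2$annot$taxon_id, res$annot$taxon_id)
  expect_equal(nrow(res2$log), 0)
})

test_that("annotation runs end to end and never refines below the LCA", {
  h <- rbind(hit("o1", "Sebastes_auriculatus", 98, 400),
             hit("o1", "Sebastes_auriculatus", 98, 398),
             hit("o2", "Sebastes_auriculatus", 96, 350),
             hit("o3", "Oxyjulis_californica", 90, 250),
             hit("o4", "Sebastes_mystinus", 80, 400))
  ann <- annotate_otus(h, tax)
  expect_equal(ann$rank[ann$otu_id == "o1"], "species")
  expect_equal(ann$rank[ann$otu_id == "o2"], "genus")      # species gate fails
  expect_equal(ann$taxon_id[ann$otu_id == "o3"], "Labridae")
  expect_equal(ann$provenance[ann$otu_id == "o4"], "unassigned")
  # rank monotonicity against the raw LCA on the retained hits
  kept <- filter_hits(h)
  for (o in c("o1", "o2", "o3")) {
    lca <- weighted_lca(kept[kept$otu_id == o, ], tax)
    ri_lca <- kelpbeta:::rank_index(tax$rank[[lca]])
    ri_ann <- kelpbeta:::rank_index(ann$rank[ann$otu_id == o])
    expect_gte(ri_ann, ri_lca)
  }
})

test_that("outfmt-6 hits and taxonomy tables read from disk", {
  hp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("o1", "Sebastes_auriculatus", "98.5", "170", "2", "0",
                   "1", "170", "1", "170", "1e-70", "310", sep = "\t"), hp)
  h <- read_blast_hits(hp)
  expect_equal(h$otu_id, "o1")
  expect_equal(h$bitscore, 310)
  tp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(taxon_id = c("root", "F1"),
                                parent_id = c("", "root"),
                                rank = c("root", "family")),
                     tp, sep = "\t", row.names = FALSE, quote = FALSE)
  tt <- read_taxonomy(tp)
  expect_equal(unname(tt$depth[["F1"]]), 1L)
})
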