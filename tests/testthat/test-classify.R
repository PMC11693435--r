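toy_classify <- function(q, ann = toy_annotation()) {
  classify_category(q, assign_gene(q, ann))
}

test_that("junction chains list introns in genomic order", {
  expect_equal(junction_chain(toy_query(c(100, 300), c(200, 400))),
               tiv(200, 300))
  expect_equal(nrow(junction_chain(toy_query(100, 200))), 0L)
  expect_equal(junction_chain(toy_query(c(100, 300, 500), c(200, 400, 600))),
               tiv(c(200, 400), c(300, 500)))
})

test_that("spliced queries receive the splice-defined categories", {
  # identical chain with jittered ends -> FSM; ends never affect category
  cl <- toy_classify(toy_query(c(120, 300, 500), c(200, 400, 580)))
  expect_equal(cl$category, "FSM")
  expect_equal(cl$associated_transcript, "T1")
  # consecutive sub-run -> ISM
  cl <- toy_classify(toy_query(c(310, 500), c(400, 590)))
  expect_equal(cl$category, "ISM")
  expect_equal(cl$associated_transcript, "T1")
  # known donor paired with known acceptor never joined -> NIC
  cl <- toy_classify(toy_query(c(100, 500), c(200, 600)))
  expect_equal(cl$category, "NIC")
  expect_equal(cl$nic_subtype, "known_splicesite_combination")
  # exon spanning a reference junction with both flanks -> NIC retention
  cl <- toy_classify(toy_query(c(100, 500), c(400, 600)))
  expect_equal(cl$category, "NIC")
  expect_equal(cl$nic_subtype, "full_intron_retention")
  # novel splice site -> NNC
  cl <- toy_classify(toy_query(c(100, 330, 500), c(200, 400, 600)))
  expect_equal(cl$category, "NNC")
  expect_true(is.na(cl$associated_transcript))
  # no overlapping gene -> intergenic
  cl <- toy_classify(toy_query(c(5000, 5300), c(5200, 5400)))
  expect_equal(cl$category, "intergenic")
})

test_that("spliced queries on a single-exon gene are NNC, never intergenic", {
  cl <- toy_classify(toy_query(c(1000, 1600), c(1400, 2000)))
  expect_equal(cl$category, "NNC")
  expect_equal(cl$associated_gene, "G2")
})

test_that("monoexon queries follow the documented convention", {
  # contained in one reference exon -> ISM
  cl <- toy_classify(toy_query(310, 390))
  expect_equal(cl$category, "ISM")
  # spanning a reference junction -> NIC full intron retention
  cl <- toy_classify(toy_query(150, 350))
  expect_equal(cl$category, "NIC")
  expect_equal(cl$nic_subtype, "full_intron_retention")
  # overlapping the gene but neither contained nor spanning -> genic_other
  cl <- toy_classify(toy_query(150, 250))
  expect_equal(cl$category, "genic_other")
})

test_that("gene assignment maximises exonic overlap with recorded ties", {
  far <- gene_model(list(ref_transcript(
    "T3", "G3", "chr1", "+", tiv(c(100, 560), c(130, 600)))))
  ann <- annotation_set(list(toy_gene(), far))
  # 150 bp overlap with G1 exons beats 30 bp with G3
  q <- toy_query(c(100, 300), c(200, 350))
  g <- assign_gene(q, ann)
  expect_equal(g$gene_id, "G1")
  expect_null(assign_gene(toy_query(9000, 9100), ann))
  # exact tie -> lexicographically first, flagged
  twin_a <- gene_model(list(ref_transcript("Ta", "GA", "chr2", "+",
                                           tiv(10, 110))))
  twin_b <- gene_model(list(ref_transcript("Tb", "GB", "chr2", "+",
                                           tiv(10, 110))))
  g <- assign_gene(toy_query(20, 80, chrom = "chr2"),
                   annotation_set(list(twin_b, twin_a)))
  expect_equal(g$gene_id, "GA")
  expect_true(attr(g, "tie"))
})

test_that("canonical splice-motif filter is strand aware", {
  base <- strrep("A", 700)
  put <- function(s, at, what) {
    substr(s, at + 1, at + nchar(what)) <- what
    s
  }
  # + strand intron [200,300): GT at 200, AG at 298
  plus <- put(put(base, 200, "GT"), 298, "AG")
  genome <- Biostrings::DNAStringSet(c(chr1 = plus))
  q <- toy_query(c(100, 300), c(200, 400))
  expect_true(canonical_filter(q, genome))
  # wrong motif
  bad <- Biostrings::DNAStringSet(c(chr1 = put(put(base, 200, "CT"),
                                               298, "AC")))
  expect_false(canonical_filter(q, bad))
  # - strand: same genomic motif CT..AC reads GT..AG after revcomp
  qm <- toy_query(c(100, 300), c(200, 400), strand = "-")
  expect_true(canonical_filter(qm, bad))
  expect_false(canonical_filter(qm, genome))
  # GC..AG accepted
  gc <- Biostrings::DNAStringSet(c(chr1 = put(put(base, 200, "GC"),
                                              298, "AG")))
  expect_true(canonical_filter(q, gc))
  expect_error(canonical_filter(toy_query(c(100, 900), c(200, 950)),
                                genome), "outside genome bounds")
})

test_that("category assignment matches the exhaustive per-transcript oracle", {
  n_loci <- 0L; n_q <- 0L
  for (seed in 1:4) {
    spec <- fixture_spec(seed = 100 + seed, n_genes = 12)
    ann <- generate_annotation(spec, genome = FALSE)$annotation
    set.seed(seed)
    for (g in ann$genes) {
      n_loci <- n_loci + 1L
      for (r in 1:4) {
        q <- random_query(g, sprintf("rq%d", r))
        got <- classify_category(q, g)$category
        want <- oracle_category(q, g)
        expect_identical(got, want)
        n_q <- n_q + 1L
      }
    }
  }
  expect_gte(n_q, 150L)
})

test_that("classification is invariant under the strand-mirror transform", {
  M <- 50000000L
  for (seed in 1:2) {
    spec <- fixture_spec(seed = 200 + seed, n_genes = 8)
    ann <- generate_annotation(spec, genome = FALSE)$annotation
    set.seed(seed)
    for (g in ann$genes) {
      gm <- mirror_gene(g, M)
      for (r in 1:3) {
        q <- random_query(g)
        cl <- classify_category(q, g)
        clm <- classify_category(mirror_query(q, M), gm)
        expect_identical(clm$category, cl$category)
        expect_identical(clm$nic_subtype, cl$nic_subtype)
      }
    }
  }
})

test_that("the classification table covers every query exactly once", {
  spec <- fixture_spec(seed = 33, n_genes = 6)
  gen <- generate_annotation(spec, genome = TRUE)
  set.seed(33)
  queries <- list()
  for (g in gen$annotation$genes) {
    p <- try(plant_isoform(g, "FSM", paste0("fsm_", g$gene_id)),
             silent = TRUE)
    if (!inherits(p, "try-error")) queries[[length(queries) + 1L]] <- p$query
    queries[[length(queries) + 1L]] <- random_query(g, paste0("rq_",
                                                              g$gene_id))
  }
  res <- classify_transcripts(queries, gen$annotation)
  expect_equal(nrow(res$classification), length(queries))
  expect_setequal(res$classification$isoform,
                  vapply(queries, `[[`, "", "isoform_id"))
  expect_true(all(res$classification$structural_category %in%
                    c("FSM", "ISM", "NIC", "NNC", "intergenic",
                      "genic_other")))
  # FSM/ISM carry an associated transcript, the novel categories do not
  cls <- res$classification
  expect_true(all(!is.na(cls$associated_transcript[
    cls$structural_category %in% c("FSM", "ISM")])))
  expect_true(all(is.na(cls$associated_transcript[
    cls$structural_category %in% c("NIC", "NNC")])))
  # with a genome, the canonical flag is computed; reference-derived FSM
  # plants use canonical reference junctions
  res2 <- classify_transcripts(queries, gen$annotation,
                               genome = gen$genome,
                               drop_noncanonical = FALSE)
  fsm <- res2$classification$structural_category == "FSM"
  expect_true(all(res2$classification$canonical[fsm]))
})
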