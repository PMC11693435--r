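# Hand-built toy locus used throughout: gene G1 on chr1 (+) with
#   T1:  exons [100,200) [300,400) [500,600), CDS [150,550)
#   T1b: same exons, alternate CDS [250,550) (CDS-in-one/UTR-in-other)
# and single-exon gene G2: exon [1000,2000), CDS [1100,1900).

tiv <- isoclass:::iv

toy_T1 <- function(strand = "+") {
  ref_transcript("T1", "G1", "chr1", strand,
                 tiv(c(100, 300, 500), c(200, 400, 600)),
                 cds_span = c(150, 550))
}

toy_gene <- function(alt_cds = TRUE) {
  trs <- list(toy_T1())
  if (alt_cds)
    trs <- c(trs, list(ref_transcript(
      "T1b", "G1", "chr1", "+",
      tiv(c(100, 300, 500), c(200, 400, 600)), cds_span = c(250, 550))))
  gene_model(trs)
}

toy_single_exon_gene <- function() {
  gene_model(list(ref_transcript("T2", "G2", "chr1", "+", tiv(1000, 2000),
                                 cds_span = c(1100, 1900))))
}

toy_annotation <- function() {
  annotation_set(list(toy_gene(), toy_single_exon_gene()))
}

toy_query <- function(starts, ends, strand = "+", id = "q",
                      chrom = "chr1") {
  query_transcript(id, chrom, strand, tiv(starts, ends))
}

# --- strand-mirror transform: reflect all coordinates about M, flip strand

mirror_exons <- function(ex, M) tiv(M - ex[, 2L], M - ex[, 1L])

mirror_gene <- function(g, M) {
  gene_model(lapply(g$transcripts, function(tr) {
    ref_transcript(tr$transcript_id, tr$gene_id, tr$chrom,
                   if (tr$strand == "+") "-" else "+",
                   mirror_exons(tr$exons, M),
                   cds_span = if (is.null(tr$cds_span)) NULL
                              else c(M - tr$cds_span[2L],
                                     M - tr$cds_span[1L]))
  }))
}

mirror_query <- function(q, M) {
  query_transcript(q$isoform_id, q$chrom,
                   if (q$strand == "+") "-" else "+",
                   mirror_exons(q$exons, M))
}
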