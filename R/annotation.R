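#' Reference transcript model
#'
#' Builds a reference transcript from its exon intervals and optional CDS
#' span. All coordinates are 0-based half-open genomic positions; GTF input
#' is converted at the I/O boundary (see [read_gtf()]).
#'
#' @param transcript_id,gene_id identifiers from the annotation.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals, 0-based
#'   half-open; rows are sorted and must not overlap.
#' @param cds_span optional length-2 vector: the genomic span from
#'   translation start to stop (stop codon included), projected to the
#'   genome. Transcripts without an annotated CDS use `NULL` and contribute
#'   exonic positions labelled UTR.
#' @param biotype transcript biotype string (informational).
#' @return An object of class `ref_transcript`.
#' @export
ref_transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                           cds_span = NULL, biotype = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- iv(exons[, 1L], exons[, 2L])
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons of transcript ", transcript_id, " overlap")
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    stopifnot(length(cds_span) == 2L, cds_span[1L] < cds_span[2L])
    if (cds_span[1L] >= max(exons[, 2L]) || cds_span[2L] <= min(exons[, 1L]))
      stop("cds_span of transcript ", transcript_id,
           " lies outside the exon span")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_span = cds_span, biotype = biotype),
            class = "ref_transcript")
}

transcript_junctions <- function(tr) {
  n <- nrow(tr$exons)
  if (n < 2L) return(iv_empty())
  iv(tr$exons[-n, 2L], tr$exons[-1L, 1L])
}

# exonic CDS segments of one transcript (exons intersected with cds_span)
transcript_cds_segments <- function(tr) {
  if (is.null(tr$cds_span)) return(iv_empty())
  s <- pmax(tr$exons[, 1L], tr$cds_span[1L])
  e <- pmin(tr$exons[, 2L], tr$cds_span[2L])
  keep <- s < e
  iv(s[keep], e[keep])
}

#' Build a gene model from reference transcripts
#'
#' Derives the per-gene indices that all classification decisions consult:
#' the sets of known donor and acceptor splice sites (in transcription
#' sense), the set of known junctions (introns, in genomic orientation), the
#' exon union, the union of exonic CDS segments over transcripts, the gene
#' span, and the single-exon-gene flag.
#'
#' A junction is stored as the intron interval `[donor-side boundary,
#' acceptor-side boundary)` in genomic orientation; on the minus strand the
#' donor is the interval's end coordinate and the acceptor its start.
#'
#' @param transcripts list of [ref_transcript()] objects sharing gene_id,
#'   chrom and strand.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(transcripts) {
  if (!length(transcripts)) stop("gene_model needs at least one transcript")
  gid <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(gid) != 1L || length(chrom) != 1L || length(strand) != 1L)
    stop("transcripts of one gene must share gene_id, chrom and strand")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  transcripts <- transcripts[order(names(transcripts))]

  juncs <- iv_empty()
  exon_all <- iv_empty()
  cds_all <- iv_empty()
  for (tr in transcripts) {
    juncs <- rbind(juncs, transcript_junctions(tr))
    exon_all <- rbind(exon_all, tr$exons)
    cds_all <- rbind(cds_all, transcript_cds_segments(tr))
  }
  juncs <- unique(iv(juncs[, 1L], juncs[, 2L]))
  if (strand == "+") {
    donors <- sort(unique(juncs[, 1L])); acceptors <- sort(unique(juncs[, 2L]))
  } else {
    donors <- sort(unique(juncs[, 2L])); acceptors <- sort(unique(juncs[, 1L]))
  }
  exon_union <- iv_union(exon_all)
  structure(list(gene_id = gid, chrom = chrom, strand = strand,
                 transcripts = transcripts,
                 donors = donors, acceptors = acceptors,
                 junctions = juncs, junction_keys = iv_keys(juncs),
                 exon_union = exon_union,
                 cds_union = iv_union(cds_all),
                 span = c(min(exon_union[, 1L]), max(exon_union[, 2L])),
                 single_exon = all(vapply(transcripts,
                                          function(t) nrow(t$exons) == 1L,
                                          logical(1)))),
            class = "gene_model")
}

#' Label a genomic position relative to a gene
#'
#' Applies the multi-transcript priority rules: a position inside the exonic
#' CDS of *any* transcript of the gene is `CDS` even if it is UTR or intron
#' in another transcript; otherwise a position inside any exon is `UTR`
#' (exonic priority over intron); otherwise `intron` within the gene span,
#' and `intergenic` beyond it.
#'
#' @param gene a [gene_model()].
#' @param pos 0-based genomic coordinate on the gene's chromosome.
#' @return one of `"CDS"`, `"UTR"`, `"intron"`, `"intergenic"`.
#' @export
label_position <- function(gene, pos) {
  if (iv_contains_point(gene$cds_union, pos)) return("CDS")
  if (iv_contains_point(gene$exon_union, pos)) return("UTR")
  if (pos >= gene$span[1L] && pos < gene$span[2L]) return("intron")
  "intergenic"
}

#' Annotation set: a collection of gene models
#'
#' @param genes list of [gene_model()] objects.
#' @return object of class `annotation_set` with a chrom/strand index used
#'   by [assign_gene()].
#' @export
annotation_set <- function(genes) {
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  genes <- genes[order(names(genes))]
  idx <- data.table::data.table(
    gene_id = names(genes),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    span_start = vapply(genes, function(g) g$span[1L], integer(1)),
    span_end = vapply(genes, function(g) g$span[2L], integer(1)))
  structure(list(genes = genes, index = idx), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$genes), "genes,",
      sum(vapply(x$genes, function(g) length(g$transcripts), integer(1))),
      "transcripts\n")
  invisible(x)
}

#' Read a GENCODE-dialect GTF into gene models
#'
#' Parses exon, CDS and stop_codon feature lines (via rtracklayer), converts
#' 1-based inclusive GTF coordinates to the package's 0-based half-open
#' convention, merges stop_codon lines into the CDS span, and groups
#' transcripts into [gene_model()]s. Transcripts whose exons mix strands or
#' chromosomes are rejected with a warning.
#'
#' @param path GTF file path.
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", path,
                                          "': ", conditionMessage(e)))
  ft <- as.character(gr$type)
  keep <- ft %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]; ft <- ft[keep]
  if (!length(gr)) stop("no exon/CDS records in ", path)
  df <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = ft,
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    biotype = if ("transcript_type" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$transcript_type) else NA_character_)
  if (anyNA(df$gene_id) || anyNA(df$transcript_id))
    stop("GTF records missing gene_id/transcript_id attributes in ", path)
  txs <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, ]
    if (length(unique(sub$strand)) != 1L || length(unique(sub$chrom)) != 1L) {
      warning("transcript ", tid, " mixes strands/chromosomes; skipped")
      next
    }
    ex <- sub[sub$type == "exon", ]
    if (!nrow(ex)) next
    cds <- sub[sub$type %in% c("CDS", "stop_codon"), ]
    cds_span <- if (nrow(cds)) c(min(cds$start), max(cds$end)) else NULL
    txs[[tid]] <- ref_transcript(
      transcript_id = tid, gene_id = ex$gene_id[1L], chrom = ex$chrom[1L],
      strand = ex$strand[1L], exons = iv(ex$start, ex$end),
      cds_span = cds_span, biotype = ex$biotype[1L])
  }
  if (!length(txs)) stop("no usable transcripts in ", path)
  by_gene <- split(txs, vapply(txs, `[[`, "", "gene_id"))
  annotation_set(lapply(by_gene, gene_model))
}

#' Write gene models to GTF
#'
#' Inverse of [read_gtf()]: emits exon and CDS lines, converting back to
#' 1-based inclusive coordinates. Round-tripping an annotation through
#' [write_gtf()] and [read_gtf()] reproduces identical exon coordinates.
#'
#' @param annotation an [annotation_set()].
#' @param path output file path.
#' @export
write_gtf <- function(annotation, path) {
  rows <- list()
  for (g in annotation$genes) {
    for (tr in g$transcripts) {
      ex <- tr$exons
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = tr$chrom, start = ex[, 1L], end = ex[, 2L],
        strand = tr$strand, type = "exon",
        gene_id = tr$gene_id, transcript_id = tr$transcript_id)
      cds <- transcript_cds_segments(tr)
      if (nrow(cds))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = tr$chrom, start = cds[, 1L], end = cds[, 2L],
          strand = tr$strand, type = "CDS",
          gene_id = tr$gene_id, transcript_id = tr$transcript_id)
    }
  }
  df <- data.table::rbindlist(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand, type = df$type,
    gene_id = df$gene_id, transcript_id = df$transcript_id)
  # phase is not consumed by read_gtf; silence the exporter's reminder
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}
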