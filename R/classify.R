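#' Query transcript (a mapped long-read isoform)
#'
#' @param isoform_id identifier of the collapsed isoform.
#' @param chrom,strand mapping location.
#' @param exons two-column matrix (start, end), 0-based half-open, sorted,
#'   non-overlapping.
#' @param sample_id optional sample of origin.
#' @return object of class `query_transcript`.
#' @export
query_transcript <- function(isoform_id, chrom, strand, exons,
                             sample_id = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- iv(exons[, 1L], exons[, 2L])
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons of query ", isoform_id, " overlap")
  structure(list(isoform_id = isoform_id, chrom = chrom, strand = strand,
                 exons = exons, sample_id = sample_id),
            class = "query_transcript")
}

#' Junction chain of a query transcript
#'
#' @param q a [query_transcript()].
#' @return two-column matrix of intron intervals in genomic order; zero rows
#'   for a monoexon query.
#' @export
junction_chain <- function(q) {
  n <- nrow(q$exons)
  if (n < 2L) return(iv_empty())
  iv(q$exons[-n, 2L], q$exons[-1L, 1L])
}

#' Assign a query transcript to a gene
#'
#' Returns the same-strand gene with maximal exonic base overlap with the
#' query; `NULL` if no query exon overlaps any gene's span. Ties are broken
#' by the number of shared splice sites, then lexicographic gene_id; a tie
#' is recorded in the `"tie"` attribute of the result.
#'
#' @param q a [query_transcript()].
#' @param annotation an [annotation_set()].
#' @return a [gene_model()] or `NULL`.
#' @export
assign_gene <- function(q, annotation) {
  idx <- annotation$index
  cand <- idx[idx$chrom == q$chrom & idx$strand == q$strand, ]
  if (!nrow(cand)) return(NULL)
  # keep genes whose span overlaps at least one query exon
  hits <- vapply(seq_len(nrow(cand)), function(i) {
    any(q$exons[, 1L] < cand$span_end[i] & q$exons[, 2L] > cand$span_start[i])
  }, logical(1))
  cand <- cand[hits, ]
  if (!nrow(cand)) return(NULL)
  jq <- junction_chain(q)
  qsites <- if (q$strand == "+") list(d = jq[, 1L], a = jq[, 2L])
            else list(d = jq[, 2L], a = jq[, 1L])
  score <- t(vapply(cand$gene_id, function(gid) {
    g <- annotation$genes[[gid]]
    c(iv_overlap(q$exons, g$exon_union),
      sum(qsites$d %in% g$donors) + sum(qsites$a %in% g$acceptors))
  }, numeric(2)))
  ord <- order(-score[, 1L], -score[, 2L], cand$gene_id)
  best <- ord[1L]
  tie <- length(ord) > 1L &&
    all(score[ord[2L], ] == score[best, ])
  g <- annotation$genes[[cand$gene_id[best]]]
  attr(g, "tie") <- tie
  g
}

.empty_class <- function(isoform_id) {
  list(isoform_id = isoform_id, category = NA_character_,
       associated_gene = NA_character_, associated_transcript = NA_character_,
       nic_subtype = NA_character_, nnc_features = NULL, canonical = NA)
}

# is chain `sub` a consecutive sub-run of chain `full` (both key vectors)?
.is_subrun <- function(sub, full) {
  p <- length(sub); m <- length(full)
  if (p == 0L || p > m) return(FALSE)
  for (i in seq_len(m - p + 1L))
    if (all(full[i:(i + p - 1L)] == sub)) return(TRUE)
  FALSE
}

#' Structural category of a query transcript
#'
#' Assigns one of the SQANTI-style structural categories by comparing the
#' query's splice-junction chain with the assigned gene's reference
#' transcripts. Transcript end positions never affect the category (they
#' vary with reverse-transcription truncation); the categories are entirely
#' splice-defined:
#'
#' * **FSM** - junction chain identical to a reference transcript's chain;
#' * **ISM** - chain is a consecutive sub-run of a reference chain;
#' * **NIC** - every splice site known to the gene, with subtype
#'   `full_intron_retention` (a query exon fully spans a reference junction
#'   together with both flanking exons), `known_junction_combination`
#'   (every junction known, chain novel), or
#'   `known_splicesite_combination` (a junction pairs known sites not
#'   joined in any reference transcript) - checked in that order;
#' * **NNC** - at least one splice site absent from the gene's donor or
#'   acceptor set.
#'
#' Spliced queries on a single-exon gene have no known sites to match and
#' fall through to NNC - never intergenic. Monoexon queries use a
#' documented convention: ISM if contained in a single reference exon, NIC
#' `full_intron_retention` if fully spanning a reference junction, else
#' `genic_other`. Queries with no assignable gene are `intergenic`.
#'
#' @param q a [query_transcript()].
#' @param gene the assigned [gene_model()], or `NULL`.
#' @return a list with elements `isoform_id`, `category`, `associated_gene`,
#'   `associated_transcript`, `nic_subtype`, `nnc_features` (filled by
#'   [annotate_nnc()] at the pipeline level), `canonical`.
#' @export
classify_category <- function(q, gene) {
  out <- .empty_class(q$isoform_id)
  n_ex <- nrow(q$exons)
  if (is.null(gene)) {
    out$category <- "intergenic"
    return(out)
  }
  out$associated_gene <- gene$gene_id
  if (n_ex == 1L) return(.classify_monoexon(q, gene, out))

  jq <- junction_chain(q)
  kq <- iv_keys(jq)
  # FSM: identical chain (transcripts pre-sorted by id for determinism)
  for (tr in gene$transcripts) {
    kt <- iv_keys(transcript_junctions(tr))
    if (length(kt) == length(kq) && all(kt == kq)) {
      out$category <- "FSM"; out$associated_transcript <- tr$transcript_id
      return(out)
    }
  }
  donors_q <- if (q$strand == "+") jq[, 1L] else jq[, 2L]
  accs_q <- if (q$strand == "+") jq[, 2L] else jq[, 1L]
  all_known <- all(donors_q %in% gene$donors) && all(accs_q %in% gene$acceptors)
  spans_junc <- nrow(gene$junctions) > 0L &&
    any(vapply(seq_len(n_ex), function(i) {
      any(q$exons[i, 1L] < gene$junctions[, 1L] &
          q$exons[i, 2L] > gene$junctions[, 2L])
    }, logical(1)))
  # full intron retention outranks ISM: a truncated (ISM) read never spans
  # a reference junction, so a sub-run chain with a junction-spanning exon
  # is a retention event, not a truncation
  if (all_known && spans_junc) {
    out$category <- "NIC"; out$nic_subtype <- "full_intron_retention"
    return(out)
  }
  # ISM: consecutive sub-run of one reference chain
  for (tr in gene$transcripts) {
    kt <- iv_keys(transcript_junctions(tr))
    if (.is_subrun(kq, kt)) {
      out$category <- "ISM"; out$associated_transcript <- tr$transcript_id
      return(out)
    }
  }
  if (all_known) {
    out$category <- "NIC"
    out$nic_subtype <-
      if (all(kq %in% gene$junction_keys)) "known_junction_combination"
      else "known_splicesite_combination"
    return(out)
  }
  out$category <- "NNC"
  out
}

.classify_monoexon <- function(q, gene, out) {
  e <- q$exons[1L, ]
  for (tr in gene$transcripts) {
    if (iv_contains_interval(tr$exons, e[1L], e[2L])) {
      out$category <- "ISM"
      out$associated_transcript <- tr$transcript_id
      return(out)
    }
  }
  if (nrow(gene$junctions) > 0L &&
      any(e[1L] < gene$junctions[, 1L] & e[2L] > gene$junctions[, 2L])) {
    out$category <- "NIC"; out$nic_subtype <- "full_intron_retention"
    return(out)
  }
  out$category <- "genic_other"
  out
}

#' Canonical splice-motif check
#'
#' A query is canonical iff every junction's intron-terminal dinucleotides,
#' read in transcription sense, are one of GT..AG, GC..AG or AT..AC. The
#' classification pipeline can drop non-canonical isoforms when a genome is
#' supplied (mirroring the removal of isoforms with noncanonical splice
#' sites before downstream analysis).
#'
#' @param q a [query_transcript()].
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome.
#' @return logical flag.
#' @export
canonical_filter <- function(q, genome) {
  jq <- junction_chain(q)
  if (!nrow(jq)) return(TRUE)
  if (!q$chrom %in% names(genome))
    stop("chromosome ", q$chrom, " of isoform ", q$isoform_id,
         " absent from genome")
  seq <- genome[[q$chrom]]
  if (max(jq[, 2L]) > length(seq))
    stop("junction of isoform ", q$isoform_id, " outside genome bounds")
  ok <- vapply(seq_len(nrow(jq)), function(i) {
    intron <- Biostrings::subseq(seq, jq[i, 1L] + 1L, jq[i, 2L])
    if (q$strand == "-") intron <- Biostrings::reverseComplement(intron)
    motif <- paste0(as.character(Biostrings::subseq(intron, 1L, 2L)),
                    as.character(Biostrings::subseq(intron,
                                                    length(intron) - 1L,
                                                    length(intron))))
    motif %in% c("GTAG", "GCAG", "ATAC")
  }, logical(1))
  all(ok)
}

#' Classify a set of query transcripts
#'
#' Runs gene assignment, structural categorisation, NNC feature annotation
#' and (optionally) the canonical splice-motif filter over a list of query
#' transcripts, producing the classification table and the per-junction
#' feature table.
#'
#' @param queries list of [query_transcript()] objects.
#' @param annotation an [annotation_set()].
#' @param genome optional [Biostrings::DNAStringSet]; when supplied, the
#'   canonical flag is computed and (with `drop_noncanonical = TRUE`)
#'   non-canonical isoforms are removed.
#' @param drop_noncanonical drop isoforms failing [canonical_filter()].
#' @return object of class `isoclass_result`: a list with `classification`
#'   (one data.table row per isoform: isoform, chrom, strand, length, exons,
#'   structural_category, associated_gene, associated_transcript,
#'   subcategory, canonical) and `features` (data.table isoform x feature x
#'   interval for NNC isoforms).
#' @export
classify_transcripts <- function(queries, annotation, genome = NULL,
                                 drop_noncanonical = !is.null(genome)) {
  empty_cls <- data.table::data.table(
    isoform = character(0), chrom = character(0), strand = character(0),
    length = integer(0), exons = integer(0),
    structural_category = character(0), associated_gene = character(0),
    associated_transcript = character(0), subcategory = character(0),
    canonical = logical(0))
  rows <- vector("list", length(queries))
  feat_rows <- list()
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    gene <- assign_gene(q, annotation)
    cl <- classify_category(q, gene)
    canonical <- if (!is.null(genome)) canonical_filter(q, genome) else NA
    sub <- NA_character_
    if (identical(cl$category, "NIC")) sub <- cl$nic_subtype
    if (identical(cl$category, "NNC")) {
      ft <- annotate_nnc(q, gene)
      sub <- paste(ft$feature, collapse = ";")
      if (nrow(ft))
        feat_rows[[length(feat_rows) + 1L]] <-
          data.table::data.table(isoform = q$isoform_id, ft)
    }
    rows[[i]] <- data.table::data.table(
      isoform = q$isoform_id, chrom = q$chrom, strand = q$strand,
      length = iv_width(q$exons), exons = nrow(q$exons),
      structural_category = cl$category,
      associated_gene = cl$associated_gene,
      associated_transcript = cl$associated_transcript,
      subcategory = sub, canonical = canonical)
  }
  cls <- if (length(rows)) data.table::rbindlist(rows) else empty_cls
  feats <- if (length(feat_rows)) data.table::rbindlist(feat_rows)
           else data.table::data.table(isoform = character(0),
                                       feature = character(0),
                                       start = integer(0), end = integer(0))
  if (drop_noncanonical && !is.null(genome)) {
    dropped <- cls$isoform[!cls$canonical]
    if (length(dropped))
      message(length(dropped), " isoform(s) removed by canonical filter")
    cls <- cls[cls$canonical %in% TRUE, ]
    feats <- feats[feats$isoform %in% cls$isoform, ]
  }
  structure(list(classification = cls, features = feats),
            class = "isoclass_result")
}

#' @export
print.isoclass_result <- function(x, ...) {
  tab <- table(x$classification$structural_category)
  cat("isoclass_result:", nrow(x$classification), "isoforms (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
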