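#' The seven novel-junction features of NNC isoforms
#'
#' @return character vector of the seven feature labels.
#' @export
nnc_feature_values <- function() {
  c("alt3_junction", "alt5_junction", "cds_cds_junction",
    "cds_utr_junction", "utr_utr_junction", "partial_intron_retention",
    "novel_exon")
}

#' The intra-exonic junction roll-up
#'
#' CDS_CDS, CDS_UTR and UTR_UTR junctions - junctions whose two novel splice
#' sites both fall in reference exonic sequence - are collectively
#' intra-exonic junctions (IEJs); an IEJ confined to one coding exon is an
#' exitron.
#'
#' @return character vector of the three IEJ feature labels.
#' @export
intra_exonic_features <- function() {
  c("cds_cds_junction", "cds_utr_junction", "utr_utr_junction")
}

#' Call one splice site against a gene model
#'
#' A site is known iff its boundary coordinate is in the gene's donor
#' (side = "donor") or acceptor (side = "acceptor") set, in transcription
#' sense. Novel sites carry their [label_position()] location, used by the
#' feature rules (CDS priority over UTR, exonic priority over intron are
#' baked into the label).
#'
#' @param gene a [gene_model()].
#' @param pos boundary coordinate of the site (intron edge).
#' @param side `"donor"` or `"acceptor"`.
#' @return list with `pos`, `side`, `known`, and `location` (`NA` when
#'   known).
#' @export
call_splice_site <- function(gene, pos, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  known <- if (side == "donor") pos %in% gene$donors else pos %in% gene$acceptors
  list(pos = pos, side = side, known = known,
       location = if (known) NA_character_ else label_position(gene, pos))
}

#' Annotate an NNC isoform with novel-junction features
#'
#' Implements the seven-feature taxonomy for novel-not-in-catalog isoforms.
#' Novel exons are detected first: an internal query exon whose two boundary
#' splice sites are both novel and intronic, and which overlaps no reference
#' exon of the gene, emits `novel_exon` and consumes both flanking
#' junctions. Each remaining junction carrying at least one novel site then
#' emits exactly one feature:
#'
#' * known donor + novel exonic acceptor -> `alt3_junction` (the acceptor
#'   exon is truncated);
#' * novel exonic donor + known acceptor -> `alt5_junction`;
#' * two novel exonic sites -> `cds_cds_junction` / `cds_utr_junction` /
#'   `utr_utr_junction` by the two location labels (an intra-exonic
#'   junction; within a single coding exon this is an exitron);
#' * exactly one novel site located in an intron, with the query exon
#'   bearing it overlapping a reference exon -> `partial_intron_retention`;
#' * any other pattern (novel intergenic site, mixed novel intronic +
#'   novel exonic sites, ...) -> `complex`, surfaced rather than guessed.
#'
#' Multiple features can be present in a single isoform; features are
#' returned in genomic-coordinate order. Distinct (junction, feature) pairs
#' are reported, so a feature occurring twice is listed twice.
#'
#' @param q a [query_transcript()] classified as NNC against `gene`.
#' @param gene the assigned [gene_model()].
#' @return data.table with columns `feature`, `start`, `end` (the junction
#'   interval, or the exon interval for `novel_exon`).
#' @export
annotate_nnc <- function(q, gene) {
  cl <- classify_category(q, gene)
  if (!identical(cl$category, "NNC"))
    stop("annotate_nnc() called on a non-NNC isoform (", q$isoform_id,
         " is ", cl$category, ")")
  jq <- junction_chain(q)
  k <- nrow(jq)
  n_ex <- nrow(q$exons)
  # roles of genomic junction boundaries by strand
  left_side <- if (q$strand == "+") "donor" else "acceptor"
  right_side <- if (q$strand == "+") "acceptor" else "donor"
  calls_l <- lapply(seq_len(k), function(i)
    call_splice_site(gene, jq[i, 1L], left_side))
  calls_r <- lapply(seq_len(k), function(i)
    call_splice_site(gene, jq[i, 2L], right_side))

  consumed <- logical(k)
  feats <- list()
  add <- function(feature, start, end)
    feats[[length(feats) + 1L]] <<-
      data.table::data.table(feature = feature,
                             start = as.integer(start), end = as.integer(end))

  # pass 1: novel exons (consume both flanking junctions)
  if (n_ex >= 3L) {
    for (x in 2:(n_ex - 1L)) {
      a <- calls_r[[x - 1L]]  # site at exon start
      d <- calls_l[[x]]       # site at exon end
      if (!a$known && !d$known &&
          identical(a$location, "intron") && identical(d$location, "intron") &&
          iv_overlap(q$exons[x, , drop = FALSE], gene$exon_union) == 0L) {
        add("novel_exon", q$exons[x, 1L], q$exons[x, 2L])
        consumed[x - 1L] <- TRUE
        consumed[x] <- TRUE
      }
    }
  }

  exonic <- function(cc) !cc$known && cc$location %in% c("CDS", "UTR")
  # pass 2: per-junction labels
  for (i in seq_len(k)) {
    if (consumed[i]) next
    L <- calls_l[[i]]; R <- calls_r[[i]]
    if (L$known && R$known) next
    don <- if (q$strand == "+") L else R
    acc <- if (q$strand == "+") R else L
    if (don$known && exonic(acc)) {
      add("alt3_junction", jq[i, 1L], jq[i, 2L])
    } else if (exonic(don) && acc$known) {
      add("alt5_junction", jq[i, 1L], jq[i, 2L])
    } else if (exonic(don) && exonic(acc)) {
      labs <- sort(c(don$location, acc$location))
      feature <- if (all(labs == "CDS")) "cds_cds_junction"
                 else if (all(labs == "UTR")) "utr_utr_junction"
                 else "cds_utr_junction"
      add(feature, jq[i, 1L], jq[i, 2L])
    } else {
      novel_intronic_l <- !L$known && identical(L$location, "intron")
      novel_intronic_r <- !R$known && identical(R$location, "intron")
      if (xor(novel_intronic_l, novel_intronic_r) &&
          (L$known || R$known)) {
        # the exon bearing the novel intronic site extends into the intron;
        # require it to overlap reference exonic sequence
        bearing <- if (novel_intronic_l) i else i + 1L
        if (iv_overlap(q$exons[bearing, , drop = FALSE],
                       gene$exon_union) > 0L) {
          add("partial_intron_retention", jq[i, 1L], jq[i, 2L])
        } else {
          add("complex", jq[i, 1L], jq[i, 2L])
        }
      } else {
        add("complex", jq[i, 1L], jq[i, 2L])
      }
    }
  }
  out <- if (length(feats)) data.table::rbindlist(feats)
         else data.table::data.table(feature = character(0),
                                     start = integer(0), end = integer(0))
  out[order(out$start, out$end), ]
}

#' Count NNC features per group, by transcripts and by reads
#'
#' Tabulates feature occurrences from a classification result, optionally
#' weighted by read counts from a [count_tensor()]. An isoform carrying k
#' features contributes to k rows; distinct (junction, feature) pairs count
#' separately.
#'
#' @param result an `isoclass_result` from [classify_transcripts()].
#' @param tensor optional [count_tensor()] supplying read counts; without it
#'   read counts are reported as the number of contributing isoforms.
#' @param group_by grouping column: `"sample"`, `"group"` or `"cell_type"`
#'   (the latter two need `tensor`).
#' @return data.table with columns group, feature, n_transcripts, n_reads.
#' @export
count_features <- function(result, tensor = NULL, group_by = "sample") {
  feats <- result$features
  empty <- data.table::data.table(group = character(0), feature = character(0),
                                  n_transcripts = integer(0),
                                  n_reads = integer(0))
  if (!nrow(feats)) return(empty)
  ft <- data.table::as.data.table(feats)
  if (is.null(tensor)) {
    out <- ft[, list(n_transcripts = .N), by = "feature"]
    out <- data.table::data.table(group = "all", out,
                                  n_reads = out$n_transcripts)
    data.table::setcolorder(out, c("group", "feature", "n_transcripts",
                                   "n_reads"))
    return(out[order(out$group, out$feature), ])
  }
  counts <- data.table::as.data.table(tensor$counts)
  grp_col <- switch(group_by,
                    sample = "sample_id",
                    cell_type = "cell_type",
                    group = {
                      counts <- merge(counts, tensor$samples,
                                      by = "sample_id")
                      "group"
                    },
                    stop("unknown group_by: ", group_by))
  per <- counts[, list(n_reads = sum(n)),
                by = c("isoform_id", grp_col)]
  data.table::setnames(per, grp_col, "group")
  merged <- merge(ft, per, by.x = "isoform", by.y = "isoform_id",
                  allow.cartesian = TRUE)
  if (!nrow(merged)) return(empty)
  out <- merged[, list(n_transcripts = length(unique(paste(isoform, start, end))),
                       n_reads = sum(n_reads)),
                by = c("group", "feature")]
  out[order(out$group, out$feature), ]
}
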