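# Brute-force oracles: re-derive category, position labels and NNC features
# by exhaustive scans over every reference transcript, independently of the
# package's precomputed gene-level sets.

oracle_label <- function(transcripts, pos) {
  in_cds <- FALSE; in_exon <- FALSE
  lo <- Inf; hi <- -Inf
  for (tr in transcripts) {
    for (r in seq_len(nrow(tr$exons))) {
      s <- tr$exons[r, 1L]; e <- tr$exons[r, 2L]
      lo <- min(lo, s); hi <- max(hi, e)
      if (pos >= s && pos < e) {
        in_exon <- TRUE
        if (!is.null(tr$cds_span) && pos >= tr$cds_span[1L] &&
            pos < tr$cds_span[2L])
          in_cds <- TRUE
      }
    }
  }
  if (in_cds) "CDS"
  else if (in_exon) "UTR"
  else if (pos >= lo && pos < hi) "intron"
  else "intergenic"
}

oracle_site_known <- function(transcripts, pos, side) {
  for (tr in transcripts) {
    ex <- tr$exons; m <- nrow(ex)
    if (m < 2L) next
    for (kk in seq_len(m - 1L)) {
      a <- ex[kk, 2L]; b <- ex[kk + 1L, 1L]
      d <- if (tr$strand == "+") a else b
      ac <- if (tr$strand == "+") b else a
      if (side == "donor" && pos == d) return(TRUE)
      if (side == "acceptor" && pos == ac) return(TRUE)
    }
  }
  FALSE
}

.oracle_chain_str <- function(ex) {
  m <- nrow(ex)
  if (m < 2L) return("")
  paste0(";", paste(ex[-m, 2L], ex[-1L, 1L], sep = "-", collapse = ";"), ";")
}

oracle_category <- function(q, gene) {
  trs <- gene$transcripts
  n <- nrow(q$exons)
  if (n == 1L) {
    for (tr in trs) for (r in seq_len(nrow(tr$exons)))
      if (tr$exons[r, 1L] <= q$exons[1L, 1L] &&
          tr$exons[r, 2L] >= q$exons[1L, 2L])
        return("ISM")
    for (tr in trs) {
      ex <- tr$exons; m <- nrow(ex)
      if (m < 2L) next
      for (kk in seq_len(m - 1L))
        if (q$exons[1L, 1L] < ex[kk, 2L] && q$exons[1L, 2L] > ex[kk + 1L, 1L])
          return("NIC")
    }
    return("genic_other")
  }
  qc <- .oracle_chain_str(q$exons)
  for (tr in trs)
    if (nzchar(.oracle_chain_str(tr$exons)) &&
        .oracle_chain_str(tr$exons) == qc)
      return("FSM")
  qj <- cbind(q$exons[-n, 2L], q$exons[-1L, 1L])
  all_known <- TRUE
  for (i in seq_len(nrow(qj))) {
    dpos <- if (q$strand == "+") qj[i, 1L] else qj[i, 2L]
    apos <- if (q$strand == "+") qj[i, 2L] else qj[i, 1L]
    if (!oracle_site_known(trs, dpos, "donor") ||
        !oracle_site_known(trs, apos, "acceptor")) {
      all_known <- FALSE; break
    }
  }
  spans <- FALSE
  for (tr in trs) {
    ex <- tr$exons; m <- nrow(ex)
    if (m < 2L) next
    for (kk in seq_len(m - 1L)) for (x in seq_len(n))
      if (q$exons[x, 1L] < ex[kk, 2L] && q$exons[x, 2L] > ex[kk + 1L, 1L])
        spans <- TRUE
  }
  if (all_known && spans) return("NIC")
  for (tr in trs) {
    tc <- .oracle_chain_str(tr$exons)
    if (nzchar(tc) && grepl(qc, tc, fixed = TRUE)) return("ISM")
  }
  if (all_known) return("NIC")
  "NNC"
}

oracle_features <- function(q, gene) {
  trs <- gene$transcripts
  n <- nrow(q$exons)
  if (n < 2L) return(character(0))
  qj <- cbind(q$exons[-n, 2L], q$exons[-1L, 1L])
  k <- nrow(qj)
  overlaps_ref_exon <- function(s, e) {
    for (tr in trs) for (r in seq_len(nrow(tr$exons)))
      if (s < tr$exons[r, 2L] && e > tr$exons[r, 1L]) return(TRUE)
    FALSE
  }
  a_side <- if (q$strand == "+") "acceptor" else "donor"
  d_side <- if (q$strand == "+") "donor" else "acceptor"
  feats <- character(0)
  consumed <- rep(FALSE, k)
  if (n >= 3L) for (x in 2:(n - 1L)) {
    sa <- q$exons[x, 1L]; sd <- q$exons[x, 2L]
    if (!oracle_site_known(trs, sa, a_side) &&
        !oracle_site_known(trs, sd, d_side) &&
        oracle_label(trs, sa) == "intron" &&
        oracle_label(trs, sd) == "intron" &&
        !overlaps_ref_exon(sa, sd)) {
      feats <- c(feats, "novel_exon")
      consumed[x - 1L] <- TRUE; consumed[x] <- TRUE
    }
  }
  for (i in seq_len(k)) {
    if (consumed[i]) next
    dpos <- if (q$strand == "+") qj[i, 1L] else qj[i, 2L]
    apos <- if (q$strand == "+") qj[i, 2L] else qj[i, 1L]
    dk <- oracle_site_known(trs, dpos, "donor")
    ak <- oracle_site_known(trs, apos, "acceptor")
    if (dk && ak) next
    dl <- if (dk) NA_character_ else oracle_label(trs, dpos)
    al <- if (ak) NA_character_ else oracle_label(trs, apos)
    dexonic <- !dk && dl %in% c("CDS", "UTR")
    aexonic <- !ak && al %in% c("CDS", "UTR")
    if (dk && aexonic) feats <- c(feats, "alt3_junction")
    else if (dexonic && ak) feats <- c(feats, "alt5_junction")
    else if (dexonic && aexonic) {
      labs <- sort(c(dl, al))
      feats <- c(feats, if (all(labs == "CDS")) "cds_cds_junction"
                 else if (all(labs == "UTR")) "utr_utr_junction"
                 else "cds_utr_junction")
    } else {
      d_int <- !dk && identical(dl, "intron")
      a_int <- !ak && identical(al, "intron")
      if (xor(d_int, a_int) && (dk || ak)) {
        novel_left <- if (d_int) (q$strand == "+") else (q$strand == "-")
        bearing <- if (novel_left) i else i + 1L
        if (overlaps_ref_exon(q$exons[bearing, 1L], q$exons[bearing, 2L]))
          feats <- c(feats, "partial_intron_retention")
        else feats <- c(feats, "complex")
      } else feats <- c(feats, "complex")
    }
  }
  sort(feats)
}
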