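#' Specification for the synthetic fixture generator
#'
#' Defines the deterministic toy study the other modules are validated
#' against: a multi-gene annotation with multi-transcript genes (including
#' exon-skipping transcripts that create exon-in-one/intron-in-other and
#' CDS-in-one/UTR-in-other positions), a fraction of single-exon genes, and
#' a grouped, cell-typed molecule simulation. Group sizes default to the
#' study design (four condition groups; five control samples and three per
#' disease group).
#'
#' @param seed integer seed; the same spec + seed always produces
#'   byte-identical outputs.
#' @param n_genes number of genes.
#' @param transcripts_per_gene,exons_per_transcript length-2 inclusive
#'   ranges.
#' @param exon_len,intron_len,utr_len length-2 ranges in bp.
#' @param frac_single_exon fraction of genes with a single exon.
#' @param groups named integer vector: samples per group.
#' @param cell_types cell-type labels.
#' @param cells_per_type barcodes per cell type per sample.
#' @param molecules_per_gene molecules simulated per sample per gene.
#' @param dup_rate probability a molecule's (barcode, UMI) pair is emitted a
#'   second time (exercises deduplication).
#' @param na_rate probability a molecule carries a barcode absent from the
#'   cell-type map (reads from unassigned cell types).
#' @param switches list of planted major-isoform switches, each
#'   `list(gene=, group=, isoform=, shift=)`: in that group the isoform's
#'   expected proportion is raised by `shift`, other isoforms scaled down.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 6L,
                         transcripts_per_gene = c(2L, 3L),
                         exons_per_transcript = c(5L, 8L),
                         exon_len = c(100L, 250L),
                         intron_len = c(150L, 600L),
                         utr_len = c(60L, 120L),
                         frac_single_exon = 0.2,
                         groups = c(ND = 5L, AD = 3L, DLB = 3L, PD = 3L),
                         cell_types = c("Ex", "Inh", "Mic", "Oli",
                                        "OPC", "Ast", "End", "Per"),
                         cells_per_type = 25L,
                         molecules_per_gene = 300L,
                         dup_rate = 0.1,
                         na_rate = 0.05,
                         switches = list()) {
  stopifnot(n_genes >= 1L, frac_single_exon >= 0, frac_single_exon < 1,
            exons_per_transcript[1L] >= 4L,
            exon_len[1L] >= 80L, intron_len[1L] >= 100L,
            all(groups >= 1L))
  structure(as.list(environment()), class = "fixture_spec")
}

.rint <- function(range) {
  if (range[1L] >= range[2L]) range[1L]
  else sample(range[1L]:range[2L], 1L)
}

# one multi-transcript gene at genomic offset `at`; returns gene_model
.make_multi_gene <- function(gid, chrom, strand, at, spec) {
  n_ex <- .rint(spec$exons_per_transcript)
  elens <- vapply(seq_len(n_ex), function(i) .rint(spec$exon_len), integer(1))
  ilens <- vapply(seq_len(n_ex - 1L), function(i) .rint(spec$intron_len),
                  integer(1))
  starts <- at + cumsum(c(0L, elens[-n_ex] + ilens))
  ends <- starts + elens
  exA <- iv(starts, ends)
  utr5 <- min(.rint(spec$utr_len), elens[1L] - 30L)
  utr3 <- min(.rint(spec$utr_len), elens[n_ex] - 30L)
  cdsA <- c(starts[1L] + utr5, ends[n_ex] - utr3)
  trs <- list(ref_transcript(paste0(gid, ".t1"), gid, chrom, strand, exA,
                             cds_span = cdsA))
  n_tx <- .rint(spec$transcripts_per_gene)
  skippable <- 2:(n_ex - 1L)
  skips <- sample(skippable, min(n_tx - 1L, length(skippable)))
  for (t in seq_along(skips)) {
    k <- skips[t]
    exB <- exA[-k, , drop = FALSE]
    # alternate CDS start in this transcript's second exon: creates
    # CDS-in-one/UTR-in-other positions upstream
    cs <- exB[2L, 1L] + min(30L, exB[2L, 2L] - exB[2L, 1L] - 10L)
    cdsB <- c(cs, cdsA[2L])
    trs[[length(trs) + 1L]] <-
      ref_transcript(paste0(gid, ".t", t + 1L), gid, chrom, strand, exB,
                     cds_span = cdsB)
  }
  gene_model(trs)
}

.make_single_exon_gene <- function(gid, chrom, strand, at, spec) {
  len <- sum(vapply(1:4, function(i) .rint(spec$exon_len), integer(1)))
  utr5 <- .rint(spec$utr_len); utr3 <- .rint(spec$utr_len)
  ex <- iv(at, at + len)
  gene_model(list(ref_transcript(paste0(gid, ".t1"), gid, chrom, strand, ex,
                                 cds_span = c(at + utr5, at + len - utr3))))
}

#' Generate a deterministic toy annotation (and optional genome)
#'
#' Genes are placed along one chromosome with intergenic gaps; a configured
#' fraction are single-exon. Multi-transcript genes include exon-skipping
#' transcripts with alternate CDS starts, so the annotation always contains
#' positions that are CDS in one transcript and UTR in another, and exonic
#' in one and intronic in another. The optional genome is uniform random
#' sequence with every reference intron forced to the canonical GT..AG
#' motif (strand-aware).
#'
#' @param spec a [fixture_spec()].
#' @param genome also build the genome sequence (slower for large specs).
#' @return list with `annotation` (an [annotation_set()]) and `genome`
#'   (a [Biostrings::DNAStringSet] or `NULL`).
#' @export
generate_annotation <- function(spec, genome = TRUE) {
  set.seed(spec$seed)
  n_single <- round(spec$frac_single_exon * spec$n_genes)
  single_idx <- if (n_single > 0L) sample(spec$n_genes, n_single) else integer(0)
  genes <- vector("list", spec$n_genes)
  at <- 1000L
  chrom <- "chrS"
  for (i in seq_len(spec$n_genes)) {
    gid <- sprintf("G%03d", i)
    strand <- sample(c("+", "-"), 1L)
    genes[[i]] <- if (i %in% single_idx)
      .make_single_exon_gene(gid, chrom, strand, at, spec)
    else
      .make_multi_gene(gid, chrom, strand, at, spec)
    at <- genes[[i]]$span[2L] + .rint(c(2000L, 5000L))
  }
  ann <- annotation_set(genes)
  gen <- NULL
  if (genome) {
    len <- at + 1000L
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (g in ann$genes) {
      j <- g$junctions
      for (r in seq_len(nrow(j))) {
        a <- j[r, 1L]; b <- j[r, 2L]
        if (g$strand == "+") {
          bases[(a + 1L):(a + 2L)] <- c("G", "T")
          bases[(b - 1L):b] <- c("A", "G")
        } else {
          bases[(a + 1L):(a + 2L)] <- c("C", "T")
          bases[(b - 1L):b] <- c("A", "C")
        }
      }
    }
    gen <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(gen) <- chrom
  }
  list(annotation = ann, genome = gen)
}

.plant_fail <- function(...) stop("infeasible plant: ", ..., call. = FALSE)

# longest transcript (most exons) of a gene, deterministically
.ref_tx <- function(gene) {
  nex <- vapply(gene$transcripts, function(t) nrow(t$exons), integer(1))
  gene$transcripts[[which.max(nex)]]
}

#' Plant a query isoform with a known true label on a gene
#'
#' Constructs a minimal edit of a reference transcript whose true structural
#' category (and, for NNC targets, feature set) is known by construction.
#' Supported targets: `"FSM"`, `"ISM"`, the NIC subtypes
#' (`"full_intron_retention"`, `"known_junction_combination"`,
#' `"known_splicesite_combination"`), and the seven NNC features (a
#' character vector of several features plants a multi-feature isoform).
#' Intra-exonic targets on a single-exon gene produce the two-exon
#' single-exon-gene case. Infeasible targets (e.g. `utr_utr_junction` on a
#' gene without a long enough UTR) raise an error so the caller can pick
#' another gene.
#'
#' @param gene a [gene_model()].
#' @param target character vector: category/subtype or feature(s).
#' @param isoform_id id for the planted isoform.
#' @return list with `query` (a [query_transcript()]) and `truth`
#'   (`category`, `features`, `nic_subtype`).
#' @export
plant_isoform <- function(gene, target, isoform_id = "planted") {
  features7 <- nnc_feature_values()
  if (length(target) > 1L) {
    if (!all(target %in% features7))
      .plant_fail("multi-feature plants must all be NNC features")
    return(.plant_multi_feature(gene, target, isoform_id))
  }
  tr <- .ref_tx(gene)
  ex <- tr$exons
  n <- nrow(ex)
  mk <- function(exons, category, features = character(0),
                 nic_subtype = NA_character_) {
    list(query = query_transcript(isoform_id, gene$chrom, gene$strand,
                                  exons),
         truth = list(category = category, features = features,
                      nic_subtype = nic_subtype))
  }
  switch(target,
    FSM = {
      if (n < 2L) .plant_fail("FSM plant needs a spliced transcript")
      j <- min(15L, ex[1L, 2L] - ex[1L, 1L] - 5L,
               ex[n, 2L] - ex[n, 1L] - 5L)
      ex[1L, 1L] <- ex[1L, 1L] + j
      ex[n, 2L] <- ex[n, 2L] - j
      mk(ex, "FSM")
    },
    ISM = {
      if (n < 3L) .plant_fail("ISM plant needs >= 3 exons")
      mk(ex[2:n, , drop = FALSE], "ISM")
    },
    full_intron_retention = {
      if (n < 4L) .plant_fail("internal intron retention needs >= 4 exons")
      for (k in sample(2:(n - 2L))) {
        ex2 <- ex
        ex2[k, 2L] <- ex2[k + 1L, 2L]
        ex2 <- ex2[-(k + 1L), , drop = FALSE]
        kq <- iv_keys(iv(ex2[-nrow(ex2), 2L], ex2[-1L, 1L]))
        clash <- any(vapply(gene$transcripts, function(t)
          .is_subrun(kq, iv_keys(transcript_junctions(t))), logical(1)))
        if (!clash) return(mk(ex2, "NIC",
                              nic_subtype = "full_intron_retention"))
      }
      .plant_fail("no internal junction usable for intron retention")
    },
    known_splicesite_combination = {
      if (n < 3L) .plant_fail("exon skip needs >= 3 exons")
      for (k in sample(2:(n - 1L))) {
        key <- paste(ex[k - 1L, 2L], ex[k + 1L, 1L], sep = "-")
        if (!key %in% gene$junction_keys)
          return(mk(ex[-k, , drop = FALSE], "NIC",
                    nic_subtype = "known_splicesite_combination"))
      }
      .plant_fail("every exon skip matches a known junction")
    },
    known_junction_combination = {
      # combine the skip junctions of two different reference transcripts
      skips <- list()
      for (t in gene$transcripts) {
        kt <- iv_keys(transcript_junctions(t))
        novel <- setdiff(kt, iv_keys(transcript_junctions(tr)))
        if (length(novel) == 1L) skips[[t$transcript_id]] <- novel
      }
      if (length(skips) < 2L)
        .plant_fail("needs two transcripts skipping different exons")
      pair <- utils::head(names(skips), 2L)
      drop_exons <- integer(0)
      for (p in pair) {
        key <- as.integer(strsplit(skips[[p]], "-")[[1L]])
        drop_exons <- c(drop_exons,
                        which(ex[, 1L] > key[1L] & ex[, 2L] < key[2L]))
      }
      drop_exons <- unique(drop_exons)
      if (length(drop_exons) < 2L)
        .plant_fail("skip junctions do not bracket distinct exons")
      ex2 <- ex[-drop_exons, , drop = FALSE]
      kq <- iv_keys(iv(ex2[-nrow(ex2), 2L], ex2[-1L, 1L]))
      if (!all(kq %in% gene$junction_keys))
        .plant_fail("combined chain uses an unknown junction")
      if (any(vapply(gene$transcripts, function(t)
        .is_subrun(kq, iv_keys(transcript_junctions(t))), logical(1))))
        .plant_fail("combined chain matches a reference chain")
      mk(ex2, "NIC", nic_subtype = "known_junction_combination")
    },
    alt3_junction = .plant_site_shift(gene, tr, isoform_id, "acceptor"),
    alt5_junction = .plant_site_shift(gene, tr, isoform_id, "donor"),
    cds_cds_junction = .plant_iej(gene, tr, isoform_id, "CDS", "CDS"),
    cds_utr_junction = .plant_iej(gene, tr, isoform_id, "CDS", "UTR"),
    utr_utr_junction = .plant_iej(gene, tr, isoform_id, "UTR", "UTR"),
    partial_intron_retention = .plant_pir(gene, tr, isoform_id),
    novel_exon = .plant_novel_exon(gene, tr, isoform_id),
    .plant_fail("unknown target '", target, "'"))
}

# novel site inside an exon truncating it: alt3 (acceptor moves) or
# alt5 (donor moves); strand-aware
.plant_site_shift <- function(gene, tr, isoform_id, side) {
  ex <- tr$exons
  n <- nrow(ex)
  if (n < 2L) .plant_fail("site shift needs a spliced transcript")
  # genomic boundary that moves: acceptor = intron end on + / start on -;
  # donor the other way round
  move_right <- (side == "acceptor") == (gene$strand == "+")
  for (i in sample(seq_len(n - 1L))) {
    if (move_right) {
      # move downstream-genomic exon start rightwards into the exon
      w <- ex[i + 1L, 2L] - ex[i + 1L, 1L]
      d <- min(20L, w - 20L)
      if (d < 5L) next
      pos <- ex[i + 1L, 1L] + d
      if (pos %in% c(gene$donors, gene$acceptors)) next
      ex2 <- ex; ex2[i + 1L, 1L] <- pos
    } else {
      w <- ex[i, 2L] - ex[i, 1L]
      d <- min(20L, w - 20L)
      if (d < 5L) next
      pos <- ex[i, 2L] - d
      if (pos %in% c(gene$donors, gene$acceptors)) next
      ex2 <- ex; ex2[i, 2L] <- pos
    }
    feat <- if (side == "acceptor") "alt3_junction" else "alt5_junction"
    return(list(query = query_transcript(isoform_id, gene$chrom,
                                         gene$strand, ex2),
                truth = list(category = "NNC", features = feat,
                             nic_subtype = NA_character_)))
  }
  .plant_fail("no exon wide enough for a ", side, " shift")
}

# intra-exonic junction with site labels lab1/lab2 (may be a single-exon
# gene: the Fig-4B two-exon case)
.plant_iej <- function(gene, tr, isoform_id, lab1, lab2) {
  ex <- tr$exons
  labs <- sort(c(lab1, lab2))
  pick_region <- function(lab, exon) {
    # sub-intervals of `exon` whose positions carry label `lab`
    reg <- if (lab == "CDS") gene$cds_union else gene$exon_union
    s <- pmax(reg[, 1L], exon[1L]); e <- pmin(reg[, 2L], exon[2L])
    keep <- s < e
    reg <- iv(s[keep], e[keep])
    if (lab == "UTR") {
      # exonic minus CDS within the exon
      out_s <- integer(0); out_e <- integer(0)
      for (r in seq_len(nrow(reg))) {
        cur_s <- reg[r, 1L]
        cds <- gene$cds_union
        for (cr in seq_len(nrow(cds))) {
          cs <- max(cds[cr, 1L], reg[r, 1L]); ce <- min(cds[cr, 2L], reg[r, 2L])
          if (cs < ce) {
            if (cur_s < cs) { out_s <- c(out_s, cur_s); out_e <- c(out_e, cs) }
            cur_s <- ce
          }
        }
        if (cur_s < reg[r, 2L]) { out_s <- c(out_s, cur_s)
                                  out_e <- c(out_e, reg[r, 2L]) }
      }
      reg <- if (length(out_s)) iv(out_s, out_e) else iv_empty()
    }
    reg
  }
  for (xi in sample(nrow(ex))) {
    exon <- ex[xi, ]
    r1 <- pick_region(labs[1L], exon)
    r2 <- pick_region(labs[2L], exon)
    if (!nrow(r1) || !nrow(r2)) next
    # choose x < y, x in r1-or-r2, y in the other, margins >= 5 from edges
    cands <- list(c(1L, 2L), c(2L, 1L))
    for (ord in cands) {
      ra <- list(r1, r2)[[ord[1L]]]; rb <- list(r1, r2)[[ord[2L]]]
      for (ia in seq_len(nrow(ra))) for (ib in seq_len(nrow(rb))) {
        x_lo <- ra[ia, 1L] + 5L; x_hi <- ra[ia, 2L] - 5L
        y_lo <- rb[ib, 1L] + 5L; y_hi <- rb[ib, 2L] - 5L
        if (x_hi <= x_lo || y_hi <= y_lo) next
        if (y_hi <= x_lo + 6L) next
        x <- max(x_lo, min(x_hi - 1L, x_lo + 3L))
        y <- min(y_hi - 1L, max(y_lo, x + 8L))
        if (y <= x + 5L) next
        if (x <= exon[1L] + 2L || y >= exon[2L] - 2L) next
        if (any(c(x, y) %in% c(gene$donors, gene$acceptors))) next
        ex2 <- rbind(ex[seq_len(xi - 1L), , drop = FALSE],
                     c(exon[1L], x), c(y, exon[2L]),
                     if (xi < nrow(ex)) ex[(xi + 1L):nrow(ex), ,
                                          drop = FALSE])
        feat <- if (all(labs == "CDS")) "cds_cds_junction"
                else if (all(labs == "UTR")) "utr_utr_junction"
                else "cds_utr_junction"
        return(list(query = query_transcript(isoform_id, gene$chrom,
                                             gene$strand, iv(ex2[, 1L],
                                                             ex2[, 2L])),
                    truth = list(category = "NNC", features = feat,
                                 nic_subtype = NA_character_)))
      }
    }
  }
  .plant_fail("no exon region supports a ", lab1, "_", lab2, " junction")
}

.plant_pir <- function(gene, tr, isoform_id) {
  ex <- tr$exons
  n <- nrow(ex)
  if (n < 2L) .plant_fail("intron retention needs a spliced transcript")
  jq <- transcript_junctions(tr)
  for (i in sample(nrow(jq))) {
    ilen <- jq[i, 2L] - jq[i, 1L]
    d <- min(30L, ilen - 20L)
    if (d < 5L) next
    pos <- jq[i, 1L] + d
    if (pos %in% c(gene$donors, gene$acceptors)) next
    if (label_position(gene, pos) != "intron") next
    ex2 <- ex; ex2[i, 2L] <- pos
    return(list(query = query_transcript(isoform_id, gene$chrom,
                                         gene$strand, ex2),
                truth = list(category = "NNC",
                             features = "partial_intron_retention",
                             nic_subtype = NA_character_)))
  }
  .plant_fail("no intron wide enough for partial retention")
}

.plant_novel_exon <- function(gene, tr, isoform_id) {
  ex <- tr$exons
  if (nrow(ex) < 2L) .plant_fail("novel exon needs an intron")
  jq <- transcript_junctions(tr)
  for (i in sample(nrow(jq))) {
    ilen <- jq[i, 2L] - jq[i, 1L]
    if (ilen < 70L) next
    u <- jq[i, 1L] + 15L
    w <- min(30L, ilen - 40L)
    if (any(c(u, u + w) %in% c(gene$donors, gene$acceptors))) next
    if (iv_overlap(iv(u, u + w), gene$exon_union) > 0L) next
    if (label_position(gene, u) != "intron" ||
        label_position(gene, u + w) != "intron") next
    ex2 <- iv(c(ex[, 1L], u), c(ex[, 2L], u + w))
    return(list(query = query_transcript(isoform_id, gene$chrom,
                                         gene$strand, ex2),
                truth = list(category = "NNC", features = "novel_exon",
                             nic_subtype = NA_character_)))
  }
  .plant_fail("no intron wide enough for a novel exon")
}

.plant_multi_feature <- function(gene, targets, isoform_id) {
  # apply single-feature plants sequentially on disjoint parts of the
  # transcript; simple strategy: plant the first feature, then re-plant the
  # remaining ones on the edited exon structure when their edits are
  # disjoint from earlier ones
  tr <- .ref_tx(gene)
  cur <- list(query = query_transcript(isoform_id, gene$chrom, gene$strand,
                                       tr$exons),
              truth = list(category = "NNC", features = character(0),
                           nic_subtype = NA_character_))
  for (tg in targets) {
    fake_tr <- ref_transcript(tr$transcript_id, tr$gene_id, tr$chrom,
                              tr$strand, cur$query$exons,
                              cds_span = NULL)
    one <- switch(tg,
      alt3_junction = .plant_site_shift(gene, fake_tr, isoform_id,
                                        "acceptor"),
      alt5_junction = .plant_site_shift(gene, fake_tr, isoform_id, "donor"),
      cds_cds_junction = .plant_iej(gene, fake_tr, isoform_id, "CDS", "CDS"),
      cds_utr_junction = .plant_iej(gene, fake_tr, isoform_id, "CDS", "UTR"),
      utr_utr_junction = .plant_iej(gene, fake_tr, isoform_id, "UTR", "UTR"),
      partial_intron_retention = .plant_pir(gene, fake_tr, isoform_id),
      novel_exon = .plant_novel_exon(gene, fake_tr, isoform_id),
      .plant_fail("unsupported multi-feature target ", tg))
    cur$query <- one$query
    cur$truth$features <- c(cur$truth$features, one$truth$features)
  }
  # verify the combination still yields exactly the requested features
  got <- annotate_nnc(cur$query, gene)
  if (!identical(sort(got$feature), sort(cur$truth$features)))
    .plant_fail("multi-feature edits interfered")
  cur$truth$features <- sort(cur$truth$features)
  cur
}

#' Random query transcript for fuzz testing
#'
#' Applies 1-3 random splice edits (site shifts into exons or introns, exon
#' skips, intron retentions, novel exons, end truncations) to a random
#' reference transcript of the gene, producing queries spanning all
#' structural categories with no ground-truth label attached.
#'
#' @param gene a [gene_model()].
#' @param isoform_id id for the query.
#' @return a [query_transcript()].
#' @export
random_query <- function(gene, isoform_id = "rq") {
  tr <- gene$transcripts[[sample(length(gene$transcripts), 1L)]]
  ex <- tr$exons
  for (edit in seq_len(sample(0:3, 1L))) {
    n <- nrow(ex)
    op <- sample(c("shift", "skip", "retain", "insert", "truncate"), 1L)
    if (op == "shift" && n >= 2L) {
      i <- sample(n, 1L); side <- sample(1:2, 1L)
      delta <- sample(-40:40, 1L)
      cand <- ex
      cand[i, side] <- cand[i, side] + delta
      if (cand[i, 1L] < cand[i, 2L] &&
          (i == 1L || cand[i, 1L] > cand[i - 1L, 2L]) &&
          (i == n || cand[i, 2L] < cand[i + 1L, 1L]))
        ex <- cand
    } else if (op == "skip" && n >= 3L) {
      ex <- ex[-sample(2:(n - 1L), 1L), , drop = FALSE]
    } else if (op == "retain" && n >= 2L) {
      k <- sample(n - 1L, 1L)
      ex[k, 2L] <- ex[k + 1L, 2L]
      ex <- ex[-(k + 1L), , drop = FALSE]
    } else if (op == "insert" && n >= 2L) {
      jq <- iv(ex[-n, 2L], ex[-1L, 1L])
      i <- sample(nrow(jq), 1L)
      ilen <- jq[i, 2L] - jq[i, 1L]
      if (ilen > 60L) {
        u <- jq[i, 1L] + sample(10:(ilen - 40L), 1L)
        w <- sample(15:30, 1L)
        if (u + w < jq[i, 2L] - 5L)
          ex <- iv(c(ex[, 1L], u), c(ex[, 2L], u + w))
      }
    } else if (op == "truncate" && n >= 3L) {
      if (sample(2L, 1L) == 1L) ex <- ex[-1L, , drop = FALSE]
      else ex <- ex[-nrow(ex), , drop = FALSE]
    }
  }
  query_transcript(isoform_id, gene$chrom, gene$strand, ex)
}

#' Simulate grouped, cell-typed molecule tables
#'
#' For every sample and gene, molecule counts are drawn multinomially over
#' the gene's reference isoforms (base proportions decay geometrically with
#' isoform rank). Planted switches shift the target isoform's expected
#' proportion in the specified group, scaling the others down
#' proportionally. Each molecule carries a cell barcode drawn from the
#' sample's per-cell-type pools (or, at `na_rate`, an unmapped barcode) and
#' a unique UMI; at `dup_rate`, a duplicate record with the same
#' (barcode, UMI) is injected to exercise deduplication.
#'
#' @param spec a [fixture_spec()].
#' @param annotation an [annotation_set()] (from [generate_annotation()]).
#' @return list with `molecules`, `cell_map`, `samples` data.tables and
#'   `truth` (expected group proportions per gene, planted switches, exact
#'   injected-duplicate count).
#' @export
simulate_molecules <- function(spec, annotation) {
  set.seed(spec$seed + 1L)
  groups <- spec$groups
  samples <- data.table::data.table(
    sample_id = unlist(lapply(names(groups), function(g)
      sprintf("%s_%d", g, seq_len(groups[[g]])))),
    group = rep(names(groups), unname(groups)))
  cell_map <- data.table::rbindlist(lapply(samples$sample_id, function(s)
    data.table::data.table(
      sample_id = s,
      barcode = as.vector(vapply(spec$cell_types, function(ct)
        sprintf("BC_%s_%s_%02d", s, ct, seq_len(spec$cells_per_type)),
        character(spec$cells_per_type))),
      cell_type = rep(spec$cell_types, each = spec$cells_per_type))))

  # expected isoform proportions per gene and group
  base_props <- list(); group_props <- list()
  for (g in annotation$genes) {
    ids <- names(g$transcripts)
    p <- 0.6^(seq_along(ids) - 1L)
    p <- p / sum(p)
    names(p) <- ids
    base_props[[g$gene_id]] <- p
    gp <- lapply(names(groups), function(grp) p)
    names(gp) <- names(groups)
    group_props[[g$gene_id]] <- gp
  }
  for (sw in spec$switches) {
    p <- group_props[[sw$gene]][[sw$group]]
    if (is.null(p)) stop("switch plant names unknown gene/group")
    if (!sw$isoform %in% names(p)) stop("switch plant names unknown isoform")
    others <- setdiff(names(p), sw$isoform)
    if (sw$shift > sum(p[others]))
      stop("proportion shift of ", sw$shift, " exceeds available mass")
    p[others] <- p[others] * (1 - (p[[sw$isoform]] + sw$shift)) /
      sum(p[others])
    p[[sw$isoform]] <- 1 - sum(p[others])
    group_props[[sw$gene]][[sw$group]] <- p
  }

  recs <- list()
  umi_counter <- 0L
  n_dup <- 0L
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample_id[si]; grp <- samples$group[si]
    pool <- cell_map$barcode[cell_map$sample_id == s]
    for (g in annotation$genes) {
      p <- group_props[[g$gene_id]][[grp]]
      counts <- stats::rmultinom(1L, spec$molecules_per_gene, p)[, 1L]
      iso <- rep(names(p), counts)
      nm <- length(iso)
      if (!nm) next
      unmapped <- stats::runif(nm) < spec$na_rate
      bc <- character(nm)
      bc[!unmapped] <- sample(pool, sum(!unmapped), replace = TRUE)
      if (any(unmapped))
        bc[unmapped] <- sprintf("BCNA_%s_%06d", s,
                                umi_counter + which(unmapped))
      umi <- sprintf("U%08d", umi_counter + seq_len(nm))
      umi_counter <- umi_counter + nm
      rec <- data.table::data.table(
        read_id = sprintf("r_%s_%s_%06d", s, g$gene_id, seq_len(nm)),
        isoform_id = iso, barcode = bc, umi = umi, sample_id = s)
      dup <- stats::runif(nm) < spec$dup_rate
      if (any(dup)) {
        d <- rec[dup, ]
        flip <- stats::runif(nrow(d)) < 0.5 & length(p) > 1L
        if (any(flip))
          d$isoform_id[flip] <- vapply(d$isoform_id[flip], function(x)
            sample(setdiff(names(p), x), 1L), character(1))
        d$read_id <- paste0(d$read_id, "_dup")
        rec <- rbind(rec, d)
        n_dup <- n_dup + nrow(d)
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  molecules <- data.table::rbindlist(recs)
  truth_props <- data.table::rbindlist(lapply(names(group_props), function(gid)
    data.table::rbindlist(lapply(names(groups), function(grp) {
      p <- group_props[[gid]][[grp]]
      data.table::data.table(gene_id = gid, group = grp,
                             isoform_id = names(p), prop = unname(p))
    }))))
  list(molecules = molecules, cell_map = cell_map, samples = samples,
       truth = list(group_props = truth_props,
                    switches = spec$switches,
                    n_duplicates = n_dup))
}
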