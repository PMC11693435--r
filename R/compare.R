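#' Deduplicate molecule records and link them to cell types
#'
#' Long-read molecules are identified by their (cell barcode, UMI, sample)
#' triple; duplicated triples are counted once, keeping the first-seen
#' isoform assignment (conflicting assignments are tallied in the
#' `"dup_conflicts"` attribute). Barcodes absent from the cell-type map
#' accumulate under cell type `NA` (reads from unassigned cell types).
#'
#' @param records data.frame/data.table with columns read_id, isoform_id,
#'   barcode, umi, sample_id.
#' @param cell_map data.frame with columns sample_id, barcode, cell_type.
#' @param samples data.frame with columns sample_id, group.
#' @return a [count_tensor()].
#' @export
dedup_and_link <- function(records, cell_map, samples) {
  records <- data.table::as.data.table(records)
  cell_map <- data.table::as.data.table(cell_map)
  samples <- data.table::as.data.table(samples)
  need <- c("read_id", "isoform_id", "barcode", "umi", "sample_id")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  missing_s <- setdiff(unique(records$sample_id), unique(cell_map$sample_id))
  if (nrow(records) && length(missing_s))
    stop("sample(s) absent from cell-type map: ",
         paste(missing_s, collapse = ", "))
  key <- paste(records$sample_id, records$barcode, records$umi, sep = "\r")
  first <- !duplicated(key)
  dups <- records[!first, ]
  kept <- records[first, ]
  # conflicting isoform assignments among dropped duplicates
  conflicts <- 0L
  if (nrow(dups)) {
    first_iso <- kept$isoform_id[match(key[!first], key[first])]
    conflicts <- sum(dups$isoform_id != first_iso)
  }
  merged <- merge(kept, cell_map, by = c("sample_id", "barcode"),
                  all.x = TRUE, sort = FALSE)
  merged$cell_type[is.na(merged$cell_type)] <- NA_character_
  counts <- merged[, list(n = .N),
                   by = c("isoform_id", "sample_id", "cell_type")]
  count_tensor(counts, samples, dup_conflicts = conflicts,
               n_duplicates = nrow(dups))
}

#' Molecule count tensor
#'
#' Deduplicated molecule counts indexed by (isoform, sample, cell type),
#' with the sample-to-group map needed by all group-level comparisons.
#'
#' @param counts data.frame with columns isoform_id, sample_id, cell_type, n.
#' @param samples data.frame with columns sample_id, group.
#' @param dup_conflicts,n_duplicates bookkeeping from [dedup_and_link()].
#' @return object of class `count_tensor`.
#' @export
count_tensor <- function(counts, samples, dup_conflicts = 0L,
                         n_duplicates = 0L) {
  counts <- data.table::as.data.table(counts)
  samples <- data.table::as.data.table(samples)
  stopifnot(all(c("isoform_id", "sample_id", "cell_type", "n") %in%
                  names(counts)),
            all(c("sample_id", "group") %in% names(samples)))
  if (nrow(counts) && any(counts$n < 0))
    stop("counts must be non-negative")
  data.table::setorder(counts, isoform_id, sample_id, cell_type)
  structure(list(counts = counts, samples = samples,
                 dup_conflicts = dup_conflicts, n_duplicates = n_duplicates),
            class = "count_tensor")
}

#' @export
print.count_tensor <- function(x, ...) {
  cat("count_tensor:", sum(x$counts$n), "molecules,",
      length(unique(x$counts$isoform_id)), "isoforms,",
      nrow(x$samples), "samples\n")
  invisible(x)
}

# counts of one gene's isoforms, optionally restricted by cell type and
# structural category, as (isoform_id, sample_id, n)
.gene_counts <- function(tensor, classification, gene, cell_type = NULL,
                         restrict = NULL) {
  cls <- data.table::as.data.table(classification)
  iso <- cls$isoform[cls$associated_gene %in% gene]
  if (!is.null(restrict))
    iso <- intersect(iso, cls$isoform[cls$structural_category %in% restrict])
  cc <- tensor$counts[tensor$counts$isoform_id %in% iso, ]
  if (!is.null(cell_type)) {
    ct_filter <- cell_type
    cc <- cc[cc$cell_type %in% ct_filter, ]
  }
  if (!nrow(cc))
    return(data.table::data.table(isoform_id = character(0),
                                  sample_id = character(0), n = integer(0)))
  cc[, list(n = sum(n)), by = c("isoform_id", "sample_id")]
}

#' Per-sample isoform proportions and group means
#'
#' For each sample, the proportion of each of the gene's isoforms among the
#' sample's reads for that gene (sums to 1); samples with zero reads for
#' the gene are excluded (a zero vector is not a proportion) and listed in
#' the `"excluded_samples"` attribute. Group means are unweighted means of
#' the per-sample proportion vectors - proportions are computed per sample
#' first, then averaged within each group.
#'
#' @param tensor a [count_tensor()].
#' @param classification classification table mapping isoforms to genes.
#' @param gene gene_id.
#' @param cell_type optional cell type filter.
#' @param restrict optional structural-category filter, e.g. `"FSM"` to
#'   reproduce FSM-restricted proportion plots.
#' @return list with `per_sample` and `group_mean` data.tables (columns
#'   sample_id/group, isoform_id, prop).
#' @export
isoform_proportions <- function(tensor, classification, gene,
                                cell_type = NULL, restrict = NULL) {
  cc <- .gene_counts(tensor, classification, gene, cell_type, restrict)
  all_samples <- unique(tensor$samples$sample_id)
  if (!nrow(cc)) {
    warning("no reads for gene ", gene, " in scope")
    out <- list(per_sample = data.table::data.table(sample_id = character(0),
                                                    isoform_id = character(0),
                                                    prop = numeric(0)),
                group_mean = data.table::data.table(group = character(0),
                                                    isoform_id = character(0),
                                                    prop = numeric(0)))
    attr(out, "excluded_samples") <- all_samples
    return(out)
  }
  isoforms <- sort(unique(cc$isoform_id))
  # complete missing isoform x sample cells with zero before normalising
  grid <- data.table::CJ(isoform_id = isoforms,
                         sample_id = unique(cc$sample_id))
  cc <- merge(grid, cc, by = c("isoform_id", "sample_id"), all.x = TRUE)
  cc$n[is.na(cc$n)] <- 0L
  cc[, total := sum(n), by = "sample_id"]
  per <- cc[cc$total > 0L, ]
  per[, prop := n / total]
  per <- per[, c("sample_id", "isoform_id", "prop")]
  data.table::setorder(per, sample_id, isoform_id)
  withg <- merge(per, tensor$samples, by = "sample_id")
  gm <- withg[, list(prop = mean(prop)), by = c("group", "isoform_id")]
  data.table::setorder(gm, group, isoform_id)
  out <- list(per_sample = per, group_mean = gm)
  attr(out, "excluded_samples") <-
    setdiff(all_samples, unique(per$sample_id))
  out
}

#' Major (highest-expressed) isoform of a gene in a group
#'
#' Expression is the group mean of per-sample proportions (samples first,
#' then averaged). Ties are broken lexicographically and flagged via the
#' `"tie"` attribute.
#'
#' @inheritParams isoform_proportions
#' @param group group label.
#' @return isoform_id, or `NULL` when the group has no reads for the gene.
#' @export
major_isoform <- function(tensor, classification, gene, group,
                          cell_type = NULL, restrict = NULL) {
  pr <- suppressWarnings(
    isoform_proportions(tensor, classification, gene, cell_type, restrict))
  grp_label <- group
  gm <- pr$group_mean[pr$group_mean$group == grp_label, ]
  if (!nrow(gm)) return(NULL)
  gm <- gm[order(-gm$prop, gm$isoform_id), ]
  out <- gm$isoform_id[1L]
  attr(out, "tie") <- nrow(gm) > 1L && gm$prop[2L] == gm$prop[1L]
  out
}

#' Detect major-isoform switching between condition groups
#'
#' Major isoform switching is a gene whose highest-expressed isoform
#' differs between two conditions. One event is emitted per unordered group
#' pair whose major isoforms differ.
#'
#' @inheritParams isoform_proportions
#' @param groups groups to compare (default: all groups in the tensor).
#' @return data.table with columns gene_id, cell_type, group_a, group_b,
#'   major_iso_a, major_iso_b.
#' @export
detect_switching <- function(tensor, classification, gene, cell_type = NULL,
                             groups = NULL, restrict = NULL) {
  if (is.null(groups)) groups <- sort(unique(tensor$samples$group))
  majors <- lapply(groups, function(g)
    major_isoform(tensor, classification, gene, g, cell_type, restrict))
  names(majors) <- groups
  rows <- list()
  if (length(groups) >= 2L) {
    for (i in 1:(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      a <- majors[[i]]; b <- majors[[j]]
      if (is.null(a) || is.null(b) || identical(as.character(a),
                                                as.character(b))) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = gene,
        cell_type = if (is.null(cell_type)) NA_character_ else cell_type,
        group_a = groups[i], group_b = groups[j],
        major_iso_a = as.character(a), major_iso_b = as.character(b))
    }
  }
  if (length(rows)) data.table::rbindlist(rows)
  else data.table::data.table(gene_id = character(0), cell_type = character(0),
                              group_a = character(0), group_b = character(0),
                              major_iso_a = character(0),
                              major_iso_b = character(0))
}

#' Compare an isoform's usage between each group and a reference group
#'
#' For each non-reference group, a one-way ANOVA on the per-sample
#' proportions of the isoform (that group versus the reference group),
#' followed by Sidak's multiple-comparisons correction over the family of
#' comparisons: p_adj = 1 - (1 - p)^m with m the number of non-reference
#' groups. Groups contributing fewer than two samples with reads for the
#' gene are reported as NA.
#'
#' @inheritParams isoform_proportions
#' @param isoform isoform_id to test.
#' @param reference_group the control group every other group is compared to.
#' @param groups groups to include (default: all).
#' @return data.table with one row per comparison: group, reference, n_ref,
#'   n_grp, F, p, p_adj.
#' @export
compare_proportion <- function(tensor, classification, gene, isoform,
                               reference_group, cell_type = NULL,
                               groups = NULL, restrict = NULL) {
  pr <- suppressWarnings(
    isoform_proportions(tensor, classification, gene, cell_type, restrict))
  per <- merge(pr$per_sample, tensor$samples, by = "sample_id")
  per <- per[per$isoform_id == isoform, ]
  if (is.null(groups)) groups <- sort(unique(tensor$samples$group))
  others <- setdiff(groups, reference_group)
  m <- length(others)
  ref_vals <- per$prop[per$group == reference_group]
  rows <- lapply(others, function(g) {
    vals <- per$prop[per$group == g]
    if (length(ref_vals) < 2L || length(vals) < 2L)
      return(data.table::data.table(group = g, reference = reference_group,
                                    n_ref = length(ref_vals),
                                    n_grp = length(vals),
                                    F = NA_real_, p = NA_real_,
                                    p_adj = NA_real_))
    y <- c(ref_vals, vals)
    f <- factor(rep(c("ref", "grp"), c(length(ref_vals), length(vals))))
    if (stats::var(y) == 0) {
      # zero variance everywhere: F undefined
      return(data.table::data.table(group = g, reference = reference_group,
                                    n_ref = length(ref_vals),
                                    n_grp = length(vals),
                                    F = NA_real_, p = NA_real_,
                                    p_adj = NA_real_))
    }
    tst <- stats::oneway.test(y ~ f, var.equal = TRUE)
    p <- unname(tst$p.value)
    data.table::data.table(group = g, reference = reference_group,
                           n_ref = length(ref_vals), n_grp = length(vals),
                           F = unname(tst$statistic), p = p,
                           p_adj = sidak_adjust(p, m))
  })
  data.table::rbindlist(rows)
}

#' Sidak multiple-comparison adjustment
#'
#' @param p raw p-value(s).
#' @param m number of comparisons in the family.
#' @return adjusted p-value(s), 1 - (1 - p)^m.
#' @export
sidak_adjust <- function(p, m) 1 - (1 - p)^m

#' Read proportions per structural category
#'
#' Per grouping unit, the proportion of reads in each structural category
#' (FSM, ISM, NIC, NNC, other); proportions sum to 1 per unit. Grouping by
#' `"sample"` gives per-individual proportions; `"group_cell_type"` first
#' sums reads across the samples of each group, per cell type, before
#' normalising.
#'
#' @param tensor a [count_tensor()].
#' @param classification classification table; every counted isoform must
#'   appear in it.
#' @param group_by `"sample"`, `"group"`, or `"group_cell_type"`.
#' @return data.table with the grouping columns, category, n_reads, prop.
#' @export
category_read_proportions <- function(tensor, classification,
                                      group_by = c("sample", "group",
                                                   "group_cell_type")) {
  group_by <- match.arg(group_by)
  cls <- data.table::as.data.table(classification)
  cc <- data.table::copy(tensor$counts)
  missing_iso <- setdiff(unique(cc$isoform_id), cls$isoform)
  if (length(missing_iso))
    stop("counted isoform(s) without classification: ",
         paste(utils::head(missing_iso, 5L), collapse = ", "))
  cat_map <- cls$structural_category[match(cc$isoform_id, cls$isoform)]
  cc$category <- ifelse(cat_map %in% c("FSM", "ISM", "NIC", "NNC"),
                        cat_map, "other")
  cc <- merge(cc, tensor$samples, by = "sample_id")
  by_cols <- switch(group_by,
                    sample = "sample_id",
                    group = "group",
                    group_cell_type = c("group", "cell_type"))
  agg <- cc[, list(n_reads = sum(n)), by = c(by_cols, "category")]
  agg[, prop := n_reads / sum(n_reads), by = by_cols]
  data.table::setorderv(agg, c(by_cols, "category"))
  agg[]
}

#' Isoform membership across groups and intersection counts
#'
#' An isoform is a member of a group iff its reads summed over the group's
#' samples reach `min_reads`. Intersection counts partition the detected
#' isoforms by their exact membership pattern (the cells of an UpSet plot).
#'
#' @param tensor a [count_tensor()].
#' @param min_reads detection threshold per group (>= 1).
#' @param classification optional classification table for category
#'   filtering.
#' @param categories optional structural categories to keep (e.g. `"NIC"`).
#' @return list with `membership` (isoform x group logical table) and
#'   `intersections` (pattern, n_isoforms).
#' @export
group_intersections <- function(tensor, min_reads = 1L,
                                classification = NULL, categories = NULL) {
  stopifnot(min_reads >= 1L)
  cc <- merge(tensor$counts, tensor$samples, by = "sample_id")
  if (!is.null(categories)) {
    if (is.null(classification))
      stop("category filtering needs a classification table")
    cls <- data.table::as.data.table(classification)
    keep <- cls$isoform[cls$structural_category %in% categories]
    cc <- cc[cc$isoform_id %in% keep, ]
  }
  groups <- sort(unique(tensor$samples$group))
  per <- cc[, list(n = sum(n)), by = c("isoform_id", "group")]
  per <- per[per$n >= min_reads, ]
  if (!nrow(per))
    return(list(membership = data.table::data.table(isoform_id = character(0)),
                intersections = data.table::data.table(
                  pattern = character(0), n_isoforms = integer(0))))
  wide <- data.table::dcast(per, isoform_id ~ group,
                            value.var = "n", fill = 0L)
  for (g in groups) if (!g %in% names(wide)) wide[[g]] <- 0L
  memb <- data.table::data.table(isoform_id = wide$isoform_id)
  for (g in groups) memb[[g]] <- wide[[g]] >= min_reads
  pattern <- apply(as.matrix(memb[, groups, with = FALSE]), 1L, function(r)
    paste(groups[r], collapse = "&"))
  inter <- data.table::data.table(pattern = pattern)[
    , list(n_isoforms = .N), by = "pattern"]
  data.table::setorder(inter, pattern)
  list(membership = memb, intersections = inter)
}

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames of the 5'->3' transcript sequence for
#' ATG-to-stop open reading frames and returns the longest (length in
#' nucleotides including the stop codon; ties broken by smallest start).
#'
#' @param sequence transcript nucleotide string in transcription sense.
#' @param min_len minimum ORF length in nucleotides including the stop
#'   (default 75).
#' @return list with `start` (0-based), `end` (half-open), `frame` (0..2),
#'   `peptide`; or `NULL` when no ORF reaches `min_len`.
#' @export
longest_orf <- function(sequence, min_len = 75L) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (frame + 3L > n) next
    codons <- substring(s, starts, starts + 2L)
    open_at <- NA_integer_  # codon index of earliest ATG since last stop
    for (ci in seq_along(codons)) {
      cd <- codons[ci]
      if (is.na(open_at) && cd == "ATG") open_at <- ci
      if (!is.na(open_at) && cd %in% stops) {
        orf_start <- starts[open_at] - 1L       # 0-based
        orf_end <- starts[ci] + 2L              # half-open, includes stop
        len <- orf_end - orf_start
        if (len >= min_len &&
            (is.null(best) || len > best$len ||
             (len == best$len && orf_start < best$start))) {
          best <- list(start = orf_start, end = orf_end, frame = frame,
                       len = len)
        }
        open_at <- NA_integer_
      }
    }
  }
  if (is.null(best)) return(NULL)
  cds <- substr(s, best$start + 1L, best$end - 3L)  # strip stop codon
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  list(start = best$start, end = best$end, frame = best$frame, peptide = pep)
}
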