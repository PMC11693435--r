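# Output writers and the pipeline entry points behind the command line.

.pkg_version <- function() {
  as.character(utils::packageVersion("isoclass"))
}

# polynomial rolling hash of a string, as 8 hex digits; used to stamp
# outputs with a config fingerprint so identical (inputs, config) runs are
# recognisable
.config_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.config_header <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE)
  c(sprintf("## isoclass v%s config_hash=%s", .pkg_version(),
            .config_hash(as.character(js))),
    sprintf("## config=%s", as.character(js)))
}

#' Write a table as TSV with a tool/config header
#'
#' @param x data.frame/data.table.
#' @param path output path.
#' @param config parameter list recorded verbatim in the header.
#' @export
write_tsv_with_header <- function(x, path, config = list()) {
  writeLines(.config_header(config), path)
  suppressWarnings(
    data.table::fwrite(x, path, sep = "\t", append = TRUE,
                       col.names = TRUE, quote = FALSE))
  invisible(path)
}

#' Read a TSV written by [write_tsv_with_header()]
#'
#' @param path file path.
#' @return data.table (header comment lines skipped).
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path)
  skip <- sum(startsWith(lines, "##"))
  data.table::fread(path, sep = "\t", skip = skip, header = TRUE)
}

.category_rgb <- c(FSM = "27,158,119", ISM = "217,95,2", NIC = "117,112,179",
                   NNC = "230,171,2", intergenic = "102,102,102",
                   genic_other = "166,118,29")

#' Write query transcripts as BED12, coloured by structural category
#'
#' @param queries list of [query_transcript()] objects.
#' @param classification classification table from [classify_transcripts()].
#' @param path output path.
#' @export
write_bed12 <- function(queries, classification, path) {
  cls <- data.table::as.data.table(classification)
  rows <- vapply(queries, function(q) {
    ex <- q$exons
    cat <- cls$structural_category[match(q$isoform_id, cls$isoform)]
    rgb <- .category_rgb[[if (is.na(cat)) "genic_other" else cat]]
    chromStart <- ex[1L, 1L]
    paste(q$chrom, chromStart, ex[nrow(ex), 2L], q$isoform_id, 0L,
          q$strand, chromStart, chromStart, rgb, nrow(ex),
          paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
          paste0(paste(ex[, 1L] - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read query transcripts from BED12
#'
#' Blocks become exons; coordinates are already 0-based half-open in BED.
#'
#' @param path BED12 file path.
#' @return list of [query_transcript()] objects.
#' @export
read_bed12 <- function(path) {
  bed <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(bed), function(i) {
    blocks <- bed$blocks[[i]]
    chromStart <- GenomicRanges::start(bed)[i] - 1L
    starts <- chromStart + IRanges::start(blocks) - 1L
    ends <- chromStart + IRanges::end(blocks)
    query_transcript(bed$name[i],
                     as.character(GenomicRanges::seqnames(bed))[i],
                     as.character(GenomicRanges::strand(bed))[i],
                     iv(starts, ends))
  })
}

#' Read query transcripts from a GTF of transcript models
#'
#' @param path GTF path (exon lines with transcript_id attributes). An
#'   empty file yields an empty list with a warning.
#' @return list of [query_transcript()] objects.
#' @export
read_query_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    warning("query file ", path, " contains no transcripts")
    return(list())
  }
  ann <- read_gtf(path)
  out <- list()
  for (g in ann$genes) for (tr in g$transcripts)
    out[[length(out) + 1L]] <- query_transcript(tr$transcript_id, tr$chrom,
                                                tr$strand, tr$exons)
  out
}

#' Write query transcripts as a GTF of transcript models
#'
#' Each query becomes exon lines under its own gene_id/transcript_id
#' (the layout produced by long-read collapse pipelines).
#'
#' @param queries list of [query_transcript()] objects.
#' @param path output path.
#' @export
write_query_gtf <- function(queries, path) {
  if (!length(queries)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- data.table::rbindlist(lapply(queries, function(q)
    data.table::data.table(chrom = q$chrom, start = q$exons[, 1L],
                           end = q$exons[, 2L], strand = q$strand,
                           id = q$isoform_id)))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand, type = "exon",
    gene_id = rows$id, transcript_id = rows$id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Classification pipeline entry point
#'
#' Reads the reference annotation and the query transcript models, runs
#' [classify_transcripts()] (with the canonical splice-motif filter when a
#' genome is supplied), and writes the classification TSV, the per-junction
#' feature TSV, a BED12 track and a run-summary JSON into `out_dir`.
#'
#' @param config list with elements `annotation` (GTF path), `queries`
#'   (GTF or BED12 path), optional `genome` (FASTA), `out_dir`, and flag
#'   `canonical_filter`.
#' @return the `isoclass_result`, invisibly.
#' @export
run_classify <- function(config) {
  req <- c("annotation", "queries", "out_dir")
  if (!all(req %in% names(config)))
    stop("config must name: ", paste(req, collapse = ", "))
  if (isTRUE(config$canonical_filter) && is.null(config$genome))
    stop("canonical_filter requested but no genome supplied")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_gtf(config$annotation)
  queries <- if (grepl("\\.bed$", config$queries, ignore.case = TRUE))
    read_bed12(config$queries) else read_query_gtf(config$queries)
  genome <- if (!is.null(config$genome))
    Biostrings::readDNAStringSet(config$genome) else NULL
  if (!is.null(genome)) names(genome) <- sub(" .*", "", names(genome))
  res <- classify_transcripts(queries, ann, genome = genome,
                              drop_noncanonical =
                                isTRUE(config$canonical_filter))
  write_tsv_with_header(res$classification,
                        file.path(config$out_dir, "classification.tsv"),
                        config)
  write_tsv_with_header(res$features,
                        file.path(config$out_dir, "nnc_features.tsv"),
                        config)
  write_bed12(queries, res$classification,
              file.path(config$out_dir, "isoforms.bed"))
  summ <- as.list(table(res$classification$structural_category))
  jsonlite::write_json(list(tool = "isoclass", version = .pkg_version(),
                            n_isoforms = nrow(res$classification),
                            category_counts = summ),
                       file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("classified ", nrow(res$classification), " isoforms: ",
          paste(names(summ), unlist(summ), sep = "=", collapse = ", "))
  invisible(res)
}

#' Comparison pipeline entry point
#'
#' Loads a classification TSV plus molecule/cell-type/sample TSVs, builds
#' the deduplicated count tensor, and writes the category-proportion,
#' per-gene isoform-proportion, switching, intersection and ANOVA tables.
#'
#' @param config list with paths `classification`, `molecules`,
#'   `cell_types`, `samples`, `out_dir`; optional `reference_group`
#'   (default first group alphabetically), `min_reads` (default 1),
#'   `fsm_restrict` (default TRUE: proportions/switching/ANOVA on
#'   FSM-classified isoforms only), `cell_type` filter.
#' @return list of the output tables, invisibly.
#' @export
run_compare <- function(config) {
  req <- c("classification", "molecules", "cell_types", "samples", "out_dir")
  if (!all(req %in% names(config)))
    stop("config must name: ", paste(req, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- read_tsv_table(config$classification)
  mols <- data.table::fread(config$molecules, sep = "\t",
                            colClasses = "character")
  cmap <- data.table::fread(config$cell_types, sep = "\t",
                            colClasses = "character")
  smp <- data.table::fread(config$samples, sep = "\t",
                           colClasses = "character")
  missing_iso <- setdiff(unique(mols$isoform_id), cls$isoform)
  if (length(missing_iso))
    stop("molecule table references isoform(s) absent from classification: ",
         paste(utils::head(missing_iso, 5L), collapse = ", "))
  tensor <- dedup_and_link(mols, cmap, smp)
  restrict <- if (isTRUE(config$fsm_restrict %||% TRUE)) "FSM" else NULL
  min_reads <- config$min_reads %||% 1L
  ref <- config$reference_group %||% sort(unique(smp$group))[1L]

  catprop <- category_read_proportions(tensor, cls, "sample")
  genes <- sort(unique(stats::na.omit(cls$associated_gene)))
  prop_rows <- list(); switch_rows <- list(); anova_rows <- list()
  for (g in genes) {
    pr <- try(suppressWarnings(
      isoform_proportions(tensor, cls, g, cell_type = config[["cell_type"]],
                          restrict = restrict)), silent = TRUE)
    if (inherits(pr, "try-error") || !nrow(pr$group_mean)) next
    prop_rows[[g]] <- data.table::data.table(gene_id = g, pr$group_mean)
    sw <- detect_switching(tensor, cls, g, cell_type = config[["cell_type"]],
                           restrict = restrict)
    if (nrow(sw)) switch_rows[[g]] <- sw
    for (iso in unique(pr$group_mean$isoform_id)) {
      an <- compare_proportion(tensor, cls, g, iso, reference_group = ref,
                               cell_type = config[["cell_type"]],
                               restrict = restrict)
      anova_rows[[paste(g, iso)]] <-
        data.table::data.table(gene_id = g, isoform_id = iso, an)
    }
  }
  props <- data.table::rbindlist(prop_rows)
  switches <- if (length(switch_rows)) data.table::rbindlist(switch_rows)
              else data.table::data.table(gene_id = character(0))
  anova <- if (length(anova_rows)) data.table::rbindlist(anova_rows)
           else data.table::data.table(gene_id = character(0))
  inter <- group_intersections(tensor, min_reads = min_reads)

  write_tsv_with_header(catprop,
                        file.path(config$out_dir,
                                  "category_proportions.tsv"), config)
  write_tsv_with_header(props,
                        file.path(config$out_dir, "isoform_proportions.tsv"),
                        config)
  write_tsv_with_header(switches,
                        file.path(config$out_dir, "switching_events.tsv"),
                        config)
  write_tsv_with_header(anova,
                        file.path(config$out_dir, "anova_results.tsv"),
                        config)
  write_tsv_with_header(inter$membership,
                        file.path(config$out_dir,
                                  "intersection_membership.tsv"), config)
  write_tsv_with_header(inter$intersections,
                        file.path(config$out_dir, "intersection_counts.tsv"),
                        config)
  feat_counts <- if ("subcategory" %in% names(cls)) {
    fres <- .features_from_classification(cls)
    count_features(fres, tensor, group_by = "group")
  } else NULL
  if (!is.null(feat_counts))
    write_tsv_with_header(feat_counts,
                          file.path(config$out_dir, "feature_counts.tsv"),
                          config)
  invisible(list(tensor = tensor, category_proportions = catprop,
                 proportions = props, switches = switches, anova = anova,
                 intersections = inter, feature_counts = feat_counts))
}

# rebuild a minimal feature table from the semicolon-joined subcategory
# column of a classification TSV
.features_from_classification <- function(cls) {
  nnc <- cls[cls$structural_category == "NNC" & !is.na(cls$subcategory) &
               nzchar(cls$subcategory), ]
  if (!nrow(nnc))
    return(list(features = data.table::data.table(isoform = character(0),
                                                  feature = character(0),
                                                  start = integer(0),
                                                  end = integer(0))))
  feats <- data.table::rbindlist(lapply(seq_len(nrow(nnc)), function(i) {
    fs <- strsplit(nnc$subcategory[i], ";", fixed = TRUE)[[1L]]
    data.table::data.table(isoform = nnc$isoform[i], feature = fs,
                           start = seq_along(fs), end = seq_along(fs))
  }))
  list(features = feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixture-simulation pipeline entry point
#'
#' Generates the full fixture bundle for a [fixture_spec()]: annotation GTF,
#' genome FASTA, planted-isoform query GTF with its truth table, molecule /
#' cell-type / sample TSVs and the simulation truth tables.
#'
#' @param spec a [fixture_spec()] or path to a YAML file of its fields.
#' @param out_dir output directory.
#' @return list of generated objects, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    vals <- yaml::read_yaml(spec)
    known <- names(formals(fixture_spec))
    bad <- setdiff(names(vals), known)
    if (length(bad))
      stop("unknown fixture spec key(s): ", paste(bad, collapse = ", "))
    if ("groups" %in% names(vals)) vals$groups <- unlist(vals$groups)
    spec <- do.call(fixture_spec, vals)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_annotation(spec, genome = TRUE)
  write_gtf(gen$annotation, file.path(out_dir, "annotation.gtf"))
  Biostrings::writeXStringSet(gen$genome, file.path(out_dir, "genome.fa"))
  sim <- simulate_molecules(spec, gen$annotation)
  cfg <- list(seed = spec$seed, n_genes = spec$n_genes)
  data.table::fwrite(sim$molecules, file.path(out_dir, "molecules.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$cell_map, file.path(out_dir, "cell_types.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$truth$group_props,
                     file.path(out_dir, "truth_group_proportions.tsv"),
                     sep = "\t")
  jsonlite::write_json(list(n_duplicates = sim$truth$n_duplicates,
                            switches = spec$switches, config = cfg),
                       file.path(out_dir, "truth_simulation.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(annotation = gen$annotation, genome = gen$genome,
                 simulation = sim))
}
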