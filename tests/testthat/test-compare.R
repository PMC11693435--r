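simple_samples <- function(groups = c(g1 = 2L, g2 = 2L)) {
  data.table::data.table(
    sample_id = unlist(lapply(names(groups), function(g)
      paste0(g, "_s", seq_len(groups[[g]])))),
    group = rep(names(groups), unname(groups)))
}

simple_cls <- function(isoforms, gene = "G1", category = "FSM") {
  data.table::data.table(isoform = isoforms,
                         structural_category = category,
                         associated_gene = gene)
}

tensor_from_counts <- function(counts_by_sample, samples) {
  # counts_by_sample: named list sample -> named vector isoform -> count
  rows <- data.table::rbindlist(lapply(names(counts_by_sample), function(s) {
    v <- counts_by_sample[[s]]
    data.table::data.table(isoform_id = names(v), sample_id = s,
                           cell_type = "Ex", n = as.integer(v))
  }))
  count_tensor(rows[rows$n > 0L, ], samples)
}

test_that("deduplication keeps one count per (barcode, UMI, sample)", {
  recs <- data.table::data.table(
    read_id = c("r1", "r2", "r3"),
    isoform_id = c("A", "B", "A"),
    barcode = c("bc1", "bc1", "bc2"),
    umi = c("u1", "u1", "u2"),
    sample_id = "s1")
  cmap <- data.table::data.table(sample_id = "s1",
                                 barcode = c("bc1", "bc2"),
                                 cell_type = c("Ex", "Inh"))
  smp <- data.table::data.table(sample_id = "s1", group = "ND")
  t <- dedup_and_link(recs, cmap, smp)
  expect_equal(sum(t$counts$n), 2L)
  # first-seen isoform wins for the duplicated UMI; conflict logged
  expect_equal(t$counts$n[t$counts$isoform_id == "A"], c(1L, 1L))
  expect_equal(t$dup_conflicts, 1L)
  # unmapped barcode accumulates under cell type NA
  recs2 <- data.table::data.table(read_id = "r9", isoform_id = "A",
                                  barcode = "nope", umi = "u9",
                                  sample_id = "s1")
  t2 <- dedup_and_link(recs2, cmap, smp)
  expect_true(is.na(t2$counts$cell_type[1]))
  # unknown sample errors; empty stream gives an empty tensor
  expect_error(dedup_and_link(
    data.table::data.table(read_id = "r", isoform_id = "A", barcode = "b",
                           umi = "u", sample_id = "sX"), cmap, smp),
    "absent from cell-type map")
  t0 <- dedup_and_link(recs[0, ], cmap, smp)
  expect_equal(sum(t0$counts$n), 0L)
})

test_that("dedup totals equal the number of unique molecule triples", {
  spec <- fixture_spec(seed = 21, n_genes = 3, molecules_per_gene = 120L)
  gen <- generate_annotation(spec, genome = FALSE)
  sim <- simulate_molecules(spec, gen$annotation)
  t <- dedup_and_link(sim$molecules, sim$cell_map, sim$samples)
  uniq <- nrow(unique(sim$molecules[, c("sample_id", "barcode", "umi")]))
  expect_equal(sum(t$counts$n), uniq)
  expect_equal(nrow(sim$molecules) - sim$truth$n_duplicates, uniq)
})

test_that("per-sample proportions normalise to one and average by group", {
  smp <- simple_samples()
  cls <- simple_cls(c("A", "B", "C"))
  t <- tensor_from_counts(list(g1_s1 = c(A = 6, B = 2, C = 2),
                               g1_s2 = c(A = 1, B = 0, C = 0),
                               g2_s1 = c(A = 0, B = 1, C = 0)), smp)
  pr <- isoform_proportions(t, cls, "G1")
  s1 <- pr$per_sample[pr$per_sample$sample_id == "g1_s1", ]
  expect_equal(s1$prop[order(s1$isoform_id)], c(0.6, 0.2, 0.2))
  expect_equal(sum(s1$prop), 1)
  # samples (1,0,0) and (0,1,0) -> group means per group
  gm <- pr$group_mean
  g1A <- gm$prop[gm$group == "g1" & gm$isoform_id == "A"]
  expect_equal(g1A, mean(c(0.6, 1)))
  # zero-count sample excluded and reported
  expect_equal(attr(pr, "excluded_samples"), "g2_s2")
  # all proportion vectors sum to 1
  sums <- tapply(pr$per_sample$prop, pr$per_sample$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("category restriction drops other categories before normalising", {
  smp <- simple_samples(c(g1 = 1L))
  cls <- data.table::data.table(isoform = c("A", "B"),
                                structural_category = c("FSM", "NNC"),
                                associated_gene = "G1")
  t <- tensor_from_counts(list(g1_s1 = c(A = 3, B = 9)), smp)
  pr <- isoform_proportions(t, cls, "G1", restrict = "FSM")
  expect_equal(pr$per_sample$isoform_id, "A")
  expect_equal(pr$per_sample$prop, 1)
})

test_that("the major isoform is the argmax of group-mean proportions", {
  smp <- simple_samples(c(g1 = 1L))
  cls <- simple_cls(c("A", "B"))
  t <- tensor_from_counts(list(g1_s1 = c(A = 10, B = 5)), smp)
  expect_equal(as.character(major_isoform(t, cls, "G1", "g1")), "A")
  # tie broken lexicographically with a flag
  t <- tensor_from_counts(list(g1_s1 = c(A = 5, B = 5)), smp)
  m <- major_isoform(t, cls, "G1", "g1")
  expect_equal(as.character(m), "A")
  expect_true(attr(m, "tie"))
  # sample-then-average: proportions (0.6,0.4) and (0.2,0.8) -> B wins
  smp2 <- simple_samples(c(g1 = 2L))
  t <- tensor_from_counts(list(g1_s1 = c(A = 6, B = 4),
                               g1_s2 = c(A = 2, B = 8)), smp2)
  expect_equal(as.character(major_isoform(t, cls, "G1", "g1")), "B")
})

test_that("switch events appear for every group pair with different majors", {
  smp <- simple_samples(c(g1 = 1L, g2 = 1L, g3 = 1L))
  cls <- simple_cls(c("A", "B"))
  t <- tensor_from_counts(list(g1_s1 = c(A = 10, B = 5),
                               g2_s1 = c(A = 3, B = 8),
                               g3_s1 = c(A = 9, B = 1)), smp)
  sw <- detect_switching(t, cls, "G1")
  # majors: g1 A, g2 B, g3 A -> exactly two events
  expect_equal(nrow(sw), 2L)
  expect_setequal(paste(sw$group_a, sw$group_b),
                  c("g1 g2", "g2 g3"))
  # identical majors -> no event
  t2 <- tensor_from_counts(list(g1_s1 = c(A = 10), g2_s1 = c(A = 7),
                                g3_s1 = c(A = 2)), smp)
  expect_equal(nrow(detect_switching(t2, cls, "G1")), 0L)
})

test_that("switch detection equals brute-force recomputation on random tensors", {
  set.seed(55)
  cls <- simple_cls(c("A", "B", "C"))
  for (rep in 1:25) {
    smp <- simple_samples(c(g1 = 2L, g2 = 2L, g3 = 2L))
    counts <- lapply(stats::setNames(smp$sample_id, smp$sample_id),
                     function(s) stats::setNames(rpois(3, 5), c("A", "B", "C")))
    counts <- lapply(counts, function(v) { v[sample(3, 1)] <- v[sample(3, 1)] +
                                             sample(0:10, 1); v })
    keep <- vapply(counts, sum, numeric(1)) > 0
    t <- tensor_from_counts(counts[keep], smp)
    sw <- detect_switching(t, cls, "G1")
    # brute force: recompute group-mean proportions directly
    brute_major <- function(grp) {
      ss <- smp$sample_id[smp$group == grp]
      mats <- lapply(ss, function(s) {
        v <- counts[[s]]
        if (sum(v) == 0) return(NULL)
        v / sum(v)
      })
      mats <- Filter(Negate(is.null), mats)
      if (!length(mats)) return(NULL)
      mm <- colMeans(do.call(rbind, mats))
      names(sort(-mm))[1]  # lexicographic tie-break via stable sort
    }
    for (i in seq_len(nrow(sw))) {
      expect_false(identical(brute_major(sw$group_a[i]),
                             brute_major(sw$group_b[i])))
    }
    groups <- unique(smp$group)
    n_brute <- 0L
    for (a in 1:2) for (b in (a + 1):3) {
      ma <- brute_major(groups[a]); mb <- brute_major(groups[b])
      if (!is.null(ma) && !is.null(mb) && ma != mb) n_brute <- n_brute + 1L
    }
    expect_equal(nrow(sw), n_brute)
  }
})

test_that("ANOVA against the reference group applies the Sidak correction", {
  expect_equal(sidak_adjust(0.02, 3), 1 - 0.98^3)
  expect_equal(sidak_adjust(0.02, 3), 0.058808)
  smp <- simple_samples(c(ctrl = 2L, d1 = 2L, d2 = 2L))
  cls <- simple_cls(c("A", "B"))
  # identical values in every group (with within-group variance): p = 1
  t <- tensor_from_counts(list(ctrl_s1 = c(A = 5, B = 5),
                               ctrl_s2 = c(A = 6, B = 4),
                               d1_s1 = c(A = 5, B = 5),
                               d1_s2 = c(A = 6, B = 4),
                               d2_s1 = c(A = 5, B = 5),
                               d2_s2 = c(A = 6, B = 4)), smp)
  an <- compare_proportion(t, cls, "G1", "A", reference_group = "ctrl")
  expect_equal(nrow(an), 2L)
  expect_true(all(an$p > 0.99))
  # zero variance everywhere: F undefined, reported NA
  t <- tensor_from_counts(list(ctrl_s1 = c(A = 5, B = 5),
                               ctrl_s2 = c(A = 5, B = 5),
                               d1_s1 = c(A = 5, B = 5),
                               d1_s2 = c(A = 5, B = 5),
                               d2_s1 = c(A = 5, B = 5),
                               d2_s2 = c(A = 5, B = 5)), smp)
  an <- compare_proportion(t, cls, "G1", "A", reference_group = "ctrl")
  expect_true(all(is.na(an$F)))
  # a group with fewer than two samples is reported NA
  smp2 <- simple_samples(c(ctrl = 2L, d1 = 1L))
  t2 <- tensor_from_counts(list(ctrl_s1 = c(A = 5, B = 5),
                                ctrl_s2 = c(A = 2, B = 8),
                                d1_s1 = c(A = 5, B = 5)), smp2)
  an2 <- compare_proportion(t2, cls, "G1", "A", reference_group = "ctrl")
  expect_true(is.na(an2$p[an2$group == "d1"]))
})

test_that("category read proportions sum to one per grouping unit", {
  smp <- simple_samples(c(g1 = 1L))
  cls <- data.table::data.table(
    isoform = c("A", "B", "C"),
    structural_category = c("FSM", "NIC", "NNC"),
    associated_gene = "G1")
  t <- tensor_from_counts(list(g1_s1 = c(A = 6, B = 2, C = 2)), smp)
  cp <- category_read_proportions(t, cls, "sample")
  expect_equal(cp$prop[order(cp$category)],
               c(0.6, 0.2, 0.2)[order(c("FSM", "NIC", "NNC"))])
  expect_equal(sum(cp$prop), 1)
  # missing classification errors with the isoform named
  t2 <- tensor_from_counts(list(g1_s1 = c(A = 1, Z = 1)), smp)
  expect_error(category_read_proportions(t2, cls), "Z")
  # group x cell-type units sum reads across samples before normalising
  smp3 <- simple_samples(c(g1 = 2L))
  rows <- data.table::data.table(
    isoform_id = c("A", "C", "A"),
    sample_id = c("g1_s1", "g1_s1", "g1_s2"),
    cell_type = "Ex", n = c(3L, 1L, 4L))
  t3 <- count_tensor(rows, smp3)
  cp3 <- category_read_proportions(t3, cls, "group_cell_type")
  expect_equal(cp3$prop[cp3$category == "FSM"], 7 / 8)
  expect_equal(sum(cp3$prop), 1)
})

test_that("group intersections partition isoforms by membership pattern", {
  smp <- simple_samples(c(g1 = 1L, g2 = 1L))
  t <- tensor_from_counts(list(g1_s1 = c(A = 3, B = 2, D = 1),
                               g2_s1 = c(B = 4, C = 1, D = 1)), smp)
  gi <- group_intersections(t, min_reads = 1L)
  pat <- function(p) gi$intersections$n_isoforms[
    gi$intersections$pattern == p]
  expect_equal(pat("g1"), 1L)          # A
  expect_equal(pat("g1&g2"), 2L)       # B, D
  expect_equal(pat("g2"), 1L)          # C
  # partition: counts sum to the number of member isoforms
  expect_equal(sum(gi$intersections$n_isoforms), nrow(gi$membership))
  # min_reads = 2 drops isoforms with a single read everywhere
  gi2 <- group_intersections(t, min_reads = 2L)
  expect_false("C" %in% gi2$membership$isoform_id)
  expect_false("D" %in% gi2$membership$isoform_id)
  expect_true(all(c("A", "B") %in% gi2$membership$isoform_id))
})

test_that("longest-ORF selection scans all three forward frames", {
  orf <- longest_orf("ATGAAATAA", min_len = 9)
  expect_equal(orf$start, 0L)
  expect_equal(orf$end, 9L)
  expect_equal(orf$peptide, "MK")
  # longer ORF in another frame wins
  seq2 <- paste0("G", "ATG", strrep("GCA", 8), "TAA")   # 30 nt in frame 1
  seq2 <- paste0("ATGAAATAA", seq2)
  orf <- longest_orf(seq2, min_len = 9)
  expect_equal(orf$end - orf$start, 30L)
  expect_equal(orf$frame, 1L)
  expect_null(longest_orf("CCCCCCCCCCCC", min_len = 9))
  expect_null(longest_orf("ATGAAATAA", min_len = 75))
  # brute-force agreement on random sequences
  brute <- function(s, min_len) {
    best <- NULL
    n <- nchar(s)
    for (i in seq_len(n - 2)) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
          len <- j + 3 - i
          if (len >= min_len && (is.null(best) || len > best$len ||
                                 (len == best$len && i - 1 < best$start)))
            best <- list(start = i - 1, len = len)
          break
        }
        j <- j + 3
      }
    }
    best
  }
  set.seed(77)
  for (r in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    got <- longest_orf(s, min_len = 30)
    want <- brute(s, 30)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$start, want$start)
      expect_equal(got$end - got$start, want$len)
    }
  }
})
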