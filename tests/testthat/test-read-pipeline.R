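# Read pipeline: demultiplexing, UMI collapse, translation, clone
# classification under the <=1-alteration rule, tallying and conservation.

make_read <- function(barcode, umi, segs) {
  df <- data.frame(cluster_id = "r1", sample_index = barcode, umi = umi,
                   stringsAsFactors = FALSE)
  for (i in seq_along(segs)) df[[paste0("seg", i)]] <- segs[i]
  df
}

test_that("demultiplexing assigns by barcode and reports discards", {
  p <- toy_parent()
  d <- build_library(p)
  cc <- simulate_panning(planted_truth(d$clones$clone_id,
                                       d$clones$clone_id[2]),
                         depth = 100, seed = 1)
  sim <- emit_reads(cc, d, seed = 2)
  dm <- demultiplex(sim$reads, sim$index_map)
  expect_equal(sum(vapply(dm$samples, nrow, integer(1))), nrow(sim$reads))
  expect_equal(dm$n_discarded, 0L)
  expect_equal(sort(names(dm$samples)), sort(unname(sim$index_map)))

  # foreign barcode is discarded at tolerance 0, rescued at tolerance 1
  reads <- sim$reads
  bc <- names(sim$index_map)[1]
  substr(reads$sample_index[1], 1, 1) <-
    setdiff(c("A", "C", "G", "T"), substr(reads$sample_index[1], 1, 1))[1]
  dm0 <- demultiplex(reads, sim$index_map)
  expect_equal(dm0$n_discarded, 1L)
  dm1 <- demultiplex(reads, sim$index_map, max_mismatch = 1)
  expect_equal(dm1$n_discarded, 0L)

  expect_error(demultiplex(reads, stats::setNames(c("a", "b"),
                                                  c(bc, bc))),
               "duplicate barcode")
})

test_that("UMI collapse merges identical (UMI, sequence) pairs only", {
  u <- strrep("A", 14)
  r5 <- do.call(rbind, replicate(5, make_read("AABB", u, c("ATGAAA")),
                                 simplify = FALSE))
  m5 <- collapse_umis(r5)
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$n_reads, 5L)

  r2 <- rbind(make_read("AABB", u, "ATGAAA"), make_read("AABB", u, "ATGCCC"))
  expect_equal(nrow(collapse_umis(r2)), 2L)

  # geometric duplication: molecules recovered regardless of dup depth
  p <- toy_parent()
  d <- build_library(p)
  cc <- simulate_panning(planted_truth(d$clones$clone_id,
                                       d$clones$clone_id[2]),
                         depth = 300, seed = 5)
  sim <- emit_reads(cc, d, dup_mean = 3, seed = 6)
  dm <- demultiplex(sim$reads, sim$index_map)
  n_mol <- vapply(dm$samples, function(r) nrow(collapse_umis(r)),
                  integer(1))
  # UMI collisions are possible but vanishingly rare at 4^14 space
  expect_equal(unname(n_mol[colnames(cc$counts)]),
               unname(colSums(cc$counts)))
})

test_that("translation flags stop codons and non-ACGT bases", {
  p <- toy_parent()
  d <- build_library(p)
  bb_window <- window_peptide(backbone_sequence(d), p)
  ci <- p$cdr_intervals[order(p$cdr_intervals$start), ]
  segs <- mapply(function(s, e)
    reverse_translate(substring(p$aa_sequence, s + 1, e)),
    ci$start, ci$end)
  ok <- assemble_translate(make_read("AABB", strrep("A", 14), segs))
  expect_equal(ok$peptide, bb_window)

  bad_stop <- segs; substr(bad_stop[1], 1, 3) <- "TAA"
  expect_true(is.na(assemble_translate(
    make_read("AABB", strrep("A", 14), bad_stop))$peptide))

  bad_base <- segs; substr(bad_base[2], 1, 1) <- "N"
  expect_true(is.na(assemble_translate(
    make_read("AABB", strrep("A", 14), bad_base))$peptide))

  # frame_map trimming: pad a segment and trim it back
  padded <- segs; padded[1] <- paste0("GG", padded[1], "C")
  fm <- list(list(offset = 2, length = nchar(segs[1])),
             list(offset = 0, length = nchar(segs[2])))
  tr <- assemble_translate(make_read("AABB", strrep("A", 14), padded), fm)
  expect_equal(tr$peptide, bb_window)
})

test_that("classification follows the one-or-zero-alteration rule", {
  p <- toy_parent()
  d <- build_library(p)
  bb <- window_peptide(backbone_sequence(d), p)
  peps <- design_clone_window_peptides(d)
  expect_equal(classify_peptides(bb, d)$assigned, "parent")
  expect_equal(classify_peptides(bb, d)$n_alterations, 0L)

  some <- names(peps)[c(3, 12)]
  cl <- classify_peptides(unname(peps[some]), d)
  expect_equal(cl$assigned, some)
  expect_equal(cl$n_alterations, c(1L, 1L))

  # two alterations -> unassigned
  two <- bb
  substr(two, 1, 1) <- "W"; substr(two, 3, 3) <- "W"
  expect_equal(classify_peptides(two, d)$assigned, "unassigned")

  # one alteration at a site whose amino acid was excluded -> unassigned
  sites <- enumerate_sites(p, stats::setNames(list("W"),
                                              p$position_labels[1]))
  d_ex <- build_library(p, sites)
  one_w <- bb; substr(one_w, 1, 1) <- "W"
  expect_equal(classify_peptides(one_w, d_ex)$assigned, "unassigned")
  expect_equal(classify_peptides(one_w, d_ex)$n_alterations, 1L)
})

test_that("classification agrees with the exhaustive Hamming oracle", {
  p <- toy_parent()
  d <- apply_backbone(build_library(p), build_library(p)$clones$clone_id[7])
  bb <- window_peptide(backbone_sequence(d), p)
  peps <- design_clone_window_peptides(d)
  clone_peps <- peps[names(peps) != "parent"]
  set.seed(42)
  W <- nchar(bb)
  pepv <- vapply(1:1000, function(i) {
    x <- strsplit(bb, "")[[1]]
    k <- sample(0:3, 1, prob = c(0.2, 0.4, 0.25, 0.15))
    if (k > 0) {
      pos <- sample(W, k)
      x[pos] <- sample(c("A", "C", "D", "W", "Y", "K", "R"), k,
                       replace = TRUE)
    }
    paste(x, collapse = "")
  }, character(1))
  got <- classify_peptides(pepv, d)$assigned
  want <- vapply(pepv, oracle_classify, character(1),
                 backbone_pep = bb, clone_peps = clone_peps)
  expect_equal(got, unname(want))
})

test_that("tallying conserves molecules and excludes unusable ones", {
  p <- toy_parent()
  d <- build_library(p)
  # empty input -> all-zero table
  empty <- tally_clones(list(s1 = data.frame(assigned = character(0),
                                             n_alterations = integer(0))),
                        d, c(s1 = "input_library"))
  expect_true(all(empty$counts == 0L))

  cc <- simulate_panning(planted_truth(d$clones$clone_id,
                                       d$clones$clone_id[2]),
                         depth = 500, seed = 9)
  sim <- emit_reads(cc, d, error_rate = 0.01, dup_mean = 2, seed = 10)
  out <- count_reads(sim$reads, d, sim$index_map, SAMPLE_ROLES)
  qc <- out$qc
  expect_true(all(qc$assigned + qc$unassigned + qc$untranslatable +
                    qc$length_mismatch == qc$molecules))
  expect_equal(unname(colSums(out$counts)[qc$sample]), qc$assigned)
  expect_equal(attr(qc, "n_discarded"), 0L)
})

test_that("error-free synthetic reads round-trip to the source counts", {
  p <- toy_parent()
  d <- build_library(p)
  cc <- simulate_panning(planted_truth(d$clones$clone_id,
                                       d$clones$clone_id[4]),
                         depth = 800, seed = 21)
  sim <- emit_reads(cc, d, error_rate = 0, dup_mean = 2.5, seed = 22)
  out <- count_reads(sim$reads, d, sim$index_map, SAMPLE_ROLES)
  expect_identical(out$counts[rownames(cc$counts), colnames(cc$counts)],
                   cc$counts)
  # read-level counting (no UMI collapse) counts duplicates instead
  out_r <- count_reads(sim$reads, d, sim$index_map, SAMPLE_ROLES,
                       unit = "reads")
  expect_true(all(out_r$counts >= out$counts))
  expect_equal(sum(out_r$counts), nrow(sim$reads))
})

test_that("segmented reads survive a TSV round trip", {
  p <- toy_parent()
  d <- build_library(p)
  cc <- simulate_panning(planted_truth(d$clones$clone_id,
                                       d$clones$clone_id[2]),
                         depth = 50, seed = 31)
  sim <- emit_reads(cc, d, seed = 32)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_segment_tsv(sim$reads, tf)
  back <- read_segment_tsv(tf)
  expect_equal(back, sim$reads, ignore_attr = TRUE)
  out <- count_reads(back, d, sim$index_map, SAMPLE_ROLES)
  expect_identical(out$counts[rownames(cc$counts), ], cc$counts)
})
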