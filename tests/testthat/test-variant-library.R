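# Site-saturation library design: site enumeration, variant counts,
# iterative backbones, reverse translation.

test_that("site enumeration gives 19 substitutions per labeled position", {
  p <- example_parent()
  sites <- enumerate_sites(p)
  expect_equal(nrow(sites), 74L)
  expect_true(all(lengths(sites$allowed) == 19L))
  # allowed sets never contain the parent amino acid
  expect_false(any(mapply(`%in%`, sites$parent_aa, sites$allowed)))

  # per-site exclusions shrink the allowed set
  lab <- sites$site_label[1]
  excl <- sites$allowed[[1]][1:5]
  s2 <- enumerate_sites(p, stats::setNames(list(excl), lab))
  expect_equal(length(s2$allowed[[1]]), 14L)
  expect_error(enumerate_sites(p, list(nosuch = "A")), "unknown position")
})

test_that("parent with no labeled positions yields an empty site list", {
  p <- example_parent()
  p0 <- parent_scfv(p$id, p$aa_sequence, p$cdr_intervals,
                    stats::setNames(character(0), character(0)))
  expect_equal(nrow(enumerate_sites(p0)), 0L)
  d0 <- build_library(p0)
  expect_equal(d0$clones$clone_id, "parent")
})

test_that("reference configuration enumerates 1,406 variants plus parent", {
  p <- example_parent()
  d <- build_library(p)
  expect_equal(nrow(d$clones), 1407L)
  expect_equal(sum(d$clones$clone_id != "parent"), 1406L)
  expect_false(anyDuplicated(d$clones$clone_id) > 0)
})

test_that("backbone rounds remove one site each: 1,387 then 1,368 variants", {
  p <- example_parent()
  d1 <- build_library(p)
  top1 <- d1$clones$clone_id[2]
  d2 <- apply_backbone(d1, top1)
  expect_equal(d2$round_number, 2L)
  expect_equal(nrow(d2$sites), 73L)
  expect_equal(sum(d2$clones$clone_id != "parent"), 1387L)
  top2 <- d2$clones$clone_id[2]
  d3 <- apply_backbone(d2, top2)
  expect_equal(sum(d3$clones$clone_id != "parent"), 1368L)
  # cumulative backbone: two substitutions, both listed in every clone id
  expect_equal(nrow(d3$backbone), 2L)
  expect_true(all(grepl(top1, d3$clones$clone_id[-1], fixed = TRUE)))
  # applying the parent entry keeps the sites and bumps the round
  d2b <- apply_backbone(d1, "parent")
  expect_equal(d2b$round_number, 2L)
  expect_equal(d2b$sites, d1$sites)
  expect_error(apply_backbone(d1, "Z999Q"), "not in this design")
})

test_that("library size identity holds against brute-force enumeration", {
  p <- toy_parent()
  set.seed(11)
  for (rep in 1:5) {
    sites <- enumerate_sites(p)
    sites <- sites[sample(nrow(sites), 5), ]
    # random exclusions per site
    excl <- lapply(seq_len(nrow(sites)), function(i)
      sample(sites$allowed[[i]], sample(0:18, 1)))
    names(excl) <- sites$site_label
    sites2 <- enumerate_sites(p, excl)
    sites2 <- sites2[sites2$site_label %in% sites$site_label, ]
    d <- build_library(p, sites2)
    # brute force: every (site, substitution) pair produces one unique
    # full-length sequence
    seqs <- character(0)
    for (i in seq_len(nrow(sites2))) {
      for (aa in sites2$allowed[[i]]) {
        s <- strsplit(p$aa_sequence, "")[[1]]
        s[sites2$seq_index[i] + 1] <- aa
        seqs <- c(seqs, paste(s, collapse = ""))
      }
    }
    expect_equal(sum(d$clones$clone_id != "parent"), length(unique(seqs)))
  }
})

test_that("every clone is Hamming distance 1 from the round backbone", {
  p <- example_parent()
  d2 <- apply_backbone(build_library(p), "R26K")
  bb <- backbone_sequence(d2)
  seqs <- library_sequences(d2)
  d_par <- oracle_hamming(bb, seqs[["parent"]])
  expect_equal(d_par, 0)
  dist1 <- vapply(seqs[names(seqs) != "parent"], oracle_hamming,
                  numeric(1), a = bb)
  expect_true(all(dist1 == 1))
})

test_that("clone IDs follow the <parent><label><new> comma-joined convention", {
  p <- example_parent()
  d <- build_library(p)
  v <- d$clones[d$clones$clone_id != "parent", ]
  expect_true(all(d$clones$clone_id[-1] ==
                    paste0(v$parent_aa, v$site_label, v$new_aa)))
  # backbone mutations are prepended in CDR order (light before heavy)
  d2 <- apply_backbone(d, "R26K")
  expect_true(all(startsWith(d2$clones$clone_id[-1], "R26K,")))
  expect_error(build_library(p, enumerate_sites(p), backbone = "R26K"),
               "overlap")
})

test_that("reverse translation round-trips through translation", {
  expect_equal(reverse_translate("M"), "ATG")
  p <- toy_parent()
  d <- build_library(p)
  aa <- library_sequences(d)[c(1, 5, 20)]
  nt <- reverse_translate(aa)
  expect_equal(nchar(nt), 3L * nchar(aa), ignore_attr = TRUE)
  back <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                             no.init.codon = TRUE))
  expect_equal(unname(back), unname(aa))
})

test_that("parent validation rejects malformed annotation", {
  expect_error(parent_scfv("x", "MKTB", data.frame(cdr = "L1", start = 0,
                                                   end = 2)),
               "non-canonical")
  expect_error(parent_scfv("x", "MKTAY",
                           data.frame(cdr = c("L1", "L2"),
                                      start = c(0, 1), end = c(3, 4))),
               "overlap")
  expect_error(parent_scfv("x", "MKTAY",
                           data.frame(cdr = "L1", start = 0, end = 9)),
               "bounds|length")
})

test_that("FASTA + TSV round trip preserves the design inputs", {
  p <- example_parent()
  td <- withr::local_tempdir()
  fa <- file.path(td, "parent.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(p$aa_sequence, p$id)), fa)
  tsv <- file.path(td, "cdrs.tsv")
  utils::write.table(p$cdr_intervals, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- read_parent_fasta(fa, tsv)
  expect_equal(p2$aa_sequence, p$aa_sequence)
  expect_equal(p2$position_labels, p$position_labels)
  d <- build_library(toy_parent())
  man <- write_library(d, file.path(td, "lib"))
  expect_true(file.exists(file.path(td, "lib", "library_aa.fasta")))
  expect_equal(nrow(man), nrow(d$clones))
})
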