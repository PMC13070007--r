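# Shared fixtures and independent oracles used across test files.

SAMPLE_ROLES <- c(input_library = "input_library",
                  trbc2_bound = "trbc2_bound",
                  trbc1_bound = "trbc1_bound")

# Small parent scFv: two CDRs, 10 labeled positions, 18 aa total.
toy_parent <- function() {
  parent_scfv("toy", "MKTAYIAKQRGSHMWNDE",
              data.frame(cdr = c("L1", "H1"), start = c(3, 10),
                         end = c(8, 15)))
}

# Independent Hamming distance (loops over split characters; no package
# helpers).
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# Brute-force classification oracle: scan {backbone} + all enumerated
# clone window peptides for an exact match, applying the <=1-alteration
# rule directly.
oracle_classify <- function(pep, backbone_pep, clone_peps) {
  if (nchar(pep) != nchar(backbone_pep)) return("length_mismatch")
  db <- oracle_hamming(pep, backbone_pep)
  if (db == 0) return("parent")
  if (db == 1) {
    hits <- names(clone_peps)[vapply(clone_peps, identical, logical(1),
                                     y = pep)]
    if (length(hits) == 1) return(hits)
  }
  "unassigned"
}

# Window peptides of every clone in a design, computed independently of
# classify_peptides (via full sequences and direct substring extraction).
design_clone_window_peptides <- function(design) {
  ci <- design$parent$cdr_intervals
  ci <- ci[order(ci$start), ]
  seqs <- library_sequences(design)
  peps <- vapply(seqs, function(s) {
    paste(mapply(substring, s, ci$start + 1, ci$end), collapse = "")
  }, character(1))
  names(peps) <- names(seqs)
  peps
}
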