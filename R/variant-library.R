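# Site-saturation scFv variant library design: parent annotation, site
# enumeration, library construction and iterative backbone fixing.

#' Annotated parent scFv
#'
#' Bundles a parent single-chain variable fragment (scFv) amino-acid
#' sequence with its six CDR intervals and the display labels of the
#' mutable positions. CDR intervals use 0-based half-open coordinates
#' (the convention of the interval TSV input); labels are opaque strings
#' chosen by the user (typically the residue number, e.g. \code{"30"}),
#' and every labeled position must fall inside a CDR interval.
#'
#' @param id sequence identifier.
#' @param aa_sequence amino-acid string over the canonical 20-letter
#'   alphabet.
#' @param cdr_intervals data.frame with columns \code{cdr} (one of
#'   L1, L2, L3, H1, H2, H3), \code{start}, \code{end} (0-based half-open,
#'   non-overlapping, within sequence bounds).
#' @param position_labels named character vector mapping 0-based sequence
#'   index (as the name) to a display label, or \code{NULL} to label every
#'   CDR position with its 1-based residue number.
#' @return object of class \code{parent_scfv}.
#' @examples
#' p <- parent_scfv("toy", "MKVLSAGRT",
#'                  data.frame(cdr = c("L1", "H1"), start = c(1, 6),
#'                             end = c(4, 9)))
#' p$position_labels
#' @export
parent_scfv <- function(id, aa_sequence, cdr_intervals,
                        position_labels = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(aa_sequence), length(aa_sequence) == 1L)
  aa <- strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  if (!all(aa %in% AA20))
    stopf("parent sequence contains non-canonical amino acids: %s",
          paste(unique(setdiff(aa, AA20)), collapse = ","))
  ci <- as.data.frame(cdr_intervals)
  if (!all(c("cdr", "start", "end") %in% names(ci)))
    stopf("cdr_intervals needs columns cdr, start, end")
  ci$cdr <- as.character(ci$cdr)
  if (!all(ci$cdr %in% CDR_NAMES))
    stopf("unknown CDR name(s): %s",
          paste(setdiff(ci$cdr, CDR_NAMES), collapse = ","))
  if (anyDuplicated(ci$cdr)) stopf("duplicated CDR names in intervals")
  L <- nchar(aa_sequence)
  if (any(ci$start < 0) || any(ci$end > L) || any(ci$start >= ci$end))
    stopf("CDR intervals must satisfy 0 <= start < end <= sequence length")
  o <- order(ci$start)
  so <- ci[o, , drop = FALSE]
  if (any(so$start[-1] < so$end[-nrow(so)]))
    stopf("CDR intervals overlap")
  # all 0-based indices covered by some CDR
  cdr_idx <- unlist(mapply(seq, ci$start, ci$end - 1L, SIMPLIFY = FALSE))
  if (is.null(position_labels)) {
    position_labels <- as.character(sort(cdr_idx) + 1L)
    names(position_labels) <- as.character(sort(cdr_idx))
  } else {
    idx <- suppressWarnings(as.integer(names(position_labels)))
    if (anyNA(idx)) stopf("position_labels names must be 0-based indices")
    if (!all(idx %in% cdr_idx))
      stopf("labeled position(s) outside all CDR intervals")
    if (anyDuplicated(position_labels))
      stopf("position labels must be unique")
    position_labels <- position_labels[order(idx)]
  }
  structure(
    list(id = id, aa_sequence = aa_sequence,
         cdr_intervals = ci[order(match(ci$cdr, CDR_NAMES)), , drop = FALSE],
         position_labels = position_labels),
    class = "parent_scfv")
}

#' @export
print.parent_scfv <- function(x, ...) {
  cat(sprintf("Parent scFv '%s': %d aa, %d CDRs, %d labeled positions\n",
              x$id, nchar(x$aa_sequence), nrow(x$cdr_intervals),
              length(x$position_labels)))
  invisible(x)
}

# CDR name of a 0-based index (NA if outside all CDRs)
cdr_of_index <- function(parent, idx) {
  ci <- parent$cdr_intervals
  out <- rep(NA_character_, length(idx))
  for (i in seq_len(nrow(ci)))
    out[idx >= ci$start[i] & idx < ci$end[i]] <- ci$cdr[i]
  out
}

# Canonical site ordering: CDR rank L1..H3, then ascending sequence index.
site_order <- function(parent, idx) {
  order(match(cdr_of_index(parent, idx), CDR_NAMES), idx)
}

lookup_label_index <- function(parent, labels) {
  pos <- match(labels, parent$position_labels)
  if (anyNA(pos))
    stopf("unknown position label(s): %s",
          paste(labels[is.na(pos)], collapse = ","))
  as.integer(names(parent$position_labels)[pos])
}

parent_aa_at <- function(parent, idx0) {
  if (!length(idx0)) return(character(0))
  substring(parent$aa_sequence, idx0 + 1L, idx0 + 1L)
}

#' Enumerate mutable sites of a parent scFv
#'
#' Builds one site specification per labeled CDR position. The allowed
#' substitutions at a site default to the 19 non-parental canonical amino
#' acids; a per-site exclusion map removes further amino acids (modeling
#' curation such as dropping residues rare in human CDRs). Sites whose
#' allowed set becomes empty are dropped.
#'
#' @param parent a \code{\link{parent_scfv}}.
#' @param exclusions named list, position label -> character vector of
#'   excluded amino acids. Unknown labels are an error.
#' @return data.frame with columns \code{site_label}, \code{seq_index}
#'   (0-based), \code{parent_aa} and a list-column \code{allowed}, ordered
#'   by CDR (L1..H3) then position.
#' @export
enumerate_sites <- function(parent, exclusions = list()) {
  stopifnot(inherits(parent, "parent_scfv"))
  if (length(exclusions) && is.null(names(exclusions)))
    stopf("exclusions must be a named list (names = position labels)")
  if (length(exclusions))
    lookup_label_index(parent, names(exclusions))  # validates labels
  idx <- as.integer(names(parent$position_labels))
  labels <- unname(parent$position_labels)
  ord <- site_order(parent, idx)
  idx <- idx[ord]; labels <- labels[ord]
  parent_aa <- parent_aa_at(parent, idx)
  allowed <- lapply(seq_along(idx), function(i) {
    excl <- exclusions[[labels[i]]] %||% character(0)
    setdiff(AA20, c(parent_aa[i], excl))
  })
  keep <- lengths(allowed) > 0L
  data.frame(site_label = labels, seq_index = idx, parent_aa = parent_aa,
             allowed = I(allowed), stringsAsFactors = FALSE)[keep, ,
                                                             drop = FALSE]
}

# Parse mutation strings like "V30K": first char = original amino acid,
# last char = replacement, middle = position label.
parse_mutations <- function(parent, muts) {
  muts <- muts[nzchar(muts)]
  if (!length(muts))
    return(data.frame(site_label = character(0), seq_index = integer(0),
                      parent_aa = character(0), new_aa = character(0),
                      stringsAsFactors = FALSE))
  old <- substring(muts, 1L, 1L)
  new <- substring(muts, nchar(muts), nchar(muts))
  lab <- substring(muts, 2L, nchar(muts) - 1L)
  if (any(!old %in% AA20) || any(!new %in% AA20) || any(!nzchar(lab)))
    stopf("malformed mutation string(s): %s", paste(muts, collapse = ","))
  idx <- lookup_label_index(parent, lab)
  paa <- parent_aa_at(parent, idx)
  if (!all(paa == old))
    stopf("mutation string parent amino acid mismatch at %s",
          paste(muts[paa != old], collapse = ","))
  data.frame(site_label = lab, seq_index = idx, parent_aa = old,
             new_aa = new, stringsAsFactors = FALSE)
}

mutation_string <- function(parent, subs) {
  if (!nrow(subs)) return("parent")
  subs <- subs[site_order(parent, subs$seq_index), , drop = FALSE]
  paste0(subs$parent_aa, subs$site_label, subs$new_aa, collapse = ",")
}

#' Build a site-saturation variant library
#'
#' Enumerates every single-substitution variant of the current round's
#' backbone: for each mutable site, the backbone amino acid is replaced by
#' each allowed substitution, one change per clone. The library also
#' carries a zero-alteration \code{"parent"} entry (the backbone itself).
#' With 74 sites and 19 substitutions each this yields the reference
#' configuration of 1,406 variants + 1 parent.
#'
#' Clones are enumerated deterministically: sites in CDR order (L1..H3,
#' ascending position), substitutions alphabetically. Clone IDs are
#' comma-joined mutation strings over the cumulative substitutions
#' (backbone + new), e.g. \code{"V30K,S32R,R27Y"}.
#'
#' @param parent a \code{\link{parent_scfv}}.
#' @param sites site table from \code{\link{enumerate_sites}} (default:
#'   all labeled sites, no exclusions).
#' @param backbone character vector of fixed mutation strings carried from
#'   previous rounds (e.g. \code{c("V30K")}), or empty for round 1.
#' @param round_number selection round, >= 1.
#' @return object of class \code{library_design} with elements
#'   \code{round_number}, \code{parent}, \code{backbone} (data.frame),
#'   \code{sites}, and \code{clones} (data.frame: \code{clone_id},
#'   \code{site_label}, \code{seq_index}, \code{parent_aa}, \code{new_aa};
#'   first row is the parent entry).
#' @export
build_library <- function(parent, sites = enumerate_sites(parent),
                          backbone = character(0), round_number = 1L) {
  stopifnot(inherits(parent, "parent_scfv"), is_count(round_number),
            round_number >= 1)
  bb <- if (is.data.frame(backbone)) backbone else
    parse_mutations(parent, as.character(backbone))
  if (anyDuplicated(bb$seq_index)) stopf("duplicate backbone positions")
  if (any(sites$seq_index %in% bb$seq_index))
    stopf("backbone positions overlap mutable sites: %s",
          paste(intersect(sites$site_label, bb$site_label), collapse = ","))
  n_per_site <- lengths(sites$allowed)
  site_rep <- rep(seq_len(nrow(sites)), n_per_site)
  new_aa <- unlist(lapply(sites$allowed, sort), use.names = FALSE)
  # vectorized clone IDs: insert each new mutation token into the sorted
  # backbone token list at its CDR-order position
  ckey <- function(idx) match(cdr_of_index(parent, idx), CDR_NAMES) *
    1e7 + idx
  bb_ord <- order(ckey(bb$seq_index))
  bb_tok <- paste0(bb$parent_aa, bb$site_label, bb$new_aa)[bb_ord]
  bb_key <- sort(ckey(bb$seq_index))
  tok <- paste0(sites$parent_aa[site_rep], sites$site_label[site_rep],
                new_aa)
  pos <- findInterval(ckey(sites$seq_index[site_rep]), bb_key)
  prefix <- vapply(0:length(bb_tok), function(j)
    if (j == 0) "" else paste0(paste(bb_tok[seq_len(j)], collapse = ","),
                               ","), character(1))
  suffix <- vapply(0:length(bb_tok), function(j)
    if (j == length(bb_tok)) "" else
      paste0(",", paste(bb_tok[seq(j + 1, length(bb_tok))],
                        collapse = ",")), character(1))
  clone_id <- paste0(prefix[pos + 1L], tok, suffix[pos + 1L])
  clones <- data.frame(
    clone_id = c("parent", clone_id),
    site_label = c(NA_character_, sites$site_label[site_rep]),
    seq_index = c(NA_integer_, sites$seq_index[site_rep]),
    parent_aa = c(NA_character_, sites$parent_aa[site_rep]),
    new_aa = c(NA_character_, new_aa),
    stringsAsFactors = FALSE)
  if (anyDuplicated(clones$clone_id)) stopf("clone IDs are not unique")
  stopifnot(nrow(clones) == 1L + sum(n_per_site))
  structure(list(round_number = as.integer(round_number), parent = parent,
                 backbone = bb, sites = sites, clones = clones),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf(
    "Library design, round %d: %d sites, %d variants (+1 parent entry)\n",
    x$round_number, nrow(x$sites), nrow(x$clones) - 1L))
  if (nrow(x$backbone))
    cat("  backbone:", mutation_string(x$parent, x$backbone), "\n")
  invisible(x)
}

#' Backbone amino-acid sequence of a library round
#'
#' The parent sequence with all fixed backbone substitutions applied;
#' every variant of the round differs from it at exactly one position.
#' @param design a \code{library_design}.
#' @return amino-acid string.
#' @export
backbone_sequence <- function(design) {
  aa <- strsplit(design$parent$aa_sequence, "", fixed = TRUE)[[1]]
  if (nrow(design$backbone))
    aa[design$backbone$seq_index + 1L] <- design$backbone$new_aa
  paste(aa, collapse = "")
}

#' Full amino-acid sequences of all clones in a library
#'
#' @param design a \code{library_design}.
#' @return named character vector (names = clone IDs); the parent entry is
#'   the backbone sequence itself.
#' @export
library_sequences <- function(design) {
  bb <- backbone_sequence(design)
  cl <- design$clones
  out <- rep(bb, nrow(cl))
  var <- !is.na(cl$seq_index)
  if (any(var)) {
    m <- char_matrix(out[var])
    m[cbind(seq_len(sum(var)), cl$seq_index[var] + 1L)] <- cl$new_aa[var]
    out[var] <- apply(m, 1L, paste, collapse = "")
  }
  names(out) <- cl$clone_id
  out
}

#' Fix a selected clone as the next round's backbone
#'
#' Produces the next-round library design: the selected clone's cumulative
#' substitutions become the fixed backbone, its positions are removed from
#' the mutable sites, and the round number is incremented. Applying the
#' parent entry leaves the sites unchanged.
#'
#' @param design a \code{library_design}.
#' @param clone_id ID of a clone in \code{design} (or \code{"parent"}).
#' @return new \code{library_design}.
#' @export
apply_backbone <- function(design, clone_id) {
  stopifnot(inherits(design, "library_design"))
  i <- match(clone_id, design$clones$clone_id)
  if (is.na(i)) stopf("clone '%s' is not in this design", clone_id)
  cl <- design$clones[i, ]
  bb <- design$backbone
  sites <- design$sites
  if (!is.na(cl$seq_index)) {
    bb <- rbind(bb, data.frame(site_label = cl$site_label,
                               seq_index = cl$seq_index,
                               parent_aa = cl$parent_aa,
                               new_aa = cl$new_aa,
                               stringsAsFactors = FALSE))
    sites <- sites[sites$seq_index != cl$seq_index, , drop = FALSE]
  }
  build_library(design$parent, sites, bb,
                round_number = design$round_number + 1L)
}

#' Default codon table for reverse translation
#'
#' One fixed codon per amino acid (common E. coli-compatible choices); any
#' table covering the 20 canonical amino acids can be substituted.
#' @return named character vector, amino acid -> codon.
#' @export
default_codon_table <- function() {
  c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
    H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
    P = "CCG", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
    W = "TGG", Y = "TAT")
}

#' Reverse-translate an amino-acid sequence
#'
#' Deterministic reverse translation with one codon per amino acid;
#' translating the output reproduces the input exactly.
#' @param aa_sequence amino-acid string (or vector of strings).
#' @param codon_table named character vector covering all amino acids used.
#' @return nucleotide string(s) of length 3x the input.
#' @export
reverse_translate <- function(aa_sequence, codon_table = default_codon_table()) {
  stopifnot(all(AA20 %in% names(codon_table)))
  vapply(aa_sequence, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(codon_table))
    if (length(bad)) stopf("no codon for: %s", paste(bad, collapse = ","))
    paste(codon_table[aa], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- CDR windows -----------------------------------------------------------

#' CDR window map of a parent scFv
#'
#' The sequencing assay observes only the CDR-covering windows of the
#' scFv. Windows are the CDR intervals in sequence order; the map links
#' each 1-based position of the concatenated window peptide to its 0-based
#' index on the full sequence.
#' @param parent a \code{parent_scfv}.
#' @return data.frame with columns \code{window_pos} (1-based position in
#'   the concatenated peptide), \code{seq_index} (0-based), \code{cdr}.
#' @export
cdr_windows <- function(parent) {
  ci <- parent$cdr_intervals[order(parent$cdr_intervals$start), ,
                             drop = FALSE]
  idx <- unlist(mapply(seq, ci$start, ci$end - 1L, SIMPLIFY = FALSE))
  data.frame(window_pos = seq_along(idx), seq_index = as.integer(idx),
             cdr = rep(ci$cdr, ci$end - ci$start),
             stringsAsFactors = FALSE)
}

#' Extract the concatenated CDR window peptide from full sequences
#'
#' @param aa_sequences character vector of full-length amino-acid
#'   sequences (same length as the parent).
#' @param parent a \code{parent_scfv}.
#' @return character vector of window peptides.
#' @export
window_peptide <- function(aa_sequences, parent) {
  w <- cdr_windows(parent)
  vapply(aa_sequences, function(s) {
    paste(substring(s, w$seq_index + 1L, w$seq_index + 1L), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- IO --------------------------------------------------------------------

#' Read a parent scFv from FASTA plus a CDR interval TSV
#'
#' The TSV has columns \code{cdr}, \code{start}, \code{end} (0-based
#' half-open) and optionally \code{index}, \code{label} rows defining
#' position labels (one row per labeled position with \code{cdr = NA}), or
#' a separate label TSV may be supplied.
#'
#' @param fasta path to a single-record amino-acid FASTA.
#' @param cdr_tsv path to the interval TSV.
#' @param labels_tsv optional TSV with columns \code{index} (0-based) and
#'   \code{label}.
#' @return a \code{\link{parent_scfv}}.
#' @export
read_parent_fasta <- function(fasta, cdr_tsv, labels_tsv = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (length(seqs) != 1L) stopf("expected exactly one FASTA record")
  ci <- utils::read.delim(cdr_tsv, stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.null(labels_tsv)) {
    lt <- utils::read.delim(labels_tsv, stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(lt$label),
                              as.character(lt$index))
  }
  parent_scfv(sub("\\s.*$", "", names(seqs)[1]), as.character(seqs[[1]]),
              ci[, c("cdr", "start", "end")], labels)
}

#' Write library FASTA files and a clone manifest
#'
#' Writes amino-acid and nucleotide FASTA for every clone plus a CSV
#' manifest (clone_id, site, substitution, sequence).
#' @param design a \code{library_design}.
#' @param dir output directory (created if needed).
#' @param codon_table passed to \code{\link{reverse_translate}}.
#' @return invisibly, the manifest data.frame.
#' @export
write_library <- function(design, dir, codon_table = default_codon_table()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aa <- library_sequences(design)
  nt <- reverse_translate(aa, codon_table)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aa),
                              file.path(dir, "library_aa.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(nt, names(aa))),
    file.path(dir, "library_nt.fasta"))
  manifest <- cbind(design$clones, aa_sequence = unname(aa),
                    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "library_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
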