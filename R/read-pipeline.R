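# Segmented amplicon reads -> per-sample, per-clone molecule counts:
# demultiplexing, UMI collapse, in-frame translation of the CDR windows,
# clone classification under the <=1-alteration rule, and tallying.

seg_cols <- function(reads) grep("^seg[0-9]+$", names(reads), value = TRUE)

#' Read / write segmented amplicon reads (TSV record format)
#'
#' One row per sequencing cluster: \code{cluster_id}, \code{sample_index}
#' (demultiplexing barcode), \code{umi} (14-mer) and one \code{segN}
#' column per sequencing read covering the scFv CDR windows.
#' @param path TSV file path.
#' @return data.frame of reads.
#' @export
read_segment_tsv <- function(path) {
  reads <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("cluster_id", "sample_index", "umi")
  if (!all(need %in% names(reads)))
    stopf("reads TSV must have columns %s and seg1..segN",
          paste(need, collapse = ", "))
  validate_reads(reads)
  reads
}

#' @rdname read_segment_tsv
#' @param reads data.frame of reads.
#' @export
write_segment_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_reads <- function(reads) {
  if (!nrow(reads)) return(invisible(reads))
  if (any(nchar(reads$umi) != 14L))
    stopf("UMIs must be 14-mers")
  if (any(grepl("[^ACGTN]", reads$umi)))
    stopf("UMIs must be over {A,C,G,T,N}")
  if (!length(seg_cols(reads))) stopf("no segment columns (seg1..segN)")
  invisible(reads)
}

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the unique sample whose barcode is within
#' \code{max_mismatch} of its \code{sample_index}; reads matching no
#' barcode (or more than one at equal distance) are discarded.
#'
#' @param reads data.frame of segmented reads.
#' @param index_map named character vector, barcode -> sample name.
#' @param max_mismatch allowed Hamming distance (default 0).
#' @return list with \code{samples} (named list of read data.frames) and
#'   \code{n_discarded}.
#' @export
demultiplex <- function(reads, index_map, max_mismatch = 0L) {
  if (anyDuplicated(names(index_map)))
    stopf("duplicate barcode in index map")
  if (anyDuplicated(index_map))
    stopf("duplicate sample name in index map")
  validate_reads(reads)
  barcodes <- names(index_map)
  if (max_mismatch == 0L) {
    hit <- match(reads$sample_index, barcodes)
  } else {
    d <- vapply(barcodes, function(b) {
      sel <- nchar(reads$sample_index) == nchar(b)
      out <- rep(NA_integer_, nrow(reads))
      if (any(sel)) out[sel] <- hamming_to(b, reads$sample_index[sel])
      out
    }, integer(nrow(reads)))
    d <- matrix(d, nrow = nrow(reads))
    best <- apply(d, 1L, function(r) {
      ok <- which(!is.na(r) & r <= max_mismatch)
      if (length(ok) == 1L) ok else NA_integer_
    })
    hit <- best
  }
  samples <- lapply(seq_along(barcodes), function(i)
    reads[which(hit == i), , drop = FALSE])
  names(samples) <- unname(index_map)
  list(samples = samples, n_discarded = sum(is.na(hit)))
}

#' Collapse PCR duplicates by UMI
#'
#' Reads within a sample sharing both the UMI and the full concatenated
#' segment sequence collapse to one molecule; the same UMI with a
#' different sequence stays a distinct molecule. Zero UMI mismatch
#' tolerance.
#'
#' @param reads data.frame of reads from one sample.
#' @return data.frame of molecules: \code{molecule_id}, \code{umi}, the
#'   segment columns, and \code{n_reads} (duplicate count).
#' @export
collapse_umis <- function(reads) {
  sc <- seg_cols(reads)
  if (!nrow(reads)) {
    out <- reads[, c("umi", sc), drop = FALSE]
    out$molecule_id <- character(0)
    out$n_reads <- integer(0)
    return(out[, c("molecule_id", "umi", sc, "n_reads")])
  }
  key <- do.call(paste, c(reads[c("umi", sc)], sep = "|"))
  first <- !duplicated(key)
  out <- reads[first, c("umi", sc), drop = FALSE]
  out$n_reads <- as.integer(table(key)[key[first]])
  out$molecule_id <- sprintf("m%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("molecule_id", "umi", sc, "n_reads")]
}

#' Assemble and translate molecule segments into the CDR window peptide
#'
#' Trims each segment per the frame map, concatenates the in-frame
#' nucleotides, and translates them. Molecules with a non-ACGT base or an
#' internal stop codon are flagged untranslatable (peptide \code{NA}).
#'
#' @param molecules data.frame from \code{\link{collapse_umis}} (or raw
#'   reads, for read-level counting).
#' @param frame_map list with one \code{list(offset, length)} entry per
#'   segment giving the 0-based nucleotide offset and in-frame length
#'   kept from that segment, or \code{NULL} to use each segment whole.
#' @return the input with a \code{peptide} character column added
#'   (\code{NA} = untranslatable).
#' @export
assemble_translate <- function(molecules, frame_map = NULL) {
  sc <- seg_cols(molecules)
  if (!is.null(frame_map) && length(frame_map) != length(sc))
    stopf("frame_map must have one entry per segment")
  if (!nrow(molecules)) {
    molecules$peptide <- character(0)
    return(molecules)
  }
  parts <- lapply(seq_along(sc), function(i) {
    s <- molecules[[sc[i]]]
    if (is.null(frame_map)) return(s)
    off <- frame_map[[i]]$offset
    len <- frame_map[[i]]$length
    substring(s, off + 1L, off + len)
  })
  nt <- do.call(paste0, parts)
  ok <- !grepl("[^ACGT]", nt) & nchar(nt) %% 3L == 0L
  pep <- rep(NA_character_, length(nt))
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt[ok]),
                                             no.init.codon = TRUE))
    aa[grepl("\\*", aa)] <- NA_character_  # internal stop codon
    pep[ok] <- aa
  }
  molecules$peptide <- pep
  molecules
}

# Per-design classification context: backbone window peptide plus a
# (window position, amino acid) -> clone_id lookup for the variants.
design_window_context <- function(design) {
  w <- cdr_windows(design$parent)
  bb_pep <- window_peptide(backbone_sequence(design), design$parent)
  cl <- design$clones[!is.na(design$clones$seq_index), , drop = FALSE]
  wpos <- w$window_pos[match(cl$seq_index, w$seq_index)]
  if (anyNA(wpos)) stopf("design has sites outside the CDR windows")
  list(backbone_peptide = bb_pep, width = nchar(bb_pep),
       lookup = stats::setNames(cl$clone_id, paste(wpos, cl$new_aa)))
}

#' Classify CDR window peptides against a library design
#'
#' Applies the one-or-zero-alteration rule: a peptide identical to the
#' round's backbone is \code{"parent"}; exactly one alteration matching an
#' enumerated clone assigns that clone; one alteration outside the design
#' or two or more alterations is \code{"unassigned"}. Untranslatable
#' (\code{NA}) peptides are \code{"untranslatable"}; a wrong-length
#' peptide is \code{"length_mismatch"}.
#'
#' @param peptides character vector of window peptides (\code{NA} allowed).
#' @param design a \code{library_design}.
#' @return data.frame with columns \code{assigned} and
#'   \code{n_alterations} (\code{NA} where not applicable).
#' @export
classify_peptides <- function(peptides, design) {
  ctx <- design_window_context(design)
  n <- length(peptides)
  assigned <- rep("unassigned", n)
  nalt <- rep(NA_integer_, n)
  untr <- is.na(peptides)
  assigned[untr] <- "untranslatable"
  lenok <- !untr & nchar(peptides) == ctx$width
  assigned[!untr & !lenok] <- "length_mismatch"
  if (any(lenok)) {
    idx <- which(lenok)
    m <- char_matrix(peptides[idx])
    ref <- matrix(strsplit(ctx$backbone_peptide, "", fixed = TRUE)[[1]],
                  nrow = length(idx), ncol = ctx$width, byrow = TRUE)
    diffs <- m != ref
    k <- as.integer(rowSums(diffs))
    nalt[idx] <- k
    assigned[idx[k == 0L]] <- "parent"
    one <- which(k == 1L)
    if (length(one)) {
      wpos <- max.col(diffs[one, , drop = FALSE], ties.method = "first")
      aa <- m[cbind(one, wpos)]
      hit <- ctx$lookup[paste(wpos, aa)]
      ok <- !is.na(hit)
      assigned[idx[one[ok]]] <- unname(hit[ok])
    }
  }
  data.frame(assigned = assigned, n_alterations = nalt,
             stringsAsFactors = FALSE)
}

#' Per-sample, per-clone molecule count table
#'
#' Container for the tallied counts: a clones x samples integer matrix
#' (rows: \code{"parent"} plus every enumerated clone), sample roles, and
#' per-sample QC totals.
#' @param counts integer matrix, rownames = clone IDs, colnames = samples.
#' @param roles named character vector, sample -> role in
#'   \{\code{input_library}, \code{trbc2_bound}, \code{trbc1_bound}\}.
#' @param qc optional per-sample QC data.frame.
#' @export
clone_counts <- function(counts, roles, qc = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (!all(colnames(counts) %in% names(roles)))
    stopf("every sample column needs a role")
  ok_roles <- c("input_library", "trbc2_bound", "trbc1_bound")
  if (!all(roles %in% ok_roles))
    stopf("roles must be in {%s}", paste(ok_roles, collapse = ", "))
  structure(list(counts = counts, roles = roles[colnames(counts)], qc = qc),
            class = "clone_counts")
}

#' @export
print.clone_counts <- function(x, ...) {
  cat(sprintf("Clone count table: %d clones x %d samples (total %d molecules)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  for (s in colnames(x$counts))
    cat(sprintf("  %s [%s]: %d molecules\n", s, x$roles[[s]],
                sum(x$counts[, s])))
  invisible(x)
}

#' Tally classified molecules into a clone count table
#'
#' @param assignments named list (per sample) of classification
#'   data.frames from \code{\link{classify_peptides}}.
#' @param design the \code{library_design} the molecules were classified
#'   against.
#' @param roles named character vector, sample -> role.
#' @return a \code{\link{clone_counts}} object; unassigned,
#'   untranslatable and length-mismatch molecules are excluded from the
#'   counts but reported in \code{$qc}.
#' @export
tally_clones <- function(assignments, design, roles) {
  ids <- design$clones$clone_id
  counts <- sapply(assignments, function(a) {
    tab <- table(factor(a$assigned, levels = ids))
    as.integer(tab)
  })
  counts <- matrix(counts, nrow = length(ids),
                   dimnames = list(ids, names(assignments)))
  qc <- do.call(rbind, lapply(names(assignments), function(s) {
    a <- assignments[[s]]
    data.frame(sample = s, molecules = nrow(a),
               assigned = sum(a$assigned %in% ids),
               unassigned = sum(a$assigned == "unassigned"),
               untranslatable = sum(a$assigned == "untranslatable"),
               length_mismatch = sum(a$assigned == "length_mismatch"),
               stringsAsFactors = FALSE)
  }))
  clone_counts(counts, roles, qc)
}

#' Full read-counting pipeline
#'
#' Demultiplex, collapse UMIs (optional), translate and classify, then
#' tally: segmented reads in, \code{\link{clone_counts}} out.
#'
#' @param reads data.frame of segmented reads.
#' @param design a \code{library_design}.
#' @param index_map named character vector, barcode -> sample.
#' @param roles named character vector, sample -> role.
#' @param frame_map per-segment trimming (see
#'   \code{\link{assemble_translate}}).
#' @param unit count UMI-collapsed \code{"molecules"} (default) or raw
#'   \code{"reads"}.
#' @param max_mismatch barcode mismatch tolerance.
#' @return a \code{\link{clone_counts}}; \code{$qc} also records the
#'   demultiplexing discard count as attribute \code{"n_discarded"}.
#' @export
count_reads <- function(reads, design, index_map, roles, frame_map = NULL,
                        unit = c("molecules", "reads"), max_mismatch = 0L) {
  unit <- match.arg(unit)
  dm <- demultiplex(reads, index_map, max_mismatch)
  assignments <- lapply(dm$samples, function(r) {
    mol <- if (unit == "molecules") collapse_umis(r) else r
    mol <- assemble_translate(mol, frame_map)
    classify_peptides(mol$peptide, design)
  })
  out <- tally_clones(assignments, design, roles)
  attr(out$qc, "n_discarded") <- dm$n_discarded
  out
}

#' Write / read a clone count table as CSV
#' @param x a \code{clone_counts}.
#' @param path CSV path.
#' @export
write_counts_csv <- function(x, path) {
  df <- data.frame(clone_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @param roles named character vector, sample -> role.
#' @export
read_counts_csv <- function(path, roles) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$clone_id
  clone_counts(m, roles)
}
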