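# Synthetic data generators: panning counts under multinomial sampling,
# segmented UMI-tagged reads with PCR duplication and substitution errors,
# flow-cytometry tables and dose-response curves. Every generator takes an
# explicit seed and records it on its output.

#' Ground truth for a simulated panning experiment
#'
#' Per-clone input fractions plus capture probabilities on TRBC2+ and
#' TRBC1+ cells. The bound-pool composition is proportional to
#' \code{fraction * capture probability}.
#' @param clone_ids character vector of clone IDs (should match a
#'   \code{library_design}).
#' @param input_fractions per-clone fractions summing to 1.
#' @param p_trbc2,p_trbc1 capture probabilities in (0, 1].
#' @return object of class \code{panning_truth}.
#' @export
panning_truth <- function(clone_ids, input_fractions, p_trbc2, p_trbc1) {
  n <- length(clone_ids)
  stopifnot(length(input_fractions) == n, length(p_trbc2) == n,
            length(p_trbc1) == n, all(input_fractions >= 0),
            abs(sum(input_fractions) - 1) < 1e-8,
            all(p_trbc2 > 0), all(p_trbc2 <= 1),
            all(p_trbc1 > 0), all(p_trbc1 <= 1))
  structure(list(clone_ids = clone_ids,
                 input_fractions = input_fractions,
                 p_trbc2 = p_trbc2, p_trbc1 = p_trbc1),
            class = "panning_truth")
}

#' Capture probability from affinity at a given analyte concentration
#'
#' Optional equilibrium link for affinity-driven scenarios:
#' \code{p = C / (C + KD)} (the fractional occupancy of a 1:1 binding
#' isotherm).
#' @param KD_nM equilibrium dissociation constant, nM.
#' @param C_nM free concentration, nM.
#' @export
capture_prob_from_affinity <- function(KD_nM, C_nM) {
  stopifnot(all(KD_nM > 0), all(C_nM > 0))
  C_nM / (C_nM + KD_nM)
}

#' Uniform truth with one planted high-selectivity clone
#'
#' Uniform input fractions; every clone shares the same TRBC1 capture
#' probability and a baseline TRBC2 capture probability, except one
#' planted clone whose TRBC2 capture is \code{advantage}-fold higher.
#' @param clone_ids clone IDs.
#' @param top_clone the planted clone's ID.
#' @param p_base baseline capture probability (both cell lines).
#' @param advantage fold increase of the planted clone's TRBC2 capture.
#' @return a \code{\link{panning_truth}}.
#' @export
planted_truth <- function(clone_ids, top_clone, p_base = 0.02,
                          advantage = 10) {
  stopifnot(top_clone %in% clone_ids, p_base * advantage <= 1)
  n <- length(clone_ids)
  p2 <- rep(p_base, n)
  p2[clone_ids == top_clone] <- p_base * advantage
  panning_truth(clone_ids, rep(1 / n, n), p2, rep(p_base, n))
}

#' Simulate one panning round as a clone count table
#'
#' Input-library counts are multinomial(depth, input fractions); the two
#' bound pools are multinomial(depth, q) with q proportional to
#' \code{fraction * capture probability} for the respective cell line.
#' @param truth a \code{\link{panning_truth}}.
#' @param depth molecules per sample.
#' @param seed integer seed (recorded as attribute \code{"seed"}).
#' @return a \code{\link{clone_counts}} with samples
#'   \code{input_library}, \code{trbc2_bound}, \code{trbc1_bound}.
#' @export
simulate_panning <- function(truth, depth = 1e5, seed = NULL) {
  stopifnot(inherits(truth, "panning_truth"), depth > 0)
  if (!is.null(seed)) set.seed(seed)
  f <- truth$input_fractions
  q2 <- f * truth$p_trbc2; q2 <- q2 / sum(q2)
  q1 <- f * truth$p_trbc1; q1 <- q1 / sum(q1)
  m <- cbind(input_library = stats::rmultinom(1, depth, f)[, 1],
             trbc2_bound = stats::rmultinom(1, depth, q2)[, 1],
             trbc1_bound = stats::rmultinom(1, depth, q1)[, 1])
  rownames(m) <- truth$clone_ids
  out <- clone_counts(m, c(input_library = "input_library",
                           trbc2_bound = "trbc2_bound",
                           trbc1_bound = "trbc1_bound"))
  attr(out, "seed") <- seed
  out
}

# Fixed 8-mer sample barcodes with pairwise Hamming distance >= 6, so a
# single sequencing error never makes demultiplexing ambiguous.
default_barcodes <- function(n) {
  pool <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT",
            "AACCGGTT", "CCAATTGG", "GGTTAACC", "TTGGCCAA")
  if (n > length(pool)) stopf("too many samples for the barcode pool")
  pool[seq_len(n)]
}

random_umis <- function(n) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), 14L * n, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# Independent per-base substitution errors on equal-length strings.
mutate_bases <- function(strings, rate) {
  if (rate <= 0 || !length(strings)) return(strings)
  m <- char_matrix(strings)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      m[i] <- sample(setdiff(bases, m[i]), 1L)
    }
    strings <- apply(m, 1L, paste, collapse = "")
  }
  strings
}

#' Emit segmented sequencing reads from a clone count table
#'
#' Inverse of the read pipeline: each counted molecule becomes a read
#' record with the sample barcode, a fresh random 14-mer UMI and one
#' nucleotide segment per CDR (reverse-translated from the clone's
#' sequence). PCR duplicates follow a geometric distribution with the
#' given mean; substitution errors are applied per base per read after
#' duplication.
#'
#' @param counts a \code{\link{clone_counts}} whose row names are clones
#'   of \code{design}.
#' @param design the \code{library_design}.
#' @param error_rate per-base substitution error rate in [0, 0.05].
#' @param dup_mean mean reads per molecule (>= 1; 1 = no duplication).
#' @param seed integer seed (recorded on the output).
#' @param codon_table passed to \code{\link{reverse_translate}}.
#' @return list with \code{reads} (segmented read data.frame) and
#'   \code{index_map} (barcode -> sample, for
#'   \code{\link{demultiplex}}); attribute \code{"seed"} on the reads.
#' @export
emit_reads <- function(counts, design, error_rate = 0, dup_mean = 1,
                       seed = NULL, codon_table = default_codon_table()) {
  stopifnot(inherits(counts, "clone_counts"),
            inherits(design, "library_design"),
            error_rate >= 0, error_rate <= 0.05, dup_mean >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(counts$counts)
  if (!all(ids %in% design$clones$clone_id))
    stopf("count table rows are not clones of the design")
  # per-clone nucleotide segments, one per CDR interval in sequence order
  ci <- design$parent$cdr_intervals[
    order(design$parent$cdr_intervals$start), , drop = FALSE]
  seqs <- library_sequences(design)[ids]
  seg_nt <- lapply(seq_len(nrow(ci)), function(i) {
    aa <- substring(seqs, ci$start[i] + 1L, ci$end[i])
    reverse_translate(aa, codon_table)
  })
  samples <- colnames(counts$counts)
  barcodes <- default_barcodes(length(samples))
  index_map <- stats::setNames(samples, barcodes)
  rows <- list()
  for (s in seq_along(samples)) {
    n_mol_per_clone <- counts$counts[, s]
    mol_clone <- rep(seq_along(ids), n_mol_per_clone)
    n_mol <- length(mol_clone)
    if (!n_mol) next
    umis <- random_umis(n_mol)
    dups <- 1L + stats::rgeom(n_mol, prob = 1 / dup_mean)
    read_mol <- rep(seq_len(n_mol), dups)
    df <- data.frame(sample_index = barcodes[s],
                     umi = umis[read_mol],
                     stringsAsFactors = FALSE)
    for (k in seq_along(seg_nt)) {
      sv <- seg_nt[[k]][mol_clone][read_mol]
      df[[paste0("seg", k)]] <- mutate_bases(sv, error_rate)
    }
    rows[[s]] <- df
  }
  reads <- do.call(rbind, rows)
  if (is.null(reads))
    reads <- data.frame(sample_index = character(0), umi = character(0),
                        seg1 = character(0), stringsAsFactors = FALSE)
  reads <- cbind(cluster_id = sprintf("r%07d", seq_len(nrow(reads))),
                 reads, stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  attr(reads, "seed") <- seed
  list(reads = reads, index_map = index_map)
}

#' Simulate flow-cytometry quadrant counts
#'
#' Multinomial draw of n cells over the four TRBC1/TRBC2 co-staining
#' quadrants.
#' @param composition probabilities for (trbc1_only, trbc2_only,
#'   dual_pos, dual_neg), summing to 1.
#' @param n total cells.
#' @param seed integer seed.
#' @return named integer vector of quadrant counts (attribute
#'   \code{"seed"}).
#' @export
simulate_flow_quadrants <- function(composition, n, seed = NULL) {
  stopifnot(length(composition) == 4L, abs(sum(composition) - 1) < 1e-8,
            n > 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(1, n, composition)[, 1]
  names(counts) <- c("trbc1_only", "trbc2_only", "dual_pos", "dual_neg")
  attr(counts, "seed") <- seed
  counts
}

#' Simulate a patient T cell count table
#'
#' Binomially splits the T cells into malignant (TRBC2+ CD26-) and normal
#' compartments.
#' @param frac_cancer true malignant fraction of T cells.
#' @param total_T total T cells.
#' @param seed integer seed.
#' @return list with \code{cancer}, \code{normal}, \code{total_T}
#'   (attribute \code{"seed"}).
#' @export
simulate_patient_flow <- function(frac_cancer, total_T, seed = NULL) {
  stopifnot(frac_cancer >= 0, frac_cancer <= 1, total_T > 0)
  if (!is.null(seed)) set.seed(seed)
  cancer <- stats::rbinom(1, total_T, frac_cancer)
  out <- list(cancer = cancer, normal = total_T - cancer,
              total_T = total_T)
  attr(out, "seed") <- seed
  out
}

#' Simulate a dose-response table from a 4PL curve
#'
#' @param top,bottom,ic50,hill generating 4PL parameters.
#' @param doses dose levels (> 0).
#' @param noise_sd Gaussian noise standard deviation on the response.
#' @param seed integer seed.
#' @return data.frame \code{dose}, \code{response} (attribute
#'   \code{"seed"}).
#' @export
simulate_dose_response <- function(top, bottom, ic50, hill, doses,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(all(doses > 0), ic50 > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  r <- fourpl_response(doses, top, bottom, ic50, hill)
  if (noise_sd > 0) r <- r + stats::rnorm(length(doses), 0, noise_sd)
  out <- data.frame(dose = doses, response = r)
  attr(out, "seed") <- seed
  out
}

#' Built-in example parent scFv with 74 labeled CDR positions
#'
#' A deterministic synthetic scFv (VL-linker-VH layout) whose six CDRs
#' total 74 positions, mirroring the reference site-saturation
#' configuration (74 sites x 19 substitutions = 1,406 variants). The
#' sequence is fixed, not derived from any real antibody.
#' @return a \code{\link{parent_scfv}}.
#' @export
example_parent <- function() {
  pieces <- c(
    FR1 = "EIVLTQSPGTLSLSPGERATLSCRA",
    L1  = "RASQSVSSSYL",            # 11
    FRa = "WYQQKPGQAPRLLIY",
    L2  = "GASSRAT",                # 7
    FRb = "GIPDRFSGSGSGTDF",
    L3  = "QQYGSSPWT",              # 9
    LNK = "TLTISRLEPEDFAVYYCGGGGSGGGGSSGG",
    H1  = "GFTFSSYAMS",             # 10
    FRc = "WVRQAPGKGLEWVSA",
    H2  = "AISGSGGSTYYADSVKG",      # 17
    FRd = "RFTISRDNSKNTLYL",
    H3  = "ARDRGYSSGWYYGMDVWGQG",   # 20
    FR4 = "GQGTLVTVSSASTKG")
  ends <- cumsum(nchar(pieces))
  starts <- ends - nchar(pieces)
  cdrs <- c("L1", "L2", "L3", "H1", "H2", "H3")
  ci <- data.frame(cdr = cdrs, start = starts[cdrs], end = ends[cdrs],
                   stringsAsFactors = FALSE)
  parent_scfv("synthetic-scfv-74", paste(pieces, collapse = ""), ci)
}
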