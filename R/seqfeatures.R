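# Sequence-level scalar features for disordered regions: charge composition
# (FCR, NCPR), charge patterning (kappa, SCD), hydropathy patterning (SHD),
# and residue-class fractions.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Residue classes. Histidine is treated as uncharged at neutral pH (its bead
# charge is ~0 in residue-level CG models) and is tracked in its own
# "histidine" class rather than with the aromatics Y/W/F.
AA_CLASSES <- list(
  aromatic  = c("F", "W", "Y"),
  aliphatic = c("A", "I", "L", "M", "V"),
  polar     = c("N", "Q", "S", "T", "G", "H", "C"),
  proline   = "P",
  glycine   = "G",
  positive  = c("R", "K"),
  negative  = c("D", "E")
)

# Kyte-Doolittle hydropathy, raw scale (-4.5 .. 4.5).
KD_RAW <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' Per-residue hydropathy scale
#'
#' Returns a named numeric vector over the 20 canonical residues. The default
#' is Kyte-Doolittle linearly rescaled to `[0, 1]` (so R = 0, I = 1); the raw
#' scale or a user-supplied named vector can be used instead.
#'
#' @param scale `"kd_norm"` (default), `"kd"`, or a named numeric vector
#'   covering all 20 canonical residues.
#' @return Named numeric vector of length 20.
#' @export
hydropathy_scale <- function(scale = "kd_norm") {
  if (is.numeric(scale)) {
    if (!all(AA_ALPHABET %in% names(scale)))
      stop("custom hydropathy scale must name all 20 canonical residues")
    return(scale[AA_ALPHABET])
  }
  switch(match.arg(scale, c("kd_norm", "kd")),
    kd      = KD_RAW[AA_ALPHABET],
    kd_norm = (KD_RAW[AA_ALPHABET] + 4.5) / 9
  )
}

validate_seq <- function(seq, id = NULL) {
  if (length(seq) != 1L || !is.character(seq))
    stop("sequence must be a single character string")
  seq <- toupper(seq)
  if (endsWith(seq, "*")) {
    warning(sprintf("stripping terminal stop codon '*' from %s",
                    if (is.null(id)) "sequence" else id))
    seq <- sub("\\*$", "", seq)
  }
  if (nchar(seq) == 0L)
    stop(sprintf("empty sequence%s", if (is.null(id)) "" else paste0(" for record '", id, "'")))
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("non-canonical residue '%s' at position %d%s",
                 chars[bad[1]], bad[1],
                 if (is.null(id)) "" else paste0(" in record '", id, "'")))
  seq
}

#' Read amino-acid sequences from a FASTA file
#'
#' Sequences are validated against the 20 canonical one-letter residues;
#' lowercase input is upcased and a terminal `*` is stripped with a warning.
#' Any other non-canonical character is an error naming the record and
#' position (no silent substitution).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = record ids, first
#'   whitespace-delimited token of each header), in file order.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs <- as.character(ss)
  out <- vapply(seq_along(seqs), function(i) validate_seq(seqs[i], ids[i]),
                character(1))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

seq_chars <- function(seq) strsplit(validate_seq(seq), "")[[1]]

charge_vector <- function(chars) {
  q <- numeric(length(chars))
  q[chars %in% c("R", "K")] <- 1
  q[chars %in% c("D", "E")] <- -1
  q
}

#' Residue-class fractions and mean hydropathy
#'
#' @param seq Amino-acid sequence (single string).
#' @param scale Hydropathy scale, see [hydropathy_scale()].
#' @return Named list: one fraction per class in `AA_CLASSES` plus
#'   `mean_hydropathy`.
#' @export
compute_fractions <- function(seq, scale = "kd_norm") {
  chars <- seq_chars(seq)
  h <- hydropathy_scale(scale)
  fr <- lapply(AA_CLASSES, function(cls) mean(chars %in% cls))
  c(fr, list(mean_hydropathy = mean(h[chars])))
}

#' Net and total charge per residue
#'
#' NCPR = (n_pos - n_neg)/L, FCR = (n_pos + n_neg)/L, with R/K positive and
#' D/E negative (histidine uncharged).
#'
#' @inheritParams compute_fractions
#' @return Named list with `ncpr` and `fcr`.
#' @export
ncpr_fcr <- function(seq) {
  q <- charge_vector(seq_chars(seq))
  list(ncpr = mean(q), fcr = mean(abs(q)))
}

# Blob-average charge-asymmetry deviation for one blob size g:
# delta(g) = mean over sliding blobs of (sigma_blob - sigma_seq)^2, where
# sigma = (f+ - f-)^2 / (f+ + f-) (0 for an uncharged blob).
delta_blob <- function(q, g) {
  L <- length(q)
  sigma_of <- function(qs) {
    fp <- mean(qs == 1); fm <- mean(qs == -1)
    if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
  }
  sig_seq <- sigma_of(q)
  n <- L - g + 1L
  s <- vapply(seq_len(n), function(i) sigma_of(q[i:(i + g - 1L)]), numeric(1))
  mean((s - sig_seq)^2)
}

# Maximally segregated arrangement of the same composition: all negatives,
# then neutrals, then positives. Deterministic reference for delta_max.
segregated_charges <- function(q) {
  c(rep(-1, sum(q == -1)), rep(0, sum(q == 0)), rep(1, sum(q == 1)))
}

#' Charge-patterning parameter kappa
#'
#' Normalized asymmetry of positive/negative charge patterning: 0 for
#' well-mixed, 1 for maximally segregated charge blocks. Computed as
#' delta/delta_max with delta the blob-level charge-asymmetry deviation
#' averaged over blob sizes 5 and 6, and delta_max evaluated on the
#' deterministic fully segregated arrangement of the same composition.
#'
#' @inheritParams compute_fractions
#' @param blobs Blob sizes to average over (default `c(5, 6)`).
#' @return Kappa in `[0, 1]`, or `NA_real_` when undefined (no charged
#'   residues, all charges of one sign summing to delta_max = 0 is impossible
#'   by construction, or sequence shorter than the largest blob).
#' @export
kappa <- function(seq, blobs = c(5L, 6L)) {
  q <- charge_vector(seq_chars(seq))
  if (all(q == 0)) return(NA_real_)
  if (length(q) < max(blobs)) return(NA_real_)
  qmax <- segregated_charges(q)
  num <- mean(vapply(blobs, function(g) delta_blob(q, g), numeric(1)))
  den <- mean(vapply(blobs, function(g) delta_blob(qmax, g), numeric(1)))
  if (den == 0) return(NA_real_)
  num / den
}

#' Sequence charge decoration (SCD)
#'
#' Distance-weighted sum over charged pairs:
#' SCD = (1/L) * sum_{i<j} q_i q_j (j - i)^(1/2).
#' Negative values indicate alternating (polyampholyte-like) patterns;
#' positive values indicate like-charge blocks.
#'
#' @inheritParams compute_fractions
#' @export
scd <- function(seq) {
  q <- charge_vector(seq_chars(seq))
  L <- length(q)
  if (L < 2L) stop("SCD requires at least 2 residues")
  idx <- which(q != 0)
  if (length(idx) < 2L) return(0)
  total <- 0
  for (a in seq_len(length(idx) - 1L)) {
    i <- idx[a]; rest <- idx[(a + 1L):length(idx)]
    total <- total + q[i] * sum(q[rest] * sqrt(rest - i))
  }
  total / L
}

#' Sequence hydropathy decoration (SHD)
#'
#' SHD = (1/L) * sum_{i<j} (h_i + h_j) / (j - i), with h the per-residue
#' hydropathy on the configured scale (default Kyte-Doolittle rescaled to
#' `[0, 1]`, so SHD >= 0).
#'
#' @inheritParams compute_fractions
#' @export
shd <- function(seq, scale = "kd_norm") {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 2L) stop("SHD requires at least 2 residues")
  h <- unname(hydropathy_scale(scale)[chars])
  total <- 0
  for (i in seq_len(L - 1L)) {
    j <- (i + 1L):L
    total <- total + sum((h[i] + h[j]) / (j - i))
  }
  total / L
}

#' Full feature vector for one sequence
#'
#' @inheritParams compute_fractions
#' @return One-row data.frame with fcr, ncpr, kappa, scd, shd,
#'   mean_hydropathy and the residue-class fractions.
#' @export
sequence_features <- function(seq, scale = "kd_norm") {
  fr <- compute_fractions(seq, scale)
  nf <- ncpr_fcr(seq)
  L <- nchar(validate_seq(seq))
  data.frame(
    length = L,
    fcr = nf$fcr, ncpr = nf$ncpr,
    kappa = kappa(seq),
    scd = if (L >= 2) scd(seq) else NA_real_,
    shd = if (L >= 2) shd(seq, scale) else NA_real_,
    mean_hydropathy = fr$mean_hydropathy,
    frac_aromatic = fr$aromatic, frac_aliphatic = fr$aliphatic,
    frac_polar = fr$polar, frac_proline = fr$proline,
    frac_glycine = fr$glycine, frac_positive = fr$positive,
    frac_negative = fr$negative
  )
}

#' Feature table for many sequences
#'
#' @param seqs Named character vector of sequences (e.g. from
#'   [parse_fasta()]).
#' @inheritParams compute_fractions
#' @return data.frame with an `id` column and one feature row per sequence.
#' @export
feature_table <- function(seqs, scale = "kd_norm") {
  rows <- lapply(seq_along(seqs), function(i) {
    cbind(data.frame(id = if (is.null(names(seqs))) as.character(i)
                          else names(seqs)[i]),
          sequence_features(seqs[[i]], scale))
  })
  do.call(rbind, rows)
}

#' Write a feature table as TSV
#'
#' Undefined kappa values are written as `"."`.
#' @param tab data.frame from [feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(tab, path) {
  out <- tab
  out$kappa <- ifelse(is.na(out$kappa), ".", format(out$kappa, digits = 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
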