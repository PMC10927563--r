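# Conservation of IDR dimensions across homolog sets: MSA reading,
# projection of reference domain boundaries through the alignment, the
# published set/length filters, dispersion statistics and BLOSUM62-based
# MSA similarity scores.

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal format (auto-detected). All rows must
#' have equal length; ungapping any row must yield a valid canonical
#' sequence.
#'
#' @param path Alignment file.
#' @return List of class `msa`: `ids`, `rows` (gapped strings), `width`.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  fmt <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  aln <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = fmt),
                  error = function(e)
                    stop("ragged or malformed alignment in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  rows <- as.character(aln)
  if (length(rows) == 0) stop("empty alignment: ", path)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1)
    stop("ragged alignment rows (widths ", paste(unique(widths), collapse = ", "), ")")
  for (i in seq_along(rows)) {
    ungapped <- gsub("-", "", rows[i])
    if (nchar(ungapped) > 0) validate_seq(ungapped, names(rows)[i])
  }
  structure(list(ids = names(rows), rows = unname(toupper(rows)),
                 width = unname(widths[1])), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids), x$width))
  invisible(x)
}

# Map: ungapped reference position -> alignment column.
ungapped_to_columns <- function(row) {
  chars <- strsplit(row, "")[[1]]
  which(chars != "-")
}

#' Project reference domain boundaries through an MSA
#'
#' The reference protein's folded/IDR segmentation (ungapped coordinates,
#' tiling the full reference) is mapped to alignment columns; each member's
#' homologous IDR is its ungapped residues falling within the IDR column
#' span. Because folded-domain spans are projected as column intervals,
#' member insertions relative to the reference inside an IDR span (columns
#' gapped in the reference) are absorbed into that IDR.
#'
#' @param msa `msa` object.
#' @param reference_id Row id of the reference protein.
#' @param ref_domains data.frame with `start`, `end` (1-based inclusive,
#'   ungapped reference coordinates) and `kind` (`"folded"` or `"idr"`),
#'   tiling the reference without overlap.
#' @return data.frame: `member_id`, `domain_index`, `kind`, `start`, `end`
#'   (member-local ungapped coordinates; 0-length intervals have
#'   `end < start`), `seq`.
#' @export
project_reference_idrs <- function(msa, reference_id, ref_domains) {
  ri <- match(reference_id, msa$ids)
  if (is.na(ri)) stop("reference id '", reference_id, "' absent from MSA")
  ord <- order(ref_domains$start)
  ref_domains <- ref_domains[ord, ]
  reflen <- nchar(gsub("-", "", msa$rows[ri]))
  if (ref_domains$start[1] != 1 || ref_domains$end[nrow(ref_domains)] != reflen ||
      (nrow(ref_domains) > 1 &&
       any(ref_domains$start[-1] != ref_domains$end[-nrow(ref_domains)] + 1)))
    stop("ref_domains must tile the ungapped reference without overlap")
  refcols <- ungapped_to_columns(msa$rows[ri])
  out <- list()
  for (mi in seq_along(msa$ids)) {
    chars <- strsplit(msa$rows[mi], "")[[1]]
    res_cols <- which(chars != "-")
    # member ungapped index per column
    memidx <- integer(msa$width)
    memidx[res_cols] <- seq_along(res_cols)
    for (d in seq_len(nrow(ref_domains))) {
      # column span of this domain: from the column after the previous
      # domain's last reference column through this domain's last
      # reference column (absorbs reference-gap columns between domains)
      col_end <- refcols[ref_domains$end[d]]
      col_start <- if (d == 1) 1L else refcols[ref_domains$end[d - 1]] + 1L
      if (d == nrow(ref_domains)) col_end <- msa$width
      inside <- res_cols[res_cols >= col_start & res_cols <= col_end]
      if (length(inside) == 0) {
        s <- 1L; e <- 0L; sq <- ""
      } else {
        s <- memidx[inside[1]]; e <- memidx[inside[length(inside)]]
        sq <- paste(chars[inside], collapse = "")
      }
      out[[length(out) + 1L]] <- data.frame(
        member_id = msa$ids[mi], domain_index = d,
        kind = ref_domains$kind[d], start = s, end = e, seq = sq)
    }
  }
  do.call(rbind, out)
}

#' Build homolog IDR sets from projected domains
#'
#' @param projected Output of [project_reference_idrs()].
#' @param reference_id Reference member id.
#' @return List of homolog IDR sets, one per IDR domain: each a list with
#'   `set_id`, `reference_id`, `members` (data.frame id, seq, length).
#' @export
homolog_idr_sets <- function(projected, reference_id) {
  idr_idx <- unique(projected$domain_index[projected$kind == "idr"])
  lapply(idr_idx, function(d) {
    sub <- projected[projected$domain_index == d & projected$kind == "idr", ]
    list(set_id = paste0("idr_", d), reference_id = reference_id,
         members = data.frame(id = sub$member_id, seq = sub$seq,
                              length = nchar(sub$seq)))
  })
}

#' Filter homolog IDR sets
#'
#' Applies, in order: drop sets whose reference IDR copy is shorter than
#' `min_ref_len` (default 40); drop individual members shorter than
#' `min_member_len` (default 15); keep only sets retaining more than
#' `min_members` members (default 10, strict) including the reference.
#'
#' @param sets List from [homolog_idr_sets()].
#' @param min_ref_len,min_member_len,min_members Filter parameters.
#' @return Filtered list; a per-set log in `attr(, "filter_log")`.
#' @export
filter_homolog_sets <- function(sets, min_ref_len = 40L,
                                min_member_len = 15L, min_members = 10L) {
  log <- list(); kept <- list()
  for (s in sets) {
    ref_row <- s$members[s$members$id == s$reference_id, ]
    if (nrow(ref_row) == 0 || ref_row$length[1] < min_ref_len) {
      log[[length(log) + 1L]] <- data.frame(
        set_id = s$set_id, action = "dropped",
        reason = sprintf("reference IDR %s residues < %d",
                         if (nrow(ref_row)) ref_row$length[1] else "absent",
                         min_ref_len))
      next
    }
    before <- nrow(s$members)
    s$members <- s$members[s$members$length >= min_member_len, ]
    n_dropped <- before - nrow(s$members)
    if (nrow(s$members) <= min_members ||
        !s$reference_id %in% s$members$id) {
      log[[length(log) + 1L]] <- data.frame(
        set_id = s$set_id, action = "dropped",
        reason = sprintf("%d members after length filter (need > %d with reference)",
                         nrow(s$members), min_members))
      next
    }
    log[[length(log) + 1L]] <- data.frame(
      set_id = s$set_id, action = "kept",
      reason = sprintf("%d members (%d short members removed)",
                       nrow(s$members), n_dropped))
    kept[[length(kept) + 1L]] <- s
  }
  attr(kept, "filter_log") <- do.call(rbind, log)
  kept
}

#' Dispersion statistics for one homolog IDR set
#'
#' Sample (n-1) standard deviation of member lengths and of estimated Re
#' across the set, plus the mean Re and the Gaussian-chain null Re
#' evaluated at each member length (the length-driven expectation a
#' "buffered" set would deviate from).
#'
#' @param set One homolog IDR set (list with `members`).
#' @param estimator Function(sequence) -> Re (A).
#' @param b_eff Null-model segment length.
#' @return List of class `conservation_stats`: `n`, `sd_length`, `sd_re`,
#'   `mean_re`, `null_re` (per member).
#' @export
conservation_stats <- function(set, estimator, b_eff = 3.81) {
  m <- set$members
  if (nrow(m) < 2) stop("need at least 2 members")
  re <- vapply(m$seq, estimator, numeric(1), USE.NAMES = FALSE)
  structure(list(
    set_id = set$set_id, n = nrow(m),
    sd_length = stats::sd(m$length), sd_re = stats::sd(re),
    mean_re = mean(re),
    null_re = vapply(m$length, function(L) afrc_reference(max(L, 2), b_eff)$re_null,
                     numeric(1))
  ), class = "conservation_stats")
}

#' @export
print.conservation_stats <- function(x, ...) {
  cat(sprintf("%s: n = %d, sd(length) = %.2f residues, sd(Re) = %.2f A (mean Re %.2f A)\n",
              x$set_id, x$n, x$sd_length, x$sd_re, x$mean_re))
  invisible(x)
}

#' Load a substitution matrix in NCBI text layout
#'
#' @param path Matrix file; default is the shipped BLOSUM62.
#' @return Square integer matrix with residue dimnames.
#' @export
load_substitution_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "BLOSUM62.txt", package = "idrsim",
                        mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]),
                  numeric(length(header))))
  rownames(mat) <- vapply(rows, `[`, character(1), 1)
  colnames(mat) <- header
  if (!isTRUE(all.equal(unname(mat), unname(t(mat)))))
    stop("substitution matrix is not symmetric")
  mat
}

#' MSA similarity: normalized SumOfPairs and StarScore
#'
#' SumOfPairs: per column, the substitution score summed over all unordered
#' row pairs. StarScore: per column, the score of the most common residue
#' (consensus; ties broken alphabetically) against every row. Column scores
#' are summed over the alignment, then divided by the number of rows and by
#' the alignment length. Pairs involving a gap contribute 0 and gap-majority
#' columns still count toward the length normalization.
#'
#' @param msa `msa` object with >= 2 rows.
#' @param matrix Substitution matrix (default: shipped BLOSUM62).
#' @return List: `sum_of_pairs_norm`, `star_score_norm`, and the
#'   unnormalized totals `sum_of_pairs`, `star_score`.
#' @export
msa_similarity <- function(msa, matrix = NULL) {
  if (length(msa$ids) < 2) stop("need at least 2 aligned sequences")
  if (is.null(matrix)) matrix <- load_substitution_matrix()
  rows <- do.call(rbind, strsplit(msa$rows, ""))
  n <- nrow(rows); L <- ncol(rows)
  sop <- 0; star <- 0
  score <- function(a, b) {
    if (a == "-" || b == "-") return(0)
    matrix[a, b]
  }
  for (col in seq_len(L)) {
    cc <- rows[, col]
    res <- cc[cc != "-"]
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      sop <- sop + score(cc[i], cc[j])
    if (length(res) > 0) {
      tab <- table(res)
      consensus <- sort(names(tab)[tab == max(tab)])[1]
      for (i in seq_len(n)) star <- star + score(consensus, cc[i])
    }
  }
  list(sum_of_pairs = sop, star_score = star,
       sum_of_pairs_norm = sop / (n * L), star_score_norm = star / (n * L))
}

#' Conservation table across a directory of homolog MSAs
#'
#' Convenience wrapper reproducing the per-set output table: one row per
#' retained IDR set with member count, length and Re dispersion, and the
#' two MSA similarity scores of the whole alignment.
#'
#' @param msa_paths Character vector of alignment files.
#' @param reference_ids Reference id per alignment.
#' @param domains_list List of `ref_domains` data.frames per alignment.
#' @param estimator Function(sequence) -> Re (A).
#' @return data.frame: set_id, n, sd_length, sd_re, sop_norm, star_norm.
#' @export
homolog_conservation_table <- function(msa_paths, reference_ids,
                                       domains_list, estimator) {
  out <- list()
  for (i in seq_along(msa_paths)) {
    msa <- read_msa(msa_paths[i])
    proj <- project_reference_idrs(msa, reference_ids[i], domains_list[[i]])
    sets <- filter_homolog_sets(homolog_idr_sets(proj, reference_ids[i]))
    sim <- msa_similarity(msa)
    for (s in sets) {
      cs <- conservation_stats(s, estimator)
      out[[length(out) + 1L]] <- data.frame(
        msa = basename(msa_paths[i]), set_id = s$set_id, n = cs$n,
        sd_length = cs$sd_length, sd_re = cs$sd_re,
        sop_norm = sim$sum_of_pairs_norm, star_norm = sim$star_score_norm)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
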