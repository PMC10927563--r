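# Proteome-scale IDR informatics: sliding-window normalized-Re profiles,
# quantile-tail subregion calling, amino-acid enrichment, and the apparent
# Rg-vs-length scaling fit.

#' Load IDR annotations against a protein FASTA
#'
#' The TSV must have columns `protein_id`, `start`, `end` (1-based
#' inclusive coordinates into the FASTA sequences). IDR substrings are
#' extracted and a length filter (default keep 35-3000 residues) is
#' applied; filtered rows are reported in the `rejected` attribute.
#'
#' @param fasta Path to protein FASTA.
#' @param tsv Path to annotation TSV.
#' @param min_len,max_len Length filter bounds (inclusive).
#' @return data.frame: `protein_id`, `start`, `end`, `seq`; rejected rows in
#'   `attr(, "rejected")`.
#' @export
load_idr_annotations <- function(fasta, tsv, min_len = 35L, max_len = 3000L) {
  seqs <- parse_fasta(fasta)
  ann <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  out <- list(); rejected <- list()
  for (r in seq_len(nrow(ann))) {
    pid <- ann$protein_id[r]; s <- ann$start[r]; e <- ann$end[r]
    if (!pid %in% names(seqs))
      stop("row ", r, ": protein '", pid, "' not in FASTA")
    L <- nchar(seqs[[pid]])
    if (s < 1 || e > L || s > e)
      stop("row ", r, ": coordinates (", s, ",", e, ") out of bounds for '",
           pid, "' (length ", L, ")")
    idr_len <- e - s + 1L
    if (idr_len < min_len || idr_len > max_len) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        protein_id = pid, start = s, end = e, length = idr_len)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      protein_id = pid, start = s, end = e,
      seq = substr(seqs[[pid]], s, e))
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(protein_id = character(), start = integer(),
                         end = integer(), seq = character())
  attr(res, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else NULL
  res
}

#' Sliding-window normalized end-to-end profile
#'
#' For every window of `w` residues the estimator's Re is divided by the
#' Gaussian-chain null Re of a `w`-mer, giving a local normalized
#' end-to-end distance. IDRs shorter than the window give an empty profile
#' with a warning.
#'
#' @param idr One row of [load_idr_annotations()] output, or a list with
#'   `protein_id`, `start`, `seq`.
#' @param estimator Function(sequence) -> Re in A.
#' @param w Window size, residues (default 51).
#' @param b_eff Null-model segment length, see [afrc_reference()].
#' @return data.frame: `protein_id`, `window_start` (protein coordinates),
#'   `value`.
#' @export
window_profile <- function(idr, estimator, w = 51L, b_eff = 3.81) {
  seq <- idr$seq; L <- nchar(seq)
  if (L < w) {
    warning("IDR shorter than window (", L, " < ", w, "); empty profile")
    return(data.frame(protein_id = character(), window_start = integer(),
                      value = numeric()))
  }
  null_re <- afrc_reference(w, b_eff)$re_null
  starts <- seq_len(L - w + 1L)
  vals <- vapply(starts, function(i)
    estimator(substr(seq, i, i + w - 1L)) / null_re, numeric(1))
  data.frame(protein_id = idr$protein_id,
             window_start = idr$start + starts - 1L, value = vals)
}

#' Call compact/expanded subregions from pooled window profiles
#'
#' Thresholds are the empirical `q` and `1 - q` order-statistic quantiles
#' (type 1, inverse CDF) of the pooled window values; windows strictly
#' below the lower threshold are `compact`, strictly above the upper
#' threshold `expanded` (ties at a threshold are unlabeled, which makes the
#' tail counts exact). Per-protein counts are reported with a
#' ">= min_count per protein" filter (default 10).
#'
#' @param profiles data.frame of pooled window rows (rbind of
#'   [window_profile()] outputs).
#' @param q Tail fraction (default 0.025).
#' @param min_count Per-protein subregion count filter.
#' @return List: `thresholds` (lower, upper), `calls` (protein_id,
#'   window_start, label, value), `protein_counts` (per protein and label,
#'   with `passes_filter`).
#' @export
call_subregions <- function(profiles, q = 0.025, min_count = 10L) {
  v <- profiles$value
  n <- length(v)
  if (n < 1 / q)
    stop("need at least ", ceiling(1 / q), " pooled windows")
  # order-statistic thresholds: with k = floor(n*q), the lower threshold is
  # the (k+1)-th smallest value, so strictly-below labeling marks exactly k
  # windows when values are distinct (ties shrink the tail, never grow it)
  k <- floor(n * q)
  srt <- sort(v)
  lo <- srt[k + 1]
  hi <- srt[n - k]
  lab <- ifelse(v < lo, "compact", ifelse(v > hi, "expanded", NA))
  calls <- profiles[!is.na(lab), c("protein_id", "window_start", "value")]
  calls$label <- lab[!is.na(lab)]
  if (nrow(calls) > 0) {
    counts <- as.data.frame(table(protein_id = calls$protein_id,
                                  label = calls$label),
                            stringsAsFactors = FALSE)
    names(counts)[3] <- "n_windows"
    counts <- counts[counts$n_windows > 0, ]
    counts$passes_filter <- counts$n_windows >= min_count
  } else {
    counts <- data.frame(protein_id = character(), label = character(),
                         n_windows = integer(), passes_filter = logical())
  }
  list(thresholds = c(lower = lo, upper = hi), calls = calls,
       protein_counts = counts)
}

#' Merge contiguous called windows into maximal runs
#'
#' Optional post-process: overlapping/adjacent windows of the same label in
#' the same protein are merged into maximal subregion runs.
#'
#' @param calls `calls` data.frame from [call_subregions()].
#' @param w Window size used to build the profiles.
#' @return data.frame: `protein_id`, `start`, `end`, `label`, `n_windows`.
#' @export
merge_subregions <- function(calls, w = 51L) {
  if (nrow(calls) == 0)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), label = character(),
                      n_windows = integer()))
  out <- list()
  for (key in unique(paste(calls$protein_id, calls$label))) {
    sub <- calls[paste(calls$protein_id, calls$label) == key, ]
    sub <- sub[order(sub$window_start), ]
    run_start <- sub$window_start[1]; prev <- sub$window_start[1]; nwin <- 1L
    flush <- function(s, p, nw) data.frame(
      protein_id = sub$protein_id[1], start = s, end = p + w - 1L,
      label = sub$label[1], n_windows = nw)
    for (i in seq_len(nrow(sub))[-1]) {
      cur <- sub$window_start[i]
      if (cur <= prev + w) { prev <- cur; nwin <- nwin + 1L }
      else {
        out[[length(out) + 1L]] <- flush(run_start, prev, nwin)
        run_start <- cur; prev <- cur; nwin <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush(run_start, prev, nwin)
  }
  do.call(rbind, out)
}

#' Amino-acid enrichment of tail windows over background
#'
#' Per residue: log2 of the pseudocounted tail frequency over the
#' pseudocounted background frequency. Identical compositions give 0 for
#' every residue; a residue at twice the background frequency approaches +1
#' as the pseudocount vanishes.
#'
#' @param tail_windows Character vector of tail window sequences.
#' @param all_windows Character vector of background window sequences.
#' @param pseudocount Added per residue class (default 0.5).
#' @return data.frame: `residue`, `log2_enrichment`, for all 20 residues.
#' @export
aa_enrichment <- function(tail_windows, all_windows, pseudocount = 0.5) {
  if (length(tail_windows) == 0 || length(all_windows) == 0)
    stop("both window sets must be non-empty")
  count_aa <- function(ws) {
    chars <- unlist(strsplit(toupper(paste(ws, collapse = "")), ""))
    vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1))
  }
  tc <- count_aa(tail_windows); bc <- count_aa(all_windows)
  tf <- (tc + pseudocount) / (sum(tc) + 20 * pseudocount)
  bf <- (bc + pseudocount) / (sum(bc) + 20 * pseudocount)
  data.frame(residue = AA_ALPHABET,
             log2_enrichment = log2(tf) - log2(bf),
             row.names = NULL)
}

#' Apparent scaling exponent of Rg versus chain length
#'
#' Log-log least-squares fit of Rg against length over a set of (length,
#' Rg) records, the proteome-scale analogue of the single-chain scaling
#' fit. Per-record deviations from the fitted line (positive = more
#' expanded than the trend) are returned.
#'
#' @param records data.frame with columns `length` and `rg`.
#' @return Object of class `scaling_fit` with additional `deviations`
#'   (log-space residuals, one per record).
#' @export
proteome_scaling_fit <- function(records) {
  if (nrow(records) < 10) stop("need at least 10 records")
  span <- max(records$length) / min(records$length)
  if (span < 10) stop("lengths must span at least one decade (span = ",
                      round(span, 2), ")")
  x <- log(records$length); y <- log(records$rg)
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(nu = unname(fit$coefficients[2]),
                 prefactor_r0 = exp(unname(fit$coefficients[1])),
                 residual_norm = sqrt(sum(fit$residuals^2)),
                 n_points = nrow(records),
                 deviations = unname(fit$residuals)),
            class = "scaling_fit")
}

#' Closed-form window estimator for testing and fast scans
#'
#' A simple composition-based Re estimator: Gaussian-chain baseline scaled
#' down with the fraction of aromatic residues and up with the fraction of
#' charged residues (the directions seen in simulated titrations). Not a
#' trained predictor; it satisfies the estimator plugin contract
#' (sequence -> Re in A) for tests and examples.
#'
#' @param seq Sequence.
#' @param b_eff Baseline segment length.
#' @return Re estimate, A.
#' @export
stub_estimator <- function(seq, b_eff = 3.81) {
  fr <- compute_fractions(seq)
  nf <- ncpr_fcr(seq)
  base <- afrc_reference(seq, b_eff)$re_null
  base * (1 - 0.6 * fr$aromatic + 0.35 * nf$fcr)
}

#' Simulator-backed window estimator factory
#'
#' Returns an estimator closure that runs a desk-preset Langevin simulation
#' for each sequence and returns the mean Re. Results are memoized within
#' the closure. Intended for small numbers of windows.
#'
#' @param params `cg_params`.
#' @param config `sim_config` (desk-scale recommended).
#' @param seed Base seed.
#' @return Function(sequence) -> Re (A).
#' @export
simulate_estimator <- function(params, config = NULL, seed = 1L) {
  if (is.null(config)) config <- sim_config("desk", production_ns = 50,
                                            equilibration_ns = 2, seed = seed)
  cache <- new.env()
  function(seq) {
    key <- seq
    if (!is.null(cache[[key]])) return(cache[[key]])
    trajs <- simulate_protocol(seq, params, preset = "desk", seed = seed,
                               config = config)
    val <- ensemble_summary(trajs, fit_min_delta = 5)$mean_re
    cache[[key]] <- val
    val
  }
}
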