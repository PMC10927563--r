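# Synthetic IDR sequence design: composition-constrained random sequences,
# kappa-targeted charge patterning via seeded swap search, feature titration
# libraries, and sticker-spacer constructs.

# Disorder-promoting residues used to fill unspecified composition. Designs
# are kept download-free: instead of calling an external disorder predictor,
# the background alphabet is restricted to residues that strongly favor
# disorder; `disorder_filter` is a plugin hook for an external predictor.
DISORDER_BACKGROUND <- c("G", "S", "T", "N", "Q", "P", "E", "D", "K", "R", "A")

DESIGN_MIN_LEN <- 10L
DESIGN_MAX_LEN <- 750L

check_design_length <- function(length) {
  if (length < DESIGN_MIN_LEN || length > DESIGN_MAX_LEN)
    stop(sprintf("design length must be in [%d, %d], got %d",
                 DESIGN_MIN_LEN, DESIGN_MAX_LEN, length))
  as.integer(length)
}

# Largest-remainder apportionment: counts_i ~ fractions_i * total, summing
# exactly to round(sum(fractions) * total) (equals `total` when the
# fractions sum to 1; any shortfall is the caller's background fill).
largest_remainder_counts <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw + 1e-9)
  rem <- round(sum(raw)) - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Design a sequence with fixed residue composition
#'
#' Residue counts are `round(fraction * length)` by largest-remainder
#' apportionment (counts sum exactly to `length`); any unspecified remainder
#' is filled uniformly from a disorder-promoting background alphabet.
#' Positions are shuffled by a seeded generator, so identical spec + seed
#' gives an identical sequence.
#'
#' @param fractions Named numeric vector, residue -> target fraction;
#'   must sum to at most 1.
#' @param length Sequence length (10-750 residues).
#' @param seed Integer seed.
#' @param background Residues used to fill the unspecified remainder.
#' @param disorder_filter Optional function(seq) -> logical; if supplied,
#'   designs are redrawn (new shuffles) until it returns TRUE (max 100
#'   attempts).
#' @return Single character string.
#' @export
design_by_composition <- function(fractions, length, seed,
                                  background = DISORDER_BACKGROUND,
                                  disorder_filter = NULL) {
  length <- check_design_length(length)
  if (is.null(names(fractions)) || !all(names(fractions) %in% AA_ALPHABET))
    stop("fractions must be named by canonical residues")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (sum(fractions) > 1 + 1e-9) stop("fractions sum exceeds 1")
  counts <- largest_remainder_counts(fractions, length)
  names(counts) <- names(fractions)
  n_fill <- length - sum(counts)
  rng <- local_rng(seed)
  chars <- rep(names(counts), counts)
  if (n_fill > 0) {
    # deterministic uniform fill so that composition depends only on the
    # spec, never on the seed (the seed only shuffles positions)
    if (base::length(background) == 0) stop("empty background alphabet")
    bg_counts <- largest_remainder_counts(
      rep(1 / base::length(background), base::length(background)), n_fill)
    chars <- c(chars, rep(background, bg_counts))
  }
  for (attempt in seq_len(100L)) {
    seq <- paste(rng$sample(chars, base::length(chars)), collapse = "")
    if (is.null(disorder_filter) || isTRUE(disorder_filter(seq))) return(seq)
  }
  stop("disorder_filter rejected 100 consecutive designs")
}

# Seeded RNG scoped to one design call; does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample = function(x, size, replace = FALSE)
      with_state(function() sample(x, size, replace = replace)),
    runif = function(n) with_state(function() stats::runif(n)),
    sample_int = function(n, size) with_state(function() sample.int(n, size))
  )
}

#' Design a sequence with a target kappa
#'
#' Starts from a composition design and performs a seeded stochastic
#' position-swap search (greedy pair swaps accepting moves toward the
#' target) until `|kappa - target| <= tolerance` or the swap budget is
#' exhausted. Composition is unchanged by construction. For `target = 1`
#' the maximally segregated arrangement is returned in closed form.
#'
#' @param composition Named fractions, must include charged residues.
#' @param target_kappa Target in `[0, 1]`.
#' @param tolerance Accept window around the target.
#' @param length Sequence length.
#' @param seed Integer seed.
#' @param max_swaps Swap budget (default 1e5).
#' @return Character string whose kappa is within tolerance of target.
#' @export
design_by_kappa <- function(composition, target_kappa, tolerance = 0.02,
                            length, seed, max_swaps = 1e5) {
  if (target_kappa < 0 || target_kappa > 1) stop("target_kappa must be in [0, 1]")
  seq0 <- design_by_composition(composition, length, seed)
  chars <- strsplit(seq0, "")[[1]]
  q <- charge_vector(chars)
  if (all(q == 0)) stop("composition contains no charged residues; kappa undefined")
  if (base::length(chars) < 6L) stop("sequence too short for kappa")

  if (target_kappa >= 1 - 1e-12) {
    # closed form: all negatives, then neutrals, then positives
    ord <- order(q)  # -1 first, then 0, then +1 (stable)
    return(paste(chars[ord], collapse = ""))
  }

  k_of <- function(ch) kappa(paste(ch, collapse = ""))
  cur <- k_of(chars)
  if (is.na(cur)) stop("kappa undefined for designed composition")
  rng <- local_rng(seed + 1L)
  best <- cur; best_chars <- chars
  n <- base::length(chars)
  swaps_done <- 0
  while (abs(cur - target_kappa) > tolerance && swaps_done < max_swaps) {
    ij <- rng$sample_int(n, 2L)
    if (chars[ij[1]] == chars[ij[2]]) { swaps_done <- swaps_done + 1; next }
    cand <- chars
    cand[ij] <- cand[rev(ij)]
    k_new <- k_of(cand)
    if (!is.na(k_new) && abs(k_new - target_kappa) < abs(cur - target_kappa)) {
      chars <- cand; cur <- k_new
      if (abs(cur - target_kappa) < abs(best - target_kappa)) {
        best <- cur; best_chars <- chars
      }
    }
    swaps_done <- swaps_done + 1
  }
  if (abs(cur - target_kappa) > tolerance)
    stop(sprintf("kappa target %.3f unreachable within %d swaps; best achieved %.4f",
                 target_kappa, as.integer(max_swaps), best))
  paste(chars, collapse = "")
}

#' Titration library along one sequence-feature axis
#'
#' Generates `n_per_value` independent sequences (distinct seeds) at each
#' requested feature value, holding length fixed. The defaults (100
#' sequences per value, length 100) match the library design used for
#' feature-titration experiments.
#'
#' @param feature One of `"ncpr"`, `"fcr"`, `"kappa"`, `"hydropathy"`, or
#'   `"composition"` (for `"composition"` each value must be a named
#'   fraction map).
#' @param values Numeric vector of target values (or list of fraction maps).
#' @param n_per_value Sequences per value (default 100).
#' @param length Sequence length (default 100).
#' @param seed Base seed; per-record seeds are derived deterministically.
#' @param tolerance Per-record accept window on the achieved feature.
#' @return List with `records` (named character vector) and `provenance`
#'   (data.frame: id, feature, target, achieved, seed); per-value failures
#'   are collected in `failures` and do not abort the series.
#' @export
design_titration_series <- function(feature, values, n_per_value = 100L,
                                    length = 100L, seed = 1L,
                                    tolerance = 0.02) {
  feature <- match.arg(feature,
    c("ncpr", "fcr", "kappa", "hydropathy", "composition"))
  if (n_per_value < 1L) stop("n_per_value must be >= 1")
  records <- character(0); prov <- list(); failures <- list()
  rec_i <- 0L
  for (vi in seq_along(values)) {
    val <- if (is.list(values)) values[[vi]] else values[vi]
    for (ri in seq_len(n_per_value)) {
      rec_i <- rec_i + 1L
      rec_seed <- seed * 10000L + rec_i
      id <- sprintf("%s_%03d_%03d", feature, vi, ri)
      res <- tryCatch({
        s <- design_for_feature(feature, val, length, rec_seed, tolerance)
        ach <- achieved_feature(feature, s)
        if (feature != "composition" && abs(ach - val) > tolerance + 1e-9)
          stop(sprintf("achieved %.4f vs target %.4f", ach, val))
        list(seq = s, achieved = ach)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[base::length(failures) + 1L]] <-
          data.frame(id = id, target = if (is.numeric(val)) val else NA_real_,
                     message = conditionMessage(res))
      } else {
        records[[id]] <- res$seq
        prov[[base::length(prov) + 1L]] <- data.frame(
          id = id, feature = feature,
          target = if (is.numeric(val)) val else NA_real_,
          achieved = res$achieved, seed = rec_seed)
      }
    }
  }
  list(records = records,
       provenance = if (base::length(prov)) do.call(rbind, prov) else NULL,
       failures = if (base::length(failures)) do.call(rbind, failures) else NULL)
}

# One designed sequence at a single feature value.
design_for_feature <- function(feature, value, length, seed, tolerance) {
  switch(feature,
    composition = design_by_composition(value, length, seed),
    ncpr = {
      if (abs(value) > 1) stop("ncpr must be in [-1, 1]")
      # fixed total charge fraction 0.5 unless |ncpr| requires more
      fcr <- max(0.5, abs(value))
      fp <- (fcr + value) / 2; fm <- (fcr - value) / 2
      design_by_composition(c(K = fp, E = fm), length, seed,
                            background = setdiff(DISORDER_BACKGROUND,
                                                 c("E", "D", "K", "R")))
    },
    fcr = {
      if (value < 0 || value > 1) stop("fcr must be in [0, 1]")
      design_by_composition(c(K = value / 2, E = value / 2), length, seed,
                            background = setdiff(DISORDER_BACKGROUND,
                                                 c("E", "D", "K", "R")))
    },
    kappa = design_by_kappa(c(K = 0.25, E = 0.25, G = 0.25, S = 0.25),
                            value, tolerance, length, seed),
    hydropathy = design_by_hydropathy(value, length, seed, tolerance)
  )
}

# Mean-hydropathy targeting: mix of a low-hydropathy and a high-hydropathy
# disorder-compatible residue, interpolated to hit the target mean on the
# normalized Kyte-Doolittle scale.
design_by_hydropathy <- function(target, length, seed, tolerance) {
  h <- hydropathy_scale("kd_norm")
  lo <- "Q"; hi <- "A"   # 0.111 and 0.7 on the normalized scale
  if (target < h[lo] - tolerance || target > h[hi] + tolerance)
    stop(sprintf("mean hydropathy %.3f outside reachable range [%.3f, %.3f]",
                 target, h[lo], h[hi]))
  f_hi <- (target - h[lo]) / (h[hi] - h[lo])
  f_hi <- min(max(f_hi, 0), 1)
  design_by_composition(stats::setNames(c(f_hi, 1 - f_hi), c(hi, lo)),
                        length, seed, background = c(lo, hi))
}

achieved_feature <- function(feature, seq) {
  switch(feature,
    composition = NA_real_,
    ncpr = ncpr_fcr(seq)$ncpr,
    fcr = ncpr_fcr(seq)$fcr,
    kappa = kappa(seq),
    hydropathy = compute_fractions(seq)$mean_hydropathy
  )
}

#' Sticker-spacer construct
#'
#' Concatenates `n_repeats` blocks of a glycine-serine spacer followed by a
#' polytyrosine sticker: block = ("GS" x spacer_len/2) + ("Y" x sticker_len).
#' Total length = n_repeats * (spacer_len + sticker_len).
#'
#' @param n_repeats Number of sticker-spacer repeats (default 8).
#' @param spacer_len Spacer length in residues; must be even, 2-120.
#' @param sticker_len Tyrosines per sticker, 0-8.
#' @return Character string.
#' @export
build_sticker_spacer <- function(n_repeats = 8L, spacer_len, sticker_len) {
  if (spacer_len %% 2 != 0) stop("spacer_len must be even (GS dipeptide repeats)")
  if (spacer_len < 2 || spacer_len > 120) stop("spacer_len must be in [2, 120]")
  if (sticker_len < 0 || sticker_len > 8) stop("sticker_len must be in [0, 8]")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  block <- paste0(strrep("GS", spacer_len / 2), strrep("Y", sticker_len))
  strrep(block, n_repeats)
}

#' Write a design library to FASTA plus a provenance TSV
#'
#' @param library List from [design_titration_series()].
#' @param fasta_path,prov_path Output paths.
#' @export
write_library <- function(library, fasta_path, prov_path) {
  write_fasta(library$records, fasta_path)
  utils::write.table(library$provenance, prov_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
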