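# Homolog conservation: MSA I/O, boundary projection, filters, dispersion
# statistics, BLOSUM62 similarity scores.

write_fasta_msa <- function(rows, dir) {
  path <- file.path(dir, "aln.fasta")
  writeLines(unlist(lapply(names(rows), function(id) c(paste0(">", id), rows[[id]]))),
             path)
  path
}

write_clustal_msa <- function(rows, dir) {
  path <- file.path(dir, "aln.aln")
  width <- nchar(rows[[1]])
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               paste0(formatC(names(rows), width = 12, flag = "-"), rows),
               paste0(strrep(" ", 12), strrep(" ", width)), ""),
             path)
  path
}

test_that("aligned FASTA and Clustal encodings parse identically; ragged rows fail", {
  rows <- c(s1 = "MKV-AYEGSP", s2 = "MKVQAYEGSP", s3 = "MKV--YEGSP")
  dir <- withr::local_tempdir()
  m1 <- read_msa(write_fasta_msa(rows, dir))
  m2 <- read_msa(write_clustal_msa(rows, dir))
  expect_equal(m1$rows, m2$rows)
  expect_equal(m1$ids, m2$ids)
  expect_equal(m1$width, 10)

  bad <- c(s1 = "MKVAYEGSPQ", s2 = "MKVAYEGSP")
  expect_error(read_msa(write_fasta_msa(bad, dir)), "ragged|different number|nchar")
})

test_that("gapless identical MSA projects reference intervals verbatim", {
  rows <- c(ref = "MKVAYEGSPQRT", h1 = "MKVAYEGSPQRT", h2 = "MKVAYEGSPQRT")
  dir <- withr::local_tempdir()
  msa <- read_msa(write_fasta_msa(rows, dir))
  dom <- data.frame(start = c(1, 5), end = c(4, 12),
                    kind = c("folded", "idr"))
  proj <- project_reference_idrs(msa, "ref", dom)
  idr <- proj[proj$kind == "idr", ]
  expect_equal(idr$start, rep(5L, 3))
  expect_equal(idr$end, rep(12L, 3))
  expect_equal(unique(idr$seq), "YEGSPQRT")
})

test_that("member insertions inside an IDR span are absorbed into the member IDR", {
  # reference has a 5-column gap inside the IDR where h1 carries residues
  rows <- c(ref = "MKVA-----GSPQ", h1 = "MKVAEEEEEGSPQ")
  dir <- withr::local_tempdir()
  msa <- read_msa(write_fasta_msa(rows, dir))
  dom <- data.frame(start = c(1, 4), end = c(3, 8),
                    kind = c("folded", "idr"))
  proj <- project_reference_idrs(msa, "ref", dom)
  idr <- proj[proj$kind == "idr", ]
  ref_len <- nchar(idr$seq[idr$member_id == "ref"])
  h1_len <- nchar(idr$seq[idr$member_id == "h1"])
  expect_equal(h1_len, ref_len + 5)

  # member fully gapped across an IDR span gives an empty member IDR
  rows2 <- c(ref = "MKVAYEGS", h2 = "MKV-----")
  msa2 <- read_msa(write_fasta_msa(rows2, dir))
  dom2 <- data.frame(start = c(1, 4), end = c(3, 8),
                     kind = c("folded", "idr"))
  proj2 <- project_reference_idrs(msa2, "ref", dom2)
  expect_equal(proj2$seq[proj2$kind == "idr" & proj2$member_id == "h2"], "")

  expect_error(project_reference_idrs(msa2, "nope", dom2), "absent")
})

test_that("projection conserves residues: segments concatenate to the full sequence", {
  rows <- c(ref = "MKV--AYEGSPQRTAE", h1 = "MKVDDAYE--PQRTAE",
            h2 = "M-VDDAYEGSPQ--AE")
  dir <- withr::local_tempdir()
  msa <- read_msa(write_fasta_msa(rows, dir))
  dom <- data.frame(start = c(1, 4, 10), end = c(3, 9, 14),
                    kind = c("folded", "idr", "folded"))
  proj <- project_reference_idrs(msa, "ref", dom)
  for (id in msa$ids) {
    segs <- proj[proj$member_id == id, ]
    segs <- segs[order(segs$domain_index), ]
    expect_equal(paste(segs$seq, collapse = ""),
                 gsub("-", "", rows[[id]]))
  }
})

make_set <- function(lengths, ref_len = 60, n_extra = 0) {
  ids <- c("ref", paste0("h", seq_along(lengths)))
  lens <- c(ref_len, lengths)
  list(set_id = "s", reference_id = "ref",
       members = data.frame(id = ids,
                            seq = vapply(lens, function(L)
                              if (L > 0) strrep("G", L) else "", character(1)),
                            length = lens))
}

test_that("homolog filters implement the 40/15/>10 rules", {
  # set with exactly 10 surviving members is dropped (strict > 10)
  s10 <- make_set(rep(50, 9))   # ref + 9 = 10 members
  expect_length(filter_homolog_sets(list(s10)), 0)

  s11 <- make_set(rep(50, 10))  # 11 members
  expect_length(filter_homolog_sets(list(s11)), 1)

  # reference IDR of 39 residues: whole set omitted
  s39 <- make_set(rep(50, 12), ref_len = 39)
  expect_length(filter_homolog_sets(list(s39)), 0)

  # member of 14 residues dropped, set retained while still > 10
  s14 <- make_set(c(rep(50, 11), 14))
  kept <- filter_homolog_sets(list(s14))
  expect_length(kept, 1)
  expect_equal(nrow(kept[[1]]$members), 12)  # 13 - 1 short member
  expect_false(any(kept[[1]]$members$length < 15))
  lg <- attr(kept, "filter_log")
  expect_true(any(grepl("1 short", lg$reason)))
})

test_that("conservation statistics use sample s.d. over lengths and estimated Re", {
  s <- make_set(c(60, 60))
  est_const <- function(sq) 42
  cs <- conservation_stats(s, est_const)
  expect_equal(cs$sd_length, 0)
  expect_equal(cs$sd_re, 0)

  s2 <- list(set_id = "t", reference_id = "a",
             members = data.frame(id = c("a", "b"),
                                  seq = c(strrep("G", 100), strrep("G", 102)),
                                  length = c(100, 102)))
  cs2 <- conservation_stats(s2, function(sq) nchar(sq))
  expect_equal(cs2$sd_length, sqrt(2))
  expect_equal(cs2$sd_re, sqrt(2))
  expect_error(conservation_stats(list(set_id = "u", reference_id = "a",
                                       members = s2$members[1, ]), est_const),
               "at least 2")
})

test_that("conformational buffering contrast: length-invariant estimator lowers sd_re", {
  lens <- withr::with_seed(8, sample(40:120, 12))
  s <- list(set_id = "b", reference_id = "ref",
            members = data.frame(id = c("ref", paste0("h", 1:11)),
                                 seq = vapply(lens, function(L) strrep("G", L),
                                              character(1)),
                                 length = lens))
  est_afrc <- function(sq) afrc_reference(nchar(sq))$re_null
  est_buffered <- function(sq) afrc_reference(80)$re_null
  expect_lt(conservation_stats(s, est_buffered)$sd_re,
            conservation_stats(s, est_afrc)$sd_re)
})

test_that("shipped BLOSUM62 fixture matches the Biostrings reference matrix", {
  m <- load_substitution_matrix()
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(m[aa, aa], BLOSUM62[aa, aa])
})

test_that("SumOfPairs and StarScore match definitions and brute-force oracles", {
  dir <- withr::local_tempdir()
  # 2-row single-column alignment A/A: SumOfPairs total = S(A,A) = 4
  m <- read_msa(write_fasta_msa(c(a = "A", b = "A"), dir))
  sim <- msa_similarity(m)
  expect_equal(sim$sum_of_pairs, 4)
  expect_equal(sim$sum_of_pairs_norm, 4 / (2 * 1))

  # identical k-row MSA: star total = k * sum_cols S(a, a)
  rows <- c(r1 = "MKVAY", r2 = "MKVAY", r3 = "MKVAY", r4 = "MKVAY")
  m4 <- read_msa(write_fasta_msa(rows, dir))
  B <- load_substitution_matrix()
  self_sum <- sum(vapply(strsplit("MKVAY", "")[[1]], function(a) B[a, a],
                         numeric(1)))
  expect_equal(msa_similarity(m4)$star_score, 4 * self_sum)

  # brute-force oracle on random gapped toy MSAs
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (sd in 1:4) {
    mat <- withr::with_seed(sd, matrix(sample(c(aa, "-"), 24, replace = TRUE,
                                              prob = c(rep(1, 20), 4)), 4, 6))
    # guarantee no all-gap row
    mat[, 1] <- withr::with_seed(sd + 50, sample(aa, 4, replace = TRUE))
    rows <- apply(mat, 1, paste, collapse = "")
    names(rows) <- paste0("r", 1:4)
    msa <- read_msa(write_fasta_msa(rows, dir))
    sim <- msa_similarity(msa)
    sop <- 0; star <- 0
    sc <- function(a, b) if (a == "-" || b == "-") 0 else B[a, b]
    for (col in 1:6) {
      for (i in 1:3) for (j in (i + 1):4) sop <- sop + sc(mat[i, col], mat[j, col])
      res <- mat[mat[, col] != "-", col]
      if (length(res)) {
        tab <- table(res)
        cons <- sort(names(tab)[tab == max(tab)])[1]
        for (i in 1:4) star <- star + sc(cons, mat[i, col])
      }
    }
    expect_equal(sim$sum_of_pairs, sop)
    expect_equal(sim$star_score, star)
    expect_equal(sim$sum_of_pairs_norm, sop / (4 * 6))

    # row-order invariance
    perm <- rows[c(3, 1, 4, 2)]
    sim_p <- msa_similarity(read_msa(write_fasta_msa(perm, dir)))
    expect_equal(sim_p$sum_of_pairs, sim$sum_of_pairs)
    expect_equal(sim_p$star_score, sim$star_score)
  }
})

test_that("progressively mutating one row strictly lowers both normalized scores", {
  base <- strrep("MKVAYEGSPQ", 2)
  rows <- stats::setNames(rep(base, 5), paste0("r", 1:5))
  dir <- withr::local_tempdir()
  prev <- msa_similarity(read_msa(write_fasta_msa(rows, dir)))
  muts <- c("W", "W", "C", "C", "H")  # low-similarity replacements
  pos <- withr::with_seed(3, sample(nchar(base), 5))
  chars <- strsplit(base, "")[[1]]
  for (step in 1:5) {
    chars[pos[step]] <- muts[step]
    rows["r5"] <- paste(chars, collapse = "")
    cur <- msa_similarity(read_msa(write_fasta_msa(rows, dir)))
    expect_lt(cur$sum_of_pairs_norm, prev$sum_of_pairs_norm)
    expect_lt(cur$star_score_norm, prev$star_score_norm)
    prev <- cur
  }
})

test_that("homolog conservation table wires projection, filters and scoring together", {
  dir <- withr::local_tempdir()
  n <- 12
  rows <- stats::setNames(c(
    paste0(strrep("M", 10), strrep("G", 50)),
    replicate(n - 1, paste0(strrep("M", 10), strrep("G", 50)))),
    c("ref", paste0("h", 1:(n - 1))))
  path <- write_fasta_msa(rows, dir)
  dom <- data.frame(start = c(1, 11), end = c(10, 60),
                    kind = c("folded", "idr"))
  tab <- homolog_conservation_table(path, "ref", list(dom),
                                    estimator = function(s) afrc_reference(nchar(s))$re_null)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n, n)
  expect_equal(tab$sd_length, 0)
  expect_equal(tab$sd_re, 0)
})
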