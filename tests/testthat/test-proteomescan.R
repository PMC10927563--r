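# Sliding-window proteome informatics: annotation loading, window
# profiles, tail calling, enrichment, apparent scaling fit.

make_annotation_fixture <- function(dir) {
  seqs <- c(p1 = strrep("MKVAYEGSPQ", 10),              # 100 residues
            p2 = strrep("GS", 30),                      # 60 residues
            p3 = strrep("EK", 40))                      # 80 residues
  fasta <- file.path(dir, "prot.fasta")
  writeLines(unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]]))),
             fasta)
  tsv <- file.path(dir, "idrs.tsv")
  writeLines(c("protein_id\tstart\tend",
               "p1\t1\t100",
               "p2\t1\t60",
               "p3\t10\t43",   # 34 residues: filtered under defaults
               "p3\t1\t80"),
             tsv)
  list(fasta = fasta, tsv = tsv, seqs = seqs)
}

test_that("IDR annotations are extracted, length-filtered and bounds-checked", {
  dir <- withr::local_tempdir()
  fx <- make_annotation_fixture(dir)
  ann <- load_idr_annotations(fx$fasta, fx$tsv)
  expect_equal(nrow(ann), 3)          # the 34-residue row is filtered out
  expect_equal(attr(ann, "rejected")$length, 34)
  expect_equal(ann$seq[1], fx$seqs[["p1"]])
  expect_equal(nchar(ann$seq), ann$end - ann$start + 1)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("protein_id\tstart\tend", "p1\t50\t10"), bad)
  expect_error(load_idr_annotations(fx$fasta, bad), "row 1")
  writeLines(c("protein_id\tstart\tend", "p2\t1\t61"), bad)
  expect_error(load_idr_annotations(fx$fasta, bad), "out of bounds")
})

test_that("window profiles have L - w + 1 windows and normalize by the null", {
  idr <- list(protein_id = "x", start = 1, seq = strrep("G", 51))
  prof <- window_profile(idr, function(s) 50)
  expect_equal(nrow(prof), 1)

  idr$seq <- strrep("G", 60)
  prof <- window_profile(idr, function(s) 50)
  expect_equal(nrow(prof), 10)
  # constant estimator -> flat profile at const / null_re(51)
  expect_equal(unique(prof$value), 50 / afrc_reference(51)$re_null)

  idr$seq <- strrep("G", 40)
  expect_warning(empty <- window_profile(idr, function(s) 50), "shorter")
  expect_equal(nrow(empty), 0)
})

test_that("window starts shift with the IDR offset but values do not", {
  sq <- paste0(strrep("E", 30), strrep("Y", 21), strrep("G", 30))
  est <- function(s) stub_estimator(s)
  p1 <- window_profile(list(protein_id = "a", start = 1, seq = sq), est)
  p2 <- window_profile(list(protein_id = "a", start = 8, seq = sq), est)
  expect_equal(p2$window_start, p1$window_start + 7)
  expect_equal(p2$value, p1$value)
})

test_that("tail calling labels exactly the 2.5% extremes of 1,000 distinct windows", {
  vals <- withr::with_seed(1, runif(1000))
  profiles <- data.frame(protein_id = rep(sprintf("p%02d", 1:20), each = 50),
                         window_start = rep(1:50, 20), value = vals)
  res <- call_subregions(profiles, q = 0.025)
  expect_equal(sum(res$calls$label == "compact"), 25)
  expect_equal(sum(res$calls$label == "expanded"), 25)
  expect_true(all(res$calls$value[res$calls$label == "compact"] <
                  res$thresholds["lower"]))

  # all-equal values: strict inequality labels nothing
  flat <- profiles; flat$value <- 1
  expect_equal(nrow(call_subregions(flat)$calls), 0)

  expect_error(call_subregions(profiles[1:20, ]), "at least 40")
})

test_that("per-protein counting applies the >= 10 subregion filter", {
  # protein A: 12 compact windows; protein B: 3
  profiles <- data.frame(
    protein_id = c(rep("A", 12), rep("B", 3), rep("bg", 600)),
    window_start = c(1:12, 1:3, 1:600),
    value = c(rep(0.1, 12), rep(0.12, 3), withr::with_seed(2, runif(600, 0.5, 1.5))))
  res <- call_subregions(profiles, q = 0.025)
  ca <- res$protein_counts[res$protein_counts$protein_id == "A" &
                           res$protein_counts$label == "compact", ]
  cb <- res$protein_counts[res$protein_counts$protein_id == "B" &
                           res$protein_counts$label == "compact", ]
  expect_equal(ca$n_windows, 12)
  expect_true(ca$passes_filter)
  expect_false(cb$passes_filter)
})

test_that("merged subregions form maximal runs of overlapping windows", {
  calls <- data.frame(protein_id = "A", window_start = c(1, 4, 7, 200),
                      value = 0.1, label = "compact")
  runs <- merge_subregions(calls, w = 51)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$n_windows, c(3, 1))
  expect_equal(runs$start, c(1, 200))
  expect_equal(runs$end, c(7 + 50, 200 + 50))
})

test_that("amino-acid enrichment matches hand arithmetic and is antisymmetric", {
  # identical compositions -> all zero
  e0 <- aa_enrichment(c("GSGS"), c("SGSG"))
  expect_equal(e0$log2_enrichment, rep(0, 20))

  # Y at twice the background frequency, vanishing pseudocount -> +1
  e1 <- aa_enrichment(c("YYGG"), c("YGGG"), pseudocount = 1e-9)
  expect_equal(e1$log2_enrichment[e1$residue == "Y"], 1, tolerance = 1e-6)

  # worked 2-window toy with pseudocount 0.5, checked by direct arithmetic
  tail_w <- c("YYG", "YGG"); bg_w <- c("GGG", "YGG")
  pc <- 0.5
  tc <- c(Y = 3, G = 3); bc <- c(Y = 1, G = 5)
  hand_y <- log2((tc["Y"] + pc) / (6 + 20 * pc)) - log2((bc["Y"] + pc) / (6 + 20 * pc))
  e2 <- aa_enrichment(tail_w, bg_w, pc)
  expect_equal(e2$log2_enrichment[e2$residue == "Y"], unname(hand_y))

  # swapping tail and background negates every value
  e3 <- aa_enrichment(bg_w, tail_w, pc)
  expect_equal(e3$log2_enrichment, -e2$log2_enrichment)
})

test_that("apparent scaling fit recovers generator exponents", {
  lens <- round(seq(35, 1500, length.out = 60))
  rec <- data.frame(length = lens, rg = 2.5 * lens^0.56)
  fit <- proteome_scaling_fit(rec)
  expect_equal(fit$nu, 0.56, tolerance = 1e-12)
  expect_equal(fit$prefactor_r0, 2.5, tolerance = 1e-10)

  rec2 <- data.frame(length = lens, rg = 4 * lens^0.5)
  expect_equal(proteome_scaling_fit(rec2)$nu, 0.50, tolerance = 1e-12)

  noisy <- rec
  noisy$rg <- noisy$rg * withr::with_seed(5, exp(rnorm(60, 0, 0.01)))
  expect_equal(proteome_scaling_fit(noisy)$nu, 0.56, tolerance = 0.01)
  expect_equal(length(proteome_scaling_fit(noisy)$deviations), 60)

  expect_error(proteome_scaling_fit(rec[1:5, ]), "at least 10")
  narrow <- data.frame(length = seq(100, 160, length.out = 20),
                       rg = 2.5 * seq(100, 160, length.out = 20)^0.56)
  expect_error(proteome_scaling_fit(narrow), "decade")
})

test_that("charged 51-mers score higher normalized Re than aromatic 51-mers", {
  ek <- design_by_composition(c(E = 0.4, K = 0.4), 51, seed = 1,
                              background = c("G", "S"))
  yy <- design_by_composition(c(Y = 0.4), 51, seed = 1,
                              background = c("G", "S"))
  p <- params_fixture()
  est <- simulate_estimator(p, sim_config("desk", production_ns = 20,
                                          equilibration_ns = 2,
                                          save_interval_ns = 0.2, seed = 4))
  expect_gt(est(ek), est(yy))
})
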