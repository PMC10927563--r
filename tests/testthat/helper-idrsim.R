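# Shared fixtures: cached parameter set, random sequences, and an
# independent brute-force energy oracle written directly from the pair
# potential definitions (kept free of the package's C++ path).

params_fixture <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- load_parameter_set("mpipi")
    p
  }
})

random_seq <- function(n, seed, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  withr::with_seed(seed, paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

# O(N^2) reference energy: plain double loop over the R-level scalar
# energy functions, 1-2 exclusions, no minimum image (valid far from the
# box boundary).
oracle_energy <- function(coords, seq, params) {
  chars <- strsplit(seq, "")[[1]]
  n <- nrow(coords)
  pair_key <- function(a, b) paste(min(a, b), max(a, b))
  ptab <- params$pairs
  rownames(ptab) <- paste(pmin(ptab$res_i, ptab$res_j),
                          pmax(ptab$res_i, ptab$res_j))
  e <- 0
  for (i in 1:(n - 1)) {
    r <- sqrt(sum((coords[i, ] - coords[i + 1, ])^2))
    e <- e + bonded_energy(r, params$bond)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j == i + 1) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    pp <- ptab[pair_key(chars[i], chars[j]), ]
    e <- e + wang_frenkel_energy(r, pp$epsilon, pp$sigma, pp$mu, pp$nu_wf)
    qi <- params$beads[chars[i], "charge"]
    qj <- params$beads[chars[j], "charge"]
    e <- e + debye_huckel_energy(r, qi, qj, params$electro)
  }
  e
}

write_temp_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}
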