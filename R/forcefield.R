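# One-bead-per-residue force field: Wang-Frenkel short-range pair potential,
# Debye-Hueckel screened electrostatics, harmonic bonds. Parameter sets are
# loaded from structured text files and fully validated before use.

# Physical constants (energy kcal/mol, length A, charge e, mass Da)
KB_KCAL <- 0.0019872041          # Boltzmann, kcal/mol/K
COULOMB_K <- 332.06371           # e^2*NA/(4*pi*eps0), kcal*A/mol

#' Load and validate a force-field parameter set
#'
#' Reads a structured-text parameter file with `[meta]`, `[beads]`,
#' `[pairs]`, `[bonds]` and `[electrostatics]` sections (units: A, kcal/mol,
#' Da, e). All 20 bead types and all 210 unordered residue pairs must be
#' present; duplicated pair rows with conflicting values are a symmetry
#' error. Each pair's interaction cutoff is 3 sigma.
#'
#' The builtin name `"mpipi"` resolves to the shipped
#' `params_mpipi_synthetic.prm`: a parameter set with the Mpipi functional
#' form whose pair epsilons are constructed by combination rules from
#' per-residue stickiness values (with cation-pi boosts), not the published
#' pair table; see the file header. `"mpipi-gg"` is a slot for a
#' user-supplied fine-tuned file.
#'
#' @param name_or_path `"mpipi"`, or a path to a parameter file.
#' @return Object of class `cg_params`.
#' @export
load_parameter_set <- function(name_or_path = "mpipi") {
  path <- if (file.exists(name_or_path)) {
    name_or_path
  } else if (name_or_path == "mpipi") {
    system.file("extdata", "params_mpipi_synthetic.prm", package = "idrsim",
                mustWork = TRUE)
  } else if (name_or_path == "mpipi-gg") {
    stop("no mpipi-gg parameter file is shipped; supply a path to your own ",
         "fine-tuned parameter file")
  } else {
    stop("unknown parameter set or missing file: ", name_or_path)
  }
  parse_parameter_file(path)
}

parse_parameter_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  beads <- list(); pairs <- list(); kv <- list(meta = list(), bonds = list(),
                                              electrostatics = list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (is.na(section)) stop("content before first section header in ", path)
    if (section %in% c("meta", "bonds", "electrostatics")) {
      parts <- strsplit(ln, "\\s*=\\s*")[[1]]
      if (length(parts) != 2) stop("bad key-value line: ", ln)
      kv[[section]][[parts[1]]] <- parts[2]
    } else if (section == "beads") {
      p <- strsplit(ln, "\\s+")[[1]]
      if (length(p) != 4) stop("bead line needs 'residue mass charge sigma': ", ln)
      beads[[length(beads) + 1L]] <- data.frame(
        residue = p[1], mass = as.numeric(p[2]), charge = as.numeric(p[3]),
        sigma = as.numeric(p[4]))
    } else if (section == "pairs") {
      p <- strsplit(ln, "\\s+")[[1]]
      if (length(p) != 6) stop("pair line needs 'i j epsilon sigma mu nu': ", ln)
      pairs[[length(pairs) + 1L]] <- data.frame(
        res_i = p[1], res_j = p[2], epsilon = as.numeric(p[3]),
        sigma = as.numeric(p[4]), mu = as.numeric(p[5]),
        nu_wf = as.numeric(p[6]))
    } else stop("unknown section [", section, "]")
  }
  beads <- do.call(rbind, beads)
  pairs <- do.call(rbind, pairs)
  validate_parameter_set(beads, pairs, kv, path)
}

validate_parameter_set <- function(beads, pairs, kv, path) {
  if (is.null(beads) || nrow(beads) == 0) stop("no [beads] section in ", path)
  unknown <- setdiff(beads$residue, AA_ALPHABET)
  if (length(unknown)) stop("unknown residue key(s): ", paste(unknown, collapse = ", "))
  missing_beads <- setdiff(AA_ALPHABET, beads$residue)
  if (length(missing_beads))
    stop("missing bead type(s): ", paste(missing_beads, collapse = ", "))
  if (any(beads$sigma <= 0) || any(beads$mass <= 0))
    stop("bead sigma and mass must be positive")
  if (any(abs(beads$charge) > 1)) stop("bead charges must be in [-1, 1]")

  unknown <- setdiff(c(pairs$res_i, pairs$res_j), AA_ALPHABET)
  if (length(unknown)) stop("unknown residue key(s) in pairs: ",
                            paste(unknown, collapse = ", "))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pk <- key(pairs$res_i, pairs$res_j)
  # duplicated unordered pair with conflicting values -> symmetry error
  if (anyDuplicated(pk)) {
    for (k in unique(pk[duplicated(pk)])) {
      rows <- pairs[pk == k, c("epsilon", "sigma", "mu", "nu_wf")]
      if (nrow(unique(rows)) > 1)
        stop("asymmetric parameters for pair (", k, ")")
    }
    pairs <- pairs[!duplicated(pk), ]
    pk <- key(pairs$res_i, pairs$res_j)
  }
  all_pairs <- outer(AA_ALPHABET, AA_ALPHABET, key)
  need <- unique(all_pairs[upper.tri(all_pairs, diag = TRUE)])
  miss <- setdiff(need, pk)
  if (length(miss))
    stop("missing pair parameter(s): ", paste(head(miss, 10), collapse = "; "),
         if (length(miss) > 10) sprintf(" ... (%d total)", length(miss)) else "")
  if (any(pairs$epsilon < 0)) stop("pair epsilon must be >= 0")

  num <- function(sec, key) {
    v <- kv[[sec]][[key]]
    if (is.null(v)) stop("missing required value '", key, "' in [", sec, "]")
    as.numeric(v)
  }
  version <- kv$meta$version
  if (is.null(version)) version <- "custom"
  if (!version %in% c("mpipi", "mpipi-gg", "custom"))
    stop("version must be one of mpipi, mpipi-gg, custom")
  ps <- structure(list(
    version = version,
    beads = beads[match(AA_ALPHABET, beads$residue), ],
    pairs = pairs,
    bond = list(k = num("bonds", "k"), r0 = num("bonds", "r0")),
    electro = list(
      dielectric = num("electrostatics", "dielectric"),
      ionic_strength = num("electrostatics", "ionic_strength"),
      temperature = num("electrostatics", "temperature"),
      coulomb_cutoff = num("electrostatics", "coulomb_cutoff"))
  ), class = "cg_params")
  if (ps$electro$dielectric <= 0 || ps$electro$ionic_strength < 0)
    stop("non-physical electrostatics parameters")
  rownames(ps$beads) <- ps$beads$residue
  ps
}

#' @export
print.cg_params <- function(x, ...) {
  cat(sprintf("Coarse-grained parameter set '%s'\n", x$version))
  cat(sprintf("  %d bead types, %d pair entries\n", nrow(x$beads), nrow(x$pairs)))
  cat(sprintf("  bond: k = %.3g kcal/mol/A^2, r0 = %.3g A\n", x$bond$k, x$bond$r0))
  cat(sprintf("  electrostatics: dielectric %.3g, I = %.3g M, T = %.4g K, cutoff %.3g A (lambda_D = %.2f A)\n",
              x$electro$dielectric, x$electro$ionic_strength,
              x$electro$temperature, x$electro$coulomb_cutoff,
              debye_length(x$electro$ionic_strength, x$electro$temperature,
                           x$electro$dielectric)))
  invisible(x)
}

#' Debye screening length
#'
#' lambda_D = sqrt(eps0 * eps_r * kB * T / (2 * NA * e^2 * I)), returned
#' in Angstrom. At I = 0.150 M, T = 300 K, eps_r = 80 this is ~7.8 A.
#'
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param dielectric Relative permittivity.
#' @export
debye_length <- function(ionic_strength, temperature = 300,
                         dielectric = 80) {
  if (ionic_strength < 0 || dielectric <= 0 || temperature <= 0)
    stop("non-physical inputs to debye_length")
  if (ionic_strength == 0) return(Inf)
  eps0 <- 8.8541878128e-12; kb <- 1.380649e-23
  na <- 6.02214076e23; e <- 1.602176634e-19
  lam_m <- sqrt(eps0 * dielectric * kb * temperature /
                (2 * na * e^2 * ionic_strength * 1000))
  lam_m * 1e10
}

#' Wang-Frenkel pair energy
#'
#' U(r) = eps * alpha * ((sigma/r)^(2 mu) - 1) * ((rc/r)^(2 mu) - 1)^(2 nu)
#' with rc = 3 sigma and alpha the closed-form normalization that makes the
#' minimum depth exactly -eps. Identically zero for r >= rc.
#'
#' @param r Distance(s), A (> 0).
#' @param epsilon Well depth, kcal/mol.
#' @param sigma Pair size, A.
#' @param mu,nu_wf Dimensionless exponents.
#' @return Energy, kcal/mol.
#' @export
wang_frenkel_energy <- function(r, epsilon, sigma, mu = 2, nu_wf = 1) {
  if (any(r <= 0)) stop("r must be positive")
  rc <- 3 * sigma
  rs <- (rc / sigma)^(2 * mu)
  alpha <- 2 * nu_wf * rs * ((1 + 2 * nu_wf) / (2 * nu_wf * (rs - 1)))^(2 * nu_wf + 1)
  u <- epsilon * alpha * ((sigma / r)^(2 * mu) - 1) * ((rc / r)^(2 * mu) - 1)^(2 * nu_wf)
  ifelse(r >= rc, 0, u)
}

#' Debye-Hueckel pair energy
#'
#' Screened Coulomb interaction truncated and energy-shifted to zero at the
#' Coulomb cutoff: U(r) = K qi qj / (eps_r r) exp(-r/lambda_D) - U(rc).
#'
#' @param r Distance(s), A (> 0).
#' @param qi,qj Charges, e.
#' @param electro List with `dielectric`, `ionic_strength`, `temperature`,
#'   `coulomb_cutoff` (as in a `cg_params` object).
#' @return Energy, kcal/mol.
#' @export
debye_huckel_energy <- function(r, qi, qj, electro) {
  if (any(r <= 0)) stop("r must be positive")
  if (electro$dielectric <= 0 || electro$ionic_strength < 0)
    stop("non-physical electrostatics parameters")
  lam <- debye_length(electro$ionic_strength, electro$temperature,
                      electro$dielectric)
  rc <- electro$coulomb_cutoff
  pref <- COULOMB_K * qi * qj / electro$dielectric
  u <- pref * exp(-r / lam) / r - pref * exp(-rc / lam) / rc
  ifelse(r >= rc | qi * qj == 0, 0, u)
}

#' Harmonic bond energy
#'
#' U(r) = k (r - r0)^2.
#' @param r Bond length(s), A.
#' @param bond List with `k` (kcal/mol/A^2) and `r0` (A).
#' @export
bonded_energy <- function(r, bond) {
  if (any(r <= 0)) stop("r must be positive")
  bond$k * (r - bond$r0)^2
}

# Flattened force-field tables for the C++ engine. `nonbonded = FALSE`
# zeroes pair epsilons and charges (ideal / Gaussian chain limit).
ff_tables <- function(seq, params, box = 500, hard_floor = 1.0,
                      nonbonded = TRUE) {
  chars <- seq_chars(seq)
  type <- match(chars, AA_ALPHABET) - 1L
  nt <- length(AA_ALPHABET)
  eps <- sig <- mu <- nu <- matrix(0, nt, nt)
  idx <- function(res) match(res, AA_ALPHABET)
  for (r in seq_len(nrow(params$pairs))) {
    i <- idx(params$pairs$res_i[r]); j <- idx(params$pairs$res_j[r])
    eps[i, j] <- eps[j, i] <- params$pairs$epsilon[r]
    sig[i, j] <- sig[j, i] <- params$pairs$sigma[r]
    mu[i, j] <- mu[j, i] <- params$pairs$mu[r]
    nu[i, j] <- nu[j, i] <- params$pairs$nu_wf[r]
  }
  charge <- params$beads$charge[type + 1L]
  if (!nonbonded) {
    eps[] <- 0
    charge[] <- 0
  }
  list(type = type, charge = charge, eps = eps, sig = sig, mu = mu, nu = nu,
       bond_k = params$bond$k, bond_r0 = params$bond$r0,
       dielectric = params$electro$dielectric,
       lambda_d = debye_length(params$electro$ionic_strength,
                               params$electro$temperature,
                               params$electro$dielectric),
       coulomb_cutoff = params$electro$coulomb_cutoff,
       box = box, hard_floor = hard_floor)
}

#' Total potential energy and analytic forces of a configuration
#'
#' Sums harmonic bonds and nonbonded pair terms (Wang-Frenkel +
#' Debye-Hueckel) with 1-2 bonded pairs excluded from the nonbonded sum and
#' the minimum-image convention in a cubic box. Forces are the analytic
#' negative gradient; Newton's third law holds pairwise by construction.
#'
#' @param coords N x 3 matrix, A.
#' @param seq Amino-acid sequence of length N.
#' @param params `cg_params` object.
#' @param box Cubic box edge, A (must be at least twice the largest cutoff).
#' @param hard_floor Nonbonded distance (A) below which the configuration is
#'   rejected as overlapping.
#' @return List: `energy` (total, kcal/mol), components `bond`, `wf`,
#'   `elec`, and `forces` (N x 3, kcal/mol/A).
#' @export
total_energy_forces <- function(coords, seq, params, box = 500,
                                hard_floor = 0.5) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  chars <- seq_chars(seq)
  if (nrow(coords) != length(chars))
    stop("coords rows (", nrow(coords), ") != sequence length (", length(chars), ")")
  max_cut <- max(3 * params$pairs$sigma, params$electro$coulomb_cutoff)
  if (box < 2 * max_cut)
    stop("box edge must be at least twice the largest cutoff (", 2 * max_cut, " A)")
  out <- cpp_energy_forces(coords, ff_tables(seq, params, box, hard_floor))
  if (isTRUE(out$overlap))
    stop("overlapping beads (nonbonded distance < ", hard_floor,
         " A); re-minimize the configuration")
  out[c("energy", "bond", "wf", "elec", "forces")]
}
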