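# Energy backends: the MFCC core only needs `evaluate(atoms) -> kcal/mol`.
# The built-in classical pairwise potential exists so that the conjugate-cap
# cancellation can be verified exactly against a brute-force cross-pair sum;
# it makes no force-field claim.

#' Default Lennard-Jones parameter table
#'
#' Generic per-element well depths (kcal/mol) and size parameters (Angstrom)
#' for the built-in pairwise backend. The values are round, force-field-like
#' magnitudes adequate for a verification potential; override freely.
#' @export
DEFAULT_LJ_PARAMS <- list(
  H = c(epsilon = 0.016, sigma = 2.50),
  C = c(epsilon = 0.086, sigma = 3.40),
  N = c(epsilon = 0.170, sigma = 3.25),
  O = c(epsilon = 0.210, sigma = 2.96),
  S = c(epsilon = 0.250, sigma = 3.50)
)

#' Parameters for the built-in pairwise backend
#'
#' @param coulomb_constant Coulomb prefactor in kcal A mol^-1 e^-2.
#' @param relative_dielectric Scalar screening divisor applied to every
#'   Coulomb term. The default of 40 mirrors the implicit-solvent dielectric
#'   used for the quantum single points this backend stands in for.
#' @param lj_params Named list per element of `c(epsilon=, sigma=)`.
#' @param lj_enabled,coulomb_enabled Toggle either term.
#' @return A list of class `"backend_params"`.
#' @export
backend_params <- function(coulomb_constant = 332.0637,
                           relative_dielectric = 40,
                           lj_params = DEFAULT_LJ_PARAMS,
                           lj_enabled = TRUE, coulomb_enabled = TRUE) {
  if (relative_dielectric <= 0) abort("relative_dielectric must be > 0")
  for (el in names(lj_params)) {
    p <- lj_params[[el]]
    if (p[["epsilon"]] < 0 || p[["sigma"]] <= 0) {
      abort("invalid Lennard-Jones parameters: need epsilon >= 0, sigma > 0")
    }
  }
  structure(
    list(
      coulomb_constant = coulomb_constant,
      relative_dielectric = relative_dielectric,
      lj_params = lj_params,
      lj_enabled = lj_enabled,
      coulomb_enabled = coulomb_enabled
    ),
    class = "backend_params"
  )
}

#' Read backend parameters from a YAML file
#'
#' @param path YAML file with any of the fields of [backend_params()];
#'   `lj_params` as a mapping element -> {epsilon, sigma}.
#' @return A `"backend_params"` object.
#' @export
read_backend_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  lj <- DEFAULT_LJ_PARAMS
  if (!is.null(cfg$lj_params)) {
    lj <- map(cfg$lj_params, function(p) {
      c(epsilon = as.numeric(p$epsilon), sigma = as.numeric(p$sigma))
    })
  }
  backend_params(
    coulomb_constant = cfg$coulomb_constant %||% 332.0637,
    relative_dielectric = cfg$relative_dielectric %||% 40,
    lj_params = lj,
    lj_enabled = cfg$lj_enabled %||% TRUE,
    coulomb_enabled = cfg$coulomb_enabled %||% TRUE
  )
}

# pairwise term matrices for a set of atoms; returns total energy
pairwise_sum <- function(coords, charge, element, params,
                         mask = NULL) {
  n <- nrow(coords)
  if (n < 2) {
    return(0)
  }
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  upper <- upper.tri(r)
  if (!is.null(mask)) upper <- upper & mask
  if (any(upper & r == 0)) {
    abort("singularity error: two distinct atoms at identical coordinates")
  }
  e <- 0
  if (params$coulomb_enabled) {
    if (anyNA(charge)) abort("parameter error: atom missing charge")
    qq <- tcrossprod(charge)
    e <- e + sum(params$coulomb_constant * qq[upper] /
      (params$relative_dielectric * r[upper]))
  }
  if (params$lj_enabled) {
    missing <- setdiff(unique(element), names(params$lj_params))
    if (length(missing) > 0) {
      abort(paste0(
        "parameter error: no Lennard-Jones entry for element(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    eps <- map_dbl(element, ~ params$lj_params[[.x]][["epsilon"]])
    sig <- map_dbl(element, ~ params$lj_params[[.x]][["sigma"]])
    # Lorentz-Berthelot combining
    sij <- outer(sig, sig, "+") / 2
    eij <- sqrt(outer(eps, eps))
    sr6 <- (sij[upper] / r[upper])^6
    e <- e + sum(4 * eij[upper] * (sr6^2 - sr6))
  }
  e
}

#' Classical pairwise potential energy of an atom collection
#'
#' Sum over unordered atom pairs of a screened Coulomb term
#' `k q_i q_j / (eps_r r_ij)` and a Lennard-Jones term with Lorentz-Berthelot
#' combining rules (arithmetic-mean sigma, geometric-mean epsilon). No cutoff
#' is applied: the conjugate-cap cancellation this backend verifies is
#' algebraic and a cutoff would break it.
#'
#' @param atoms Atom tibble with `x`, `y`, `z`, `charge`, `element`.
#' @param params A [backend_params()] object.
#' @return Energy in kcal/mol (0 for fewer than two atoms).
#' @export
pairwise_energy <- function(atoms, params = backend_params()) {
  if (nrow(atoms) < 2) {
    return(0)
  }
  pairwise_sum(
    as.matrix(atoms[, c("x", "y", "z")]),
    atoms$charge, atoms$element, params
  )
}

#' Direct cross-pair interaction energy between two groups
#'
#' Brute-force sum of pairwise terms over cross pairs only. For any
#' pairwise-additive potential this equals
#' `pairwise_energy(a + b) - pairwise_energy(a) - pairwise_energy(b)` exactly;
#' it is the oracle against which the conjugate-cap combination is checked.
#'
#' @param group_a,group_b Disjoint atom tibbles.
#' @param params A [backend_params()] object.
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy_direct <- function(group_a, group_b,
                                      params = backend_params()) {
  if (length(intersect(group_a$eleno, group_b$eleno)) > 0) {
    abort("argument error: groups share atom serial numbers")
  }
  na <- nrow(group_a)
  nb <- nrow(group_b)
  if (na == 0 || nb == 0) {
    return(0)
  }
  all <- bind_rows(group_a, group_b)
  idx <- c(rep(1L, na), rep(2L, nb))
  cross <- outer(idx, idx, "!=")
  pairwise_sum(
    as.matrix(all[, c("x", "y", "z")]),
    all$charge, all$element, params,
    mask = cross
  )
}

#' Construct an energy backend
#'
#' A backend is the contract the MFCC core consumes: a function from an atom
#' tibble to a single energy in kcal/mol, plus a flag stating whether the
#' potential is pairwise additive (which makes per-region energy attribution
#' exact).
#'
#' @param evaluate Function `atoms -> numeric(1)`; must return 0 for empty and
#'   single-atom input when `pairwise_additive` is `TRUE`.
#' @param pairwise_additive Logical.
#' @param label Human-readable backend name.
#' @return An object of class `"energy_backend"`.
#' @export
energy_backend <- function(evaluate, pairwise_additive, label = "custom") {
  structure(
    list(
      evaluate = evaluate,
      pairwise_additive = pairwise_additive,
      label = label
    ),
    class = "energy_backend"
  )
}

#' The built-in classical pairwise backend
#'
#' @param params A [backend_params()] object.
#' @return An `"energy_backend"` wrapping [pairwise_energy()].
#' @export
pairwise_backend <- function(params = backend_params()) {
  energy_backend(
    evaluate = function(atoms) pairwise_energy(atoms, params),
    pairwise_additive = TRUE,
    label = "classical pairwise (Coulomb + LJ)"
  )
}

#' File-exchange backend for an external quantum engine
#'
#' Builds a backend that, for every evaluation, writes the atom collection to
#' PDB and XYZ files, invokes a user-supplied command, and reads back a single
#' total energy in Hartree (converted at [HARTREE_TO_KCAL_MOL]). Intended for
#' wiring the decomposition to a quantum-chemistry code; nothing in this
#' package invokes it.
#'
#' @param run Function `(pdb_path, xyz_path) -> numeric(1)` returning the
#'   total energy in Hartree (e.g. a [system2()] wrapper that parses the
#'   engine's output file).
#' @param label Backend name.
#' @return An `"energy_backend"` with `pairwise_additive = FALSE`.
#' @export
external_backend <- function(run, label = "external quantum engine") {
  energy_backend(
    evaluate = function(atoms) {
      if (nrow(atoms) == 0) {
        return(0)
      }
      pdb <- tempfile(fileext = ".pdb")
      xyz <- tempfile(fileext = ".xyz")
      on.exit(unlink(c(pdb, xyz)))
      write_pdb(atoms, pdb)
      write_xyz(atoms, xyz)
      hartree <- run(pdb, xyz)
      hartree * HARTREE_TO_KCAL_MOL
    },
    pairwise_additive = FALSE,
    label = label
  )
}

#' Write an atom tibble in XYZ format
#'
#' @param atoms Atom tibble.
#' @param path Optional output path.
#' @return XYZ text, invisibly when `path` is given.
#' @export
write_xyz <- function(atoms, path = NULL) {
  lines <- c(
    as.character(nrow(atoms)),
    "generated by fragdecomp",
    sprintf("%-2s %12.6f %12.6f %12.6f", atoms$element, atoms$x, atoms$y, atoms$z)
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
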