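# Structures and trajectories are plain tibbles, one row per atom, with the
# columns documented in `read_pdb()`. A single-frame structure has frame == 1
# everywhere; a trajectory carries multiple frame values sharing one topology.

.AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common His protonation-variant names are preserved verbatim but still
  # recognised as amino acids
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP"
)

#' Default water residue names
#'
#' Residue names recognised as water when classifying residues. Explicit-solvent
#' trajectories and crystal structures use different conventions, so the set is
#' configurable in every function that needs it.
#' @export
WATER_RES_NAMES <- c("HOH", "WAT", "TIP3", "SOL")

residue_kind <- function(res_name, record_type, water_names = WATER_RES_NAMES) {
  dplyr::case_when(
    res_name %in% water_names ~ "water",
    res_name %in% .AA3 ~ "amino_acid",
    record_type == "HETATM" ~ "ligand",
    TRUE ~ "other"
  )
}

element_from_name <- function(name) {
  # PDB atom names encode the element in the leading alphabetic characters;
  # strip digits/primes, prefer two-letter elements only for common cases
  stripped <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(stripped, 1, 2))
  one <- toupper(substr(stripped, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"), two, one)
}

#' Read a structure or trajectory from PDB text
#'
#' Parses PDB-dialect text (ATOM/HETATM records, optional MODEL/ENDMDL blocks)
#' into an atom tibble. Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param source Path to a PDB file, or a character scalar containing PDB text
#'   (recognised by embedded newlines).
#' @param model_policy `"first"` returns the first MODEL only; `"all"` returns
#'   every MODEL as a frame of a trajectory tibble.
#' @param water_names Residue names treated as water.
#' @param charge_from_b If `TRUE`, the B-factor column is interpreted as a
#'   per-atom partial charge (the convention used by [write_pdb()] when charges
#'   are present).
#' @param time_step_ns Frame spacing used to populate `time_ns` (frame i gets
#'   `(i - 1) * time_step_ns`).
#'
#' @return A tibble with one row per atom and columns `frame`, `time_ns`,
#'   `eleno` (serial), `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom),
#'   `chain`, `resno`, `insert`, `resid` (residue name), `kind` (one of
#'   `amino_acid`, `water`, `ligand`, `other`), `charge`.
#' @export
read_pdb <- function(source, model_policy = c("first", "all"),
                     water_names = WATER_RES_NAMES,
                     charge_from_b = FALSE, time_step_ns = 1) {
  model_policy <- match.arg(model_policy)
  path <- source
  if (length(source) == 1 && grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(source, "\n")[[1]], path)
    on.exit(unlink(path))
  } else if (length(source) > 1) {
    path <- tempfile(fileext = ".pdb")
    writeLines(source, path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = (model_policy == "all"), verbose = FALSE),
    error = function(e) abort(paste0("PDB parse error: ", conditionMessage(e)))
  )
  at <- pdb$atom
  n_atoms <- nrow(at)
  xyz <- pdb$xyz
  n_models <- if (model_policy == "all") nrow(xyz) else 1L
  if (ncol(xyz) != 3L * n_atoms) {
    abort("topology error: models do not share a common atom table")
  }
  one_frame <- function(i) {
    v <- xyz[i, ]
    tibble(
      frame = i,
      time_ns = (i - 1) * time_step_ns,
      eleno = as.integer(at$eleno),
      elety = as.character(at$elety),
      element = ifelse(is.na(at$elesy) | at$elesy == "",
        element_from_name(at$elety), toupper(as.character(at$elesy))
      ),
      x = v[seq(1, length(v), 3)],
      y = v[seq(2, length(v), 3)],
      z = v[seq(3, length(v), 3)],
      chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
      resno = as.integer(at$resno),
      insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
      resid = as.character(at$resid),
      kind = residue_kind(
        as.character(at$resid), as.character(at$type), water_names
      ),
      charge = if (charge_from_b) as.numeric(at$b) else NA_real_
    )
  }
  out <- list_rbind(map(seq_len(n_models), one_frame))
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z)) {
    abort("PDB parse error: non-numeric coordinate field")
  }
  out
}

#' Write a structure or trajectory to PDB text
#'
#' Formats an atom tibble as PDB ATOM/HETATM records; multi-frame input becomes
#' a multi-MODEL file. Per-model formatting is delegated to
#' [bio3d::write.pdb()]. If a `charge` column is present and non-missing it is
#' stored in the B-factor field so that [read_pdb()] can recover it.
#'
#' @param structure Atom tibble (see [read_pdb()]).
#' @param path Optional file path; when given the text is also written there.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(structure, path = NULL) {
  if (any(abs(c(structure$x, structure$y, structure$z)) >= 10000)) {
    abort("formatting error: coordinate out of range for fixed 8.3 PDB fields")
  }
  frames <- sort(unique(structure$frame))
  fmt_frame <- function(f) {
    s <- dplyr::filter(structure, .data$frame == f)
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    b <- if (!is.null(s$charge) && !anyNA(s$charge)) s$charge else rep(0, nrow(s))
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
      type = ifelse(s$kind %in% c("amino_acid"), "ATOM", "HETATM"),
      resno = s$resno, resid = s$resid, eleno = s$eleno, elety = s$elety,
      chain = s$chain, insert = ifelse(s$insert == "", NA, s$insert),
      o = rep(1, nrow(s)), b = b, elesy = s$element
    )
    lines <- readLines(tmp)
    lines[!grepl("^END$", lines)]
  }
  if (length(frames) == 1) {
    txt <- c(fmt_frame(frames[1]), "END")
  } else {
    txt <- unlist(map(seq_along(frames), function(i) {
      c(sprintf("MODEL     %4d", i), fmt_frame(frames[i]), "ENDMDL")
    }))
    txt <- c(txt, "END")
  }
  txt <- paste(txt, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Minimum inter-atomic distance between two atom groups
#'
#' The closest-atom distance used for residue selection, pose assignment and
#' the distances quoted alongside per-residue energies.
#'
#' @param group_a,group_b Atom tibbles (or data frames with `x`, `y`, `z`).
#' @return Minimum Euclidean distance in Angstrom over all cross pairs.
#' @export
min_atom_distance <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    abort("min_atom_distance: both atom groups must be non-empty")
  }
  a <- as.matrix(group_a[, c("x", "y", "z")])
  b <- as.matrix(group_b[, c("x", "y", "z")])
  # cross-pair squared distances without forming the full dist() of the union
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Load and validate a ligand region map
#'
#' A region map partitions the ligand's heavy atoms into three labelled
#' interaction regions (`i`, `ii`, `iii`) used to attribute per-residue
#' energies to parts of the ligand.
#'
#' @param config Path to a YAML/JSON file, or a named list of character
#'   vectors with names `i`, `ii`, `iii`.
#' @param ligand Optional ligand atom tibble; when given, heavy atoms missing
#'   from the map trigger a warning naming them.
#' @return A named list of atom-name character vectors with class
#'   `"region_map"`.
#' @export
load_region_map <- function(config, ligand = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!all(c("i", "ii", "iii") %in% names(config))) {
    abort("region map must declare regions 'i', 'ii' and 'iii'")
  }
  config <- map(config[c("i", "ii", "iii")], as.character)
  all_atoms <- unlist(config, use.names = FALSE)
  dup <- unique(all_atoms[duplicated(all_atoms)])
  if (length(dup) > 0) {
    abort(paste0(
      "region map validation error: atom(s) in more than one region: ",
      paste(dup, collapse = ", ")
    ))
  }
  if (!is.null(ligand)) {
    heavy <- ligand$elety[ligand$element != "H"]
    missing <- setdiff(heavy, all_atoms)
    if (length(missing) > 0) {
      warn(paste0(
        "region map does not cover ligand heavy atom(s): ",
        paste(missing, collapse = ", ")
      ))
    }
  }
  structure(config, class = c("region_map", "list"))
}

#' Extract the atoms of one residue
#'
#' @param structure Atom tibble.
#' @param chain Chain identifier.
#' @param resno Residue sequence number.
#' @param insert Insertion code (default empty).
#' @param frame Frame to extract from (default first frame present).
#' @return Atom tibble for the residue.
#' @export
residue_atoms <- function(structure, chain, resno, insert = "", frame = NULL) {
  f <- frame %||% min(structure$frame)
  out <- dplyr::filter(
    structure,
    .data$frame == f, .data$chain == !!chain,
    .data$resno == !!resno, .data$insert == !!insert
  )
  if (nrow(out) == 0) {
    abort(sprintf("residue %s%d%s not found", chain, resno, insert))
  }
  out
}

# Resolve a ligand argument: an atom tibble passes through; a character value
# selects by residue name within the given frame.
as_ligand <- function(structure, ligand, frame = NULL) {
  if (is.data.frame(ligand)) {
    return(ligand)
  }
  f <- frame %||% min(structure$frame)
  out <- dplyr::filter(structure, .data$frame == f, .data$resid == ligand)
  if (nrow(out) == 0) abort(sprintf("ligand '%s' not found in structure", ligand))
  out
}

# unique residue table of one frame, in file (chain) order
residue_table <- function(structure, frame = NULL) {
  f <- frame %||% min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  dplyr::distinct(
    s, .data$chain, .data$resno, .data$insert, .data$resid, .data$kind
  )
}
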