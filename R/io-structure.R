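#' Construct a C-alpha structure model
#'
#' A structure model is a tibble with one row per residue: `residue_number`
#' (as numbered in the source file), C-alpha coordinates `x`, `y`, `z` in
#' Angstrom, and `plddt`, the per-residue confidence on the 0--100 scale as
#' written by structure-prediction pipelines into the B-factor column.
#'
#' @param residue_number Integer residue numbers, strictly increasing.
#' @param x,y,z C-alpha coordinates (Angstrom).
#' @param plddt Per-residue confidence, 0--100.
#' @param structure_id,chain_id Identifiers carried as attributes.
#' @return A tibble of class `ecis_structure`.
#' @export
structure_model <- function(residue_number, x, y, z, plddt,
                            structure_id = "model", chain_id = "A") {
  if (is.unsorted(residue_number, strictly = TRUE)) {
    abort("residue numbers must be strictly increasing",
          class = "ecisfiber_integrity_error")
  }
  if (!all(is.finite(c(x, y, z)))) {
    abort("coordinates must be finite", class = "ecisfiber_integrity_error")
  }
  out <- tibble(
    residue_number = as.integer(residue_number),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    plddt = pmin(100, pmax(0, as.numeric(plddt)))
  )
  attr(out, "structure_id") <- structure_id
  attr(out, "chain_id") <- chain_id
  class(out) <- c("ecis_structure", class(out))
  out
}

#' Read a predicted structure from a PDB file
#'
#' Reads C-alpha atoms of one chain of a PDB file (via bio3d) into a
#' [structure_model()] tibble. Per-residue confidence (pLDDT) is taken from
#' the B-factor column; residue numbering is preserved exactly as in the
#' file. Residues lacking a C-alpha atom are skipped with a warning count.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default `"A"`.
#' @return An `ecis_structure` tibble.
#' @export
read_structure <- function(path, chain = "A") {
  if (!file.exists(path)) {
    abort(sprintf("structure file not found: %s", path),
          class = "ecisfiber_io_error")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  atoms <- pdb$atom
  chains <- sort(unique(atoms$chain))
  if (!chain %in% chains) {
    abort(sprintf("chain '%s' not present; available chains: %s",
                  chain, paste(chains, collapse = ", ")),
          class = "ecisfiber_io_error")
  }
  ch <- atoms[atoms$chain == chain, , drop = FALSE]
  all_res <- unique(ch$resno)
  ca <- ch[ch$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  n_missing <- length(setdiff(all_res, ca$resno))
  if (n_missing > 0) {
    warn(sprintf("%d residue(s) without a C-alpha atom skipped", n_missing))
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  structure_model(
    residue_number = ca$resno,
    x = ca$x, y = ca$y, z = ca$z,
    plddt = ca$b,
    structure_id = sub("\\.pdb$", "", basename(path)),
    chain_id = chain
  )
}

#' Write a structure model to a PDB file
#'
#' Emits one C-alpha ATOM record per residue with the model's residue
#' numbering, chain identifier, and pLDDT in the B-factor column (fixed
#' 8.3 coordinate precision).
#'
#' @param model An `ecis_structure` tibble.
#' @param path Output PDB path.
#' @param chain Chain identifier to write; defaults to the model's
#'   `chain_id` attribute.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, chain = NULL) {
  chain <- chain %||% attr(model, "chain_id") %||% "A"
  n <- nrow(model)
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = model$residue_number,
    resid = rep("ALA", n),
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = rep(chain, n),
    o = rep(1, n),
    b = model$plddt
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
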