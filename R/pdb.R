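## PDB reading (via bio3d) and fixed-width v3.3 writing.

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_123 <- structure(names(AA_321), names = unname(AA_321))

#' Read a backbone model from a PDB file
#'
#' Parses the first model of a PDB v3.x file with [bio3d::read.pdb()],
#' keeping ATOM records of standard amino acids. Alternate location
#' indicators other than '' or 'A' are dropped with a warning; hydrogens are
#' never read (amide hydrogens are rebuilt by [place_amide_hydrogens()] so
#' hydrogen-bond geometry is consistent across input sources). Residues are
#' renumbered 1..N; original chain/number/insertion codes are recorded in
#' the provenance string. Residues missing any of N, CA, C, O are flagged
#' incomplete and excluded from geometry operations.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; default keeps the first chain.
#' @return a `backbone_model`.
#' @export
read_pdb <- function(path, chain = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(AA_321), , drop = FALSE]
  if (nrow(at) == 0) stop("no standard-residue ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(!alt %in% c("", "A"))) {
    warning("dropping alternate locations other than ''/A")
  }
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  at <- at[!grepl("^H|^[0-9]H", at$elety), , drop = FALSE]  # no hydrogens
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$resno, ins, sep = "_")
  ukey <- unique(key)
  newno <- match(key, ukey)
  residues <- data.frame(
    resno = seq_along(ukey),
    aa = unname(AA_321[at$resid[match(ukey, key)]]),
    repeat_unit = NA_integer_, region = NA_character_,
    incomplete = FALSE, break_after = FALSE,
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(resno = newno, name = at$elety,
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(atoms$resno, atoms$name))
  atoms <- atoms[!dup, , drop = FALSE]
  xyz <- as.matrix(at[!dup, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  m <- new_backbone_model(
    residues, atoms, xyz,
    provenance = sprintf("read_pdb(%s) chain %s; original numbering %s",
                         basename(path), chain,
                         paste(ukey[c(1, length(ukey))], collapse = "..")))
  for (i in m$residues$resno) {
    have <- m$atoms$name[m$atoms$resno == i]
    if (!all(BACKBONE_ATOMS %in% have)) m$residues$incomplete[i] <- TRUE
  }
  # declare chain breaks where the peptide bond is missing or too long
  for (i in seq_len(n_residues(m) - 1)) {
    C <- atom_xyz(m, i, "C"); N <- atom_xyz(m, i + 1, "N")
    if (is.null(C) || is.null(N) || vnorm(N - C) > 1.8) {
      m$residues$break_after[i] <- TRUE
    }
  }
  m
}

pdb_element <- function(name) {
  substr(gsub("^[0-9]+", "", name), 1, 1)
}

#' Write a backbone model as fixed-width PDB v3.3
#'
#' Emits ATOM records with occupancy 1.00, B-factor 0.00 and the element
#' column filled, residues numbered 1..N on chain A, a TER record at each
#' chain end and a final END.
#'
#' @param model a `backbone_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  if (any(nchar(model$atoms$name) > 4)) {
    stop("atom names longer than 4 characters cannot be written")
  }
  lines <- character(0)
  serial <- 0L
  res <- model$residues
  atom_order <- c("N", "CA", "C", "O", "CB")
  for (i in res$resno) {
    rows <- which(model$atoms$resno == i)
    nm <- model$atoms$name[rows]
    ord <- order(match(nm, atom_order, nomatch = length(atom_order) + 1))
    rows <- rows[ord]; nm <- nm[ord]
    res3 <- AA_123[res$aa[match(i, res$resno)]]
    if (is.na(res3)) res3 <- "ALA"
    for (k in seq_along(rows)) {
      serial <- serial + 1L
      xyz <- model$xyz[rows[k], ]
      aname <- nm[k]
      afield <- if (nchar(aname) < 4) sprintf(" %-3s", aname) else aname
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, afield, res3, "A", i, xyz[1], xyz[2], xyz[3], 1, 0,
        pdb_element(aname)))
    }
  }
  last3 <- AA_123[res$aa[nrow(res)]]
  if (is.na(last3)) last3 <- "ALA"
  lines <- c(lines,
             sprintf("TER   %5d      %3s %s%4d", serial + 1L, last3, "A",
                     res$resno[nrow(res)]),
             "END")
  writeLines(lines, path)
  invisible(path)
}
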