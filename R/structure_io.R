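# Structure input: PDB parsing, partner splitting, sequence extraction.
#
# A `hs_structure` is a light container over a per-atom data.frame in PDB
# author numbering: columns chain, resno, insert, resid (3-letter), aa
# (1-letter), elety (atom name), elesy (element), x, y, z, o (occupancy).
# Parsing is delegated to bio3d; normalisation (altloc selection, hydrogen /
# water / het removal, first model only) is applied on top.

new_structure <- function(atoms, pdb_id = "XXXX") {
  rownames(atoms) <- NULL
  structure(list(pdb_id = pdb_id, atoms = atoms), class = "hs_structure")
}

#' @export
print.hs_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<hs_structure %s: %d chains, %d residues, %d atoms>\n",
              x$pdb_id, length(unique(x$atoms$chain)), nrow(rk),
              nrow(x$atoms)))
  invisible(x)
}

## Unique residue identifiers in structure order.
residue_keys <- function(s) {
  a <- s$atoms
  id <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(id)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             aa = a$aa[first], stringsAsFactors = FALSE)
}

residue_id <- function(chain, resno, insert = "") {
  paste(chain, resno, insert, sep = "|")
}

atom_residue_id <- function(s) {
  residue_id(s$atoms$chain, s$atoms$resno, s$atoms$insert)
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records into a normalised structure: only the first
#' MODEL is kept, hydrogens and waters are removed, and where alternate
#' locations exist only the highest-occupancy conformer (ties broken by file
#' order) is retained. HETATM groups other than water are dropped unless
#' \code{keep_het = TRUE}.
#'
#' @param path path to a PDB-format file.
#' @param pdb_id identifier stored on the structure; defaults to the file
#'   base name.
#' @param keep_het retain non-water HETATM records (default drops them).
#' @return an object of class \code{hs_structure}.
#' @export
read_pdb <- function(path, pdb_id = NULL, keep_het = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines))) {
    stop("no ATOM records in ", path, call. = FALSE)
  }
  ## validate coordinate fields before handing off to the parser, so that a
  ## malformed record is reported with its line number
  for (i in which(is_atom)) {
    ln <- lines[[i]]
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    num <- suppressWarnings(as.numeric(coords))
    if (anyNA(num) || any(!is.finite(num))) {
      stop(sprintf("unparsable ATOM/HETATM record at line %d of %s", i, path),
           call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE, verbose = FALSE)
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1

  ## drop hydrogens/deuterium and waters; het policy
  a <- a[!(toupper(a$elesy) %in% c("H", "D")), , drop = FALSE]
  a <- a[!(toupper(a$resid) %in% WATER_RESIDUES), , drop = FALSE]
  if (!keep_het) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("structure is empty after normalization: ", path,
                         call. = FALSE)

  ## altloc: keep highest occupancy per (residue, atom name), first on ties
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(match(key, unique(key)), -a$o,
               seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")),
         , drop = FALSE]
  ## restore file order
  a <- a[order(as.integer(rownames(a))), , drop = FALSE]

  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert,
    resid = toupper(a$resid), aa = aa_one_letter(a$resid),
    elety = a$elety, elesy = toupper(a$elesy),
    x = a$x, y = a$y, z = a$z, o = a$o,
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (is.null(pdb_id)) {
    pdb_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path),
                          ignore.case = TRUE))
  }
  new_structure(atoms, pdb_id = pdb_id)
}

#' Define the two binding partners of a complex
#'
#' @param side_a,side_b character vectors of chain identifiers; must be
#'   disjoint and non-empty.
#' @return a \code{partner_spec} object.
#' @export
partner_spec <- function(side_a, side_b) {
  side_a <- as.character(side_a); side_b <- as.character(side_b)
  if (length(side_a) == 0 || length(side_b) == 0)
    stop("both partner sides must list at least one chain", call. = FALSE)
  if (length(intersect(side_a, side_b)) > 0)
    stop("partner sides share chains: ",
         paste(intersect(side_a, side_b), collapse = ", "), call. = FALSE)
  structure(list(side_a = side_a, side_b = side_b), class = "partner_spec")
}

## Parse "A:B" / "AB:C" style partner strings (chains concatenated, sides
## separated by ':').
parse_partner_spec <- function(txt) {
  parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("partner spec must be '<chains>:<chains>', got ",
                               txt, call. = FALSE)
  partner_spec(strsplit(parts[1], "")[[1]], strsplit(parts[2], "")[[1]])
}

#' Split a complex into its two binding partners
#'
#' @param s an \code{hs_structure} of the full complex.
#' @param spec a \code{\link{partner_spec}}; every listed chain must exist in
#'   \code{s}.
#' @return list with elements \code{a} and \code{b}, each an
#'   \code{hs_structure} holding one side with unchanged coordinates.
#' @export
split_partners <- function(s, spec) {
  stopifnot(inherits(s, "hs_structure"), inherits(spec, "partner_spec"))
  have <- unique(s$atoms$chain)
  missing <- setdiff(c(spec$side_a, spec$side_b), have)
  if (length(missing) > 0)
    stop("partner spec names chain(s) absent from structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  take <- function(side) {
    new_structure(s$atoms[s$atoms$chain %in% side, , drop = FALSE],
                  pdb_id = s$pdb_id)
  }
  list(a = take(spec$side_a), b = take(spec$side_b))
}

#' Extract the one-letter sequence of a chain
#'
#' Residues appear in structure order; nonstandard residues without a known
#' parent map to \code{"X"}.
#'
#' @param s an \code{hs_structure}.
#' @param chain_id single chain identifier.
#' @return character scalar, one letter per residue.
#' @export
extract_sequence <- function(s, chain_id) {
  stopifnot(inherits(s, "hs_structure"))
  if (!chain_id %in% s$atoms$chain)
    stop("chain '", chain_id, "' not in structure", call. = FALSE)
  rk <- residue_keys(s)
  paste(rk$aa[rk$chain == chain_id], collapse = "")
}

#' Serialise a structure to PDB text
#'
#' Writes plain ATOM records (TER between chains). Round-tripping through
#' \code{\link{read_pdb}} preserves atom count, residue count and coordinates
#' to the 3-decimal precision of the format.
#'
#' @param s an \code{hs_structure}.
#' @param path optional output file; when \code{NULL} the text is returned.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$elety[i]
      ## PDB atom-name column convention: element right-justified in 13-14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (sub$is_hetero[i]) "HETATM" else "ATOM", serial, nm_fmt, "",
        sub$resid[i], ch, sub$resno[i], sub$insert[i],
        sub$x[i], sub$y[i], sub$z[i], sub$o[i], 0, sub$elesy[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
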