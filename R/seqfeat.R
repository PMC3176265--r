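# Sequence-derived features: physicochemical scales, PSI-BLAST PSSM parsing
# and logistic normalisation, alignment-column sequence entropy, and
# ConSurf-style conservation grades (parsed, or estimated from an MSA).

#' Physicochemical property vector of an amino acid
#'
#' Six scales per residue type (hydrophobicity, hydrophilicity, polarity,
#' polarizability, beta-sheet propensity, average accessible surface area),
#' pinned to AAindex accessions recorded in
#' \code{attr(physchem(aa), "accessions")}.
#'
#' @param aa one-letter code(s) of standard amino acids.
#' @return named numeric vector (one residue) or matrix (several) of the six
#'   values.
#' @export
physchem <- function(aa) {
  bad <- setdiff(aa, rownames(PHYSCHEM_TABLE))
  if (length(bad) > 0)
    stop("no physicochemical values for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- PHYSCHEM_TABLE[aa, , drop = length(aa) == 1]
  attr(out, "accessions") <- PHYSCHEM_ACCESSIONS
  out
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the 20 substitution-score columns of the standard PSI-BLAST text
#' PSSM (query residue in column 2). Weighted-percentage columns, if
#' present, are ignored.
#'
#' @param path PSSM file path.
#' @return list of class \code{pssm_profile}: \code{scores} (positions x 20
#'   integer matrix, columns in A R N D C Q E G H I L K M F P S T W Y V
#'   order), \code{query} (one-letter sequence), \code{normalized}
#'   (\code{\link{normalize_pssm}} applied elementwise).
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ## locate the column-header line: 20+ single-letter columns
  aa_cols <- NULL
  start <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20 && all(toks %in% c(AA_ONE, "X", "B", "Z", "*"))) {
      aa_cols <- toks[1:20]
      start <- i + 1
      break
    }
  }
  if (is.na(start)) stop("not a PSI-BLAST PSSM: no amino-acid header found in ",
                         path, call. = FALSE)
  scores <- list(); query <- character(0)
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(Lambda|K |Standard|PSI|Gapped)", ln)) break
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) < 22)
      stop(sprintf("malformed PSSM row at line %d: expected >=22 fields, got %d",
                   i, length(toks)), call. = FALSE)
    vals <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(vals))
      stop(sprintf("non-integer PSSM score at line %d", i), call. = FALSE)
    scores[[length(scores) + 1]] <- vals
    query <- c(query, toks[2])
  }
  if (length(scores) == 0) stop("PSSM contains no score rows: ", path,
                                call. = FALSE)
  m <- do.call(rbind, scores)
  colnames(m) <- aa_cols
  ## reorder columns to canonical order if needed
  m <- m[, AA_ONE, drop = FALSE]
  structure(list(scores = m, query = paste(query, collapse = ""),
                 normalized = normalize_pssm(m)),
            class = "pssm_profile")
}

#' Logistic normalisation of a PSSM score
#'
#' Maps a raw integer substitution score into (0, 1) via
#' \code{1 / (1 + exp(-x))}; strictly increasing, midpoint 0.5 at x = 0.
#'
#' @param x raw score(s).
#' @return value(s) in (0, 1), same shape as \code{x}.
#' @export
normalize_pssm <- function(x) 1 / (1 + exp(-x))

#' Sequence entropy of an alignment column
#'
#' Shannon entropy of the amino-acid distribution in one multiple-alignment
#' column, normalised to [0, 100]: 0 for a fully conserved column, 100 when
#' all 20 residue types are equally frequent. Gap characters are excluded
#' from the probabilities.
#'
#' @param column character vector (or single string) of column residues;
#'   gaps \code{"-"}, \code{"."} and \code{"X"} are ignored.
#' @return entropy in [0, 100]; \code{NA} for a column with no residues.
#' @export
sequence_entropy <- function(column) {
  if (length(column) == 1 && nchar(column[1]) > 1)
    column <- strsplit(column, "")[[1]]
  column <- toupper(column)
  column <- column[column %in% AA_ONE]
  if (length(column) == 0) return(NA_real_)
  p <- table(column) / length(column)
  h <- -sum(p * log(p))
  100 * h / log(20)
}

## Per-column entropies of an MSA given as a character vector of aligned
## sequences (equal length).
msa_column_entropies <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  apply(mat, 2, sequence_entropy)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path FASTA file with equal-length (gapped) sequences.
#' @return character vector of aligned sequences, named by FASTA identifiers.
#' @export
read_msa <- function(path) {
  aln <- bio3d::read.fasta(path)
  seqs <- apply(aln$ali, 1, paste, collapse = "")
  if (length(unique(nchar(seqs))) != 1)
    stop("FASTA sequences are not aligned (unequal lengths): ", path,
         call. = FALSE)
  seqs
}

#' Conservation grades per alignment position
#'
#' Returns ConSurf-style grades on the 1--9 scale (9 = most conserved, 1 =
#' most variable). Either parses a grade file (TSV with columns position,
#' aa, grade) or, as a fallback estimator, bins per-column sequence entropy
#' into nine quantile classes of the protein, inverted so that the
#' lowest-entropy (most conserved) columns receive grade 9. The source used
#' is recorded in \code{attr(, "provenance")}.
#'
#' @param grades_file optional ConSurf-style TSV path.
#' @param msa optional character vector of aligned sequences (or a FASTA
#'   path) for the entropy-quantile fallback.
#' @return integer vector of grades in 1..9, one per position.
#' @export
conservation_grade <- function(grades_file = NULL, msa = NULL) {
  if (!is.null(grades_file)) {
    tab <- utils::read.table(grades_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!"grade" %in% names(tab))
      stop("grade file lacks a 'grade' column: ", grades_file, call. = FALSE)
    g <- as.integer(tab$grade)
    if (anyNA(g) || any(g < 1 | g > 9))
      stop("grades outside 1..9 in ", grades_file, call. = FALSE)
    attr(g, "provenance") <- "consurf_file"
    return(g)
  }
  if (is.null(msa)) stop("supply grades_file or msa", call. = FALSE)
  if (length(msa) == 1 && file.exists(msa)) msa <- read_msa(msa)
  ent <- msa_column_entropies(msa)
  g <- entropy_to_grade(ent)
  attr(g, "provenance") <- "entropy_quantile_fallback"
  g
}

## Quantile binning of entropies into inverted 1..9 grades; monotone
## non-increasing in entropy. NA entropies (all-gap columns) get NA grades.
entropy_to_grade <- function(ent) {
  ok <- !is.na(ent)
  g <- rep(NA_integer_, length(ent))
  n <- sum(ok)
  if (n == 0) return(g)
  q <- (rank(ent[ok], ties.method = "min") - 1) / n
  gg <- 1L + as.integer(floor(9 * (1 - q)))
  g[ok] <- pmin(9L, pmax(1L, gg))
  g
}

## Sequence-feature table for one chain: 20 normalised PSSM columns, entropy
## and conservation grade per residue position, keyed to structure numbering.
## Structure residue i of the chain is matched to profile/alignment position
## i after ungapping the first MSA sequence; a mismatch in length yields NA
## rows (flagged), not an error.
seqfeat_table <- function(s, chain_id, pssm = NULL, msa = NULL,
                          grades_file = NULL) {
  rk <- residue_keys(s)
  rk <- rk[rk$chain == chain_id, , drop = FALSE]
  n <- nrow(rk)
  out <- data.frame(pdb_id = s$pdb_id, chain = rk$chain, resseq = rk$resno,
                    icode = rk$insert, aa = rk$aa, stringsAsFactors = FALSE)

  pm <- matrix(NA_real_, n, 20,
               dimnames = list(NULL, FEATURE_GROUPS$PSSM))
  if (!is.null(pssm)) {
    if (is.character(pssm)) pssm <- parse_pssm(pssm)
    k <- min(n, nrow(pssm$scores))
    pm[seq_len(k), ] <- pssm$normalized[seq_len(k), ]
  }
  out <- cbind(out, as.data.frame(pm))

  ent <- rep(NA_real_, n); grd <- rep(NA_integer_, n)
  if (!is.null(msa) || !is.null(grades_file)) {
    if (!is.null(msa)) {
      if (length(msa) == 1 && file.exists(msa)) msa <- read_msa(msa)
      col_ent <- msa_column_entropies(msa)
      ## map structure positions through the ungapped first sequence
      ref <- strsplit(msa[1], "")[[1]]
      pos_map <- which(!(ref %in% c("-", ".")))
      k <- min(n, length(pos_map))
      ent[seq_len(k)] <- col_ent[pos_map[seq_len(k)]]
      if (is.null(grades_file)) {
        g_all <- entropy_to_grade(col_ent)
        grd[seq_len(k)] <- g_all[pos_map[seq_len(k)]]
      }
    }
    if (!is.null(grades_file)) {
      g <- conservation_grade(grades_file = grades_file)
      k <- min(n, length(g))
      grd[seq_len(k)] <- g[seq_len(k)]
    }
  }
  out$seq_entropy <- ent
  out$cons_grade <- grd

  phy <- matrix(NA_real_, n, 6, dimnames = list(NULL, FEATURE_GROUPS$Phy))
  std <- rk$aa %in% rownames(PHYSCHEM_TABLE)
  if (any(std)) phy[std, ] <- PHYSCHEM_TABLE[rk$aa[std], , drop = FALSE]
  cbind(out, as.data.frame(phy))
}
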