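# Deterministic generators for test fixtures: toy two-chain complexes with
# engineered contacts, feature matrices with planted class structure,
# alignments, PSI-BLAST-dialect PSSMs, and mutation tables whose label
# compositions match the published alanine-scanning study designs.
#
# Toy complexes use idealized extended geometry: chains run along x with
# 3.8 A CA spacing, side chains extend along +/-y toward the partner. All
# geometric features in the package depend only on interatomic distances,
# so rotamer realism is not needed.

## side-chain templates: atom name -> (dy, dx, element) offsets from CA,
## with dy pointing toward the partner
SC_TEMPLATES <- list(
  GLY = NULL,
  ALA = list(CB = c(1.53, 0, "C")),
  SER = list(CB = c(1.53, 0, "C"), OG = c(2.90, 0.3, "O")),
  LYS = list(CB = c(1.53, 0, "C"), CG = c(2.90, 0.3, "C"),
             CD = c(4.20, 0, "C"), CE = c(5.50, 0.3, "C"),
             NZ = c(6.80, 0, "N")),
  GLU = list(CB = c(1.53, 0, "C"), CG = c(2.90, 0.3, "C"),
             CD = c(4.20, 0, "C"), OE1 = c(5.20, 0.5, "O"),
             OE2 = c(4.30, -0.9, "O")),
  ASP = list(CB = c(1.53, 0, "C"), CG = c(2.90, 0.3, "C"),
             OD1 = c(3.90, 0.5, "O"), OD2 = c(3.90, -0.8, "O")),
  ARG = list(CB = c(1.53, 0, "C"), CG = c(2.90, 0.3, "C"),
             CD = c(4.20, 0, "C"), NE = c(5.40, 0.3, "N"),
             CZ = c(6.60, 0, "C"), NH1 = c(7.40, 0.8, "N"),
             NH2 = c(7.40, -0.8, "N"))
)

sc_tip_y <- function(resid) {
  tpl <- SC_TEMPLATES[[resid]]
  if (is.null(tpl)) 0 else max(vapply(tpl, function(a) as.numeric(a[1]), 0))
}

#' Generate a toy two-chain complex
#'
#' Two idealized extended chains facing each other across a gap, with
#' optional engineered cross-interface contacts at exact distances. The
#' \code{gap} is the y-distance between the side-chain tip planes of the
#' two chains (so \code{gap = 100} gives fully separated partners with no
#' interface residues).
#'
#' @param n_res residues per chain.
#' @param gap tip-to-tip separation in Angstrom.
#' @param contacts list of engineered contacts, each a list with
#'   \code{type} ("salt_bridge" = LYS NZ vs GLU OE1, or "hbond" = SER OG vs
#'   SER OG), \code{res_a}/\code{res_b} (residue indices on chains A/B) and
#'   \code{dist} (functional-atom distance, Angstrom).
#' @param res_type default residue type for unengineered positions.
#' @param pdb_id identifier stamped on the output.
#' @return an \code{hs_structure}; write it with \code{\link{write_pdb}}
#'   for reader round-trips.
#' @export
make_toy_complex <- function(n_res = 6, gap = 2.0, contacts = list(),
                             res_type = "ALA", pdb_id = "TOY1") {
  types_a <- rep(res_type, n_res)
  types_b <- rep(res_type, n_res)
  for (ct in contacts) {
    if (ct$res_a > n_res || ct$res_b > n_res)
      stop("engineered contact indexes a residue beyond n_res", call. = FALSE)
    if (ct$dist < 0) stop("contact distance must be >= 0", call. = FALSE)
    if (ct$type == "salt_bridge") {
      types_a[ct$res_a] <- "LYS"; types_b[ct$res_b] <- "GLU"
    } else if (ct$type == "hbond") {
      types_a[ct$res_a] <- "SER"; types_b[ct$res_b] <- "SER"
    } else stop("unknown contact type: ", ct$type, call. = FALSE)
  }
  tip_a <- max(c(0, vapply(types_a, sc_tip_y, 0)))
  tip_b <- max(c(0, vapply(types_b, sc_tip_y, 0)))
  ysep <- tip_a + gap + tip_b   # CA-plane separation

  build_res <- function(resid, chain, idx, y0, dir) {
    ca <- c(3.8 * (idx - 1), y0, 0)
    atoms <- list(
      N  = c(ca[1] - 1.46, ca[2] + dir * 0.50, 0, "N"),
      CA = c(ca[1], ca[2], 0, "C"),
      C  = c(ca[1] + 1.51, ca[2] - dir * 0.30, 0, "C"),
      O  = c(ca[1] + 2.11, ca[2] - dir * 1.40, 0, "O")
    )
    tpl <- SC_TEMPLATES[[resid]]
    for (nm in names(tpl)) {
      off <- tpl[[nm]]
      atoms[[nm]] <- c(ca[1] + as.numeric(off[2]),
                       ca[2] + dir * as.numeric(off[1]), 0, off[3])
    }
    data.frame(chain = chain, resno = idx, insert = "", resid = resid,
               aa = aa_one_letter(resid),
               elety = names(atoms),
               elesy = vapply(atoms, function(a) a[4], ""),
               x = vapply(atoms, function(a) as.numeric(a[1]), 0),
               y = vapply(atoms, function(a) as.numeric(a[2]), 0),
               z = vapply(atoms, function(a) as.numeric(a[3]), 0),
               o = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
  }

  rows_a <- do.call(rbind, lapply(seq_len(n_res), function(i)
    build_res(types_a[i], "A", i, 0, +1)))
  rows_b <- do.call(rbind, lapply(seq_len(n_res), function(i)
    build_res(types_b[i], "B", i, ysep, -1)))

  ## place engineered contacts at their exact distances by shifting the
  ## chain-B residue along y
  tip_atom <- c(salt_bridge_a = "NZ", salt_bridge_b = "OE1",
                hbond_a = "OG", hbond_b = "OG")
  for (ct in contacts) {
    an <- if (ct$type == "salt_bridge") c("NZ", "OE1") else c("OG", "OG")
    ya <- rows_a$y[rows_a$resno == ct$res_a & rows_a$elety == an[1]]
    sel_b <- rows_b$resno == ct$res_b
    yb <- rows_b$y[sel_b & rows_b$elety == an[2]]
    xa <- rows_a$x[rows_a$resno == ct$res_a & rows_a$elety == an[1]]
    xb <- rows_b$x[sel_b & rows_b$elety == an[2]]
    ## align x of the B residue with the A tip atom, then set the y gap
    rows_b$x[sel_b] <- rows_b$x[sel_b] + (xa - xb)
    dy2 <- ct$dist^2
    if (dy2 < 0) stop("unrealizable contact placement", call. = FALSE)
    rows_b$y[sel_b] <- rows_b$y[sel_b] - (yb - ya - ct$dist)
  }

  new_structure(rbind(rows_a, rows_b), pdb_id = pdb_id)
}

#' Generate a synthetic feature dataset with planted class structure
#'
#' Labels are drawn at the requested prevalence (or fixed count); columns
#' of the informative groups are shifted by \code{d} standard deviations
#' for positives over unit-variance Gaussian noise. Ground truth (which
#' groups carry signal) is returned for recovery tests.
#'
#' @param n rows.
#' @param prevalence positive-class fraction in (0,1).
#' @param d standardized mean shift on informative columns.
#' @param groups named integer vector: feature-group name -> number of
#'   columns.
#' @param informative names of groups that carry the shift.
#' @param seed RNG seed.
#' @param fixed_count when TRUE, exactly \code{round(n * prevalence)}
#'   positives.
#' @return an \code{hs_dataset} with \code{feature_groups} set and
#'   \code{ground_truth} attached.
#' @export
make_synthetic_dataset <- function(n = 377, prevalence = 182 / 377, d = 1,
                                   groups = c(grpA = 4, grpB = 4),
                                   informative = "grpA", seed = 1,
                                   fixed_count = TRUE) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0,1)", call. = FALSE)
  if (d < 0) stop("class separation d must be >= 0", call. = FALSE)
  if (d > 0 && length(informative) == 0)
    warning("d > 0 but no informative group requested", call. = FALSE)
  set.seed(seed)
  npos <- round(n * prevalence)
  y <- if (fixed_count) {
    yy <- rep(FALSE, n); yy[sample.int(n, npos)] <- TRUE; yy
  } else stats::runif(n) < prevalence
  cols <- unlist(mapply(function(g, k) paste0(g, "_", seq_len(k)),
                        names(groups), groups, SIMPLIFY = FALSE),
                 use.names = FALSE)
  X <- matrix(stats::rnorm(n * length(cols)), n, length(cols),
              dimnames = list(NULL, cols))
  for (g in informative) {
    gc <- grep(paste0("^", g, "_"), cols)
    X[y, gc] <- X[y, gc] + d
  }
  ds <- dataset_from_matrix(X, y, combo = paste(names(groups),
                                                collapse = "+"))
  ds$feature_groups <- lapply(names(groups), function(g)
    grep(paste0("^", g, "_"), cols, value = TRUE))
  names(ds$feature_groups) <- names(groups)
  attr(ds, "ground_truth") <- list(informative = informative, d = d,
                                   prevalence = prevalence, seed = seed)
  ds
}

#' Generate a synthetic aligned FASTA MSA
#'
#' Designated columns are invariant (fixed residue); all other columns are
#' sampled uniformly over the 20 amino acids.
#'
#' @param n_seqs sequences.
#' @param n_cols alignment columns.
#' @param conserved_positions indices of invariant columns.
#' @param seed RNG seed.
#' @param path optional output FASTA path.
#' @return named character vector of aligned sequences (written to
#'   \code{path} when given).
#' @export
make_synthetic_msa <- function(n_seqs = 50, n_cols = 12,
                               conserved_positions = integer(0), seed = 1,
                               path = NULL) {
  set.seed(seed)
  mat <- matrix(sample(AA_ONE, n_seqs * n_cols, replace = TRUE),
                n_seqs, n_cols)
  for (p in conserved_positions) mat[, p] <- mat[1, p]
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("seq", seq_len(n_seqs))
  if (!is.null(path)) {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  }
  invisible(seqs)
}

#' Generate a PSI-BLAST-dialect ASCII PSSM
#'
#' Writes the standard text layout (two header lines, position and query
#' residue, 20 score columns, 20 percentage columns, two information
#' columns) for a given or random query sequence.
#'
#' @param query one-letter query sequence; random when NULL.
#' @param n length of the random query.
#' @param seed RNG seed.
#' @param path optional output path.
#' @return the matrix of raw scores, invisibly; lines written to
#'   \code{path} when given.
#' @export
make_synthetic_pssm <- function(query = NULL, n = 8, seed = 1, path = NULL) {
  set.seed(seed)
  if (is.null(query)) query <- paste(sample(AA_ONE, n, replace = TRUE),
                                     collapse = "")
  qs <- strsplit(query, "")[[1]]
  n <- length(qs)
  scores <- matrix(sample(-6:8, n * 20, replace = TRUE), n, 20,
                   dimnames = list(NULL, AA_ONE))
  ## the query residue scores well against itself
  for (i in seq_len(n)) if (qs[i] %in% AA_ONE) scores[i, qs[i]] <- 7L
  lines <- c("",
             "Last position-specific scoring matrix computed, weighted, observed percentages rounded down",
             paste0("            ", paste(sprintf("%3s", c(AA_ONE, AA_ONE)),
                                          collapse = "")))
  for (i in seq_len(n)) {
    pct <- sprintf("%3d", rep(5L, 20))
    lines <- c(lines, paste0(sprintf("%5d %s  ", i, qs[i]),
                             paste(sprintf("%3d", scores[i, ]), collapse = ""),
                             " ", paste(pct, collapse = ""),
                             sprintf("  %4.2f %4.2f", 0.5, 0.1)))
  }
  lines <- c(lines, "", "                      K         Lambda")
  if (!is.null(path)) writeLines(lines, path)
  attr(scores, "query") <- query
  attr(scores, "lines") <- lines
  invisible(scores)
}

#' Synthetic alanine-scanning training mutation table
#'
#' A stand-in for the published 25-complex training table, which is not
#' redistributable here: 377 mutations over 25 synthetic complex
#' identifiers with a ddg distribution constructed so that the hot-spot
#' rule reproduces the published design margins exactly -- 182 mutations
#' with ddg >= 1 kcal/mol (of which 84 have ddg >= 2 kcal/mol) and 195
#' below 1 kcal/mol. Residue identities and ddg values within each stratum
#' are random; only the stratum counts are meaningful.
#'
#' @param seed RNG seed.
#' @param n_antibody number of complexes flagged antigen-antibody.
#' @return data.frame with columns pdb_id, chain, resseq, icode, wt_aa,
#'   ddg, is_antibody_complex.
#' @export
synthetic_training_mutations <- function(seed = 42, n_antibody = 5) {
  set.seed(seed)
  n <- 377
  ## strata: 84 with ddg >= 2; 98 in [1, 2); 195 < 1 (a handful negative)
  ddg <- c(stats::runif(84, 2.0, 6.5),
           stats::runif(98, 1.0, 1.999),
           stats::runif(165, 0.0, 0.999),
           stats::runif(30, -1.5, -0.001))
  complexes <- sprintf("SYN%02d", 1:25)
  pdb <- sort(sample(rep(complexes, length.out = n)))
  aa_pool <- setdiff(AA_ONE, "A")   # alanine cannot be mutated to alanine
  out <- data.frame(
    pdb_id = pdb,
    chain = sample(c("A", "B"), n, replace = TRUE),
    resseq = NA_integer_,
    icode = "",
    wt_aa = sample(aa_pool, n, replace = TRUE),
    ddg = sample(ddg),
    is_antibody_complex = pdb %in% complexes[seq_len(n_antibody)],
    stringsAsFactors = FALSE
  )
  ## unique residue numbers within each complex/chain
  for (p in complexes) {
    idx <- which(out$pdb_id == p)
    out$resseq[idx] <- sample(1:400, length(idx))
  }
  out
}

#' Synthetic BID-style independent test mutation table
#'
#' A stand-in for the published 23-complex test table: 148 mutations with
#' effect categories distributed so that the Strong/Intermediate hot-spot
#' rule yields 80 hot spots and 68 non-hot spots.
#'
#' @param seed RNG seed.
#' @return data.frame with columns pdb_id, chain, resseq, icode, wt_aa,
#'   bid_category, is_antibody_complex.
#' @export
synthetic_bid_mutations <- function(seed = 42) {
  set.seed(seed)
  n <- 148
  cats <- c(rep("Strong", 45), rep("Intermediate", 35),
            rep("Weak", 25), rep("Insignificant", 30),
            rep("Negative-weak", 8), rep("Negative-strong", 5))
  complexes <- sprintf("BID%02d", 1:23)
  pdb <- sort(sample(rep(complexes, length.out = n)))
  out <- data.frame(
    pdb_id = pdb,
    chain = sample(c("A", "B"), n, replace = TRUE),
    resseq = NA_integer_,
    icode = "",
    wt_aa = sample(setdiff(AA_ONE, "A"), n, replace = TRUE),
    bid_category = sample(cats),
    is_antibody_complex = FALSE,
    stringsAsFactors = FALSE
  )
  for (p in complexes) {
    idx <- which(out$pdb_id == p)
    out$resseq[idx] <- sample(1:400, length(idx))
  }
  out
}
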