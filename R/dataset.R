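# Mutation labeling and model-matrix assembly.
#
# Mutation tables are CSVs keyed by (pdb_id, chain, resseq, icode) with
# either a ddg column (kcal/mol, alanine-scanning energies) or a
# bid_category column (Strong/Intermediate/Weak/Insignificant/
# Negative-weak/Negative-strong), plus an is_antibody_complex flag.

#' Hot-spot label from an alanine-scanning energy
#'
#' A mutation is a hot spot when the binding free-energy change on mutation
#' to alanine is at least \code{threshold} kcal/mol (inclusive).
#'
#' @param ddg numeric vector of energies (kcal/mol).
#' @param threshold hot-spot cutoff in kcal/mol (1.0 by default; 2.0 is the
#'   stricter definition used for balanced comparisons).
#' @return logical vector.
#' @export
label_from_ddg <- function(ddg, threshold = 1.0) {
  if (anyNA(ddg)) stop("missing ddg value(s)", call. = FALSE)
  ddg >= threshold
}

#' Hot-spot label from a BID effect category
#'
#' Strong and Intermediate mutations are hot spots; Weak, Insignificant,
#' Negative-weak and Negative-strong are not.
#'
#' @param category character vector of BID categories.
#' @return logical vector.
#' @export
label_from_bid <- function(category) {
  bad <- setdiff(category, BID_CATEGORIES)
  if (length(bad) > 0)
    stop("unknown BID category: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  category %in% BID_HOTSPOT_CATEGORIES
}

#' Read a mutation table CSV
#'
#' @param path CSV with columns pdb_id, chain, resseq, icode, wt_aa and one
#'   of ddg / bid_category, plus optionally is_antibody_complex.
#' @param threshold ddg hot-spot threshold passed to
#'   \code{\link{label_from_ddg}}.
#' @return data.frame with an added logical \code{label} column.
#' @export
read_mutations <- function(path, threshold = 1.0) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(icode = "character"))
  m$icode[is.na(m$icode)] <- ""
  if ("ddg" %in% names(m) && any(!is.na(m$ddg))) {
    m$label <- label_from_ddg(m$ddg, threshold)
  } else if ("bid_category" %in% names(m)) {
    m$label <- label_from_bid(m$bid_category)
  } else {
    stop("mutation table needs a ddg or bid_category column: ", path,
         call. = FALSE)
  }
  m
}

#' Assemble a model-ready dataset
#'
#' Joins per-residue feature tables onto labelled mutation rows by
#' (pdb_id, chain, resseq, icode) and builds the feature matrix for the
#' selected feature groups. Mutation rows whose residue fails the interface
#' filter (delta ASA >= 1 Angstrom^2) are dropped with a warning when ASA
#' features are available. Missing feature cells are imputed with the column
#' mean and flagged per row.
#'
#' @param features data.frame (or list of data.frames, merged by key) of
#'   per-residue features; columns beyond the key are feature candidates.
#' @param mutations labelled mutation data.frame (see
#'   \code{\link{read_mutations}}) or CSV path.
#' @param combo character vector of feature-group names among
#'   \code{names(FEATURE_GROUPS)}: ASA, BC, Phy, PSSM, ECS, SE.
#' @param threshold ddg threshold used when \code{mutations} is a path.
#' @param apply_interface_filter drop mutation rows not called interface
#'   residues (requires an \code{is_interface} column in \code{features}).
#' @return object of class \code{hs_dataset}: list with \code{records}
#'   (joined data.frame), \code{X} (numeric matrix), \code{y} (logical),
#'   \code{groups} (complex id per row), \code{combo}, \code{imputed}
#'   (logical per row).
#' @export
assemble_dataset <- function(features, mutations, combo,
                             threshold = 1.0, apply_interface_filter = TRUE) {
  if (length(combo) == 0) stop("empty feature combination", call. = FALSE)
  bad <- setdiff(combo, names(FEATURE_GROUPS))
  if (length(bad) > 0)
    stop("unknown feature group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.character(mutations)) mutations <- read_mutations(mutations, threshold)
  if (is.list(features) && !is.data.frame(features)) {
    key <- c("pdb_id", "chain", "resseq", "icode")
    features <- Reduce(function(x, y) {
      merge(x, y[, c(key, setdiff(names(y), names(x)))], by = key,
            all.x = TRUE, sort = FALSE)
    }, features)
  }
  key_of <- function(d) paste(d$pdb_id, d$chain, d$resseq, d$icode, sep = "|")
  fk <- key_of(features); mk <- key_of(mutations)
  idx <- match(mk, fk)
  if (anyNA(idx))
    stop("mutation rows with no feature record: ",
         paste(mk[is.na(idx)], collapse = "; "), call. = FALSE)
  rows <- cbind(mutations, features[idx, setdiff(names(features),
                                                 names(mutations)),
                                    drop = FALSE])
  if (apply_interface_filter && "is_interface" %in% names(rows)) {
    drop <- !rows$is_interface
    if (any(drop)) {
      warning(sum(drop), " mutation row(s) fail the interface filter ",
              "(delta ASA < 1 A^2) and were excluded", call. = FALSE)
      rows <- rows[!drop, , drop = FALSE]
    }
  }
  cols <- unlist(FEATURE_GROUPS[combo], use.names = FALSE)
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0)
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(rows[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  imputed <- unname(rowSums(is.na(X)) > 0)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) {
      mu <- mean(X[!nas, j])
      X[nas, j] <- if (is.finite(mu)) mu else 0
    }
  }
  structure(list(records = rows, X = X, y = rows$label,
                 groups = rows$pdb_id, combo = combo, imputed = imputed),
            class = "hs_dataset")
}

#' @export
print.hs_dataset <- function(x, ...) {
  cat(sprintf("<hs_dataset: %d rows (%d hot spots), %d features [%s]>\n",
              length(x$y), sum(x$y), ncol(x$X),
              paste(x$combo, collapse = "+")))
  invisible(x)
}

## Construct an hs_dataset directly from a matrix + labels (used by the
## synthetic generator and tests).
dataset_from_matrix <- function(X, y, groups = NULL, combo = "SYN") {
  stopifnot(nrow(X) == length(y))
  if (is.null(groups)) groups <- rep("synthetic", length(y))
  records <- data.frame(pdb_id = groups, label = y,
                        stringsAsFactors = FALSE)
  structure(list(records = records, X = X, y = y, groups = groups,
                 combo = combo, imputed = rep(FALSE, length(y))),
            class = "hs_dataset")
}

subset_dataset <- function(ds, keep) {
  structure(list(records = ds$records[keep, , drop = FALSE],
                 X = ds$X[keep, , drop = FALSE], y = ds$y[keep],
                 groups = ds$groups[keep], combo = ds$combo,
                 imputed = ds$imputed[keep]),
            class = "hs_dataset")
}

#' Balance a dataset by lowest-energy non-hot spots
#'
#' Keeps every hot spot plus the \code{n} non-hot-spot rows with the
#' smallest ddg (ties broken lexicographically by pdb_id, chain, resseq).
#' With \code{n} equal to the hot-spot count this yields the balanced
#' design used with the 2 kcal/mol hot-spot definition.
#'
#' @param ds an \code{hs_dataset} whose records carry a \code{ddg} column.
#' @param n number of non-hot spots to retain.
#' @return a subset \code{hs_dataset}, original row order preserved.
#' @export
balance_lowest_ddg <- function(ds, n) {
  stopifnot(inherits(ds, "hs_dataset"))
  if (!"ddg" %in% names(ds$records))
    stop("records lack a ddg column", call. = FALSE)
  non <- which(!ds$y)
  if (n > length(non))
    stop("requested ", n, " non-hot spots but only ", length(non),
         " available", call. = FALSE)
  r <- ds$records[non, , drop = FALSE]
  ord <- order(r$ddg, r$pdb_id, r$chain, r$resseq)
  keep_non <- non[ord[seq_len(n)]]
  keep <- sort(c(which(ds$y), keep_non))
  subset_dataset(ds, keep)
}

#' Split a dataset by antigen-antibody membership
#'
#' @param ds an \code{hs_dataset} whose records carry a logical
#'   \code{is_antibody_complex} column.
#' @return list with \code{ab_plus} (all rows) and \code{ab_minus} (rows of
#'   complexes not flagged antigen-antibody).
#' @export
split_ab <- function(ds) {
  stopifnot(inherits(ds, "hs_dataset"))
  flag <- ds$records$is_antibody_complex
  if (is.null(flag) || anyNA(flag))
    stop("records lack complete is_antibody_complex flags", call. = FALSE)
  flag <- as.logical(flag)
  ab_minus <- subset_dataset(ds, !flag)
  if (length(ab_minus$y) == 0)
    warning("all complexes are antigen-antibody; Ab- subset is empty",
            call. = FALSE)
  list(ab_plus = ds, ab_minus = ab_minus)
}
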