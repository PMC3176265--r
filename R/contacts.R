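# Cross-interface biochemical contacts: hydrogen bonds, salt bridges and
# van der Waals atomic contacts, counted per residue against the opposite
# binding partner only.

## All unordered point pairs with distance < cutoff, via a uniform cell grid
## (cell edge = cutoff, 27-neighbourhood scan). Returns a 2-column index
## matrix; the O(n^2) scan in the test-suite serves as its oracle.
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min), "-") / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  cut2 <- cutoff^2
  for (b in names(buckets)) {
    ids <- buckets[[b]]
    c0 <- as.integer(strsplit(b, ",", fixed = TRUE)[[1]])
    for (k in seq_len(nrow(offs))) {
      nb_key <- paste(c0 + offs[k, ], collapse = ",")
      jds <- buckets[[nb_key]]
      if (is.null(jds)) next
      for (i in ids) {
        js <- jds[jds > i]
        if (length(js) == 0) next
        d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
          (xyz[js, 3] - xyz[i, 3])^2
        hit <- js[d2 < cut2]
        if (length(hit) > 0) {
          out_i <- c(out_i, rep.int(i, length(hit)))
          out_j <- c(out_j, hit)
        }
      }
    }
  }
  cbind(out_i, out_j, deparse.level = 0)
}

## Cross-partner atom pairs with distance < cutoff, as a data.frame of
## (ia, ib, dist) where ia indexes atoms of `a` and ib atoms of `b`.
cross_pairs <- function(a, b, cutoff) {
  na <- nrow(a$atoms)
  xyz <- rbind(as.matrix(a$atoms[, c("x", "y", "z")]),
               as.matrix(b$atoms[, c("x", "y", "z")]))
  nb <- neighbor_pairs(xyz, cutoff)
  if (nrow(nb) == 0)
    return(data.frame(ia = integer(0), ib = integer(0), dist = numeric(0)))
  cross <- (nb[, 1] <= na) != (nb[, 2] <= na)
  nb <- nb[cross, , drop = FALSE]
  if (nrow(nb) == 0)
    return(data.frame(ia = integer(0), ib = integer(0), dist = numeric(0)))
  ia <- pmin(nb[, 1], nb[, 2])
  ib <- pmax(nb[, 1], nb[, 2]) - na
  d <- sqrt(rowSums((as.matrix(a$atoms[ia, c("x", "y", "z")]) -
                     as.matrix(b$atoms[ib, c("x", "y", "z")]))^2))
  data.frame(ia = ia, ib = ib, dist = d)
}

## Atom-level annotation helpers -------------------------------------------

charge_sign <- function(resid, elety, include_his = TRUE) {
  pos <- CHARGED_ATOMS_POSITIVE
  if (!include_his) pos$HIS <- NULL
  s <- integer(length(resid))
  for (r in names(pos)) s[resid == r & elety %in% pos[[r]]] <- 1L
  for (r in names(CHARGED_ATOMS_NEGATIVE))
    s[resid == r & elety %in% CHARGED_ATOMS_NEGATIVE[[r]]] <- -1L
  s
}

## is this atom a donor, and what is its antecedent atom name?
donor_antecedent <- function(resid, elety) {
  out <- rep(NA_character_, length(resid))
  out[elety == "N" & resid != "PRO"] <- "CA"
  for (r in names(HB_DONORS)) {
    tab <- HB_DONORS[[r]]
    hit <- resid == r & elety %in% names(tab)
    out[hit] <- tab[elety[hit]]
  }
  out
}

is_acceptor <- function(resid, elety) {
  out <- elety == "O" | elety == "OXT"
  for (r in names(HB_ACCEPTORS)) out <- out | (resid == r & elety %in% HB_ACCEPTORS[[r]])
  out
}

#' Cross-interface salt bridges of one residue
#'
#' Counts (negative, positive) side-chain atom pairs, one atom from each
#' binding partner, within \code{cutoff} (default 7 Angstrom) that involve
#' the given residue. Histidine ND1/NE2 count as positive unless
#' \code{include_his = FALSE}.
#'
#' @param a,b \code{hs_structure} partners.
#' @param chain,resseq,icode residue identifier (must lie in \code{a} or
#'   \code{b}).
#' @param cutoff distance threshold in Angstrom.
#' @param include_his treat histidine as positively charged.
#' @return integer count.
#' @export
salt_bridges <- function(a, b, chain, resseq, icode = "", cutoff = 7.0,
                         include_his = TRUE) {
  counts <- contact_counts(a, b, sb_cutoff = cutoff,
                           include_his = include_his)
  lookup_count(counts, chain, resseq, icode, "n_salt_bridges")
}

#' Cross-interface hydrogen bonds of one residue
#'
#' Heavy-atom geometric criterion: donor--acceptor distance at most
#' \code{dist_cutoff} and the angle antecedent--donor--acceptor at least
#' \code{min_angle} degrees, donors/acceptors from an embedded per-residue
#' table. Both orientations (donor on either partner) are counted.
#'
#' @inheritParams salt_bridges
#' @param dist_cutoff donor-to-acceptor heavy-atom distance (Angstrom).
#' @param min_angle minimum angle at the donor (degrees).
#' @return integer count.
#' @export
hydrogen_bonds <- function(a, b, chain, resseq, icode = "",
                           dist_cutoff = 3.5, min_angle = 90) {
  counts <- contact_counts(a, b, hb_dist = dist_cutoff, hb_angle = min_angle)
  lookup_count(counts, chain, resseq, icode, "n_hbonds")
}

#' Cross-interface atomic contacts of one residue
#'
#' Heavy-atom pairs, one per partner, closer than the sum of their van der
#' Waals radii plus \code{slack} Angstrom.
#'
#' @inheritParams salt_bridges
#' @param slack distance slack beyond the radii sum (Angstrom).
#' @return integer count.
#' @export
atomic_contacts <- function(a, b, chain, resseq, icode = "", slack = 0.25) {
  counts <- contact_counts(a, b, ac_slack = slack)
  lookup_count(counts, chain, resseq, icode, "n_atomic_contacts")
}

lookup_count <- function(counts, chain, resseq, icode, col) {
  hit <- counts$chain == chain & counts$resseq == resseq &
    counts$icode == icode
  if (!any(hit))
    stop("residue ", residue_id(chain, resseq, icode),
         " not found in either partner", call. = FALSE)
  counts[[col]][hit]
}

## Per-residue contact table for all residues of both partners.
contact_counts <- function(a, b, hb_dist = 3.5, hb_angle = 90,
                           sb_cutoff = 7.0, ac_slack = 0.25,
                           include_his = TRUE,
                           radii = VDW_RADII, fallback_radius = 1.8) {
  aa_ <- a$atoms; ab <- b$atoms
  rk <- rbind(residue_keys(a), residue_keys(b))
  rid_all <- residue_id(rk$chain, rk$resno, rk$insert)
  out <- data.frame(chain = rk$chain, resseq = rk$resno, icode = rk$insert,
                    n_hbonds = 0L, n_salt_bridges = 0L,
                    n_atomic_contacts = 0L, stringsAsFactors = FALSE)
  maxcut <- max(sb_cutoff, hb_dist,
                2 * max(vdw_radius(c(aa_$elesy, ab$elesy), radii = radii,
                                   fallback = fallback_radius)) + ac_slack)
  pr <- cross_pairs(a, b, maxcut)
  if (nrow(pr) == 0) return(out)

  rid_a <- atom_residue_id(a); rid_b <- atom_residue_id(b)
  add <- function(col, ia, ib) {
    t1 <- table(factor(rid_a[ia], levels = rid_all))
    t2 <- table(factor(rid_b[ib], levels = rid_all))
    out[[col]] <<- out[[col]] + as.integer(t1 + t2)
  }

  ## salt bridges: opposite formal signs within cutoff
  sa <- charge_sign(aa_$resid, aa_$elety, include_his)
  sb_ <- charge_sign(ab$resid, ab$elety, include_his)
  hit <- pr$dist < sb_cutoff & sa[pr$ia] * sb_[pr$ib] == -1L
  add("n_salt_bridges", pr$ia[hit], pr$ib[hit])

  ## atomic contacts: vdW overlap within slack
  ra <- vdw_radius(aa_$elesy, radii = radii, fallback = fallback_radius)
  rb <- vdw_radius(ab$elesy, radii = radii, fallback = fallback_radius)
  hit <- pr$dist < ra[pr$ia] + rb[pr$ib] + ac_slack
  add("n_atomic_contacts", pr$ia[hit], pr$ib[hit])

  ## hydrogen bonds, both donor orientations
  hb_hits <- function(don, acc, pr_d, pr_a) {
    ante <- donor_antecedent(don$atoms$resid, don$atoms$elety)
    accf <- is_acceptor(acc$atoms$resid, acc$atoms$elety)
    cand <- which(pr$dist <= hb_dist & !is.na(ante[pr_d]) & accf[pr_a])
    keep <- logical(length(cand))
    rid_d <- atom_residue_id(don)
    for (k in seq_along(cand)) {
      i <- pr_d[cand[k]]; j <- pr_a[cand[k]]
      ## antecedent atom within the donor residue
      ai <- which(rid_d == rid_d[i] & don$atoms$elety == ante[i])
      if (length(ai) == 0) { keep[k] <- TRUE; next }  # no antecedent resolved
      v1 <- unlist(don$atoms[ai[1], c("x", "y", "z")]) -
        unlist(don$atoms[i, c("x", "y", "z")])
      v2 <- unlist(acc$atoms[j, c("x", "y", "z")]) -
        unlist(don$atoms[i, c("x", "y", "z")])
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      keep[k] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= hb_angle
    }
    cand[keep]
  }
  h1 <- hb_hits(a, b, pr$ia, pr$ib)   # donor on side a
  h2 <- hb_hits(b, a, pr$ib, pr$ia)   # donor on side b
  add("n_hbonds", c(pr$ia[h1], pr$ia[h2]), c(pr$ib[h1], pr$ib[h2]))
  out
}

#' Contact features for one residue of a complex
#'
#' Aggregates cross-interface hydrogen bonds, salt bridges and atomic
#' contacts for a residue against the opposite partner only.
#'
#' @param complex an \code{hs_structure}.
#' @param spec a \code{\link{partner_spec}}.
#' @param chain,resseq,icode residue identifier.
#' @param ... tuning parameters passed to the individual counters
#'   (\code{hb_dist}, \code{hb_angle}, \code{sb_cutoff}, \code{ac_slack},
#'   \code{include_his}).
#' @return one-row data.frame with \code{n_hbonds}, \code{n_salt_bridges},
#'   \code{n_atomic_contacts}.
#' @export
contact_features <- function(complex, spec, chain, resseq, icode = "", ...) {
  parts <- split_partners(complex, spec)
  counts <- contact_counts(parts$a, parts$b, ...)
  hit <- counts$chain == chain & counts$resseq == resseq &
    counts$icode == icode
  if (!any(hit))
    stop("residue ", residue_id(chain, resseq, icode),
         " not found in either partner", call. = FALSE)
  counts[hit, c("n_hbonds", "n_salt_bridges", "n_atomic_contacts"),
         drop = FALSE]
}

## Full contact table for a complex (all residues of both sides).
contact_feature_table <- function(complex, spec, ...) {
  parts <- split_partners(complex, spec)
  contact_counts(parts$a, parts$b, ...)
}
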