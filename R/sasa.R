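# Solvent-accessible surface area: Shrake-Rupley sphere-point sampling and
# the derived interface features (delta ASA, relative burial, relASA).
#
# Test points are placed on a golden-spiral lattice, so results are exactly
# reproducible for a fixed number of points. Accuracy is limited by the
# quadrature: the isolated-sphere error is O(1/n_points).

## n approximately evenly spaced unit vectors (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples points on the solvent-expanded sphere of every heavy atom and
#' counts the fraction not occluded by any neighbouring atom's expanded
#' sphere. Deterministic for a fixed \code{n_points}.
#'
#' @param s an \code{hs_structure}.
#' @param probe probe sphere radius in Angstrom (water = 1.4).
#' @param n_points sphere sample points per atom; the isolated-atom error
#'   decreases as 1/n_points.
#' @param radii named per-element van der Waals radii (Angstrom).
#' @param radii_overrides optional named vector of per-atom-name radius
#'   overrides.
#' @param fallback_radius radius for elements absent from \code{radii};
#'   \code{NA} (default) makes unknown elements an error.
#' @return list of class \code{sasa_result} with \code{per_atom} (Angstrom^2,
#'   one value per atom row), \code{per_residue} (named by
#'   \code{chain|resno|insert}), \code{probe_radius}, \code{n_sphere_points}.
#' @export
shrake_rupley <- function(s, probe = 1.4, n_points = 960, radii = VDW_RADII,
                          radii_overrides = NULL, fallback_radius = NA_real_) {
  stopifnot(inherits(s, "hs_structure"))
  a <- s$atoms
  n <- nrow(a)
  if (n == 0) stop("empty structure", call. = FALSE)
  rad <- vdw_radius(a$elesy, a$elety, radii = radii,
                    overrides = radii_overrides, fallback = fallback_radius)
  rext <- rad + probe
  xyz <- cbind(a$x, a$y, a$z)
  pts <- sphere_points(n_points)

  ## neighbour candidates via cell list on the largest interaction distance
  maxcut <- 2 * max(rext)
  nb <- neighbor_pairs(xyz, maxcut)
  ## adjacency lists (symmetric)
  adj <- vector("list", n)
  if (nrow(nb) > 0) {
    keep <- sqrt(rowSums((xyz[nb[, 1], , drop = FALSE] -
                          xyz[nb[, 2], , drop = FALSE])^2)) <
      (rext[nb[, 1]] + rext[nb[, 2]])
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb) > 0) {
      adj <- split(c(nb[, 2], nb[, 1]), factor(c(nb[, 1], nb[, 2]),
                                               levels = seq_len(n)))
    }
  }

  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    js <- adj[[i]]
    for (j in js) {
      if (!any(acc)) break
      d2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- d2 >= rext[j]^2
    }
    per_atom[i] <- 4 * pi * rext[i]^2 * sum(acc) / n_points
  }

  rid <- atom_residue_id(s)
  per_residue <- tapply(per_atom, factor(rid, levels = unique(rid)), sum)
  structure(list(per_atom = per_atom,
                 per_residue = per_residue[],
                 probe_radius = probe, n_sphere_points = n_points),
            class = "sasa_result")
}

#' Reference tripeptide accessibility for a residue type
#'
#' All-atom accessibility of residue type X in an extended ALA-X-ALA
#' tripeptide, used as the denominator of relASA.
#'
#' @param aa one-letter code(s).
#' @return area(s) in Angstrom^2.
#' @export
reference_area <- function(aa) {
  out <- TRIPEPTIDE_REF_ASA[aa]
  if (anyNA(out))
    stop("no reference area for residue type(s): ",
         paste(unique(aa[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

## Full per-residue ASA feature table for a complex: monomer-state ASA is
## computed on each isolated partner (identical coordinates), complex-state
## ASA on the whole assembly. Negative delta_asa within quadrature noise
## (0.1 A^2) clamps to 0. delta_asa_pct is NA when asa_monomer is 0.
asa_feature_table <- function(complex, spec, probe = 1.4, n_points = 960,
                              interface_min_dasa = 1.0, ...) {
  parts <- split_partners(complex, spec)
  sasa_cx <- shrake_rupley(complex, probe = probe, n_points = n_points, ...)
  sasa_a <- shrake_rupley(parts$a, probe = probe, n_points = n_points, ...)
  sasa_b <- shrake_rupley(parts$b, probe = probe, n_points = n_points, ...)

  rk <- residue_keys(complex)
  rid <- residue_id(rk$chain, rk$resno, rk$insert)
  mono <- c(sasa_a$per_residue, sasa_b$per_residue)[rid]
  cx <- sasa_cx$per_residue[rid]
  delta <- mono - cx
  delta[delta < 0 & delta > -0.1] <- 0
  pct <- ifelse(mono > 0, 100 * delta / mono, NA_real_)
  rel <- cx / reference_area_safe(rk$aa)
  data.frame(
    pdb_id = complex$pdb_id, chain = rk$chain, resseq = rk$resno,
    icode = rk$insert, aa = rk$aa,
    asa_monomer = unname(mono), asa_complex = unname(cx),
    delta_asa = unname(delta), delta_asa_pct = unname(pct),
    rel_asa = unname(rel),
    is_interface = unname(delta >= interface_min_dasa),
    stringsAsFactors = FALSE
  )
}

## relASA denominator; unknown residue types ('X') give NA rather than error
## so that het/nonstandard rows propagate as missing.
reference_area_safe <- function(aa) {
  out <- TRIPEPTIDE_REF_ASA[aa]
  unname(out)
}

#' Interface ASA features for one residue
#'
#' Computes monomer-state and complex-state accessibility of a residue, the
#' absolute and relative change on binding, relASA against the extended
#' tripeptide reference, and the interface call (delta ASA >= 1 Angstrom^2).
#'
#' @param complex an \code{hs_structure} of the full complex.
#' @param spec a \code{\link{partner_spec}}.
#' @param chain,resseq,icode residue identifier (author numbering).
#' @param ... passed to \code{\link{shrake_rupley}}.
#' @return one-row data.frame with columns \code{asa_monomer},
#'   \code{asa_complex}, \code{delta_asa}, \code{delta_asa_pct},
#'   \code{rel_asa}, \code{is_interface}.
#' @export
residue_asa_features <- function(complex, spec, chain, resseq, icode = "",
                                 ...) {
  tab <- asa_feature_table(complex, spec, ...)
  hit <- tab$chain == chain & tab$resseq == resseq & tab$icode == icode
  if (!any(hit))
    stop("residue ", residue_id(chain, resseq, icode),
         " not found in structure", call. = FALSE)
  tab[hit, , drop = FALSE]
}
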