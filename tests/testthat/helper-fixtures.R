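# Hand-built miniature structures for geometry tests.

## data.frame-of-atoms constructor: each atom is
## list(chain, resno, resid, elety, elesy, x, y, z)
mini_structure <- function(atoms, pdb_id = "MINI") {
  df <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(chain = a$chain, resno = a$resno, insert = "",
               resid = a$resid, aa = hotspotr:::aa_one_letter(a$resid),
               elety = a$elety, elesy = a$elesy,
               x = a$x, y = a$y, z = a$z, o = 1, is_hetero = FALSE,
               stringsAsFactors = FALSE)
  }))
  hotspotr:::new_structure(df, pdb_id = pdb_id)
}

atomd <- function(chain, resno, resid, elety, elesy, x, y = 0, z = 0) {
  list(chain = chain, resno = resno, resid = resid, elety = elety,
       elesy = elesy, x = x, y = y, z = z)
}

## brute-force O(n^2) neighbour-pair oracle
brute_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sum((xyz[i, ] - xyz[j, ])^2) < cutoff^2)
      out <- rbind(out, c(i, j))
  }
  out
}

canon_pairs <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

## features + mutations CSV pair with a separable physicochemical signal,
## for CLI round trips
write_separable_csvs <- function(dir, n = 60, seed = 1, d = 3) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  phy <- hotspotr:::FEATURE_GROUPS$Phy
  X <- matrix(rnorm(n * length(phy)), n)
  X[y, ] <- X[y, ] + d
  colnames(X) <- phy
  feats <- cbind(data.frame(pdb_id = "SYN01", chain = "A", resseq = seq_len(n),
                            icode = "", aa = "K", stringsAsFactors = FALSE),
                 as.data.frame(X))
  muts <- data.frame(pdb_id = "SYN01", chain = "A", resseq = seq_len(n),
                     icode = "", wt_aa = "K", ddg = ifelse(y, 2.5, 0.2),
                     is_antibody_complex = FALSE, stringsAsFactors = FALSE)
  fp <- file.path(dir, "features.csv"); mp <- file.path(dir, "mutations.csv")
  write.csv(feats, fp, row.names = FALSE)
  write.csv(muts, mp, row.names = FALSE)
  list(features = fp, mutations = mp, y = y)
}
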