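test_that("ddg labeling is inclusive at the threshold", {
  expect_true(label_from_ddg(1.0, 1.0))
  expect_false(label_from_ddg(0.99, 1.0))
  expect_true(label_from_ddg(2.0, 2.0))
  expect_false(label_from_ddg(1.99, 2.0))
  expect_error(label_from_ddg(c(1, NA)), "missing")
  ## raising the threshold never increases the hot-spot count
  set.seed(1)
  ddg <- rnorm(200, 1, 1.5)
  counts <- vapply(c(0.5, 1, 1.5, 2, 3),
                   function(th) sum(label_from_ddg(ddg, th)), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(sum(label_from_ddg(ddg, 1)) + sum(!label_from_ddg(ddg, 1)),
               length(ddg))
})

test_that("BID categories map Strong/Intermediate to hot spots", {
  expect_true(all(label_from_bid(c("Strong", "Intermediate"))))
  expect_false(any(label_from_bid(c("Weak", "Insignificant",
                                    "Negative-weak", "Negative-strong"))))
  expect_error(label_from_bid("Moderate"), "Moderate")
})

test_that("shipped synthetic study tables reproduce the design margins", {
  tr <- read.csv(system.file("extdata", "synthetic_training_mutations.csv",
                             package = "hotspotr"))
  expect_equal(nrow(tr), 377)
  expect_equal(sum(label_from_ddg(tr$ddg, 1)), 182)
  expect_equal(sum(!label_from_ddg(tr$ddg, 1)), 195)
  expect_equal(sum(label_from_ddg(tr$ddg, 2)), 84)
  te <- read.csv(system.file("extdata", "synthetic_bid_mutations.csv",
                             package = "hotspotr"))
  expect_equal(nrow(te), 148)
  expect_equal(sum(label_from_bid(te$bid_category)), 80)
  ## the shipped files equal the generator output at the recorded seed
  expect_equal(tr$ddg, synthetic_training_mutations(seed = 42)$ddg)
})

make_feature_frame <- function(n = 10) {
  cols <- unlist(hotspotr:::FEATURE_GROUPS, use.names = FALSE)
  X <- matrix(rnorm(n * length(cols)), n, dimnames = list(NULL, cols))
  cbind(data.frame(pdb_id = "SYN01", chain = "A", resseq = seq_len(n),
                   icode = "", aa = "K", is_interface = TRUE,
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}

make_mutation_frame <- function(n = 10, ddg = NULL) {
  if (is.null(ddg)) ddg <- seq(-0.5, 3.5, length.out = n)
  data.frame(pdb_id = "SYN01", chain = "A", resseq = seq_len(n), icode = "",
             wt_aa = "K", ddg = ddg, is_antibody_complex = FALSE,
             stringsAsFactors = FALSE)
}

test_that("assembled matrices have the column arithmetic of their combos", {
  feats <- make_feature_frame(12)
  muts <- make_mutation_frame(12)
  muts$label <- label_from_ddg(muts$ddg)
  ds <- assemble_dataset(feats, muts, combo = c("Phy", "PSSM", "ECS", "SE"))
  expect_equal(ncol(ds$X), 6 + 20 + 1 + 1)
  ds2 <- assemble_dataset(feats, muts, combo = c("ASA", "BC"))
  expect_equal(ncol(ds2$X), 5 + 3)
  expect_equal(length(ds$y), 12)
  expect_error(assemble_dataset(feats, muts, combo = character(0)), "empty")
  expect_error(assemble_dataset(feats, muts, combo = "XYZ"), "XYZ")
  ## unresolvable key
  bad <- muts; bad$resseq[1] <- 999
  expect_error(assemble_dataset(feats, bad, combo = "Phy"), "999")
})

test_that("interface filter excludes non-interface rows with a warning", {
  feats <- make_feature_frame(8)
  feats$is_interface[c(2, 5)] <- FALSE
  muts <- make_mutation_frame(8)
  muts$label <- label_from_ddg(muts$ddg)
  expect_warning(ds <- assemble_dataset(feats, muts, combo = "Phy"),
                 "interface")
  expect_equal(length(ds$y), 6)
})

test_that("missing feature cells are mean-imputed and flagged", {
  feats <- make_feature_frame(8)
  feats$hydrophobicity[3] <- NA
  muts <- make_mutation_frame(8)
  muts$label <- label_from_ddg(muts$ddg)
  ds <- assemble_dataset(feats, muts, combo = "Phy")
  expect_false(anyNA(ds$X))
  expect_equal(which(ds$imputed), 3)
  expect_equal(ds$X[3, "hydrophobicity"],
               mean(feats$hydrophobicity[-3]))
})

test_that("balancing keeps hot spots plus the lowest-ddg non-hot spots", {
  feats <- make_feature_frame(8)
  ddg <- c(2.5, 0.4, 3.0, 0.9, 0.1, 1.5, 0.7, 0.2)
  muts <- make_mutation_frame(8, ddg = ddg)
  muts$label <- label_from_ddg(muts$ddg)
  ds <- assemble_dataset(feats, muts, combo = "Phy")  # 3 hot, 5 non-hot
  bal <- balance_lowest_ddg(ds, 3)
  expect_equal(length(bal$y), 6)
  expect_equal(sum(bal$y), 3)
  expect_setequal(bal$records$ddg[!bal$y], c(0.1, 0.2, 0.4))
  expect_error(balance_lowest_ddg(ds, 6), "only 5")
  ## ties at the cutoff resolve by lexicographic residue key
  muts2 <- make_mutation_frame(8, ddg = c(2.5, 0.5, 3.0, 0.5, 0.5, 1.5,
                                          0.5, 0.2))
  muts2$label <- label_from_ddg(muts2$ddg)
  ds2 <- assemble_dataset(feats, muts2, combo = "Phy")
  bal2 <- balance_lowest_ddg(ds2, 2)
  expect_equal(sort(bal2$records$resseq[!bal2$y]), c(2, 8))
})

test_that("antibody split keeps all rows in Ab+ and drops flagged complexes", {
  feats <- make_feature_frame(9)
  muts <- make_mutation_frame(9)
  muts$label <- label_from_ddg(muts$ddg)
  muts$pdb_id <- rep(c("SYN01", "SYN02", "SYN03"), each = 3)
  feats$pdb_id <- muts$pdb_id
  muts$is_antibody_complex <- muts$pdb_id == "SYN02"
  ds <- assemble_dataset(feats, muts, combo = "Phy")
  sp <- split_ab(ds)
  expect_equal(length(sp$ab_plus$y), 9)
  expect_equal(length(sp$ab_minus$y), 6)
  expect_false("SYN02" %in% sp$ab_minus$groups)
  ## no antibody complexes: identity
  muts$is_antibody_complex <- FALSE
  sp2 <- split_ab(assemble_dataset(feats, muts, combo = "Phy"))
  expect_equal(sp2$ab_minus$y, sp2$ab_plus$y)
  ## all antibody: empty with a warning
  muts$is_antibody_complex <- TRUE
  expect_warning(sp3 <- split_ab(assemble_dataset(feats, muts,
                                                  combo = "Phy")), "empty")
  expect_length(sp3$ab_minus$y, 0)
})
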