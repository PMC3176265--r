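## two single-residue partners with a charged pair at distance d
charged_pair <- function(d, res_b = "GLU", atom_b = "OE1") {
  a <- mini_structure(list(atomd("A", 1, "LYS", "CA", "C", 0, 0),
                           atomd("A", 1, "LYS", "NZ", "N", 0, 6.8)))
  b <- mini_structure(list(atomd("B", 1, res_b, "CA", "C", 0, 6.8 + d + 2),
                           atomd("B", 1, res_b, atom_b, "O", 0, 6.8 + d)))
  list(a = a, b = b)
}

test_that("salt bridges obey the 7 Angstrom opposite-charge rule", {
  p <- charged_pair(6.9)
  expect_equal(salt_bridges(p$a, p$b, "A", 1), 1L)
  p <- charged_pair(7.1)
  expect_equal(salt_bridges(p$a, p$b, "A", 1), 0L)
  ## same-sign pair never counts
  b_arg <- mini_structure(list(atomd("B", 1, "ARG", "CA", "C", 0, 14),
                               atomd("B", 1, "ARG", "NH1", "N", 0, 12)))
  a <- charged_pair(5)$a
  expect_equal(salt_bridges(a, b_arg, "A", 1), 0L)
  ## histidine positivity is switchable
  b_his <- mini_structure(list(atomd("B", 1, "HIS", "CA", "C", 0, 12),
                               atomd("B", 1, "HIS", "ND1", "N", 0, 10)))
  a_glu <- mini_structure(list(atomd("A", 1, "GLU", "CA", "C", 0, 0),
                               atomd("A", 1, "GLU", "OE1", "O", 0, 5)))
  expect_equal(salt_bridges(a_glu, b_his, "A", 1), 1L)
  expect_equal(salt_bridges(a_glu, b_his, "A", 1, include_his = FALSE), 0L)
})

test_that("hydrogen bonds need donor/acceptor identity, distance and angle", {
  ## SER OG (donor, antecedent CB) facing a partner backbone O
  ser_at <- function(d) mini_structure(list(
    atomd("A", 1, "SER", "CB", "C", 0, -1.5),
    atomd("A", 1, "SER", "OG", "O", 0, 0),
    atomd("A", 1, "SER", "CA", "C", 0, -2.5)))
  bb <- function(y) mini_structure(list(
    atomd("B", 1, "GLY", "C", "C", 0.5, y + 1.2),
    atomd("B", 1, "GLY", "O", "O", 0, y),
    atomd("B", 1, "GLY", "CA", "C", 1.5, y + 2)))
  expect_equal(hydrogen_bonds(ser_at(), bb(2.9), "A", 1), 1L)
  expect_equal(hydrogen_bonds(ser_at(), bb(4.2), "A", 1), 0L)
  ## acceptor behind the antecedent: angle < 90 degrees fails
  bad <- mini_structure(list(
    atomd("B", 1, "GLY", "C", "C", 0.5, -4.2),
    atomd("B", 1, "GLY", "O", "O", 0, -3.0),   # 3.0 A but behind CB
    atomd("B", 1, "GLY", "CA", "C", 1.5, -5)))
  expect_equal(hydrogen_bonds(ser_at(), bad, "A", 1), 0L)
  ## ALA has no side-chain donor/acceptor: nothing beyond backbone range
  ala <- mini_structure(list(atomd("A", 1, "ALA", "CB", "C", 0, 0)))
  far <- mini_structure(list(atomd("B", 1, "ALA", "CB", "C", 0, 4.5)))
  expect_equal(hydrogen_bonds(ala, far, "A", 1), 0L)
})

test_that("atomic contacts use the van der Waals overlap slack", {
  carbons <- function(d) list(
    a = mini_structure(list(atomd("A", 1, "ALA", "CB", "C", 0, 0))),
    b = mini_structure(list(atomd("B", 1, "ALA", "CB", "C", 0, d))))
  ## default radii C = 1.76: threshold 3.77
  p <- carbons(3.5)
  expect_equal(atomic_contacts(p$a, p$b, "A", 1), 1L)
  p <- carbons(3.8)
  expect_equal(atomic_contacts(p$a, p$b, "A", 1), 0L)
  p <- carbons(20)
  expect_equal(atomic_contacts(p$a, p$b, "A", 1), 0L)
  ## monotone in slack
  p <- carbons(4.0)
  expect_equal(atomic_contacts(p$a, p$b, "A", 1, slack = 0.6), 1L)
})

test_that("contact_features aggregates the three counters per residue", {
  ## constructed truth: salt bridge at 3.2 A that is also a vdW contact,
  ## with the donor antecedent placed so the H-bond angle test fails
  a <- mini_structure(list(atomd("A", 1, "LYS", "CE", "C", 0, 1.0),
                           atomd("A", 1, "LYS", "NZ", "N", 0, 0)))
  b <- mini_structure(list(atomd("B", 1, "GLU", "CD", "C", 0, 4.4),
                           atomd("B", 1, "GLU", "OE1", "O", 0, 3.2)))
  cx <- hotspotr:::new_structure(rbind(a$atoms, b$atoms))
  cf <- contact_features(cx, partner_spec("A", "B"), "A", 1)
  expect_equal(cf$n_hbonds, 0L)          # angle CE-NZ-OE1 = 0 < 90
  expect_equal(cf$n_salt_bridges, 1L)
  expect_gte(cf$n_atomic_contacts, 1L)
  ## fully separated partners: all zero
  s <- make_toy_complex(n_res = 3, gap = 100)
  cf0 <- contact_features(s, partner_spec("A", "B"), "A", 1)
  expect_equal(unlist(cf0), c(n_hbonds = 0L, n_salt_bridges = 0L,
                              n_atomic_contacts = 0L))
  expect_error(contact_features(s, partner_spec("A", "B"), "C", 1),
               "not found")
})

test_that("accelerated neighbour search equals the brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:60, 1)
    xyz <- matrix(runif(n * 3, 0, 15), n, 3)
    cutoff <- runif(1, 2, 8)
    fast <- canon_pairs(hotspotr:::neighbor_pairs(xyz, cutoff))
    slow <- canon_pairs(brute_pairs(xyz, cutoff))
    expect_equal(unname(fast), unname(slow))
  }
})

test_that("counters are symmetric across sides and rigid-motion invariant", {
  s <- make_toy_complex(n_res = 5, gap = 0.6,
                        contacts = list(list(type = "salt_bridge",
                                             res_a = 2, res_b = 2,
                                             dist = 6.5)))
  tab <- hotspotr:::contact_feature_table(s, partner_spec("A", "B"))
  a_rows <- tab$chain == "A"
  for (col in c("n_hbonds", "n_salt_bridges", "n_atomic_contacts")) {
    expect_equal(sum(tab[[col]][a_rows]), sum(tab[[col]][!a_rows]))
  }
  ## rigid rotation + translation of the whole complex
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2$atoms$x <- xyz[, 1] + 5; s2$atoms$y <- xyz[, 2] - 3
  s2$atoms$z <- xyz[, 3] + 11
  tab2 <- hotspotr:::contact_feature_table(s2, partner_spec("A", "B"))
  expect_equal(tab2[, 4:6], tab[, 4:6])
  ## enlarging cutoffs never decreases counts
  wide <- hotspotr:::contact_feature_table(s, partner_spec("A", "B"),
                                           sb_cutoff = 9, hb_dist = 4.5,
                                           ac_slack = 1)
  expect_true(all(wide$n_salt_bridges >= tab$n_salt_bridges))
  expect_true(all(wide$n_hbonds >= tab$n_hbonds))
  expect_true(all(wide$n_atomic_contacts >= tab$n_atomic_contacts))
})
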