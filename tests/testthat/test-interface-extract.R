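test_that("heavy-atom contact respects the inclusive 4.5 A boundary", {
  r1 <- data.frame(x = 0, y = 0, z = 0)
  at <- function(d) data.frame(x = d, y = 0, z = 0)
  expect_true(heavy_atom_contact(r1, at(4.4)))
  expect_false(heavy_atom_contact(r1, at(4.6)))
  expect_true(heavy_atom_contact(r1, at(4.5)))   # boundary inclusive
  expect_error(heavy_atom_contact(r1, r1[0, ]),
               class = "pcalign_data_error")
})

test_that("per-pair CA cutoffs follow mean + xi * sd and are symmetric", {
  m <- matrix(8, 20, 20); s <- matrix(0.5, 20, 20)
  m[3, 9] <- m[9, 3] <- 6.2   # D-K
  s[3, 9] <- s[9, 3] <- 0.8
  tab <- cutoff_table(m, s, xi = 0.5)
  expect_equal(ca_cutoff("D", "K", tab), 6.2 + 0.5 * 0.8)
  expect_equal(ca_cutoff("K", "D", tab), ca_cutoff("D", "K", tab))
  expect_equal(ca_cutoff("S", "K", cutoff_table(m, s, xi = 0)), 8)
  expect_error(ca_cutoff("Z", "K", tab), class = "pcalign_data_error")
})

test_that("cutoff table estimation pools contacting pairs and fills gaps", {
  # three S-K contacts with CA-CA distances 6, 7, 8 A
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- character(0)
  s <- 0L
  for (k in 1:3) {
    d <- c(6, 7, 8)[k]
    y0 <- (k - 1) * 40
    s <- s + 1L
    lines <- c(lines, pdb_atom_line(s, "CA", "SER", "A", k, 0, y0, 0,
                                    elem = "C"))
    s <- s + 1L
    lines <- c(lines, pdb_atom_line(s, "CB", "SER", "A", k, 2.2, y0, 0,
                                    elem = "C"))
    s <- s + 1L
    lines <- c(lines, pdb_atom_line(s, "CA", "LYS", "B", k, d, y0, 0,
                                    elem = "C"))
    s <- s + 1L
    lines <- c(lines, pdb_atom_line(s, "CB", "LYS", "B", k, d - 2.2, y0, 0,
                                    elem = "C"))
  }
  writeLines(c(lines, "END"), p)
  st <- read_structure(p)
  tab <- suppressMessages(compute_cutoff_table(list(st), xi = 0.5))
  expect_equal(tab$mean["S", "K"], 7)
  expect_equal(tab$sd["S", "K"], 1)
  expect_equal(ca_cutoff("S", "K", tab), 7.5)
  # unobserved pair types get the global fill, matrices stay symmetric
  expect_equal(tab$mean["W", "W"], 7)
  expect_equal(unname(tab$mean), unname(t(tab$mean)))
  expect_equal(unname(tab$sd), unname(t(tab$sd)))
})

test_that("cutoff tables round-trip through the text format", {
  tab <- uniform_cutoff_table(7.5, xi = 0.25)
  p <- withr::local_tempfile(fileext = ".txt")
  write_cutoff_table(tab, p)
  tab2 <- read_cutoff_table(p)
  expect_equal(tab2$mean, tab$mean)
  expect_equal(tab2$xi, 0.25)
})

test_that("atomic extraction matches the brute-force all-pairs oracle", {
  for (seed in 1:12) {
    p <- withr::local_tempfile(fileext = ".pdb")
    write_random_structure(p, nres = 5L, seed = seed)
    st <- read_structure(p)
    oracle <- brute_force_contacts(st, "A", "B")
    if (length(oracle) == 0L) {
      expect_error(extract_interface(st, "A", "B", mode = "atomic"),
                   class = "pcalign_data_error")
      next
    }
    iface <- extract_interface(st, "A", "B", mode = "atomic")
    rt <- pcalign:::residue_table(st)
    key <- function(i) paste(rt$chain[i], rt$resno[i])
    got <- sort(vapply(which(iface$contacts & upper.tri(iface$contacts)),
                       function(idx) {
                         ij <- arrayInd(idx, dim(iface$contacts))
                         paste(iface$residues$chain[ij[1]],
                               iface$residues$resno[ij[1]], "|",
                               iface$residues$chain[ij[2]],
                               iface$residues$resno[ij[2]])
                       }, character(1)))
    want <- sort(vapply(oracle, function(ij)
      paste(key(ij[1]), "|", key(ij[2])), character(1)))
    expect_identical(got, want)
  }
})

test_that("CA-only extraction uses the per-pair cutoff table", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, elem = "C"),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0, elem = "C"),
    pdb_atom_line(3, "CA", "LYS", "B", 1, 0, 7.2, 0, elem = "C"),
    pdb_atom_line(4, "CA", "GLY", "B", 2, 20, 7.2, 0, elem = "C"),
    "END"), p)
  st <- read_structure(p)
  # S-K cutoff 7.5 captures the 7.2 A pair; everything else is apart
  aa <- rownames(uniform_cutoff_table()$mean)
  m <- matrix(6, 20, 20, dimnames = list(aa, aa))
  m["S", "K"] <- m["K", "S"] <- 7.5
  tab <- cutoff_table(m, m * 0, xi = 0.5)
  iface <- extract_interface(st, "A", "B", mode = "ca_only", table = tab)
  expect_equal(nrow(iface$residues), 2L)
  expect_setequal(iface$residues$aa, c("S", "K"))
  # with a uniform 6 A table there is no interface at all
  expect_error(extract_interface(st, "A", "B", mode = "ca_only",
                                 table = uniform_cutoff_table(6)),
               class = "pcalign_data_error")
})

test_that("extraction is invariant under rigid motion of the structure", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_dimer(p)
  st <- read_structure(p)
  iface <- extract_interface(st, "A", "B")
  set.seed(42)
  r <- random_rotation()
  tr <- runif(3, -30, 30)
  st2 <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(r)
  st2$atoms$x <- xyz[, 1] + tr[1]
  st2$atoms$y <- xyz[, 2] + tr[2]
  st2$atoms$z <- xyz[, 3] + tr[3]
  iface2 <- extract_interface(st2, "A", "B")
  expect_identical(iface2$residues, iface$residues)
  expect_identical(iface2$contacts, iface$contacts)
})

test_that("contact-map restriction and interface invariants hold", {
  x <- generate_synthetic_interface(fixture_spec(8, seed = 5))
  n <- nrow(x$residues)
  expect_identical(contact_map_for(x, seq_len(n)), x$contacts)
  expect_identical(dim(contact_map_for(x, integer(0))), c(0L, 0L))
  i <- which(x$contacts[1, ])[1]
  expect_identical(contact_map_for(x, c(1L, i)),
                   matrix(c(FALSE, TRUE, TRUE, FALSE), 2L, 2L))
  expect_error(contact_map_for(x, c(1L, n + 1L)),
               class = "pcalign_data_error")
  # no orphan residues; symmetric map with empty intra-fragment blocks
  expect_true(all(rowSums(x$contacts) > 0))
  expect_identical(x$contacts, t(x$contacts))
  same_frag <- outer(x$residues$fragment, x$residues$fragment, `==`)
  expect_false(any(x$contacts & same_frag))
})
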