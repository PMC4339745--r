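# Shared test helpers: in-code PDB text builders and brute-force oracles.

# One ATOM record in fixed-width PDB layout.
pdb_atom_line <- function(serial, name, res3, chain, resno, x, y, z,
                          elem = substr(name, 1, 1), type = "ATOM",
                          altloc = " ", occ = 1, icode = " ") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, altloc, res3, chain, resno, icode,
          x, y, z, occ, 0, elem)
}

# A two-chain atomic dimer: each residue carries N, CA, C, O (+CB unless
# GLY), the chains facing each other across a `gap` Angstrom y-offset.
write_test_dimer <- function(path, resA = c("SER", "LYS", "ALA"),
                             resB = c("ARG", "ASP", "GLY"), gap = 5.2) {
  lines <- character(0)
  s <- 0L
  add <- function(name, res, chain, resno, x, y, z) {
    s <<- s + 1L
    lines <<- c(lines, pdb_atom_line(s, name, res, chain, resno, x, y, z))
  }
  for (i in seq_along(resA)) {
    x <- (i - 1) * 3.8
    z <- 1.1 * (i %% 2)  # zigzag keeps the CA trace non-collinear
    add("N", resA[i], "A", i, x - 0.5, 0.8, z)
    add("CA", resA[i], "A", i, x, 0.0, z)
    add("C", resA[i], "A", i, x + 0.8, -0.9, z + 0.4)
    add("O", resA[i], "A", i, x + 0.7, -1.9, z - 0.3)
    if (resA[i] != "GLY") add("CB", resA[i], "A", i, x + 0.3, 1.2, z + 1.1)
  }
  for (i in seq_along(resB)) {
    x <- (i - 1) * 3.8 + 0.6
    z <- 1.1 * (i %% 2)
    add("N", resB[i], "B", i, x - 0.5, gap + 0.6, z + 1.0)
    add("CA", resB[i], "B", i, x, gap, z + 1.3)
    add("C", resB[i], "B", i, x + 0.8, gap - 0.6, z + 1.9)
    add("O", resB[i], "B", i, x + 0.7, gap - 1.3, z + 2.9)
    if (resB[i] != "GLY") add("CB", resB[i], "B", i, x + 0.3, gap - 1.2,
                              z + 0.3)
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

# Random atomic two-chain structure written to a temp PDB: nres residues
# per chain, 1-4 heavy atoms each, coordinates in a box so that some
# inter-chain pairs fall under 4.5 A.
write_random_structure <- function(path, nres = 5L, seed = 1L) {
  set.seed(seed)
  aa3 <- c("ALA", "SER", "LYS", "ASP", "PHE", "HIS", "GLY", "THR")
  lines <- character(0)
  s <- 0L
  for (chain in c("A", "B")) {
    base <- if (chain == "A") c(0, 0, 0) else runif(3, 2, 6)
    for (i in seq_len(nres)) {
      res <- sample(aa3, 1)
      ctr <- base + runif(3, 0, 8)
      natoms <- sample(1:4, 1)
      names <- c("CA", "CB", "CG", "CD")[seq_len(natoms)]
      for (k in seq_len(natoms)) {
        p <- ctr + runif(3, -1, 1)
        s <- s + 1L
        lines <- c(lines, pdb_atom_line(s, names[k], res, chain, i,
                                        p[1], p[2], p[3], elem = "C"))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Brute-force maximum-weight perfect matching over min(n,m) pairs of a
# weight matrix, by enumeration over permutations (n, m <= 7).
brute_force_matching <- function(w) {
  n <- nrow(w); m <- ncol(w)
  flip <- n > m
  if (flip) w <- t(w)
  rows <- nrow(w); cols <- ncol(w)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(cols))) {
    tot <- sum(w[cbind(seq_len(rows), p[seq_len(rows)])])
    if (tot > best) best <- tot
  }
  best
}

# Brute-force interfacial extraction oracle: residue pairs across the two
# chain sets whose minimum heavy-atom distance is <= cutoff.
brute_force_contacts <- function(s, chains1, chains2, cutoff = 4.5) {
  at <- s$atoms
  rt <- pcalign:::residue_table(s)
  out <- list()
  for (i in which(rt$chain %in% chains1)) {
    ri <- at[at$chain == rt$chain[i] & at$resno == rt$resno[i] &
             at$insert == rt$insert[i], ]
    for (j in which(rt$chain %in% chains2)) {
      rj <- at[at$chain == rt$chain[j] & at$resno == rt$resno[j] &
               at$insert == rt$insert[j], ]
      dmin <- Inf
      for (a in seq_len(nrow(ri))) for (b in seq_len(nrow(rj))) {
        d <- sqrt(sum((c(ri$x[a], ri$y[a], ri$z[a]) -
                       c(rj$x[b], rj$y[b], rj$z[b]))^2))
        dmin <- min(dmin, d)
      }
      if (dmin <= cutoff) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] + q[1] * q[2]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[3] * q[4] - q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3L, 3L)
}
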