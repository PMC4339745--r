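# Per-amino-acid-pair C-alpha--C-alpha contact cutoffs.  For backbone-only
# models a residue pair counts as contacting when its CA-CA distance is at
# most  mean_{ij} + xi * sd_{ij},  where mean/sd are the statistics of CA-CA
# distances over heavy-atom-contacting inter-chain residue pairs of that
# amino-acid-type pair, pooled from atomic-resolution structures, and xi is
# a fixed multiplier (default 0.5).

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Cutoff tables for C-alpha-level contact detection
#'
#' A cutoff table holds symmetric 20 x 20 matrices of the mean and standard
#' deviation of CA-CA distances between heavy-atom-contacting residues of
#' each unordered amino-acid-type pair, plus the multiplier `xi`; the
#' effective cutoff for a pair is `mean + xi * sd` (see [ca_cutoff()]).
#' `cutoff_table()` builds one from full matrices, `uniform_cutoff_table()`
#' builds the documented flat fallback (a single distance for all pairs,
#' default 8 A with zero spread), and [compute_cutoff_table()] estimates one
#' from atomic-resolution structures.
#'
#' @param mean,sd symmetric 20 x 20 numeric matrices (Angstrom) with
#'   dimnames over the one-letter amino-acid codes.
#' @param xi non-negative multiplier applied to `sd` (default 0.5).
#' @return an object of class `pc_cutoff_table`.
#' @examples
#' tab <- uniform_cutoff_table()
#' ca_cutoff("S", "K", tab)
#' @export
cutoff_table <- function(mean, sd, xi = 0.5) {
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  stopifnot(all(dim(mean) == c(20L, 20L)), all(dim(sd) == c(20L, 20L)),
            xi >= 0)
  if (is.null(dimnames(mean))) dimnames(mean) <- list(.aa20, .aa20)
  if (is.null(dimnames(sd))) dimnames(sd) <- dimnames(mean)
  if (max(abs(mean - t(mean))) > 1e-9 || max(abs(sd - t(sd))) > 1e-9) {
    pc_stop_data("cutoff table matrices must be symmetric")
  }
  if (any(mean <= 0) || any(sd < 0)) {
    pc_stop_data("cutoff table needs mean > 0 and sd >= 0")
  }
  structure(list(mean = mean[.aa20, .aa20], sd = sd[.aa20, .aa20], xi = xi),
            class = "pc_cutoff_table")
}

#' @rdname cutoff_table
#' @param distance flat mean distance in Angstrom.
#' @export
uniform_cutoff_table <- function(distance = 8, xi = 0.5) {
  m <- matrix(distance, 20L, 20L, dimnames = list(.aa20, .aa20))
  cutoff_table(m, m * 0, xi = xi)
}

#' @export
print.pc_cutoff_table <- function(x, ...) {
  cat(sprintf("pc_cutoff_table: mean range [%.2f, %.2f] A, xi = %.2f\n",
              min(x$mean), max(x$mean), x$xi))
  invisible(x)
}

#' Effective CA-CA contact cutoff for an amino-acid pair
#'
#' @param aa1,aa2 one-letter codes.
#' @param table a `pc_cutoff_table`.
#' @return the cutoff `mean + xi * sd` in Angstrom; symmetric in the two
#'   codes.
#' @export
ca_cutoff <- function(aa1, aa2, table) {
  if (!all(c(aa1, aa2) %in% .aa20)) {
    pc_stop_data(paste0("amino-acid code absent from cutoff table: ",
                        paste(setdiff(c(aa1, aa2), .aa20), collapse = ", ")))
  }
  unname(table$mean[cbind(aa1, aa2)] + table$xi * table$sd[cbind(aa1, aa2)])
}

#' Estimate a cutoff table from atomic-resolution structures
#'
#' For every inter-chain residue pair in heavy-atom contact
#' ([heavy_atom_contact()], default 4.5 A), the CA-CA distance is recorded
#' and pooled by unordered amino-acid-type pair; each pair type's mean and
#' sd are its table entries.  Pair types with fewer than two observations
#' are filled with the global mean/sd over all recorded distances (reported
#' via `message()`).
#'
#' @param structures list of atomic-mode `pc_structure` objects.
#' @param heavy_cutoff heavy-atom contact distance, Angstrom.
#' @param xi multiplier stored in the resulting table.
#' @return a `pc_cutoff_table`.
#' @export
compute_cutoff_table <- function(structures, heavy_cutoff = 4.5, xi = 0.5) {
  if (inherits(structures, "pc_structure")) structures <- list(structures)
  structures <- Filter(function(s) s$mode == "atomic", structures)
  if (length(structures) == 0L) {
    pc_stop_data("no atomic-mode structures to estimate cutoffs from")
  }
  obs_a <- character(0); obs_b <- character(0); obs_d <- numeric(0)
  for (s in structures) {
    cp <- contact_pairs_atomic(s, unique(s$atoms$chain), heavy_cutoff)
    if (is.null(cp) || nrow(cp) == 0L) next
    obs_a <- c(obs_a, cp$aa1); obs_b <- c(obs_b, cp$aa2)
    obs_d <- c(obs_d, cp$ca_dist)
  }
  ok <- !is.na(obs_d)
  obs_a <- obs_a[ok]; obs_b <- obs_b[ok]; obs_d <- obs_d[ok]
  if (length(obs_d) < 2L) {
    pc_stop_data("fewer than two contacting residue pairs observed")
  }
  key <- paste(pmin(obs_a, obs_b), pmax(obs_a, obs_b))
  mu <- tapply(obs_d, key, mean)
  sg <- tapply(obs_d, key, stats::sd)
  n <- tapply(obs_d, key, length)
  gmu <- mean(obs_d); gsd <- stats::sd(obs_d)

  m <- matrix(gmu, 20L, 20L, dimnames = list(.aa20, .aa20))
  sdm <- matrix(gsd, 20L, 20L, dimnames = list(.aa20, .aa20))
  filled <- 0L
  for (i in seq_along(.aa20)) for (j in i:20L) {
    k <- paste(.aa20[i], .aa20[j])
    if (!is.na(mu[k]) && n[k] >= 2L) {
      m[i, j] <- m[j, i] <- mu[k]
      sdm[i, j] <- sdm[j, i] <- sg[k]
    } else {
      filled <- filled + 1L
    }
  }
  if (filled > 0L) {
    message(sprintf(
      "compute_cutoff_table: %d of 210 pair types had < 2 observations; filled with global mean %.2f A (sd %.2f A)",
      filled, gmu, gsd))
  }
  cutoff_table(m, sdm, xi = xi)
}

#' Read or write a cutoff table as whitespace-delimited text
#'
#' The format is one line per unordered pair, `AA1 AA2 mean sd`, preceded
#' by a comment line `# xi <value>`; all 210 unordered pairs must be
#' present on read.
#'
#' @param path file path.
#' @param table a `pc_cutoff_table` (for writing).
#' @return `read_cutoff_table()` returns a `pc_cutoff_table`;
#'   `write_cutoff_table()` returns `path` invisibly.
#' @export
read_cutoff_table <- function(path) {
  if (!file.exists(path)) pc_stop_user(paste0("file not found: ", path))
  lines <- readLines(path)
  xi_line <- grep("^#\\s*xi\\b", lines, value = TRUE)
  xi <- if (length(xi_line) > 0L) {
    as.numeric(sub("^#\\s*xi\\s+", "", xi_line[1]))
  } else 0.5
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- read.table(text = lines, col.names = c("aa1", "aa2", "mean", "sd"),
                      stringsAsFactors = FALSE)
  m <- matrix(NA_real_, 20L, 20L, dimnames = list(.aa20, .aa20))
  sdm <- m
  ok <- parts$aa1 %in% .aa20 & parts$aa2 %in% .aa20
  if (!all(ok)) pc_stop_data("cutoff table has unknown amino-acid codes")
  m[cbind(parts$aa1, parts$aa2)] <- parts$mean
  m[cbind(parts$aa2, parts$aa1)] <- parts$mean
  sdm[cbind(parts$aa1, parts$aa2)] <- parts$sd
  sdm[cbind(parts$aa2, parts$aa1)] <- parts$sd
  if (anyNA(m)) pc_stop_data("cutoff table is missing amino-acid pairs")
  cutoff_table(m, sdm, xi = xi)
}

#' @rdname read_cutoff_table
#' @export
write_cutoff_table <- function(table, path) {
  stopifnot(inherits(table, "pc_cutoff_table"))
  lines <- c(sprintf("# xi %g", table$xi))
  for (i in seq_along(.aa20)) for (j in i:20L) {
    lines <- c(lines, sprintf("%s %s %.4f %.4f", .aa20[i], .aa20[j],
                              table$mean[i, j], table$sd[i, j]))
  }
  writeLines(lines, path)
  invisible(path)
}

# All inter-chain residue pairs of a structure in heavy-atom contact,
# with their CA-CA distances.  Used by compute_cutoff_table.
contact_pairs_atomic <- function(s, chains, heavy_cutoff) {
  rt <- residue_table(s)
  rt <- rt[rt$chain %in% chains, , drop = FALSE]
  if (nrow(rt) < 2L) return(NULL)
  at <- s$atoms
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  akey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ridx <- match(akey, rkey)
  keep <- !is.na(ridx)
  adj <- atom_contact_residue_pairs(cbind(at$x, at$y, at$z)[keep, , drop = FALSE],
                                    ridx[keep], heavy_cutoff)
  if (nrow(adj) == 0L) return(NULL)
  i <- adj[, 1]; j <- adj[, 2]
  inter <- rt$chain[i] != rt$chain[j]
  i <- i[inter]; j <- j[inter]
  if (length(i) == 0L) return(NULL)
  d <- sqrt((rt$ca_x[i] - rt$ca_x[j])^2 + (rt$ca_y[i] - rt$ca_y[j])^2 +
            (rt$ca_z[i] - rt$ca_z[j])^2)
  data.frame(i = i, j = j, aa1 = rt$aa[i], aa2 = rt$aa[j], ca_dist = d,
             stringsAsFactors = FALSE)
}
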