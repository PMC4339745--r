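# PDB-format I/O.  Parsing is delegated to bio3d::read.pdb; on top of that
# we resolve altlocs by occupancy, drop hydrogens and waters, map the
# common nonstandard residues (MSE, SEC, PYL) onto the 20-letter alphabet,
# and flag whether the model carries side chains or is a C-alpha trace.

.nonstandard_map <- c(MSE = "MET", SEC = "CYS", PYL = "LYS")
.backbone_atoms <- c("N", "CA", "C", "O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (plus the HETATM records of MSE/SEC/PYL, which are
#' mapped to MET/CYS/LYS), keeping heavy atoms only.  Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken towards
#' altloc "A"); other HETATM residues, waters and residues outside the
#' 20-letter alphabet are dropped with a warning.  Only one MODEL of a
#' multi-model file is used.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based MODEL to read (default first).
#' @param id identifier stored in the result; defaults to the file name.
#' @return an object of class `pc_structure`: a list with `id`, `atoms`
#'   (data frame with columns `chain`, `resno`, `insert`, `aa`, `elety`,
#'   `x`, `y`, `z`), and `mode` (`"atomic"` or `"ca_only"`, see
#'   [detect_resolution_mode()]).
#' @examples
#' pdb <- system.file("extdata", "toy_dimer.pdb", package = "pcalign")
#' s <- read_structure(pdb)
#' s$mode
#' @export
read_structure <- function(path, model_index = 1L, id = NULL) {
  if (!file.exists(path)) pc_stop_user(paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) pc_stop_data(paste0("cannot parse PDB file ", path,
                                            ": ", conditionMessage(e))))
  at <- pdb$atom
  if (nrow(at) == 0L) pc_stop_data(paste0("no ATOM records in ", path))

  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models) {
    pc_stop_user(sprintf("model %d requested but file has %d model(s)",
                         model_index, n_models))
  }
  if (model_index > 1L) {
    m <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
  }

  # element symbol, falling back to the first non-digit character of the name
  elesy <- at$elesy
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1L, 1L)
  keep <- !(toupper(elesy) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]

  # HETATM: keep only the mapped nonstandard residues
  het <- at$type == "HETATM"
  mapped <- at$resid %in% names(.nonstandard_map)
  at$resid[het & mapped] <- .nonstandard_map[at$resid[het & mapped]]
  at <- at[!het | mapped, , drop = FALSE]
  at$resid[at$resid %in% names(.nonstandard_map)] <-
    .nonstandard_map[at$resid[at$resid %in% names(.nonstandard_map)]]

  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  bad <- is.na(aa1) | aa1 == "X"
  if (any(bad)) {
    warning(sprintf("dropping %d atom(s) of nonstandard residue type(s): %s",
                    sum(bad), paste(unique(at$resid[bad]), collapse = ", ")))
    at <- at[!bad, , drop = FALSE]
    aa1 <- aa1[!bad]
  }
  if (nrow(at) == 0L) pc_stop_data(paste0("no standard residues in ", path))
  at$aa <- aa1
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # resolve altlocs: per (residue, atom name) keep highest occupancy,
  # ties towards the alphabetically first altloc ('' sorts before 'A')
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  at <- at[order(at$chain, at$resno, at$insert, match(at$elety,
           c(.backbone_atoms, sort(unique(at$elety))))), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      insert = at$insert, aa = at$aa, elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  s <- structure(list(id = id %||% basename(path), atoms = atoms,
                      mode = NA_character_), class = "pc_structure")
  s$mode <- detect_resolution_mode(s)
  s
}

# One row per residue, in (chain, resno, insert) order, with CA coordinates
# where present.
residue_table <- function(s) {
  at <- s$atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  res <- at[first, c("chain", "resno", "insert", "aa")]
  ca <- at[at$elety == "CA", , drop = FALSE]
  idx <- match(paste(res$chain, res$resno, res$insert, sep = "\r"),
               paste(ca$chain, ca$resno, ca$insert, sep = "\r"))
  res$ca_x <- ca$x[idx]; res$ca_y <- ca$y[idx]; res$ca_z <- ca$z[idx]
  rownames(res) <- NULL
  res
}

#' Detect whether a structure carries side chains
#'
#' A model is classed `"ca_only"` when fewer than half of its residues carry
#' at least one non-backbone heavy atom (backbone = N, CA, C, O).  Glycine,
#' which has no heavy side-chain atoms, is excluded from the denominator.
#'
#' @param s a `pc_structure`.
#' @return `"atomic"` or `"ca_only"`.
#' @export
detect_resolution_mode <- function(s) {
  at <- s$atoms
  if (nrow(at) == 0L) pc_stop_data("structure has no residues")
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  res_aa <- at$aa[!duplicated(key)]
  res_key <- key[!duplicated(key)]
  nongly <- res_key[res_aa != "G"]
  if (length(nongly) == 0L) return("atomic")
  side <- unique(key[!(at$elety %in% .backbone_atoms)])
  frac <- mean(nongly %in% side)
  if (frac < 0.5) "ca_only" else "atomic"
}

#' @export
print.pc_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("pc_structure '%s': %d chain(s), %d residues, %d atoms, mode=%s\n",
              x$id, length(unique(rt$chain)), nrow(rt), nrow(x$atoms), x$mode))
  invisible(x)
}

#' Write a structure as PDB
#'
#' Serializes the retained heavy atoms back to PDB ATOM records.
#'
#' @param s a `pc_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  write_pdb_atoms(path, chain = at$chain, resno = at$resno,
                  insert = at$insert, aa = at$aa, elety = at$elety,
                  xyz = cbind(at$x, at$y, at$z))
}

# Minimal fixed-width ATOM record writer (CA-level output has no fields
# bio3d's writer does not cover, but this keeps the column layout explicit).
write_pdb_atoms <- function(path, chain, resno, insert, aa, elety, xyz) {
  aa3 <- bio3d::aa123(aa)
  name4 <- ifelse(nchar(elety) < 4L, sprintf(" %-3s", elety),
                  sprintf("%-4s", elety))
  elem <- toupper(substr(gsub("[0-9]", "", elety), 1L, 1L))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_along(aa) %% 100000L, name4, aa3, chain, resno,
    ifelse(insert == "", " ", insert), xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
    elem)
  con <- tryCatch(file(path, "w"),
                  error = function(e) pc_stop_user(paste0("cannot write ", path)))
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}

#' Write an alignment to disk
#'
#' Writes (a) `<out_prefix>.pdb`, the C-alpha records of both interfaces
#' with interface 2 transformed into interface 1's frame and relabeled to
#' chains that do not collide with interface 1's, and (b)
#' `<out_prefix>.tsv`, a tab-separated residue-correspondence table whose
#' '#'-prefixed header records the alignment-level scores.
#'
#' @param result a `pc_alignment` from [align_and_score()].
#' @param i1,i2 the interfaces the result was computed on.
#' @param out_prefix output path prefix.
#' @return invisibly, a character vector of the two file paths.
#' @export
write_alignment <- function(result, i1, i2, out_prefix) {
  stopifnot(inherits(result, "pc_alignment"))
  r1 <- i1$residues
  r2 <- i2$residues
  ca2 <- apply_transform(result$transform, i2$ca)
  used <- unique(r1$chain)
  pool <- setdiff(c(LETTERS, letters, 0:9), used)
  relabel <- stats::setNames(pool[seq_along(unique(r2$chain))],
                             unique(r2$chain))
  pdb_path <- paste0(out_prefix, ".pdb")
  write_pdb_atoms(pdb_path,
                  chain = c(r1$chain, relabel[r2$chain]),
                  resno = c(r1$resno, r2$resno),
                  insert = c(r1$insert, r2$insert),
                  aa = c(r1$aa, r2$aa),
                  elety = rep("CA", nrow(r1) + nrow(r2)),
                  xyz = rbind(i1$ca, ca2))

  tsv_path <- paste0(out_prefix, ".tsv")
  hdr <- c(
    sprintf("# pc_score\t%.6f", result$pc),
    sprintf("# pc_score_raw\t%.6f", result$pc_raw),
    sprintf("# f_c\t%.6f", result$f_c),
    sprintf("# L_ali\t%d", result$L_ali),
    sprintf("# L_ave\t%.1f", result$L_ave),
    sprintf("# coverage\t%.6f", result$coverage),
    sprintf("# rmsd\t%.6f", result$rmsd),
    paste("#", paste(c("chain1", "resnum1", "aa1", "chem1", "chain2",
                       "resnum2", "aa2", "chem2", "distance_A",
                       "same_chem_flag", "equivalence_score"),
                     collapse = "\t")))
  con <- tryCatch(file(tsv_path, "w"),
                  error = function(e) pc_stop_user(paste0("cannot write ",
                                                          tsv_path)))
  on.exit(close(con))
  writeLines(hdr, con)
  p <- result$pairs
  if (nrow(p) > 0L) {
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t%d\t%s\t%s\t%.3f\t%d\t%.4f",
                    r1$chain[p$idx1], r1$resno[p$idx1], r1$aa[p$idx1],
                    r1$chem[p$idx1], r2$chain[p$idx2], r2$resno[p$idx2],
                    r2$aa[p$idx2], r2$chem[p$idx2], p$d, p$same_chem,
                    p$eq_score)
    writeLines(rows, con)
  }
  invisible(c(pdb_path, tsv_path))
}
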