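# Interface extraction: find the residues of two chain sets that contact
# each other, keep their C-alpha coordinates, chemical classes and fragment
# labels, and record the inter-fragment contact map.

#' Heavy-atom residue contact test
#'
#' Two residues are in contact when at least two heavy atoms, one from each
#' residue, lie within `cutoff` of each other (boundary inclusive).
#'
#' @param r1,r2 single-residue atom data frames with columns `x`, `y`, `z`
#'   (as sliced from a `pc_structure`'s `atoms`).
#' @param cutoff distance in Angstrom (default 4.5).
#' @return logical.
#' @export
heavy_atom_contact <- function(r1, r2, cutoff = 4.5) {
  if (nrow(r1) == 0L || nrow(r2) == 0L) {
    pc_stop_data("residue with no heavy atoms in contact test")
  }
  d <- cross_dist(cbind(r1$x, r1$y, r1$z), cbind(r2$x, r2$y, r2$z))
  min(d) <= cutoff
}

#' Interfaces
#'
#' An interface is the pair of binding fragments, A and B, formed by the
#' mutually contacting residues of two sides of a complex.  It stores one
#' row per interfacial residue (fragment A block first), the residues'
#' C-alpha coordinates ("bare bones" representation), chemical classes and
#' fragment labels, and the boolean inter-fragment contact map.
#' `new_interface()` is the low-level constructor used by
#' [extract_interface()] and the synthetic generator; it enforces the
#' structural invariants (nonempty fragments, symmetric contact map with no
#' intra-fragment entries, no residue without an inter-fragment contact).
#'
#' @param residues data frame with columns `chain`, `resno`, `insert`,
#'   `aa`, `fragment` (`"A"`/`"B"`).
#' @param ca n x 3 matrix of C-alpha coordinates, Angstrom.
#' @param contacts n x n logical matrix, TRUE only for contacting
#'   inter-fragment pairs.
#' @param id free-text identifier.
#' @return an object of class `pc_interface`.
#' @export
new_interface <- function(residues, ca, contacts, id = "interface") {
  ca <- matrix(as.numeric(ca), ncol = 3L)
  n <- nrow(residues)
  stopifnot(nrow(ca) == n, all(dim(contacts) == c(n, n)))
  if (!all(residues$fragment %in% c("A", "B")) ||
      !any(residues$fragment == "A") || !any(residues$fragment == "B")) {
    pc_stop_data("interface needs nonempty fragments A and B")
  }
  ordA <- order(residues$fragment)  # A block then B block
  residues <- residues[ordA, , drop = FALSE]
  ca <- ca[ordA, , drop = FALSE]
  contacts <- contacts[ordA, ordA, drop = FALSE]
  same_frag <- outer(residues$fragment, residues$fragment, `==`)
  if (any(contacts & same_frag)) {
    pc_stop_data("contact map has intra-fragment or diagonal entries")
  }
  if (!isTRUE(all.equal(contacts, t(contacts)))) {
    pc_stop_data("contact map must be symmetric")
  }
  if (any(rowSums(contacts) == 0L)) {
    pc_stop_data("orphan interfacial residue with no inter-fragment contact")
  }
  if (!all(is.finite(ca))) pc_stop_data("non-finite C-alpha coordinate")
  residues$chem <- classify_residue(residues$aa)
  rownames(residues) <- NULL
  structure(list(id = id, residues = residues, ca = ca,
                 contacts = contacts), class = "pc_interface")
}

#' @export
print.pc_interface <- function(x, ...) {
  nA <- sum(x$residues$fragment == "A")
  nB <- sum(x$residues$fragment == "B")
  cat(sprintf("pc_interface '%s': %d + %d residues, %d inter-fragment contacts\n",
              x$id, nA, nB, sum(x$contacts) / 2L))
  invisible(x)
}

#' @export
interface_size <- function(iface) nrow(iface$residues)

#' Extract the interface between two chain sets
#'
#' Tests every residue pair with one residue per side.  At atomic
#' resolution a pair contacts when two heavy atoms, one per residue, are
#' within `heavy_cutoff`; for C-alpha-only models the CA-CA distance is
#' compared against the per-amino-acid-pair cutoff of `table`
#' ([ca_cutoff()]).  Residues with at least one cross-side contact form
#' fragments A (side 1) and B (side 2); only their C-alpha coordinates are
#' retained.
#'
#' @param s a `pc_structure`.
#' @param chains1,chains2 disjoint character vectors of chain identifiers.
#' @param mode `"auto"` (use `s$mode`), `"atomic"` or `"ca_only"`.
#' @param table a `pc_cutoff_table` (used in C-alpha mode).
#' @param heavy_cutoff heavy-atom contact distance, Angstrom.
#' @return a `pc_interface`.
#' @examples
#' pdb <- system.file("extdata", "toy_dimer.pdb", package = "pcalign")
#' iface <- extract_interface(read_structure(pdb), "A", "B")
#' iface
#' @export
extract_interface <- function(s, chains1, chains2, mode = "auto",
                              table = uniform_cutoff_table(),
                              heavy_cutoff = 4.5) {
  stopifnot(inherits(s, "pc_structure"))
  mode <- match.arg(mode, c("auto", "atomic", "ca_only"))
  if (length(intersect(chains1, chains2)) > 0L) {
    pc_stop_user("chain sets must be disjoint")
  }
  have <- unique(s$atoms$chain)
  missing <- setdiff(c(chains1, chains2), have)
  if (length(missing) > 0L) {
    pc_stop_user(paste0("chain(s) not in structure: ",
                        paste(missing, collapse = ", ")))
  }
  eff <- if (mode == "auto") s$mode else mode

  rt <- residue_table(s)
  side <- ifelse(rt$chain %in% chains1, 1L,
                 ifelse(rt$chain %in% chains2, 2L, 0L))
  rt <- rt[side != 0L, , drop = FALSE]
  side <- side[side != 0L]
  if (anyNA(rt$ca_x)) {
    bad <- rt[is.na(rt$ca_x), ]
    pc_stop_data(paste0("residue(s) lacking a CA atom: ",
                        paste(bad$chain, bad$resno, collapse = "; ")))
  }
  n1 <- sum(side == 1L)
  if (n1 == 0L || sum(side == 2L) == 0L) {
    pc_stop_data("one of the chain sets contributes no residues")
  }

  if (eff == "atomic") {
    at <- s$atoms
    rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
    akey <- paste(at$chain, at$resno, at$insert, sep = "\r")
    ridx <- match(akey, rkey)
    keep <- !is.na(ridx)
    adj <- atom_contact_residue_pairs(
      cbind(at$x, at$y, at$z)[keep, , drop = FALSE], ridx[keep], heavy_cutoff)
    cmat <- matrix(FALSE, nrow(rt), nrow(rt))
    if (nrow(adj) > 0L) {
      cmat[adj] <- TRUE
      cmat[adj[, 2:1, drop = FALSE]] <- TRUE
    }
  } else {
    ca <- cbind(rt$ca_x, rt$ca_y, rt$ca_z)
    d <- cross_dist(ca, ca)
    cut <- matrix(ca_cutoff(rep(rt$aa, times = nrow(rt)),
                            rep(rt$aa, each = nrow(rt)), table),
                  nrow(rt), nrow(rt))
    cmat <- d <= cut
  }
  cross <- outer(side, side, `!=`)
  cmat <- cmat & cross

  inter <- rowSums(cmat) > 0L
  if (!any(inter & side == 1L) || !any(inter & side == 2L)) {
    pc_stop_data(sprintf("no interface between {%s} and {%s}",
                         paste(chains1, collapse = ","),
                         paste(chains2, collapse = ",")))
  }
  rt <- rt[inter, , drop = FALSE]
  cmat <- cmat[inter, inter, drop = FALSE]
  frag <- ifelse(side[inter] == 1L, "A", "B")
  new_interface(
    data.frame(chain = rt$chain, resno = rt$resno, insert = rt$insert,
               aa = rt$aa, fragment = frag, stringsAsFactors = FALSE),
    cbind(rt$ca_x, rt$ca_y, rt$ca_z), cmat,
    id = sprintf("%s:%s|%s", s$id, paste(chains1, collapse = ""),
                 paste(chains2, collapse = "")))
}

#' Restrict an interface's contact map to a residue subset
#'
#' @param iface a `pc_interface`.
#' @param subset integer vector of unique residue indices; the result rows
#'   follow `subset` order.
#' @return a `length(subset)` square logical matrix.
#' @export
contact_map_for <- function(iface, subset) {
  n <- nrow(iface$residues)
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(matrix(FALSE, 0L, 0L))
  if (any(subset < 1L | subset > n) || anyDuplicated(subset)) {
    pc_stop_data("subset indices must be unique and in range")
  }
  iface$contacts[subset, subset, drop = FALSE]
}

# Apply a rigid transform to an interface's coordinates (contacts unchanged).
transform_interface <- function(iface, transform) {
  iface$ca <- apply_transform(transform, iface$ca)
  iface
}
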