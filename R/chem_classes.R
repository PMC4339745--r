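# Six coarse chemical classes for the 20 standard amino acids, defined by
# the prominent side-chain functional group(s).  Each class carries the set
# of functional groups it exposes; two classes are match-compatible when the
# sets intersect.

.chem_class_of <- c(
  K = "donor", R = "donor",
  E = "acceptor", D = "acceptor",
  N = "mixed_da", Q = "mixed_da", S = "mixed_da", T = "mixed_da",
  F = "aromatic", W = "aromatic",
  C = "aliphatic", A = "aliphatic", I = "aliphatic", L = "aliphatic",
  M = "aliphatic", P = "aliphatic", V = "aliphatic", G = "aliphatic",
  H = "mixed_da_aromatic", Y = "mixed_da_aromatic")

.chem_groups <- list(
  donor             = "donor_group",
  acceptor          = "acceptor_group",
  mixed_da          = c("donor_group", "acceptor_group"),
  aromatic          = "aromatic_group",
  aliphatic         = "aliphatic_group",
  mixed_da_aromatic = c("donor_group", "acceptor_group", "aromatic_group"))

# Bitmask encoding of the group sets (donor=1, acceptor=2, aromatic=4,
# aliphatic=8), used by the hashing kernel for O(1) compatibility tests.
.group_bits <- c(donor_group = 1L, acceptor_group = 2L,
                 aromatic_group = 4L, aliphatic_group = 8L)

.chem_mask <- vapply(.chem_groups, function(g) sum(.group_bits[g]), integer(1))

#' Chemical classes of amino acids
#'
#' Residues are coarse-grained into six classes by their dominant side-chain
#' functional groups: hydrogen-bond donor (K, R), acceptor (E, D), mixed
#' donor/acceptor (N, Q, S, T), aromatic (F, W), aliphatic (C, A, I, L, M,
#' P, V, G) and mixed donor/acceptor-or-aromatic (H, Y).  Because the
#' classes are not mutually exclusive in the functional groups they expose,
#' two residues are considered *match-compatible* when their classes share
#' at least one group (e.g. N matches both R, via the donor group, and D,
#' via the acceptor group).
#'
#' @param aa one-letter amino-acid code (one of the 20 standard codes).
#' @return `classify_residue()` returns the class label, one of
#'   `"donor"`, `"acceptor"`, `"mixed_da"`, `"aromatic"`, `"aliphatic"`,
#'   `"mixed_da_aromatic"`.
#' @examples
#' classify_residue("K")
#' chem_compatible("mixed_da", classify_residue("R"))
#' @export
classify_residue <- function(aa) {
  cls <- unname(.chem_class_of[aa])
  if (anyNA(cls)) {
    pc_stop_data(paste0("cannot classify amino-acid code(s): ",
                        paste(unique(aa[is.na(cls)]), collapse = ", ")))
  }
  cls
}

#' @rdname classify_residue
#' @param c1,c2 class labels as returned by `classify_residue()`.
#' @return `chem_compatible()` returns TRUE when the two classes share at
#'   least one functional group.  Symmetric and reflexive.
#' @export
chem_compatible <- function(c1, c2) {
  m1 <- .chem_mask[c1]
  m2 <- .chem_mask[c2]
  if (anyNA(m1) || anyNA(m2)) pc_stop_data("unknown chemical class label")
  unname(bitwAnd(m1, m2) != 0L)
}

#' @rdname classify_residue
#' @param label class label.
#' @return `chem_groups()` returns the character vector of functional groups
#'   exposed by a class.
#' @export
chem_groups <- function(label) {
  g <- .chem_groups[[label]]
  if (is.null(g)) pc_stop_data("unknown chemical class label")
  g
}

# Integer bitmask for the hashing kernel.
chem_mask <- function(label) {
  m <- .chem_mask[label]
  if (anyNA(m)) pc_stop_data("unknown chemical class label")
  unname(m)
}
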