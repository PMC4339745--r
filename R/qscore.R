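# Q-score: similarity of two interfaces formed by copies of the same
# protein (quasi-equivalent viral capsid subunits), as the normalized inner
# product of their residue-level contact maps.

#' Residue-level contact map between two same-sequence subunits
#'
#' Builds the N x N 0/1 matrix whose (i, j) entry records a contact
#' between residue i of the first subunit and residue j of the second,
#' where N is the common protein length and i, j index positions along the
#' sequence.  Contacts use the same criteria as [extract_interface()]
#' (heavy-atom 4.5 A at atomic resolution, per-pair C-alpha cutoffs
#' otherwise).  The two chains must carry identical sequences.
#'
#' @param s a `pc_structure`.
#' @param chain1,chain2 single chain identifiers of the two subunits.
#' @inheritParams extract_interface
#' @return an N x N logical matrix (not necessarily symmetric: the two
#'   subunits are distinct molecules).
#' @export
capsid_contact_map <- function(s, chain1, chain2, mode = "auto",
                               table = uniform_cutoff_table(),
                               heavy_cutoff = 4.5) {
  stopifnot(inherits(s, "pc_structure"), length(chain1) == 1L,
            length(chain2) == 1L)
  rt <- residue_table(s)
  r1 <- rt[rt$chain == chain1, , drop = FALSE]
  r2 <- rt[rt$chain == chain2, , drop = FALSE]
  if (nrow(r1) == 0L || nrow(r2) == 0L) {
    pc_stop_user("chain absent from structure")
  }
  if (nrow(r1) != nrow(r2) || any(r1$aa != r2$aa)) {
    pc_stop_data("subunits must have identical sequences for the Q-score")
  }
  n <- nrow(r1)
  eff <- if (mode == "auto") s$mode else match.arg(mode,
                                                   c("atomic", "ca_only"))
  m <- matrix(FALSE, n, n)
  if (eff == "atomic") {
    at <- s$atoms
    rkey <- c(paste(r1$chain, r1$resno, r1$insert, sep = "\r"),
              paste(r2$chain, r2$resno, r2$insert, sep = "\r"))
    akey <- paste(at$chain, at$resno, at$insert, sep = "\r")
    ridx <- match(akey, rkey)
    keep <- !is.na(ridx)
    adj <- atom_contact_residue_pairs(
      cbind(at$x, at$y, at$z)[keep, , drop = FALSE], ridx[keep],
      heavy_cutoff)
    if (nrow(adj) > 0L) {
      cross <- (adj[, 1] <= n) != (adj[, 2] <= n)
      adj <- adj[cross, , drop = FALSE]
      i <- pmin(adj[, 1], adj[, 2])
      j <- pmax(adj[, 1], adj[, 2]) - n
      m[cbind(i, j)] <- TRUE
    }
  } else {
    d <- cross_dist(cbind(r1$ca_x, r1$ca_y, r1$ca_z),
                    cbind(r2$ca_x, r2$ca_y, r2$ca_z))
    cut <- matrix(ca_cutoff(rep(r1$aa, times = n), rep(r2$aa, each = n),
                            table), n, n)
    m <- d <= cut
  }
  m
}

#' Q-score of two quasi-equivalent interfaces
#'
#' `2 * <Na, Nb> / (<Na, Na> + <Nb, Nb>)` with `<.,.>` the element-wise
#' sum-product of the two subunit-level contact maps: 1 for identical
#' contact maps, 0 for maps sharing no contact.
#'
#' @param a,b contact maps from [capsid_contact_map()] (equal dimension;
#'   at least one nonempty).
#' @return scalar in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 0, 0, 1), 2, 2)
#' q_score(a, a)
#' @export
q_score <- function(a, b) {
  a <- as.matrix(a) + 0
  b <- as.matrix(b) + 0
  if (!all(dim(a) == dim(b))) {
    pc_stop_data("contact maps must have equal dimensions")
  }
  denom <- sum(a * a) + sum(b * b)
  if (denom == 0) pc_stop_data("both contact maps are empty")
  2 * sum(a * b) / denom
}
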