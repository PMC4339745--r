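# Candidate superpositions by geometric hashing.  Interface-1 C-alpha
# points are expressed in local reference frames built from ordered
# in-fragment point triplets, binned, and stored in a hash table keyed by
# (bin, fragment label); interface-2 frames probe the table and vote.
# Frame pairs with enough votes yield rigid-transform candidates, which are
# clustered (degenerate frame pairs produce near-identical transforms) and
# ranked by summed votes.

# internal unchecked constructor (rotations from frame algebra are
# orthonormal by construction)
new_transform <- function(rotation, translation) {
  structure(list(rotation = rotation, translation = translation),
            class = "pc_transform")
}

#' Parameters for geometric hashing
#'
#' @param bin_width hash bin width on frame-local coordinates, Angstrom.
#' @param min_votes minimum votes for a candidate; `NULL` (default) means
#'   `max(4, ceiling(0.25 * n_min))` where `n_min` is the residue count of
#'   the smaller interface.
#' @param max_candidates candidates retained after clustering (default 100,
#'   both fragment mappings combined).
#' @param rot_tol,trans_tol clustering tolerances: two transforms are
#'   degenerate when their relative rotation is within `rot_tol` degrees
#'   and their translations within `trans_tol` Angstrom.
#' @param frame_dmin,frame_dmax admissible pairwise distances within a
#'   frame-defining point triplet, Angstrom.
#' @param min_area minimum triangle area of a triplet, squared Angstrom
#'   (guards against near-collinear frames).
#' @param max_frames cap on frames per interface (deterministic stride
#'   subsampling).
#' @param chem_match `"compatible"` (default; residues vote when their
#'   chemical classes share a functional group) or `"identical"`
#'   (class labels must be equal).
#' @return a list of class `pc_hash_params`.
#' @export
hash_params <- function(bin_width = 2, min_votes = NULL,
                        max_candidates = 100L, rot_tol = 15, trans_tol = 3,
                        frame_dmin = 3, frame_dmax = 13, min_area = 1,
                        max_frames = 600L,
                        chem_match = c("compatible", "identical")) {
  chem_match <- match.arg(chem_match)
  stopifnot(bin_width > 0, max_candidates >= 1L, rot_tol > 0, trans_tol > 0,
            frame_dmin >= 0, frame_dmax > frame_dmin, min_area >= 0,
            max_frames >= 1L)
  structure(list(bin_width = bin_width, min_votes = min_votes,
                 max_candidates = as.integer(max_candidates),
                 rot_tol = rot_tol, trans_tol = trans_tol,
                 frame_dmin = frame_dmin, frame_dmax = frame_dmax,
                 min_area = min_area, max_frames = as.integer(max_frames),
                 chem_match = chem_match),
            class = "pc_hash_params")
}

check_fragment_geometry <- function(iface) {
  for (fr in c("A", "B")) {
    idx <- which(iface$residues$fragment == fr)
    if (length(idx) < 3L) {
      pc_stop_data(sprintf("fragment %s of '%s' has fewer than 3 residues",
                           fr, iface$id))
    }
    x <- scale(iface$ca[idx, , drop = FALSE], scale = FALSE)
    if (svd(x, nu = 0, nv = 0)$d[2] < 1e-6) {
      pc_stop_data(sprintf("fragment %s of '%s' is collinear", fr, iface$id))
    }
  }
  invisible(TRUE)
}

frag_int <- function(iface) ifelse(iface$residues$fragment == "A", 1L, 2L)

# Bitmask per residue for the voting kernel: functional-group bits under
# "compatible" matching, one private bit per class under "identical".
chem_vote_mask2 <- function(iface, chem_match) {
  if (chem_match == "compatible") {
    chem_mask(iface$residues$chem)
  } else {
    bitwShiftL(1L, match(iface$residues$chem, names(.chem_groups)) - 1L)
  }
}

#' Generate candidate superpositions of two interfaces
#'
#' Runs sequence-order-independent geometric hashing for both fragment
#' mappings (A-A'/B-B' and A-B'/B-A'), clusters degenerate transforms
#' within each mapping, and returns the top candidates ranked by summed
#' votes; equal-vote candidates are ordered by a smooth geometric quality
#' rescoring (then frame enumeration order), which keeps the ranking
#' equivariant under rigid motion of either interface.  Every candidate
#' transform applies to interface 2's coordinates.
#'
#' @param i1,i2 `pc_interface` objects; each fragment needs at least three
#'   non-collinear residues.
#' @param params a [hash_params()] list.
#' @return list of candidates, each a list with elements `transform`
#'   (`pc_transform`), `votes` and `mapping` (`"AB"` or `"BA"`).
#' @export
geometric_hash_candidates <- function(i1, i2, params = hash_params()) {
  check_fragment_geometry(i1)
  check_fragment_geometry(i2)
  min_votes <- params$min_votes %||%
    max(4L, ceiling(0.25 * min(interface_size(i1), interface_size(i2))))

  f1 <- frag_int(i1)
  m1 <- chem_vote_mask2(i1, params$chem_match)
  m2 <- chem_vote_mask2(i2, params$chem_match)
  frames1 <- enumerate_frames_cpp(i1$ca, f1, params$frame_dmin,
                                  params$frame_dmax, params$min_area,
                                  params$max_frames)
  f2_raw <- frag_int(i2)
  frames2 <- enumerate_frames_cpp(i2$ca, f2_raw, params$frame_dmin,
                                  params$frame_dmax, params$min_area,
                                  params$max_frames)

  out <- list()
  for (mapping in c("AB", "BA")) {
    f2 <- if (mapping == "AB") f2_raw else 3L - f2_raw
    raw <- hash_vote_cpp(i1$ca, f1, m1, frames1, i2$ca, f2, m2, frames2,
                         params$bin_width, as.integer(min_votes))
    if (nrow(raw) == 0L) next
    # rank by votes with ties broken by deterministic frame order (frame
    # enumeration is geometry-intrinsic, so ranking is equivariant under
    # rigid motion of either interface)
    ord <- order(-raw[, 3], raw[, 2], raw[, 1])
    raw <- raw[ord, , drop = FALSE]
    if (nrow(raw) > 30000L) raw <- raw[seq_len(30000L), , drop = FALSE]
    # binning tolerance lets near-miss transforms collect the same votes
    # as an exact superposition; re-rank the head of the list by a smooth
    # geometric quality score so exact transforms lead their clusters
    head_n <- min(nrow(raw), 600L)
    qual <- hash_quality_cpp(i1$ca, f1, m1, i2$ca, f2, m2,
                             raw[seq_len(head_n), 3:15, drop = FALSE],
                             params$bin_width)
    head_idx <- seq_len(head_n)
    reord <- head_idx[order(-raw[head_idx, 3], -qual)]
    raw[head_idx, ] <- raw[reord, , drop = FALSE]
    cl <- cluster_candidate_matrix(raw[, 3:15, drop = FALSE],
                                   params$rot_tol, params$trans_tol,
                                   rep_cap = 20L * params$max_candidates)
    keep <- seq_len(min(nrow(cl), params$max_candidates))
    out[[mapping]] <- lapply(keep, function(k) {
      list(transform = new_transform(matrix(cl[k, 2:10], 3L, 3L),
                                     cl[k, 11:13]),
           votes = cl[k, 1], mapping = mapping)
    })
  }
  cands <- c(out[["AB"]], out[["BA"]])
  if (length(cands) == 0L) return(list())
  votes <- vapply(cands, `[[`, numeric(1), "votes")
  cands <- cands[order(-votes)]  # stable: preserves within-mapping ranking
  cands[seq_len(min(length(cands), params$max_candidates))]
}

# Greedy leader clustering on a candidate matrix with columns
# (votes, R column-major 9, t 3), sorted by votes descending.  Relative
# rotation angle via tr(Rrep^T Rk) = elementwise sum-product; the relative
# translation norm equals ||tk - trep|| (rotations are isometries).
cluster_candidate_matrix <- function(cand, rot_tol, trans_tol,
                                     rep_cap = 0L) {
  cluster_cands_cpp(cand, cos(rot_tol * pi / 180), trans_tol^2,
                    as.integer(rep_cap))
}

#' Cluster degenerate transform candidates
#'
#' Greedy leader clustering in input order (candidates must be sorted by
#' votes descending): a candidate joins an existing representative when the
#' relative rotation angle is within `rot_tol` degrees and the translation
#' offset within `trans_tol` Angstrom; the representative accumulates the
#' cluster's votes.  Output is re-sorted by summed votes.
#'
#' @param cands list of candidates as returned by
#'   [geometric_hash_candidates()].
#' @param rot_tol,trans_tol tolerances (degrees, Angstrom).
#' @return clustered candidate list.
#' @export
cluster_transformations <- function(cands, rot_tol = 15, trans_tol = 3) {
  if (length(cands) == 0L) return(cands)
  mat <- t(vapply(cands, function(c) {
    c(c$votes, as.numeric(c$transform$rotation), c$transform$translation)
  }, numeric(13)))
  mapping <- vapply(cands, `[[`, character(1), "mapping")
  out <- list()
  for (mp in unique(mapping)) {
    sel <- mapping == mp
    cl <- cluster_candidate_matrix(mat[sel, , drop = FALSE], rot_tol,
                                   trans_tol)
    out <- c(out, lapply(seq_len(nrow(cl)), function(k) {
      list(transform = new_transform(matrix(cl[k, 2:10], 3L, 3L),
                                     cl[k, 11:13]),
           votes = cl[k, 1], mapping = mp)
    }))
  }
  votes <- vapply(out, `[[`, numeric(1), "votes")
  out[order(-votes)]
}
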