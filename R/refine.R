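# Iterative refinement of a candidate superposition: alternate
# maximum-weight bipartite matching of residues (weights = equivalence
# scores, solved per fragment block so matches never cross fragments) with
# Kabsch superposition over the matched C-alpha pairs, until the summed
# equivalence score stops improving.

#' Residue-pair equivalence score
#'
#' `1 / (1 + 0.25 * (1 - same_chem) + d^2 / 16)`: 1 for a same-class pair
#' at zero distance, strictly decreasing in distance; a same-class pair at
#' 8 A scores exactly 0.2 (the inclusion threshold used at scoring time).
#'
#' @param d C-alpha distance after superposition, Angstrom (>= 0).
#' @param same_chem 1 when the two residues have the same chemical class
#'   label, 0 otherwise.
#' @return score in (0, 1].
#' @examples
#' equivalence_score(0, 1)   # 1
#' equivalence_score(8, 1)   # 0.2
#' @export
equivalence_score <- function(d, same_chem) {
  if (any(d < 0)) pc_stop_data("distance must be non-negative")
  stopifnot(all(same_chem %in% c(0, 1)))
  1 / (1 + 0.25 * (1 - same_chem) + d^2 / 16)
}

#' Optimal residue matching under a superposition
#'
#' Places interface 2 with `transform`, builds the equivalence-score weight
#' matrix within each fragment pairing (A with A' and B with B' under
#' `mapping`; `"BA"` pairs A with B'), and solves each block as a
#' maximum-weight bipartite assignment (Hungarian algorithm).  `min(n1,
#' n2)` residues per block are matched; matches never cross fragment
#' blocks.
#'
#' @param i1,i2 `pc_interface` objects.
#' @param transform `pc_transform` applied to interface 2.
#' @param mapping `"AB"` or `"BA"`.
#' @return data frame of matched pairs with columns `idx1`, `idx2`
#'   (residue indices), `d` (Angstrom), `same_chem` (0/1), `eq_score`,
#'   ordered by `idx1`.
#' @export
optimal_matching <- function(i1, i2, transform, mapping = "AB") {
  stopifnot(mapping %in% c("AB", "BA"))
  blocks <- matching_blocks(i1, i2, mapping)
  m <- match_pairs_mat(i1$ca, apply_transform(transform, i2$ca), blocks)
  pairs_matrix_to_df(m)
}

# Precompute the per-block index sets and chemical-identity penalties used
# by every matching call during refinement.
matching_blocks <- function(i1, i2, mapping) {
  frag1 <- i1$residues$fragment
  frag2 <- i2$residues$fragment
  if (mapping == "BA") frag2 <- ifelse(frag2 == "A", "B", "A")
  lapply(c("A", "B"), function(fr) {
    a <- which(frag1 == fr)
    b <- which(frag2 == fr)
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    same <- outer(i1$residues$chem[a], i2$residues$chem[b], `==`) + 0
    list(a = a, b = b, same = same, penalty = 0.25 * (1 - same))
  })
}

# Matrix-returning core: columns idx1, idx2, d, same_chem, eq_score,
# ordered by idx1.  ca2 must already carry the candidate transform.
match_pairs_mat <- function(ca1, ca2, blocks) {
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    bl <- blocks[[k]]
    if (is.null(bl)) next
    d <- cross_dist(ca1[bl$a, , drop = FALSE], ca2[bl$b, , drop = FALSE])
    w <- 1 / (1 + bl$penalty + d * d / 16)
    # maximize total weight: convert to costs; solver needs rows <= cols
    flip <- length(bl$a) > length(bl$b)
    cost <- if (flip) t(max(w) - w) else max(w) - w
    asg <- hungarian_cpp(cost)
    if (flip) {
      ii <- cbind(asg, seq_along(bl$b))
      pa <- bl$a[asg]; pb <- bl$b
    } else {
      ii <- cbind(seq_along(bl$a), asg)
      pa <- bl$a; pb <- bl$b[asg]
    }
    out[[k]] <- cbind(pa, pb, d[ii], bl$same[ii], w[ii])
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(0, 0L, 5L)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

pairs_matrix_to_df <- function(m) {
  data.frame(idx1 = as.integer(m[, 1]), idx2 = as.integer(m[, 2]),
             d = m[, 3], same_chem = m[, 4], eq_score = m[, 5])
}

#' Kabsch superposition
#'
#' The proper rotation and translation minimizing the summed squared error
#' `sum ||x1 - (R x2 + t)||^2` over paired points, via SVD of the
#' cross-covariance with the determinant correction that excludes
#' reflections.
#'
#' @param x1,x2 paired n x 3 coordinate matrices (n >= 3, not collinear).
#' @return a `pc_transform` mapping `x2` onto `x1`.
#' @export
kabsch_superpose <- function(x1, x2) {
  x1 <- matrix(as.numeric(x1), ncol = 3L)
  x2 <- matrix(as.numeric(x2), ncol = 3L)
  n <- nrow(x1)
  if (n < 3L || nrow(x2) != n) {
    pc_stop_data("Kabsch needs at least 3 point pairs")
  }
  res <- kabsch_core(x1, x2)
  if (!res$ok) {
    pc_stop_data("degenerate (collinear) geometry in Kabsch superposition")
  }
  new_transform(res$r, res$t)
}

# Unchecked core shared with the refinement loop; degeneracy is read off
# the cross-covariance spectrum (collinear point sets leave the rotation
# about the joint axis undetermined).
kabsch_core <- function(x1, x2) {
  c1 <- colMeans(x1); c2 <- colMeans(x2)
  y1 <- sweep(x1, 2L, c1); y2 <- sweep(x2, 2L, c2)
  h <- crossprod(y2, y1)  # 3x3: x2 -> x1
  s <- svd(h)
  # a collinear point set on either side forces rank(H) <= 1
  ok <- s$d[2] > 1e-9 * max(s$d[1], 1e-12) && s$d[2] > 1e-12
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(ok = ok, r = r, t = as.numeric(c1 - r %*% c2))
}

#' Refinement parameters
#'
#' @param tol convergence tolerance on the summed equivalence score.
#' @param max_iter iteration cap.
#' @export
refine_params <- function(tol = 1e-6, max_iter = 100L) {
  stopifnot(tol > 0, max_iter >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter)),
            class = "pc_refine_params")
}

#' Refine a candidate superposition
#'
#' Starting from a hashing candidate, alternates [optimal_matching()] and
#' [kabsch_superpose()] over the matched C-alpha pairs.  Iteration stops
#' when the matched-pair set repeats, the summed equivalence score improves
#' by less than `params$tol`, or `params$max_iter` is reached; the
#' best-scoring iterate seen is returned.  If matching ever yields fewer
#' than 3 pairs the last valid iterate is returned flagged as degenerate.
#'
#' @param i1,i2 `pc_interface` objects.
#' @param candidate a candidate from [geometric_hash_candidates()] (list
#'   with `transform` and `mapping`).
#' @param params a [refine_params()] list.
#' @return list with `transform`, `pairs` (matched-pair data frame),
#'   `mapping`, `score` (summed equivalence score), `iterations`,
#'   `degenerate`.
#' @export
refine_alignment <- function(i1, i2, candidate, params = refine_params()) {
  mapping <- candidate$mapping %||% "AB"
  stopifnot(mapping %in% c("AB", "BA"))
  blocks <- matching_blocks(i1, i2, mapping)
  refine_with_blocks(i1, i2, candidate$transform, mapping, blocks, params)
}

# Core used by refine_alignment and align_and_score (the latter hoists the
# block construction across the candidate list).
refine_with_blocks <- function(i1, i2, transform, mapping, blocks, params) {
  empty <- matrix(0, 0L, 0L)
  blA <- blocks[[1]]
  blB <- blocks[[2]]
  res <- refine_cpp(i1$ca, i2$ca,
                    blA$a %||% integer(0), blB$a %||% integer(0),
                    blA$b %||% integer(0), blB$b %||% integer(0),
                    blA$same %||% empty, blB$same %||% empty,
                    transform$rotation, transform$translation,
                    params$tol, params$max_iter)
  list(transform = new_transform(res$rotation, res$translation),
       pairs = pairs_matrix_to_df(res$pairs), mapping = mapping,
       score = res$score, iterations = res$iterations,
       degenerate = res$degenerate)
}
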