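# PC-score: combine the per-pair equivalence scores of a refined alignment
# with the fraction of shared inter-fragment contacts, normalize by the
# average interface size, and remove the residual size dependence with a
# fitted power scaling.

#' Fraction of common contacts between aligned residue subsets
#'
#' Given the contact maps of the two interfaces restricted to the aligned
#' residues (same pair order), returns
#' `<N1,N2> / (0.5 * (<N1,N1> + <N2,N2>))` where `<.,.>` is the
#' element-wise sum-product.  0 when both maps are empty (no contact
#' evidence).
#'
#' @param map1,map2 square logical/0-1 matrices of equal dimension in
#'   aligned-pair order.
#' @return scalar in `[0, 1]`.
#' @export
fraction_common_contacts <- function(map1, map2) {
  map1 <- as.matrix(map1) + 0
  map2 <- as.matrix(map2) + 0
  if (!all(dim(map1) == dim(map2)) || nrow(map1) != ncol(map1)) {
    pc_stop_data("contact maps must be square and of equal dimension")
  }
  denom <- 0.5 * (sum(map1 * map1) + sum(map2 * map2))
  if (denom == 0) return(0)
  sum(map1 * map2) / denom
}

#' Raw PC-score
#'
#' `(f_c / L_ave) * sum(eq_score)` over the retained aligned pairs (those
#' with equivalence score >= 0.20).
#'
#' @param pairs matched-pair data frame (column `eq_score`).
#' @param f_c fraction of common contacts ([fraction_common_contacts()]).
#' @param L_ave average number of interfacial residues of the two
#'   interfaces.
#' @return scalar in `[0, 1]`.
#' @export
pc_score_raw <- function(pairs, f_c, L_ave) {
  stopifnot(L_ave > 0, f_c >= 0, f_c <= 1)
  if (nrow(pairs) == 0L) return(0)
  (f_c / L_ave) * sum(pairs$eq_score)
}

#' Size scaling of the raw PC-score
#'
#' Removes the dependence of the raw score on interface size:
#' `pc = raw ^ (log(0.3) / log(0.14 + 0.29 * 0.97^L_ave))`.  The exponent
#' is positive for all `L_ave > 0` and tends to `log(0.3)/log(0.14)`
#' (about 0.612) for large interfaces; `raw = 1` maps to 1 at any size.
#'
#' @param raw raw score in `[0, 1]`.
#' @param L_ave average interface size (residues).
#' @return scaled PC-score in `[0, 1]`.
#' @export
scale_pc_score <- function(raw, L_ave) {
  if (any(raw < 0 | raw > 1)) pc_stop_data("raw score must lie in [0, 1]")
  stopifnot(all(L_ave > 0))
  raw^(log(0.3) / log(0.14 + 0.29 * 0.97^L_ave))
}

pc_scale_exponent <- function(L_ave) log(0.3) / log(0.14 + 0.29 * 0.97^L_ave)

empty_alignment_result <- function(i1, i2) {
  structure(list(
    transform = identity_transform(),
    pairs = data.frame(idx1 = integer(0), idx2 = integer(0), d = numeric(0),
                       same_chem = numeric(0), eq_score = numeric(0)),
    mapping = NA_character_, L_ali = 0L,
    L_ave = (interface_size(i1) + interface_size(i2)) / 2,
    f_c = 0, pc_raw = 0, pc = 0, coverage = 0, rmsd = NA_real_,
    p_value = NA_real_, votes = 0, iterations = 0L, degenerate = FALSE),
    class = "pc_alignment")
}

# Score one refined alignment: prune pairs below the 0.20 equivalence
# threshold, compute f_c over the aligned subsets, then raw and scaled
# scores.
score_refined <- function(i1, i2, refined, eq_threshold = 0.20) {
  pairs <- refined$pairs[refined$pairs$eq_score >= eq_threshold, ,
                         drop = FALSE]
  L_ave <- (interface_size(i1) + interface_size(i2)) / 2
  res <- empty_alignment_result(i1, i2)
  res$transform <- refined$transform
  res$mapping <- refined$mapping
  res$iterations <- refined$iterations
  res$degenerate <- refined$degenerate
  if (nrow(pairs) == 0L) return(res)
  f_c <- fraction_common_contacts(contact_map_for(i1, pairs$idx1),
                                  contact_map_for(i2, pairs$idx2))
  res$pairs <- pairs
  res$L_ali <- nrow(pairs)
  res$f_c <- f_c
  res$pc_raw <- pc_score_raw(pairs, f_c, L_ave)
  res$pc <- scale_pc_score(res$pc_raw, L_ave)
  res$coverage <- res$L_ali / L_ave
  res$rmsd <- sqrt(mean(pairs$d^2))
  res
}

#' Align two interfaces and score the best superposition
#'
#' The full pipeline: geometric hashing over both fragment mappings
#' ([geometric_hash_candidates()]), iterative Hungarian/Kabsch refinement
#' of each retained candidate ([refine_alignment()]), equivalence-score
#' pruning at 0.20, contact-overlap and size-normalized scoring; the
#' candidate with the highest scaled PC-score wins.
#'
#' @param i1,i2 `pc_interface` objects.
#' @param hash a [hash_params()] list.
#' @param refine a [refine_params()] list.
#' @param eq_threshold equivalence-score inclusion threshold for scoring
#'   (default 0.20).
#' @param background optional numeric vector of background PC-scores for
#'   an empirical p-value ([empirical_pvalue()]).
#' @return an object of class `pc_alignment`: list with `transform`
#'   (applies to interface 2), `pairs`, `mapping`, `L_ali`, `L_ave`,
#'   `f_c`, `pc_raw`, `pc`, `coverage`, `rmsd` and `p_value`.
#' @examples
#' x <- generate_synthetic_interface(fixture_spec(n_per_fragment = 10,
#'                                                seed = 1))
#' res <- align_and_score(x, x)
#' res$pc
#' @export
align_and_score <- function(i1, i2, hash = hash_params(),
                            refine = refine_params(), eq_threshold = 0.20,
                            background = NULL) {
  stopifnot(inherits(i1, "pc_interface"), inherits(i2, "pc_interface"))
  cands <- geometric_hash_candidates(i1, i2, hash)
  best <- empty_alignment_result(i1, i2)
  blocks <- list(AB = matching_blocks(i1, i2, "AB"),
                 BA = matching_blocks(i1, i2, "BA"))
  for (cand in cands) {
    refined <- refine_with_blocks(i1, i2, cand$transform, cand$mapping,
                                  blocks[[cand$mapping]], refine)
    scored <- score_refined(i1, i2, refined, eq_threshold)
    scored$votes <- cand$votes
    if (scored$pc > best$pc) best <- scored
  }
  if (!is.null(background)) {
    best$p_value <- empirical_pvalue(best$pc, background)
  }
  best
}

#' Empirical p-value against a background score distribution
#'
#' Add-one rank estimate: `(1 + #(background >= score)) / (n + 1)`.
#'
#' @param score observed PC-score.
#' @param background nonempty numeric vector of background scores (e.g.
#'   from [background_scores()]).
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(score, background) {
  if (length(background) == 0L) {
    pc_stop_data("empty background distribution")
  }
  (1 + sum(background >= score)) / (length(background) + 1)
}

#' @export
print.pc_alignment <- function(x, ...) {
  cat(sprintf(
    "pc_alignment: PC-score %.4f (raw %.4f), f_c %.3f, L_ali %d, L_ave %.1f\n",
    x$pc, x$pc_raw, x$f_c, x$L_ali, x$L_ave))
  cat(sprintf("  coverage %.3f, RMSD %s A, mapping %s%s%s\n", x$coverage,
              ifelse(is.na(x$rmsd), "NA", sprintf("%.3f", x$rmsd)),
              x$mapping,
              ifelse(is.na(x$p_value), "",
                     sprintf(", p = %.4g", x$p_value)),
              ifelse(x$degenerate, " [degenerate]", "")))
  invisible(x)
}

#' @export
as.data.frame.pc_alignment <- function(x, ...) x$pairs

#' One-row summary of an alignment result
#'
#' @param object a `pc_alignment`.
#' @param ... ignored.
#' @return one-row data frame with the alignment-level quantities.
#' @export
summary.pc_alignment <- function(object, ...) {
  data.frame(pc = object$pc, pc_raw = object$pc_raw, f_c = object$f_c,
             L_ali = object$L_ali, L_ave = object$L_ave,
             coverage = object$coverage, rmsd = object$rmsd,
             p_value = object$p_value, mapping = object$mapping,
             iterations = object$iterations,
             degenerate = object$degenerate)
}
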