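# Seeded synthetic interfaces: jittered grid patches facing each other at a
# separation tuned to hit a target inter-fragment contact fraction under
# the flat 8 A C-alpha criterion.  Everything here is reproducible from
# (spec, seed) and leaves the caller's RNG state untouched.

with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.class_sizes <- vapply(names(.chem_groups), function(cl)
  sum(.chem_class_of == cl), numeric(1))

#' Specification of a synthetic interface
#'
#' @param n_per_fragment residues per binding fragment (>= 3); a length-2
#'   vector gives the two fragments different sizes.
#' @param spacing grid spacing between neighboring residues within a
#'   fragment, Angstrom.
#' @param contact_fraction target fraction of inter-fragment residue pairs
#'   in contact under the flat 8 A C-alpha criterion (must be > 0).
#' @param chem_distribution weights over the six chemical classes (in the
#'   order donor, acceptor, mixed_da, aromatic, aliphatic,
#'   mixed_da_aromatic); the default weights classes by how many amino
#'   acids they contain, i.e. residue types uniform over the 20-letter
#'   alphabet.
#' @param seed integer seed recorded in the generated interface.
#' @return a list of class `pc_fixture_spec`.
#' @export
fixture_spec <- function(n_per_fragment = 20L, spacing = 3.8,
                         contact_fraction = 0.15,
                         chem_distribution = NULL, seed = 1L) {
  n <- as.integer(rep(n_per_fragment, length.out = 2L))
  if (any(n < 3L)) pc_stop_data("need at least 3 residues per fragment")
  if (spacing <= 0) pc_stop_data("spacing must be positive")
  if (contact_fraction <= 0 || contact_fraction > 1) {
    pc_stop_data("contact_fraction must lie in (0, 1]")
  }
  w <- chem_distribution %||% unname(.class_sizes)
  if (length(w) != 6L || any(w < 0) || sum(w) == 0) {
    pc_stop_data("chem_distribution needs 6 non-negative weights")
  }
  structure(list(n_per_fragment = n, spacing = spacing,
                 contact_fraction = contact_fraction,
                 chem_distribution = w / sum(w), seed = as.integer(seed)),
            class = "pc_fixture_spec")
}

# Dart-throwing placement over a mixture of 1-3 anisotropic Gaussian
# blobs: n in-plane points with a minimum separation, in an irregular
# footprint (real binding sites are lumpy patches, not uniform discs).
# The blob spread is widened when packing fails and tightened until the
# patch admits at least one frame-quality triplet (pairwise distances
# 3.2-12.5 A, area >= 1.2 A^2) so hashing always has a reference frame.
scatter_blobs <- function(n, spacing) {
  nb <- sample(1:3, 1L)
  side <- spacing * sqrt(n) * 1.4
  ctr <- matrix(runif(2L * nb, 0.2 * side, 0.8 * side), nb, 2L)
  sdv <- matrix(runif(2L * nb, 0.2 * side, 0.45 * side), nb, 2L)
  repeat {
    pts <- matrix(0, n, 2L)
    k <- 0L
    tries <- 0L
    while (k < n) {
      b <- if (nb > 1L) sample(nb, 1L) else 1L
      cand <- rnorm(2L, ctr[b, ], sdv[b, ])
      if (k == 0L ||
          min((pts[seq_len(k), 1] - cand[1])^2 +
              (pts[seq_len(k), 2] - cand[2])^2) >= spacing^2) {
        k <- k + 1L
        pts[k, ] <- cand
      }
      tries <- tries + 1L
      if (tries > 600L * n) {
        sdv <- sdv * 1.15
        tries <- 0L
      }
    }
    fr <- enumerate_frames_cpp(cbind(pts, 0), rep(1L, n), 3.2, 12.5, 1.2, 1L)
    if (nrow(fr) > 0L) return(pts)
    sdv <- sdv * 0.8
  }
}

sample_aas <- function(n, class_weights) {
  cls <- sample(names(.chem_groups), n, replace = TRUE,
                prob = class_weights)
  vapply(cls, function(cl) {
    aas <- names(.chem_class_of)[.chem_class_of == cl]
    aas[sample.int(length(aas), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic interface
#'
#' Places fragment A on a jittered grid patch and fragment B on a parallel
#' patch; the patch separation is tuned (bisection, within the range that
#' guarantees every residue keeps at least one cross-fragment contact) so
#' that the realized contact fraction under the flat 8 A C-alpha criterion
#' approximates `spec$contact_fraction`.  Amino acids are drawn from
#' `spec$chem_distribution`.  Deterministic given the spec (including its
#' seed).
#'
#' @param spec a [fixture_spec()].
#' @return a `pc_interface` whose contact map uses the 8 A flat cutoff.
#' @export
generate_synthetic_interface <- function(spec) {
  stopifnot(inherits(spec, "pc_fixture_spec"))
  with_seed(spec$seed, function() {
    nA <- spec$n_per_fragment[1]
    nB <- spec$n_per_fragment[2]
    nmin <- min(nA, nB)
    zjit <- 0.6    # A per-residue height noise
    offmax <- 2.5  # A max in-plane offset of a residue from its partner
    # fragment A: irregular blob scatter bent by a random quadratic height
    # field (interfaces are curved patches, not flat sheets)
    xyA <- scatter_blobs(nA, spec$spacing)
    q <- runif(3L, -0.06, 0.06)
    bend <- function(xy) {
      xc <- xy[, 1] - mean(xyA[, 1]); yc <- xy[, 2] - mean(xyA[, 2])
      q[1] * xc^2 + q[2] * yc^2 + q[3] * xc * yc
    }
    a <- cbind(xyA, bend(xyA) + runif(nA, -zjit, zjit))
    # fragment B: the first nmin residues face a distinct fragment-A
    # partner across the interface normal at a random in-plane offset,
    # following the partner's height (guarantees no orphans for
    # equal-size fragments); extras are scattered over the same footprint
    xyB <- matrix(0, nmin, 2L)
    for (i in seq_len(nmin)) {
      for (try in 1:20) {  # keep B residues from overlapping each other
        ang <- runif(1L, 0, 2 * pi)
        rad <- runif(1L, 0, offmax)
        cand <- xyA[i, ] + c(rad * cos(ang), rad * sin(ang))
        if (i == 1L ||
            min((xyB[seq_len(i - 1L), 1] - cand[1])^2 +
                (xyB[seq_len(i - 1L), 2] - cand[2])^2) >= 9) break
      }
      xyB[i, ] <- cand
    }
    zB <- a[seq_len(nmin), 3] + runif(nmin, -zjit, zjit)
    if (nB > nA) {
      extra <- scatter_blobs(nB, spec$spacing)[seq_len(nB - nA) + nA, ,
                                               drop = FALSE]
      xyB <- rbind(xyB, extra)
      zB <- c(zB, bend(extra) + runif(nB - nA, -zjit, zjit))
    }
    b0 <- cbind(xyB, zB)
    frac_at <- function(dz) {
      b <- b0; b[, 3] <- b0[, 3] + dz
      mean(cross_dist(a, b) <= 8)
    }
    # a paired partner sits within sqrt(hi^2 + offmax^2) + height noise
    # < 8 A even at the top of the separation range
    lo <- 3
    hi <- sqrt(64 - offmax^2) - 2 * zjit - 0.2
    if (frac_at(hi) >= spec$contact_fraction) {
      dz <- hi
    } else if (frac_at(lo) <= spec$contact_fraction) {
      dz <- lo
    } else {
      for (k in 1:40) {
        mid <- (lo + hi) / 2
        if (frac_at(mid) >= spec$contact_fraction) lo <- mid else hi <- mid
      }
      dz <- (lo + hi) / 2
    }
    # unequal fragments can leave outlying residues contact-free at large
    # separations; close the gap until none remain
    repeat {
      b <- b0; b[, 3] <- b0[, 3] + dz
      cross <- cross_dist(a, b) <= 8
      if (all(rowSums(cross) > 0L) && all(colSums(cross) > 0L)) break
      dz <- dz - 0.25
      if (dz < 2) {
        pc_stop_data("cannot generate an orphan-free interface for this spec")
      }
    }
    ca <- rbind(a, b)
    contacts <- matrix(FALSE, nA + nB, nA + nB)
    contacts[seq_len(nA), nA + seq_len(nB)] <- cross
    contacts[nA + seq_len(nB), seq_len(nA)] <- t(cross)
    residues <- data.frame(
      chain = rep(c("A", "B"), c(nA, nB)),
      resno = c(seq_len(nA), seq_len(nB)),
      insert = "",
      aa = sample_aas(nA + nB, spec$chem_distribution),
      fragment = rep(c("A", "B"), c(nA, nB)),
      stringsAsFactors = FALSE)
    new_interface(residues, ca, contacts,
                  id = sprintf("synthetic_n%d+%d_seed%d", nA, nB,
                               spec$seed))
  })
}

#' Apply a random rigid transform to an interface
#'
#' Samples a uniform random proper rotation (normalized quaternion) and a
#' translation uniform in `[-20, 20]^3` Angstrom; the contact map is
#' unchanged.
#'
#' @param iface a `pc_interface`.
#' @param seed integer seed.
#' @return list with `interface` (the transformed copy) and `transform`
#'   (the ground-truth `pc_transform` that was applied).
#' @export
apply_random_rigid <- function(iface, seed) {
  with_seed(seed, function() {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    r <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
      2 * (q[2] * q[4] - q[1] * q[3]),
      2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] + q[1] * q[2]),
      2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3L, 3L)
    tr <- rigid_transform(r, runif(3, -20, 20))
    list(interface = transform_interface(iface, tr), transform = tr)
  })
}

#' Perturb C-alpha positions with half-normal noise
#'
#' Emulates a noisy low-resolution trace: each C-alpha is displaced along
#' an independent uniform random direction by `|g|`, `g ~ N(0, sigma^2)`.
#' For a `pc_structure` all non-CA atoms are dropped first (the model is
#' reduced to its backbone trace); for a `pc_interface` the annotated
#' contact map is kept.
#'
#' @param x a `pc_structure` or `pc_interface`.
#' @param sigma Gaussian displacement scale, Angstrom (default 1).
#' @param seed integer seed.
#' @return same type as `x`.
#' @export
perturb_backbone <- function(x, sigma = 1, seed = 1L) {
  stopifnot(sigma >= 0)
  displace <- function(xyz) {
    n <- nrow(xyz)
    u <- matrix(rnorm(3L * n), n, 3L)
    u <- u / sqrt(rowSums(u^2))
    xyz + u * abs(rnorm(n, 0, sigma))
  }
  with_seed(seed, function() {
    if (inherits(x, "pc_interface")) {
      x$ca <- displace(x$ca)
      x
    } else if (inherits(x, "pc_structure")) {
      x$atoms <- x$atoms[x$atoms$elety == "CA", , drop = FALSE]
      xyz <- displace(cbind(x$atoms$x, x$atoms$y, x$atoms$z))
      x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
      x$mode <- "ca_only"
      x
    } else {
      pc_stop_user("perturb_backbone needs a pc_structure or pc_interface")
    }
  })
}

#' Background PC-score distribution from unrelated interface pairs
#'
#' Aligns `n` pairs of independently generated synthetic interfaces (sizes
#' drawn uniformly from `size_range` residues per fragment) and returns
#' their PC-scores.  Used for empirical p-values
#' ([empirical_pvalue()]).
#'
#' @param n number of pairs (default 1000).
#' @param seed integer seed.
#' @param size_range range of residues per fragment.
#' @param hash,refine pipeline parameters.
#' @return numeric vector of length `n`.
#' @export
background_scores <- function(n = 1000L, seed = 1L, size_range = c(10L, 30L),
                              hash = hash_params(),
                              refine = refine_params()) {
  stopifnot(n >= 1L)
  plan <- with_seed(seed, function() {
    data.frame(s1 = sample.int(.Machine$integer.max - 1L, n),
               s2 = sample.int(.Machine$integer.max - 1L, n),
               n1 = sample(size_range[1]:size_range[2], n, replace = TRUE),
               n2 = sample(size_range[1]:size_range[2], n, replace = TRUE))
  })
  vapply(seq_len(n), function(k) {
    x <- generate_synthetic_interface(
      fixture_spec(n_per_fragment = plan$n1[k], seed = plan$s1[k]))
    y <- generate_synthetic_interface(
      fixture_spec(n_per_fragment = plan$n2[k], seed = plan$s2[k]))
    align_and_score(x, y, hash = hash, refine = refine)$pc
  }, numeric(1))
}
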