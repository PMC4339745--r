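test_that("self-hashing ranks the identity transform first with full votes", {
  for (n in c(6L, 15L)) {
    x <- generate_synthetic_interface(fixture_spec(n, seed = n))
    cands <- geometric_hash_candidates(x, x)
    expect_gt(length(cands), 0L)
    top <- cands[[1]]
    expect_lt(rotation_angle(top$transform), 1e-6)
    expect_lt(max(abs(top$transform$translation)), 1e-6)
    expect_identical(top$mapping, "AB")
    # every residue votes for the identity frame pairs
    expect_gte(top$votes, 2L * n)
  }
})

test_that("a known rigid motion is recovered by the top candidate", {
  x <- generate_synthetic_interface(fixture_spec(12, seed = 4))
  ang <- 30 * pi / 180
  r <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  tr <- rigid_transform(r, c(5, 0, 0))
  y <- pcalign:::transform_interface(x, tr)
  top <- geometric_hash_candidates(x, y)[[1]]
  # candidate maps interface 2 back onto interface 1
  rel <- compose_transforms(top$transform, tr)
  expect_lt(rotation_angle(rel) * 180 / pi, 1)
  expect_lt(sqrt(sum(rel$translation^2)), 0.5)
})

test_that("mirror images cannot collect full votes under proper rotations", {
  # only proper rotations are generated, so a chiral point cloud's mirror
  # image can never match point-for-point; checked on the raw per-frame-
  # pair votes at a bin width fine enough to resolve the chirality
  for (seed in c(9L, 19L, 29L)) {
    x <- generate_synthetic_interface(fixture_spec(10, seed = seed))
    y <- x
    y$ca[, 3] <- -y$ca[, 3]
    n <- nrow(x$residues)
    f1 <- pcalign:::frag_int(x)
    m1 <- pcalign:::chem_vote_mask2(x, "compatible")
    fr1 <- pcalign:::enumerate_frames_cpp(x$ca, f1, 3, 13, 1, 600L)
    raw_self <- pcalign:::hash_vote_cpp(x$ca, f1, m1, fr1, x$ca, f1, m1,
                                        fr1, 0.5, 4L)
    raw_mirr <- pcalign:::hash_vote_cpp(x$ca, f1, m1, fr1, y$ca, f1, m1,
                                        fr1, 0.5, 4L)
    expect_identical(max(raw_self[, 3]), as.numeric(n))
    expect_lt(if (nrow(raw_mirr)) max(raw_mirr[, 3]) else 0, n)
    # and the full pipeline cannot reach a perfect score on the mirror
    expect_lt(align_and_score(x, y)$pc, 0.999)
  }
})

test_that("hashing is deterministic and equivariant under pre-rotation", {
  x <- generate_synthetic_interface(fixture_spec(10, seed = 2))
  y <- generate_synthetic_interface(fixture_spec(10, seed = 20))
  c1 <- geometric_hash_candidates(x, y)
  c2 <- geometric_hash_candidates(x, y)
  expect_identical(c1, c2)

  set.seed(1)
  g <- rigid_transform(random_rotation(), runif(3, -10, 10))
  y2 <- pcalign:::transform_interface(y, g)
  c3 <- geometric_hash_candidates(x, y2)
  # composing a candidate for (x, g.y) with g reproduces a candidate for
  # (x, y); near-tied candidates may swap rank, so the leading candidates
  # are matched set-wise (far down the list, bin-boundary flips under the
  # rotation can legitimately regroup low-vote clusters)
  expect_equal(length(c3), length(c1))
  for (k in seq_len(min(5L, length(c3)))) {
    comp <- compose_transforms(c3[[k]]$transform, g)
    hit <- any(vapply(c1, function(cand) {
      rel <- compose_transforms(invert_transform(comp), cand$transform)
      rotation_angle(rel) < 1e-6 && sqrt(sum(rel$translation^2)) < 1e-6
    }, logical(1)))
    expect_true(hit, label = sprintf("candidate %d equivariant match", k))
  }

  # for a rigid-copy pair the exact transform leads both rankings
  z <- apply_random_rigid(x, seed = 77)
  t1 <- geometric_hash_candidates(x, z$interface)[[1]]$transform
  z2 <- pcalign:::transform_interface(z$interface, g)
  t2 <- geometric_hash_candidates(x, z2)[[1]]$transform
  rel <- compose_transforms(invert_transform(compose_transforms(t2, g)), t1)
  expect_lt(rotation_angle(rel), 1e-6)
  expect_lt(sqrt(sum(rel$translation^2)), 1e-6)
})

test_that("degenerate fragment geometry is rejected", {
  x <- generate_synthetic_interface(fixture_spec(6, seed = 8))
  y <- x
  idx <- which(y$residues$fragment == "A")
  y$ca[idx, 2:3] <- 0  # flatten fragment A onto a line
  y$ca[idx, 1] <- seq_along(idx) * 3.8
  expect_error(geometric_hash_candidates(x, y),
               class = "pcalign_data_error")
})

test_that("clustering merges degenerate transforms and sums votes", {
  t1 <- rigid_transform(diag(3), c(0, 0, 0))
  ang <- pi / 2
  t2 <- rigid_transform(matrix(c(cos(ang), sin(ang), 0, -sin(ang),
                                 cos(ang), 0, 0, 0, 1), 3, 3), c(0, 0, 0))
  cands <- list(list(transform = t1, votes = 10, mapping = "AB"),
                list(transform = t1, votes = 6, mapping = "AB"),
                list(transform = t2, votes = 5, mapping = "AB"))
  cl <- cluster_transformations(cands, rot_tol = 15, trans_tol = 3)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$votes, 16)
  expect_equal(cl[[2]]$votes, 5)

  # coverage: every input candidate lies within tolerance of some
  # representative
  x <- generate_synthetic_interface(fixture_spec(10, seed = 31))
  y <- generate_synthetic_interface(fixture_spec(10, seed = 32))
  raw <- geometric_hash_candidates(x, y, hash_params(max_candidates = 50L))
  cl2 <- cluster_transformations(raw, rot_tol = 15, trans_tol = 3)
  for (cand in raw) {
    ok <- any(vapply(cl2, function(rep) {
      rel <- compose_transforms(invert_transform(rep$transform),
                                cand$transform)
      rotation_angle(rel) * 180 / pi <= 15 + 1e-9 &&
        sqrt(sum((cand$transform$translation -
                  rep$transform$translation)^2)) <= 3 + 1e-9
    }, logical(1)))
    expect_true(ok)
  }
})
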