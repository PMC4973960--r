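test_that("single residue sits in the canonical frame", {
  p <- geometry_params()
  ch <- build_chain(NA, NA)
  expect_equal(ch$n_res, 1L)
  expect_equal(ch$N[1, ], c(0, 0, 0))
  expect_equal(ch$CA[1, ], c(p$b_n_ca, 0, 0))
  expect_equal(ch$C[1, 3], 0)  # C stays in the xy-plane
  expect_equal(sqrt(sum((ch$C[1, ] - ch$CA[1, ])^2)), p$b_ca_c)
  v1 <- ch$N[1, ] - ch$CA[1, ]; v2 <- ch$C[1, ] - ch$CA[1, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, p$a_n_ca_c, tolerance = 1e-9)
})

test_that("construction is deterministic and validates input", {
  d <- make_mixed_chain(15, seed = 5)
  c1 <- build_chain(d$phi, d$psi)
  c2 <- build_chain(d$phi, d$psi)
  expect_identical(c1$CA, c2$CA)
  expect_identical(c1$C, c2$C)
  expect_error(build_chain(numeric(0), numeric(0)), ">= 1")
  expect_error(build_chain(c(0, NA, 0), c(0, 0, 0)), "non-finite")
})

test_that("trans-extended chain matches the independent planar oracle", {
  n <- 4
  ch <- build_chain(rep(180, n), rep(180, n), 180)
  got <- matrix(NA_real_, 3 * n, 3)
  got[seq(1, by = 3, length.out = n), ] <- ch$N
  got[seq(2, by = 3, length.out = n), ] <- ch$CA
  got[seq(3, by = 3, length.out = n), ] <- ch$C
  expect_lt(max(abs(got[, 3])), 1e-9)  # planar
  expect_lt(max(abs(got[, 1:2] - oracle_planar_chain(n))), 1e-6)
})

test_that("mirror-image chains are isometric", {
  d <- make_mixed_chain(12, seed = 7)
  c1 <- build_chain(d$phi, d$psi)
  c2 <- build_chain(-d$phi, -d$psi)
  expect_equal(chain_dist(c1), chain_dist(c2), tolerance = 1e-9)
})

test_that("built coordinates reproduce the input internal coordinates", {
  p <- geometry_params()
  d <- make_mixed_chain(20, seed = 9)
  om <- wrap_angle(175 + 3 * sin(seq_len(20)))
  ch <- build_chain(d$phi, d$psi, om, p)
  rec <- extract_dihedrals(ch)
  expect_equal(rec$phi[-1], wrap_angle(d$phi[-1]), tolerance = 1e-3)
  expect_equal(rec$psi[-20], wrap_angle(d$psi[-20]), tolerance = 1e-3)
  expect_equal(rec$omega[-1], om[-1], tolerance = 1e-3)
  dcn <- sqrt(rowSums((ch$N[-1, ] - ch$C[-20, ])^2))
  expect_equal(dcn, rep(p$b_c_n, 19), tolerance = 1e-6)
  dnca <- sqrt(rowSums((ch$CA - ch$N)^2))
  expect_equal(dnca, rep(p$b_n_ca, 20), tolerance = 1e-6)
})

test_that("end_to_end uses the CA endpoints and respects bounds", {
  ch <- build_chain(rep(-63, 20), rep(-43, 20))
  expect_equal(end_to_end(ch),
               sqrt(sum((ch$CA[20, ] - ch$CA[1, ])^2)))
  # triangle inequality against the per-residue CA-CA spans
  span <- sqrt(rowSums((ch$CA[-1, ] - ch$CA[-20, ])^2))
  expect_lte(end_to_end(ch), sum(span))
  expect_error(end_to_end(build_chain(NA, NA)), ">= 2")
})

test_that("radius_of_gyration matches the pairwise-distance oracle", {
  d <- make_mixed_chain(10, seed = 13)
  ch <- build_chain(d$phi, d$psi)
  rg <- radius_of_gyration(ch)
  m <- rbind(ch$N, ch$CA, ch$C)
  n <- nrow(m)
  # brute-force double loop: Rg^2 = sum_ij d_ij^2 / (2 n^2)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + sum((m[i, ] - m[j, ])^2)
  expect_equal(rg, sqrt(acc / (2 * n^2)), tolerance = 1e-9)
  expect_gt(radius_of_gyration(build_chain(NA, NA)), 0)  # 3-atom residue
})

test_that("Re and Rg are invariant under rigid motions", {
  d <- make_mixed_chain(10, seed = 17)
  ch <- build_chain(d$phi, d$psi)
  rot <- random_rotation(99)
  moved <- ch
  for (a in c("N", "CA", "C"))
    moved[[a]] <- sweep(ch[[a]] %*% t(rot), 2, c(3, -7, 11), "+")
  expect_equal(end_to_end(moved), end_to_end(ch), tolerance = 1e-9)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(ch),
               tolerance = 1e-9)
})

test_that("re_map is dense, mirror-symmetric and validates its step", {
  map <- re_map(8, 30)
  expect_equal(nrow(map), 144)
  key <- paste(map$phi, map$psi)
  mirror <- match(paste(wrap_angle(-map$phi), wrap_angle(-map$psi)), key)
  expect_equal(map$re, map$re[mirror], tolerance = 1e-9)
  expect_error(re_map(8, 23), "divide")
})

test_that("re_stats_by_r is seeded, conservative and honest about bins", {
  st1 <- re_stats_by_r(5, samples_per_bin = 20, seed = 3)
  st2 <- re_stats_by_r(5, samples_per_bin = 20, seed = 3)
  expect_identical(st1, st2)
  expect_equal(nrow(st1), 100)  # default 0.01 bins
  filled <- st1$n >= 2
  expect_true(any(filled))
  expect_true(all(st1$re_sd[filled] >= 0))
  expect_true(all(is.na(st1$re_sd[!filled])))  # missing, not fabricated
})

test_that("roundtrip RMSD shrinks with sigma and bounds the angle error", {
  chains <- lapply(1:3, function(i) make_mixed_chain(40, seed = i))
  prev <- Inf
  for (s in c(1, 10, 100, 1e3, 1e5)) {
    rt <- roundtrip_rmsd(chains, s)
    expect_lte(rt$angle_rmsd, 1 / s)
    expect_lte(rt$ca_rmsd, prev + 1e-12)
    prev <- rt$ca_rmsd
  }
  rt <- roundtrip_rmsd(chains, 1e5, superpose = TRUE)
  expect_lt(rt$ca_rmsd, 1e-3)
})
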