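test_that("rcode conserves counts and normalizes to a unit peak", {
  rc <- rcode(rep(0.355, 100), normalize = TRUE)
  expect_equal(sum(rc$counts), 100)
  expect_equal(sum(rc$counts > 0), 1)
  expect_equal(max(rc$heights), 1)
  set.seed(3)
  r <- runif(777)
  expect_equal(sum(rcode(r)$counts), 777)
  expect_equal(sum(rcode(c(r, NA))$counts), 777)  # NA dropped, not binned
  expect_equal(rcode(1.0)$counts[100], 1)          # r = 1 clamps into last bin
  empty <- rcode(numeric(0), normalize = TRUE)
  expect_equal(sum(empty$counts), 0)
  expect_equal(max(empty$heights), 0)
  expect_error(rcode(0.5, bin_width = 0.03), "divide")
  expect_error(rcode(1.2), "\\[0, 1\\]")
})

test_that("a synthetic helix ensemble peaks at its closed-form r", {
  d <- sample_motif("alpha", 1e4, sd = 5, seed = 42)
  r <- rama_number(d$phi, d$psi)
  rc <- rcode(r, normalize = TRUE)
  expected <- (mean(d$phi + d$psi) + 360) / 720
  expect_lt(abs(rcode_peak(rc) - expected), 0.02)
  expect_lt(abs(rcode_peak(rc) - 0.36), 0.02)  # the helix landmark
})

test_that("class_rcode_matrix orders synthetic classes along r", {
  mk <- function(m, s) {
    d <- sample_motif(m, 2000, sd = 8, seed = s)
    rama_number(d$phi, d$psi)
  }
  groups <- list(alpha = mk("alpha", 1), beta = mk("beta", 2),
                 alpha2 = mk("alpha", 1))
  m <- class_rcode_matrix(groups)
  expect_equal(dim(m), c(100L, 3L))
  expect_equal(unname(apply(m, 2, max)), c(1, 1, 1))
  expect_identical(m[, "alpha"], m[, "alpha2"])  # identical classes
  mids <- as.numeric(rownames(m))
  expect_lt(mids[which.max(m[, "alpha"])], mids[which.max(m[, "beta"])])
  expect_warning(class_rcode_matrix(list(a = mk("alpha", 1),
                                         void = numeric(0))), "empty class")
})

test_that("residue_trace maps chains/frames and enforces conformers", {
  d <- make_sigma_chain(9, state = c(-60, 150))
  rec <- trajectory_records(list(d))
  tr <- residue_trace(rec)
  expect_equal(dim(tr), c(9L, 1L))
  r0 <- rama_number(-60, 150)
  expect_equal(unname(tr[c(1, 3, 5), 1]), rep(r0, 3), tolerance = 1e-6)
  expect_equal(unname(tr[c(2, 4), 1]), rep(1 - r0, 2), tolerance = 1e-6)

  bad <- rbind(rec, transform(rec, model = 2)[-1, ])
  expect_error(residue_trace(bad), "conformers")
  rec$chain[1] <- "B"
  expect_error(residue_trace(rec), "one chain")

  # constant all-helix chain gives a flat trace
  cst <- trajectory_records(list(data.frame(phi = rep(-63, 8),
                                            psi = rep(-43, 8))))
  expect_lt(diff(range(residue_trace(cst))), 1e-12)
})

test_that("rcode_timeseries windows frames and conserves counts", {
  traj <- make_trajectory(12, switch_frame = 6, n_residues = 10,
                          noise_sd = 2, seed = 5)
  tr <- residue_trace(trajectory_records(traj))
  ts <- rcode_timeseries(tr, frame_bin = 12)
  expect_length(ts, 1)
  expect_equal(ts[[1]]$counts, rcode(as.vector(tr))$counts)

  ts <- rcode_timeseries(tr, frame_bin = 5)
  expect_length(ts, 3)  # trailing partial window kept
  expect_equal(vapply(ts, function(x) x$n, 0), c(`1-5` = 50, `6-10` = 50,
                                                 `11-12` = 20))
  # before the switch: a single state near r = 0.5; after: two states
  before <- ts[[1]]; after <- ts[[3]]
  expect_true(all(abs(rep(before$mids, before$counts) - 0.5) < 0.1))
  r_after <- rep(after$mids, after$counts)
  expect_gt(sum(abs(r_after - 0.375) < 0.05), 0)
  expect_gt(sum(abs(r_after - 0.625) < 0.05), 0)
})

test_that("alternation_score matches its defining cases", {
  expect_equal(alternation_score(rep(c(0.3, 0.7), 5)), 1)
  expect_equal(alternation_score(rep(0.4, 8)), 0)
  expect_equal(alternation_score(seq(0.1, 0.9, by = 0.1)), 0)
  expect_true(is.na(alternation_score(c(0.1, 0.9))))
  # undefined cells drop triplets from the denominator
  expect_equal(alternation_score(c(0.3, 0.7, 0.3, NA, 0.3, 0.7, 0.3)), 1)
})

test_that("density_region returns the smallest cell set with the mass", {
  d <- sample_motif("alpha", 3000, sd = 6, seed = 9)
  reg <- density_region(d$phi, d$psi, mass = 0.7)
  expect_gte(sum(reg$count), 0.7 * attr(reg, "n"))
  # removing the last (smallest) cell drops below the target: minimality
  expect_lt(sum(reg$count) - min(reg$count), 0.7 * attr(reg, "n"))
  reg9 <- density_region(d$phi, d$psi, mass = 0.9)
  expect_lte(nrow(reg), nrow(reg9))
  all_cells <- density_region(d$phi, d$psi, mass = 1)
  expect_equal(sum(all_cells$count), attr(all_cells, "n"))
  expect_error(density_region(1:5, 1:5), "at least 10")
})

test_that("motif landmarks carry the canonical r positions", {
  lm <- motif_landmarks()
  expect_equal(lm$r[lm$name == "alpha"], 0.36)
  expect_equal(lm$r[lm$name == "beta"], 0.52)
  expect_equal(lm$r[lm$name == "loop"], 0.62)
  expect_true(all(lm$lo >= 0 & lm$hi <= 1 & lm$lo < lm$hi))
  wide <- motif_landmarks(width = 0.1)
  expect_true(all(wide$hi - wide$lo >= lm$hi - lm$lo))
})
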