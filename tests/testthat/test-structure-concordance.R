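test_that("Cbeta distances measure planted trimer geometry", {
  dir <- tempfile("trimer")
  pairs <- data.frame(residue1 = "G10", residue2 = "G20",
                      intersubunit = FALSE)
  d <- list(closed = matrix(c(5, 5, 5), 1), open = matrix(c(4, 5, 6), 1),
            desensitized = matrix(c(7, 7, 7), 1))
  paths <- generate_structure_fixture(pairs, d, dir)
  expect_equal(cbeta_distances(paths[["closed"]], c(10, 20), "intra"),
               c(5, 5, 5), tolerance = 0.01)
  expect_equal(sort(cbeta_distances(paths[["open"]], c(10, 20), "intra")),
               c(4, 5, 6), tolerance = 0.01)
  ## symmetry of the arguments (intrasubunit)
  expect_equal(cbeta_distances(paths[["closed"]], c(10, 20), "intra"),
               cbeta_distances(paths[["closed"]], c(20, 10), "intra"))
  ## missing residue raises a named error
  expect_error(cbeta_distances(paths[["closed"]], c(10, 99), "intra"),
               "residue 99")
})

test_that("distance records average subunits and states with the sign convention", {
  dir <- tempfile("rec")
  pairs <- data.frame(residue1 = "S83", residue2 = "T289",
                      intersubunit = TRUE)
  d <- list(closed = 14.03, open = 12.03, desensitized = 11.13)
  paths <- generate_structure_fixture(pairs, d, dir)
  rec <- state_distance_record(as.list(paths), c("S83", "T289"), "inter")
  expect_equal(rec$avg_distance, 12.4, tolerance = 0.005)
  expect_equal(rec$delta_open_closed, -2.0, tolerance = 0.01)
  expect_equal(rec$delta_desens_open, -0.9, tolerance = 0.01)
  ## identical structures give zero deltas
  same <- list(closed = paths[["closed"]], open = paths[["closed"]],
               desensitized = paths[["closed"]])
  rec0 <- state_distance_record(same, c("S83", "T289"), "inter")
  expect_equal(rec0$delta_open_closed, 0)
  expect_equal(rec0$delta_desens_open, 0)
})

test_that("distances are invariant under rigid-body motion", {
  dir <- tempfile("rigid")
  pairs <- data.frame(residue1 = "G10", residue2 = "G20",
                      intersubunit = TRUE)
  d <- list(closed = 8.4, open = 8.4, desensitized = 8.4)
  paths <- generate_structure_fixture(pairs, d, dir)
  pdb <- bio3d::read.pdb(paths[["closed"]])
  d0 <- cbeta_distances(pdb, c(10, 20), "inter")
  ## translate + rotate all coordinates
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(pdb$atom[, c("x", "y", "z")]) %*% R
  pdb$atom$x <- xyz[, 1] + 11.3
  pdb$atom$y <- xyz[, 2] - 4.2
  pdb$atom$z <- xyz[, 3] + 0.9
  expect_equal(cbeta_distances(pdb, c(10, 20), "inter"), d0,
               tolerance = 1e-6)
})

test_that("transition deltas select the associated distance change", {
  t2 <- read_table2()
  recs <- asicvcf:::records_from_table(t2)
  expect_equal(transition_delta(recs[["S83 Q358"]], "o")$delta, 4.5)
  expect_equal(transition_delta(recs[["S83 Q358"]], "o")$transition,
               "open_minus_closed")
  expect_equal(transition_delta(recs[["A81 M210"]], "i")$delta, -3.0)
  expect_equal(transition_delta(recs[["Q84 R206"]], "d")$delta, 0.0)
  expect_equal(transition_delta(recs[["A81 L369"]], "less_than_o")$delta,
               -2.4)
  expect_error(transition_delta(recs[["S83 Q358"]], "x"), "association")
})

test_that("pair classification follows polarity, threshold and exclusions", {
  mk <- function(r1, r2, pol, assoc, excl = FALSE)
    list(residue1 = r1, residue2 = r2, polarity = pol, association = assoc,
         excluded = excl)
  rec <- function(r1, r2, d_oc, d_do)
    distance_record(r1, r2, 10, d_oc, d_do)
  expect_equal(classify_pair(mk("S83", "T289", "neg", "o"),
                             rec("S83", "T289", -2.0, -0.9))$label,
               "consistent")
  expect_equal(classify_pair(mk("S83", "E359", "neg", "o"),
                             rec("S83", "E359", 3.0, -1.0))$label,
               "contradicts")
  expect_equal(classify_pair(mk("Q84", "Y417", "neg", "i"),
                             rec("Q84", "Y417", 0.0, -0.4))$label,
               "indeterminate")
  expect_equal(classify_pair(mk("A81", "M210", "pos", "i"),
                             rec("A81", "M210", -0.4, -3.0))$label,
               "contradicts")
  expect_equal(classify_pair(mk("A81", "P205", "pos", "i", excl = TRUE),
                             rec("A81", "P205", 0.1, -0.5))$label,
               "excluded")
  ## threshold boundary: |delta| = threshold is interpretable
  expect_equal(classify_pair(mk("X1", "X2", "neg", "i"),
                             rec("X1", "X2", 0, -1.0))$label, "consistent")
  expect_error(classify_pair(mk("S83", "T289", "neg", "o"),
                             rec("A81", "M210", -1, -1)), "different pairs")
})

test_that("flipping polarity and negating deltas preserves the label", {
  flip <- c(neg = "pos", pos = "neg")
  t1 <- read_table1()
  recs <- asicvcf:::records_from_table(read_table2())
  for (i in seq_len(nrow(t1))) {
    r <- recs[[asicvcf:::pair_key(t1$residue1[i], t1$residue2[i])]]
    ann <- as.list(t1[i, ])
    lab <- classify_pair(ann, r, apply_exclusion = FALSE)$label
    ann2 <- ann
    ann2$polarity <- unname(flip[ann$polarity])
    r2 <- distance_record(r$residue1, r$residue2, r$avg_distance,
                          -r$delta_open_closed, -r$delta_desens_open)
    expect_equal(classify_pair(ann2, r2, apply_exclusion = FALSE)$label, lab)
  }
})

test_that("the packaged tables reproduce the printed classification 22/22", {
  ct <- concordance_table(read_table1(), read_table2())
  expect_equal(nrow(ct), 22L)
  expect_true(all(ct$font_match))
})

test_that("the exclusion rules single out exactly the two starred pairs", {
  ex <- apply_exclusions(read_table1(), read_table2())
  excl <- ex[ex$excluded, ]
  expect_equal(nrow(excl), 2L)
  expect_setequal(paste(excl$residue1, excl$residue2),
                  c("A81 P205", "A81 T209"))
  expect_equal(excl$exclusion_reason[excl$residue2 == "P205"],
               "distance_gt_20A")
  expect_equal(excl$exclusion_reason[excl$residue2 == "T209"],
               "non_desensitizing")
  ## recomputed flags agree with the transcribed ones
  expect_equal(ex$excluded, read_table1()$excluded)
})

test_that("table summary counts match the study totals", {
  s <- summarize_table(read_table1(), read_table2())
  expect_equal(s$closed_open, 6L)
  expect_equal(s$closed_open_intrasubunit, 2L)
  expect_equal(s$closed_open_intersubunit, 4L)
  expect_equal(s$open_desens, 16L)
  expect_equal(s$excluded, 2L)
  expect_equal(s$open_desens_retained, 14L)
  expect_equal(s$open_desens_contradicts, 3L)
  expect_equal(s$loop_205_210, 9L)
  expect_equal(s$loop_205_210_opening, 2L)
  expect_equal(s$loop_205_210_desens, 7L)
  expect_equal(s$palm_thumb_closed_open, 4L)
  expect_equal(s$palm_thumb_open_desens, 6L)
  ## duplicate pair+component entries are rejected
  t1 <- read_table1()
  expect_error(summarize_table(rbind(t1, t1[1, ])), "duplicate")
})
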