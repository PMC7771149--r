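test_that("mother identifiers are deterministic and injective", {
  expect_identical(make_mother_uid("UNI", TRUE, FALSE, 3), "UNI.K1.U0.3")
  expect_identical(make_mother_uid("P5", FALSE, FALSE, 1), "P5.K0.U0.1")
  expect_false(make_mother_uid("UNI", TRUE, FALSE, 3) ==
                 make_mother_uid("UNI", TRUE, FALSE, 4))
  # injectivity over a grid of inputs
  grid <- expand.grid(clone = c("UNI", "P5"), k = c(TRUE, FALSE),
                      u = c(TRUE, FALSE), i = 1:7)
  uids <- make_mother_uid(grid$clone, grid$k, grid$u, grid$i)
  expect_equal(anyDuplicated(uids), 0)
  expect_error(make_mother_uid("UNI", TRUE, FALSE, 0), "mother_index")
})

test_that("juvenile tables round-trip through CSV and are validated", {
  df <- tiny_juvenile_table(10)
  df$body_length_mm[3] <- NA  # missing measurement preserved, not zeroed
  path <- withr::local_tempfile(fileext = ".csv")
  write_juvenile_table(df, path)
  back <- read_juvenile_table(path)
  expect_identical(back$clone, df$clone)
  expect_identical(back$neckteeth, df$neckteeth)
  expect_identical(as.character(back$pedestal), df$pedestal)
  expect_identical(back$mother_uid, df$mother_uid)
  expect_true(is.na(back$body_length_mm[3]))
  expect_equal(back$body_length_mm[-3], df$body_length_mm[-3])
  expect_s3_class(back$pedestal, "ordered")

  bad <- df
  bad$pedestal[4] <- "D"
  expect_error(validate_juvenile_table(bad), "row 4")
  expect_error(validate_juvenile_table(df[, setdiff(names(df), "neckteeth")]),
               "neckteeth")
  bad2 <- df
  bad2$neckteeth[2] <- 6L
  expect_error(validate_juvenile_table(bad2), "row 2")
  bad3 <- df
  bad3$instar[5] <- 2L
  bad3$survived_to_instar2[5] <- FALSE
  expect_error(validate_juvenile_table(bad3), "row 5")
})

test_that("effectivity tables validate and round-trip", {
  df <- data.frame(treatment = c("control", "PAR", "UVR"),
                   exposure_hours = c(2L, 4L, 8L),
                   mother_uid = make_effectivity_mother_uid(
                     c("control", "PAR", "UVR"), c(2, 4, 8), 1),
                   neckteeth = c(0L, 3L, 5L),
                   pedestal = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effectivity_table(df, path)
  back <- read_effectivity_table(path)
  expect_identical(as.character(back$treatment), df$treatment)
  expect_identical(back$neckteeth, df$neckteeth)
  bad <- df
  bad$exposure_hours[2] <- 5L
  expect_error(validate_effectivity_table(bad), "row 2")
  bad$exposure_hours[2] <- 4L
  bad$treatment[1] <- "dark"
  expect_error(validate_effectivity_table(bad), "row 1")
})

test_that("Tollrian induction score follows the weighted capped sum", {
  expect_equal(tollrian_induction_score(0, "A"), 0)
  expect_equal(tollrian_induction_score(3, "B"), 60)
  expect_equal(tollrian_induction_score(5, "C"), 100)  # capped at 100
  # monotone in both components for non-negative weights
  for (ped in 1:2) {
    expect_true(all(diff(tollrian_induction_score(0:5, rep(c("A", "B", "C")[ped], 6))) >= 0))
  }
  for (k in c(0L, 2L, 5L)) {
    sc <- tollrian_induction_score(rep(k, 3), c("A", "B", "C"))
    expect_true(all(diff(sc) >= 0))
  }
  expect_error(induction_weights(per_tooth_percent = -1), "non-negative")
  expect_error(induction_weights(cap = 40), "cap")
  # custom weights flow through
  w <- induction_weights(per_tooth_percent = 5, pedestal_percent = c(A = 0, B = 10, C = 20),
                         cap = 50)
  expect_equal(tollrian_induction_score(4, "C", w), 40)
})

test_that("landmark lengths are Euclidean distances, invariant to rigid motion", {
  lm <- landmark_set(head_top = c(0.10, 0.90), spina_base = c(0.10, 0.20),
                     spina_tip = c(0.10, 0.20), ventral_mid = c(0, 0),
                     dorsal_mid = c(0.3, 0.4))
  len <- landmark_lengths(lm)
  expect_equal(unname(len["body_length_mm"]), 0.70)
  expect_equal(unname(len["body_width_mm"]), 0.5)  # 3-4-5 triangle
  expect_equal(unname(len["spina_length_mm"]), 0)  # coincident points
  expect_error(landmark_set(head_top = c(0, NA), spina_base = c(0, 0),
                            spina_tip = c(0, 0), ventral_mid = c(0, 0),
                            dorsal_mid = c(0, 0)), "head_top")

  # translation + rotation invariance
  set.seed(42)
  for (rep in 1:5) {
    pts <- lapply(1:5, function(i) runif(2, 0, 2))
    names(pts) <- c("head_top", "spina_base", "spina_tip", "ventral_mid",
                    "dorsal_mid")
    base <- landmark_lengths(do.call(landmark_set, pts))
    theta <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    shift <- runif(2, -5, 5)
    moved <- lapply(pts, function(p) drop(Rm %*% p) + shift)
    expect_equal(landmark_lengths(do.call(landmark_set, moved)), base,
                 tolerance = 1e-10)
  }
})

test_that("landmark tables are read with computed lengths appended", {
  df <- data.frame(id = 1:2,
                   head_top_x = c(0.1, 0), head_top_y = c(0.9, 1),
                   spina_base_x = c(0.1, 0), spina_base_y = c(0.2, 0),
                   spina_tip_x = c(0.1, 0.3), spina_tip_y = c(0.1, 0.4),
                   ventral_mid_x = 0, ventral_mid_y = 0,
                   dorsal_mid_x = 0.3, dorsal_mid_y = 0.4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  out <- read_landmark_table(path)
  expect_equal(out$body_length_mm, c(0.7, 1))
  expect_equal(out$spina_length_mm, c(0.1, 0.5))
  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(read_landmark_table(path), "head_top_x")
})
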