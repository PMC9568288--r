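test_that("mean probing depth averages the six sites", {
  expect_equal(mean_probing_depth(c(3, 3, 3, 3, 3, 3)), 3.0)
  expect_equal(mean_probing_depth(c(2, 3, 4, 4, 3, 2)), 3.0)
  expect_equal(mean_probing_depth(c(5, 6, 5, 6, 5, 6)), 5.5)
  expect_error(mean_probing_depth(c(3, 3, 3)), "exactly 6")
  expect_error(mean_probing_depth(c(3, 3, 3, 3, 3, -1)), ">= 0")
  # matrix form: one row per implant
  m <- rbind(c(2, 3, 4, 4, 3, 2), c(5, 6, 5, 6, 5, 6))
  expect_equal(mean_probing_depth(m), c(3.0, 5.5))
})

test_that("crestal bone loss is a validated pass-through in mm", {
  expect_equal(crestal_bone_loss(0), 0)
  expect_equal(crestal_bone_loss(2.5), 2.5)
  expect_error(crestal_bone_loss(-1), ">= 0")
})

test_that("classification matches the diagnostic criteria in both modes", {
  healthy <- make_record()
  for (mode in c("pragmatic", "strict")) {
    expect_equal(as.character(classify_implants(healthy, mode)$diagnosis),
                 "healthy")
  }
  # bone loss above 2 mm with visible plaque and bleeding: peri-implantitis
  pi_rec <- make_record(mgi = 2L, mpi = 2L, crestal_bone_loss_mm = 2.5,
                        pd_mesiobuccal_mm = 4, pd_midbuccal_mm = 4,
                        pd_distobuccal_mm = 4, pd_distolingual_mm = 4,
                        pd_midlingual_mm = 4, pd_mesiolingual_mm = 4)
  expect_equal(as.character(classify_implants(pi_rec)$diagnosis),
               "peri_implantitis")
  # mild inflammation without suppuration defeats the strict conjunctions
  mild <- make_record(mgi = 1L, mpi = 1L, crestal_bone_loss_mm = 1)
  expect_warning(
    strict <- classify_implants(mild, "strict"),
    "indeterminate")
  expect_equal(as.character(strict$diagnosis), "indeterminate")
  expect_equal(as.character(classify_implants(mild)$diagnosis), "mucositis")
})

test_that("pragmatic classification is total over a findings grid", {
  grid <- expand.grid(mgi = 0:3, mpi = 0:3, supp = c(FALSE, TRUE),
                      pd = c(3, 5, 6), loss = c(0, 1, 2, 2.5, 4))
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_record(implant_id = paste0("I", i), mgi = g$mgi, mpi = g$mpi,
                suppuration = g$supp, crestal_bone_loss_mm = g$loss,
                pd_mesiobuccal_mm = g$pd, pd_midbuccal_mm = g$pd,
                pd_distobuccal_mm = g$pd, pd_distolingual_mm = g$pd,
                pd_midlingual_mm = g$pd, pd_mesiolingual_mm = g$pd)
  }))
  out <- classify_implants(recs, "pragmatic")
  expect_false(anyNA(out$diagnosis))
  expect_true(all(out$diagnosis %in%
                    c("healthy", "mucositis", "peri_implantitis")))
  # strict and pragmatic agree wherever a strict conjunction holds
  strict <- suppressWarnings(classify_implants(recs, "strict"))
  det <- strict$diagnosis != "indeterminate"
  expect_true(any(det))
  expect_equal(as.character(strict$diagnosis[det]),
               as.character(out$diagnosis[det]))
})

test_that("increasing bone loss never demotes peri-implantitis", {
  for (loss in seq(0, 6, by = 0.5)) {
    lab <- as.character(classify_implants(
      make_record(mgi = 2L, crestal_bone_loss_mm = loss))$diagnosis)
    expected <- if (loss > 2) "peri_implantitis" else "mucositis"
    expect_equal(lab, expected, info = paste("loss =", loss))
  }
  # boundary: exactly 2 mm stays mucositis
  expect_equal(as.character(classify_implants(
    make_record(mgi = 1L, crestal_bone_loss_mm = 2))$diagnosis),
    "mucositis")
})
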