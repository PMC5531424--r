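test_that("spike-referenced dCt matches hand arithmetic and the floor rule", {
  raw <- make_raw_ct(list(
    c1 = list(
      spike1 = 13, spike4 = 15,
      genes = c(mid = 20, at_ref = sqrt(13 * 15), low = 35)
    )
  ))
  expr <- normalize_cts(qc_filter(raw))
  expect_equal(expr$mid, sqrt(13 * 15) - 20, tolerance = 1e-12)
  expect_equal(expr$at_ref, 0, tolerance = 1e-12)
  # raw dCt = sqrt(195) - 35 = -21.04 < -17: assigned the floor exactly
  expect_identical(expr$low, -17)
  fr <- attr(expr, "floor_report")
  expect_equal(fr$reason[fr$gene == "low"], "measured_below_floor")
})

test_that("non-detected genes get the floor, tagged distinctly", {
  raw <- make_raw_ct(list(
    c1 = list(spike1 = 14, spike4 = 14, genes = c(g1 = NA_real_, g2 = 12))
  ))
  expr <- normalize_cts(qc_filter(raw))
  expect_identical(expr$g1, -17)
  fr <- attr(expr, "floor_report")
  expect_equal(fr$reason[fr$gene == "g1"], "assigned_floor")
})

test_that("cells with failed or missing spikes are dropped; failed gene readings masked", {
  raw <- make_raw_ct(list(
    good = list(spike1 = 13, spike4 = 15, genes = c(g1 = 20, g2 = 22)),
    bad_spike = list(
      spike1 = 13, spike4 = 15, genes = c(g1 = 20, g2 = 22),
      flags = c(spike4 = "Failed")
    ),
    failed_gene = list(
      spike1 = 13, spike4 = 15, genes = c(g1 = 20, g2 = 22),
      flags = c(g1 = "Failed")
    )
  ))
  out <- qc_filter(raw)
  expect_setequal(unique(out$cell_id), c("good", "failed_gene"))
  expect_equal(qc_report(out)$dropped_cells, "bad_spike")
  masked <- qc_report(out)$masked_readings
  expect_equal(masked$cell_id, "failed_gene")
  expect_equal(masked$assay, "g1")
  # the masked reading surfaces as floor after normalisation
  expr <- normalize_cts(out)
  expect_identical(expr$g1[expr$cell_id == "failed_gene"], -17)
})

test_that("qc_filter is a no-op on an all-OK table", {
  raw <- make_raw_ct(list(
    c1 = list(spike1 = 13, spike4 = 15, genes = c(g1 = 20, g2 = 25)),
    c2 = list(spike1 = 14, spike4 = 14, genes = c(g1 = 21, g2 = NA_real_))
  ))
  out <- qc_filter(raw)
  expect_equal(
    dplyr::arrange(as.data.frame(out), cell_id, assay),
    dplyr::arrange(as.data.frame(raw), cell_id, assay),
    ignore_attr = TRUE
  )
})

test_that("duplicate readings: consistent ones averaged, divergent ones masked", {
  raw <- dplyr::bind_rows(
    make_raw_ct(list(
      c1 = list(spike1 = 13, spike4 = 15, genes = c(g_ok = 20, g_bad = 20))
    )),
    tibble::tibble(
      cell_id = "c1", assay = c("g_ok", "g_bad"),
      ct = c(20.5, 22), flag = "OK"
    )
  )
  out <- qc_filter(raw)
  expect_equal(out$ct[out$assay == "g_ok"], 20.25)
  expect_true(is.na(out$ct[out$assay == "g_bad"]))
  expect_equal(out$flag[out$assay == "g_bad"], "Inconsistent")
})

test_that("masked-reading count matches the generator's Failed count exactly", {
  cfg <- expression_sim_config(dropout_fail_rate = 0.05, seed = 11)
  sim <- simulate_expression(cfg, c(multiprimed = 96))
  out <- qc_filter(sim$ct)
  dropped <- qc_report(out)$dropped_cells
  expected_masked <- sim$ct |>
    dplyr::filter(
      flag == "Failed", !assay %in% c("spike1", "spike4"),
      !cell_id %in% dropped
    ) |>
    nrow()
  expect_equal(nrow(qc_report(out)$masked_readings), expected_masked)
  spike_failed <- sim$ct |>
    dplyr::filter(flag == "Failed", assay %in% c("spike1", "spike4")) |>
    dplyr::distinct(cell_id) |>
    dplyr::pull(cell_id)
  expect_setequal(dropped, spike_failed)
})

test_that("dCt is monotone decreasing in gene Ct until the floor, then flat", {
  cts <- seq(10, 40, by = 0.5)
  raw <- purrr::imap_dfr(cts, function(ct, i) {
    tibble::tibble(
      cell_id = sprintf("c%03d", i),
      assay = c("spike1", "spike4", "g"),
      ct = c(13, 15, ct), flag = "OK"
    )
  })
  expr <- normalize_cts(qc_filter(raw))
  dct <- expr$g[order(expr$cell_id)]
  above <- dct > -17
  expect_true(all(diff(dct[above]) < 0))
  expect_true(all(dct[!above] == -17))
})

test_that("adding c cycles to spikes and genes leaves dCt unchanged when spikes are equal", {
  base <- make_raw_ct(list(
    c1 = list(spike1 = 14, spike4 = 14, genes = c(g1 = 20, g2 = 24))
  ))
  shifted <- dplyr::mutate(base, ct = ct + 3)
  e1 <- normalize_cts(qc_filter(base))
  e2 <- normalize_cts(qc_filter(shifted))
  expect_identical(e1$g1, e2$g1)
  expect_identical(e1$g2, e2$g2)
})

test_that("normalisation round-trips a floored matrix re-encoded as Ct", {
  cfg <- expression_sim_config(seed = 3, dropout_fail_rate = 0)
  sim <- simulate_expression(cfg, c(lineage1 = 20))
  expr <- normalize_cts(qc_filter(sim$ct))
  genes <- setdiff(names(expr), "cell_id")
  # re-encode with fixed symmetric spikes: Ct = 14 - dCt
  re_raw <- expr |>
    tidyr::pivot_longer(dplyr::all_of(genes), names_to = "assay", values_to = "dct") |>
    dplyr::mutate(ct = 14 - dct, flag = "OK") |>
    dplyr::select(cell_id, assay, ct, flag)
  spikes <- tidyr::expand_grid(
    cell_id = expr$cell_id, assay = c("spike1", "spike4")
  ) |>
    dplyr::mutate(ct = 14, flag = "OK")
  e2 <- normalize_cts(qc_filter(dplyr::bind_rows(spikes, re_raw)))
  m1 <- as.matrix(expr[genes])
  m2 <- as.matrix(e2[match(expr$cell_id, e2$cell_id), genes])
  expect_true(max(abs(m1 - m2)) < 1e-9)
})

test_that("normalisation is invariant to cell and gene order", {
  cfg <- expression_sim_config(seed = 5)
  sim <- simulate_expression(cfg, c(multiprimed = 15))
  perm <- sim$ct[sample(nrow(sim$ct)), ]
  e1 <- normalize_cts(qc_filter(sim$ct))
  e2 <- normalize_cts(qc_filter(perm))
  e2 <- e2[match(e1$cell_id, e2$cell_id), names(e1)]
  expect_equal(as.data.frame(e1), as.data.frame(e2), ignore_attr = TRUE)
})

test_that("format and value errors are raised", {
  no_spike <- tibble::tibble(
    cell_id = "c1", assay = "g1", ct = 20, flag = "OK"
  )
  expect_error(qc_filter(no_spike), "spike")
  neg <- make_raw_ct(list(
    c1 = list(spike1 = -1, spike4 = 15, genes = c(g1 = 20))
  ))
  expect_error(qc_filter(neg), "positive")
  three_spikes <- make_raw_ct(list(
    c1 = list(spike1 = 13, spike4 = 15, genes = c(g1 = 20))
  ))
  expect_error(
    normalize_cts(three_spikes, spikes = c("spike1", "spike4", "spike9")),
    "two spike"
  )
})

test_that("raw Ct tables round-trip through the wide CSV dialect", {
  cfg <- expression_sim_config(seed = 8)
  sim <- simulate_expression(cfg, c(lineage1 = 10), time_point = "48h")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_csv(sim$ct, path)
  back <- read_ct_csv(path)
  orig <- dplyr::arrange(sim$ct, cell_id, assay)
  back <- dplyr::arrange(back, cell_id, assay)[names(orig)]
  expect_equal(as.data.frame(back), as.data.frame(orig), ignore_attr = TRUE)
})

test_that("column maps adapt a permissive Biomark-style export", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Chamber ID,Spike I,Spike IV,GATA1",
    "A01,13,15,20"
  ), path)
  raw <- read_ct_csv(path, column_map = c(
    cell_id = "Chamber ID", spike1 = "Spike I", spike4 = "Spike IV"
  ))
  expr <- normalize_cts(qc_filter(raw))
  expect_equal(expr$GATA1, sqrt(195) - 20, tolerance = 1e-12)
})
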