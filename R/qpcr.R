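#' Quality-filter a raw single-cell Ct table
#'
#' Applies the published filtering rules: per-gene readings flagged
#' `"Failed"`, and inconsistent duplicate readings, are masked (set to
#' missing); any cell whose `spike1` or `spike4` reading is missing, failed or
#' inconsistent is dropped entirely. "Inconsistent" is defined operationally
#' as duplicate readings of the same assay in the same cell disagreeing by
#' more than `dup_tol` cycles; single readings are never inconsistent.
#' Surviving duplicate readings are collapsed to their mean.
#'
#' @param ct Long raw Ct tibble with columns `cell_id`, `assay`, `ct`, `flag`
#'   (`"OK"`/`"Failed"`/`"Inconsistent"`), e.g. from [simulate_expression()]
#'   or [read_ct_csv()]. Extra label columns (`time_point`, `condition`,
#'   `fraction`, `donor`) are carried through.
#' @param spikes The two spike assay names; both must be present.
#' @param dup_tol Maximum allowed disagreement (cycles) between duplicate
#'   readings before they are declared inconsistent.
#' @return Filtered tibble of the same layout, one row per (cell, assay);
#'   masked readings have `ct = NA` and keep their flag. The QC report is
#'   attached as attribute `"qc_report"` (see [qc_report()]).
#' @export
qc_filter <- function(ct, spikes = c("spike1", "spike4"), dup_tol = 1) {
  check_ct_table(ct, spikes)
  labels <- intersect(names(ct), setdiff(.meta_cols, "cell_id"))

  collapsed <- ct |>
    dplyr::group_by(.data$cell_id, .data$assay) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(labels), ~ .x[1]),
      n_read = dplyr::n(),
      spread = ifelse(
        sum(!is.na(.data$ct)) > 1,
        max(.data$ct, na.rm = TRUE) - min(.data$ct, na.rm = TRUE), 0
      ),
      any_failed = any(.data$flag == "Failed"),
      any_inconsistent = any(.data$flag == "Inconsistent"),
      ct = mean(.data$ct[.data$flag == "OK"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      inconsistent = .data$any_inconsistent |
        (.data$n_read > 1 & .data$spread > dup_tol),
      masked = .data$any_failed | .data$inconsistent | is.nan(.data$ct),
      flag = dplyr::case_when(
        .data$inconsistent ~ "Inconsistent",
        .data$any_failed ~ "Failed",
        .default = "OK"
      ),
      ct = ifelse(.data$masked, NA_real_, .data$ct)
    )

  bad_cells <- collapsed |>
    dplyr::filter(.data$assay %in% spikes, .data$masked | is.na(.data$ct)) |>
    dplyr::distinct(.data$cell_id)
  # cells lacking a spike row entirely are dropped too
  no_spike <- collapsed |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_sp = sum(.data$assay %in% spikes), .groups = "drop") |>
    dplyr::filter(.data$n_sp < length(spikes)) |>
    dplyr::select("cell_id")
  dropped <- dplyr::distinct(dplyr::bind_rows(bad_cells, no_spike))

  out <- collapsed |>
    dplyr::anti_join(dropped, by = "cell_id") |>
    dplyr::select(
      "cell_id", dplyr::all_of(labels), "assay", "ct", "flag"
    )
  masked_tbl <- collapsed |>
    dplyr::filter(.data$masked, !.data$assay %in% spikes) |>
    dplyr::anti_join(dropped, by = "cell_id") |> # dropped cells listed apart
    dplyr::select("cell_id", "assay", "flag")
  attr(out, "qc_report") <- list(
    dropped_cells = dropped$cell_id,
    masked_readings = masked_tbl,
    n_cells_in = dplyr::n_distinct(ct$cell_id),
    n_cells_out = dplyr::n_distinct(out$cell_id)
  )
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param ct A tibble returned by [qc_filter()].
#' @return A list with `dropped_cells`, `masked_readings`, cell counts.
#' @export
qc_report <- function(ct) {
  rep <- attr(ct, "qc_report")
  if (is.null(rep)) abort("no QC report attached; run qc_filter() first")
  rep
}

check_ct_table <- function(ct, spikes) {
  need <- c("cell_id", "assay", "ct", "flag")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) {
    abort(paste0("raw Ct table lacks columns: ", paste(miss, collapse = ", ")))
  }
  have_spikes <- ct |>
    dplyr::distinct(.data$assay) |>
    dplyr::pull("assay")
  if (!all(spikes %in% have_spikes)) {
    abort(paste0(
      "spike assays missing from table: ",
      paste(setdiff(spikes, have_spikes), collapse = ", ")
    ))
  }
  if (any(ct$ct <= 0, na.rm = TRUE)) {
    abort("Ct values must be positive where present")
  }
  invisible(ct)
}

#' Spike-normalise a filtered Ct table to a floored dCt expression matrix
#'
#' For each cell, the normalisation reference is the geometric mean of the
#' two spike-in Cts, `s = sqrt(Ct_spike1 * Ct_spike4)`; each detected gene
#' gets `dCt = s - Ct_gene` (higher dCt = higher expression). Any dCt below
#' the floor, and any non-detected gene, is assigned the floor value
#' (default -17). Exactly two spike channels are required.
#'
#' @param ct Long Ct tibble that has passed [qc_filter()].
#' @param floor dCt floor (default -17).
#' @param spikes The two spike assay names.
#' @return Wide tibble: `cell_id`, any label columns, then one numeric dCt
#'   column per gene. Attribute `"floor_report"` records, per floored value,
#'   whether it was `"assigned_floor"` (non-detected) or
#'   `"measured_below_floor"`.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   cell_id = "c1",
#'   assay = c("spike1", "spike4", "GATA1"),
#'   ct = c(13, 15, 20),
#'   flag = "OK"
#' )
#' normalize_cts(qc_filter(raw)) # GATA1 dCt = sqrt(13*15) - 20
normalize_cts <- function(ct, floor = -17, spikes = c("spike1", "spike4")) {
  if (length(spikes) != 2) {
    abort("exactly two spike channels are required for the geometric mean")
  }
  check_ct_table(ct, spikes)
  labels <- intersect(names(ct), setdiff(.meta_cols, "cell_id"))

  spike_ref <- ct |>
    dplyr::filter(.data$assay %in% spikes) |>
    tidyr::pivot_wider(
      id_cols = "cell_id", names_from = "assay", values_from = "ct"
    )
  if (anyNA(spike_ref[spikes])) {
    abort("cells with missing spike readings present; run qc_filter() first")
  }
  if (any(spike_ref[[spikes[1]]] <= 0 | spike_ref[[spikes[2]]] <= 0)) {
    abort("non-positive spike Ct: geometric mean undefined")
  }
  spike_ref$spike_geomean <- sqrt(
    spike_ref[[spikes[1]]] * spike_ref[[spikes[2]]]
  )

  long <- ct |>
    dplyr::filter(!.data$assay %in% spikes) |>
    dplyr::left_join(
      dplyr::select(spike_ref, "cell_id", "spike_geomean"),
      by = "cell_id"
    ) |>
    dplyr::mutate(
      raw_dct = .data$spike_geomean - .data$ct,
      reason = dplyr::case_when(
        is.na(.data$ct) ~ "assigned_floor",
        .data$raw_dct < floor ~ "measured_below_floor",
        .default = NA_character_
      ),
      dct = pmax(dplyr::coalesce(.data$raw_dct, floor), floor)
    )

  floor_report <- long |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("cell_id", gene = "assay", "reason")

  wide <- long |>
    dplyr::select(
      "cell_id", dplyr::all_of(labels), gene = "assay", "dct"
    ) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "dct")
  attr(wide, "floor_report") <- floor_report
  attr(wide, "floor") <- floor
  wide
}

#' Read / write raw Ct tables as wide CSV
#'
#' The on-disk dialect is one row per cell: a `cell_id` first column, one Ct
#' column per assay (the two spike channels named `spike1`/`spike4`), and an
#' optional `<assay>_flag` column per assay with values `"OK"`, `"Failed"` or
#' `"Inconsistent"`. Empty Ct cells mean "not detected". `column_map` renames
#' non-standard Biomark export headers, e.g.
#' `c(cell_id = "Chamber ID", spike1 = "Spike I")`.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping standard names
#'   (values = headers found in the file).
#' @return [read_ct_csv()]: a long tibble (`cell_id`, `assay`, `ct`, `flag`).
#' @export
read_ct_csv <- function(path, column_map = NULL) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      names(wide)[names(wide) == column_map[[std]]] <- std
    }
  }
  if (!"cell_id" %in% names(wide)) {
    abort(paste0("no cell_id column in ", path))
  }
  label_cols <- intersect(names(wide), setdiff(.meta_cols, "cell_id"))
  flag_cols <- grep("_flag$", names(wide), value = TRUE)
  assay_cols <- setdiff(names(wide), c("cell_id", label_cols, flag_cols))
  ct_long <- wide |>
    dplyr::select("cell_id", dplyr::all_of(c(label_cols, assay_cols))) |>
    tidyr::pivot_longer(
      dplyr::all_of(assay_cols),
      names_to = "assay", values_to = "ct"
    )
  if (length(flag_cols) > 0) {
    flag_long <- wide |>
      dplyr::select("cell_id", dplyr::all_of(flag_cols)) |>
      tidyr::pivot_longer(
        dplyr::all_of(flag_cols),
        names_to = "assay", values_to = "flag"
      ) |>
      dplyr::mutate(assay = sub("_flag$", "", .data$assay))
    ct_long <- dplyr::left_join(
      ct_long, flag_long, by = c("cell_id", "assay")
    )
    ct_long$flag <- dplyr::coalesce(ct_long$flag, "OK")
  } else {
    ct_long$flag <- "OK"
  }
  dplyr::relocate(ct_long, "cell_id", "assay", "ct", "flag")
}

#' @rdname read_ct_csv
#' @param ct Long raw Ct tibble.
#' @export
write_ct_csv <- function(ct, path) {
  labels <- intersect(names(ct), setdiff(.meta_cols, "cell_id"))
  cts <- ct |>
    dplyr::select("cell_id", dplyr::all_of(labels), "assay", "ct") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "ct")
  flags <- ct |>
    dplyr::select("cell_id", "assay", "flag") |>
    dplyr::mutate(assay = paste0(.data$assay, "_flag")) |>
    tidyr::pivot_wider(names_from = "assay", values_from = "flag")
  readr::write_csv(
    dplyr::left_join(cts, flags, by = "cell_id"), path, progress = FALSE
  )
  invisible(path)
}

#' Write / read a dCt expression matrix as TSV with a JSON label sidecar
#'
#' The TSV holds `cell_id` plus one column per gene; cell-level labels
#' (time point, condition, fraction, donor) go to `<path>.labels.json`.
#'
#' @param expr Wide dCt tibble from [normalize_cts()].
#' @param path TSV path.
#' @return The path (write) or the reassembled wide tibble (read).
#' @export
write_expression_tsv <- function(expr, path) {
  labels <- intersect(names(expr), setdiff(.meta_cols, "cell_id"))
  readr::write_tsv(
    dplyr::select(expr, -dplyr::all_of(labels)), path, progress = FALSE
  )
  side <- dplyr::select(expr, "cell_id", dplyr::all_of(labels))
  jsonlite::write_json(side, paste0(path, ".labels.json"), digits = NA)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".labels.json")
  if (file.exists(sidecar)) {
    side <- tibble::as_tibble(jsonlite::read_json(sidecar, simplifyVector = TRUE))
    if (ncol(side) > 1) {
      expr <- dplyr::left_join(side, expr, by = "cell_id")
    }
  }
  expr
}
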