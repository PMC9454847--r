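CELL_TABLE_COLS <- c("cell_id", "core_id", "patient_id", "x_um", "y_um",
                     TME_MARKERS, "hladr_area_pct")
WINDOW_COLS <- c("window_cx_um", "window_cy_um", "window_r_um")

new_cohort <- function(cells, cores, patients) {
  structure(list(cells = cells, cores = cores, patients = patients),
            class = "tme_cohort")
}

#' @export
print.tme_cohort <- function(x, ...) {
  cat(sprintf("<tme_cohort> %d patients, %d cores, %d cells\n",
              nrow(x$patients), nrow(x$cores), nrow(x$cells)))
  if (!all(is.na(x$patients$stratum))) {
    cat(sprintf("  HLA-DR strata: %d HIGH / %d LOW (threshold %.3f%%)\n",
                sum(x$patients$stratum == "HIGH", na.rm = TRUE),
                sum(x$patients$stratum == "LOW", na.rm = TRUE),
                attr(x, "hladr_threshold") %||% NA_real_))
  }
  if ("phenotype" %in% names(x$cells) && !all(is.na(x$cells$phenotype))) {
    tab <- table(factor(x$cells$phenotype, levels = TME_PHENOTYPES))
    cat("  phenotypes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Circle window for one row of the cores table.
core_window <- function(core_row) {
  circle_window(core_row$window_cx_um, core_row$window_cy_um, core_row$window_r_um)
}

#' Read a per-cell table into a cohort
#'
#' The CSV must have columns `cell_id`, `core_id`, `patient_id`, `x_um`,
#' `y_um`, the eight 0/1 marker columns (CD3, CD8, FoxP3, CD163, PanCK, PDL1,
#' GZMB, Ki67) and `hladr_area_pct` (constant within a core). Optional
#' `window_cx_um`, `window_cy_um`, `window_r_um` give a circular window per
#' core; otherwise a window is inferred with [infer_window()].
#'
#' @param path Path to a UTF-8 CSV file with header.
#' @param nominal_radius Core radius (um) used by [infer_window()] when the
#'   table carries no window geometry.
#' @return A `tme_cohort`: list of data frames `cells` (one row per cell),
#'   `cores` (one row per core, with window geometry and `hladr_area_pct`),
#'   and `patients` (with `hladr_mean_pct`, stratum unset).
#' @export
read_cell_table <- function(path, nominal_radius = 300) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(CELL_TABLE_COLS, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("x_um", "y_um", "hladr_area_pct", TME_MARKERS)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("parse error: non-numeric value in column '", col,
             "' at data row ", bad[1])
      }
      df[[col]] <- conv
    }
  }
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    stop("parse error: missing/non-finite coordinate at data row ",
         which(!is.finite(df$x_um) | !is.finite(df$y_um))[1])
  }
  for (mk in TME_MARKERS) {
    if (!all(df[[mk]] %in% c(0, 1))) {
      stop("validation error: marker column '", mk, "' must be 0/1")
    }
  }

  cells <- data.frame(
    cell_id = as.character(df$cell_id),
    core_id = as.character(df$core_id),
    patient_id = as.character(df$patient_id),
    x = df$x_um, y = df$y_um,
    stringsAsFactors = FALSE
  )
  for (mk in TME_MARKERS) cells[[mk]] <- as.integer(df[[mk]])
  cells$phenotype <- NA_character_

  has_window <- all(WINDOW_COLS %in% names(df))
  core_ids <- unique(cells$core_id)
  cores <- do.call(rbind, lapply(core_ids, function(cid) {
    idx <- cells$core_id == cid
    pid <- unique(cells$patient_id[idx])
    if (length(pid) != 1) {
      stop("validation error: core '", cid, "' maps to multiple patient_ids")
    }
    hla <- unique(df$hladr_area_pct[idx])
    if (length(hla) != 1) {
      stop("validation error: hladr_area_pct not constant within core '", cid, "'")
    }
    if (!is.finite(hla) || hla < 0 || hla > 100) {
      stop("validation error: hladr_area_pct must be in [0, 100] for core '", cid, "'")
    }
    if (has_window) {
      w <- circle_window(unique(df$window_cx_um[idx])[1],
                         unique(df$window_cy_um[idx])[1],
                         unique(df$window_r_um[idx])[1])
      # tolerance covers the 0.01 um write precision of write_cell_table
      if (!all(in_window(w, cells$x[idx], cells$y[idx], tol = 0.02))) {
        stop("validation error: cells outside stated window in core '", cid, "'")
      }
    } else {
      w <- infer_window(cells$x[idx], cells$y[idx], radius = nominal_radius)
    }
    data.frame(core_id = cid, patient_id = pid,
               window_cx_um = w$cx, window_cy_um = w$cy, window_r_um = w$r,
               hladr_area_pct = hla, n_cells = sum(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(cores) <- NULL

  patients <- stats::aggregate(hladr_area_pct ~ patient_id, cores, mean)
  names(patients)[2] <- "hladr_mean_pct"
  patients$stratum <- NA_character_
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  rownames(patients) <- NULL

  new_cohort(cells, cores, patients)
}

#' Write a cohort back to the cell-table CSV format
#'
#' Inverse of [read_cell_table()]; coordinates are written to 0.01 um.
#'
#' @param cohort A `tme_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "tme_cohort"))
  cells <- cohort$cells
  cores <- cohort$cores
  i <- match(cells$core_id, cores$core_id)
  out <- data.frame(
    cell_id = cells$cell_id, core_id = cells$core_id,
    patient_id = cells$patient_id,
    x_um = round(cells$x, 2), y_um = round(cells$y, 2),
    stringsAsFactors = FALSE
  )
  for (mk in TME_MARKERS) out[[mk]] <- cells[[mk]]
  out$hladr_area_pct <- cores$hladr_area_pct[i]
  out$window_cx_um <- cores$window_cx_um[i]
  out$window_cy_um <- cores$window_cy_um[i]
  out$window_r_um <- cores$window_r_um[i]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assign a lineage phenotype from binary marker calls
#'
#' Phenotyping follows lineage precedence CD3 > CD163 > pancytokeratin, so a
#' cell positive for CD3 is a T cell regardless of other lineage markers:
#' CD3+CD8+ is a cytotoxic T cell, CD3+CD8-FoxP3+ a regulatory T cell,
#' CD3+CD8-FoxP3- a helper T cell; CD3-CD163+ an antigen-presenting cell;
#' CD3-CD163-PanCK+ an epithelial (tumor) cell; all-negative cells are OTHER.
#' GZMB, Ki67 and PD-L1 mark activation/checkpoint state and never change the
#' phenotype.
#'
#' @param markers Named vector (or 1-row list) with 0/1 entries for all of
#'   [TME_MARKERS].
#' @return Phenotype string, one of [TME_PHENOTYPES].
#' @examples
#' assign_phenotype(c(CD3 = 1, CD8 = 1, FoxP3 = 0, CD163 = 0, PanCK = 0,
#'                    PDL1 = 0, GZMB = 0, Ki67 = 0))
#' @export
assign_phenotype <- function(markers) {
  if (!all(TME_MARKERS %in% names(markers))) {
    stop("all eight marker flags must be present: ",
         paste(setdiff(TME_MARKERS, names(markers)), collapse = ", "))
  }
  m <- lapply(markers[TME_MARKERS], function(v) as.integer(v) == 1L)
  if (m$CD3) {
    if (m$CD8) "TCELL_CTL" else if (m$FoxP3) "TCELL_TREG" else "TCELL_HELPER"
  } else if (m$CD163) {
    "APC"
  } else if (m$PanCK) {
    "EPITHELIAL"
  } else {
    "OTHER"
  }
}

#' Assign phenotypes to all cells of a cohort or cell data frame
#'
#' Vectorised [assign_phenotype()]. Biologically contradictory lineage
#' co-positivity (e.g. CD3+PanCK+) is resolved by the precedence rule and
#' counted per core in the `"lineage_conflicts"` attribute.
#'
#' @param x A `tme_cohort` or a cell data frame with the marker columns.
#' @return Same type as `x` with the `phenotype` column set.
#' @export
assign_phenotypes <- function(x) {
  UseMethod("assign_phenotypes")
}

#' @export
assign_phenotypes.data.frame <- function(x) {
  miss <- setdiff(TME_MARKERS, names(x))
  if (length(miss)) stop("missing marker column(s): ", paste(miss, collapse = ", "))
  x$phenotype <- ifelse(
    x$CD3 == 1,
    ifelse(x$CD8 == 1, "TCELL_CTL",
           ifelse(x$FoxP3 == 1, "TCELL_TREG", "TCELL_HELPER")),
    ifelse(x$CD163 == 1, "APC",
           ifelse(x$PanCK == 1, "EPITHELIAL", "OTHER"))
  )
  conflict <- (x$CD3 == 1 & (x$CD163 == 1 | x$PanCK == 1)) |
    (x$CD3 == 0 & x$CD163 == 1 & x$PanCK == 1)
  if ("core_id" %in% names(x)) {
    counts <- tapply(conflict, x$core_id, sum)
    attr(x, "lineage_conflicts") <-
      data.frame(core_id = names(counts), n_conflicts = as.integer(counts),
                 stringsAsFactors = FALSE, row.names = NULL)
  } else {
    attr(x, "lineage_conflicts") <- sum(conflict)
  }
  x
}

#' @export
assign_phenotypes.tme_cohort <- function(x) {
  cells <- assign_phenotypes(x$cells)
  attr(x, "lineage_conflicts") <- attr(cells, "lineage_conflicts")
  x$cells <- cells
  x
}

#' Stratify patients around the cohort mean HLA-DR surface area
#'
#' The threshold is the arithmetic mean of the per-patient HLA-DR positive
#' surface-area percentages (each the mean over that patient's cores).
#' Patients at or above the threshold are HIGH, below it LOW. Using the mean
#' rather than a biological cutoff avoids choosing an arbitrary expression
#' threshold; unequal group sizes are expected.
#'
#' @param x A `tme_cohort`, or a patients data frame with `hladr_mean_pct`.
#' @return `x` with `stratum` filled in; the threshold is attached as
#'   attribute `"hladr_threshold"`.
#' @export
stratify_cohort <- function(x) {
  UseMethod("stratify_cohort")
}

#' @export
stratify_cohort.data.frame <- function(x) {
  stopifnot("hladr_mean_pct" %in% names(x))
  if (nrow(x) == 0) stop("empty cohort")
  if (nrow(x) < 2) stop("need at least 2 patients to stratify")
  v <- x$hladr_mean_pct
  stopifnot(all(is.finite(v)))
  thr <- mean(v)
  x$stratum <- ifelse(v >= thr, "HIGH", "LOW")
  if (all(x$stratum == "HIGH")) {
    warning("all patients have identical HLA-DR values; everyone stratified HIGH")
  }
  attr(x, "hladr_threshold") <- thr
  x
}

#' @export
stratify_cohort.tme_cohort <- function(x) {
  pats <- stratify_cohort(x$patients)
  x$patients <- pats
  attr(x, "hladr_threshold") <- attr(pats, "hladr_threshold")
  x
}
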