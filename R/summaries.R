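#' Default metric panels
#'
#' The standard battery of per-core spatial metrics, organised into the five
#' result families used for reporting and per-family Benjamini-Hochberg
#' adjustment: intercellular distances, engagement, immune infiltration,
#' population mixing (G AUC), and activation-stratified metrics. Each row
#' names a metric type, a reference cell group, an optional target group, and
#' optional marker-state filters (e.g. activated CTLs are
#' `TCELL_CTL` with `ref_state = "GZMB+Ki67+"`).
#'
#' Metric types:
#' \describe{
#'   \item{mean_nn}{mean nearest-neighbor distance ref -> target (um)}
#'   \item{engagement_pct}{percent of ref cells with >= 1 target within the
#'     engagement radius}
#'   \item{mean_contacts}{mean simultaneous target contacts among engaged ref
#'     cells}
#'   \item{g_auc}{area under the KM-corrected cross-G curve (um)}
#'   \item{fraction_pct}{ref group as percent of all cells in the core}
#'   \item{state_fraction_pct}{percent of ref-group cells satisfying
#'     `ref_state`}
#'   \item{count_ratio}{ref-group count / target-group count}
#' }
#'
#' @return Data frame with columns `family`, `metric`, `ref`, `ref_state`,
#'   `target`, `target_state`.
#' @export
default_metric_panels <- function() {
  p <- function(family, metric, ref, target = NA, ref_state = NA, target_state = NA) {
    data.frame(family = family, metric = metric, ref = ref,
               ref_state = ref_state, target = target,
               target_state = target_state, stringsAsFactors = FALSE)
  }
  rbind(
    p("distances", "mean_nn", "TCELL", "APC"),
    p("distances", "mean_nn", "TCELL_HELPER", "APC"),
    p("distances", "mean_nn", "TCELL", "EPITHELIAL"),
    p("distances", "mean_nn", "TCELL_CTL", "EPITHELIAL"),
    p("engagement", "engagement_pct", "TCELL", "APC"),
    p("engagement", "engagement_pct", "TCELL_HELPER", "APC"),
    p("engagement", "mean_contacts", "TCELL_HELPER", "APC"),
    p("engagement", "engagement_pct", "TCELL_CTL", "EPITHELIAL"),
    p("engagement", "engagement_pct", "TCELL_CTL", "APC"),
    p("engagement", "engagement_pct", "TCELL_CTL", "EPITHELIAL",
      target_state = "PDL1-"),
    p("engagement", "engagement_pct", "TCELL_CTL", "EPITHELIAL",
      target_state = "PDL1+"),
    p("infiltration", "fraction_pct", "IMMUNE"),
    p("infiltration", "fraction_pct", "TCELL"),
    p("infiltration", "fraction_pct", "TCELL_HELPER"),
    p("infiltration", "fraction_pct", "TCELL_CTL"),
    p("infiltration", "count_ratio", "TCELL_CTL", "TCELL_TREG"),
    p("mixing", "g_auc", "TCELL_HELPER", "APC"),
    p("mixing", "g_auc", "TCELL_CTL", "EPITHELIAL"),
    p("activation", "engagement_pct", "TCELL_CTL", "EPITHELIAL",
      ref_state = "GZMB+Ki67+"),
    p("activation", "state_fraction_pct", "TCELL_HELPER", ref_state = "Ki67+"),
    p("activation", "engagement_pct", "TCELL_HELPER", "APC",
      ref_state = "Ki67+")
  )
}

metric_id <- function(metric, ref, ref_state, target, target_state) {
  rl <- group_label(ref, ref_state)
  tl <- ifelse(is.na(target), "", group_label(target, target_state))
  ifelse(nzchar(tl), paste(metric, rl, tl, sep = "|"), paste(metric, rl, sep = "|"))
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the spatial analysis. Defaults follow the
#' standard protocol: 40 um engagement radius, G AUC evaluated to 60 um on a
#' 1 um grid, per-core metrics averaged (unweighted) over a patient's cores,
#' significance level 0.05 for both the Shapiro-Wilk normality gate and the
#' reported tests.
#'
#' @param engagement_radius Contact radius in um (> 0).
#' @param g_auc_radius Upper limit of the G AUC integral in um (> 0).
#' @param r_step G-curve grid step in um; must divide `g_auc_radius`.
#' @param aggregation `"core_mean"` (equal weight per core) or `"pooled"`
#'   (denominator-weighted; see [aggregate_patients()]).
#' @param alpha Significance level / Shapiro-Wilk gate level.
#' @param seed Optional integer seed for any resampling.
#' @return A list of class `run_config`.
#' @export
run_config <- function(engagement_radius = 40, g_auc_radius = 60, r_step = 1,
                       aggregation = c("core_mean", "pooled"), alpha = 0.05,
                       seed = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(engagement_radius > 0, g_auc_radius > 0, r_step > 0,
            abs(g_auc_radius / r_step - round(g_auc_radius / r_step)) < 1e-9,
            alpha > 0, alpha < 1)
  structure(list(engagement_radius = engagement_radius,
                 g_auc_radius = g_auc_radius, r_step = r_step,
                 aggregation = aggregation, alpha = alpha, seed = seed),
            class = "run_config")
}

summary_row <- function(panel_row, value, n_ref, n_target) {
  data.frame(
    metric = panel_row$metric, family = panel_row$family,
    ref = panel_row$ref, ref_state = panel_row$ref_state,
    target = panel_row$target, target_state = panel_row$target_state,
    value = value, n_ref = n_ref, n_target = n_target,
    metric_id = metric_id(panel_row$metric, panel_row$ref, panel_row$ref_state,
                          panel_row$target, panel_row$target_state),
    stringsAsFactors = FALSE
  )
}

#' Spatial metric summary for one core
#'
#' Computes every panel metric on one core's phenotyped cells. Metrics whose
#' reference or target set is empty are reported with `value = NA` (missing),
#' never dropped, so patient aggregation and cohort comparison see a complete
#' metric grid.
#'
#' @param cells Data frame of this core's cells with `phenotype` assigned.
#' @param window The core's `tme_window`.
#' @param panels Metric definitions, as from [default_metric_panels()].
#' @param config A [run_config()].
#' @return Data frame with one row per panel metric: `metric`, `family`,
#'   `ref`, `ref_state`, `target`, `target_state`, `value`, `n_ref`,
#'   `n_target`, `metric_id`.
#' @export
summarize_core <- function(cells, window, panels = default_metric_panels(),
                           config = run_config()) {
  stopifnot(inherits(window, "tme_window"))
  if (any(is.na(cells$phenotype))) stop("phenotypes must be assigned first")
  n_all <- nrow(cells)
  r_grid <- seq(0, config$g_auc_radius, by = config$r_step)

  rows <- lapply(seq_len(nrow(panels)), function(i) {
    pr <- panels[i, , drop = FALSE]
    ref_cells <- select_cells(cells, pr$ref, pr$ref_state)
    n_ref <- nrow(ref_cells)

    if (pr$metric == "fraction_pct") {
      val <- if (n_all > 0) 100 * n_ref / n_all else NA_real_
      return(summary_row(pr, val, n_ref, n_all))
    }
    if (pr$metric == "state_fraction_pct") {
      base <- select_cells(cells, pr$ref, NA)
      val <- if (nrow(base) > 0) 100 * n_ref / nrow(base) else NA_real_
      return(summary_row(pr, val, n_ref, nrow(base)))
    }

    tgt_cells <- select_cells(cells, pr$target, pr$target_state)
    n_tgt <- nrow(tgt_cells)

    if (pr$metric == "count_ratio") {
      val <- if (n_tgt > 0) n_ref / n_tgt else NA_real_
      return(summary_row(pr, val, n_ref, n_tgt))
    }

    same_set <- identical(pr$ref, pr$target) &&
      identical(pr$ref_state, pr$target_state)
    if (n_ref == 0 || n_tgt == 0 || (same_set && n_tgt < 2)) {
      return(summary_row(pr, NA_real_, n_ref, n_tgt))
    }

    val <- switch(pr$metric,
      mean_nn = mean(nn_distances(ref_cells, tgt_cells, exclude_self = same_set)),
      engagement_pct = engagement_stats(ref_cells, tgt_cells,
                                        radius = config$engagement_radius,
                                        exclude_self = same_set)$engaged_pct,
      mean_contacts = engagement_stats(ref_cells, tgt_cells,
                                       radius = config$engagement_radius,
                                       exclude_self = same_set)$mean_contacts,
      g_auc = {
        crv <- cross_g_km(ref_cells, tgt_cells, window, r_grid,
                          exclude_self = same_set)
        if (is.null(crv)) NA_real_ else curve_auc(crv, config$g_auc_radius)
      },
      stop("unknown metric type: ", pr$metric)
    )
    summary_row(pr, val, n_ref, n_tgt)
  })
  do.call(rbind, rows)
}

#' Per-core summaries for a whole cohort
#'
#' Runs [summarize_core()] on every core. Phenotypes must be assigned.
#'
#' @param cohort A `tme_cohort` with phenotypes assigned.
#' @inheritParams summarize_core
#' @return Data frame of core-level rows with `unit_id` (core), `level =
#'   "CORE"`, and `patient_id` prepended to the [summarize_core()] columns.
#' @export
summarize_cohort <- function(cohort, panels = default_metric_panels(),
                             config = run_config()) {
  stopifnot(inherits(cohort, "tme_cohort"))
  out <- lapply(seq_len(nrow(cohort$cores)), function(i) {
    cr <- cohort$cores[i, ]
    cells <- cohort$cells[cohort$cells$core_id == cr$core_id, , drop = FALSE]
    s <- summarize_core(cells, core_window(cr), panels, config)
    cbind(data.frame(unit_id = cr$core_id, level = "CORE",
                     patient_id = cr$patient_id, stringsAsFactors = FALSE), s)
  })
  do.call(rbind, out)
}

#' Aggregate core-level summaries to patients
#'
#' `method = "core_mean"` (default) gives each valid core equal weight: a
#' patient's value is the unweighted mean over cores where the metric is
#' non-missing (missing only if missing in every core) — triplicate cores
#' carry equal design weight. `method = "pooled"` weights each core by its
#' metric denominator (`n_ref` for distances/engagement, total cells for
#' fractions; count ratios become ratios of summed counts), which equals
#' computing the metric on the patient's pooled cells for all metrics except
#' `g_auc`, where it is a weighted mean of per-core AUCs.
#'
#' @param core_summaries Output of [summarize_cohort()].
#' @param method Aggregation rule.
#' @return Data frame of patient-level rows (`level = "PATIENT"`), one per
#'   patient x metric, with summed `n_ref`/`n_target` and the number of
#'   contributing cores `n_cores`.
#' @export
aggregate_patients <- function(core_summaries,
                               method = c("core_mean", "pooled")) {
  method <- match.arg(method)
  if (nrow(core_summaries) == 0) stop("no core summaries to aggregate")
  key <- paste(core_summaries$patient_id, core_summaries$metric_id, sep = "\r")
  groups <- split(seq_len(nrow(core_summaries)), key)
  rows <- lapply(groups, function(idx) {
    g <- core_summaries[idx, , drop = FALSE]
    ok <- !is.na(g$value)
    val <- if (!any(ok)) {
      NA_real_
    } else if (method == "core_mean") {
      mean(g$value[ok])
    } else {
      if (g$metric[1] == "count_ratio") {
        if (sum(g$n_target[ok]) > 0) sum(g$n_ref[ok]) / sum(g$n_target[ok]) else NA_real_
      } else {
        w <- if (g$metric[1] %in% c("fraction_pct", "state_fraction_pct")) {
          g$n_target[ok]
        } else if (g$metric[1] == "mean_contacts") {
          g$n_ref[ok]  # contact means weighted by ref count
        } else {
          g$n_ref[ok]
        }
        if (sum(w) > 0) stats::weighted.mean(g$value[ok], w) else mean(g$value[ok])
      }
    }
    data.frame(
      unit_id = g$patient_id[1], level = "PATIENT", patient_id = g$patient_id[1],
      metric = g$metric[1], family = g$family[1],
      ref = g$ref[1], ref_state = g$ref_state[1],
      target = g$target[1], target_state = g$target_state[1],
      value = val, n_ref = sum(g$n_ref, na.rm = TRUE),
      n_target = sum(g$n_target, na.rm = TRUE),
      n_cores = sum(ok), metric_id = g$metric_id[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id, out$metric_id), , drop = FALSE]
}
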