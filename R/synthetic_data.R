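# Lineage marker template per phenotype; activation/checkpoint flags (GZMB,
# Ki67, PDL1) start at 0 and are drawn separately from the state rates.
PHENOTYPE_MARKERS <- list(
  TCELL_HELPER = c(CD3 = 1L),
  TCELL_CTL    = c(CD3 = 1L, CD8 = 1L),
  TCELL_TREG   = c(CD3 = 1L, FoxP3 = 1L),
  APC          = c(CD163 = 1L),
  EPITHELIAL   = c(PanCK = 1L),
  OTHER        = c()
)

#' Configuration of the synthetic TMA cohort generator
#'
#' Describes a two-stratum cohort of patients with circular TMA cores.
#' Each phenotype is a Poisson point pattern in the core disc, optionally
#' with a fraction of its cells attracted to a parent phenotype
#' (Thomas-style isotropic Gaussian displacements, resampled into the disc).
#' Activation/checkpoint flags are independent Bernoulli per cell given
#' phenotype and stratum; the per-patient HLA-DR positive surface-area
#' percent is Gaussian per stratum, truncated to `[0, 100]`, and copied to
#' the patient's cores.
#'
#' Defaults emulate a 149-patient cohort in triplicate 0.6 mm cores whose
#' stratum effects run in the directions observed for MHC-II-high tumors:
#' the HIGH stratum has denser immune infiltrate, stronger helper-T-to-APC
#' and CTL-to-epithelium attraction, and higher activation rates.
#' `effect = "null"` gives both strata the identical LOW-stratum parameters
#' (including the HLA-DR distribution), for type-I-error studies.
#'
#' @param n_patients Number of patients.
#' @param cores_per_patient Cores per patient (default 3).
#' @param core_radius Core radius in um (default 300; a 0.6 mm punch).
#' @param stratum_fraction_high Probability a patient is latently HIGH.
#' @param densities Named list `HIGH`/`LOW` of per-phenotype intensities
#'   (um^-2) over [TME_PHENOTYPES].
#' @param attraction Named list `HIGH`/`LOW`; each entry keyed by offspring
#'   phenotype with fields `parent`, `sigma` (um), `fraction` in `[0, 1]`.
#' @param state_rates Named list `HIGH`/`LOW`; each entry keyed by phenotype
#'   giving named Bernoulli rates for activation/checkpoint markers.
#' @param hladr_area Named list `HIGH`/`LOW` of `c(mean, sd)` percent.
#' @param effect `"stratified"` (defaults as given) or `"null"` (LOW
#'   parameters copied to both strata).
#' @param seed Integer seed; fixes the whole cohort.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 149,
                             cores_per_patient = 3,
                             core_radius = 300,
                             stratum_fraction_high = 0.5,
                             densities = NULL,
                             attraction = NULL,
                             state_rates = NULL,
                             hladr_area = NULL,
                             effect = c("stratified", "null"),
                             seed = 1L) {
  effect <- match.arg(effect)
  densities <- densities %||% list(
    HIGH = c(TCELL_HELPER = 5.6e-5, TCELL_CTL = 2.2e-5, TCELL_TREG = 6e-6,
             APC = 1.2e-4, EPITHELIAL = 1.5e-4, OTHER = 8.5e-4),
    LOW  = c(TCELL_HELPER = 2.4e-5, TCELL_CTL = 8e-6, TCELL_TREG = 4e-6,
             APC = 6e-5, EPITHELIAL = 1.5e-4, OTHER = 9.6e-4)
  )
  attraction <- attraction %||% list(
    HIGH = list(
      TCELL_HELPER = list(parent = "APC", sigma = 25, fraction = 0.5),
      TCELL_CTL = list(parent = "EPITHELIAL", sigma = 15, fraction = 0.5)
    ),
    LOW = list(
      TCELL_HELPER = list(parent = "APC", sigma = 25, fraction = 0.1),
      TCELL_CTL = list(parent = "EPITHELIAL", sigma = 15, fraction = 0.1)
    )
  )
  state_rates <- state_rates %||% list(
    HIGH = list(TCELL_CTL = c(GZMB = 0.6, Ki67 = 0.6),
                TCELL_HELPER = c(Ki67 = 0.15),
                EPITHELIAL = c(PDL1 = 0.2)),
    LOW  = list(TCELL_CTL = c(GZMB = 0.45, Ki67 = 0.45),
                TCELL_HELPER = c(Ki67 = 0.08),
                EPITHELIAL = c(PDL1 = 0.2))
  )
  hladr_area <- hladr_area %||% list(HIGH = c(mean = 14, sd = 6),
                                     LOW = c(mean = 4.5, sd = 2.5))
  if (effect == "null") {
    densities$HIGH <- densities$LOW
    attraction$HIGH <- attraction$LOW
    state_rates$HIGH <- state_rates$LOW
    hladr_area$HIGH <- hladr_area$LOW
  }
  cfg <- structure(
    list(n_patients = n_patients, cores_per_patient = cores_per_patient,
         core_radius = core_radius,
         stratum_fraction_high = stratum_fraction_high,
         densities = densities, attraction = attraction,
         state_rates = state_rates, hladr_area = hladr_area,
         effect = effect, seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$cores_per_patient >= 1,
            cfg$core_radius > 0,
            cfg$stratum_fraction_high >= 0, cfg$stratum_fraction_high <= 1,
            is.finite(cfg$seed))
  for (s in c("HIGH", "LOW")) {
    d <- cfg$densities[[s]]
    if (is.null(d) || !all(TME_PHENOTYPES %in% names(d))) {
      stop("densities$", s, " must name every phenotype")
    }
    if (any(d < 0)) stop("densities must be nonnegative")
    for (off in names(cfg$attraction[[s]])) {
      rule <- cfg$attraction[[s]][[off]]
      if (!off %in% TME_PHENOTYPES) stop("unknown offspring phenotype: ", off)
      if (!rule$parent %in% TME_PHENOTYPES) stop("unknown parent phenotype: ", rule$parent)
      stopifnot(rule$sigma > 0, rule$fraction >= 0, rule$fraction <= 1)
    }
    for (ph in names(cfg$state_rates[[s]])) {
      r <- cfg$state_rates[[s]][[ph]]
      if (any(r < 0 | r > 1)) stop("state rates must lie in [0, 1]")
      bad <- setdiff(names(r), TME_MARKERS)
      if (length(bad)) stop("unknown state marker(s): ", paste(bad, collapse = ", "))
    }
    h <- cfg$hladr_area[[s]]
    stopifnot(is.finite(h[["mean"]]), h[["sd"]] >= 0)
  }
  invisible(cfg)
}

# Uniform points in a disc (polar inversion sampling).
runif_disc <- function(n, cx, cy, R) {
  r <- R * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

empty_cells_df <- function() {
  df <- data.frame(x = numeric(0), y = numeric(0),
                   phenotype = character(0), stringsAsFactors = FALSE)
  for (mk in TME_MARKERS) df[[mk]] <- integer(0)
  df
}

make_cells_df <- function(xy, phenotype) {
  n <- nrow(xy)
  df <- data.frame(x = xy[, 1], y = xy[, 2],
                   phenotype = rep(phenotype, n), stringsAsFactors = FALSE)
  for (mk in TME_MARKERS) df[[mk]] <- 0L
  tmpl <- PHENOTYPE_MARKERS[[phenotype]]
  for (mk in names(tmpl)) df[[mk]] <- rep(tmpl[[mk]], n)
  df
}

apply_state_rates <- function(cells, rates) {
  for (ph in names(rates)) {
    idx <- which(cells$phenotype == ph)
    if (!length(idx)) next
    for (mk in names(rates[[ph]])) {
      cells[[mk]][idx] <- stats::rbinom(length(idx), 1L, rates[[ph]][[mk]])
    }
  }
  cells
}

#' Simulate one core under complete spatial randomness
#'
#' Per phenotype, the cell count is Poisson with mean `lambda * pi * R^2`
#' and positions are uniform in the disc — the null spatial model of the
#' G-function analysis.
#'
#' @param densities Named vector of intensities (um^-2) over
#'   [TME_PHENOTYPES] (missing names mean absent phenotypes).
#' @param core_radius Disc radius (um).
#' @param center Disc center, length-2 numeric.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return List with `cells` (data frame: x, y, phenotype, marker flags),
#'   `window` (a [circle_window()]), and `counts` per phenotype.
#' @export
sample_csr_core <- function(densities, core_radius = 300, center = c(0, 0),
                            seed = NULL) {
  stopifnot(all(densities >= 0), core_radius > 0)
  with_seed(seed, {
    phens <- intersect(TME_PHENOTYPES, names(densities))
    area <- pi * core_radius^2
    counts <- stats::setNames(
      vapply(phens, function(ph) stats::rpois(1, densities[[ph]] * area), numeric(1)),
      phens
    )
    parts <- lapply(phens, function(ph) {
      n <- counts[[ph]]
      if (n == 0) return(NULL)
      make_cells_df(runif_disc(n, center[1], center[2], core_radius), ph)
    })
    parts <- Filter(Negate(is.null), parts)
    cells <- if (length(parts)) do.call(rbind, parts) else empty_cells_df()
    list(cells = cells, window = circle_window(center[1], center[2], core_radius),
         counts = counts)
  })
}

# Gaussian displacement from a parent, resampled until inside the disc.
displace_into_disc <- function(px, py, sigma, cx, cy, R) {
  n <- length(px)
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x[todo] <- px[todo] + stats::rnorm(length(todo), 0, sigma)
    y[todo] <- py[todo] + stats::rnorm(length(todo), 0, sigma)
    todo <- todo[(x[todo] - cx)^2 + (y[todo] - cy)^2 > R^2]
  }
  cbind(x = x, y = y)
}

#' Simulate one core with parent-offspring attraction
#'
#' Phenotypes without an attraction rule are placed as in
#' [sample_csr_core()]. For each offspring phenotype with a rule, a binomial
#' `fraction` of its (still Poisson) count is placed as isotropic Gaussian
#' displacements (sd `sigma`) from uniformly chosen parent cells, resampled
#' until inside the disc; the remainder is CSR. Clustering moves cells — the
#' per-phenotype count distribution does not depend on `sigma` or
#' `fraction`. If the parent phenotype drew zero cells, the offspring fall
#' back to CSR (noted in the `fallback_csr` attribute of `cells`).
#'
#' @param config A [synthetic_config()].
#' @param stratum `"HIGH"` or `"LOW"`: which parameter set to use.
#' @inheritParams sample_csr_core
#' @return As [sample_csr_core()], with state flags drawn from the stratum's
#'   rates.
#' @export
sample_clustered_core <- function(config, stratum = c("HIGH", "LOW"),
                                  center = c(0, 0), seed = NULL) {
  stratum <- match.arg(stratum)
  validate_synthetic_config(config)
  dens <- config$densities[[stratum]]
  rules <- config$attraction[[stratum]]
  R <- config$core_radius
  cx <- center[1]; cy <- center[2]
  with_seed(seed, {
    area <- pi * R^2
    # counts first, in canonical order: the count stream is independent of
    # the clustering geometry
    counts <- stats::setNames(
      vapply(TME_PHENOTYPES, function(ph) stats::rpois(1, dens[[ph]] * area),
             numeric(1)),
      TME_PHENOTYPES
    )
    offspring <- intersect(TME_PHENOTYPES, names(rules))
    parents_first <- c(setdiff(TME_PHENOTYPES, offspring), offspring)
    placed <- list()
    fallback <- character(0)
    for (ph in parents_first) {
      n <- counts[[ph]]
      if (n == 0) { placed[[ph]] <- NULL; next }
      if (!ph %in% offspring) {
        placed[[ph]] <- runif_disc(n, cx, cy, R)
        next
      }
      rule <- rules[[ph]]
      par_xy <- placed[[rule$parent]]
      if (is.null(par_xy) || nrow(par_xy) == 0) {
        fallback <- c(fallback, ph)
        placed[[ph]] <- runif_disc(n, cx, cy, R)
        next
      }
      n_clust <- stats::rbinom(1, n, rule$fraction)
      xy_clust <- if (n_clust > 0) {
        pick <- sample.int(nrow(par_xy), n_clust, replace = TRUE)
        displace_into_disc(par_xy[pick, 1], par_xy[pick, 2], rule$sigma, cx, cy, R)
      } else NULL
      xy_csr <- if (n_clust < n) runif_disc(n - n_clust, cx, cy, R) else NULL
      placed[[ph]] <- rbind(xy_clust, xy_csr)
    }
    parts <- lapply(TME_PHENOTYPES, function(ph) {
      if (is.null(placed[[ph]])) NULL else make_cells_df(placed[[ph]], ph)
    })
    parts <- Filter(Negate(is.null), parts)
    cells <- if (length(parts)) do.call(rbind, parts) else empty_cells_df()
    cells <- apply_state_rates(cells, config$state_rates[[stratum]])
    attr(cells, "fallback_csr") <- fallback
    list(cells = cells, window = circle_window(cx, cy, R), counts = counts)
  })
}

# Gaussian truncated to [lo, hi] by rejection.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [synthetic_config()]: each patient gets a
#' latent stratum (HIGH with probability `stratum_fraction_high`), an HLA-DR
#' surface-area percent from the stratum's truncated Gaussian (copied to all
#' of the patient's cores), and `cores_per_patient` cores from
#' [sample_clustered_core()]. The whole cohort is a pure function of the
#' config, including its seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (a `tme_cohort` with phenotypes already set)
#'   and `truth` (data frame `patient_id`, `latent_stratum`,
#'   `hladr_area_pct` for recovery studies).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, {
    all_cells <- list(); all_cores <- list(); truth <- list()
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", p)
      stratum <- if (stats::runif(1) < config$stratum_fraction_high) "HIGH" else "LOW"
      hla <- rtrunc_norm(1, config$hladr_area[[stratum]][["mean"]],
                         config$hladr_area[[stratum]][["sd"]])
      for (k in seq_len(config$cores_per_patient)) {
        cid <- sprintf("%s_C%d", pid, k)
        core <- sample_clustered_core(config, stratum)
        cells <- core$cells
        if (nrow(cells)) {
          cells$cell_id <- sprintf("%s_%05d", cid, seq_len(nrow(cells)))
          cells$core_id <- cid
          cells$patient_id <- pid
          all_cells[[cid]] <- cells
        }
        all_cores[[cid]] <- data.frame(
          core_id = cid, patient_id = pid,
          window_cx_um = core$window$cx, window_cy_um = core$window$cy,
          window_r_um = core$window$r, hladr_area_pct = hla,
          n_cells = nrow(cells), stringsAsFactors = FALSE
        )
      }
      truth[[pid]] <- data.frame(patient_id = pid, latent_stratum = stratum,
                                 hladr_area_pct = hla, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, all_cells)
    rownames(cells) <- NULL
    col_order <- c("cell_id", "core_id", "patient_id", "x", "y",
                   TME_MARKERS, "phenotype")
    cells <- cells[, col_order]
    cores <- do.call(rbind, all_cores); rownames(cores) <- NULL
    patients <- stats::aggregate(hladr_area_pct ~ patient_id, cores, mean)
    names(patients)[2] <- "hladr_mean_pct"
    patients$stratum <- NA_character_
    truth <- do.call(rbind, truth); rownames(truth) <- NULL
    list(cohort = new_cohort(cells, cores, patients), truth = truth)
  })
}
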