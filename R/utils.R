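`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parse a marker-state filter string
#'
#' State filters select cells by activation/checkpoint markers on top of a
#' lineage phenotype, e.g. `"GZMB+Ki67+"` (activated CTL) or `"PDL1-"`
#' (PD-L1-negative). Each token is a marker name followed by `+` (required
#' positive) or `-` (required negative).
#'
#' @param state Filter string, or `NA`/`""` for no filter.
#' @return Named logical vector of marker requirements (empty if no filter).
#' @examples
#' parse_state_filter("GZMB+Ki67+")
#' parse_state_filter("PDL1-")
#' @export
parse_state_filter <- function(state) {
  if (is.null(state) || is.na(state) || !nzchar(state)) {
    return(stats::setNames(logical(0), character(0)))
  }
  m <- gregexpr("([A-Za-z0-9]+)([+-])", state)[[1]]
  toks <- regmatches(state, list(m))[[1]]
  if (length(toks) == 0 || sum(nchar(toks)) != nchar(state)) {
    stop("cannot parse state filter: ", state)
  }
  markers <- sub("[+-]$", "", toks)
  signs <- substring(toks, nchar(toks))
  bad <- setdiff(markers, TME_MARKERS)
  if (length(bad)) stop("unknown marker(s) in state filter: ", paste(bad, collapse = ", "))
  stats::setNames(signs == "+", markers)
}

#' Select cells belonging to a group, optionally filtered by marker state
#'
#' @param cells Data frame of phenotyped cells (column `phenotype` plus the
#'   eight marker columns).
#' @param group One of [TME_GROUPS]: a phenotype, `"TCELL"` (all CD3+
#'   phenotypes), `"IMMUNE"` (T cells and APCs), or `"ALL"`.
#' @param state Optional state filter string (see [parse_state_filter()]).
#' @return The subset of `cells` in the group satisfying the state filter.
#' @export
select_cells <- function(cells, group, state = NA) {
  group <- match.arg(group, TME_GROUPS)
  keep <- switch(group,
    TCELL  = cells$phenotype %in% c("TCELL_HELPER", "TCELL_CTL", "TCELL_TREG"),
    IMMUNE = cells$phenotype %in% c("TCELL_HELPER", "TCELL_CTL", "TCELL_TREG", "APC"),
    ALL    = rep(TRUE, nrow(cells)),
    cells$phenotype == group
  )
  req <- parse_state_filter(state)
  for (mk in names(req)) {
    keep <- keep & ((cells[[mk]] == 1) == req[[mk]])
  }
  cells[keep, , drop = FALSE]
}

# Human-readable group label with state suffix, for tidy metric ids.
group_label <- function(group, state = NA) {
  if (is.null(state) || is.na(state) || !nzchar(state)) group else paste0(group, "[", state, "]")
}
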