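#' Row identities of one abdominal segment
#'
#' The seventeen cell rows of a larval ventral abdominal segment in
#' anteroposterior order, wrapping to row 0 of the next segment. Rows 0-6
#' carry denticles, T1-T3 are tendon (muscle attachment) cells, and rows
#' 7-11, -2 and -1 are undenticulate.
#'
#' @return A data.frame with columns `row_id`, `compartment` ("A" or "P")
#'   and `cell_class` ("denticulate", "undenticulate" or "tendon"), one row
#'   per cell row in anteroposterior order.
#' @export
#' @examples
#' segment_rows()
segment_rows <- function() {
  ids <- c("0", "1", "T1", "2", "3", "4", "T2", "5", "6",
           "7", "8", "9", "T3", "10", "11", "-2", "-1")
  data.frame(
    row_id = ids,
    # rows -2, -1, 0, 1 belong to the P compartment; T1 opens the next
    # segment's A territory
    compartment = ifelse(ids %in% c("0", "1", "-2", "-1"), "P", "A"),
    cell_class = ifelse(ids %in% c("T1", "T2", "T3"), "tendon",
                 ifelse(ids %in% as.character(0:6), "denticulate",
                        "undenticulate")),
    stringsAsFactors = FALSE
  )
}

# default Ds-activity values: scalars with ordinal meaning only, chosen to
# satisfy the wild-type constraints (troughs at T1/T2, unique maximum in
# row 10, high T3/row 11) so that the neighbour-comparison rule reproduces
# the observed denticle/Dachs polarity of every row
.default_activity <- c(
  "0" = 0.40, "1" = 0.30, "T1" = 0.20, "2" = 0.35, "3" = 0.40, "4" = 0.45,
  "T2" = 0.25, "5" = 0.50, "6" = 0.55, "7" = 0.60, "8" = 0.65, "9" = 0.70,
  "T3" = 0.80, "10" = 1.00, "11" = 0.85, "-2" = 0.60, "-1" = 0.50
)

#' Build a Ds-activity landscape for one segment
#'
#' Assigns a Ds activity value to each of the seventeen cell rows of a
#' segment. `"wild_type"` has single-cell troughs at the tendon rows T1 and
#' T2, a profile rising through the A compartment to a unique maximum in
#' row 10, and high values around T3. `"polarity_modified"` emulates
#' overexpression of an active Ds form in T1/T2 (tendon-driver larvae):
#' identical to wild type except that T1 and T2 become peaks. A custom
#' activity map covering all seventeen rows can be supplied instead.
#'
#' Activities are ordinal: the model only ever compares them, so any
#' monotone re-scaling yields identical polarity predictions.
#'
#' @param scenario `"wild_type"`, `"polarity_modified"` or `"custom"`.
#' @param activities Named numeric vector mapping every `row_id` to an
#'   activity; required when `scenario = "custom"`, ignored otherwise.
#' @return A data.frame of class `"segment_landscape"` with columns
#'   `row_id`, `compartment`, `cell_class`, `ds_activity`; the scenario is
#'   kept in `attr(x, "scenario")`.
#' @export
#' @examples
#' wt <- build_landscape("wild_type")
#' pm <- build_landscape("polarity_modified")
#' pm$ds_activity[pm$row_id == "T1"]
build_landscape <- function(scenario = c("wild_type", "polarity_modified", "custom"),
                            activities = NULL) {
  scenario <- match.arg(scenario)
  rows <- segment_rows()
  act <- switch(scenario,
    wild_type = .default_activity,
    polarity_modified = {
      a <- .default_activity
      a[c("T1", "T2")] <- 1.20
      a
    },
    custom = {
      if (is.null(activities)) {
        stop("scenario = \"custom\" requires an `activities` map", call. = FALSE)
      }
      missing <- setdiff(rows$row_id, names(activities))
      if (length(missing) > 0) {
        stop("custom activity map is missing rows: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      activities
    }
  )
  act <- act[rows$row_id]
  if (any(!is.finite(act)) || any(act < 0)) {
    stop("all activities must be finite and non-negative", call. = FALSE)
  }
  rows$ds_activity <- unname(act)
  attr(rows, "scenario") <- scenario
  class(rows) <- c("segment_landscape", "data.frame")
  rows
}

#' @export
print.segment_landscape <- function(x, ...) {
  cat("Segment Ds-activity landscape (", attr(x, "scenario"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Build a cell graph with one typical cell per row
#'
#' Each cell abuts the previous row on its anterior face and the next row on
#' its posterior face; the segment wraps, so row -1 abuts row 0 of the next
#' segment. The result is the adjacency structure used by
#' [predict_polarity()] for typical (two-neighbour) cells.
#'
#' @param landscape A `segment_landscape`.
#' @return A data.frame of class `"cell_graph"` with one row per membrane
#'   region: `cell_id`, `row_id`, `face` ("anterior"/"posterior") and
#'   `neighbour_row`.
#' @export
typical_cell_graph <- function(landscape) {
  ids <- landscape$row_id
  n <- length(ids)
  ant <- ids[c(n, seq_len(n - 1))]
  post <- ids[c(seq_len(n)[-1], 1)]
  g <- data.frame(
    cell_id = paste0("cell_", ids),
    row_id = rep(ids, 2L),
    face = rep(c("anterior", "posterior"), each = n),
    neighbour_row = c(ant, post),
    stringsAsFactors = FALSE
  )
  g <- g[order(match(g$row_id, ids), g$face), ]
  rownames(g) <- NULL
  class(g) <- c("cell_graph", "data.frame")
  g
}

#' Build the graph of a single atypical cell
#'
#' An atypical cell abuts two different neighbours on one of its
#' anteroposterior faces, giving that face two membrane regions which can be
#' polarized independently (multipolarity).
#'
#' @param row_id Row of the atypical cell.
#' @param anterior Character vector of row ids abutting the anterior face
#'   (length 1 or 2).
#' @param posterior Character vector of row ids abutting the posterior face
#'   (length 1 or 2).
#' @param cell_id Identifier for the cell.
#' @return A `"cell_graph"` data.frame with one row per membrane region.
#' @export
#' @examples
#' # wild-type row-4 atypical cell: posterior face abuts both T2 and a
#' # neighbouring row-4 cell
#' atypical_cell_graph("4", anterior = "3", posterior = c("T2", "4"))
atypical_cell_graph <- function(row_id, anterior, posterior,
                                cell_id = paste0("atypical_", row_id)) {
  if (length(anterior) < 1 || length(posterior) < 1) {
    stop("each face must abut at least one neighbour", call. = FALSE)
  }
  g <- data.frame(
    cell_id = cell_id,
    row_id = row_id,
    face = c(rep("anterior", length(anterior)),
             rep("posterior", length(posterior))),
    neighbour_row = c(anterior, posterior),
    stringsAsFactors = FALSE
  )
  class(g) <- c("cell_graph", "data.frame")
  g
}

# activity a neighbour row carries in the comparison (its per-row total;
# activities are ordinal so no face scaling is applied here)
.presented_activity <- function(landscape, row, viewer_side) {
  i <- match(row, landscape$row_id)
  if (anyNA(i)) {
    stop("unknown neighbour row(s): ",
         paste(unique(row[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  landscape$ds_activity[i]
}

#' Predict polarity of every membrane region from a Ds landscape
#'
#' Applies the neighbour-comparison rule: a cell points its denticles
#' towards the neighbour presenting the higher Ds activity. Each membrane
#' region (a face together with one abutting neighbour) is paired with the
#' opposite face and called `"anterior"` if the anterior-side activity
#' exceeds the posterior-side activity, `"posterior"` for the reverse, and
#' `"ambiguous"` on exact ties. Tendon cells give `"no-call"` (their Dachs
#' is cytoplasmic). A cell whose face abuts two neighbours receives one call
#' per region, so multipolarity is representable.
#'
#' After [propagate()], a landscape carries per-face effective activities;
#' polarity is then read from each cell's own face asymmetry (Ds is
#' excluded from the face abutting the higher-activity neighbour, so the
#' depleted face marks the direction the denticles point), which reduces to
#' the plain neighbour comparison at zero rounds.
#'
#' @param landscape A `segment_landscape`, possibly carrying per-face
#'   effective activities from [propagate()].
#' @param graph A `"cell_graph"`; defaults to [typical_cell_graph()].
#' @return A data.frame of polarity calls with columns `cell_id`, `row_id`,
#'   `face`, `neighbour_row`, `direction`, `dachs_side`, `reason`.
#' @export
#' @examples
#' calls <- predict_polarity(build_landscape("wild_type"))
#' subset(calls, face == "posterior")[, c("row_id", "direction", "dachs_side")]
predict_polarity <- function(landscape, graph = typical_cell_graph(landscape)) {
  stopifnot(inherits(landscape, "segment_landscape"))
  cls <- landscape$cell_class[match(graph$row_id, landscape$row_id)]
  if (anyNA(cls)) stop("graph contains cells with unknown rows", call. = FALSE)

  has_faces <- !is.null(landscape$face_anterior)
  out <- lapply(split(seq_len(nrow(graph)), graph$cell_id), function(idx) {
    regions <- graph[idx, ]
    ri <- match(regions$row_id[1], landscape$row_id)
    tendon <- landscape$cell_class[ri] == "tendon"
    ant <- regions[regions$face == "anterior", ]
    post <- regions[regions$face == "posterior", ]
    if (nrow(ant) == 0 || nrow(post) == 0) {
      regions$direction <- "no-call"
      regions$reason <- "missing anterior or posterior neighbour"
      return(regions)
    }
    # activity seen across each face; the cell is posterior to its anterior
    # neighbours and anterior to its posterior neighbours
    a_act <- .presented_activity(landscape, ant$neighbour_row, "posterior")
    p_act <- .presented_activity(landscape, post$neighbour_row, "anterior")
    call_one <- function(a, p) {
      if (a > p) "anterior" else if (p > a) "posterior" else "ambiguous"
    }
    if (tendon) {
      regions$direction <- "no-call"
      regions$reason <- "tendon cell"
      return(regions)
    }
    if (has_faces) {
      # propagated landscape: read the cell's own face asymmetry
      fa <- landscape$face_anterior[ri]
      fp <- landscape$face_posterior[ri]
      regions$direction <- if (fa < fp) "anterior" else
        if (fp < fa) "posterior" else "ambiguous"
      regions$reason <- "from propagated face asymmetry"
      return(regions)
    }
    dirs <- character(nrow(regions))
    for (k in seq_len(nrow(regions))) {
      r <- regions[k, ]
      if (r$face == "anterior") {
        # this region's own anterior activity vs the opposite face; a
        # two-neighbour opposite face is summarized by its region calls, so
        # compare against each single posterior neighbour in turn (mean if 2)
        dirs[k] <- call_one(.presented_activity(landscape, r$neighbour_row, "posterior"),
                            mean(p_act))
      } else {
        dirs[k] <- call_one(mean(a_act),
                            .presented_activity(landscape, r$neighbour_row, "anterior"))
      }
    }
    regions$direction <- dirs
    regions$reason <- ""
    regions
  })
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls <- calls[order(match(calls$row_id, landscape$row_id),
                       calls$cell_id, calls$face, calls$neighbour_row), ]
  rownames(calls) <- NULL
  calls$dachs_side <- predict_dachs_side(
    calls$direction,
    landscape$cell_class[match(calls$row_id, landscape$row_id)]
  )
  class(calls) <- c("polarity_calls", "data.frame")
  calls
}

#' Dachs side implied by a polarity call
#'
#' Dachs accumulates on the membrane facing the neighbour with the least Ds,
#' i.e. on the side opposite to the denticle direction. Tendon cells keep
#' Dachs in the cytoplasm; ambiguous directions give an ambiguous side.
#'
#' @param direction Character vector of directions
#'   (`"anterior"`, `"posterior"`, `"ambiguous"`, `"no-call"`).
#' @param cell_class Character vector, recycled, of cell classes.
#' @return Character vector of Dachs sides (`"anterior"`, `"posterior"`,
#'   `"cytoplasmic"`, `"ambiguous"`).
#' @export
#' @examples
#' predict_dachs_side("anterior", "denticulate")  # "posterior"
predict_dachs_side <- function(direction, cell_class = "denticulate") {
  cell_class <- rep_len(cell_class, length(direction))
  out <- ifelse(cell_class == "tendon", "cytoplasmic",
         ifelse(direction == "anterior", "posterior",
         ifelse(direction == "posterior", "anterior", "ambiguous")))
  out
}

#' Propagate Ds activity between neighbouring faces
#'
#' Formalizes intercellular propagation: extra Ds activity in a neighbour
#' attracts Ft to the facing membrane, which excludes Ds there and lets it
#' accumulate on the cell's far side. Implemented as a conserved, bounded
#' relaxation between each cell's two face pools: per round, a fraction
#' `gain` of the pool re-equilibrates towards an allocation in which the
#' anterior-face share equals the posterior facing activity divided by the
#' sum of both facing activities — i.e. Ds moves away from the face whose
#' neighbour presents more. Each cell's total activity is preserved
#' exactly; `rounds = 0` returns the input unchanged, and repeated rounds
#' converge instead of saturating.
#'
#' @param landscape A `segment_landscape`.
#' @param rounds Number of relaxation rounds (>= 0).
#' @param gain Fraction in (0, 1) of the facing difference moved per round.
#' @return The landscape with per-face columns `face_anterior` and
#'   `face_posterior` holding effective activities (each initially half the
#'   row total).
#' @export
propagate <- function(landscape, rounds = 1, gain = 0.2) {
  stopifnot(inherits(landscape, "segment_landscape"))
  if (rounds < 0) stop("rounds must be >= 0", call. = FALSE)
  if (rounds > 0 && (gain <= 0 || gain >= 1)) {
    stop("gain must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(landscape)
  fa <- landscape$face_anterior
  fp <- landscape$face_posterior
  if (is.null(fa)) {
    fa <- landscape$ds_activity / 2
    fp <- landscape$ds_activity / 2
  }
  prev <- c(n, seq_len(n - 1))
  nxt <- c(seq_len(n)[-1], 1)
  tot <- fa + fp
  r <- 0
  while (r < rounds) {
    facing_ant <- 2 * fp[prev]   # what the anterior neighbour presents
    facing_post <- 2 * fa[nxt]   # what the posterior neighbour presents
    denom <- facing_ant + facing_post
    # Ds excluded from the face with the higher-activity neighbour
    share_ant <- ifelse(denom > 0, facing_post / denom, 0.5)
    fa <- (1 - gain) * fa + gain * tot * share_ant
    fp <- tot - fa
    r <- r + 1
  }
  landscape$face_anterior <- fa
  landscape$face_posterior <- fp
  landscape
}

.dachs_categories <- c("anterior membrane", "posterior membrane",
                       "uniform membrane", "uniform cytoplasm")

#' Summarize Dachs localization scores per cell row
#'
#' Takes per-cell categorical scores of tagged-Dachs localization (scored by
#' eye in the source assay) and tabulates, for every row, the percentage of
#' cells in each category together with the cell count.
#'
#' @param records Data.frame with columns `row_id` and `category`; category
#'   must be one of `"anterior membrane"`, `"posterior membrane"`,
#'   `"uniform membrane"`, `"uniform cytoplasm"`.
#' @return Data.frame with columns `row_id`, `category`, `n_cells`,
#'   `percent` (percentages within a row sum to 100) and `row_total`.
#' @export
summarize_dachs_localization <- function(records) {
  stopifnot(is.data.frame(records), all(c("row_id", "category") %in% names(records)))
  bad <- setdiff(unique(records$category), .dachs_categories)
  if (length(bad) > 0) {
    stop("unknown Dachs localization categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(records$row_id, levels = unique(records$row_id)),
               factor(records$category, levels = .dachs_categories))
  totals <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("row_id", "category", "n_cells")
  out$row_total <- totals[out$row_id]
  out$percent <- 100 * out$n_cells / out$row_total
  out <- out[order(match(out$row_id, unique(records$row_id))), ]
  rownames(out) <- NULL
  out
}

#' Sample noisy Dachs localization records from model predictions
#'
#' Converts the deterministic Dachs-side prediction of a landscape into
#' per-cell categorical records, replacing each record with a random other
#' category at rate `noise`. Ambiguous calls map to `"uniform membrane"`,
#' tendon cells to `"uniform cytoplasm"`.
#'
#' @param landscape A `segment_landscape`.
#' @param n_per_row Cells scored per row.
#' @param noise Probability that a cell is scored in a random non-modal
#'   category.
#' @param seed Integer seed.
#' @return Data.frame with columns `row_id`, `cell_id`, `category`.
#' @export
gen_dachs_records <- function(landscape, n_per_row = 30, noise = 0.1, seed = 1) {
  calls <- predict_polarity(landscape)
  # one modal category per row, from the posterior-face call of its typical cell
  side <- vapply(landscape$row_id, function(r) {
    d <- calls$dachs_side[calls$row_id == r][1]
    d
  }, character(1))
  modal <- ifelse(side == "cytoplasmic", "uniform cytoplasm",
           ifelse(side == "ambiguous", "uniform membrane",
                  paste(side, "membrane")))
  old <- .restore_seed(seed)
  on.exit(old())
  recs <- do.call(rbind, lapply(seq_along(modal), function(i) {
    cat_i <- rep(modal[i], n_per_row)
    flip <- stats::runif(n_per_row) < noise
    if (any(flip)) {
      cat_i[flip] <- vapply(cat_i[flip], function(m) {
        sample(setdiff(.dachs_categories, m), 1)
      }, character(1))
    }
    data.frame(row_id = landscape$row_id[i],
               cell_id = sprintf("%s_%02d", landscape$row_id[i], seq_len(n_per_row)),
               category = cat_i, stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs
}
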