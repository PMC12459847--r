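#' Aggregate ES layers to village means
#'
#' Area-weighted (cell-count) mean of every service layer over the valid
#' cells of each village. Villages with no valid cell are dropped with a
#' warning.
#'
#' @param es An [assemble_es_stack()] result.
#' @param villages A [village_tessellation()] on the same grid.
#' @param mask Optional logical matrix of cells to exclude (e.g. masked
#'   water).
#' @return `data.frame` with `village_id`, `date_tag` and one column per
#'   service (raw means).
#' @export
aggregate_villages <- function(es, villages, mask = NULL) {
  stopifnot(inherits(es, "es_stack"), inherits(villages, "village_tessellation"))
  idr <- villages$id_raster
  stop_if_misaligned(idr, es$layers[[1]], "village ids / ES layers")
  ids <- as.vector(idr$values)
  drop <- rep(FALSE, length(ids))
  if (!is.null(mask)) drop <- drop | as.vector(mask)
  out <- data.frame(village_id = villages$ids)
  for (nm in names(es$layers)) {
    v <- as.vector(es$layers[[nm]]$values)
    ok <- !is.na(v) & !drop
    m <- rowsum(v[ok], ids[ok])
    cnt <- rowsum(rep(1, sum(ok)), ids[ok])
    means <- stats::setNames(m[, 1] / cnt[, 1], rownames(m))
    out[[nm]] <- means[as.character(out$village_id)]
  }
  bad <- !stats::complete.cases(out)
  if (any(bad)) {
    warning(sprintf("%d village(s) with no valid cells dropped", sum(bad)),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$date_tag <- es$date_tag
  out[, c("village_id", "date_tag", names(es$layers))]
}

#' Min-max normalize village ES tables
#'
#' Rescales every indicator to `[0, 1]` as
#' `(x - min) / (max - min)`, pooling the observations of all supplied
#' tables (typically both dates) so that normalized levels are comparable
#' across time; `pool = FALSE` normalizes each table separately. A
#' constant indicator rescales to all zeros with a warning.
#'
#' @param ... One or more village ES tables from [aggregate_villages()].
#' @param pool Pool dates before taking min/max (default `TRUE`).
#' @return A single `data.frame` stacking the input tables with indicators
#'   normalized.
#' @export
normalize_village_es <- function(..., pool = TRUE) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.data.frame(tabs[[1]]) == FALSE) tabs <- tabs[[1]]
  stopifnot(all(vapply(tabs, is.data.frame, TRUE)))
  all_tab <- do.call(rbind, tabs)
  if (nrow(all_tab) < 2) stop("need at least 2 rows to normalize")
  ind <- setdiff(names(all_tab), c("village_id", "date_tag"))
  if (pool) {
    for (nm in ind) all_tab[[nm]] <- minmax(all_tab[[nm]], warn_label = nm)
  } else {
    for (dt in unique(all_tab$date_tag)) {
      sel <- all_tab$date_tag == dt
      for (nm in ind) all_tab[[nm]][sel] <- minmax(all_tab[[nm]][sel],
                                                   warn_label = nm)
    }
  }
  all_tab
}

#' Spearman trade-off/synergy matrix
#'
#' Rank correlation between every pair of service indicators over the
#' villages of a stratum. Positive coefficients indicate synergy, negative
#' trade-off. `mode = "levels"` correlates the values of one date;
#' `mode = "changes"` correlates per-village differences `t1 - t0`.
#' Zero-variance indicators yield `NA` coefficients with a warning.
#'
#' @param table Normalized village table ([normalize_village_es()]) with
#'   both dates when `mode = "changes"`.
#' @param indicators Indicator columns (default: the eight services found).
#' @param mode `"levels"` or `"changes"`.
#' @param date For `mode = "levels"`, which `date_tag` to use.
#' @param villages Optional subset of village ids (a stratum, e.g. one
#'   transition type); minimum 5.
#' @return List with `R` (symmetric correlation matrix, unit diagonal) and
#'   `n` (number of villages used).
#' @export
spearman_matrix <- function(table, indicators = NULL,
                            mode = c("levels", "changes"), date = NULL,
                            villages = NULL) {
  mode <- match.arg(mode)
  if (is.null(indicators)) {
    indicators <- intersect(es_indicator_names(), names(table))
  }
  if (mode == "levels") {
    if (is.null(date)) date <- table$date_tag[1]
    tab <- table[table$date_tag == date, , drop = FALSE]
    X <- as.matrix(tab[, indicators])
    rownames(X) <- tab$village_id
  } else {
    dts <- unique(table$date_tag)
    if (length(dts) != 2) stop("mode='changes' needs exactly two dates")
    a <- table[table$date_tag == dts[1], , drop = FALSE]
    b <- table[table$date_tag == dts[2], , drop = FALSE]
    common <- intersect(a$village_id, b$village_id)
    X <- as.matrix(b[match(common, b$village_id), indicators]) -
      as.matrix(a[match(common, a$village_id), indicators])
    rownames(X) <- common
  }
  if (!is.null(villages)) X <- X[rownames(X) %in% as.character(villages), , drop = FALSE]
  if (nrow(X) < 5) stop("stratum has fewer than 5 villages")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance indicator(s): ",
            paste(indicators[sds == 0], collapse = ", "),
            "; coefficients set to NA", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(X, method = "spearman"))
  R[sds == 0, ] <- NA; R[, sds == 0] <- NA
  diag(R) <- 1
  list(R = R, n = nrow(X))
}

# ---- coupling coordination degree model ------------------------------------

#' CCDM configuration
#'
#' Indicator weights and model variants of the coupling-coordination
#' analysis. The default weights are 0.12 for every service and 0.16 for
#' habitat quality (summing to exactly 1 over the eight indicators, with
#' nitrogen and phosphorus counted separately). Nutrient outputs are
#' disservices and by default are inverted (`1 - normalized value`) into
#' purification scores before entering the model.
#'
#' @param weights Named non-negative weights over the eight indicators.
#' @param coupling_variant `"gm_am_ratio"` (default; the
#'   geometric-to-arithmetic-mean ratio form which attains 1 exactly when
#'   all subsystems are equal and 0 when any is absent) or
#'   `"printed_product"` (the product-over-pairwise-sums form, kept for
#'   fidelity testing).
#' @param d_combiner `"product"` (default, `D = C * T`) or `"sqrt_product"`
#'   (`D = sqrt(C * T)`, the conventional alternative).
#' @param disservices `"invert"` (default) or `"raw"` handling of TN/TP.
#' @return Object of class `ccdm_config`.
#' @export
ccdm_config <- function(weights = NULL,
                        coupling_variant = c("gm_am_ratio", "printed_product"),
                        d_combiner = c("product", "sqrt_product"),
                        disservices = c("invert", "raw")) {
  if (is.null(weights)) {
    weights <- stats::setNames(rep(0.12, 8), es_indicator_names())
    weights[["HQ"]] <- 0.16
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(weights = weights,
                 coupling_variant = match.arg(coupling_variant),
                 d_combiner = match.arg(d_combiner),
                 disservices = match.arg(disservices)),
            class = "ccdm_config")
}

#' Coupling degree of a subsystem vector
#'
#' Measures how evenly the `k` normalized subsystem levels co-occur. The
#' default variant is `C = (prod U)^(1/k) / (mean U)` (geometric over
#' arithmetic mean), which is 1 exactly when all levels are equal and 0
#' when any level is 0. The `printed_product` variant computes
#' `C = [prod(U) / prod_{i<j}(U_i + U_j)]^(1/k)`.
#'
#' @param U Numeric vector of subsystem levels in `[0, 1]`.
#' @param config A [ccdm_config()].
#' @return Coupling degree `C`.
#' @export
coupling_degree <- function(U, config = ccdm_config()) {
  if (any(U < 0 | U > 1)) stop("subsystem levels must lie in [0, 1]")
  k <- length(U)
  if (sum(U) == 0) return(0)
  if (config$coupling_variant == "gm_am_ratio") {
    gm <- prod(U)^(1 / k)
    am <- mean(U)
    return(gm / am)
  }
  pairs <- utils::combn(k, 2)
  denom <- prod(U[pairs[1, ]] + U[pairs[2, ]])
  if (denom == 0) return(0)
  (prod(U) / denom)^(1 / k)
}

#' Composite development level T
#'
#' Weighted sum of the normalized indicators; with the default weights
#' (seven at 0.12, habitat quality at 0.16) `T` lies in `[0, 1]`.
#' Indicators are expected in benefit orientation: disservices (TN, TP)
#' are inverted to purification scores upstream (see [ccdm_villages()])
#' before entering the weighted sum.
#'
#' @param U Named vector of normalized benefit-oriented indicators.
#' @param config A [ccdm_config()].
#' @return Composite level `T` in `[0, 1]`.
#' @export
composite_T <- function(U, config = ccdm_config()) {
  w <- config$weights
  if (is.null(names(U))) {
    if (length(U) != length(w)) stop("indicator/weight length mismatch")
    names(U) <- names(w)
  }
  if (!all(names(w) %in% names(U))) stop("indicator/weight name mismatch")
  sum(w * U[names(w)])
}

#' Coordination degree and level classification
#'
#' `D = C * T` (default) or `sqrt(C * T)`; classified into the six
#' coordination levels by half-open intervals: `[0, 0.2]` F (extreme
#' incoordination), `(0.2, 0.4]` E (moderate incoordination), `(0.4, 0.5]`
#' D (mild incoordination), `(0.5, 0.6]` C (low coordination),
#' `(0.6, 0.8]` B (good coordination), `(0.8, 1.0]` A (high-quality
#' coordination).
#'
#' @param C,T_comp Coupling degree and composite level in `[0, 1]`.
#' @param config A [ccdm_config()].
#' @return Coordination degree `D`.
#' @export
coordination_degree <- function(C, T_comp, config = ccdm_config()) {
  if (any(C < 0 | C > 1) || any(T_comp < 0 | T_comp > 1)) {
    stop("C and T must lie in [0, 1]")
  }
  if (config$d_combiner == "product") C * T_comp else sqrt(C * T_comp)
}

#' Coordination levels
#' @return Character vector of the six level labels, best first.
#' @export
ccdm_levels <- function() c("A", "B", "C", "D", "E", "F")

#' Descriptions of the coordination levels
#' @return Named character vector mapping level to description.
#' @export
ccdm_level_descriptions <- function() {
  c(A = "High-quality coordination", B = "Good coordination",
    C = "Low coordination", D = "Mild incoordination",
    E = "Moderate incoordination", F = "Extreme incoordination")
}

#' @rdname coordination_degree
#' @param D Coordination degree(s) in `[0, 1]`.
#' @export
classify_level <- function(D) {
  if (any(D < 0 | D > 1)) stop("D outside [0, 1]")
  breaks <- c(-1e-12, 0.2, 0.4, 0.5, 0.6, 0.8, 1)
  lab <- c("F", "E", "D", "C", "B", "A")
  lab[findInterval(D, breaks, left.open = TRUE, rightmost.closed = TRUE)]
}

#' Coupling-coordination analysis of a village table
#'
#' Applies the CCDM to every village row of a normalized table: coupling
#' degree `C` over the eight indicator levels (disservices inverted per
#' config), composite `T`, coordination degree `D` and the six-way level.
#'
#' @param table Normalized village table (one date, or pass `date`).
#' @param config A [ccdm_config()].
#' @param date Optional `date_tag` filter.
#' @return `data.frame` with `village_id`, `date_tag`, `C`, `T`, `D`,
#'   `level`.
#' @export
ccdm_villages <- function(table, config = ccdm_config(), date = NULL) {
  if (!is.null(date)) table <- table[table$date_tag == date, , drop = FALSE]
  ind <- names(config$weights)
  if (!all(ind %in% names(table))) stop("table lacks indicator columns")
  X <- as.matrix(table[, ind])
  Xeff <- X
  if (config$disservices == "invert") {
    for (nm in intersect(c("TN", "TP"), ind)) {
      Xeff[, nm] <- 1 - Xeff[, nm]
    }
  }
  C <- apply(Xeff, 1, coupling_degree, config = config)
  T_comp <- apply(Xeff, 1, composite_T, config = config)
  D <- coordination_degree(C, T_comp, config)
  data.frame(village_id = table$village_id, date_tag = table$date_tag,
             C = C, T = T_comp, D = D, level = classify_level(D))
}

#' Coordination-level transfer analysis
#'
#' Cross-tabulates village coordination levels between two dates into a
#' 6 x 6 row-stochastic transfer matrix, and summarises mean `D` per
#' stratum (e.g. transition type) and date.
#'
#' @param res_t0,res_t1 [ccdm_villages()] results with matching ids.
#' @param strata Optional named vector mapping village id to a stratum
#'   label.
#' @return List with `matrix` (row-stochastic; empty from-levels give zero
#'   rows), `counts` and, when strata are given, `mean_D` per stratum and
#'   date.
#' @export
level_transfer <- function(res_t0, res_t1, strata = NULL) {
  common <- intersect(res_t0$village_id, res_t1$village_id)
  if (length(common) == 0) stop("no matching village ids")
  if (length(common) != nrow(res_t0) || length(common) != nrow(res_t1)) {
    stop("village id mismatch between dates")
  }
  l0 <- factor(res_t0$level[match(common, res_t0$village_id)],
               levels = ccdm_levels())
  l1 <- factor(res_t1$level[match(common, res_t1$village_id)],
               levels = ccdm_levels())
  cnt <- table(from = l0, to = l1)
  cnt <- matrix(as.numeric(cnt), 6, 6,
                dimnames = list(from = ccdm_levels(), to = ccdm_levels()))
  rs <- rowSums(cnt)
  out <- list(matrix = cnt / ifelse(rs == 0, 1, rs), counts = cnt)
  if (!is.null(strata)) {
    st <- strata[as.character(common)]
    lv <- sort(unique(st[!is.na(st)]))
    d0 <- res_t0$D[match(common, res_t0$village_id)]
    d1 <- res_t1$D[match(common, res_t1$village_id)]
    out$mean_D <- data.frame(
      stratum = rep(lv, 2),
      date_tag = rep(c(res_t0$date_tag[1], res_t1$date_tag[1]),
                     each = length(lv)),
      mean_D = c(tapply(d0, st, mean)[lv], tapply(d1, st, mean)[lv]))
  }
  out
}

#' Standard deviational ellipse
#'
#' Weighted second-moment summary of a point cloud: weighted mean centre,
#' semi-axes equal to the standard distances along the principal directions
#' of the weighted coordinate covariance, and the major-axis orientation in
#' degrees counter-clockwise from the +x axis, in `[0, 180)`.
#'
#' @param x,y Point coordinates.
#' @param weights Non-negative weights (default 1).
#' @return List with `center`, `semi_major`, `semi_minor`,
#'   `orientation_deg` and the weighted covariance `cov`.
#' @export
deviational_ellipse <- function(x, y, weights = NULL) {
  n <- length(x)
  if (n < 2 || length(y) != n) stop("need at least 2 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0) stop("invalid weights")
  w <- weights / sum(weights)
  cx <- sum(w * x); cy <- sum(w * y)
  dx <- x - cx; dy <- y - cy
  cov <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                  sum(w * dx * dy), sum(w * dy * dy)), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  ax <- sqrt(pmax(eg$values, 0))
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ang %% 180
  list(center = c(x = cx, y = cy), semi_major = ax[1], semi_minor = ax[2],
       orientation_deg = ang, cov = cov)
}
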