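#' SOM configuration
#'
#' Self-organizing-map hyper-parameters. The default map size follows the
#' ~5*sqrt(n) node heuristic (chosen at fit time when `grid_dim = NULL`),
#' with 500 training epochs and learning rate and neighbourhood radius
#' decaying linearly to a small floor.
#'
#' @param grid_dim Integer `c(rows, cols)` of the node lattice, or `NULL`
#'   for the heuristic.
#' @param epochs Training epochs (full passes over the data).
#' @param alpha0 Initial learning rate.
#' @param radius0 Initial neighbourhood radius in lattice units (`NULL`:
#'   half the larger lattice dimension).
#' @param k_range Candidate cluster counts for Davies-Bouldin selection
#'   (default 2:15).
#' @param seed Seed for codebook initialisation and row shuffling.
#' @return Object of class `som_config`.
#' @export
som_config <- function(grid_dim = NULL, epochs = 500L, alpha0 = 0.5,
                       radius0 = NULL, k_range = 2:15, seed = 1L) {
  stopifnot(epochs >= 1, alpha0 > 0, all(k_range >= 2))
  structure(list(grid_dim = grid_dim, epochs = as.integer(epochs),
                 alpha0 = alpha0, radius0 = radius0,
                 k_range = as.integer(k_range), seed = as.integer(seed)),
            class = "som_config")
}

#' Fit a self-organizing map to village ES vectors
#'
#' Online competitive learning on a rectangular node lattice with a
#' Gaussian neighbourhood: each presented row moves its best-matching node
#' and that node's lattice neighbours toward it, with learning rate and
#' radius decaying linearly over epochs. Deterministic under the config
#' seed.
#'
#' @param X Numeric matrix of rows to map (villages x indicators), or a
#'   data.frame from which the [bundle_indicator_names()] columns are
#'   taken.
#' @param config A [som_config()].
#' @return Object of class `som_fit`: `codebook` (nodes x indicators),
#'   `grid` (node lattice coordinates), `mapping` (best-matching node per
#'   row) and `qe_trace` (mean quantization error per epoch).
#' @export
fit_som <- function(X, config = som_config()) {
  if (is.data.frame(X)) {
    cols <- intersect(bundle_indicator_names(), names(X))
    if (length(cols) == 0) cols <- intersect(es_indicator_names(), names(X))
    X <- as.matrix(X[, cols])
  }
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (any(!is.finite(X))) stop("non-finite rows")
  n <- nrow(X); p <- ncol(X)
  gd <- config$grid_dim
  if (is.null(gd)) {
    m <- max(4, ceiling(5 * sqrt(n)))
    a <- ceiling(sqrt(m))
    gd <- c(a, ceiling(m / a))
  }
  n_nodes <- gd[1] * gd[2]
  grid <- cbind(row = rep(seq_len(gd[1]), times = gd[2]),
                col = rep(seq_len(gd[2]), each = gd[1]))
  radius0 <- if (is.null(config$radius0)) max(gd) / 2 else config$radius0
  # squared lattice distances between all node pairs (for neighbourhoods)
  gd2 <- outer(grid[, 1], grid[, 1], "-")^2 + outer(grid[, 2], grid[, 2], "-")^2

  with_seed(derive_seed(config$seed, "som"), {
    codebook <- X[sample.int(n, n_nodes, replace = n_nodes > n), , drop = FALSE] +
      matrix(stats::rnorm(n_nodes * p, sd = 0.02), n_nodes, p)
    qe_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      frac <- (ep - 1) / max(1, config$epochs - 1)
      alpha <- config$alpha0 * (1 - frac) + 0.01 * frac
      radius <- radius0 * (1 - frac) + 0.5 * frac
      ord <- sample.int(n)
      qe <- 0
      for (r in ord) {
        diffs <- sweep(codebook, 2, X[r, ])
        d2 <- rowSums(diffs^2)
        bmu <- which.min(d2)
        qe <- qe + sqrt(d2[bmu])
        h <- alpha * exp(-gd2[bmu, ] / (2 * radius^2))
        codebook <- codebook - h * diffs
      }
      qe_trace[ep] <- qe / n
    }
    d_all <- outer(rowSums(X^2), rep(1, n_nodes)) -
      2 * X %*% t(codebook) + outer(rep(1, n), rowSums(codebook^2))
    mapping <- max.col(-d_all, ties.method = "first")
    structure(list(codebook = codebook, grid = grid, grid_dim = gd,
                   mapping = mapping, qe_trace = qe_trace,
                   data = X, config = config),
              class = "som_fit")
  })
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %d x %d lattice, %d rows, final QE %.4f\n",
              x$grid_dim[1], x$grid_dim[2], nrow(x$data),
              utils::tail(x$qe_trace, 1)))
  invisible(x)
}

#' Davies-Bouldin index
#'
#' Cluster-validity score: the mean over clusters of the worst-case ratio
#' `(sigma_i + sigma_j) / d(c_i, c_j)`, where `sigma` is the mean distance
#' of cluster members to their centroid and `d` the centroid distance.
#' Lower is better.
#'
#' @param X Data matrix.
#' @param assignment Integer/factor cluster assignment per row.
#' @return The DB score (`Inf`, with a warning, if two centroids
#'   coincide).
#' @export
davies_bouldin <- function(X, assignment) {
  X <- as.matrix(X)
  cl <- as.integer(factor(assignment))
  k <- max(cl)
  if (k < 2) stop("Davies-Bouldin needs at least 2 clusters")
  if (any(tabulate(cl, k) == 0)) stop("empty cluster")
  cent <- rowsum(X, cl) / tabulate(cl, k)
  sig <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums(sweep(X[cl == i, , drop = FALSE], 2, cent[i, ])^2)))
  }, 0)
  ratios <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dc <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      ratios[i, j] <- ratios[j, i] <-
        if (dc == 0) Inf else (sig[i] + sig[j]) / dc
    }
  }
  if (any(is.infinite(ratios))) {
    warning("coincident cluster centroids: DB index infinite", call. = FALSE)
  }
  mean(apply(ratios, 1, max))
}

#' Bundle partition by SOM prototype clustering with DB selection
#'
#' Fits a SOM, agglomerates the node codebook vectors hierarchically
#' (Ward linkage), and for each candidate cluster count `k` maps villages
#' to the node groups; the Davies-Bouldin index over the village
#' assignments selects `k` (argmin; ties toward the smaller `k`, i.e.
#' parsimony). Candidates whose node grouping leaves fewer than `k`
#' non-empty village clusters are degenerate and skipped.
#'
#' @param X Village matrix or data.frame (see [fit_som()]).
#' @param config A [som_config()].
#' @return Object of class `bundle_partition`: `assignment` (cluster id in
#'   `1..k` per row), `k`, `db_trace` (named DB score per candidate),
#'   `profiles` (cluster mean indicator matrix), and the underlying
#'   `som`.
#' @export
select_k <- function(X, config = som_config()) {
  som <- fit_som(X, config)
  Xm <- som$data
  n <- nrow(Xm)
  if (stats::sd(as.vector(Xm)) == 0 ||
      all(apply(Xm, 2, function(cc) stats::sd(cc) == 0))) {
    stop("degenerate data: all rows identical")
  }
  # agglomerate only the occupied prototypes (nodes that are the best match
  # of at least one village), so every prototype group maps to a non-empty
  # village cluster
  occupied <- sort(unique(som$mapping))
  kr <- config$k_range[config$k_range <= min(n - 1, length(occupied))]
  if (length(kr) == 0) stop("no valid candidate cluster counts")
  hc <- stats::hclust(stats::dist(som$codebook[occupied, , drop = FALSE]),
                      method = "ward.D2")
  db <- stats::setNames(rep(NA_real_, length(kr)), kr)
  assigns <- list()
  for (i in seq_along(kr)) {
    k <- kr[i]
    node_grp <- stats::cutree(hc, k = k)
    a <- node_grp[match(som$mapping, occupied)]
    val <- suppressWarnings(davies_bouldin(Xm, a))
    if (!is.finite(val)) next
    db[i] <- val
    assigns[[as.character(k)]] <- as.integer(factor(a))
  }
  if (all(is.na(db))) stop("all candidate cluster counts degenerate")
  best <- kr[which.min(db)]  # which.min takes the first (smallest k) on ties
  assignment <- assigns[[as.character(best)]]
  prof <- rowsum(Xm, assignment) / tabulate(assignment)
  structure(list(assignment = assignment, k = as.integer(best),
                 db_trace = db, profiles = prof, som = som),
            class = "bundle_partition")
}

#' @export
print.bundle_partition <- function(x, ...) {
  cat(sprintf("<bundle_partition> k = %d (DB %.4f), %d rows\n",
              x$k, x$db_trace[[as.character(x$k)]], length(x$assignment)))
  invisible(x)
}

#' Convert a normalized village table to bundle (purification) orientation
#'
#' The bundle analysis and labeling rules read every indicator as
#' higher-is-better; the nutrient-export disservices are therefore
#' inverted (`TNp = 1 - TN`, `TPp = 1 - TP`) and renamed.
#'
#' @param table Normalized village table with `TN`, `TP` columns.
#' @return The table with `TN`/`TP` replaced by `TNp`/`TPp`.
#' @export
to_bundle_space <- function(table) {
  if (!all(c("TN", "TP") %in% names(table))) {
    stop("table lacks TN/TP columns")
  }
  table$TN <- 1 - table$TN
  table$TP <- 1 - table$TP
  names(table)[match(c("TN", "TP"), names(table))] <- c("TNp", "TPp")
  table
}

#' Bundle class vocabulary
#' @return Character vector of the seven bundle names.
#' @export
bundle_names <- function() {
  c("key_tradeoffs", "mild_tradeoffs", "key_synergistic", "cs_hq_la",
    "hq_la", "water_purification", "fp")
}

#' Name bundles from cluster mean profiles
#'
#' Rule cascade on normalized cluster means in purification orientation
#' (`TNp`/`TPp` = 1 - normalized nutrient export), with configurable
#' thresholds (`high` >= 0.6, `low` <= 0.3 by default):
#' \enumerate{
#'   \item water yield and aesthetics high, food production low and the
#'     remaining services depleted: key trade-offs;
#'   \item water yield and aesthetics high, food production low, others
#'     moderate: mild trade-offs;
#'   \item every service at least mid-level: key synergistic;
#'   \item carbon, habitat and aesthetics all high and jointly dominant:
#'     CS-HQ-LA;
#'   \item habitat and aesthetics high with strong soil conservation:
#'     HQ-LA;
#'   \item purification scores high and dominant: water purification;
#'   \item food production high and maximal: FP.
#' }
#' A profile matching no rule falls back to the nearest archetype of the
#' default [bundle_archetype_library()], recorded in the rule trace.
#'
#' @param partition A [select_k()] result, or a plain cluster-mean matrix
#'   with [bundle_indicator_names()] columns.
#' @param high,low Dominance / depletion thresholds.
#' @return `data.frame` with `cluster`, `bundle`, `rule` (trace).
#' @export
label_bundles <- function(partition, high = 0.6, low = 0.3) {
  prof <- if (inherits(partition, "bundle_partition")) partition$profiles
          else as.matrix(partition)
  bn <- bundle_indicator_names()
  if (!all(bn %in% colnames(prof))) stop("profiles must carry the 8 bundle indicators")
  prof <- prof[, bn, drop = FALSE]
  lib <- bundle_archetype_library()
  out <- lapply(seq_len(nrow(prof)), function(i) {
    p <- prof[i, ]
    others <- p[c("CS", "SC", "TNp", "TPp", "HQ")]
    top3 <- names(sort(p, decreasing = TRUE))[1:3]
    if (p[["WY"]] >= high && p[["LA"]] >= high && p[["FP"]] <= low &&
        all(others <= 0.45)) {
      c("key_tradeoffs", "WY&LA high, FP low, others depleted")
    } else if (p[["WY"]] >= high && p[["LA"]] >= high && p[["FP"]] <= low) {
      c("mild_tradeoffs", "WY&LA high, FP low, others moderate")
    } else if (all(p >= 0.5)) {
      c("key_synergistic", "all services >= 0.5")
    } else if (all(p[c("CS", "HQ", "LA")] >= high) &&
               all(c("CS", "HQ", "LA") %in% top3)) {
      c("cs_hq_la", "CS, HQ, LA high and jointly dominant")
    } else if (p[["HQ"]] >= high && p[["LA"]] >= high && p[["SC"]] >= 0.5) {
      c("hq_la", "HQ & LA high with strong SC")
    } else if (all(p[c("TNp", "TPp")] >= high) &&
               any(c("TNp", "TPp") %in% top3)) {
      c("water_purification", "purification scores high and dominant")
    } else if (p[["FP"]] >= high && p[["FP"]] == max(p)) {
      c("fp", "FP high and maximal")
    } else {
      d <- sqrt(rowSums(sweep(lib$archetypes, 2, p)^2))
      c(rownames(lib$archetypes)[which.min(d)],
        "no rule matched: nearest archetype fallback")
    }
  })
  data.frame(cluster = seq_len(nrow(prof)),
             bundle = vapply(out, `[`, "", 1),
             rule = vapply(out, `[`, "", 2))
}

#' Bundle transfer analysis between dates
#'
#' Cross-tabulates village bundle labels between two dates into a 7 x 7
#' row-stochastic transfer matrix, overall and per transition-type
#' stratum, plus bundle composition shares per stratum and date.
#'
#' @param labels_t0,labels_t1 Named character vectors (village id ->
#'   bundle name) for the two dates.
#' @param strata Optional named vector mapping village id to a transition
#'   type.
#' @return List with `matrix`, `counts`, optional `by_stratum` (list of
#'   row-stochastic matrices) and `composition` shares.
#' @export
bundle_transfer <- function(labels_t0, labels_t1, strata = NULL) {
  common <- intersect(names(labels_t0), names(labels_t1))
  if (length(common) == 0) stop("no matching village ids")
  if (length(common) != length(labels_t0) || length(common) != length(labels_t1)) {
    stop("village id mismatch between dates")
  }
  bn <- bundle_names()
  f0 <- factor(labels_t0[common], levels = bn)
  f1 <- factor(labels_t1[common], levels = bn)
  rowstoch <- function(cnt) {
    rs <- rowSums(cnt)
    cnt / ifelse(rs == 0, 1, rs)
  }
  cnt <- matrix(as.numeric(table(f0, f1)), length(bn), length(bn),
                dimnames = list(from = bn, to = bn))
  out <- list(matrix = rowstoch(cnt), counts = cnt)
  if (!is.null(strata)) {
    st <- strata[common]
    out$by_stratum <- lapply(split(seq_along(common), st), function(ix) {
      rowstoch(matrix(as.numeric(table(f0[ix], f1[ix])), length(bn),
                      length(bn), dimnames = list(from = bn, to = bn)))
    })
    comp <- function(f, tag) {
      do.call(rbind, lapply(split(seq_along(common), st), function(ix) {
        prop.table(table(f[ix]))
      }))
    }
    out$composition <- list(t0 = comp(f0), t1 = comp(f1))
  }
  out
}
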