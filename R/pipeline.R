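#' Pipeline configuration
#'
#' Collects every stage's parameters with package defaults: the synthetic
#' scenario (or external input paths), POI kernel config, classifier spec,
#' CCDM and SOM configs, the water-masking threshold and the master seed.
#'
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @param scenario List of [landscape_scenario()] arguments (the `seed`
#'   entry defaults to the master seed).
#' @param n_labeled_points Labeled sample points per date (default 1000).
#' @param water_min_area_km2 Water-body masking threshold (km2).
#' @param poi Arguments for [poi_function_config()].
#' @param classifier Arguments for [classifier_spec()].
#' @param ccdm Arguments for [ccdm_config()].
#' @param som Arguments for [som_config()].
#' @param rural_to_urban Typology flag for [type_transitions()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "esfringe_out", scenario = list(),
                            n_labeled_points = 1000,
                            water_min_area_km2 = 1, poi = list(),
                            classifier = list(), ccdm = list(), som = list(),
                            rural_to_urban = "urban_expansion", seed = 1) {
  structure(list(out_dir = out_dir, scenario = scenario,
                 n_labeled_points = n_labeled_points,
                 water_min_area_km2 = water_min_area_km2, poi = poi,
                 classifier = classifier, ccdm = ccdm, som = som,
                 rural_to_urban = rural_to_urban, seed = seed),
            class = "pipeline_config")
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Chains every stage: landscape generation, water masking, feature
#' assembly, classifier training and zone classification for both dates,
#' transition typology and transfer matrix, the eight ES layers, village
#' aggregation and normalization, Spearman change correlations,
#' coupling-coordination analysis with level transfer, deviational
#' ellipses of incoordination villages, and SOM bundle detection with
#' Davies-Bouldin selection and bundle transfer. Every output is written
#' as CSV under `config$out_dir` and hashed into a run manifest
#' (`manifest.json`); reruns with the same config produce identical
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; side effect: stage CSVs and
#'   `manifest.json` in `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_count <- 0L
  withCallingHandlers({
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
      })
    }

    sc_args <- config$scenario
    if (is.null(sc_args$seed)) sc_args$seed <- derive_seed(config$seed, "scenario")
    scen <- stage("synth", do.call(landscape_scenario, sc_args))
    pair <- stage("synth", generate_landscape_pair(scen))
    villages <- stage("synth", generate_villages(scen))

    poi_cfg <- do.call(poi_function_config, config$poi)
    masks <- lapply(pair[c("t0", "t1")], mask_water,
                    min_area_km2 = config$water_min_area_km2)
    feats <- stage("features", list(
      t0 = assemble_features(pair$t0, masks$t0, poi_cfg),
      t1 = assemble_features(pair$t1, masks$t1, poi_cfg)))

    files <- character()
    zones <- list(); models <- list(); acc <- list()
    for (dt in c("t0", "t1")) {
      truth <- pair[[paste0("truth_", dt)]]
      pts <- stage("train", generate_labeled_points(
        feats[[dt]], truth, config$n_labeled_points,
        derive_seed(config$seed, paste0("points_", dt))))
      cl_args <- config$classifier
      cl_args$seed <- derive_seed(config$seed, paste0("mlp_", dt))
      model <- stage("train", train_classifier(pts, do.call(classifier_spec, cl_args)))
      zones[[dt]] <- stage("classify", classify_zones(feats[[dt]], model, dt))
      models[[dt]] <- model
      acc[[dt]] <- data.frame(date_tag = dt, accuracy = model$accuracy,
                              recall_rural = model$recall[["rural"]],
                              recall_fringe = model$recall[["fringe"]],
                              recall_urban = model$recall[["urban"]])
      files <- c(files, write_stage_csv(pts, config$out_dir,
                                        paste0("labeled_points_", dt)))
    }
    files <- c(files, write_stage_csv(do.call(rbind, acc), config$out_dir,
                                      "classifier_accuracy"))

    trans <- stage("transitions", type_transitions(zones$t0, zones$t1,
                                                   config$rural_to_urban))
    tm <- stage("transitions", transfer_matrix(zones$t0, zones$t1))
    files <- c(files, write_stage_csv(
      data.frame(from = rep(rownames(tm$shares), 3),
                 to = rep(colnames(tm$shares), each = 3),
                 share = as.vector(tm$shares),
                 area_km2 = as.vector(tm$areas_km2)),
      config$out_dir, "transfer_matrix"))

    es <- stage("es", list(t0 = assemble_es_stack(pair$t0),
                           t1 = assemble_es_stack(pair$t1)))

    raw <- stage("aggregate", list(
      t0 = aggregate_villages(es$t0, villages, masks$t0),
      t1 = aggregate_villages(es$t1, villages, masks$t1)))
    norm <- stage("aggregate", normalize_village_es(raw$t0, raw$t1))
    # keep only villages observed at both dates (a village fully covered by
    # masked water at one date would otherwise break the paired analyses)
    both <- intersect(norm$village_id[norm$date_tag == "t0"],
                      norm$village_id[norm$date_tag == "t1"])
    norm <- norm[norm$village_id %in% both, , drop = FALSE]
    files <- c(files,
               write_stage_csv(rbind(raw$t0, raw$t1), config$out_dir,
                               "villages_es_raw"),
               write_stage_csv(norm, config$out_dir, "villages_es_norm"))

    # village strata: majority transition type
    vt <- stage("interact", village_majority(villages, trans))
    tc <- transition_codes()
    strata <- stats::setNames(names(tc)[match(vt, tc)], names(vt))
    sp <- stage("interact", spearman_matrix(norm, mode = "changes"))
    files <- c(files, write_stage_csv(
      data.frame(es_x = rep(rownames(sp$R), ncol(sp$R)),
                 es_y = rep(colnames(sp$R), each = nrow(sp$R)),
                 rho = as.vector(sp$R), n = sp$n),
      config$out_dir, "spearman_changes"))

    ccdm_cfg <- do.call(ccdm_config, config$ccdm)
    cc <- stage("ccdm", list(t0 = ccdm_villages(norm, ccdm_cfg, "t0"),
                             t1 = ccdm_villages(norm, ccdm_cfg, "t1")))
    common <- intersect(cc$t0$village_id, cc$t1$village_id)
    lt <- stage("ccdm", level_transfer(
      cc$t0[cc$t0$village_id %in% common, ],
      cc$t1[cc$t1$village_id %in% common, ], strata))
    files <- c(files,
               write_stage_csv(rbind(cc$t0, cc$t1), config$out_dir, "ccdm"),
               write_stage_csv(
                 data.frame(from = rep(rownames(lt$matrix), 6),
                            to = rep(colnames(lt$matrix), each = 6),
                            share = as.vector(lt$matrix),
                            count = as.vector(lt$counts)),
                 config$out_dir, "level_transfer"),
               write_stage_csv(lt$mean_D, config$out_dir, "mean_D_by_type"))

    # deviational ellipse of incoordination villages (D <= 0.5) per date
    sites <- villages$sites
    ell <- stage("ellipse", lapply(cc, function(r) {
      sel <- match(r$village_id[r$D <= 0.5], villages$ids)
      if (length(sel) >= 3) {
        deviational_ellipse(sites[sel, 1], sites[sel, 2])
      } else NULL
    }))
    ell_df <- do.call(rbind, lapply(names(ell), function(dt) {
      e <- ell[[dt]]
      if (is.null(e)) return(NULL)
      data.frame(date_tag = dt, center_x = e$center[["x"]],
                 center_y = e$center[["y"]], semi_major = e$semi_major,
                 semi_minor = e$semi_minor,
                 orientation_deg = e$orientation_deg)
    }))
    if (!is.null(ell_df)) {
      files <- c(files, write_stage_csv(ell_df, config$out_dir, "ellipse"))
    }

    # bundles: joint SOM over both dates in purification orientation
    bspace <- to_bundle_space(norm)
    som_args <- config$som
    if (is.null(som_args$seed)) som_args$seed <- derive_seed(config$seed, "som")
    part <- stage("bundles", select_k(bspace, do.call(som_config, som_args)))
    lab <- stage("bundles", label_bundles(part))
    vb <- lab$bundle[part$assignment]
    labels <- split(stats::setNames(vb, bspace$village_id), bspace$date_tag)
    bt <- stage("bundles", bundle_transfer(labels$t0, labels$t1, strata))
    files <- c(files,
               write_stage_csv(cbind(bspace[, c("village_id", "date_tag")],
                                     cluster = part$assignment, bundle = vb),
                               config$out_dir, "bundles"),
               write_stage_csv(data.frame(k = as.integer(names(part$db_trace)),
                                          db = unname(part$db_trace)),
                               config$out_dir, "db_trace"),
               write_stage_csv(lab, config$out_dir, "bundle_labels"),
               write_stage_csv(
                 data.frame(from = rep(rownames(bt$matrix), 7),
                            to = rep(colnames(bt$matrix), each = 7),
                            share = as.vector(bt$matrix),
                            count = as.vector(bt$counts)),
                 config$out_dir, "bundle_transfer"))

    hashes <- tools::md5sum(files)
    names(hashes) <- basename(names(hashes))
    manifest <- list(
      stages = c("synth", "features", "train", "classify", "transitions",
                 "es", "aggregate", "interact", "ccdm", "ellipse", "bundles"),
      seed = config$seed,
      config = unclass(config),
      selected_k = part$k,
      accuracy = lapply(models, function(m) unname(m$accuracy)),
      mean_D = list(t0 = mean(cc$t0$D), t1 = mean(cc$t1$D)),
      output_hashes = as.list(hashes),
      warnings = warn_count,
      started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
  }, warning = function(w) {
    warn_count <<- warn_count + 1L
    invokeRestart("muffleWarning")
  })
}
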