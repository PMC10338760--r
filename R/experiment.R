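#' Configuration of an end-to-end study run
#'
#' Binds every stage of the study design into one serializable object: a
#' cohort source, visibility/continuity/location pre-selection, the
#' train/test split, a segmenter standing in the model slot, the CTV
#' margin rule, and the output directory.  A run is reproducible from
#' config + seed.
#'
#' @param manifest path to a cohort manifest CSV ([read_manifest()]).
#' @param criteria pre-selection criteria, subset of
#'   `c("continuity", "location", "visibility")`.
#' @param mode visibility filter metric, `"contrast"` or `"cnr"`.
#' @param contrast_band,cnr_band closed exclusion bands.
#' @param margin a [margin_spec()].
#' @param segmenter a `segmenter` contract, e.g. [baseline_segmenter()].
#' @param train_fraction train share of the split (default 0.8).
#' @param seed integer seed driving the split.
#' @param out_dir run output directory.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(manifest,
                              criteria = c("continuity", "location",
                                           "visibility"),
                              mode = "contrast",
                              contrast_band = c(-10, 10),
                              cnr_band = c(-0.5, 0.1),
                              margin = margin_spec(),
                              segmenter,
                              train_fraction = 0.8,
                              seed = 1L,
                              out_dir = tempfile("cavityqa_run")) {
  stopifnot(inherits(margin, "margin_spec"), inherits(segmenter, "segmenter"))
  structure(list(manifest = manifest, criteria = criteria, mode = mode,
                 contrast_band = contrast_band, cnr_band = cnr_band,
                 margin = margin, segmenter = segmenter,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

# stage wrapper so failures name the stage they occurred in
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full 2x2 study design
#'
#' Pipeline: load cohort -> visibility metrics -> continuity/location
#' flags -> pre-selection -> seeded train/test split -> four experiment
#' arms (two model bindings x two test sets) -> per-arm GTV evaluation ->
#' GTV-to-CTV expansion of reference and predicted contours -> per-arm
#' CTV evaluation -> pooled t-test between the two models on each test
#' set.  With a deterministic segmenter a fixed seed reproduces the
#' report exactly.
#'
#' @param config an [experiment_config()].
#' @return Object of class `experiment_report`: list with `per_case`
#'   (data.frame of every contour comparison), `visibility` (per-case
#'   metric table), `removals`, `arm_summaries`, `t_tests`, `arms`,
#'   `split`, and `provenance`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))

  man <- run_stage("ingest", read_manifest(config$manifest))
  cases <- run_stage("ingest", {
    cs <- lapply(seq_len(nrow(man)), function(i) load_case(man[i, ]))
    names(cs) <- man$case_id
    cs
  })

  vis <- run_stage("visibility",
                   visibility_report(cases, mode = config$mode,
                                     contrast_band = config$contrast_band,
                                     cnr_band = config$cnr_band))

  entries <- run_stage("preselect", {
    ent <- vis
    ent$continuous <- vapply(cases, function(cs) check_continuity(cs$gtv),
                             logical(1))
    ent$in_fossa <- vapply(cases, function(cs)
      check_location(cs$gtv, cs$posterior_fossa), logical(1))
    ent
  })
  sel <- run_stage("preselect",
                   preselect(entries, criteria = config$criteria,
                             mode = config$mode,
                             contrast_band = config$contrast_band,
                             cnr_band = config$cnr_band))

  split <- run_stage("split",
                     split_cohort(man$case_id, config$train_fraction,
                                  config$seed))
  arms <- run_stage("arms",
                    build_experiment_arms(man$case_id, sel$cohort$case_id,
                                          split$test))
  empty_arms <- names(arms)[vapply(arms, function(a)
    length(a$test_ids) == 0, logical(1))]
  if (length(empty_arms))
    stop("stage 'preselect' failed: pre-selection emptied the test set (",
         paste(empty_arms, collapse = ", "), "); removals: ",
         paste(names(sel$removals), sel$removals, sep = "=",
               collapse = ", "), call. = FALSE)

  # one fitted predictor per model binding; cache predictions per
  # (model, case) since a case can sit in both test sets
  models <- run_stage("fit", {
    fulltrain <- arms[["model1_full_training.full_test"]]$train_ids
    pretrain <- arms[["model2_preselected_training.full_test"]]$train_ids
    list(model1_full_training = config$segmenter$fit(cases[fulltrain]),
         model2_preselected_training = config$segmenter$fit(cases[pretrain]))
  })
  pred_cache <- list()
  predict_case <- function(model, id) {
    key <- paste(model, id, sep = ".")
    if (is.null(pred_cache[[key]]))
      pred_cache[[key]] <<- models[[model]](cases[[id]])
    pred_cache[[key]]
  }

  per_case <- run_stage("evaluate", {
    rows <- list()
    for (arm_name in names(arms)) {
      arm <- arms[[arm_name]]
      for (id in arm$test_ids) {
        cs <- cases[[id]]
        pred <- predict_case(arm$model, id)
        g <- compare_contours(pred, cs$gtv, id, "gtv")
        ctv_ref <- expand_gtv_to_ctv(cs$gtv, cs$brain, cs$brainstem,
                                     config$margin)
        pred_in_brain <- structure_mask(pred$voxels & cs$brain$voxels,
                                        cs$image, "pred_gtv")
        ctv_row <- if (mask_is_empty(pred_in_brain)) {
          compare_contours(pred_in_brain, ctv_ref, id, "ctv")
        } else {
          ctv_pred <- expand_gtv_to_ctv(pred_in_brain, cs$brain,
                                        cs$brainstem, config$margin)
          compare_contours(ctv_pred, ctv_ref, id, "ctv")
        }
        block <- rbind(g, ctv_row)
        block <- cbind(model = arm$model, test_set = arm$test_set, block,
                       stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- block
      }
    }
    do.call(rbind, rows)
  })

  arm_summaries <- run_stage("summarize", {
    out <- list()
    for (arm_name in names(arms)) {
      arm <- arms[[arm_name]]
      for (st in c("gtv", "ctv")) {
        sub <- per_case[per_case$model == arm$model &
                          per_case$test_set == arm$test_set &
                          per_case$structure == st, ]
        out[[paste(arm_name, st, sep = ".")]] <- summarize_cohort(sub)
      }
    }
    out
  })

  t_tests <- run_stage("t_test", {
    out <- list()
    for (ts in c("full_test", "preselected_test")) {
      d1 <- per_case$dsc[per_case$model == "model1_full_training" &
                           per_case$test_set == ts &
                           per_case$structure == "gtv"]
      d2 <- per_case$dsc[per_case$model == "model2_preselected_training" &
                           per_case$test_set == ts &
                           per_case$structure == "gtv"]
      out[[ts]] <- if (length(d1) >= 2 && length(d2) >= 2)
        independent_t_test(d1, d2) else list(t = NA, p = NA,
                                             significant = NA, df = NA)
    }
    out
  })

  cfg_desc <- config[setdiff(names(config), "segmenter")]
  cfg_desc$segmenter_name <- config$segmenter$name
  cfg_json <- jsonlite::toJSON(cfg_desc, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  provenance <- list(config = cfg_desc,
                     config_hash = unname(tools::md5sum(tf)),
                     seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("cavityqa")))
  unlink(tf)

  structure(list(per_case = per_case, visibility = vis,
                 entries = sel$entries, removals = sel$removals,
                 arm_summaries = arm_summaries, t_tests = t_tests,
                 arms = lapply(arms, function(a)
                   a[c("model", "test_set", "train_ids", "test_ids")]),
                 split = split, provenance = provenance),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", length(unique(x$per_case$case_id)),
      " evaluated cases, 4 arms\n", sep = "")
  for (nm in names(x$arm_summaries)) {
    s <- x$arm_summaries[[nm]]
    dsc <- s$stats[s$stats$metric == "dsc", ]
    cat(sprintf("  %-45s DSC %.3f +/- %.3f (n=%d)\n", nm, dsc$mean, dsc$sd,
                s$n))
  }
  for (ts in names(x$t_tests))
    cat(sprintf("  t-test (%s): t=%.3f, p=%.4f\n", ts, x$t_tests[[ts]]$t,
                x$t_tests[[ts]]$p))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits per-case CSV, per-arm summary CSV, the removal table, a JSON
#' provenance block (config hash, seed, package version) and a
#' human-readable summary.  Summaries are recomputable from the per-case
#' CSV.
#'
#' @param report an `experiment_report`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    per_case = file.path(out_dir, "per_case.csv"),
    visibility = file.path(out_dir, "visibility.csv"),
    arm_summary = file.path(out_dir, "arm_summary.csv"),
    removals = file.path(out_dir, "removals.csv"),
    provenance = file.path(out_dir, "provenance.json"),
    summary = file.path(out_dir, "summary.txt"))
  utils::write.csv(report$per_case, paths$per_case, row.names = FALSE)
  utils::write.csv(report$visibility, paths$visibility, row.names = FALSE)
  arm_df <- do.call(rbind, lapply(names(report$arm_summaries), function(nm) {
    s <- report$arm_summaries[[nm]]
    cbind(arm = nm, n = s$n, s$stats, frac_dsc_gt_090 = s$frac_dsc_gt_090,
          stringsAsFactors = FALSE)
  }))
  utils::write.csv(arm_df, paths$arm_summary, row.names = FALSE)
  utils::write.csv(
    data.frame(criterion = names(report$removals),
               removed = as.integer(report$removals)),
    paths$removals, row.names = FALSE)
  jsonlite::write_json(report$provenance, paths$provenance,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  con <- file(paths$summary, "w")
  sink(con); print(report); sink(); close(con)
  invisible(paths)
}
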