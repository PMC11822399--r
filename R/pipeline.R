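# End-to-end pipeline: simulate -> features -> aggregate -> completeness ->
# associate, with a run manifest for reproducibility.

#' Run the full pipeline
#'
#' Wires the five stages together: generate (or accept) a cohort, extract
#' the daily digital measures, aggregate them into weekly markers,
#' standardize markers and clinical measures, compute completeness rates
#' with the phone-group comparison, and run the association screen. With
#' `out_dir` set, writes `daily_measures.csv`, `markers.csv`,
#' `markers_z.csv`, `clinical_z.csv`, `completeness.csv`,
#' `completeness_summary.json`, `associations.csv`, `heatmap.csv` and
#' (if `fig = TRUE`) `heatmap.png`.
#'
#' @param config a [cohort_config()]
#' @param cohort optionally, a pre-generated cohort (bypasses simulation)
#' @param out_dir optional output directory
#' @param fig render the heat-map figure (requires a working png device)
#' @return list: `manifest` (seed, config, per-stage row counts, file
#'   digests), `cohort`, `features`, `markers`, `markers_z`, `clinical_z`,
#'   `completeness`, `associations`, `heatmap`
#' @export
run_all <- function(config, cohort = NULL, out_dir = NULL, fig = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("simulate", generate_cohort(config))
  feats <- stage("features", extract_features(cohort$bundles))
  baseline_dates <- data.frame(
    participant_id = vapply(cohort$bundles, `[[`, "", "participant_id"),
    baseline_date = as.Date(vapply(cohort$bundles,
                                   function(b) format(b$baseline_date), "")),
    stringsAsFactors = FALSE)
  markers <- stage("aggregate",
                   aggregate_markers(feats$daily, feats$intertap,
                                     baseline_dates))
  markers_z <- stage("aggregate", transform_and_standardize(markers))
  clinical_z <- stage("aggregate", prepare_clinical(cohort$profiles))
  compl <- stage("completeness",
                 completeness_summary(cohort$bundles, cohort$profiles))
  assoc <- stage("associate", run_screen(markers_z, clinical_z))
  hm <- stage("associate", heatmap_matrix(assoc))

  manifest <- list(
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "clinical_scales")],
    timestamp = format(Sys.time(), tz = "UTC"),
    rows = list(participants = length(cohort$bundles),
                daily = nrow(feats$daily),
                markers = nrow(markers),
                associations = nrow(assoc)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(feats$daily, file.path(out_dir, "daily_measures.csv"))
    write_table(feats$intertap, file.path(out_dir, "intertap.csv"))
    write_table(markers, file.path(out_dir, "markers.csv"))
    write_table(markers_z$data, file.path(out_dir, "markers_z.csv"))
    write_table(clinical_z$data, file.path(out_dir, "clinical_z.csv"))
    write_table(compl$per_participant, file.path(out_dir, "completeness.csv"))
    writeLines(jsonlite::toJSON(list(cohort = compl$cohort,
                                     group_means = as.list(compl$group_means),
                                     mann_whitney = compl$comparison[c("U", "p_two_sided", "method")]),
                                auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "completeness_summary.json"))
    write_table(assoc, file.path(out_dir, "associations.csv"))
    hm_out <- data.frame(clinical_var = rownames(hm$beta), hm$beta,
                         check.names = FALSE)
    write_table(hm_out, file.path(out_dir, "heatmap.csv"))
    if (fig) plot_heatmap(hm, file.path(out_dir, "heatmap.png"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$digests <- as.list(tools::md5sum(files))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "manifest.json"))
  }

  list(manifest = manifest, cohort = cohort, features = feats,
       markers = markers, markers_z = markers_z, clinical_z = clinical_z,
       completeness = compl, associations = assoc, heatmap = hm)
}
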