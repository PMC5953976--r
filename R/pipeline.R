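#' Measure MTV with every method for one annotated patient image
#'
#' Runs the three segmentation methods on one image given its operator
#' annotations and returns one [total_mtv()] record per method:
#' * `fixed25`: one [segment_fixed()] region per seed (seeds that fall in
#'   the same connected component yield the same region once);
#' * `pct41`: one [segment_pct_max()] region per constraining box;
#' * `percist`: [choose_reference()] -> [percist_threshold()] ->
#'   [percist_tumor_finder()], then labels containing an
#'   `excluded_centers` voxel are removed via [edit_labels()].
#'
#' @param image an [suv_image()].
#' @param annotations annotation list (see [generate_phantom()] /
#'   [read_annotations()]).
#' @param cfg a [segmentation_config()].
#' @param pcfg a [percist_config()].
#' @param patient_id,observer_id provenance fields.
#' @return Named list of `mtv_record`s (`fixed25`, `pct41`, `percist`).
#' @export
measure_patient <- function(image, annotations, cfg = segmentation_config(),
                            pcfg = percist_config(),
                            patient_id = annotations$patient_id,
                            observer_id = "obs1") {
  stop_if_not_image(image)

  fixed_masks <- lapply(annotations$seeds, function(s) segment_fixed(image, s, cfg))
  fixed_masks <- unique_masks(fixed_masks)
  rec_fixed <- total_mtv(fixed_masks, image, patient_id, "fixed25", observer_id)

  pct_masks <- lapply(annotations$boxes, function(b)
    segment_pct_max(image, box_voi(b$center, b$size), cfg))
  rec_pct <- total_mtv(pct_masks, image, patient_id, "pct41", observer_id)

  ref <- choose_reference(isTRUE(annotations$liver_involved), image,
                          annotations$liver_center, annotations$aorta_center)
  thr <- percist_threshold(ref, pcfg)
  labels <- percist_tumor_finder(image, thr, cfg)
  excl <- integer(0)
  for (e in annotations$excluded_centers) {
    idx <- pmin(pmax(as.integer(round((e$center - image$origin) / image$spacing)) + 1L,
                     1L), dim(image$values))
    lab <- labels[idx[1], idx[2], idx[3]]
    if (lab > 0L) excl <- c(excl, lab)
  }
  labels <- edit_labels(labels, excluded = unique(excl))
  rec_percist <- total_mtv(label_masks(labels), image, patient_id, "percist",
                           observer_id)
  list(fixed25 = rec_fixed, pct41 = rec_pct, percist = rec_percist)
}

unique_masks <- function(masks) {
  if (length(masks) < 2L) return(masks)
  keys <- vapply(masks, function(m) paste(which(m), collapse = ","), character(1))
  masks[!duplicated(keys)]
}

#' Batch segmentation stage: one row per patient x method
#'
#' Processes a list of patients (each an image plus annotations, in memory
#' or as NIfTI/JSON paths). Per-patient failures are caught, logged to the
#' `errors` attribute of the result and do not abort the batch.
#'
#' @param patients list; each element a list with `patient_id`, `image`
#'   (an [suv_image()] or a NIfTI path) and `annotations` (a list or a
#'   JSON path).
#' @param cfg,pcfg segmentation and PERCIST configuration.
#' @param observer_id observer label stamped on every row.
#' @return Data frame with columns `patient_id`, `method`, `observer_id`,
#'   `n_lesions`, `total_mtv_cm3`, `tlg`; attribute `errors` is a data
#'   frame of failed patients (zero rows when all succeeded).
#' @export
run_segment <- function(patients, cfg = segmentation_config(),
                        pcfg = percist_config(), observer_id = "obs1") {
  rows <- list(); errs <- list()
  for (p in patients) {
    res <- tryCatch({
      image <- if (inherits(p$image, "suv_image")) p$image else read_suv_nifti(p$image)
      ann <- if (is.character(p$annotations)) read_annotations(p$annotations) else p$annotations
      recs <- measure_patient(image, ann, cfg, pcfg,
                              patient_id = p$patient_id %||% ann$patient_id,
                              observer_id = observer_id)
      do.call(rbind, lapply(recs, as.data.frame))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        patient_id = as.character(p$patient_id %||% NA_character_),
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), method = character(0),
               observer_id = character(0), n_lesions = integer(0),
               total_mtv_cm3 = numeric(0), tlg = numeric(0))
  rownames(out) <- NULL
  err_df <- if (length(errs)) do.call(rbind, errs) else
    data.frame(patient_id = character(0), error = character(0))
  if (nrow(err_df))
    warning(sprintf("%d patient(s) failed; see attr(, 'errors')", nrow(err_df)),
            call. = FALSE)
  structure(out, errors = err_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agreement stage: every pairwise comparison of MTV columns
#'
#' Reshapes a long MTV table (`patient_id`, `method`, `observer_id`,
#' `total_mtv_cm3`) to one column per method x observer and computes an
#' [agreement_report()] for every column pair.
#'
#' @param mtv a data frame as returned by [run_segment()] (or read from
#'   its CSV).
#' @return Data frame with one row per comparison (ICC, tau, median
#'   difference, limits of agreement, trend slope).
#' @export
run_compare <- function(mtv) {
  need <- c("patient_id", "method", "observer_id", "total_mtv_cm3")
  if (!all(need %in% names(mtv)))
    stop("MTV table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  mtv$column <- paste(mtv$method, mtv$observer_id, sep = ".")
  wide <- stats::reshape(mtv[c("patient_id", "column", "total_mtv_cm3")],
                         idvar = "patient_id", timevar = "column",
                         direction = "wide")
  names(wide) <- sub("^total_mtv_cm3\\.", "", names(wide))
  cols <- setdiff(names(wide), "patient_id")
  if (length(cols) < 2L)
    stop("need at least two method/observer columns to compare", call. = FALSE)
  if (anyNA(wide[cols])) {
    bad <- wide$patient_id[!stats::complete.cases(wide[cols])]
    stop("unmatched patient ids across columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(cols, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    rep <- agreement_report(
      paired_measurements(wide$patient_id, wide[[a]], wide[[b]]),
      comparison = paste(a, "vs", b))
    as.data.frame(rep)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Prognostic stage: ROC cut-off, KM, log-rank and Cox per MTV column
#'
#' @param cohort cohort table with columns `time_pfs`, `event_pfs` (and
#'   optionally `time_os`, `event_os`) plus one or more `mtv_*` columns.
#' @param methods which MTV columns to analyse (default: all `mtv_*`).
#' @param endpoints `"pfs"`, `"os"` or both (only those whose columns are
#'   present). Cut-offs for OS are re-derived from the OS ROC unless
#'   `pfs_cutoffs_for_os = TRUE`, which applies each method's PFS-derived
#'   cut-off to OS, the convention used when reporting both endpoints from
#'   one cut-off.
#' @param pfs_cutoffs_for_os reuse PFS cut-offs for the OS endpoint
#'   (default TRUE).
#' @param horizon_days ROC outcome horizon.
#' @return Data frame with one row per method x endpoint: AUC and CI,
#'   cut-off, sensitivity/specificity, group sizes and events, 5-year
#'   survival and median per group, log-rank chi-square/p, hazard ratio
#'   with CI and p. The fitted `mtv_prognosis` objects are attached as
#'   attribute `fits`.
#' @export
run_survival <- function(cohort, methods = NULL,
                         endpoints = c("pfs", "os"),
                         pfs_cutoffs_for_os = TRUE,
                         horizon_days = FIVE_YEARS_DAYS) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  if (is.null(methods))
    methods <- grep("^mtv_", names(cohort), value = TRUE)
  if (!length(methods)) stop("no `mtv_*` columns found", call. = FALSE)
  for (ep in endpoints) {
    cols <- paste0(c("time_", "event_"), ep)
    if (ep == "pfs" && !all(cols %in% names(cohort)))
      stop("cohort table must have time_pfs and event_pfs", call. = FALSE)
  }
  endpoints <- endpoints[vapply(endpoints, function(ep)
    all(paste0(c("time_", "event_"), ep) %in% names(cohort)), logical(1))]
  bad_time <- unlist(lapply(endpoints, function(ep) cohort[[paste0("time_", ep)]]))
  if (any(bad_time <= 0) ||
      !all(unlist(lapply(endpoints, function(ep)
        cohort[[paste0("event_", ep)]])) %in% c(0, 1)))
    stop("invalid cohort table: times must be > 0 and event flags 0/1",
         call. = FALSE)

  rows <- list(); fits <- list()
  pfs_cut <- list()
  for (ep in endpoints) {
    time <- cohort[[paste0("time_", ep)]]
    event <- cohort[[paste0("event_", ep)]]
    for (m in methods) {
      cutoff <- if (ep == "os" && pfs_cutoffs_for_os) pfs_cut[[m]] else NULL
      fit <- mtv_prognosis(cohort[[m]], time, event,
                           horizon_days = horizon_days, cutoff = cutoff)
      if (ep == "pfs") pfs_cut[[m]] <- fit$cutoff
      fits[[paste(m, ep, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, endpoint = ep,
        auc = fit$roc$auc, auc_lo = fit$roc$auc_ci[1], auc_hi = fit$roc$auc_ci[2],
        cutoff_cm3 = fit$cutoff,
        sens = fit$roc$optimal_sens, spec = fit$roc$optimal_spec,
        n_low = fit$km_low$n, n_high = fit$km_high$n,
        events_low = fit$km_low$events, events_high = fit$km_high$events,
        surv5_low = fit$km_low$surv_5y, surv5_high = fit$km_high$surv_5y,
        median_low = fit$km_low$median_survival,
        median_high = fit$km_high$median_survival,
        logrank_chi2 = fit$logrank$chi2, logrank_p = fit$logrank$p,
        hr = fit$cox$hr, hr_lo = fit$cox$ci_low, hr_hi = fit$cox$ci_high,
        hr_p = fit$cox$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fits = fits)
}

#' End-to-end pipeline over a YAML/list configuration
#'
#' Subcommand-style orchestration: `simulate` builds phantoms (NIfTI +
#' JSON annotations) and a cohort CSV under `out_dir`; `segment` measures
#' MTV for every simulated (or supplied) patient; `compare` runs the
#' agreement stage on the segmentation CSV; `survival` runs the prognostic
#' stage on the cohort CSV; `all` chains everything. Every JSON report
#' embeds the fully resolved configuration and the package version for
#' provenance, and all randomness flows from the single `seed` entry.
#'
#' @param config path to a YAML file or an equivalent named list. Keys:
#'   `out_dir` (required), `seed` (default 1), `n_phantoms` (default 3),
#'   `jitter_mm` (default 0: no second observer), plus optional
#'   segmentation/percist overrides (`fixed_threshold`, `max_fraction`,
#'   `connectivity`, `multiplier`, `sd_factor`) and cohort overrides
#'   (`n_patients`, `cutoff_true`).
#' @param stage one of `"simulate"`, `"segment"`, `"compare"`,
#'   `"survival"`, `"all"`.
#' @return Invisibly, a list with the tables produced by the executed
#'   stages.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "segment",
                                           "compare", "survival")) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  n_phantoms <- as.integer(cfg$n_phantoms %||% 3L)
  jitter_mm <- as.numeric(cfg$jitter_mm %||% 0)
  seg_cfg <- segmentation_config(
    fixed_threshold = cfg$fixed_threshold %||% 2.5,
    max_fraction = cfg$max_fraction %||% 0.41,
    connectivity = cfg$connectivity %||% 26L)
  pcfg <- percist_config(multiplier = cfg$multiplier %||% 1.5,
                         sd_factor = cfg$sd_factor %||% 2.0)
  results <- list()

  provenance <- list(config = cfg,
                     package = "petmtv",
                     version = as.character(utils::packageVersion("petmtv")))

  if (stage %in% c("simulate", "all")) {
    for (i in seq_len(n_phantoms)) {
      ph <- generate_phantom(example_phantom_spec(
        seed = seed + i, lesion_scale = 0.8 + 0.1 * (i %% 5)))
      write_suv_nifti(ph$image, file.path(out_dir, sprintf("phantom_%03d.nii.gz", i)))
      write_annotations(ph$annotations,
                        file.path(out_dir, sprintf("phantom_%03d.json", i)))
    }
    cohort <- generate_cohort(cohort_spec(
      n = cfg$n_patients %||% 147L,
      cutoff_true = cfg$cutoff_true %||% 400,
      seed = seed))
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    results$cohort <- cohort
  }

  if (stage %in% c("segment", "all")) {
    paths <- list.files(out_dir, pattern = "^phantom_.*\\.nii\\.gz$",
                        full.names = TRUE)
    patients <- lapply(paths, function(p) list(
      patient_id = sub("\\.nii\\.gz$", "", basename(p)),
      image = p, annotations = sub("\\.nii\\.gz$", ".json", p)))
    mtv <- run_segment(patients, seg_cfg, pcfg, observer_id = "obs1")
    if (jitter_mm > 0) {
      patients_b <- lapply(seq_along(patients), function(i) {
        p <- patients[[i]]
        img <- read_suv_nifti(p$image)
        ann <- perturb_annotations(read_annotations(p$annotations), img,
                                   jitter_mm = jitter_mm, seed = seed + i)
        list(patient_id = p$patient_id, image = img, annotations = ann)
      })
      mtv <- rbind(mtv, run_segment(patients_b, seg_cfg, pcfg,
                                    observer_id = "obs2"))
    }
    utils::write.csv(mtv, file.path(out_dir, "mtv.csv"), row.names = FALSE)
    err <- attr(mtv, "errors")
    if (!is.null(err) && nrow(err))
      utils::write.csv(err, file.path(out_dir, "segment_errors.csv"),
                       row.names = FALSE)
    results$mtv <- mtv
  }

  if (stage %in% c("compare", "all")) {
    mtv <- results$mtv %||% utils::read.csv(file.path(out_dir, "mtv.csv"),
                                            stringsAsFactors = FALSE)
    agreement <- run_compare(mtv)
    utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(provenance = provenance, agreement = agreement),
                         file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$agreement <- agreement
  }

  if (stage %in% c("survival", "all")) {
    cohort <- results$cohort %||% utils::read.csv(file.path(out_dir, "cohort.csv"),
                                                  stringsAsFactors = FALSE)
    prognosis <- run_survival(cohort)
    utils::write.csv(prognosis, file.path(out_dir, "prognosis.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(provenance = provenance,
                              prognosis = as.data.frame(prognosis)),
                         file.path(out_dir, "prognosis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$prognosis <- prognosis
  }

  invisible(results)
}
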