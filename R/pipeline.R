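#' Default run configuration
#'
#' All tunables in one list, serialized into every report for
#' provenance: gray-level count, wavelet family, GLCM pooling mode,
#' stability threshold (strictly-greater-than 0.85), McNemar
#' exact/asymptotic switch point, bootstrap replicates and seed, cohort
#' seed, and the reference sequence label.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    reference_sequence = "conventional",
    discretization = list(ng = 32L),
    wavelet = list(family = "haar", levels = 2L, mode = "symmetric"),
    glcm = list(distance = 1L, pooling = "counts"),
    stability = list(threshold = 0.85, mcnemar_exact_cutoff = 25L,
                     bootstrap_reps = 2000L, bootstrap_seed = 1L),
    cohort = list(seed = 1L, n_per_group = 4L, scale = 0.25)
  )
}

#' Load a configuration file (YAML or JSON), merged over the defaults
#'
#' @param path YAML/JSON file; `NULL` returns the defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_lists(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  stopifnot(cfg$stability$threshold > 0, cfg$stability$threshold < 1,
            cfg$stability$bootstrap_reps >= 100L)
  cfg
}

#' Simulate subcommand: write a demo cohort
#'
#' @param outdir output directory.
#' @param n_per_group subjects per group.
#' @param seed cohort seed.
#' @param scale acquisition-matrix scale factor.
#' @return manifest data frame, invisibly.
#' @export
cmd_simulate <- function(outdir, n_per_group = 4L, seed = 1L,
                         scale = 0.25) {
  build_demo_cohort(n_per_group = n_per_group, seed = seed,
                    outdir = outdir, scale = scale)
}

# Assemble the mask for one extraction task. Whole: the image's own mask.
# Intersection: the reference and fast masks, each resampled to the target
# image grid, ANDed there.
.task_mask <- function(task, volumes, masks, reference) {
  vol <- volumes[[task$sequence]]
  if (task$mask_kind == "whole") return(masks[[task$sequence]])
  ref_m <- masks_on_grid(masks[[reference]],
                         volumes[[reference]], vol)
  fast_m <- masks_on_grid(masks[[task$pairing]],
                          volumes[[task$pairing]], vol)
  intersect_masks(ref_m, fast_m)
}

# Resample a mask from its native grid to a target volume's grid
# (nearest neighbour; identity when grids match).
masks_on_grid <- function(mask, from_vol, to_vol) {
  if (identical(dim(mask), dim(to_vol$intensities))) return(mask)
  resample_nn(mask, from_vol$spacing, dim(to_vol$intensities),
              to_vol$spacing)
}

#' Extract subcommand: run the 595-feature extraction over a cohort
#'
#' Reads the manifest, enumerates the whole/intersection mask roles via
#' [enumerate_mask_set()], extracts one `FeatureVector` per task and
#' returns (and optionally writes) the long-form feature table. A failing
#' task is logged and skipped; the run continues.
#'
#' @param manifest manifest data frame or CSV path.
#' @param out optional output CSV path for the long-form table.
#' @param config configuration list.
#' @param quiet suppress per-task progress messages.
#' @return long-form feature data frame, invisibly.
#' @export
cmd_extract <- function(manifest, out = NULL, config = default_config(),
                        quiet = FALSE) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("unreadable manifest: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  ref <- config$reference_sequence
  tasks <- enumerate_mask_set(manifest, reference = ref)
  rows <- list()
  n_fail <- 0L
  for (sid in unique(tasks$subject_id)) {
    stasks <- tasks[tasks$subject_id == sid, , drop = FALSE]
    srows <- manifest[manifest$subject_id == sid, , drop = FALSE]
    volumes <- list(); masks <- list()
    for (r in seq_len(nrow(srows))) {
      sq <- srows$sequence[r]
      ok <- tryCatch({
        volumes[[sq]] <- read_volume(srows$volume_path[r],
                                     meta = list(subject_id = sid,
                                                 sequence = sq))
        masks[[sq]] <- read_mask(srows$mask_path[r], volumes[[sq]])
        TRUE
      }, error = function(e) {
        message("cannot load ", sid, "/", sq, ": ", conditionMessage(e))
        FALSE
      })
      if (!ok) { volumes[sq] <- NULL; masks[sq] <- NULL }
    }
    for (t in seq_len(nrow(stasks))) {
      task <- stasks[t, ]
      res <- tryCatch({
        needed <- unique(c(task$sequence,
                           if (task$mask_kind == "intersection")
                             c(ref, task$pairing)))
        absent <- setdiff(needed, names(volumes))
        if (length(absent)) {
          stop("volume(s) unavailable: ", paste(absent, collapse = ", "))
        }
        m <- .task_mask(task, volumes, masks, ref)
        vol <- volumes[[task$sequence]]
        vwm <- volume_with_mask(vol$intensities, vol$spacing, mask = m,
                                meta = list(subject_id = sid))
        fv <- extract_all(vwm, config)
        feature_vector_to_long(fv, task)
      }, error = function(e) {
        message("task failed (", task$role, ", ", sid, "): ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) { n_fail <- n_fail + 1L; next }
      rows[[length(rows) + 1L]] <- res
      if (!quiet) {
        message("extracted ", sid, " ", task$sequence, " ",
                task$mask_kind, "/", task$pairing)
      }
    }
  }
  if (!quiet && n_fail > 0L) message(n_fail, " task(s) failed")
  out_df <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out) && !is.null(out_df)) {
    utils::write.csv(out_df, out, row.names = FALSE)
  }
  invisible(out_df)
}

#' Analyze subcommand: stability study + report files
#'
#' @param features long-form feature table (data frame or CSV path).
#' @param outdir report directory (created).
#' @param config configuration list.
#' @return the `StabilityStudy`, invisibly.
#' @export
cmd_analyze <- function(features, outdir, config = default_config()) {
  study <- run_stability_study(features, config)
  write_study_report(study, outdir)
  invisible(study)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `extract`, `analyze`, `catalog`. Intended to
#' be called from the `inst/cli/radstab` Rscript wrapper:
#' \preformatted{
#' radstab simulate --n-per-group N --seed S --scale F --outdir DIR
#' radstab extract  --manifest CSV --out CSV [--config FILE]
#' radstab analyze  --features CSV --outdir DIR [--config FILE]
#' radstab catalog  [--out CSV]
#' }
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return integer exit status: 0 success, 1 usage error, 2 data error.
#' @export
radstab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: radstab <simulate|extract|analyze|catalog> [options]")
    1L
  }
  if (!length(args)) return(usage())
  cmd <- args[1L]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (!startsWith(a, "--")) return(usage())
    key <- gsub("-", "_", sub("^--", "", a))
    if (i == length(rest)) return(usage())
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- tryCatch(load_config(opts$config), error = function(e) {
    message("bad config: ", conditionMessage(e)); NULL
  })
  if (is.null(cfg)) return(2L)
  run <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message("error: ", conditionMessage(e)); 2L
    })
  }
  switch(cmd,
    simulate = {
      if (is.null(opts$outdir)) return(usage())
      run(cmd_simulate(opts$outdir,
                       n_per_group = as.integer(opts$n_per_group %||%
                                                cfg$cohort$n_per_group),
                       seed = as.integer(opts$seed %||% cfg$cohort$seed),
                       scale = as.numeric(opts$scale %||%
                                          cfg$cohort$scale)))
    },
    extract = {
      if (is.null(opts$manifest) || is.null(opts$out)) return(usage())
      run(cmd_extract(opts$manifest, out = opts$out, config = cfg,
                      quiet = TRUE))
    },
    analyze = {
      if (is.null(opts$features) || is.null(opts$outdir)) return(usage())
      run(cmd_analyze(opts$features, opts$outdir, config = cfg))
    },
    catalog = {
      run({
        cat <- feature_catalog()
        if (!is.null(opts$out)) write_catalog(opts$out)
        else utils::write.csv(cat, stdout(), row.names = FALSE)
      })
    },
    usage()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
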