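#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' n-denominator sample moments. Agreement index penalizing both
#' correlation loss and location/scale shift: 1 only for perfect
#' concordance. Pairs with a missing value in either list are dropped;
#' fewer than 3 complete pairs, or a zero denominator (both lists
#' constant), yield `NA` with a `reason` attribute.
#'
#' @param x,y numeric vectors of equal length (paired measurements).
#' @return scalar in \[-1, 1\], or `NA`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(structure(NA_real_, reason = "insufficient pairs", n = n))
  }
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    # zero denominator forces both lists constant AND equal (sx2 = sy2 = 0
    # and mx = my): the measurements agree exactly, so report perfect
    # concordance rather than 0/0.
    if (mx == my) return(structure(1, n = n))
    return(structure(NA_real_, reason = "zero denominator", n = n))
  }
  structure(2 * sxy / denom, n = n)
}

#' Per-feature CCC over a paired feature table
#'
#' @param paired a `PairedFeatureTable` (see [simulate_feature_pairs()]
#'   or [paired_feature_table()]).
#' @param threshold stability threshold; features with CCC strictly above
#'   it are stable.
#' @return data frame with one row per feature: `feature`, `ccc`, `n`
#'   (effective complete pairs) and `stable`.
#' @export
ccc_table <- function(paired, threshold = 0.85) {
  stopifnot(inherits(paired, "PairedFeatureTable"))
  res <- lapply(seq_along(paired$features), function(j) {
    cc <- lin_ccc(paired$x[, j], paired$y[, j])
    data.frame(feature = paired$features[j], ccc = as.numeric(cc),
               n = attr(cc, "n"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  classify_stability(out, threshold = threshold)
}

#' Construct a paired feature table
#'
#' @param x,y numeric matrices (subjects x features) of identical shape,
#'   columns aligned by feature, rows by subject.
#' @param features feature names (defaults to `colnames(x)`).
#' @param stratum named list describing the stratum (group, lesion class,
#'   mask kind, fast sequence).
#' @return object of class `PairedFeatureTable`.
#' @export
paired_feature_table <- function(x, y, features = colnames(x),
                                 stratum = list()) {
  stopifnot(identical(dim(x), dim(y)))
  if (is.null(features)) features <- sprintf("feature_%04d", seq_len(ncol(x)))
  structure(list(x = x, y = y, features = features, stratum = stratum),
            class = "PairedFeatureTable")
}

#' Classify features as stable at a strict CCC threshold
#'
#' Stable means CCC strictly greater than the threshold (default 0.85);
#' an undefined CCC is never stable.
#'
#' @param results data frame with a `ccc` column.
#' @param threshold scalar in (0, 1).
#' @return `results` with a logical `stable` column (re)computed.
#' @export
classify_stability <- function(results, threshold = 0.85) {
  stopifnot(threshold > 0, threshold < 1)
  results$stable <- !is.na(results$ccc) & results$ccc > threshold
  results
}

#' Median CCC with a bootstrap confidence interval
#'
#' Median over the defined CCC values; 95% percentile bootstrap over
#' features, seeded for reproducibility.
#'
#' @param ccc numeric vector of CCC values (NAs dropped; >= 2 required).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `(median, lo, hi)`.
#' @export
median_ccc_ci <- function(ccc, n_boot = 2000L, seed = 1L, conf = 0.95) {
  v <- ccc[!is.na(ccc)]
  if (length(v) < 2L) stop("need >= 2 defined CCC values")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(v, length(v), replace = TRUE))
  }, 0)
  a <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(a, 1 - a), names = FALSE, type = 7)
  c(median = stats::median(v), lo = qs[1], hi = qs[2])
}

#' McNemar's test on paired stability indicators
#'
#' Driven by the discordant counts b (stable under A only) and c (stable
#' under B only). For b + c >= `exact_cutoff` (default 25) the
#' continuity-corrected chi-square statistic `(|b - c| - 1)^2 / (b + c)`
#' with 1 df is used; below the cutoff the exact two-sided binomial test
#' `b ~ Binomial(b + c, 1/2)`. b + c = 0 gives p = 1 ("degenerate").
#'
#' @param stable_a,stable_b logical vectors in the same feature order.
#' @param exact_cutoff switch point between exact and asymptotic methods.
#' @return list of class `McNemarResult`: `b`, `c`, `concordant`,
#'   `statistic`, `p_value`, `method`.
#' @export
mcnemar_test <- function(stable_a, stable_b, exact_cutoff = 25L) {
  if (length(stable_a) != length(stable_b)) {
    stop("indicator lists must have equal length")
  }
  b <- sum(stable_a & !stable_b)
  cc <- sum(!stable_a & stable_b)
  conc <- sum(stable_a == stable_b)
  nd <- b + cc
  if (nd == 0L) {
    res <- list(b = b, c = cc, concordant = conc, statistic = 0,
                p_value = 1, method = "degenerate")
  } else if (nd >= exact_cutoff) {
    stat <- (abs(b - cc) - 1)^2 / nd
    res <- list(b = b, c = cc, concordant = conc, statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi2-cc")
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    res <- list(b = b, c = cc, concordant = conc, statistic = NA_real_,
                p_value = p, method = "exact-binomial")
  }
  structure(res, class = "McNemarResult")
}

#' @export
print.McNemarResult <- function(x, ...) {
  cat("McNemar: b=", x$b, " c=", x$c, " (", x$method, "), p=",
      signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Stability summary over one stratum
#'
#' The stable proportion uses the full catalog size as denominator
#' (undefined features count as unstable), matching an `x/595`
#' presentation; per-family stable counts partition the overall count.
#'
#' @param results data frame with columns `feature`, `ccc`, `stable`
#'   covering every catalog feature exactly once.
#' @param catalog the feature catalog (default [feature_catalog()]).
#' @param n_boot,seed bootstrap parameters for the median-CCC CI.
#' @return list with `n_features`, `n_stable`, `proportion`,
#'   `median_ccc`, `ci_lo`, `ci_hi`, `n_defined` and `per_family` (data
#'   frame: family, size, n_stable, proportion).
#' @export
stability_summary <- function(results, catalog = feature_catalog(),
                              n_boot = 2000L, seed = 1L) {
  missing_feats <- setdiff(catalog$name, results$feature)
  if (length(missing_feats)) {
    stop("results lack ", length(missing_feats), " catalog feature(s): ",
         paste(utils::head(missing_feats, 5), collapse = ", "),
         if (length(missing_feats) > 5) ", ...")
  }
  results <- results[match(catalog$name, results$feature), ]
  n_feat <- nrow(catalog)
  n_stable <- sum(results$stable)
  defined <- !is.na(results$ccc)
  med <- if (sum(defined) >= 2) {
    median_ccc_ci(results$ccc, n_boot = n_boot, seed = seed)
  } else c(median = NA_real_, lo = NA_real_, hi = NA_real_)
  fam <- catalog$family
  per_family <- do.call(rbind, lapply(unique(fam), function(f) {
    sel <- fam == f
    data.frame(family = f, size = sum(sel),
               n_stable = sum(results$stable[sel]),
               proportion = sum(results$stable[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  list(n_features = n_feat, n_stable = n_stable,
       proportion = n_stable / n_feat,
       median_ccc = unname(med["median"]),
       ci_lo = unname(med["lo"]), ci_hi = unname(med["hi"]),
       n_defined = sum(defined), per_family = per_family)
}

# Wide subject x feature matrix for one (sequence, mask_kind, pairing)
# cell of a long feature table, rows ordered by subject id.
.wide_values <- function(tab, subjects, features) {
  m <- matrix(NA_real_, length(subjects), length(features),
              dimnames = list(subjects, features))
  if (nrow(tab)) {
    m[cbind(match(tab$subject_id, subjects),
            match(tab$feature_name, features))] <- tab$value
  }
  m
}

#' Run the full stability study on a long-form feature table
#'
#' For every stratum (group x fast sequence x lesion class in acute /
#' chronic / overall x mask kind in whole / intersection), pairs each
#' feature's values between the reference (conventional) sequence and the
#' fast sequence across subjects, computes Lin's CCC, classifies
#' stability at the threshold, and summarizes. "Overall" pools the acute
#' and chronic lesion sets. For whole masks the pairing is each
#' sequence's own mask; for intersection masks both members use the same
#' reference-and-fast intersection mask on their own grid. When a group
#' has exactly two fast sequences, McNemar's test compares their
#' stability indicators per (lesion class, mask kind).
#'
#' @param features long-form data frame (or CSV path) with columns
#'   `subject_id`, `group`, `lesion_class`, `sequence`, `mask_kind`,
#'   `pairing`, `feature_name`, `value`.
#' @param config configuration list; uses `reference_sequence`,
#'   `stability$threshold`, `stability$bootstrap_reps`,
#'   `stability$bootstrap_seed`, `stability$mcnemar_exact_cutoff`.
#' @return list of class `StabilityStudy` with `summary` (one row per
#'   stratum), `ccc_long` (per-feature CCC per stratum), `mcnemar` (one
#'   row per comparison), `heatmap` (features x strata CCC matrix;
#'   undefined stays NA) and `config`.
#' @export
run_stability_study <- function(features, config = default_config()) {
  if (is.character(features)) {
    features <- utils::read.csv(features, stringsAsFactors = FALSE,
                                comment.char = "#")
  }
  need <- c("subject_id", "group", "lesion_class", "sequence",
            "mask_kind", "pairing", "feature_name", "value")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ref <- config$reference_sequence
  thr <- config$stability$threshold
  catalog <- feature_catalog()
  feat_names <- catalog$name
  summary_rows <- list()
  ccc_rows <- list()
  mcnemar_rows <- list()
  heat <- list()
  for (grp in sort(unique(features$group))) {
    gtab <- features[features$group == grp, ]
    fast_seqs <- sort(setdiff(unique(gtab$sequence), ref))
    for (lc in c("acute", "chronic", "overall")) {
      ltab <- if (lc == "overall") gtab else gtab[gtab$lesion_class == lc, ]
      for (mk in c("whole", "intersection")) {
        stable_by_seq <- list()
        for (fs in fast_seqs) {
          if (mk == "whole") {
            xtab <- ltab[ltab$sequence == ref & ltab$mask_kind == "whole", ]
            ytab <- ltab[ltab$sequence == fs & ltab$mask_kind == "whole", ]
          } else {
            xtab <- ltab[ltab$sequence == ref &
                         ltab$mask_kind == "intersection" &
                         ltab$pairing == fs, ]
            ytab <- ltab[ltab$sequence == fs &
                         ltab$mask_kind == "intersection" &
                         ltab$pairing == fs, ]
          }
          subjects <- sort(intersect(unique(xtab$subject_id),
                                     unique(ytab$subject_id)))
          if (length(subjects) < 3L) next
          xm <- .wide_values(xtab, subjects, feat_names)
          ym <- .wide_values(ytab, subjects, feat_names)
          pt <- paired_feature_table(xm, ym, feat_names,
                                     stratum = list(group = grp,
                                                    lesion_class = lc,
                                                    mask_kind = mk,
                                                    fast_sequence = fs))
          ct <- ccc_table(pt, threshold = thr)
          summ <- stability_summary(
            ct, catalog,
            n_boot = config$stability$bootstrap_reps,
            seed = config$stability$bootstrap_seed)
          key <- paste(grp, fs, lc, mk, sep = "|")
          summary_rows[[key]] <- data.frame(
            group = grp, fast_sequence = fs, lesion_class = lc,
            mask_kind = mk, n_subjects = length(subjects),
            n_stable = summ$n_stable, n_features = summ$n_features,
            proportion = summ$proportion, median_ccc = summ$median_ccc,
            ci_lo = summ$ci_lo, ci_hi = summ$ci_hi,
            n_defined = summ$n_defined, stringsAsFactors = FALSE)
          ct$group <- grp; ct$fast_sequence <- fs
          ct$lesion_class <- lc; ct$mask_kind <- mk
          ccc_rows[[key]] <- ct
          heat[[key]] <- ct$ccc
          stable_by_seq[[fs]] <- ct$stable
        }
        if (length(stable_by_seq) == 2L) {
          ab <- names(stable_by_seq)
          mt <- mcnemar_test(stable_by_seq[[1L]], stable_by_seq[[2L]],
                             exact_cutoff =
                               config$stability$mcnemar_exact_cutoff)
          mcnemar_rows[[paste(grp, lc, mk, sep = "|")]] <- data.frame(
            group = grp, lesion_class = lc, mask_kind = mk,
            sequence_a = ab[1L], sequence_b = ab[2L],
            b = mt$b, c = mt$c, statistic = mt$statistic,
            p_value = mt$p_value, method = mt$method,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  heatmap <- if (length(heat)) {
    do.call(cbind, stats::setNames(heat, names(heat)))
  } else NULL
  if (!is.null(heatmap)) rownames(heatmap) <- feat_names
  structure(list(
    summary = if (length(summary_rows)) do.call(rbind, summary_rows)
              else NULL,
    ccc_long = if (length(ccc_rows)) do.call(rbind, ccc_rows) else NULL,
    mcnemar = if (length(mcnemar_rows)) do.call(rbind, mcnemar_rows)
              else NULL,
    heatmap = heatmap,
    config = config
  ), class = "StabilityStudy")
}

#' @export
print.StabilityStudy <- function(x, ...) {
  cat("<StabilityStudy>\n")
  if (!is.null(x$summary)) {
    df <- x$summary
    df$proportion <- sprintf("%.1f%% (%d/%d)", 100 * df$proportion,
                             df$n_stable, df$n_features)
    print(df[, c("group", "fast_sequence", "lesion_class", "mask_kind",
                 "proportion", "median_ccc")], row.names = FALSE)
  }
  if (!is.null(x$mcnemar)) {
    cat("McNemar comparisons:\n")
    print(x$mcnemar[, c("group", "lesion_class", "mask_kind", "b", "c",
                        "p_value", "method")], row.names = FALSE)
  }
  invisible(x)
}

#' Write the study report files
#'
#' Emits `stability_summary.csv` (one stratum per row), `mcnemar.csv`,
#' `ccc_heatmap.csv` (features x strata; undefined CCCs stay blank) and
#' `config.json`, each prefixed with a config-echo comment header.
#' Outputs contain no timestamps, so reruns are byte-identical.
#'
#' @param study a `StabilityStudy`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_study_report <- function(study, outdir) {
  stopifnot(inherits(study, "StabilityStudy"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# config: ", jsonlite::toJSON(study$config,
                                               auto_unbox = TRUE))
  wr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  if (!is.null(study$summary)) {
    wr(study$summary, file.path(outdir, "stability_summary.csv"))
  }
  if (!is.null(study$mcnemar)) {
    wr(study$mcnemar, file.path(outdir, "mcnemar.csv"))
  }
  if (!is.null(study$heatmap)) {
    hm <- data.frame(feature = rownames(study$heatmap),
                     study$heatmap, check.names = FALSE,
                     stringsAsFactors = FALSE)
    wr(hm, file.path(outdir, "ccc_heatmap.csv"))
  }
  jsonlite::write_json(study$config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
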