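#' Aggregate spine measures to per-case, per-region trait rows
#'
#' Produces the predictor table used by the regression stages: for each
#' (case, region), overall spine density (per 10 um, averaged over
#' segments), mean length, mean head diameter and mean volume, plus the same
#' four traits restricted to each morphological class.  Morphology means are
#' pooled over spines by default; \code{aggregation = "per_neuron"} averages
#' neuron means instead.  Class cells with no spines are recorded as missing.
#'
#' @param spines measured, classified spine table (one row per spine) with
#'   columns case_id, region, neuron_id, segment_id, spine_class, length_um,
#'   head_diameter_um, volume_um3.
#' @param segments segment table with columns case_id, region, neuron_id,
#'   segment_id, length_um and (optionally) n_spines; spine counts are
#'   recomputed from \code{spines}.
#' @param aggregation "pooled" (default) or "per_neuron".
#' @return data.table, one row per (case_id, region).
#' @export
aggregate_features <- function(spines, segments,
                               aggregation = c("pooled", "per_neuron")) {
  aggregation <- match.arg(aggregation)
  sp <- data.table::as.data.table(spines)
  sg <- data.table::as.data.table(segments)
  if (any(sg$length_um <= 0)) stop("segment lengths must be positive")
  segkey <- c("case_id", "region", "neuron_id", "segment_id")

  # spine counts per segment, overall and per class
  cnt <- sp[, list(n_sp = .N), by = segkey]
  sg <- merge(sg, cnt, by = segkey, all.x = TRUE)
  sg[is.na(sg$n_sp), "n_sp" := 0L]
  sg[, "dens" := segment_density(sg$n_sp, sg$length_um)]
  by_cr <- c("case_id", "region")
  out <- sg[, list(mean_density = mean(dens),
                   n_neurons = length(unique(neuron_id)),
                   n_segments = .N,
                   n_spines = sum(n_sp),
                   total_dendrite_um = sum(length_um)),
            by = by_cr]

  morph_means <- function(d, suffix = "") {
    if (aggregation == "pooled") {
      mm <- d[, list(length = mean(length_um),
                     head_diameter = mean(head_diameter_um),
                     volume = mean(volume_um3)), by = by_cr]
    } else {
      nm <- d[, list(length = mean(length_um),
                     head_diameter = mean(head_diameter_um),
                     volume = mean(volume_um3)),
              by = c(by_cr, "neuron_id")]
      mm <- nm[, list(length = mean(length),
                      head_diameter = mean(head_diameter),
                      volume = mean(volume)), by = by_cr]
    }
    data.table::setnames(mm, c("length", "head_diameter", "volume"),
                         paste0(suffix, c("length", "head_diameter",
                                          "volume")))
    mm
  }
  out <- merge(out, morph_means(sp, "mean_"), by = by_cr, all.x = TRUE)

  for (cl in spine_classes()) {
    spc <- sp[sp$spine_class == cl]
    cntc <- spc[, list(n_cl = .N), by = segkey]
    sgc <- merge(sg[, c(segkey, "length_um"), with = FALSE], cntc,
                 by = segkey, all.x = TRUE)
    sgc[is.na(sgc$n_cl), "n_cl" := 0L]
    sgc[, "dens" := segment_density(sgc$n_cl, sgc$length_um)]
    dn <- sgc[, stats::setNames(list(mean(dens)), paste0(cl, "_density")),
              by = by_cr]
    out <- merge(out, dn, by = by_cr, all.x = TRUE)
    if (nrow(spc))
      out <- merge(out, morph_means(spc, paste0(cl, "_")), by = by_cr,
                   all.x = TRUE)
    else
      for (v in paste0(cl, c("_length", "_head_diameter", "_volume")))
        out[, (v) := NA_real_]
  }
  zero <- out$n_spines == 0
  if (any(zero)) {
    warning(sum(zero), " case-region rows have no spines; ",
            "morphology means recorded as missing")
  }
  data.table::setorderv(out, by_cr)
  out[]
}

#' Drop cases with missing required scores
#'
#' Removes every case with a missing value in any required column and logs
#' which cases were removed (attribute \code{"removed_cases"} and a
#' message).
#'
#' @param cases per-case covariate table.
#' @param required columns that must be complete; defaults to the pathology
#'   and memory scores the models use.
#' @return Filtered table with attribute \code{removed_cases}.
#' @export
filter_complete_cases <- function(cases,
                                  required = c("np_score", "nft_burden",
                                               "episodic_memory")) {
  ct <- data.table::as.data.table(cases)
  miss <- setdiff(required, names(ct))
  if (length(miss))
    stop("required columns absent: ", paste(miss, collapse = ", "))
  bad <- rowSums(is.na(ct[, required, with = FALSE])) > 0
  removed <- ct$case_id[bad]
  if (all(bad)) warning("all cases removed: every row has missing values")
  out <- ct[!bad]
  data.table::setattr(out, "removed_cases", removed)
  message(length(removed), " case(s) removed due to missing data; ",
          nrow(out), " remain")
  out
}

#' Split cases into discovery and validation halves
#'
#' Random, seeded, disjoint split: the discovery half gets ceiling(n/2)
#' cases and the validation half the rest (125 cases split 63/62).
#' Membership is deterministic for a given seed under this package's RNG;
#' the split is the contract, not any other software's permutation order.
#'
#' @param cases per-case table.
#' @param seed integer seed.
#' @return List with \code{discovery} and \code{validation} tables.
#' @export
split_discovery_validation <- function(cases, seed = 111) {
  ct <- data.table::as.data.table(cases)
  n <- nrow(ct)
  if (n < 2) stop("need at least 2 cases to split")
  idx <- with_seed(seed, sample(n, ceiling(n / 2)))
  list(discovery = ct[idx], validation = ct[-idx])
}

#' Merge per-case spine traits with covariates for one region
#'
#' @param features output of \code{\link{aggregate_features}}.
#' @param cases per-case covariate table.
#' @param region region label to select.
#' @return data.table, one row per case with covariates and spine traits.
#' @export
analysis_table <- function(features, cases, region) {
  ft <- data.table::as.data.table(features)
  keep <- ft[["region"]] == region  # evaluate outside [ to avoid NSE capture
  ft <- ft[which(keep)]
  if (!nrow(ft)) stop("no feature rows for region ", region)
  merge(data.table::as.data.table(cases), ft, by = "case_id")
}
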