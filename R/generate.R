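# Synthetic cohort generation.
#
# RNG layout: every (case, neuron) pair draws from its own sub-stream seeded
# by a stable hash of (cohort seed, case index, region/neuron key), so adding
# cases or neurons never shifts earlier draws.  Case covariates use the
# neuron-0 sub-stream; cohort-level draws (missingness pattern, geometry
# jitter) use reserved case-0 streams.

# Vectorized class-conditional measurement draws with rejection until every
# spine classifies as requested.  log_f_hd / log_f_len shift the lognormal
# location per spine (case-level factors).
draw_class_measures <- function(classes, log_f_hd = 0, log_f_len = 0,
                                geom = class_geometry_defaults(),
                                thresholds = classifier_thresholds(),
                                max_rounds = 200) {
  n <- length(classes)
  log_f_hd <- rep_len(log_f_hd, n)
  log_f_len <- rep_len(log_f_len, n)
  bad <- !(classes %in% spine_classes())
  if (any(bad))
    stop("unknown spine class label: ",
         paste(unique(classes[bad]), collapse = ", "))
  g <- function(field) vapply(geom, `[[`, numeric(1), field)[classes]
  lo <- vapply(geom, function(x) x$hnr_range[1], numeric(1))[classes]
  hi <- vapply(geom, function(x) x$hnr_range[2], numeric(1))[classes]
  hm <- g("head_meanlog"); hs <- g("head_sdlog")
  lml <- g("len_meanlog"); ls <- g("len_sdlog")
  head <- neck <- len <- numeric(n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    k <- length(todo)
    h <- stats::rlnorm(k, hm[todo] + log_f_hd[todo], hs[todo])
    r <- stats::runif(k, lo[todo], hi[todo])
    l <- stats::rlnorm(k, lml[todo] + log_f_len[todo], ls[todo])
    nk <- h / r
    head[todo] <- h; neck[todo] <- nk; len[todo] <- l
    ok <- classify_spine(h, nk, l, thresholds) == classes[todo]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("rejection sampling failed to realize requested spine classes; ",
         "check class_geometry against the classifier thresholds")
  list(head = head, neck = neck, length = len)
}

# Volume model: spherical head plus cylindrical neck, with per-spine
# lognormal tracing noise and an optional case-level log shift (apparent-
# volume reliability factor), quantized to whole voxels.
spine_voxels <- function(head, neck, len, voxel_dims, noise_sdlog,
                         log_shift = 0) {
  vol <- pi / 6 * head^3 + pi / 4 * neck^2 * pmax(len - head, 0)
  vol <- vol * exp(log_shift + stats::rnorm(length(vol), 0, noise_sdlog))
  pmax(1L, as.integer(round(vol / prod(voxel_dims))))
}

# Realize measured spines as 5-point backbones: four equal arc-length steps
# with jittered directions (so curvilinear length equals the drawn length
# exactly), and diameter profile [1.15 neck, 1.05 neck, neck, head,
# 0.95 head] whose interior minimum / distal maximum recover neck and head
# exactly (necks never exceed heads by construction).
build_spine_geometry <- function(m) {
  n <- nrow(m)
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - u^2))
  base <- cbind(s * cos(phi), s * sin(phi), u)
  pts <- vector("list", 5)
  pos <- cbind(seq_len(n) * 2.0, rep(0, n), rep(0, n))
  pts[[1]] <- pos
  step <- m$length_um / 4
  for (k in 1:4) {
    d <- base + 0.15 * matrix(stats::rnorm(3 * n), n, 3)
    d <- d / sqrt(rowSums(d * d))
    pos <- pos + d * step
    pts[[k + 1]] <- pos
  }
  xs <- matrix(vapply(pts, function(P) P[, 1], numeric(n)), n, 5)
  ys <- matrix(vapply(pts, function(P) P[, 2], numeric(n)), n, 5)
  zs <- matrix(vapply(pts, function(P) P[, 3], numeric(n)), n, 5)
  nk <- m$neck_diameter_um
  hd <- m$head_diameter_um
  prof <- cbind(1.15 * nk, 1.05 * nk, nk, hd, 0.95 * hd)
  idx <- rep(seq_len(n), each = 5)
  pt <- rep(1:5, n)
  data.table::data.table(
    spine_row = idx,
    point_index = pt,
    x_um = xs[cbind(idx, pt)],
    y_um = ys[cbind(idx, pt)],
    z_um = zs[cbind(idx, pt)],
    diameter_um = prof[cbind(idx, pt)])
}

#' Generate one spine geometry of a requested morphological class
#'
#' Draws class-conditional measurements (rejection-sampled until the
#' measured spine classifies as requested) and realizes them as a 5-point
#' backbone with a diameter profile that reproduces the drawn head and neck
#' diameters exactly under \code{\link{measure_spine}}.
#'
#' @param spine_class one of thin, stubby, mushroom, filopodia.
#' @param seed integer seed.
#' @param voxel_dims voxel edge lengths (um).
#' @param geom per-class distributions; see
#'   \code{\link{class_geometry_defaults}}.
#' @param thresholds classification thresholds.
#' @return Spine geometry list (backbone, diameter_profile, voxel_count,
#'   voxel_dims) as consumed by \code{\link{measure_spine}}.
#' @export
generate_spine <- function(spine_class, seed = 1,
                           voxel_dims = c(0.05, 0.05, 0.10),
                           geom = class_geometry_defaults(),
                           thresholds = classifier_thresholds()) {
  stopifnot(length(spine_class) == 1)
  with_seed(seed, {
    m <- draw_class_measures(spine_class, geom = geom,
                             thresholds = thresholds)
    vox <- spine_voxels(m$head, m$neck, m$length, voxel_dims, 0.15)
    mt <- data.table::data.table(length_um = m$length,
                                 head_diameter_um = m$head,
                                 neck_diameter_um = m$neck)
    long <- build_spine_geometry(mt)
    list(backbone = as.matrix(long[, c("x_um", "y_um", "z_um")]),
         diameter_profile = long$diameter_um,
         voxel_count = vox,
         voxel_dims = voxel_dims)
  })
}

#' Generate a synthetic cohort
#'
#' Deterministically (per seed) simulates per-case covariates, per-neuron
#' dendritic segments with classified spines, and an episodic-memory
#' composite that is linear in pathology, sex and the case's realized mean
#' spine head diameter (with region-specific effect sizes).  Exactly
#' \code{n_missing} cases receive at least one missing value among NP score,
#' NFT burden and episodic memory.
#'
#' @param params a \code{\link{cohort_params}} object.
#' @param detail \code{"measures"} returns per-spine measurements drawn from
#'   the class-conditional distributions (exactly what measuring the
#'   constructed geometry yields); \code{"geometry"} additionally constructs
#'   and returns the per-point backbone table.
#' @return An object of class \code{"spine_cohort"}: list with
#'   \code{params}, \code{cases} (one row per case), \code{spines} (one row
#'   per spine), \code{segments} (one row per dendritic segment),
#'   \code{geometry} (long backbone table or NULL) and \code{truth} (the
#'   generating coefficients and per-case latent values).
#' @export
generate_cohort <- function(params = cohort_params(),
                            detail = c("measures", "geometry")) {
  stopifnot(inherits(params, "cohort_params"))
  detail <- match.arg(detail)
  p <- params
  n <- p$n_cases
  regions <- p$regions
  nr <- length(regions)

  # --- per-case covariates and latent factors (sub-stream per case) ------
  age <- sex <- np <- nft <- zeps <- numeric(n)
  f_hd <- f_len <- f_dens <- f_vol <- matrix(0, n, nr,
                                             dimnames = list(NULL, regions))
  for (i in seq_len(n)) {
    with_seed(substream_seed(p$seed, i, 0), {
      age[i] <- stats::rnorm(1, p$age_mean, p$age_sd)
      sex[i] <- stats::rbinom(1, 1, p$p_male)
      np[i] <- max(0, stats::rnorm(1, p$np_mean +
                                     sex[i] * p$sex_pathology_shift,
                                   p$np_sd))
      nft[i] <- max(0, stats::rnorm(1, p$nft_mean +
                                      sex[i] * p$sex_pathology_shift,
                                    p$nft_sd))
      zeps[i] <- stats::rnorm(1)
      for (rr in seq_len(nr)) {
        f_hd[i, rr] <- stats::rlnorm(1, 0, p$hd_case_sdlog)
        f_len[i, rr] <- stats::rlnorm(1, 0, p$len_case_sdlog)
        f_dens[i, rr] <- stats::rlnorm(1, 0, p$dens_case_sdlog)
        f_vol[i, rr] <- stats::rlnorm(1, 0, p$vol_case_sdlog)
      }
    })
  }

  # --- spines (sub-stream per case x region x neuron) --------------------
  acc <- vector("list", n * nr * p$neurons_per_case[2])
  n_seg <- n * nr * p$neurons_per_case[2]
  seg_case <- integer(n_seg); seg_region <- character(n_seg)
  seg_neuron <- integer(n_seg); seg_len <- numeric(n_seg)
  seg_nsp <- integer(n_seg)
  ai <- 0L
  si <- 0L
  for (i in seq_len(n)) {
    n_neurons <- with_seed(
      substream_seed(p$seed, i, 999999),
      sample(p$neurons_per_case[1]:p$neurons_per_case[2], 1))
    for (rr in seq_len(nr)) {
      lf_hd <- log(f_hd[i, rr])
      lf_len <- log(f_len[i, rr])
      for (j in seq_len(n_neurons)) {
        res <- with_seed(substream_seed(p$seed, i, rr * 1000 + j), {
          sl <- stats::runif(1, p$segment_length[1], p$segment_length[2])
          k <- stats::rpois(1, sl / 10 * p$spines_per_10um * f_dens[i, rr])
          if (k > 0) {
            cls <- sample(spine_classes(), k, replace = TRUE,
                          prob = p$class_mix)
            m <- draw_class_measures(cls, lf_hd, lf_len, p$class_geometry)
            vox <- spine_voxels(m$head, m$neck, m$length, p$voxel_dims,
                                p$volume_noise_sdlog,
                                log(f_vol[i, rr]))
            list(sl = sl, k = k, cls = cls, h = m$head, nk = m$neck,
                 ln = m$length, vox = vox)
          } else list(sl = sl, k = 0L)
        })
        si <- si + 1L
        seg_case[si] <- i; seg_region[si] <- regions[rr]
        seg_neuron[si] <- j; seg_len[si] <- res$sl; seg_nsp[si] <- res$k
        if (res$k > 0) {
          ai <- ai + 1L
          acc[[ai]] <- data.table::data.table(
            case_id = i, region = regions[rr], neuron_id = j,
            segment_id = 1L, spine_id = seq_len(res$k),
            spine_class = res$cls, length_um = res$ln,
            head_diameter_um = res$h, neck_diameter_um = res$nk,
            voxel_count = res$vox)
        }
      }
    }
  }
  spines <- data.table::rbindlist(acc[seq_len(ai)])
  voxvol <- prod(p$voxel_dims)
  spines[, "volume_um3" := spines$voxel_count * voxvol]
  segments <- data.table::data.table(
    case_id = seg_case[seq_len(si)], region = seg_region[seq_len(si)],
    neuron_id = seg_neuron[seq_len(si)], segment_id = 1L,
    length_um = seg_len[seq_len(si)], n_spines = seg_nsp[seq_len(si)])

  # --- episodic memory from realized mean head diameter ------------------
  hd_mean <- matrix(NA_real_, n, nr, dimnames = list(NULL, regions))
  agg <- spines[, list(m = mean(head_diameter_um)),
                by = c("case_id", "region")]
  hd_mean[cbind(agg$case_id, match(agg$region, regions))] <- agg$m
  hd_expect <- sum(p$class_mix *
                     vapply(p$class_geometry[spine_classes()],
                            function(g) exp(g$head_meanlog +
                                              g$head_sdlog^2 / 2),
                            numeric(1)))
  hd_mean[is.na(hd_mean)] <- hd_expect  # spineless case-region (rare)
  np_expect <- p$np_mean + p$p_male * p$sex_pathology_shift
  nft_expect <- p$nft_mean + p$p_male * p$sex_pathology_shift
  beta0 <- -(sum(p$beta_hd) * hd_expect + p$beta_np * np_expect +
               p$beta_nft * nft_expect + p$beta_sex * p$p_male)
  memory <- beta0 + drop(hd_mean %*% p$beta_hd) + p$beta_np * np +
    p$beta_nft * nft + p$beta_sex * sex + p$noise_sd * zeps

  cases <- data.table::data.table(
    case_id = seq_len(n), age = age, sex = as.integer(sex),
    np_score = np, nft_burden = nft, episodic_memory = memory)
  data.table::setattr(cases, "sex_coding", c(female = 0, male = 1))

  # --- missingness: MAR over NP / NFT / episodic memory ------------------
  miss_cols <- c("np_score", "nft_burden", "episodic_memory")
  if (p$n_missing > 0) {
    with_seed(substream_seed(p$seed, 0, 1), {
      which_cases <- sample(n, p$n_missing)
      for (i in which_cases) {
        pat <- stats::rbinom(3, 1, 0.5)
        if (!any(pat == 1)) pat[sample(3, 1)] <- 1L
        for (cidx in which(pat == 1))
          data.table::set(cases, i, miss_cols[cidx], NA_real_)
      }
    })
  }

  geometry <- NULL
  if (detail == "geometry") {
    geometry <- with_seed(substream_seed(p$seed, 0, 2), {
      long <- build_spine_geometry(spines)
      long[, "case_id" := spines$case_id[long$spine_row]]
      long[, "region" := spines$region[long$spine_row]]
      long[, "neuron_id" := spines$neuron_id[long$spine_row]]
      long[, "segment_id" := spines$segment_id[long$spine_row]]
      long[, "spine_id" := spines$spine_id[long$spine_row]]
      long[, "voxel_count" := spines$voxel_count[long$spine_row]]
      long[, "voxel_x_um" := p$voxel_dims[1]]
      long[, "voxel_y_um" := p$voxel_dims[2]]
      long[, "voxel_z_um" := p$voxel_dims[3]]
      long[, "spine_row" := NULL]
      data.table::setcolorder(long, c("case_id", "region", "neuron_id",
                                      "segment_id", "spine_id",
                                      "point_index", "x_um", "y_um", "z_um",
                                      "diameter_um", "voxel_count",
                                      "voxel_x_um", "voxel_y_um",
                                      "voxel_z_um"))
      long
    })
  }

  truth <- list(
    intercept = beta0,
    beta_hd = p$beta_hd, beta_np = p$beta_np, beta_nft = p$beta_nft,
    beta_sex = p$beta_sex, noise_sd = p$noise_sd,
    case_latent = data.table::data.table(
      case_id = seq_len(n), np_latent = np, nft_latent = nft,
      noise_z = zeps, memory_latent = memory),
    mean_head_diameter = hd_mean)

  structure(list(params = p, cases = cases, spines = spines,
                 segments = segments, geometry = geometry, truth = truth),
            class = "spine_cohort")
}

#' @export
print.spine_cohort <- function(x, ...) {
  cat("Synthetic spine cohort:", x$params$n_cases, "cases,",
      nrow(x$segments), "segments,", nrow(x$spines), "spines;",
      "regions:", paste(x$params$regions, collapse = ", "), "\n")
  invisible(x)
}
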